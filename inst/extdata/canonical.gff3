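##gff-version 3
chr1	.	gene	101	460	.	+	.	ID=gA
chr1	.	mRNA	101	460	.	+	.	ID=gA.t1;Parent=gA
chr1	.	exon	101	220	.	+	.	Parent=gA.t1
chr1	.	exon	301	460	.	+	.	Parent=gA.t1
chr1	.	CDS	121	220	.	+	0	Parent=gA.t1
chr1	.	CDS	301	400	.	+	2	Parent=gA.t1
chr1	.	five_prime_UTR	101	120	.	+	.	Parent=gA.t1
chr1	.	three_prime_UTR	401	460	.	+	.	Parent=gA.t1
chr1	.	mRNA	101	430	.	+	.	ID=gA.t2;Parent=gA
chr1	.	exon	101	220	.	+	.	Parent=gA.t2
chr1	.	exon	301	430	.	+	.	Parent=gA.t2
chr1	.	CDS	121	220	.	+	0	Parent=gA.t2
chr1	.	CDS	301	400	.	+	2	Parent=gA.t2
chr2	.	gene	51	350	.	-	.	ID=gB
chr2	.	mRNA	51	350	.	-	.	ID=gB.t1;Parent=gB
chr2	.	exon	51	170	.	-	.	Parent=gB.t1
chr2	.	exon	231	350	.	-	.	Parent=gB.t1
chr2	.	CDS	51	170	.	-	0	Parent=gB.t1
chr2	.	CDS	231	350	.	-	0	Parent=gB.t1
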