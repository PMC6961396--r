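test_that("summary metrics match direct computation on a tiny gene set", {
  genome <- c(s1 = paste0("ATGGCC", strrep("A", 94), "GGGTTT",
                          strrep("A", 100)))
  ## one gene: 2 coding exons (1-6, 101-106), supported intron 7-100
  m <- gene_models(simple_gene("g1", "s1", "+", c(1, 101), c(6, 106)))
  idx <- idx_row("s1", 7, 100)
  s <- geneset_summary(m, genome, idx)
  expect_equal(s$n_genes, 1L)
  expect_equal(s$avg_coding_length, 12)
  expect_equal(s$coding_exons_per_transcript, 2)
  ## CDS = ATGGCC GGGTTT -> 7 G/C of 12
  expect_equal(s$gc_content_coding, 7 / 12)
  expect_equal(s$fraction_single_exon_genes, 0)
  expect_equal(s$n_introns_cds, 1L)
  expect_equal(s$fraction_supported_introns, 1)
  expect_equal(s$avg_intron_length, 94)
  ## empty support index -> fraction 0
  s0 <- geneset_summary(m, genome, idx[0, ])
  expect_equal(s0$fraction_supported_introns, 0)
})

test_that("UTR-only introns are excluded from CDS intron counts", {
  genome <- c(s1 = strrep("ACGT", 200))
  ## exon1 1-60 coding; exon2 101-160 coding to 130 with UTR tail;
  ## exon3 201-260 pure UTR -> intron 161-200 flanks a non-coding exon
  rows <- tibble(
    gene_id = "g1", transcript_id = "g1.t1",
    type = c("exon", "CDS", "exon", "CDS", "exon"),
    scaffold = "s1", strand = "+",
    start = c(1, 1, 101, 101, 201),
    end = c(60, 60, 160, 130, 260)
  )
  m <- gene_models(rows)
  s <- geneset_summary(m, genome, idx_row("s1", 61, 100))
  expect_equal(s$n_introns_cds, 1L)           # only 61-100
  expect_equal(s$fraction_supported_introns, 1)
})

test_that("isoform distribution counts genes by transcript number", {
  m <- gene_models(bind_rows(
    simple_gene("g1", "s1", "+", 1, 60),
    simple_gene("g2", "s1", "+", 201, 260),
    simple_gene("g3", "s1", "+", 401, 460),
    simple_gene("g3", "s1", "+", 401, 430, tx = "g3.t2")
  ))
  d <- isoform_distribution(m)
  expect_equal(d$n_genes[d$n_isoforms == 1], 2L)
  expect_equal(d$n_genes[d$n_isoforms == 2], 1L)
  expect_equal(sum(d$n_genes), 3L)
  expect_equal(nrow(isoform_distribution(m[0, ])), 0)
})

test_that("metrics equal a brute-force recomputation on the fixture", {
  fx <- default_fixture()
  s <- geneset_summary(fx$new, fx$genome, fx$idx)
  ## brute force from first principles
  cds <- fx$new[fx$new$type == "CDS", ]
  iso_len <- cds %>%
    group_by(gene_id, transcript_id) %>%
    summarise(len = sum(end - start + 1), .groups = "drop") %>%
    group_by(gene_id) %>%
    summarise(len = max(len), .groups = "drop")
  expect_equal(s$avg_coding_length, mean(iso_len$len), tolerance = 1e-9)
  n_cds_exons <- cds %>% count(transcript_id)
  expect_equal(s$coding_exons_per_transcript, mean(n_cds_exons$n),
               tolerance = 1e-9)
  expect_equal(s$n_genes, dplyr::n_distinct(cds$gene_id))
  ## isoform histogram matches the planted two-isoform count
  hist <- attr(s, "isoform_histogram")
  expect_equal(hist$n_genes[hist$n_isoforms == 2],
               fx$manifest$config$n_two_isoform)
})

test_that("adding support-index keys never lowers the supported fraction", {
  fx <- default_fixture()
  s_all <- geneset_summary(fx$new, fx$genome, fx$idx)
  half <- fx$idx[seq_len(nrow(fx$idx) %/% 2), ]
  s_half <- geneset_summary(fx$new, fx$genome, half)
  expect_lte(s_half$fraction_supported_introns,
             s_all$fraction_supported_introns)
})

test_that("premature stops are found, including codons split by introns", {
  ## clean CDS: ATG AAA TGA -> no flag
  genome <- c(s1 = paste0("ATGAAATGA", strrep("C", 50)))
  clean <- gene_models(simple_gene("ok", "s1", "+", 1, 9))
  expect_equal(nrow(find_spliced_inframe_stops(clean, genome)), 0)

  ## premature stop inside one exon: ATG TAA ... TGA
  genome2 <- c(s1 = paste0("ATGTAAAAATGA", strrep("C", 50)))
  bad <- gene_models(simple_gene("g1", "s1", "+", 1, 12))
  hit <- find_spliced_inframe_stops(bad, genome2)
  expect_equal(hit$issue, "premature_stop")
  expect_equal(hit$codon_index, 2L)
  expect_equal(hit$stop_codon, "TAA")
  expect_false(hit$split_across_intron)

  ## stop codon straddling an intron: exon1 ends mid-codon (T|AA)
  ## spliced CDS = ATGT + AATGA = ATG TAA TGA
  genome3 <- c(s1 = paste0("ATGT", strrep("G", 40), "AATGA", strrep("C", 20)))
  rows <- tibble(
    gene_id = "g2", transcript_id = "g2.t1",
    type = c("exon", "CDS", "exon", "CDS"),
    scaffold = "s1", strand = "+",
    start = c(1, 1, 45, 45), end = c(4, 4, 49, 49)
  )
  split_gene <- gene_models(rows)
  hit2 <- find_spliced_inframe_stops(split_gene, genome3)
  expect_equal(hit2$codon_index, 2L)
  expect_true(hit2$split_across_intron)

  ## CDS length not a multiple of three is flagged separately
  frame <- gene_models(simple_gene("g3", "s1", "+", 1, 10))
  hit3 <- find_spliced_inframe_stops(frame, genome2)
  expect_equal(hit3$issue, "cds_length_not_multiple_of_3")

  ## the synthetic fixture translates cleanly end to end
  fx <- default_fixture()
  st <- find_spliced_inframe_stops(bind_rows(fx$old, fx$new), fx$genome)
  expect_equal(nrow(st), 0)
})
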