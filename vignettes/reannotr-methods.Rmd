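---
title: "Evidence-based gene set merging and comparison: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-based gene set merging and comparison: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reannotr)
library(dplyr)
```

## Scope

`reannotr` implements the computational core of an evidence-based genome
reannotation: a community gene set ("old", e.g. a previous official gene
set) is confronted with a fresh RNA-Seq-informed prediction ("new"), and
the package decides, gene by gene, which annotation to trust, classifies
the structural changes between the two versions, quantifies annotation
quality, and — because reliable UTR models are one of the main gains of
such a reannotation — predicts microRNA seed sites in 3'UTRs and tests
whether miRNA target repertoires are conserved between two species.

All user-facing functions take plain tibbles and return tibbles (or small
result objects with `tidy()`, `glance()` and `autoplot()` methods), so the
whole pipeline composes with dplyr verbs.

## Coordinates and the gene-model table

Gene structures are held in a flat tibble with one row per feature
segment (`exon`, `CDS`, `five_prime_UTR`, `three_prime_UTR`) and columns
`gene_id`, `transcript_id`, `type`, `scaffold`, `strand`, `start`, `end`.
Coordinates are **1-based closed** throughout, the GFF3 and IRanges
convention; an intron spanning `start..end` has length `end - start + 1`.
We deliberately use one coordinate convention end to end (rather than a
0-based internal convention with conversion at the I/O boundary) because
every interval operation in the package is delegated to IRanges /
GenomicRanges, which use 1-based closed coordinates natively; a second
convention would buy nothing and create a conversion seam.

Minus-strand transcripts store exons in genomic order; operations that
need transcript orientation (splicing, translation, UTR extraction)
reverse-complement at the point of use. Transcripts without annotated
UTRs are legal — UTRs exist only where transcript evidence supported
them.

GFF3 is read with `rtracklayer::readGFF()` and written by the package
itself in a canonical form (fixed record order, recomputed CDS phases),
which makes `write(read(f))` byte-stable — a property the test suite
pins on committed fixtures.

## Intron evidence

Spliced-alignment records pass two stages of filtering, with all
thresholds collected in `filter_config()`:

* **Alignment prefilters.** A hit needs at least 92% identity; paired
  reads must have their mate on the same scaffold within 200 kbp and in
  proper orientation; and hits whose best and second-best alignment
  identities are within 4 percentage points of each other are discarded
  as ambiguous (they typically arise from pseudogenes or recent
  paralogs). The margin is applied to identity fractions as an absolute
  difference (0.95 vs 0.92 is ambiguous, difference 0.03 ≤ 0.04).
* **Candidate restrictions.** Each alignment gap becomes an intron
  candidate keyed by its exact (scaffold, start, end); the *multiplicity*
  of a candidate is the number of reads crossing that identical
  exon–exon boundary. A candidate survives iff its length is within
  32..350,000 bp, its splice-site dinucleotides are accepted (GT-AG by
  default; GC-AG and AT-AC can be enabled), and the summed multiplicity
  of *contradicting* candidates is at most 9 times its own multiplicity,
  with the boundary (exactly 9×) passing.

Two points in this scheme are genuine design choices rather than settled
convention, and we state them explicitly so they can be revisited:

* *Contradiction* is defined as same-scaffold, overlapping,
  non-identical intron candidates, with the count being the sum of their
  multiplicities. Exon-coverage evidence is not counted — the
  contradiction ratio is computable from intron evidence alone, which
  keeps the filter self-contained. If coverage-derived hints were
  available, the ratio could be extended to them.
* When alignments are unstranded, candidate strand is inferred from the
  splice sites: `GT..AG` on the plus strand implies `+`, `CT..AC`
  implies `-`. Candidates matching neither pattern keep strand unknown
  and are matched strand-insensitively downstream (under the default
  accepted pairs they are rejected by the splice-site filter anyway).
* Evidence from several libraries is combined by summing multiplicities
  of identical keys (`merge_candidates()`), treating libraries as
  independent read sets.

The surviving candidates form the *support index*. A transcript intron
counts as supported only if it matches an index entry at the exact
coordinates — an off-by-one intron is unsupported by design, since the
whole point of the multiplicity definition is positional identity.

## Merging an old gene set with a new prediction

The merge rule protects curated knowledge against a better-on-average
but not uniformly better prediction. For an old gene $g$ with
overlapping new genes $G$ (CDS overlap, same scaffold and strand), $g$ is
**specifically supported** iff

1. $g$ has at least one supported intron that no gene in $G$ has, and
2. every supported intron of the genes in $G$ is also an intron of $g$,

with intron sets taken as unions over isoforms. Specifically supported
old genes are kept and *all* their overlapping new genes are discarded;
otherwise the old gene is dropped in favour of the prediction. Old genes
overlapping nothing are kept when rescue evidence exists: a homolog in
another species, an annotated GO function, or RNA-Seq coverage with
FPKM ≥ 0.01 (inclusive). FPKM values are inputs here; the package does
not quantify expression.

Ambiguities the rule itself does not settle, and how we resolved them:

* Overlap for building $G$ is CDS-level on the same strand (the same
  criterion used for event detection); an old gene overlapped only on
  the opposite strand takes the rescue path.
* Chained displacement — a new gene overlapping two old genes, only one
  of them specific — is resolved old-gene-by-old-gene in coordinate
  order, and a new gene displaced by *any* specific old gene is removed
  globally. This is deterministic and independent of input row order
  (a property the tests check by shuffling).

`merge_gene_sets()` returns the merged set plus a per-gene decision log
(`kept_specific` / `kept_rescued` / `dropped`, with displaced new gene
ids), which `tidy()` exposes as a tibble.

## Structural events and gene correspondence

A **join** is a new gene whose CDS overlaps the CDSs of two or more old
genes on the same strand; a **split** is the mirror image. Events are
counted once per anchor gene (a new gene joining three old genes is one
join with three partners). A join is *supported* when a supported intron
of the anchor spans the inter-partner gap — i.e. the intron interval
covers the region between the CDS end of one partner and the CDS start
of the next, for at least one adjacent partner pair; split support uses
the old gene's bridging intron the same way. Swapping the roles of the
two gene sets swaps the join and split lists exactly, which the test
suite uses as an invariant.

Gene correspondence compares proteins (longest isoform, standard genetic
code, terminal stop removed, internal stops rendered as `X` and
flagged). Because the underlying study named no aligner, we fix a
deterministic one: global alignment with free end gaps, match +1,
mismatch 0, gap −1 (via `Biostrings::pairwiseAlignment(type =
"overlap")`). Identity is identical columns over aligned (both-non-gap)
columns; coverage is aligned columns over the length of the **old**
protein, the reference in a lift-over comparison. A new gene is
`identical` to an overlapping old gene on exact protein equality,
`near_identical` when the best overlapping pair reaches both identity
≥ 0.95 and coverage ≥ 0.95 (boundary inclusive).

What "new" and "lost" should mean is less obvious than it looks. A
threshold-based reading (no overlapping old gene *above the thresholds*)
silently absorbs the products of joins and splits: each child of a split
covers only half of the old protein, fails coverage, and would be
counted as a brand-new gene. For genome-wide bookkeeping that may be
acceptable, but it conflates structural rearrangement with genuine
novelty. `classify_correspondence()` therefore defaults to an
overlap-based novelty rule — `new` means no CDS-same-strand overlap with
any old gene at all, `lost` means an old gene overlapped by no new gene,
and sub-threshold overlapping new genes get the explicit class
`restructured` — and offers `novelty = "threshold"` for the
threshold-based tally. Under the default rule the simulator's planted
novel and lost genes are recovered exactly, with join/split products
kept out of both bins.

## Annotation metrics

`geneset_summary()` reports gene counts, average coding length (longest
isoform per gene; isoform handling is unspecified in the usual summary
tables, so the choice is stated here), coding exons per transcript, GC
content of the coding sequence, the fraction of single-exon genes,
CDS-intron counts, the fraction of CDS introns present in the support
index, mean intron length and the isoform histogram. An intron counts as
a *CDS intron* iff both flanking exons contain coding bases, which
excludes UTR-only introns; because summary tables in the literature are
ambiguous about isoform handling for intron counts, both the
all-isoform union and the longest-isoform count are reported. GC content
is reported as a fraction — published tables sometimes print a fraction
with a percent sign attached (e.g. "0.4625%"), a dimensional
inconsistency we do not reproduce.

`find_spliced_inframe_stops()` is the validator for a known gene-finder
artefact: transcripts whose spliced CDS contains a premature stop codon,
annotated by whether the offending codon straddles an intron boundary.
Transcripts whose spliced CDS length is not a multiple of three are
flagged separately rather than silently trimmed.

## miRNA seed sites and target conservation

Site prediction is purely seed-based (no thermodynamics, no context
scores). For a mature miRNA the three site types, written 5'→3' in mRNA
sense, are: `8mer` = reverse complement of positions 2–8 followed by A;
`7m8` = reverse complement of positions 2–8; `7A1` = reverse complement
of positions 2–7 followed by A. Every occurrence in a 3'UTR is reported
once with the strongest applicable type (an 8mer match is not also a
7m8 and 7A1), overlapping occurrences are all reported, 6mer sites are
deliberately excluded, and matching is done in RNA space with U/T
interchangeable on input. Target pairs are deduplicated at the
(mature miRNA, gene) level across isoforms.

For two species with miRNA homology and gene orthology maps (both may be
many-to-many; all combinations of homologous pairs are evaluated), the
number of conserved interactions for a homologous miRNA pair is the
number of orthologous gene pairs targeted on both sides. Significance
comes from a permutation null: holding species A's targets fixed,
species B's target set is resampled (equal size, without replacement)
from the orthologous-gene universe `n_perm` times (default 1000), and
the p-value is $(r+1)/(N+1)$ where $r$ counts permutations reaching the
observed conserved count — the add-one estimator avoids zero p-values.
Which side is resampled is not dictated by the method; resampling B
while holding A fixed is the default, with `resample = "A"` for the
symmetric variant. No significance cutoff is hard-coded; the analysis
returns p-values and leaves the threshold to the caller.

## The simulator and what passing tests mean

`generate_fixture()` produces a complete synthetic study — genome, old
and new gene sets, intron hints, rescue table, two-species miRNA
scenario, and a ground-truth manifest — as a pure function of its seed.
Loci are built top-down from clean open reading frames (ATG, sense
codons, TAA) with GT-AG introns, so planted genes translate without
premature stops; exon boundaries fall on codon boundaries. Intergenic
spacers guarantee that non-planted genes never overlap, so spurious
events cannot arise by accident. Planted relations cover identical and
near-identical replacements (the near-identical construction mutates
~2% of codons in a middle exon, placing each variant inside the other
gene's intron, so identity stays above the 95% boundary at full
coverage), specifically supported old genes, joins and splits with and
without supported bridging introns, novel and lost genes, and a
boundary-stress set of evidence noise in three disjoint categories
matching the three candidate filters — including retained boundary cases
at length 32, length 350,000 and contradiction exactly 9×.

The default configuration is the study-scale fixture used by the test
suite and the acceptance script: 200 old genes — 20 planted joins (12
supported), 15 splits (2 supported), 10 specifically supported loci, 8
lost genes (4 rescued), 17 near-identical and 110 identical
replacements — plus 10 novel genes, on 5 scaffolds with 40% of loci on
the minus strand, and a 10-family miRNA scenario over a 50-pair ortholog
universe in which 3 families share 4 of 9 targets between species (the
shape of the classic conserved-family examples). These sizes keep every
end-to-end check well under a minute while still exercising both
strands, multi-partner events and every filter boundary. Default UTRs
are 150 nt so that several families can target one UTR without site
collisions.

The simulator emulates the *statistical structure* of a reannotation
problem, not real genomes: no repeats, no codon-usage bias, no
alignment errors beyond the planted noise categories, exact splice
sites, and noise-free rescue evidence. Passing the recovery tests
therefore shows that the implementation computes its definitions
correctly — it does not show that the thresholds are optimal for any
particular genome.

## Numerical choices and degenerate inputs

* All boundary comparisons are inclusive where the rules say "at
  least"/"at most": identity ≥ 0.92, FPKM ≥ 0.01, length in
  [32, 350000], contradiction ≤ 9×, identity/coverage ≥ 0.95.
* Alignment tie-breaks are delegated to `pairwiseAlignment`, which is
  deterministic; pairs with no aligned columns score identity 0 and
  coverage 0.
* Best-pair selection in correspondence sorts by identity, then
  coverage, then coordinate order, so ties are deterministic.
* Empty inputs (no candidates, empty support index, empty gene sets,
  empty UTRs) return empty tibbles rather than errors; genuinely
  malformed inputs (negative FPKM, CDS outside exons, duplicate ids,
  out-of-bounds coordinates) fail loudly with the offending record
  named.
* The permutation test draws with `sample.int()` under a locally scoped
  seed, so results are reproducible without disturbing the caller's RNG
  stream.

## Known limitations

* The contradiction ratio uses intron evidence only; a pipeline with
  exon-coverage hints could count those as contradictions too.
* Correspondence uses one protein per gene (longest isoform); a
  transcript-level comparison would detect isoform-specific changes the
  gene-level view misses.
* `supported` on a join/split event refers to the bridging intron only;
  it does not grade partial support of the anchor's other introns.
* The miRNA module scores seed complementarity only — by design it will
  not reproduce predictions of thermodynamic methods, and site
  accessibility is ignored.
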