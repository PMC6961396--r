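let7 <- "UGAGGUAGUAGGUUGUAUAGUU"

test_that("seed-site strings are the documented reverse complements", {
  s <- seed_site_strings(let7)
  expect_equal(s[["8mer"]], "CUACCUCA")
  expect_equal(s[["7m8"]], "CUACCUC")
  expect_equal(s[["7A1"]], "UACCUCA")
  expect_equal(seed_site_strings("AAAAAAAA")[["8mer"]], "UUUUUUUA")
  expect_error(seed_site_strings("AAAAAAA"), "at least 8")
  ## DNA input is accepted
  expect_equal(seed_site_strings(chartr("U", "T", let7))[["8mer"]], "CUACCUCA")
})

test_that("UTR scanning reports the strongest type once per occurrence", {
  hits <- scan_utr("AAACUACCUCAAAA", let7)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$position, 4L)
  expect_equal(hits$site_type, "8mer")
  ## a G at the t1 position blocks the 8mer, leaving a 7m8
  hits2 <- scan_utr("AAACUACCUCGAAA", let7)
  expect_equal(hits2$site_type, "7m8")
  expect_equal(hits2$position, 4L)
  expect_equal(nrow(scan_utr("", let7)), 0)
  ## T/U interchangeable on input
  expect_equal(scan_utr("AAACTACCTCAAAA", let7), scan_utr("AAACUACCUCAAAA", let7))
})

test_that("scanner equals the brute-force substring oracle on random draws", {
  set.seed(77)
  alphabet <- c("A", "C", "G", "U")
  for (i in 1:300) {
    mature <- paste(sample(alphabet, 21, TRUE), collapse = "")
    utr <- paste(sample(alphabet, sample(20:60, 1), TRUE), collapse = "")
    ## spike in a site half the time so matches are not vanishingly rare
    if (i %% 2 == 0) {
      s <- seed_site_strings(mature)[[sample(3, 1)]]
      p <- sample(nchar(utr) - nchar(s), 1)
      substr(utr, p, p + nchar(s) - 1L) <- s
    }
    expect_equal(scan_utr(utr, mature), oracle_scan_utr(utr, mature),
                 label = sprintf("draw %d", i))
  }
})

test_that("3'UTRs are extracted in transcript orientation and transcribed", {
  ## '+' strand: 10 bases after the stop codon, same exon
  genome <- c(s1 = paste0("ATGAAATAA", "GGGTTTCCCA", strrep("A", 30)))
  m <- gene_models(simple_gene("g1", "s1", "+", 1, 19, utr3 = 10))
  u <- extract_3utrs(m, genome)
  expect_equal(u[["g1.t1"]], "GGGUUUCCCA")

  ## CDS ending at the transcript end -> UTR omitted
  m2 <- gene_models(simple_gene("g2", "s1", "+", 1, 9))
  expect_length(extract_3utrs(m2, genome), 0)

  ## '-' strand two-exon UTR: spliced then reverse-complemented
  ## gene on '-': CDS in exon2 (right), UTR = exon1 tail + exon2 head
  g <- "TTTTGGAACCCCCCCCCCATTTCATAAAAA"
  ##    exon1: 1-10 (UTR part 1-8 + CDS tail 9-10? keep simple below)
  genome3 <- c(s2 = g)
  rows <- tibble(
    gene_id = "g3", transcript_id = "g3.t1",
    type = c("exon", "exon", "CDS"),
    scaffold = "s2", strand = "-",
    start = c(1, 21, 21), end = c(10, 30, 26)
  )
  m3 <- gene_models(rows)
  ## transcript: revcomp(21..30) then revcomp(1..10); CDS ends at base 21
  ## (genomic), so UTR = revcomp(1..10) = revcomp("TTTTGGAACC")
  u3 <- extract_3utrs(m3, genome3)
  expect_equal(u3[["g3.t1"]], chartr("ACGT", "UGCA",
                                     paste(rev(strsplit("TTTTGGAACC", "")[[1]]),
                                           collapse = "")))
  ## transcripts without CDS are skipped with a warning
  rows_nocds <- rows[rows$type == "exon", ]
  expect_warning(extract_3utrs(gene_models(rows_nocds), genome3), "without CDS")
})

test_that("target pairs deduplicate isoforms at gene level", {
  utrs <- c(
    "g1.t1" = "AAACUACCUCAAAA",
    "g1.t2" = "GGGCUACCUCAGGG",
    "g2.t1" = "GGGGGGGGGGGGGG"
  )
  pairs <- predict_target_pairs(c(let7a = let7), utrs)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$gene_id, "g1")
  expect_equal(pairs$n_8mer, 2L)
  expect_equal(pairs$n_sites, 2L)
  ## no sites anywhere
  none <- predict_target_pairs(c(let7a = let7), utrs["g2.t1"])
  expect_equal(nrow(none), 0)
})

test_that("conserved counts enumerate orthologous pairs, many-to-many", {
  pairs_A <- tibble(mirna = "mA", gene_id = c("g1", "g2"))
  pairs_B <- tibble(mirna = "mB", gene_id = c("g1p", "g2p"))
  hom <- tibble(mirna_A = "mA", mirna_B = "mB")
  orth <- tibble(gene_A = c("g1", "g2"), gene_B = c("g1p", "g2p"))
  cc <- conserved_target_counts(pairs_A, pairs_B, hom, orth)
  expect_equal(cc$n_conserved, 2L)
  expect_equal(cc$n_A_only, 0L)
  ## empty orthology
  cc0 <- conserved_target_counts(pairs_A, pairs_B, hom, orth[0, ])
  expect_equal(cc0$n_conserved, 0L)
  expect_equal(cc0$n_A_only, 2L)
  ## one-to-two orthology counts ortholog pairs, not genes
  orth2 <- tibble(gene_A = c("g1", "g1"), gene_B = c("g1p", "g2p"))
  cc2 <- conserved_target_counts(
    tibble(mirna = "mA", gene_id = "g1"),
    tibble(mirna = "mB", gene_id = c("g1p", "g2p")),
    hom, orth2
  )
  expect_equal(cc2$n_conserved, 2L)
})

test_that("permutation p-values match enumeration and are reproducible", {
  orth <- tibble(gene_A = paste0("g", 1:4), gene_B = paste0("g", 1:4))
  tA <- c("g1", "g2"); tB <- c("g1", "g2")
  ## exact: P(resampled pair of 4 equals {g1,g2}) = 1/C(4,2) = 1/6
  pt <- permutation_pvalue(tA, tB, orth, n_perm = 2000, seed = 5)
  expect_equal(pt$observed, 2L)
  expect_lt(abs(pt$p_value - 1 / 6), 3 * sqrt((1 / 6) * (5 / 6) / 2000) + 1e-3)
  ## observed 0 -> p = 1
  pt0 <- permutation_pvalue("g1", character(0), orth, n_perm = 100, seed = 1)
  expect_equal(pt0$p_value, 1)
  ## determinism under a fixed seed
  p1 <- permutation_pvalue(tA, tB, orth, n_perm = 500, seed = 42)$p_value
  p2 <- permutation_pvalue(tA, tB, orth, n_perm = 500, seed = 42)$p_value
  expect_identical(p1, p2)
  ## oversized sample errors
  expect_error(
    permutation_pvalue(tA, paste0("g", 1:5), orth, n_perm = 10, seed = 1),
    "universe"
  )
})

test_that("planted conserved families score smaller p than unplanted ones", {
  fx <- default_fixture()
  d <- fx$dir
  pA <- predict_target_pairs(read_rna_fasta(file.path(d, "mirna_A.fa")),
                             read_rna_fasta(file.path(d, "utrs_A.fa")))
  pB <- predict_target_pairs(read_rna_fasta(file.path(d, "mirna_B.fa")),
                             read_rna_fasta(file.path(d, "utrs_B.fa")))
  hom <- readr::read_tsv(file.path(d, "mirna_homology.tsv"),
                         show_col_types = FALSE)
  orth <- readr::read_tsv(file.path(d, "orthology.tsv"),
                          show_col_types = FALSE)
  cons <- conservation_analysis(pA, pB, hom, orth, n_perm = 300, seed = 11)
  fams <- fx$manifest$mirna$families
  planted <- cons$p_value[cons$mirna_A %in% fams$mirna_A[fams$conserved]]
  unplanted <- cons$p_value[cons$mirna_A %in% fams$mirna_A[!fams$conserved]]
  expect_true(max(planted) < min(unplanted))
  expect_s3_class(ggplot2::autoplot(cons), "ggplot")
})
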