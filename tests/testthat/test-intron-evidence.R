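aln_row <- function(read_id = "r1", scaffold = "s1", strand = "+",
                    blocks = "1-100,601-700", identity = 0.99,
                    best_identity = identity, second_best_identity = NA,
                    mate_scaffold = NA, mate_distance = NA,
                    properly_oriented = NA) {
  tibble(
    read_id = read_id, scaffold = scaffold, strand = strand, blocks = blocks,
    identity = identity, best_identity = best_identity,
    second_best_identity = as.numeric(second_best_identity),
    mate_scaffold = as.character(mate_scaffold),
    mate_distance = as.numeric(mate_distance),
    properly_oriented = as.logical(properly_oriented)
  )
}

test_that("alignment prefilters apply identity, mate and ambiguity rules", {
  aln <- bind_rows(
    aln_row("below_identity", identity = 0.91),
    aln_row("at_identity", identity = 0.92),
    aln_row("far_mate", mate_scaffold = "s1", mate_distance = 250000,
            properly_oriented = TRUE),
    aln_row("ok_mate", mate_scaffold = "s1", mate_distance = 200000,
            properly_oriented = TRUE),
    aln_row("wrong_orientation", mate_scaffold = "s1", mate_distance = 100,
            properly_oriented = FALSE),
    aln_row("other_scaffold_mate", mate_scaffold = "s2", mate_distance = 100,
            properly_oriented = TRUE),
    aln_row("ambiguous", best_identity = 0.95, second_best_identity = 0.92),
    aln_row("at_margin", best_identity = 0.99, second_best_identity = 0.95),
    aln_row("unique_clear", best_identity = 0.99, second_best_identity = 0.94)
  )
  kept <- filter_alignments(aln)$read_id
  expect_setequal(kept, c("at_identity", "ok_mate", "unique_clear"))
})

test_that("candidate compilation counts identical exon-exon boundaries", {
  genome <- plain_genome(1000, plant = list(
    list(101, "GT"), list(599, "AG"),   # gap 101-600
    list(102, "T")                      # keep 102 = T for the shifted gap
  ))
  ## two reads with the identical gap, one shifted by one base
  aln <- bind_rows(
    aln_row("r1", blocks = "1-100,601-700"),
    aln_row("r2", blocks = "1-100,601-700"),
    aln_row("r3", blocks = "1-101,601-700")
  )
  cands <- compile_candidates(aln, genome)
  expect_equal(nrow(cands), 2)
  c1 <- cands[cands$start == 101, ]
  expect_equal(c1$multiplicity, 2L)
  expect_equal(c(c1$donor, c1$acceptor), c("GT", "AG"))
  expect_equal(c1$strand, "+")
  ## read conservation: summed multiplicity equals number of spliced records
  expect_equal(sum(cands$multiplicity), 3L)
  ## minus-strand sites are inferred: CT..AC on the plus strand
  genome2 <- plain_genome(1000, plant = list(list(101, "CT"), list(599, "AC")))
  c2 <- compile_candidates(aln_row("r", blocks = "1-100,601-700"), genome2)
  expect_equal(c2$strand, "-")
  expect_equal(c(c2$donor, c2$acceptor), c("GT", "AG"))
  ## gap outside genome bounds is an error naming the record
  expect_error(compile_candidates(aln_row("oob", blocks = "1-100,2001-2100"),
                                  genome), "oob")
})

test_that("contradiction counts sum overlapping non-identical multiplicities", {
  g <- plain_genome(2000, plant = list(
    list(11, "GT"), list(59, "AG"),
    list(31, "GT"),
    list(1001, "GT"), list(1059, "AG")
  ))
  cands <- bind_rows(
    idx_row("s1", 11, 60, mult = 10),     # overlapped by the next
    idx_row("s1", 31, 60, mult = 90),     # shares the acceptor
    idx_row("s1", 1001, 1060, mult = 7)   # isolated
  ) %>% select(-donor, -acceptor, -key)
  cc <- contradiction_counts(reannotr:::annotate_candidates(cands, g))
  expect_equal(cc$contradiction[cc$start == 11], 90L)
  expect_equal(cc$contradiction[cc$start == 31], 10L)
  expect_equal(cc$contradiction[cc$start == 1001], 0L)
})

test_that("candidate filter enforces length, splice sites and the 9x rule", {
  ## genome with planted candidates: len 31, len 32, noncanonical, 9x pair
  g <- plain_genome(3000, plant = list(
    list(11, "GT"), list(40, "AG"),     # len 31
    list(101, "GT"), list(131, "AG"),   # len 32
    list(201, "CC"), list(259, "GG"),   # noncanonical, len 60
    list(301, "GT"), list(359, "AG"),   # host, mult varies
    list(321, "GT")                     # child shares acceptor at 359
  ))
  base <- bind_rows(
    tibble(scaffold = "s1", start = 11L, end = 41L, strand = NA, multiplicity = 5L),
    tibble(scaffold = "s1", start = 101L, end = 132L, strand = NA, multiplicity = 5L),
    tibble(scaffold = "s1", start = 201L, end = 260L, strand = NA, multiplicity = 5L),
    tibble(scaffold = "s1", start = 301L, end = 360L, strand = NA, multiplicity = 90L),
    tibble(scaffold = "s1", start = 321L, end = 360L, strand = NA, multiplicity = 10L)
  )
  cands <- reannotr:::annotate_candidates(base, g)
  kept <- filter_candidates(cands)
  expect_false(any(kept$start == 11))        # length 31 < 32
  expect_true(any(kept$start == 101))        # length exactly 32
  expect_false(any(kept$start == 201))       # CC..GG rejected
  expect_true(any(kept$start == 321))        # 90 <= 9 x 10, boundary passes
  expect_true(any(kept$start == 301))        # host: 10 <= 9 x 90
  ## push the contradiction to 91: child must now fail
  base$multiplicity[4] <- 91L
  kept2 <- filter_candidates(reannotr:::annotate_candidates(base, g))
  expect_false(any(kept2$start == 321))
})

test_that("filtering is monotone in the configuration", {
  fx <- default_fixture()
  base_cfg <- filter_config()
  kept_base <- filter_candidates(fx$cands, base_cfg)$key
  wider <- filter_config(accepted_splice_pairs = c("GT-AG", "GC-AG", "CC-GG"),
                         contradiction_factor = 20)
  kept_wider <- filter_candidates(fx$cands, wider)$key
  expect_true(all(kept_base %in% kept_wider))
})

test_that("candidate filter matches a one-at-a-time brute-force evaluation", {
  fx <- default_fixture()
  cands <- head(arrange(fx$cands, scaffold, start), 50)
  cfg <- filter_config()
  kept <- filter_candidates(cands, cfg)$key
  brute <- character(0)
  for (i in seq_len(nrow(cands))) {
    c <- cands[i, ]
    len <- c$end - c$start + 1L
    others <- cands[-i, ]
    contra <- sum(others$multiplicity[
      others$scaffold == c$scaffold &
        others$start <= c$end & others$end >= c$start &
        !(others$start == c$start & others$end == c$end)
    ])
    ok <- len >= cfg$min_intron_len && len <= cfg$max_intron_len &&
      paste0(c$donor, "-", c$acceptor) %in% cfg$accepted_splice_pairs &&
      contra <= cfg$contradiction_factor * c$multiplicity
    if (ok) brute <- c(brute, c$key)
  }
  ## brute force restricted to the same 50 candidates
  expect_setequal(filter_candidates(cands, cfg)$key, brute)
})

test_that("supported introns require exact coordinate matches", {
  m <- gene_models(simple_gene("g1", "s1", "+", c(1, 201, 401),
                               c(100, 300, 500)))
  idx <- bind_rows(
    idx_row("s1", 101, 200),         # matches intron 1 exactly
    idx_row("s1", 302, 400)          # off by one vs intron 2 (301-400)
  )
  sup <- supported_introns(m, idx)
  expect_equal(nrow(sup), 1)
  expect_equal(sup$start, 101L)
  ## empty index -> nothing supported
  expect_equal(nrow(supported_introns(m, idx[0, ])), 0)
  ## strand-unknown index entries match either strand
  idx2 <- idx_row("s1", 101, 200, strand = "*")
  expect_equal(nrow(supported_introns(m, idx2)), 1)
})

test_that("merging candidate sets sums multiplicities of identical keys", {
  a <- idx_row("s1", 101, 200, mult = 5)
  b <- idx_row("s1", 101, 200, mult = 7)
  cc <- idx_row("s1", 301, 400, mult = 1)
  merged <- merge_candidates(a, b, cc)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$multiplicity[merged$start == 101], 12L)
})
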