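## a join scenario: new gene J spans old genes A and B with a bridging intron
join_scenario <- function(strand = "+") {
  old <- gene_models(bind_rows(
    simple_gene("oldA", "s1", strand, c(1, 201), c(100, 300)),
    simple_gene("oldB", "s1", strand, c(501, 701), c(600, 800))
  ))
  new <- gene_models(
    simple_gene("newJ", "s1", strand, c(1, 201, 501, 701),
                c(100, 300, 600, 800))
  )
  list(old = old, new = new)
}

test_that("join events require CDS overlap with >= 2 old genes, same strand", {
  sc <- join_scenario()
  ev <- detect_join_events(sc$old, sc$new, idx_row("s1", 1, 2)[0, ])
  expect_equal(nrow(ev), 1)
  expect_equal(ev$anchor_gene, "newJ")
  expect_equal(ev$partner_genes[[1]], c("oldA", "oldB"))
  expect_false(ev$supported)

  ## opposite strand: no event
  flip <- gene_models(mutate(sc$new, strand = "-"))
  expect_equal(nrow(detect_join_events(sc$old, flip, idx_row("s1", 1, 2)[0, ])), 0)

  ## three partners: still one event
  old3 <- gene_models(bind_rows(
    as_tibble(sc$old), simple_gene("oldC", "s1", "+", 901, 1000)
  ))
  new3 <- gene_models(
    simple_gene("newJ", "s1", "+", c(1, 201, 501, 701, 901),
                c(100, 300, 600, 800, 1000))
  )
  ev3 <- detect_join_events(old3, new3, idx_row("s1", 1, 2)[0, ])
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$n_partners, 3L)
})

test_that("join support needs a supported intron spanning the partner gap", {
  sc <- join_scenario()
  ## gap between oldA CDS end (300) and oldB CDS start (501) is 301-500,
  ## which is exactly newJ's middle intron
  bridge <- idx_row("s1", 301, 500)
  ev <- detect_join_events(sc$old, sc$new, bridge)
  expect_true(ev$supported)
  expect_equal(ev$supporting_introns[[1]], intron_key("s1", 301, 500, "+"))
  ## a supported intron inside partner A does not bridge
  inside <- idx_row("s1", 101, 200)
  expect_false(detect_join_events(sc$old, sc$new, inside)$supported)
})

test_that("split events mirror joins with the old gene as anchor", {
  sc <- join_scenario()
  ## relabel: the whole gene is old, the two parts are new
  old <- gene_models(as_tibble(sc$new) %>%
                       mutate(gene_id = "oldS",
                              transcript_id = "oldS.t1"))
  new <- gene_models(as_tibble(sc$old) %>%
                       mutate(gene_id = sub("old", "new", gene_id),
                              transcript_id = paste0(gene_id, ".t1")))
  ev <- detect_split_events(old, new, idx_row("s1", 1, 2)[0, ])
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "split")
  expect_equal(ev$partner_genes[[1]], c("newA", "newB"))
  expect_false(ev$supported)
  ## the old bridging intron in the index -> supported
  expect_true(detect_split_events(old, new, idx_row("s1", 301, 500))$supported)
  ## a single overlapping new gene is no split
  ev1 <- detect_split_events(old, new[new$gene_id == "newA", ],
                             idx_row("s1", 1, 2)[0, ])
  expect_equal(nrow(ev1), 0)
})

test_that("relabelling old and new swaps join and split events exactly", {
  fx <- default_fixture()
  joins <- detect_join_events(fx$old, fx$new, fx$idx)
  splits <- detect_split_events(fx$old, fx$new, fx$idx)
  joins_swapped <- detect_join_events(fx$new, fx$old, fx$idx)
  splits_swapped <- detect_split_events(fx$new, fx$old, fx$idx)
  reanchor <- function(x) arrange(select(x, -kind), anchor_gene)
  expect_equal(reanchor(joins), reanchor(splits_swapped))
  expect_equal(reanchor(splits), reanchor(joins_swapped))
})

test_that("event detection agrees with the quadratic all-pairs oracle", {
  fx <- default_fixture()
  keep_old <- head(unique(fx$old$gene_id), 100)
  keep_new <- head(unique(fx$new$gene_id), 100)
  old <- fx$old[fx$old$gene_id %in% keep_old, ]
  new <- fx$new[fx$new$gene_id %in% keep_new, ]
  ev <- detect_join_events(old, new, fx$idx)
  ora <- oracle_events(new, old)
  expect_setequal(ev$anchor_gene, ora$anchor_gene)
  for (a in ev$anchor_gene) {
    expect_equal(sort(ev$partner_genes[[which(ev$anchor_gene == a)]]),
                 ora$partners[[which(ora$anchor_gene == a)]])
  }
})

test_that("protein identity and coverage match hand-computed alignments", {
  expect_equal(protein_identity_coverage("MKVL", "MKVL"),
               c(identity = 1, coverage = 1))
  ## one substitution in four columns
  expect_equal(protein_identity_coverage("MKVL", "MKIL"),
               c(identity = 0.75, coverage = 1))
  ## truncation: 2 aligned columns over old length 4
  expect_equal(protein_identity_coverage("MKVL", "MK"),
               c(identity = 1, coverage = 0.5))
  ## internal gap: MKAYW vs MK-YW -> 4 aligned columns of 5
  expect_equal(protein_identity_coverage("MKAYW", "MKYW"),
               c(identity = 1, coverage = 0.8))
  expect_error(protein_identity_coverage("", "MK"), "empty")
})

test_that("correspondence classes follow thresholds and precedence", {
  old <- gene_models(bind_rows(
    simple_gene("oldX", "s1", "+", 1, 60),
    simple_gene("oldY", "s2", "+", 1, 60)
  ))
  new <- gene_models(bind_rows(
    simple_gene("newX", "s1", "+", 21, 80),
    simple_gene("newZ", "s3", "+", 1, 60)
  ))
  p20 <- strrep("ACDEFGHIKL", 2)           # 20 residues
  p20_mut <- paste0(substr(p20, 1, 19), "W")  # 19/20 identical = 95.0%
  proteins <- c(oldX = p20, oldY = p20, newX = p20_mut, newZ = "WWWWWWWWWW")
  rep <- classify_correspondence(old, new, proteins)
  cls <- setNames(rep$new_classes$class, rep$new_classes$gene_id)
  expect_equal(cls[["newX"]], "near_identical")   # boundary inclusive
  expect_equal(cls[["newZ"]], "new")              # no overlap at all
  expect_equal(rep$lost_genes, "oldY")
  ## exact equality beats near-identity
  proteins2 <- proteins; proteins2[["newX"]] <- p20
  rep2 <- classify_correspondence(old, new, proteins2)
  expect_equal(rep2$new_classes$class[rep2$new_classes$gene_id == "newX"],
               "identical")
  ## disjoint sets: everything new / lost
  rep3 <- classify_correspondence(old, new[new$gene_id == "newZ", ], proteins)
  expect_equal(rep3$new_classes$class, "new")
  expect_setequal(rep3$lost_genes, c("oldX", "oldY"))
  ## missing protein errors with the gene named
  expect_error(classify_correspondence(old, new, proteins[-4]), "newZ")
})

test_that("sub-threshold overlaps are restructured or new by novelty rule", {
  old <- gene_models(simple_gene("oldS", "s1", "+", 1, 120))
  new <- gene_models(simple_gene("newH", "s1", "+", 1, 60))
  proteins <- c(oldS = strrep("ACDEFGHIKL", 4), newH = strrep("ACDEFGHIKL", 2))
  over <- classify_correspondence(old, new, proteins, novelty = "overlap")
  expect_equal(over$new_classes$class, "restructured")
  expect_length(over$lost_genes, 0)
  thr <- classify_correspondence(old, new, proteins, novelty = "threshold")
  expect_equal(thr$new_classes$class, "new")
  expect_equal(thr$lost_genes, "oldS")
})

test_that("translation uses longest isoforms and flags internal stops", {
  ## CDS ATG AAA TAA -> "MK" after stop stripping
  genome <- c(s1 = paste0("ATGAAATAA", strrep("A", 20)))
  m <- gene_models(simple_gene("g1", "s1", "+", 1, 9))
  tr <- translate_genes(m, genome)
  expect_equal(tr$protein, "MK")
  expect_equal(tr$n_internal_stops, 0L)
  ## internal stop becomes X and is counted
  genome2 <- c(s1 = paste0("ATGTAAAAATAA", strrep("A", 20)))
  m2 <- gene_models(simple_gene("g2", "s1", "+", 1, 12))
  tr2 <- translate_genes(m2, genome2)
  expect_equal(tr2$protein, "MXK")
  expect_equal(tr2$n_internal_stops, 1L)
})
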