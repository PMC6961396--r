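## Seeded simulator: genomes, paired old/new gene sets with planted
## structural relations, intron evidence with controlled noise, and a
## two-species miRNA/ortholog scenario — each with a ground-truth manifest.
##
## Design notes. Gene loci are built top-down from a clean open reading
## frame (ATG, sense codons, TAA) so that every planted gene translates
## without premature stops; exon chunks are whole codons and introns are
## GT..AG with random filler. Loci are separated by random intergenic
## spacers so that no unplanted overlap (hence no spurious event) can
## arise. Evidence noise is planted in three disjoint categories matching
## the three candidate filters (length range, splice sites, contradiction
## ratio), so per-filter recall is measurable, plus explicit boundary
## cases (length 32, length 350,000, contradiction exactly 9x).

#' Simulation configuration
#'
#' Defaults describe the study-scale fixture used throughout the test
#' suite: 200 old genes in total, of which 40 participate in 20 planted
#' join events (12 with a supported bridging intron), 15 anchor planted
#' split events (2 supported), 8 are lost (4 rescued by evidence), 10 are
#' specifically supported, 17 have a near-identical replacement and 110 an
#' identical one; the new set additionally carries 10 completely new genes.
#'
#' @param seed integer RNG seed; the same seed yields byte-identical
#'   output files.
#' @param n_identical number of loci where old and new gene coincide.
#' @param n_single_exon how many of the identical loci are single-exon.
#' @param n_two_isoform how many identical-locus new genes get a second
#'   isoform (differing in 3'UTR length).
#' @param n_near_identical loci where the new gene's protein is mutated in
#'   roughly 2% of codons (above the 95% identity boundary).
#' @param n_specific loci where the old gene is specifically supported and
#'   displaces the new prediction.
#' @param n_join,n_join_supported planted join events (new gene spanning
#'   two old genes) and how many have a supported bridging intron.
#' @param n_split,n_split_supported planted split events (old gene
#'   spanning two new genes) and how many have a supported old bridge.
#' @param n_new new-set-only genes.
#' @param n_lost,n_lost_rescued old-set-only genes, and how many carry
#'   rescue evidence.
#' @param n_scaffolds scaffolds the gene loci are distributed over.
#' @param minus_strand_frac fraction of loci placed on the minus strand.
#' @param exon_codons,intron_len,utr3_len,intergenic,multiplicity
#'   integer ranges (`c(min, max)`) for structural draws.
#' @param n_noise_short,n_noise_long,n_noise_noncanonical,n_noise_contradicted
#'   planted evidence-noise counts per filter category.
#' @param include_boundary plant the boundary cases (length 32, length
#'   350,000, contradiction exactly 9x) as retained candidates.
#' @param mirna list of miRNA-scenario settings: `n_families`,
#'   `n_conserved` families with planted conserved targets,
#'   `n_targets` per non-conserved family, `n_targets_conserved_family`
#'   (species A targets of a conserved family), `n_conserved_targets` of
#'   those with orthologous sites in species B, `universe` ortholog pairs,
#'   `utr_len`, `mature_len`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_identical = 110L, n_single_exon = 15L,
                       n_two_isoform = 10L,
                       n_near_identical = 17L, n_specific = 10L,
                       n_join = 20L, n_join_supported = 12L,
                       n_split = 15L, n_split_supported = 2L,
                       n_new = 10L, n_lost = 8L, n_lost_rescued = 4L,
                       n_scaffolds = 5L, minus_strand_frac = 0.4,
                       exon_codons = c(15L, 40L),
                       intron_len = c(60L, 140L),
                       utr3_len = c(30L, 80L),
                       intergenic = c(150L, 400L),
                       multiplicity = c(20L, 200L),
                       n_noise_short = 6L, n_noise_long = 1L,
                       n_noise_noncanonical = 6L,
                       n_noise_contradicted = 6L,
                       include_boundary = TRUE,
                       mirna = list()) {
  mirna_defaults <- list(
    n_families = 10L, n_conserved = 3L, n_targets = 6L,
    n_targets_conserved_family = 9L, n_conserved_targets = 4L,
    universe = 50L, utr_len = 150L, mature_len = 22L
  )
  mirna <- utils::modifyList(mirna_defaults, mirna)
  cfg <- list(
    seed = as.integer(seed),
    n_identical = n_identical, n_single_exon = n_single_exon,
    n_two_isoform = n_two_isoform,
    n_near_identical = n_near_identical, n_specific = n_specific,
    n_join = n_join, n_join_supported = n_join_supported,
    n_split = n_split, n_split_supported = n_split_supported,
    n_new = n_new, n_lost = n_lost, n_lost_rescued = n_lost_rescued,
    n_scaffolds = n_scaffolds, minus_strand_frac = minus_strand_frac,
    exon_codons = exon_codons, intron_len = intron_len,
    utr3_len = utr3_len, intergenic = intergenic,
    multiplicity = multiplicity,
    n_noise_short = n_noise_short, n_noise_long = n_noise_long,
    n_noise_noncanonical = n_noise_noncanonical,
    n_noise_contradicted = n_noise_contradicted,
    include_boundary = include_boundary,
    mirna = mirna
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  checks <- c(
    "n_join_supported exceeds n_join" = cfg$n_join_supported <= cfg$n_join,
    "n_split_supported exceeds n_split" = cfg$n_split_supported <= cfg$n_split,
    "n_lost_rescued exceeds n_lost" = cfg$n_lost_rescued <= cfg$n_lost,
    "n_single_exon + n_two_isoform exceeds n_identical" =
      cfg$n_single_exon + cfg$n_two_isoform <= cfg$n_identical,
    "minus_strand_frac outside [0,1]" =
      cfg$minus_strand_frac >= 0 && cfg$minus_strand_frac <= 1,
    "conserved family larger than ortholog universe" =
      cfg$mirna$n_targets_conserved_family <= cfg$mirna$universe,
    "conserved targets exceed family targets" =
      cfg$mirna$n_conserved_targets <= cfg$mirna$n_targets_conserved_family,
    "conserved families exceed families" =
      cfg$mirna$n_conserved <= cfg$mirna$n_families,
    "non-conserved targets need headroom in the universe" =
      cfg$mirna$n_targets * 2L <= cfg$mirna$universe
  )
  if (!all(checks)) {
    abort(paste0("infeasible sim_config: ",
                 paste(names(checks)[!checks], collapse = "; ")))
  }
  invisible(cfg)
}

## ------------------------------------------------------------------
## locus builders (relative, '+' strand; flipped later if needed)

rint <- function(rng) sample(rng[1]:rng[2], 1L)

orf_codons <- function(n) c("ATG", sample(sense_codons, n - 2L, replace = TRUE), "TAA")

gt_ag_intron <- function(len) paste0("GT", rand_dna(len - 4L), "AG")

## an in-frame, stop-free GT..AG intron (length a multiple of 3); used
## where a new gene reads an old intron as coding sequence
coding_safe_intron <- function(n_codons) {
  first <- paste0("GT", sample(DNA_BASES, 1L))
  last <- paste0(sample(c("A", "C", "G"), 1L), "AG")
  mid <- sample(sense_codons, n_codons - 2L, replace = TRUE)
  paste(c(first, mid, last), collapse = "")
}

feat_row <- function(set, gene, tx, type, start, end) {
  tibble(set = set, gene = gene, tx = tx, type = type,
         start = as.integer(start), end = as.integer(end))
}

## identical locus: old and new gene share all coordinates
build_identical_locus <- function(cfg, single_exon = FALSE,
                                  two_isoform = FALSE) {
  n_ex <- if (single_exon) 1L else sample(2:4, 1L)
  codons <- vapply(seq_len(n_ex), function(i) rint(cfg$exon_codons), integer(1))
  orf <- orf_codons(sum(codons))
  chunks <- split(orf, rep(seq_len(n_ex), codons))
  chunk_seq <- vapply(chunks, paste, character(1), collapse = "")
  introns <- if (n_ex > 1) vapply(seq_len(n_ex - 1L), function(i)
    gt_ag_intron(rint(cfg$intron_len)), character(1)) else character(0)
  utr3 <- rand_dna(rint(cfg$utr3_len))

  pieces <- character(0)
  feats <- list(); hints <- list()
  pos <- 1L
  for (i in seq_len(n_ex)) {
    w <- nchar(chunk_seq[i])
    cds_start <- pos; cds_end <- pos + w - 1L
    exon_end <- cds_end
    if (i == n_ex) exon_end <- cds_end + nchar(utr3)
    for (s in c("old", "new")) {
      feats[[length(feats) + 1]] <- bind_rows(
        feat_row(s, 1L, 1L, "exon", cds_start, exon_end),
        feat_row(s, 1L, 1L, "CDS", cds_start, cds_end)
      )
    }
    pieces <- c(pieces, chunk_seq[i], if (i == n_ex) utr3)
    pos <- exon_end + 1L
    if (i < n_ex) {
      il <- nchar(introns[i])
      hints[[length(hints) + 1]] <- tibble(
        start = pos, end = pos + il - 1L,
        multiplicity = rint(cfg$multiplicity),
        category = "true", expected = "kept"
      )
      pieces <- c(pieces, introns[i])
      pos <- pos + il
    }
  }
  feats <- bind_rows(feats)
  if (two_isoform) {
    t2 <- feats %>% filter(set == "new") %>% mutate(tx = 2L)
    ## second isoform: shorter 3'UTR on the last exon
    last_exon <- which(t2$type == "exon" & t2$end == max(t2$end[t2$type == "exon"]))
    t2$end[last_exon] <- t2$end[last_exon] - min(10L, nchar(utr3) - 5L)
    feats <- bind_rows(feats, t2)
  }
  list(
    type = if (single_exon) "identical_single_exon" else "identical",
    seq = paste(pieces, collapse = ""),
    feats = feats, hints = bind_rows(hints),
    truth_old = tibble(gene = 1L, merge_status = "dropped"),
    truth_new = tibble(gene = 1L, expected_class = "identical", fate = "kept"),
    truth_event = NULL
  )
}

## near-identical locus: shared flanking exons; the middle exon differs
## between old (X) and new (X', ~2% of all codons mutated), each version
## sitting inside the other gene's intron
build_near_identical_locus <- function(cfg) {
  a <- rint(cfg$exon_codons); m <- rint(cfg$exon_codons)
  b <- rint(cfg$exon_codons)
  n <- a + m + b
  orf <- orf_codons(n)
  E1 <- orf[seq_len(a)]
  X <- orf[a + seq_len(m)]
  E3 <- orf[a + m + seq_len(b)]
  k <- max(1L, min(m, floor(0.02 * n)))
  Xp <- X
  mut <- sample.int(m, k)
  for (j in mut) {
    aa <- Biostrings::GENETIC_CODE[[Xp[j]]]
    alt <- sense_codons[Biostrings::GENETIC_CODE[sense_codons] != aa]
    Xp[j] <- sample(alt, 1L)
  }
  ga <- gt_ag_intron(rint(cfg$intron_len))
  gb <- gt_ag_intron(rint(cfg$intron_len))
  gc_ <- gt_ag_intron(rint(cfg$intron_len))
  utr3 <- rand_dna(rint(cfg$utr3_len))
  segs <- c(e1 = paste(E1, collapse = ""), ga = ga,
            x = paste(X, collapse = ""), gb = gb,
            xp = paste(Xp, collapse = ""), gc = gc_,
            e3 = paste(E3, collapse = ""), utr = utr3)
  off <- cumsum(c(0L, nchar(segs)))[seq_along(segs)] + 1L
  names(off) <- names(segs)
  endof <- function(nm) off[[nm]] + nchar(segs[[nm]]) - 1L
  feats <- bind_rows(
    feat_row("old", 1L, 1L, "exon", off["e1"], endof("e1")),
    feat_row("old", 1L, 1L, "CDS", off["e1"], endof("e1")),
    feat_row("old", 1L, 1L, "exon", off["x"], endof("x")),
    feat_row("old", 1L, 1L, "CDS", off["x"], endof("x")),
    feat_row("old", 1L, 1L, "exon", off["e3"], endof("utr")),
    feat_row("old", 1L, 1L, "CDS", off["e3"], endof("e3")),
    feat_row("new", 1L, 1L, "exon", off["e1"], endof("e1")),
    feat_row("new", 1L, 1L, "CDS", off["e1"], endof("e1")),
    feat_row("new", 1L, 1L, "exon", off["xp"], endof("xp")),
    feat_row("new", 1L, 1L, "CDS", off["xp"], endof("xp")),
    feat_row("new", 1L, 1L, "exon", off["e3"], endof("utr")),
    feat_row("new", 1L, 1L, "CDS", off["e3"], endof("e3"))
  )
  hints <- tibble(
    start = c(off[["ga"]], off[["gc"]]),
    end = c(endof("gb"), endof("gc")),
    multiplicity = c(rint(cfg$multiplicity), rint(cfg$multiplicity)),
    category = "true", expected = "kept"
  )
  list(
    type = "near_identical", seq = paste(segs, collapse = ""),
    feats = feats, hints = hints,
    truth_old = tibble(gene = 1L, merge_status = "dropped"),
    truth_new = tibble(gene = 1L, expected_class = "near_identical",
                       fate = "kept"),
    truth_event = NULL
  )
}

## specifically supported old gene: old has an extra supported intron that
## the overlapping new prediction reads as coding sequence
build_specific_locus <- function(cfg) {
  a <- rint(cfg$exon_codons); b <- rint(cfg$exon_codons)
  cc <- rint(cfg$exon_codons) + 45L    # long 3' exon keeps the gapped alignment optimal
  i2_codons <- sample(20:40, 1L)
  orf <- orf_codons(a + b + cc)
  E1 <- paste(orf[seq_len(a)], collapse = "")
  E2 <- paste(orf[a + seq_len(b)], collapse = "")
  E3 <- paste(orf[a + b + seq_len(cc)], collapse = "")
  i1 <- gt_ag_intron(rint(cfg$intron_len))
  i2 <- coding_safe_intron(i2_codons)
  utr3 <- rand_dna(rint(cfg$utr3_len))
  segs <- c(e1 = E1, i1 = i1, e2 = E2, i2 = i2, e3 = E3, utr = utr3)
  off <- cumsum(c(0L, nchar(segs)))[seq_along(segs)] + 1L
  names(off) <- names(segs)
  endof <- function(nm) off[[nm]] + nchar(segs[[nm]]) - 1L
  feats <- bind_rows(
    feat_row("old", 1L, 1L, "exon", off["e1"], endof("e1")),
    feat_row("old", 1L, 1L, "CDS", off["e1"], endof("e1")),
    feat_row("old", 1L, 1L, "exon", off["e2"], endof("e2")),
    feat_row("old", 1L, 1L, "CDS", off["e2"], endof("e2")),
    feat_row("old", 1L, 1L, "exon", off["e3"], endof("utr")),
    feat_row("old", 1L, 1L, "CDS", off["e3"], endof("e3")),
    feat_row("new", 1L, 1L, "exon", off["e1"], endof("e1")),
    feat_row("new", 1L, 1L, "CDS", off["e1"], endof("e1")),
    feat_row("new", 1L, 1L, "exon", off["e2"], endof("utr")),
    feat_row("new", 1L, 1L, "CDS", off["e2"], endof("e3"))
  )
  hints <- tibble(
    start = c(off[["i1"]], off[["i2"]]),
    end = c(endof("i1"), endof("i2")),
    multiplicity = c(rint(cfg$multiplicity), rint(cfg$multiplicity)),
    category = "true", expected = "kept"
  )
  list(
    type = "specific", seq = paste(segs, collapse = ""),
    feats = feats, hints = hints,
    truth_old = tibble(gene = 1L, merge_status = "kept_specific"),
    truth_new = tibble(gene = 1L, expected_class = "near_identical",
                       fate = "displaced"),
    truth_event = NULL
  )
}

## join locus: one new gene spanning two old genes; split locus is the
## mirror image (sets swapped)
build_join_like_locus <- function(cfg, kind, supported) {
  codons <- vapply(1:4, function(i) rint(cfg$exon_codons), integer(1))
  orf <- orf_codons(sum(codons))
  bounds <- cumsum(codons)
  chunk <- function(i) {
    lo <- if (i == 1) 1L else bounds[i - 1] + 1L
    paste(orf[lo:bounds[i]], collapse = "")
  }
  C <- vapply(1:4, chunk, character(1))
  ga <- gt_ag_intron(rint(cfg$intron_len))
  gb <- gt_ag_intron(rint(cfg$intron_len))
  gc_ <- gt_ag_intron(rint(cfg$intron_len))
  utr3 <- rand_dna(rint(cfg$utr3_len))
  segs <- c(c1 = C[1], ga = ga, c2 = C[2], gb = gb,
            c3 = C[3], gc = gc_, c4 = C[4], utr = utr3)
  off <- cumsum(c(0L, nchar(segs)))[seq_along(segs)] + 1L
  names(off) <- names(segs)
  endof <- function(nm) off[[nm]] + nchar(segs[[nm]]) - 1L
  ## the "whole" gene (anchor for a join, old gene for a split)
  whole_set <- if (kind == "join") "new" else "old"
  part_set <- if (kind == "join") "old" else "new"
  whole <- bind_rows(
    feat_row(whole_set, 1L, 1L, "exon", off["c1"], endof("c1")),
    feat_row(whole_set, 1L, 1L, "CDS", off["c1"], endof("c1")),
    feat_row(whole_set, 1L, 1L, "exon", off["c2"], endof("c2")),
    feat_row(whole_set, 1L, 1L, "CDS", off["c2"], endof("c2")),
    feat_row(whole_set, 1L, 1L, "exon", off["c3"], endof("c3")),
    feat_row(whole_set, 1L, 1L, "CDS", off["c3"], endof("c3")),
    feat_row(whole_set, 1L, 1L, "exon", off["c4"], endof("utr")),
    feat_row(whole_set, 1L, 1L, "CDS", off["c4"], endof("c4"))
  )
  parts <- bind_rows(
    feat_row(part_set, 1L, 1L, "exon", off["c1"], endof("c1")),
    feat_row(part_set, 1L, 1L, "CDS", off["c1"], endof("c1")),
    feat_row(part_set, 1L, 1L, "exon", off["c2"], endof("c2")),
    feat_row(part_set, 1L, 1L, "CDS", off["c2"], endof("c2")),
    feat_row(part_set, 2L, 1L, "exon", off["c3"], endof("c3")),
    feat_row(part_set, 2L, 1L, "CDS", off["c3"], endof("c3")),
    feat_row(part_set, 2L, 1L, "exon", off["c4"], endof("utr")),
    feat_row(part_set, 2L, 1L, "CDS", off["c4"], endof("c4"))
  )
  ## transcript numbering is per (set, gene), so tx = 1 in both genes
  hints <- tibble(
    start = c(off[["ga"]], off[["gc"]], if (supported) off[["gb"]]),
    end = c(endof("ga"), endof("gc"), if (supported) endof("gb")),
    multiplicity = rint(cfg$multiplicity) + c(0L, 1L, if (supported) 2L),
    category = "true", expected = "kept"
  )
  if (kind == "join") {
    truth_old <- tibble(gene = 1:2, merge_status = "dropped")
    truth_new <- tibble(gene = 1L, expected_class = "near_identical",
                        fate = "kept")
    event <- list(kind = "join", anchor = 1L, partners = 1:2,
                  supported = supported)
  } else {
    status <- if (supported) "kept_specific" else "dropped"
    truth_old <- tibble(gene = 1L, merge_status = status)
    truth_new <- tibble(
      gene = 1:2, expected_class = "restructured",
      fate = if (supported) "displaced" else "kept"
    )
    event <- list(kind = "split", anchor = 1L, partners = 1:2,
                  supported = supported)
  }
  list(
    type = kind, seq = paste(segs, collapse = ""),
    feats = bind_rows(whole, parts), hints = hints,
    truth_old = truth_old, truth_new = truth_new, truth_event = event
  )
}

## gene present in only one set
build_solo_locus <- function(cfg, set, merge_status = NULL) {
  n_ex <- sample(2:3, 1L)
  codons <- vapply(seq_len(n_ex), function(i) rint(cfg$exon_codons), integer(1))
  orf <- orf_codons(sum(codons))
  chunks <- split(orf, rep(seq_len(n_ex), codons))
  chunk_seq <- vapply(chunks, paste, character(1), collapse = "")
  utr3 <- rand_dna(rint(cfg$utr3_len))
  pieces <- character(0); feats <- list(); hints <- list()
  pos <- 1L
  for (i in seq_len(n_ex)) {
    w <- nchar(chunk_seq[i])
    exon_end <- pos + w - 1L + if (i == n_ex) nchar(utr3) else 0L
    feats[[length(feats) + 1]] <- bind_rows(
      feat_row(set, 1L, 1L, "exon", pos, exon_end),
      feat_row(set, 1L, 1L, "CDS", pos, pos + w - 1L)
    )
    pieces <- c(pieces, chunk_seq[i], if (i == n_ex) utr3)
    pos <- exon_end + 1L
    if (i < n_ex) {
      intr <- gt_ag_intron(rint(cfg$intron_len))
      if (set == "new") {
        hints[[length(hints) + 1]] <- tibble(
          start = pos, end = pos + nchar(intr) - 1L,
          multiplicity = rint(cfg$multiplicity),
          category = "true", expected = "kept"
        )
      }
      pieces <- c(pieces, intr)
      pos <- pos + nchar(intr)
    }
  }
  truth_old <- if (set == "old") {
    tibble(gene = 1L, merge_status = merge_status)
  } else tibble(gene = integer(), merge_status = character())
  truth_new <- if (set == "new") {
    tibble(gene = 1L, expected_class = "new", fate = "kept")
  } else tibble(gene = integer(), expected_class = character(),
                fate = character())
  list(
    type = if (set == "old") "lost" else "new",
    seq = paste(pieces, collapse = ""),
    feats = bind_rows(feats), hints = bind_rows(hints),
    truth_old = truth_old, truth_new = truth_new, truth_event = NULL
  )
}

## evidence-noise chunks: gene-free sequence carrying planted candidates
build_noise_chunk <- function(category, cfg) {
  pad <- function(n = 10L) rand_dna(n)
  mk <- function(seq, start, end, mult, expected) {
    list(type = paste0("noise_", category), seq = seq,
         feats = feat_row(character(0), integer(0), integer(0),
                          character(0), integer(0), integer(0)),
         hints = tibble(start = start, end = end, multiplicity = mult,
                        category = category, expected = expected),
         truth_old = NULL, truth_new = NULL, truth_event = NULL)
  }
  switch(category,
    "noise_short" = {      # canonical sites but length 20 < 32
      s <- paste0(pad(), gt_ag_intron(20L), pad())
      mk(s, 11L, 30L, rint(c(2L, 20L)), "removed")
    },
    "boundary_short" = {   # length exactly 32: retained
      s <- paste0(pad(), gt_ag_intron(32L), pad())
      mk(s, 11L, 42L, rint(c(2L, 20L)), "kept")
    },
    "noise_noncanonical" = {  # in-range length, CC..GG sites
      body <- paste0("CC", rand_dna(56L), "GG")
      s <- paste0(pad(), body, pad())
      mk(s, 11L, 70L, rint(c(2L, 20L)), "removed")
    },
    "noise_contradicted" = {  # child overwhelmed by its host (50 > 9 x 5)
      inner <- paste0("GT", rand_dna(34L), "AG")      # 38 bp child
      host <- paste0("GT", rand_dna(20L), inner)      # 60 bp host
      s <- paste0(pad(), host, pad())
      mk(s, c(11L, 33L), c(70L, 70L), c(50L, 5L),
         c("kept", "removed")) %>%
        (function(x) { x$hints$category <- c("contradiction_host", category); x })()
    },
    "boundary_contradiction" = {  # exactly 9x: 90 <= 9 x 10, both kept
      inner <- paste0("GT", rand_dna(34L), "AG")
      host <- paste0("GT", rand_dna(20L), inner)
      s <- paste0(pad(), host, pad())
      mk(s, c(11L, 33L), c(70L, 70L), c(90L, 10L), c("kept", "kept")) %>%
        (function(x) {
          x$hints$category <- c("contradiction_host", category); x
        })()
    },
    abort(paste0("unknown noise category: ", category))
  )
}

## the long-intron scaffold: one over-length candidate (350,001, removed)
## and one boundary candidate (350,000, kept)
build_long_scaffold <- function(cfg) {
  n_long <- cfg$n_noise_long
  lens <- c(rep(350001L, n_long), if (cfg$include_boundary) 350000L)
  expected <- c(rep("removed", n_long),
                if (cfg$include_boundary) "kept")
  category <- c(rep("noise_long", n_long),
                if (cfg$include_boundary) "boundary_long")
  if (length(lens) == 0) return(NULL)
  pieces <- character(0)
  hints <- list()
  pos <- 1L
  for (i in seq_along(lens)) {
    pad <- rand_dna(50L)
    body <- paste0("GT", rand_dna(lens[i] - 4L), "AG")
    pieces <- c(pieces, pad, body)
    start <- pos + 50L
    hints[[i]] <- tibble(
      start = start, end = start + lens[i] - 1L,
      multiplicity = rint(c(2L, 20L)),
      category = category[i], expected = expected[i]
    )
    pos <- start + lens[i]
  }
  pieces <- c(pieces, rand_dna(50L))
  list(seq = paste(pieces, collapse = ""), hints = bind_rows(hints))
}

## flip a '+' locus onto the '-' strand: reverse-complement the sequence
## and mirror all coordinates
flip_locus <- function(locus) {
  L <- nchar(locus$seq)
  locus$seq <- revcomp_dna(locus$seq)
  flip <- function(tbl) {
    if (is.null(tbl) || nrow(tbl) == 0) return(tbl)
    new_start <- L - tbl$end + 1L
    tbl$end <- L - tbl$start + 1L
    tbl$start <- new_start
    tbl
  }
  locus$feats <- flip(locus$feats)
  locus$hints <- flip(locus$hints)
  locus
}

## ------------------------------------------------------------------

#' Generate a complete synthetic fixture
#'
#' Writes a genome FASTA, old and new gene sets (GFF3), an intron-hints
#' GFF, a rescue-evidence TSV, the two-species miRNA scenario (mature
#' miRNA and UTR FASTA files, homology and orthology TSVs) and a
#' ground-truth manifest (JSON) into `outdir`. Output is a pure function
#' of the configuration: the same seed yields byte-identical files.
#'
#' @param cfg a [sim_config].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the file `paths` and the `manifest` as
#'   an R list.
#' @export
generate_fixture <- function(cfg = sim_config(), outdir) {
  validate_sim_config(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  with_seed(cfg$seed, generate_fixture_impl(cfg, outdir))
}

generate_fixture_impl <- function(cfg, outdir) {
  ## -- build loci ---------------------------------------------------
  loci <- list()
  add <- function(x) loci[[length(loci) + 1]] <<- x
  for (i in seq_len(cfg$n_identical)) {
    add(build_identical_locus(
      cfg,
      single_exon = i <= cfg$n_single_exon,
      two_isoform = i > cfg$n_single_exon &
        i <= cfg$n_single_exon + cfg$n_two_isoform
    ))
  }
  for (i in seq_len(cfg$n_near_identical)) add(build_near_identical_locus(cfg))
  for (i in seq_len(cfg$n_specific)) add(build_specific_locus(cfg))
  for (i in seq_len(cfg$n_join)) {
    add(build_join_like_locus(cfg, "join", i <= cfg$n_join_supported))
  }
  for (i in seq_len(cfg$n_split)) {
    add(build_join_like_locus(cfg, "split", i <= cfg$n_split_supported))
  }
  for (i in seq_len(cfg$n_new)) add(build_solo_locus(cfg, "new"))
  rescue_patterns <- list(
    rescued = list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0.01), c(0, 0, 5)),
    dropped = list(c(0, 0, 0.009), c(0, 0, 0.005), c(0, 0, 0), c(0, 0, 0))
  )
  for (i in seq_len(cfg$n_lost)) {
    rescued <- i <= cfg$n_lost_rescued
    pat <- if (rescued) {
      rescue_patterns$rescued[[(i - 1L) %% 4L + 1L]]
    } else {
      rescue_patterns$dropped[[(i - cfg$n_lost_rescued - 1L) %% 4L + 1L]]
    }
    locus <- build_solo_locus(cfg, "old",
                              merge_status = if (rescued) "kept_rescued" else "dropped")
    locus$rescue_pattern <- pat   # travels with the locus through shuffling
    add(locus)
  }
  n_gene_loci <- length(loci)
  for (i in seq_len(cfg$n_noise_short)) add(build_noise_chunk("noise_short", cfg))
  for (i in seq_len(cfg$n_noise_noncanonical)) {
    add(build_noise_chunk("noise_noncanonical", cfg))
  }
  for (i in seq_len(cfg$n_noise_contradicted)) {
    add(build_noise_chunk("noise_contradicted", cfg))
  }
  if (cfg$include_boundary) {
    add(build_noise_chunk("boundary_short", cfg))
    add(build_noise_chunk("boundary_contradiction", cfg))
  }

  ## -- place loci on scaffolds --------------------------------------
  ord <- sample.int(length(loci))
  strands <- ifelse(stats::runif(length(loci)) < cfg$minus_strand_frac,
                    "-", "+")
  scaffold_of <- sprintf("scaffold_%02d",
                         (seq_along(ord) - 1L) %% cfg$n_scaffolds + 1L)
  seqs <- setNames(vector("list", cfg$n_scaffolds),
                   sprintf("scaffold_%02d", seq_len(cfg$n_scaffolds)))
  cursors <- setNames(rep(0L, cfg$n_scaffolds), names(seqs))
  placed <- list()
  for (j in seq_along(ord)) {
    locus <- loci[[ord[j]]]
    has_genes <- nrow(locus$feats) > 0
    if (has_genes && strands[j] == "-") locus <- flip_locus(locus)
    strand <- if (has_genes) strands[j] else "+"
    sc <- scaffold_of[j]
    spacer <- rand_dna(rint(cfg$intergenic))
    offset <- cursors[[sc]] + nchar(spacer)
    seqs[[sc]] <- c(seqs[[sc]], spacer, locus$seq)
    cursors[[sc]] <- offset + nchar(locus$seq)
    if (nrow(locus$feats) > 0) {
      locus$feats$start <- locus$feats$start + offset
      locus$feats$end <- locus$feats$end + offset
      locus$feats$scaffold <- sc
      locus$feats$strand <- strand
    }
    if (nrow(locus$hints) > 0) {
      locus$hints$start <- locus$hints$start + offset
      locus$hints$end <- locus$hints$end + offset
      locus$hints$scaffold <- sc
    }
    locus$scaffold <- sc
    locus$strand <- strand
    placed[[length(placed) + 1]] <- locus
  }
  seqs <- vapply(seqs, paste, character(1), collapse = "")
  ## trailing spacer so no feature abuts a scaffold end
  seqs <- vapply(seqs, function(s) paste0(s, rand_dna(60L)), character(1))

  long_sc <- build_long_scaffold(cfg)
  if (!is.null(long_sc)) {
    seqs <- c(seqs, scaffold_long = long_sc$seq)
    long_sc$hints$scaffold <- "scaffold_long"
  }

  ## -- assign global gene ids (placement order) ---------------------
  old_i <- 0L; new_i <- 0L
  feats <- list(); hints <- list()
  genes_old <- list(); genes_new <- list(); events <- list()
  rescue_rows <- list()
  for (locus in placed) {
    id_map <- list(old = character(0), new = character(0))
    if (nrow(locus$feats) > 0) {
      for (s in c("old", "new")) {
        locals <- sort(unique(locus$feats$gene[locus$feats$set == s]))
        for (g in locals) {
          if (s == "old") {
            old_i <- old_i + 1L
            id_map$old[as.character(g)] <- sprintf("og%03d", old_i)
          } else {
            new_i <- new_i + 1L
            id_map$new[as.character(g)] <- sprintf("ng%03d", new_i)
          }
        }
      }
      f <- locus$feats %>%
        mutate(
          gene_id = ifelse(set == "old",
                           id_map$old[as.character(gene)],
                           id_map$new[as.character(gene)]),
          transcript_id = paste0(gene_id, ".t", tx)
        )
      feats[[length(feats) + 1]] <- f
    }
    if (nrow(locus$hints) > 0) hints[[length(hints) + 1]] <- locus$hints
    if (!is.null(locus$truth_old) && nrow(locus$truth_old) > 0) {
      genes_old[[length(genes_old) + 1]] <- locus$truth_old %>%
        mutate(gene_id = id_map$old[as.character(gene)],
               locus_type = locus$type, scaffold = locus$scaffold,
               strand = locus$strand) %>%
        select(-gene)
      if (locus$type == "lost") {
        pat <- locus$rescue_pattern
        rescue_rows[[length(rescue_rows) + 1]] <- tibble(
          gene_id = id_map$old[["1"]],
          has_homolog = as.integer(pat[1]),
          has_go_term = as.integer(pat[2]),
          fpkm = pat[3]
        )
      }
    }
    if (!is.null(locus$truth_new) && nrow(locus$truth_new) > 0) {
      genes_new[[length(genes_new) + 1]] <- locus$truth_new %>%
        mutate(gene_id = id_map$new[as.character(gene)],
               locus_type = locus$type) %>%
        select(-gene)
    }
    if (!is.null(locus$truth_event)) {
      ev <- locus$truth_event
      anchor_set <- if (ev$kind == "join") "new" else "old"
      partner_set <- if (ev$kind == "join") "old" else "new"
      events[[length(events) + 1]] <- tibble(
        kind = ev$kind,
        anchor_gene = id_map[[anchor_set]][as.character(ev$anchor)],
        partner_genes = list(sort(unname(
          id_map[[partner_set]][as.character(ev$partners)]
        ))),
        supported = ev$supported
      )
    }
  }
  feats <- bind_rows(feats)
  hints <- bind_rows(hints)
  if (!is.null(long_sc)) hints <- bind_rows(hints, long_sc$hints)
  hints <- hints %>% arrange(scaffold, start, end)

  old_models <- gene_models(feats %>% filter(set == "old") %>%
                              select(-set, -gene, -tx))
  new_models <- gene_models(feats %>% filter(set == "new") %>%
                              select(-set, -gene, -tx))

  ## -- miRNA two-species scenario -----------------------------------
  mir <- build_mirna_scenario(cfg$mirna)

  ## -- write files ---------------------------------------------------
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    old = file.path(outdir, "old.gff3"),
    new = file.path(outdir, "new.gff3"),
    hints = file.path(outdir, "hints.gff3"),
    rescue = file.path(outdir, "rescue.tsv"),
    mirna_A = file.path(outdir, "mirna_A.fa"),
    mirna_B = file.path(outdir, "mirna_B.fa"),
    utrs_A = file.path(outdir, "utrs_A.fa"),
    utrs_B = file.path(outdir, "utrs_B.fa"),
    mirna_homology = file.path(outdir, "mirna_homology.tsv"),
    orthology = file.path(outdir, "orthology.tsv"),
    manifest = file.path(outdir, "manifest.json")
  )
  write_fasta(seqs, paths$genome)
  write_gff3(old_models, paths$old)
  write_gff3(new_models, paths$new)
  genome <- seqs
  hint_cands <- annotate_candidates(
    hints %>% mutate(strand = NA_character_) %>%
      select(scaffold, start, end, strand, multiplicity),
    genome
  )
  write_intron_hints(hint_cands, paths$hints)
  rescue_tbl <- bind_rows(rescue_rows)
  readr::write_tsv(rescue_tbl, paths$rescue, progress = FALSE)
  write_fasta(mir$mature_A, paths$mirna_A)
  write_fasta(mir$mature_B, paths$mirna_B)
  write_fasta(mir$utrs_A, paths$utrs_A)
  write_fasta(mir$utrs_B, paths$utrs_B)
  readr::write_tsv(mir$homology, paths$mirna_homology, progress = FALSE)
  readr::write_tsv(mir$orthology, paths$orthology, progress = FALSE)

  manifest <- list(
    config = unclass(cfg),
    files = lapply(paths, basename),
    genes_old = bind_rows(genes_old) %>%
      select(gene_id, locus_type, merge_status, scaffold, strand) %>%
      arrange(gene_id),
    genes_new = bind_rows(genes_new) %>%
      select(gene_id, locus_type, expected_class, fate) %>%
      arrange(gene_id),
    events = bind_rows(events) %>% arrange(kind, anchor_gene),
    introns = hints %>%
      select(scaffold, start, end, multiplicity, category, expected),
    rescue = rescue_tbl,
    isoforms = list(
      n_two_isoform = cfg$n_two_isoform,
      n_new_genes = n_distinct(new_models$gene_id)
    ),
    mirna = mir$truth
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, manifest = manifest))
}

## ------------------------------------------------------------------
## miRNA scenario

build_mirna_scenario <- function(m) {
  rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")
  ## distinct seeds across families
  matures_A <- character(m$n_families)
  seen_sites <- character(0)
  for (i in seq_len(m$n_families)) {
    repeat {
      s <- rand_rna(m$mature_len)
      sites <- seed_site_strings(s)
      if (!any(sites %in% seen_sites)) {
        matures_A[i] <- s
        seen_sites <- c(seen_sites, sites)
        break
      }
    }
  }
  ## homologs share the first 8 positions (the seed), diverge elsewhere
  matures_B <- vapply(matures_A, function(s) {
    paste0(substr(s, 1, 8), rand_rna(m$mature_len - 8L))
  }, character(1), USE.NAMES = FALSE)
  fam_names_A <- sprintf("spA-mir-%d", seq_len(m$n_families))
  fam_names_B <- sprintf("spB-mir-%d", seq_len(m$n_families))
  genes_A <- sprintf("gA%03d", seq_len(m$universe))
  genes_B <- sprintf("gB%03d", seq_len(m$universe))
  orthology <- tibble(gene_A = genes_A, gene_B = genes_B)

  ## choose targets: conserved families share orthologous targets, the
  ## others target disjoint index sets so planted conservation is clean
  fam <- vector("list", m$n_families)
  for (i in seq_len(m$n_families)) {
    conserved <- i <= m$n_conserved
    if (conserved) {
      ia <- sample.int(m$universe, m$n_targets_conserved_family)
      shared <- ia[seq_len(m$n_conserved_targets)]
      extra_b <- sample(setdiff(seq_len(m$universe), ia),
                        m$n_targets - m$n_conserved_targets)
      ib <- c(shared, extra_b)
    } else {
      ia <- sample.int(m$universe, m$n_targets)
      ib <- sample(setdiff(seq_len(m$universe), ia), m$n_targets)
    }
    fam[[i]] <- list(conserved = conserved, ia = sort(ia), ib = sort(ib))
  }

  ## plant one site per (family, target). Each family targeting a gene
  ## gets its own non-overlapping slot of the UTR, and the result is
  ## verified with a direct substring scan (including type precedence) so
  ## that site strings occur exactly where planted; accidental matches in
  ## the random filler trigger a retry with fresh filler.
  fast_site_positions <- function(u, sites) {
    pos_of <- function(pat) {
      L <- nchar(u); k <- nchar(pat)
      if (L < k) return(integer(0))
      st <- seq_len(L - k + 1L)
      st[substring(u, st, st + k - 1L) == pat]
    }
    p8 <- pos_of(sites[["8mer"]])
    p7m8 <- setdiff(pos_of(sites[["7m8"]]), p8)
    p7a1 <- pos_of(sites[["7A1"]])
    p7a1 <- p7a1[!(p7a1 - 1L) %in% p8]
    sort(c(p8, p7m8, p7a1))
  }
  plant <- function(species) {
    matures <- if (species == "A") matures_A else matures_B
    site_tbl <- lapply(matures, seed_site_strings)
    per_gene <- lapply(seq_len(m$universe), function(gi) {
      which(vapply(fam, function(f) {
        gi %in% (if (species == "A") f$ia else f$ib)
      }, logical(1)))
    })
    utrs <- character(m$universe)
    planted <- list()
    for (gi in seq_len(m$universe)) {
      fams <- per_gene[[gi]]
      k <- length(fams)
      slot_w <- if (k > 0) (m$utr_len - 2L) %/% k else m$utr_len
      if (k > 0 && slot_w < 12L) {
        abort("infeasible miRNA scenario: too many families per UTR; widen utr_len")
      }
      done <- FALSE
      for (attempt in 1:200) {
        u <- rand_rna(m$utr_len)
        rows <- list()
        for (j in seq_along(fams)) {
          fi <- fams[j]
          type <- SITE_TYPES[(fi + gi) %% 3L + 1L]
          s <- site_tbl[[fi]][[type]]
          lo <- 2L + (j - 1L) * slot_w + 1L
          hi <- 2L + j * slot_w - nchar(s) - 1L
          pos <- sample(lo:hi, 1L)
          substr(u, pos, pos + nchar(s) - 1L) <- s
          if (type == "7m8") {
            ## an A after a 7m8 core would upgrade it to an 8mer
            after <- pos + nchar(s)
            if (substr(u, after, after) == "A") substr(u, after, after) <- "C"
          }
          if (type == "7A1") {
            ## the complement of mature position 8 in front would make it 8mer
            bad <- substr(site_tbl[[fi]][["8mer"]], 1L, 1L)
            if (substr(u, pos - 1L, pos - 1L) == bad) {
              substr(u, pos - 1L, pos - 1L) <-
                setdiff(c("A", "C", "G", "U"), bad)[1]
            }
          }
          rows[[length(rows) + 1]] <- tibble(
            gene = gi, family = fi, site_type = type, position = pos
          )
        }
        rows <- if (length(rows) > 0) bind_rows(rows) else
          tibble(gene = integer(), family = integer(),
                 site_type = character(), position = integer())
        ok <- TRUE
        for (fi in seq_len(m$n_families)) {
          got <- fast_site_positions(u, site_tbl[[fi]])
          want <- rows$position[rows$family == fi]
          if (!identical(sort(got), sort(as.integer(want)))) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          utrs[gi] <- u
          if (nrow(rows) > 0) planted[[length(planted) + 1]] <- rows
          done <- TRUE
          break
        }
      }
      if (!done) abort("could not plant miRNA sites; widen utr_len")
    }
    list(utrs = utrs, planted = bind_rows(planted))
  }
  A <- plant(species = "A")
  B <- plant(species = "B")

  names(A$utrs) <- paste0(genes_A, ".t1")
  names(B$utrs) <- paste0(genes_B, ".t1")
  truth_fams <- tibble(
    mirna_A = fam_names_A, mirna_B = fam_names_B,
    conserved = vapply(fam, `[[`, logical(1), "conserved"),
    targets_A = purrr::map(fam, ~ genes_A[.x$ia]),
    targets_B = purrr::map(fam, ~ genes_B[.x$ib]),
    n_conserved = vapply(fam, function(f) length(intersect(f$ia, f$ib)),
                         integer(1))
  )
  list(
    mature_A = setNames(matures_A, fam_names_A),
    mature_B = setNames(matures_B, fam_names_B),
    utrs_A = A$utrs, utrs_B = B$utrs,
    homology = tibble(mirna_A = fam_names_A, mirna_B = fam_names_B),
    orthology = orthology,
    truth = list(
      families = truth_fams,
      universe = m$universe,
      sites_A = A$planted, sites_B = B$planted
    )
  )
}

## ------------------------------------------------------------------

#' Validate a fixture against its manifest
#'
#' Re-derives key facts from the written files with independent simple
#' scans and checks them against the manifest: gene ids exist in the GFF3
#' files, planted intron candidates carry the splice-site dinucleotides
#' their category implies, event partners genuinely overlap their anchor's
#' CDS span, hint records agree with the manifest's intron table, and the
#' rescue table matches.
#'
#' @param outdir directory written by [generate_fixture()].
#' @return tibble with columns `check`, `ok`, `detail`; one row per check,
#'   failures naming the offending record.
#' @export
validate_manifest <- function(outdir) {
  man <- jsonlite::read_json(file.path(outdir, "manifest.json"),
                             simplifyVector = TRUE)
  res <- list()
  note <- function(check, ok, detail = "") {
    res[[length(res) + 1]] <<- tibble(check = check, ok = ok, detail = detail)
  }
  old <- read_gff3(file.path(outdir, "old.gff3"))
  new <- read_gff3(file.path(outdir, "new.gff3"))
  genome <- read_genome_fasta(file.path(outdir, "genome.fa"))

  miss_old <- setdiff(man$genes_old$gene_id, unique(old$gene_id))
  note("old gene ids present in old.gff3", length(miss_old) == 0,
       paste(miss_old, collapse = ", "))
  miss_new <- setdiff(man$genes_new$gene_id, unique(new$gene_id))
  note("new gene ids present in new.gff3", length(miss_new) == 0,
       paste(miss_new, collapse = ", "))

  intr <- as_tibble(man$introns)
  bad_sites <- character(0)
  for (i in seq_len(nrow(intr))) {
    d <- get_subseq(genome, intr$scaffold[i], intr$start[i], intr$start[i] + 1L)
    a <- get_subseq(genome, intr$scaffold[i], intr$end[i] - 1L, intr$end[i])
    canonical <- (d == "GT" && a == "AG") || (d == "CT" && a == "AC")
    want_canonical <- intr$category[i] != "noise_noncanonical"
    if (canonical != want_canonical) {
      bad_sites <- c(bad_sites, sprintf("%s:%d-%d", intr$scaffold[i],
                                        intr$start[i], intr$end[i]))
    }
  }
  note("planted intron splice sites match their category",
       length(bad_sites) == 0, paste(bad_sites, collapse = ", "))

  hint_lines <- readLines(file.path(outdir, "hints.gff3"))
  hint_lines <- hint_lines[!grepl("^#", hint_lines)]
  f <- do.call(rbind, strsplit(hint_lines, "\t", fixed = TRUE))
  hint_keys <- paste0(f[, 1], ":", f[, 4], "-", f[, 5])
  man_keys <- paste0(intr$scaffold, ":", intr$start, "-", intr$end)
  note("hints file agrees with the manifest intron table",
       setequal(hint_keys, man_keys),
       paste(
         c(setdiff(man_keys, hint_keys), setdiff(hint_keys, man_keys)),
         collapse = ", "
       ))

  spans_old <- gene_cds_spans(old)
  spans_new <- gene_cds_spans(new)
  bad_events <- character(0)
  ev <- man$events
  if (length(ev) > 0 && nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      anchor_spans <- if (ev$kind[i] == "join") spans_new else spans_old
      partner_spans <- if (ev$kind[i] == "join") spans_old else spans_new
      a <- anchor_spans %>% filter(gene_id == ev$anchor_gene[i])
      partners <- unlist(ev$partner_genes[i])
      for (p in partners) {
        ps <- partner_spans %>% filter(gene_id == p)
        if (nrow(a) == 0 || nrow(ps) == 0 ||
            a$scaffold != ps$scaffold || a$strand != ps$strand ||
            a$cds_start > ps$cds_end || a$cds_end < ps$cds_start) {
          bad_events <- c(bad_events,
                          paste0(ev$anchor_gene[i], "~", p))
        }
      }
    }
  }
  note("event anchors overlap their partners' CDS", length(bad_events) == 0,
       paste(bad_events, collapse = ", "))

  rescue <- read_rescue_table(file.path(outdir, "rescue.tsv"))
  miss_rescue <- setdiff(rescue$gene_id, unique(old$gene_id))
  note("rescue-table genes exist in old.gff3", length(miss_rescue) == 0,
       paste(miss_rescue, collapse = ", "))

  bind_rows(res)
}
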