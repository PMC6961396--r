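## Shared builders and independent oracles for the test suite.
## The oracles deliberately use plain loops and direct definitions, not the
## package's own code paths.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
  library(purrr)
})

## ---- cached default fixture (generated once per test run) -------------

.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (!is.null(.fixture_cache$fx)) return(.fixture_cache$fx)
  dir <- file.path(tempdir(), "reannotr-fixture")
  res <- generate_fixture(sim_config(seed = 421), dir)
  genome <- read_genome_fasta(file.path(dir, "genome.fa"))
  old <- read_gff3(file.path(dir, "old.gff3"))
  new <- read_gff3(file.path(dir, "new.gff3"))
  cands <- read_intron_hints(file.path(dir, "hints.gff3"), genome)
  idx <- filter_candidates(cands)
  .fixture_cache$fx <- list(
    dir = dir, manifest = res$manifest, genome = genome,
    old = old, new = new, cands = cands, idx = idx,
    rescue = read_rescue_table(file.path(dir, "rescue.tsv"))
  )
  .fixture_cache$fx
}

## ---- small model builders --------------------------------------------

## a simple multi-exon coding gene; exons/CDS share coordinates except an
## optional 3'UTR tail on the last exon
simple_gene <- function(gene_id, scaffold, strand, exon_starts, exon_ends,
                        utr3 = 0L, tx = paste0(gene_id, ".t1")) {
  n <- length(exon_starts)
  rows <- list()
  for (i in seq_len(n)) {
    cds_end <- if (i == n) exon_ends[i] - utr3 else exon_ends[i]
    rows[[length(rows) + 1]] <- tibble(
      gene_id = gene_id, transcript_id = tx,
      type = c("exon", "CDS"), scaffold = scaffold, strand = strand,
      start = exon_starts[i], end = c(exon_ends[i], cds_end)
    )
  }
  bind_rows(rows)
}

## random valid gene models for round-trip properties
random_models <- function(n_genes = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (g in seq_len(n_genes)) {
    sc <- sample(c("scafA", "scafB"), 1)
    strand <- sample(c("+", "-"), 1)
    pos <- sample(1:5000, 1)
    n_ex <- sample(1:4, 1)
    starts <- integer(0); ends <- integer(0)
    for (i in seq_len(n_ex)) {
      w <- sample(30:90, 1)
      starts <- c(starts, pos)
      ends <- c(ends, pos + w - 1L)
      pos <- pos + w + sample(35:80, 1)
    }
    utr <- if (sample(c(TRUE, FALSE), 1)) sample(10:25, 1) else 0L
    id <- sprintf("rg%02d_%d", g, sample(1e4, 1))
    rows[[length(rows) + 1]] <-
      simple_gene(id, sc, strand, starts, ends, utr3 = utr)
  }
  gene_models(bind_rows(rows))
}

## genome of 'A's with chosen dinucleotides planted (for candidate tests)
plain_genome <- function(len = 1000, scaffold = "s1", plant = list()) {
  s <- strrep("A", len)
  for (p in plant) substr(s, p[[1]], p[[1]] + nchar(p[[2]]) - 1L) <- p[[2]]
  setNames(s, scaffold)
}

## support index row from explicit coordinates
idx_row <- function(scaffold, start, end, strand = "+", mult = 10L) {
  tibble(
    scaffold = scaffold, start = as.integer(start), end = as.integer(end),
    strand = strand, multiplicity = as.integer(mult),
    donor = "GT", acceptor = "AG",
    key = intron_key(scaffold, start, end, strand)
  )
}

## ---- independent oracles ---------------------------------------------

## brute-force seed-site scanner: direct substring comparison at every
## position, with the precedence rule applied literally
oracle_scan_utr <- function(utr, mature) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  rc <- function(x) {
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }
  utr <- chartr("Tt", "Uu", toupper(utr))
  mature <- chartr("Tt", "Uu", toupper(mature))
  s8 <- paste0(rc(substr(mature, 2, 8)), "A")
  s7m8 <- rc(substr(mature, 2, 8))
  s7a1 <- paste0(rc(substr(mature, 2, 7)), "A")
  hit <- function(pat) {
    k <- nchar(pat); L <- nchar(utr)
    out <- integer(0)
    for (p in seq_len(max(0L, L - k + 1L))) {
      if (substr(utr, p, p + k - 1L) == pat) out <- c(out, p)
    }
    out
  }
  p8 <- hit(s8)
  p7m8 <- setdiff(hit(s7m8), p8)
  p7a1 <- setdiff(hit(s7a1), p8 + 1L)
  tibble(
    position = c(p8, p7m8, p7a1),
    site_type = rep(c("8mer", "7m8", "7A1"),
                    c(length(p8), length(p7m8), length(p7a1)))
  ) %>% arrange(position, match(site_type, c("8mer", "7m8", "7A1")))
}

## quadratic all-pairs event oracle: CDS-segment intersection, same strand
oracle_events <- function(anchor_models, partner_models) {
  a_cds <- filter(anchor_models, type == "CDS")
  p_cds <- filter(partner_models, type == "CDS")
  anchors <- unique(a_cds$gene_id)
  out <- list()
  for (a in anchors) {
    arows <- a_cds[a_cds$gene_id == a, ]
    partners <- character(0)
    for (p in unique(p_cds$gene_id)) {
      prows <- p_cds[p_cds$gene_id == p, ]
      found <- FALSE
      for (i in seq_len(nrow(arows))) {
        for (j in seq_len(nrow(prows))) {
          if (arows$scaffold[i] == prows$scaffold[j] &&
              arows$strand[i] == prows$strand[j] &&
              arows$start[i] <= prows$end[j] &&
              arows$end[i] >= prows$start[j]) {
            found <- TRUE
          }
        }
      }
      if (found) partners <- c(partners, p)
    }
    if (length(partners) >= 2) {
      out[[length(out) + 1]] <- tibble(
        anchor_gene = a, partners = list(sort(partners))
      )
    }
  }
  bind_rows(out)
}

## rule-by-rule reference evaluator of the merge procedure
oracle_merge <- function(old_models, new_models, idx, rescue, cfg = merge_config()) {
  tx_introns <- function(models, gid) {
    ex <- models[models$gene_id == gid & models$type == "exon", ]
    out <- list()
    for (tx in unique(ex$transcript_id)) {
      e <- ex[ex$transcript_id == tx, ]
      e <- e[order(e$start), ]
      if (nrow(e) < 2) next
      for (i in seq_len(nrow(e) - 1)) {
        out[[length(out) + 1]] <- c(e$scaffold[1], e$end[i] + 1L,
                                    e$start[i + 1] - 1L, e$strand[1])
      }
    }
    out
  }
  in_idx <- function(intr) {
    any(idx$scaffold == intr[1] & idx$start == as.integer(intr[2]) &
          idx$end == as.integer(intr[3]) &
          (idx$strand == "*" | idx$strand == intr[4]))
  }
  key_of <- function(intr) paste(intr[1], intr[2], intr[3], sep = ":")
  cds_of <- function(models, gid) models[models$gene_id == gid & models$type == "CDS", ]
  overlaps <- function(models_a, ga, models_b, gb) {
    A <- cds_of(models_a, ga); B <- cds_of(models_b, gb)
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      if (A$scaffold[i] == B$scaffold[j] && A$strand[i] == B$strand[j] &&
          A$start[i] <= B$end[j] && A$end[i] >= B$start[j]) return(TRUE)
    }
    FALSE
  }
  old_ids <- old_models %>%
    group_by(gene_id) %>%
    summarise(scaffold = scaffold[1], start = min(start), .groups = "drop") %>%
    arrange(scaffold, start, gene_id) %>% pull(gene_id)
  new_ids <- unique(new_models$gene_id)
  displaced <- character(0)
  status <- character(0)
  for (g in old_ids) {
    G <- new_ids[vapply(new_ids, function(n)
      !(n %in% displaced) && overlaps(old_models, g, new_models, n),
      logical(1))]
    if (length(G) == 0) {
      ev <- rescue[rescue$gene_id == g, ]
      ok <- nrow(ev) == 1 &&
        (ev$has_homolog || ev$has_go_term || ev$fpkm >= cfg$fpkm_threshold)
      status[g] <- if (ok) "kept_rescued" else "dropped"
    } else {
      oi <- tx_introns(old_models, g)
      ni <- unlist(lapply(G, function(n) tx_introns(new_models, n)),
                   recursive = FALSE)
      oi_keys <- vapply(oi, key_of, character(1))
      ni_keys <- if (length(ni)) vapply(ni, key_of, character(1)) else character(0)
      cond1 <- any(vapply(oi, function(i)
        in_idx(i) && !(key_of(i) %in% ni_keys), logical(1)))
      cond2 <- all(vapply(ni, function(i)
        !in_idx(i) || key_of(i) %in% oi_keys, logical(1)))
      if (length(oi) == 0) cond1 <- FALSE
      if (length(ni) == 0) cond2 <- TRUE
      if (cond1 && cond2) {
        status[g] <- "kept_specific"
        displaced <- union(displaced, G)
      } else {
        status[g] <- "dropped"
      }
    }
  }
  list(status = status, displaced = sort(displaced))
}

## random micro-instance for the merge oracle (<= 6 genes on one scaffold)
random_merge_instance <- function() {
  mk_gene <- function(id, set) {
    pos <- sample(1:600, 1)
    n_ex <- sample(1:3, 1)
    starts <- integer(0); ends <- integer(0)
    for (i in seq_len(n_ex)) {
      w <- sample(20:50, 1)
      starts <- c(starts, pos); ends <- c(ends, pos + w - 1L)
      pos <- pos + w + sample(15:40, 1)
    }
    simple_gene(id, "s1", sample(c("+", "-"), 1), starts, ends)
  }
  n_old <- sample(0:3, 1); n_new <- sample(0:3, 1)
  old <- if (n_old > 0) gene_models(bind_rows(lapply(
    seq_len(n_old), function(i) mk_gene(sprintf("old%d", i), "old")
  ))) else gene_models(simple_gene("dummy", "s1", "+", 1, 30))[0, ]
  new <- if (n_new > 0) gene_models(bind_rows(lapply(
    seq_len(n_new), function(i) mk_gene(sprintf("new%d", i), "new")
  ))) else gene_models(simple_gene("dummy", "s1", "+", 1, 30))[0, ]
  introns <- bind_rows(
    if (nrow(old) > 0) transcript_introns(old),
    if (nrow(new) > 0) transcript_introns(new)
  )
  idx <- if (!is.null(introns) && nrow(introns) > 0) {
    picked <- introns[sample(c(TRUE, FALSE), nrow(introns), replace = TRUE), ]
    if (nrow(picked) > 0) {
      tibble(
        scaffold = picked$scaffold, start = picked$start, end = picked$end,
        strand = ifelse(runif(nrow(picked)) < 0.3, "*", picked$strand),
        multiplicity = sample(1:50, nrow(picked), replace = TRUE),
        donor = "GT", acceptor = "AG"
      ) %>% mutate(key = intron_key(scaffold, start, end, strand))
    } else idx_row("s1", 1, 2)[0, ]
  } else idx_row("s1", 1, 2)[0, ]
  rescue <- if (nrow(old) > 0) tibble(
    gene_id = unique(old$gene_id),
    has_homolog = sample(c(TRUE, FALSE), n_distinct(old$gene_id), TRUE),
    has_go_term = sample(c(TRUE, FALSE), n_distinct(old$gene_id), TRUE),
    fpkm = sample(c(0, 0.005, 0.01, 2), n_distinct(old$gene_id), TRUE)
  ) else tibble(gene_id = character(), has_homolog = logical(),
                has_go_term = logical(), fpkm = numeric())
  list(old = old, new = new, idx = idx, rescue = rescue)
}
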