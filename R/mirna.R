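## Seed-based microRNA target-site prediction in 3'UTRs and cross-species
## conserved-target analysis with a permutation null.
##
## The seed region is positions 2-8 of the mature miRNA. Site types, in
## decreasing strength, written 5'->3' in mRNA sense:
##   8mer  reverse complement of positions 2-8, followed by A
##   7m8   reverse complement of positions 2-8
##   7A1   reverse complement of positions 2-7, followed by A
## All matching is done in RNA space; U and T are interchangeable on input.

SITE_TYPES <- c("8mer", "7m8", "7A1")

#' Seed-site strings of a mature miRNA
#'
#' @param mature mature miRNA sequence, 5'->3', RNA or DNA alphabet,
#'   length >= 8.
#' @return named character vector with elements `8mer`, `7m8`, `7A1`
#'   (mRNA-sense RNA strings).
#' @examples
#' seed_site_strings("UGAGGUAGUAGGUUGUAUAGUU")  # let-7 family
#' @export
seed_site_strings <- function(mature) {
  mature <- toupper(dna_to_rna(mature))
  if (nchar(mature) < 8) {
    abort("mature miRNA must be at least 8 nt long")
  }
  if (grepl("[^ACGU]", mature)) {
    abort("mature miRNA contains characters outside {A,C,G,U}")
  }
  seed7 <- substr(mature, 2, 8)
  seed6 <- substr(mature, 2, 7)
  c(
    "8mer" = paste0(revcomp_rna(seed7), "A"),
    "7m8"  = revcomp_rna(seed7),
    "7A1"  = paste0(revcomp_rna(seed6), "A")
  )
}

#' Scan a 3'UTR for seed sites
#'
#' Reports every occurrence of a site string once, with the strongest
#' applicable type: an 8mer occurrence is not additionally reported as
#' 7m8 or 7A1. Overlapping occurrences are all reported.
#'
#' @param utr UTR sequence (RNA or DNA alphabet).
#' @param mature mature miRNA sequence (see [seed_site_strings()]).
#' @return tibble with `position` (1-based start of the site in the UTR)
#'   and `site_type`.
#' @export
scan_utr <- function(utr, mature) {
  utr <- toupper(dna_to_rna(utr))
  sites <- seed_site_strings(mature)
  ## exact matching of a short site string, overlapping occurrences
  ## included: compare every window of the UTR against the pattern
  find_all <- function(pattern) {
    k <- nchar(pattern)
    L <- nchar(utr)
    if (L < k) return(integer(0))
    st <- seq_len(L - k + 1L)
    st[substring(utr, st, st + k - 1L) == pattern]
  }
  p8 <- find_all(sites[["8mer"]])
  p7m8 <- setdiff(find_all(sites[["7m8"]]), p8)
  p7a1 <- find_all(sites[["7A1"]])
  p7a1 <- p7a1[!(p7a1 - 1L) %in% p8]
  out <- tibble(
    position = as.integer(c(p8, p7m8, p7a1)),
    site_type = rep(SITE_TYPES, times = c(length(p8), length(p7m8),
                                          length(p7a1)))
  )
  out[order(out$position, match(out$site_type, SITE_TYPES)), ]
}

#' Extract 3'UTR sequences from gene models
#'
#' The 3'UTR of a transcript is its spliced exonic sequence strictly
#' downstream (in transcript orientation) of the last CDS base,
#' transcribed to RNA. Transcripts without CDS are skipped with a warning;
#' empty UTRs are omitted.
#'
#' @param models a [gene_models] tibble.
#' @param genome named character vector of scaffold sequences.
#' @return named character vector of RNA strings keyed by transcript id.
#' @export
extract_3utrs <- function(models, genome) {
  txs <- models %>% distinct(gene_id, transcript_id)
  out <- character(0)
  skipped <- character(0)
  for (tx in txs$transcript_id) {
    cds <- models %>% filter(transcript_id == tx, type == "CDS")
    if (nrow(cds) == 0) {
      skipped <- c(skipped, tx)
      next
    }
    ex <- segments_in_orientation(models, tx, "exon")
    strand <- ex$strand[1]
    exon_lens <- ex$end - ex$start + 1L
    cum_before <- cumsum(c(0L, head(exon_lens, -1)))
    ## transcript coordinate of the last CDS base
    last_cds <- if (strand == "+") max(cds$end) else min(cds$start)
    seg_i <- which(
      if (strand == "+") ex$start <= last_cds & ex$end >= last_cds
      else ex$start <= last_cds & ex$end >= last_cds
    )
    offset_in_exon <- if (strand == "+") last_cds - ex$start[seg_i] + 1L
      else ex$end[seg_i] - last_cds + 1L
    tpos <- cum_before[seg_i] + offset_in_exon
    spliced <- spliced_seq(models, genome, tx, "exon")
    if (tpos >= nchar(spliced)) next  # CDS ends at transcript end
    out[[tx]] <- dna_to_rna(substr(spliced, tpos + 1L, nchar(spliced)))
  }
  if (length(skipped) > 0) {
    warn(paste0("transcript(s) without CDS skipped during UTR extraction: ",
                paste(skipped, collapse = ", ")))
  }
  out
}

#' Predict miRNA-target pairs
#'
#' Scans every UTR with every miRNA and deduplicates at the
#' (miRNA, gene) level across transcripts, aggregating site counts.
#'
#' @param mirnas tibble with columns `name`, `sequence`, or a named
#'   character vector of mature sequences.
#' @param utrs named character vector of UTR sequences keyed by
#'   transcript id (see [extract_3utrs()]).
#' @param tx2gene tibble with `transcript_id`, `gene_id`; if `NULL`, gene
#'   ids are derived by stripping a trailing `.t<digits>` suffix.
#' @return tibble with `mirna`, `gene_id`, `n_8mer`, `n_7m8`, `n_7A1`,
#'   `n_sites`; a pair is present iff at least one site of any type exists.
#' @export
predict_target_pairs <- function(mirnas, utrs, tx2gene = NULL) {
  if (!is.data.frame(mirnas)) {
    mirnas <- tibble(name = names(mirnas), sequence = unname(mirnas))
  }
  if (is.null(tx2gene)) {
    tx2gene <- tibble(
      transcript_id = names(utrs),
      gene_id = sub("\\.t[0-9]+$", "", names(utrs))
    )
  }
  hits <- list()
  for (i in seq_len(nrow(mirnas))) {
    for (tx in names(utrs)) {
      s <- scan_utr(utrs[[tx]], mirnas$sequence[i])
      if (nrow(s) == 0) next
      hits[[length(hits) + 1]] <- s %>%
        mutate(mirna = mirnas$name[i], transcript_id = tx)
    }
  }
  if (length(hits) == 0) {
    return(tibble(mirna = character(), gene_id = character(),
                  n_8mer = integer(), n_7m8 = integer(), n_7A1 = integer(),
                  n_sites = integer()))
  }
  bind_rows(hits) %>%
    left_join(tx2gene, by = "transcript_id") %>%
    group_by(mirna, gene_id) %>%
    summarise(
      n_8mer = sum(site_type == "8mer"),
      n_7m8 = sum(site_type == "7m8"),
      n_7A1 = sum(site_type == "7A1"),
      .groups = "drop"
    ) %>%
    mutate(n_sites = n_8mer + n_7m8 + n_7A1) %>%
    arrange(mirna, gene_id)
}

## orthologous pairs (gA, gB) with gA targeted in A and gB targeted in B
count_conserved_pairs <- function(targets_A, targets_B, orthology) {
  sum(orthology$gene_A %in% targets_A & orthology$gene_B %in% targets_B)
}

#' Conserved-target counts for homologous miRNA pairs
#'
#' For every homologous miRNA pair (all combinations when the homology map
#' is many-to-many), counts the orthologous gene pairs targeted in both
#' species; remaining targets are species-specific.
#'
#' @param pairs_A,pairs_B target-pair tibbles from
#'   [predict_target_pairs()] for the two species.
#' @param mirna_homology tibble with `mirna_A`, `mirna_B`.
#' @param orthology tibble with `gene_A`, `gene_B` (may be many-to-many).
#' @return tibble with one row per homologous miRNA pair: `mirna_A`,
#'   `mirna_B`, `n_targets_A`, `n_targets_B`, `n_conserved` (orthologous
#'   pair count), `n_A_only`, `n_B_only`.
#' @export
conserved_target_counts <- function(pairs_A, pairs_B, mirna_homology,
                                    orthology) {
  rows <- purrr::pmap(mirna_homology, function(mirna_A, mirna_B, ...) {
    tA <- unique(pairs_A$gene_id[pairs_A$mirna == mirna_A])
    tB <- unique(pairs_B$gene_id[pairs_B$mirna == mirna_B])
    conserved <- orthology %>%
      filter(gene_A %in% tA, gene_B %in% tB)
    tibble(
      mirna_A = mirna_A, mirna_B = mirna_B,
      n_targets_A = length(tA), n_targets_B = length(tB),
      n_conserved = nrow(conserved),
      n_A_only = length(setdiff(tA, conserved$gene_A)),
      n_B_only = length(setdiff(tB, conserved$gene_B))
    )
  })
  bind_rows(rows)
}

#' Permutation p-value for conserved-target counts
#'
#' Holds one species' target set fixed and resamples the other species'
#' targets (same size, without replacement) from the orthologous-gene
#' universe; the p-value is `(r + 1) / (n_perm + 1)` where `r` counts
#' permutations whose conserved-pair count is at least the observed one.
#'
#' @param targets_A,targets_B character vectors of targeted gene ids in
#'   species A and B.
#' @param orthology tibble with `gene_A`, `gene_B`.
#' @param universe character vector of genes to resample from (defaults to
#'   the distinct genes of the resampled species in `orthology`).
#' @param n_perm number of permutations.
#' @param resample which side to resample (`"B"` default, or `"A"`).
#' @param seed optional integer; when given, the draw is made under a
#'   local RNG scope so results are reproducible without touching the
#'   caller's RNG state.
#' @return object of class `permutation_test`: list with `observed`,
#'   `p_value`, `n_perm`, `n_at_least`, `resample`.
#' @export
permutation_pvalue <- function(targets_A, targets_B, orthology,
                               universe = NULL, n_perm = 1000,
                               resample = c("B", "A"), seed = NULL) {
  resample <- match.arg(resample)
  if (resample == "A") {
    ## symmetric case: swap the roles
    orthology <- orthology %>% rename(gene_A = gene_B, gene_B = gene_A)
    tmp <- targets_A; targets_A <- targets_B; targets_B <- tmp
  }
  if (is.null(universe)) universe <- unique(orthology$gene_B)
  k <- length(unique(targets_B))
  if (k > length(universe)) {
    abort("resampled target set larger than the ortholog universe")
  }
  observed <- count_conserved_pairs(targets_A, targets_B, orthology)
  ## precompute: orthology rows anchored in A's fixed targets
  gB_hits <- orthology$gene_B[orthology$gene_A %in% targets_A]
  gB_idx <- match(gB_hits, universe)
  gB_idx <- gB_idx[!is.na(gB_idx)]
  n_universe <- length(universe)
  draw <- function() {
    mask <- logical(n_universe)
    mask[sample.int(n_universe, k)] <- TRUE
    sum(mask[gB_idx])
  }
  run <- function() vapply(seq_len(n_perm), function(i) draw(), integer(1))
  counts <- if (is.null(seed)) run() else with_seed(seed, run())
  r <- sum(counts >= observed)
  structure(list(
    observed = observed,
    p_value = (r + 1) / (n_perm + 1),
    n_perm = n_perm,
    n_at_least = r,
    resample = resample
  ), class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    "# permutation_test: observed %d conserved pairs, p = %.4g (%d permutations, side %s)\n",
    x$observed, x$p_value, x$n_perm, x$resample
  ))
  invisible(x)
}

#' @rdname permutation_pvalue
#' @param x a `permutation_test`.
#' @param ... unused.
#' @export
glance.permutation_test <- function(x, ...) {
  tibble(observed = x$observed, p_value = x$p_value, n_perm = x$n_perm,
         n_at_least = x$n_at_least, resample = x$resample)
}

#' Cross-species conservation analysis of miRNA targets
#'
#' Combines [conserved_target_counts()] with a permutation p-value per
#' homologous miRNA pair.
#'
#' @inheritParams conserved_target_counts
#' @inheritParams permutation_pvalue
#' @return a `conservation_result` tibble: the counts of
#'   [conserved_target_counts()] plus `p_value`. Supports [autoplot()].
#' @export
conservation_analysis <- function(pairs_A, pairs_B, mirna_homology,
                                  orthology, universe = NULL,
                                  n_perm = 1000, resample = c("B", "A"),
                                  seed = NULL) {
  resample <- match.arg(resample)
  counts <- conserved_target_counts(pairs_A, pairs_B, mirna_homology,
                                    orthology)
  seeds <- if (is.null(seed)) rep(list(NULL), nrow(counts)) else
    as.list(seed + seq_len(nrow(counts)))
  counts$p_value <- vapply(seq_len(nrow(counts)), function(i) {
    tA <- unique(pairs_A$gene_id[pairs_A$mirna == counts$mirna_A[i]])
    tB <- unique(pairs_B$gene_id[pairs_B$mirna == counts$mirna_B[i]])
    permutation_pvalue(tA, tB, orthology, universe = universe,
                       n_perm = n_perm, resample = resample,
                       seed = seeds[[i]])$p_value
  }, numeric(1))
  class(counts) <- c("conservation_result", class(counts))
  counts
}
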