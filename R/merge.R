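## Integration of an old ("previous official") gene set with a new
## prediction set. An old gene that overlaps new genes is kept only when it
## is *specifically supported*: it owns at least one RNA-Seq-supported
## intron that none of the overlapping new genes have, while every
## supported intron of those new genes is also present in it. Old genes
## with no overlapping new gene are kept when rescue evidence (homology,
## GO annotation, or RNA-Seq coverage at FPKM >= threshold) exists.

#' Merge configuration
#'
#' @param fpkm_threshold minimum FPKM for the coverage rescue criterion
#'   (boundary inclusive).
#' @param overlap_mode how gene overlap is determined when building the set
#'   of overlapping new genes; currently only `"cds_same_strand"`
#'   (CDS-interval intersection on the same scaffold and strand).
#' @return a `merge_config` list.
#' @export
merge_config <- function(fpkm_threshold = 0.01,
                         overlap_mode = "cds_same_strand") {
  stopifnot(fpkm_threshold >= 0)
  overlap_mode <- match.arg(overlap_mode, "cds_same_strand")
  structure(list(fpkm_threshold = fpkm_threshold,
                 overlap_mode = overlap_mode),
            class = "merge_config")
}

## GRanges of CDS segments carrying gene ids (strand-aware); a shared
## seqlevels set avoids seqlevel-mismatch warnings in findOverlaps
cds_granges <- function(models, seqlevels = unique(models$scaffold)) {
  cds <- models %>% filter(type == "CDS")
  GenomicRanges::GRanges(
    seqnames = factor(cds$scaffold, levels = seqlevels),
    ranges = IRanges::IRanges(cds$start, cds$end),
    strand = cds$strand,
    gene_id = cds$gene_id
  )
}

#' Gene pairs with CDS overlap on the same strand
#'
#' @param query_models,subject_models [gene_models] tibbles.
#' @return tibble with `query_gene`, `subject_gene`, one row per
#'   overlapping gene pair.
#' @export
cds_overlap_pairs <- function(query_models, subject_models) {
  lev <- union(unique(query_models$scaffold), unique(subject_models$scaffold))
  qg <- cds_granges(query_models, lev)
  sg <- cds_granges(subject_models, lev)
  if (length(qg) == 0 || length(sg) == 0) {
    return(tibble(query_gene = character(), subject_gene = character()))
  }
  hits <- GenomicRanges::findOverlaps(qg, sg)
  tibble(
    query_gene = qg$gene_id[S4Vectors::queryHits(hits)],
    subject_gene = sg$gene_id[S4Vectors::subjectHits(hits)]
  ) %>%
    distinct() %>%
    arrange(query_gene, subject_gene)
}

#' New genes overlapping an old gene
#'
#' @param old_gene_id id of a gene in `old_models`.
#' @param old_models,new_models [gene_models] tibbles.
#' @param cfg a [merge_config].
#' @return character vector of overlapping new gene ids.
#' @export
overlapping_new_genes <- function(old_gene_id, old_models, new_models,
                                  cfg = merge_config()) {
  pairs <- cds_overlap_pairs(
    old_models %>% filter(gene_id == old_gene_id), new_models
  )
  pairs$subject_gene
}

#' Rescue eligibility of isolated old genes
#'
#' @param evidence tibble with columns `has_homolog`, `has_go_term`,
#'   `fpkm` (one row per gene; see [rescue_for_genes()]).
#' @param cfg a [merge_config].
#' @return logical vector: homolog OR GO term OR FPKM >= threshold.
#' @export
rescue_eligible <- function(evidence, cfg = merge_config()) {
  evidence$has_homolog | evidence$has_go_term |
    evidence$fpkm >= cfg$fpkm_threshold
}

#' Specific-support test for one old gene
#'
#' `TRUE` iff (1) the old gene has at least one supported intron that none
#' of the overlapping new genes have, and (2) every supported intron of the
#' overlapping new genes is also an intron of the old gene. Intron sets are
#' unions over all isoforms.
#'
#' @param old_keys intron keys of the old gene (all isoforms).
#' @param new_keys intron keys of the overlapping new genes (union).
#' @param supported_keys keys present in the support index.
#' @return a single logical.
#' @export
is_specifically_supported <- function(old_keys, new_keys, supported_keys) {
  old_supported <- intersect(old_keys, supported_keys)
  new_supported <- intersect(new_keys, supported_keys)
  length(setdiff(old_supported, new_keys)) > 0 &&
    length(setdiff(new_supported, old_keys)) == 0
}

## per-gene intron keys, all and supported, from one intron computation
gene_intron_keys2 <- function(models, idx) {
  gi <- gene_introns(models)
  lev <- unique(models$gene_id)
  sup <- match_support(gi, idx)
  list(
    all = split(gi$key, factor(gi$gene_id, levels = lev)),
    sup = split(sup$key, factor(sup$gene_id, levels = lev))
  )
}

#' Merge an old and a new gene set
#'
#' Old genes are processed in coordinate order. An old gene overlapping at
#' least one not-yet-displaced new gene is kept iff it is specifically
#' supported, in which case all overlapping new genes are displaced
#' (removed globally); otherwise it is dropped. An old gene with no
#' overlapping new gene is kept iff rescue evidence applies. All new genes
#' never displaced are kept.
#'
#' @param old_models,new_models [gene_models] tibbles (gene ids must be
#'   unique across the two sets).
#' @param idx support index from [filter_candidates()].
#' @param rescue rescue-evidence tibble (see [read_rescue_table()]); may be
#'   `NULL`.
#' @param cfg a [merge_config].
#' @return an object of class `merge_result`: a list with `merged` (the
#'   merged [gene_models] tibble), `decisions` (one row per old gene:
#'   `old_gene_id`, `status` in `kept_specific` / `kept_rescued` /
#'   `dropped`, `displaced_new_ids` list-column, `reason`), and
#'   `displaced_new` (character vector). Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
merge_gene_sets <- function(old_models, new_models, idx, rescue = NULL,
                            cfg = merge_config()) {
  dup <- intersect(unique(old_models$gene_id), unique(new_models$gene_id))
  if (length(dup) > 0) {
    abort(paste0("gene id(s) present in both sets: ",
                 paste(dup, collapse = ", ")))
  }
  old_ids <- if (nrow(old_models) == 0) character(0) else {
    old_models %>%
      group_by(gene_id) %>%
      summarise(scaffold = scaffold[1], start = min(start), .groups = "drop") %>%
      arrange(scaffold, start, gene_id) %>%
      pull(gene_id)
  }

  pairs <- cds_overlap_pairs(old_models, new_models)
  overlap_map <- split(pairs$subject_gene, factor(pairs$query_gene, levels = old_ids))

  ok <- gene_intron_keys2(old_models, idx)
  nk <- gene_intron_keys2(new_models, idx)
  old_keys <- ok$all; old_sup <- ok$sup
  new_keys <- nk$all; new_sup <- nk$sup

  ev <- rescue_for_genes(old_ids, rescue)
  ev_ok <- setNames(rescue_eligible(ev, cfg), ev$gene_id)

  displaced <- character(0)
  decisions <- vector("list", length(old_ids))
  for (i in seq_along(old_ids)) {
    g <- old_ids[i]
    G <- setdiff(overlap_map[[g]] %||% character(0), displaced)
    if (length(G) == 0) {
      if (isTRUE(ev_ok[[g]])) {
        decisions[[i]] <- tibble(
          old_gene_id = g, status = "kept_rescued",
          displaced_new_ids = list(character(0)),
          reason = "no overlapping new gene; rescue evidence present"
        )
      } else {
        decisions[[i]] <- tibble(
          old_gene_id = g, status = "dropped",
          displaced_new_ids = list(character(0)),
          reason = "no overlapping new gene; no rescue evidence"
        )
      }
    } else {
      g_new_keys <- unique(unlist(new_keys[G], use.names = FALSE))
      g_new_sup <- unique(unlist(new_sup[G], use.names = FALSE))
      specific <- is_specifically_supported_keys(
        old_all = old_keys[[g]], old_sup = old_sup[[g]],
        new_all = g_new_keys, new_sup = g_new_sup
      )
      if (specific) {
        displaced <- union(displaced, G)
        decisions[[i]] <- tibble(
          old_gene_id = g, status = "kept_specific",
          displaced_new_ids = list(sort(G)),
          reason = "specifically supported; overlapping new genes displaced"
        )
      } else {
        decisions[[i]] <- tibble(
          old_gene_id = g, status = "dropped",
          displaced_new_ids = list(character(0)),
          reason = "overlapped by new gene(s) without specific support"
        )
      }
    }
  }
  decisions <- bind_rows(c(list(tibble(
    old_gene_id = character(), status = character(),
    displaced_new_ids = list(), reason = character()
  )), decisions))
  kept_old <- decisions$old_gene_id[decisions$status != "dropped"]
  merged <- bind_rows(
    old_models %>% filter(gene_id %in% kept_old),
    new_models %>% filter(!gene_id %in% displaced)
  )
  ## inputs were validated; the merged subset is canonicalized, not revalidated
  merged <- if (nrow(merged) > 0) canonical_order(merged) else merged
  structure(list(
    merged = merged,
    decisions = decisions,
    displaced_new = sort(displaced)
  ), class = "merge_result")
}

## key-level variant of the specific-support rule used internally: strand
## wildcards were already resolved when old_sup/new_sup were computed
is_specifically_supported_keys <- function(old_all, old_sup, new_all, new_sup) {
  length(setdiff(old_sup, new_all)) > 0 &&
    length(setdiff(new_sup, old_all)) == 0
}

#' @export
print.merge_result <- function(x, ...) {
  cat("# merge_result\n")
  print(glance(x))
  invisible(x)
}

#' @rdname merge_gene_sets
#' @param x a `merge_result`.
#' @param ... unused.
#' @export
tidy.merge_result <- function(x, ...) {
  x$decisions %>%
    mutate(n_displaced = lengths(displaced_new_ids))
}

#' @rdname merge_gene_sets
#' @export
glance.merge_result <- function(x, ...) {
  tibble(
    n_old = nrow(x$decisions),
    n_kept_specific = sum(x$decisions$status == "kept_specific"),
    n_kept_rescued = sum(x$decisions$status == "kept_rescued"),
    n_dropped = sum(x$decisions$status == "dropped"),
    n_new_displaced = length(x$displaced_new),
    n_merged_genes = n_distinct(x$merged$gene_id)
  )
}
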