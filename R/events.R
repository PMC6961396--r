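## Structural comparison of two gene sets: join/split events with RNA-Seq
## support, and identical / near-identical / new / lost correspondence via
## protein comparison.

## shared core: one event per anchor gene whose CDS overlaps the CDSs of
## >= 2 partner genes on the same strand; supported iff a supported intron
## of the anchor covers the inter-partner CDS gap of at least one adjacent
## partner pair
detect_events_core <- function(anchor_models, partner_models, idx, kind) {
  pairs <- cds_overlap_pairs(anchor_models, partner_models)
  if (nrow(pairs) == 0) return(empty_events())
  spans <- gene_cds_spans(partner_models)
  anchors <- pairs %>%
    count(query_gene) %>%
    filter(n >= 2) %>%
    pull(query_gene)
  if (length(anchors) == 0) return(empty_events())
  anchor_sup <- anchor_models %>%
    filter(gene_id %in% anchors) %>%
    gene_introns() %>%
    match_support(idx)
  ev <- lapply(anchors, function(a) {
    partners <- pairs %>%
      filter(query_gene == a) %>%
      inner_join(spans, by = c(subject_gene = "gene_id")) %>%
      arrange(cds_start, subject_gene)
    sup <- anchor_sup %>% filter(gene_id == a)
    bridges <- character(0)
    if (nrow(partners) >= 2 && nrow(sup) > 0) {
      for (i in seq_len(nrow(partners) - 1)) {
        gap_start <- partners$cds_end[i] + 1L
        gap_end <- partners$cds_start[i + 1] - 1L
        if (gap_start > gap_end) next
        cov <- sup$start <= gap_start & sup$end >= gap_end
        bridges <- union(bridges, sup$key[cov])
      }
    }
    tibble(
      kind = kind,
      anchor_gene = a,
      partner_genes = list(partners$subject_gene),
      n_partners = nrow(partners),
      supported = length(bridges) > 0,
      supporting_introns = list(sort(bridges))
    )
  })
  bind_rows(ev) %>% arrange(anchor_gene)
}

empty_events <- function() {
  tibble(
    kind = character(), anchor_gene = character(),
    partner_genes = list(), n_partners = integer(),
    supported = logical(), supporting_introns = list()
  )
}

#' Detect gene join events
#'
#' A join is a new gene whose CDS overlaps the CDSs of two or more old
#' genes on the same strand; it is supported when a supported intron of the
#' new gene spans the gap between two neighbouring old genes.
#'
#' @param old_models,new_models [gene_models] tibbles.
#' @param idx support index from [filter_candidates()].
#' @return tibble with one row per event: `kind`, `anchor_gene` (the new
#'   gene), `partner_genes` (list-column, coordinate order), `n_partners`,
#'   `supported`, `supporting_introns` (list-column of intron keys).
#' @export
detect_join_events <- function(old_models, new_models, idx) {
  detect_events_core(new_models, old_models, idx, "join")
}

#' Detect gene split events
#'
#' A split is an old gene whose CDS overlaps the CDSs of two or more new
#' genes on the same strand; it is supported when a supported intron of the
#' old gene spans the gap between adjacent new genes (suggesting that the
#' old joined annotation was the correct one).
#'
#' @inheritParams detect_join_events
#' @return as [detect_join_events()], anchored on the old gene.
#' @export
detect_split_events <- function(old_models, new_models, idx) {
  detect_events_core(old_models, new_models, idx, "split")
}

## ---------------------------------------------------------------------
## protein comparison

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

aa_unit_matrix <- local({
  m <- matrix(0L, length(AA_ALPHABET), length(AA_ALPHABET),
              dimnames = list(AA_ALPHABET, AA_ALPHABET))
  diag(m) <- 1L
  m
})

#' Identity and coverage of a protein pair
#'
#' Global alignment with free end gaps (match +1, mismatch 0, gap -1).
#' Identity is the fraction of identical columns among aligned
#' (both-non-gap) columns; coverage is the number of aligned columns
#' divided by the length of the *old* protein, which acts as the
#' reference.
#'
#' @param p_old,p_new amino-acid strings (standard 20 letters plus X).
#' @return named numeric vector `c(identity = , coverage = )`.
#' @export
protein_identity_coverage <- function(p_old, p_new) {
  if (!nzchar(p_old) || !nzchar(p_new)) {
    abort("protein_identity_coverage(): empty sequence")
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p_old), Biostrings::AAString(p_new),
    type = "overlap", substitutionMatrix = aa_unit_matrix,
    gapOpening = 0, gapExtension = 1
  )
  a <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
  b <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
  both <- a != "-" & b != "-"
  n_aligned <- sum(both)
  if (n_aligned == 0) {
    return(c(identity = 0, coverage = 0))
  }
  c(
    identity = sum(a[both] == b[both]) / n_aligned,
    coverage = n_aligned / nchar(p_old)
  )
}

#' Translate the longest isoform of every gene
#'
#' Spliced CDS sequences are translated with the standard genetic code; a
#' terminal stop codon is removed and internal stops are rendered as `X`
#' and counted. A trailing incomplete codon (CDS length not a multiple of
#' three) is trimmed and flagged.
#'
#' @param models a [gene_models] tibble.
#' @param genome named character vector of scaffold sequences.
#' @return tibble with `gene_id`, `transcript_id`, `protein`,
#'   `n_internal_stops`, `incomplete_codon`.
#' @export
translate_genes <- function(models, genome) {
  iso <- longest_isoforms(models)
  rows <- purrr::pmap(iso, function(gene_id, transcript_id, cds_len) {
    seq <- spliced_seq(models, genome, transcript_id, "CDS")
    trimmed <- nchar(seq) %% 3L != 0L
    if (trimmed) seq <- substr(seq, 1L, nchar(seq) - nchar(seq) %% 3L)
    if (nchar(seq) == 0) {
      return(tibble(gene_id = gene_id, transcript_id = transcript_id,
                    protein = "", n_internal_stops = 0L,
                    incomplete_codon = trimmed))
    }
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(seq), if.fuzzy.codon = "X"
    ))
    if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
    n_stop <- stringr::str_count(aa, stringr::fixed("*"))
    aa <- gsub("*", "X", aa, fixed = TRUE)
    tibble(gene_id = gene_id, transcript_id = transcript_id, protein = aa,
           n_internal_stops = n_stop, incomplete_codon = trimmed)
  })
  bind_rows(rows)
}

#' Classify gene correspondence between two annotation versions
#'
#' Every new gene is compared against the proteins of old genes whose CDS
#' it overlaps on the same strand: exact protein equality gives class
#' `identical`; otherwise the best overlapping pair reaching both the
#' identity and coverage thresholds gives `near_identical`. New genes
#' whose overlaps all stay below the thresholds are `restructured` under
#' the default novelty rule (`"overlap"`), where `new` means no CDS
#' overlap with any old gene at all and `lost` means an old gene with no
#' overlapping new gene. With `novelty = "threshold"`, sub-threshold
#' overlaps count as `new`/`lost` as well (the counting used for
#' genome-wide new/lost gene tallies).
#'
#' @param old_models,new_models [gene_models] tibbles.
#' @param proteins named character vector (or tibble with `gene_id`,
#'   `protein`) mapping every gene id in both sets to its protein; see
#'   [translate_genes()].
#' @param min_identity,min_coverage classification thresholds (boundary
#'   inclusive).
#' @param novelty `"overlap"` (default) or `"threshold"`; see above.
#' @return an object of class `correspondence_report`: list with
#'   `new_classes` (per new gene: `gene_id`, `class`, `matched_old`,
#'   `identity`, `coverage`), `lost_genes`, `thresholds`, `novelty`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
classify_correspondence <- function(old_models, new_models, proteins,
                                    min_identity = 0.95,
                                    min_coverage = 0.95,
                                    novelty = c("overlap", "threshold")) {
  novelty <- match.arg(novelty)
  if (is.data.frame(proteins)) {
    proteins <- setNames(proteins$protein, proteins$gene_id)
  }
  new_ids <- unique(new_models$gene_id)
  old_ids <- unique(old_models$gene_id)
  missing_prot <- setdiff(c(new_ids, old_ids), names(proteins))
  if (length(missing_prot) > 0) {
    abort(paste0("missing protein for gene(s): ",
                 paste(missing_prot, collapse = ", ")))
  }
  pairs <- cds_overlap_pairs(new_models, old_models)
  old_order <- gene_cds_spans(old_models) %>%
    arrange(scaffold, cds_start, gene_id) %>%
    pull(gene_id)

  rows <- lapply(new_ids, function(g) {
    cands <- pairs$subject_gene[pairs$query_gene == g]
    cands <- old_order[old_order %in% cands]
    if (length(cands) == 0) {
      return(tibble(gene_id = g, class = "new", matched_old = NA_character_,
                    identity = NA_real_, coverage = NA_real_))
    }
    p_new <- proteins[[g]]
    exact <- cands[proteins[cands] == p_new]
    if (length(exact) > 0) {
      return(tibble(gene_id = g, class = "identical", matched_old = exact[1],
                    identity = 1, coverage = 1))
    }
    sc <- t(vapply(cands, function(o) {
      protein_identity_coverage(proteins[[o]], p_new)
    }, numeric(2)))
    ok <- sc[, "identity"] >= min_identity & sc[, "coverage"] >= min_coverage
    if (any(ok)) {
      best <- which(ok)[order(-sc[ok, "identity"], -sc[ok, "coverage"])][1]
      return(tibble(gene_id = g, class = "near_identical",
                    matched_old = cands[best],
                    identity = unname(sc[best, "identity"]),
                    coverage = unname(sc[best, "coverage"])))
    }
    best <- order(-sc[, "identity"], -sc[, "coverage"])[1]
    tibble(
      gene_id = g,
      class = if (novelty == "overlap") "restructured" else "new",
      matched_old = cands[best],
      identity = unname(sc[best, "identity"]),
      coverage = unname(sc[best, "coverage"])
    )
  })
  new_classes <- bind_rows(rows)

  if (novelty == "overlap") {
    overlapped_old <- unique(pairs$subject_gene)
  } else {
    overlapped_old <- unique(new_classes$matched_old[
      new_classes$class %in% c("identical", "near_identical")
    ])
  }
  lost <- sort(setdiff(old_ids, overlapped_old))

  structure(list(
    new_classes = new_classes,
    lost_genes = lost,
    thresholds = c(identity = min_identity, coverage = min_coverage),
    novelty = novelty
  ), class = "correspondence_report")
}

#' @export
print.correspondence_report <- function(x, ...) {
  cat("# correspondence_report\n")
  print(glance(x))
  invisible(x)
}

#' @rdname classify_correspondence
#' @param x a `correspondence_report`.
#' @param ... unused.
#' @export
tidy.correspondence_report <- function(x, ...) {
  bind_rows(
    x$new_classes %>% mutate(set = "new"),
    tibble(gene_id = x$lost_genes, class = "lost",
           matched_old = NA_character_, identity = NA_real_,
           coverage = NA_real_, set = "old")
  )
}

#' @rdname classify_correspondence
#' @export
glance.correspondence_report <- function(x, ...) {
  cl <- x$new_classes$class
  tibble(
    n_identical = sum(cl == "identical"),
    n_near_identical = sum(cl == "near_identical"),
    n_restructured = sum(cl == "restructured"),
    n_new = sum(cl == "new"),
    n_lost = length(x$lost_genes),
    novelty = x$novelty
  )
}
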