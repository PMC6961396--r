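## Annotation QC metrics for a gene set, and the spliced in-frame stop
## validator.

## an intron is a "CDS intron" iff both flanking exons contain CDS bases
cds_introns <- function(models, per_gene = TRUE) {
  ex <- models %>%
    filter(type == "exon") %>%
    arrange(transcript_id, start) %>%
    group_by(transcript_id) %>%
    mutate(exon_n = row_number()) %>%
    ungroup()
  cds <- models %>% filter(type == "CDS")
  ## exon "contains CDS bases": some CDS segment of the same transcript
  ## intersects the exon
  coding_exon <- ex %>%
    left_join(cds %>% select(transcript_id, c_start = start, c_end = end),
              by = "transcript_id", relationship = "many-to-many") %>%
    group_by(transcript_id, exon_n) %>%
    summarise(coding = any(!is.na(c_start) & c_start <= end & c_end >= start),
              .groups = "drop")
  intr <- ex %>%
    group_by(gene_id, transcript_id, scaffold, strand) %>%
    reframe(
      i_start = head(end, -1) + 1L, i_end = tail(start, -1) - 1L,
      left_exon = head(exon_n, -1), right_exon = tail(exon_n, -1)
    ) %>%
    rename(start = i_start, end = i_end) %>%
    left_join(coalesce_coding(coding_exon), by = c("transcript_id", left_exon = "exon_n")) %>%
    rename(left_coding = coding) %>%
    left_join(coalesce_coding(coding_exon), by = c("transcript_id", right_exon = "exon_n")) %>%
    rename(right_coding = coding) %>%
    filter(left_coding & right_coding) %>%
    mutate(key = intron_key(scaffold, start, end, strand))
  if (per_gene) {
    intr %>% distinct(gene_id, scaffold, strand, start, end, key)
  } else {
    intr %>% select(gene_id, transcript_id, scaffold, strand, start, end, key)
  }
}

coalesce_coding <- function(x) x %>% select(transcript_id, exon_n, coding)

#' Summary metrics for a gene set
#'
#' Computes the standard annotation-improvement metrics: number of genes,
#' average coding length (total CDS of the longest isoform, mean over
#' genes), mean number of coding exons per transcript, GC content of the
#' concatenated coding sequence (reported as a fraction), fraction of
#' single-exon genes (genes whose every transcript has one exon), number
#' of CDS introns (UTR-only introns excluded; reported both as the union
#' over all isoforms and restricted to the longest isoform), fraction of
#' CDS introns present in the support index, mean CDS intron length, and
#' the isoform-count histogram.
#'
#' @param models a [gene_models] tibble.
#' @param genome named character vector of scaffold sequences.
#' @param idx support index from [filter_candidates()].
#' @return a `geneset_summary`: a one-row tibble of metrics, with the
#'   isoform histogram attached as the attribute `"isoform_histogram"`.
#'   Genes without any CDS are excluded (with a message).
#' @export
geneset_summary <- function(models, genome, idx) {
  coding_genes <- unique(models$gene_id[models$type == "CDS"])
  no_cds <- setdiff(unique(models$gene_id), coding_genes)
  if (length(no_cds) > 0) {
    inform(sprintf("excluding %d gene(s) without CDS from the summary",
                   length(no_cds)))
    models <- models %>% filter(gene_id %in% coding_genes)
  }
  iso <- longest_isoforms(models)
  avg_coding_length <- mean(iso$cds_len)

  cds_exons_per_tx <- models %>%
    filter(type == "CDS") %>%
    count(transcript_id) %>%
    pull(n) %>%
    mean()

  coding_seq <- vapply(iso$transcript_id, function(tx) {
    spliced_seq(models, genome, tx, "CDS")
  }, character(1))
  all_cds <- paste(coding_seq, collapse = "")
  gc_content <- stringr::str_count(all_cds, "[GC]") / nchar(all_cds)

  single_exon <- models %>%
    filter(type == "exon") %>%
    count(gene_id, transcript_id) %>%
    group_by(gene_id) %>%
    summarise(single = all(n == 1L), .groups = "drop")
  frac_single <- mean(single_exon$single)

  ci_all <- cds_introns(models, per_gene = TRUE) %>%
    distinct(scaffold, strand, start, end, key)
  ci_longest <- cds_introns(models, per_gene = FALSE) %>%
    semi_join(iso, by = "transcript_id") %>%
    distinct(scaffold, strand, start, end, key)
  sup <- match_support(ci_all, idx)
  frac_supported <- if (nrow(ci_all) > 0) nrow(sup) / nrow(ci_all) else NA_real_
  avg_intron_len <- if (nrow(ci_all) > 0) {
    mean(ci_all$end - ci_all$start + 1L)
  } else NA_real_

  hist <- isoform_distribution(models)
  out <- tibble(
    n_genes = length(coding_genes),
    avg_coding_length = avg_coding_length,
    coding_exons_per_transcript = cds_exons_per_tx,
    gc_content_coding = gc_content,
    fraction_single_exon_genes = frac_single,
    n_introns_cds = nrow(ci_all),
    n_introns_cds_longest = nrow(ci_longest),
    fraction_supported_introns = frac_supported,
    avg_intron_length = avg_intron_len
  )
  attr(out, "isoform_histogram") <- hist
  class(out) <- c("geneset_summary", class(out))
  out
}

#' Isoform-count distribution
#'
#' @param models a [gene_models] tibble.
#' @return tibble with `n_isoforms`, `n_genes`, `fraction`.
#' @export
isoform_distribution <- function(models) {
  if (nrow(models) == 0) {
    return(tibble(n_isoforms = integer(), n_genes = integer(),
                  fraction = numeric()))
  }
  models %>%
    distinct(gene_id, transcript_id) %>%
    count(gene_id, name = "n_isoforms") %>%
    count(n_isoforms, name = "n_genes") %>%
    mutate(fraction = n_genes / sum(n_genes))
}

#' Find transcripts with a premature stop codon in the spliced CDS
#'
#' Flags transcripts whose spliced coding sequence contains a stop codon
#' before the final codon, annotating whether the offending codon is split
#' across an intron (its bases fall in more than one CDS segment) or lies
#' inside one exon. Transcripts whose spliced CDS length is not a multiple
#' of three are reported separately.
#'
#' @param models a [gene_models] tibble.
#' @param genome named character vector of scaffold sequences.
#' @return tibble with `gene_id`, `transcript_id`, `issue`
#'   (`"premature_stop"` or `"cds_length_not_multiple_of_3"`),
#'   `codon_index`, `stop_codon`, `split_across_intron`.
#' @export
find_spliced_inframe_stops <- function(models, genome) {
  txs <- models %>% filter(type == "CDS") %>% distinct(gene_id, transcript_id)
  out <- list()
  for (i in seq_len(nrow(txs))) {
    tx <- txs$transcript_id[i]
    seg <- segments_in_orientation(models, tx, "CDS")
    seq <- spliced_seq(models, genome, tx, "CDS")
    L <- nchar(seq)
    if (L %% 3L != 0L) {
      out[[length(out) + 1]] <- tibble(
        gene_id = txs$gene_id[i], transcript_id = tx,
        issue = "cds_length_not_multiple_of_3",
        codon_index = NA_integer_, stop_codon = NA_character_,
        split_across_intron = NA
      )
      next
    }
    codons <- codon_split(seq)
    prem <- which(codons %in% stop_codons)
    prem <- prem[prem < length(codons)]
    if (length(prem) == 0) next
    seg_ends <- cumsum(seg$end - seg$start + 1L)
    for (ci in prem) {
      first_base <- (ci - 1L) * 3L + 1L
      last_base <- first_base + 2L
      seg_first <- findInterval(first_base - 1L, seg_ends) + 1L
      seg_last <- findInterval(last_base - 1L, seg_ends) + 1L
      out[[length(out) + 1]] <- tibble(
        gene_id = txs$gene_id[i], transcript_id = tx,
        issue = "premature_stop",
        codon_index = ci, stop_codon = codons[ci],
        split_across_intron = seg_last > seg_first
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(
      gene_id = character(), transcript_id = character(), issue = character(),
      codon_index = integer(), stop_codon = character(),
      split_across_intron = logical()
    ))
  }
  bind_rows(out)
}

#' @export
print.geneset_summary <- function(x, ...) {
  cat("# geneset_summary\n")
  NextMethod()
  cat("# isoform histogram:\n")
  print(attr(x, "isoform_histogram"))
  invisible(x)
}
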