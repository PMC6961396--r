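## The canonical in-memory gene-model representation: a tibble with one row
## per feature segment (exon, CDS, UTR), carrying gene and transcript ids.
## This flat "one row per interval" layout keeps every downstream operation
## a join/filter/summarise over ordinary columns.

FEATURE_TYPES <- c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")

#' Construct a validated gene-model table
#'
#' A gene-model table has one row per feature segment with columns
#' `gene_id`, `transcript_id`, `type` (one of `exon`, `CDS`,
#' `five_prime_UTR`, `three_prime_UTR`), `scaffold`, `strand` (`+`/`-`)
#' and 1-based closed `start`/`end` coordinates. The constructor checks the
#' structural invariants: one scaffold and strand per gene, exons of a
#' transcript sorted and separated by at least one base (so every intron has
#' length >= 1), and every CDS segment contained in exactly one exon of its
#' transcript.
#'
#' @param x a data frame with the columns above.
#' @return a `gene_models` tibble in canonical row order
#'   (scaffold, gene start, gene id, transcript id, feature type, start).
#' @examples
#' gene_models(tibble::tibble(
#'   gene_id = "g1", transcript_id = "g1.t1",
#'   type = c("exon", "exon", "CDS", "CDS"),
#'   scaffold = "s1", strand = "+",
#'   start = c(1, 201, 11, 201), end = c(100, 300, 100, 280)
#' ))
#' @export
gene_models <- function(x) {
  x <- as_tibble(x)
  required <- c("gene_id", "transcript_id", "type", "scaffold", "strand",
                "start", "end")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("gene_models(): missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- x[required]
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x$gene_id <- as.character(x$gene_id)
  x$transcript_id <- as.character(x$transcript_id)
  x$type <- as.character(x$type)
  x$scaffold <- as.character(x$scaffold)
  x$strand <- as.character(x$strand)
  validate_gene_models(x)
  canonical_order(x)
}

## canonical row order + class, without revalidation
canonical_order <- function(x) {
  if (nrow(x) == 0) {
    class(x) <- unique(c("gene_models", class(x)))
    return(x)
  }
  x <- x %>%
    group_by(gene_id) %>%
    mutate(gene_start = min(start)) %>%
    ungroup() %>%
    mutate(type_rank = match(type, FEATURE_TYPES)) %>%
    arrange(scaffold, gene_start, gene_id, transcript_id, type_rank, start) %>%
    select(-gene_start, -type_rank)
  class(x) <- unique(c("gene_models", class(x)))
  x
}

validate_gene_models <- function(x) {
  bad_type <- setdiff(unique(x$type), FEATURE_TYPES)
  if (length(bad_type) > 0) {
    abort(paste0("unknown feature type(s): ", paste(bad_type, collapse = ", ")))
  }
  if (!all(x$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-' for every feature")
  }
  if (any(is.na(x$start)) || any(is.na(x$end)) ||
      any(x$start < 1L) || any(x$start > x$end)) {
    abort("feature coordinates must satisfy 1 <= start <= end")
  }
  per_tx <- x %>%
    group_by(transcript_id) %>%
    summarise(
      n_scaffold = n_distinct(scaffold),
      n_strand = n_distinct(strand),
      n_gene = n_distinct(gene_id),
      .groups = "drop"
    )
  bad <- per_tx$transcript_id[per_tx$n_scaffold > 1 | per_tx$n_strand > 1 |
                                per_tx$n_gene > 1]
  if (length(bad) > 0) {
    abort(paste0("transcript(s) span multiple scaffolds/strands/genes: ",
                 paste(bad, collapse = ", ")))
  }
  ## exons sorted, non-overlapping, gaps >= 1 base
  ex <- x %>%
    filter(type == "exon") %>%
    arrange(transcript_id, start) %>%
    group_by(transcript_id) %>%
    mutate(prev_end = lag(end)) %>%
    ungroup()
  bad <- unique(ex$transcript_id[!is.na(ex$prev_end) &
                                   ex$start <= ex$prev_end + 1L])
  if (length(bad) > 0) {
    abort(paste0("overlapping or abutting exons (zero-length intron) in: ",
                 paste(bad, collapse = ", ")))
  }
  ## every CDS segment inside exactly one exon of its transcript
  cds <- x %>% filter(type == "CDS")
  if (nrow(cds) > 0) {
    exl <- x %>% filter(type == "exon")
    hit <- cds %>%
      left_join(exl %>% select(transcript_id, ex_start = start, ex_end = end),
                by = "transcript_id", relationship = "many-to-many") %>%
      group_by(transcript_id, start, end) %>%
      summarise(
        n_containing = sum(start >= ex_start & end <= ex_end, na.rm = TRUE),
        .groups = "drop"
      )
    bad <- unique(hit$transcript_id[hit$n_containing != 1L])
    if (length(bad) > 0) {
      abort(paste0(
        "CDS segment not contained in exactly one exon in transcript(s): ",
        paste(bad, collapse = ", ")
      ))
    }
  }
  invisible(x)
}

#' Introns of every transcript
#'
#' Introns are the gaps between consecutive exons of a transcript.
#'
#' @param models a [gene_models] tibble.
#' @return tibble with `gene_id`, `transcript_id`, `scaffold`, `strand`,
#'   `start`, `end` (1-based closed intron interval) and the canonical
#'   string `key`.
#' @export
transcript_introns <- function(models) {
  ex <- models[models$type == "exon", ]
  ex <- ex[order(ex$transcript_id, ex$start), ]
  n <- nrow(ex)
  empty <- tibble(
    gene_id = character(), transcript_id = character(),
    scaffold = character(), strand = character(),
    start = integer(), end = integer(), key = character()
  )
  if (n < 2) return(empty)
  ## a gap exists between consecutive rows of the same transcript
  i <- which(ex$transcript_id[-n] == ex$transcript_id[-1])
  if (length(i) == 0) return(empty)
  out <- tibble(
    gene_id = ex$gene_id[i],
    transcript_id = ex$transcript_id[i],
    scaffold = ex$scaffold[i],
    strand = ex$strand[i],
    start = ex$end[i] + 1L,
    end = ex$start[i + 1L] - 1L
  )
  out$key <- intron_key(out$scaffold, out$start, out$end, out$strand)
  out
}

#' Union of introns over all isoforms of each gene
#'
#' @param models a [gene_models] tibble.
#' @return tibble with one row per distinct (gene, intron) combination.
#' @export
gene_introns <- function(models) {
  transcript_introns(models) %>%
    distinct(gene_id, scaffold, strand, start, end, key)
}

#' Per-gene CDS span
#'
#' @param models a [gene_models] tibble.
#' @return tibble with `gene_id`, `scaffold`, `strand`, `cds_start`,
#'   `cds_end`. Genes with no CDS are omitted.
#' @export
gene_cds_spans <- function(models) {
  models %>%
    filter(type == "CDS") %>%
    group_by(gene_id, scaffold, strand) %>%
    summarise(cds_start = min(start), cds_end = max(end), .groups = "drop")
}

#' Longest coding isoform of each gene
#'
#' The isoform with the largest total CDS length; ties resolved by
#' transcript id so the choice is deterministic.
#'
#' @param models a [gene_models] tibble.
#' @return tibble with `gene_id`, `transcript_id`, `cds_len`.
#' @export
longest_isoforms <- function(models) {
  models %>%
    filter(type == "CDS") %>%
    group_by(gene_id, transcript_id) %>%
    summarise(cds_len = sum(end - start + 1L), .groups = "drop") %>%
    arrange(gene_id, desc(cds_len), transcript_id) %>%
    group_by(gene_id) %>%
    slice(1) %>%
    ungroup()
}

## feature segments of given type for one transcript, in transcript
## orientation ('-' strand reads right-to-left along the genome)
segments_in_orientation <- function(models, tx, feature = "CDS") {
  seg <- models %>%
    filter(transcript_id == tx, type == feature) %>%
    arrange(start)
  if (nrow(seg) > 0 && seg$strand[1] == "-") seg <- seg[rev(seq_len(nrow(seg))), ]
  seg
}

#' Spliced sequence of a transcript feature
#'
#' Concatenates the genomic sequence of the transcript's segments of the
#' requested feature type in transcript orientation (reverse-complemented
#' for `-` strand transcripts).
#'
#' @param models a [gene_models] tibble.
#' @param genome named character vector of scaffold sequences.
#' @param transcript_id a single transcript id.
#' @param feature `"CDS"` (default) or `"exon"`.
#' @return a single string; `""` if the transcript has no such segments.
#' @export
spliced_seq <- function(models, genome, transcript_id, feature = "CDS") {
  tx <- transcript_id
  seg <- models %>%
    filter(transcript_id == tx, type == feature) %>%
    arrange(start)
  if (nrow(seg) == 0) return("")
  pieces <- mapply(function(s, e) get_subseq(genome, seg$scaffold[1], s, e),
                   seg$start, seg$end)
  ## concatenate in genomic order, then reverse-complement the whole for
  ## '-' strand: revcomp(seq(E1) + seq(E2)) = revcomp(E2) + revcomp(E1),
  ## i.e. the transcript 5'->3' sequence
  out <- paste(pieces, collapse = "")
  if (seg$strand[1] == "-") out <- revcomp_dna(out)
  out
}

#' @export
print.gene_models <- function(x, ...) {
  n_g <- n_distinct(x$gene_id)
  n_t <- n_distinct(x$transcript_id)
  cat(sprintf("# gene_models: %d genes, %d transcripts, %d feature rows\n",
              n_g, n_t, nrow(x)))
  NextMethod()
}
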