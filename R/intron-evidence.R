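## Spliced-alignment evidence -> filtered set of supported introns.
##
## Two stages mirror the annotation workflow: (1) alignment-level prefilters
## (minimum identity, mate distance/orientation for paired reads, ambiguity
## between best and second-best hit), then (2) intron-candidate restrictions
## (length range, splice-site dinucleotides, contradiction ratio). The
## surviving candidates with their multiplicities form the support index
## used by the merge, event and metrics modules.

#' Filter configuration for intron evidence
#'
#' Defaults are the thresholds used for the insect reannotation workflow
#' this package models: alignments need >= 92% identity, paired mates must
#' map within 200 kbp on the same scaffold in proper orientation, and hits
#' whose best and second-best identities are within 4 percentage points are
#' discarded as ambiguous. Intron candidates must be 32..350,000 bp long,
#' have accepted splice-site dinucleotides (GT-AG by default; GC-AG and
#' AT-AC can be added), and must not be contradicted by overlapping
#' candidates whose summed multiplicity exceeds 9 times their own.
#'
#' @param min_identity minimum alignment identity (fraction).
#' @param max_mate_distance maximum genomic distance between mates (bp).
#' @param ambiguity_margin maximum difference between best and second-best
#'   identity (as a fraction) below which a hit counts as ambiguous.
#' @param min_intron_len,max_intron_len allowed intron length range (bp).
#' @param contradiction_factor a candidate is kept while the summed
#'   multiplicity of overlapping non-identical candidates is at most this
#'   factor times its own multiplicity (boundary inclusive).
#' @param accepted_splice_pairs character vector of `"donor-acceptor"`
#'   dinucleotide pairs in mRNA sense.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_identity = 0.92,
                          max_mate_distance = 200000L,
                          ambiguity_margin = 0.04,
                          min_intron_len = 32L,
                          max_intron_len = 350000L,
                          contradiction_factor = 9,
                          accepted_splice_pairs = "GT-AG") {
  stopifnot(
    min_identity > 0, max_mate_distance > 0, ambiguity_margin >= 0,
    min_intron_len > 0, min_intron_len <= max_intron_len,
    contradiction_factor > 0, length(accepted_splice_pairs) >= 1
  )
  structure(list(
    min_identity = min_identity,
    max_mate_distance = as.integer(max_mate_distance),
    ambiguity_margin = ambiguity_margin,
    min_intron_len = as.integer(min_intron_len),
    max_intron_len = as.integer(max_intron_len),
    contradiction_factor = contradiction_factor,
    accepted_splice_pairs = accepted_splice_pairs
  ), class = "filter_config")
}

#' Prefilter spliced-alignment records
#'
#' Keeps records with `identity >= min_identity`; paired records (those
#' with a non-missing `mate_scaffold`) must additionally have the mate on
#' the same scaffold within `max_mate_distance` and be properly oriented;
#' records whose best and second-best identities are within
#' `ambiguity_margin` of each other are discarded as ambiguous.
#'
#' @param alignments tibble with columns `read_id`, `scaffold`, `strand`,
#'   `blocks` (string `"s1-e1,s2-e2,..."` of 1-based closed aligned blocks),
#'   `identity`, `best_identity`, `second_best_identity` (NA if unique),
#'   `mate_scaffold` (NA if unpaired), `mate_distance`, `properly_oriented`.
#' @param cfg a [filter_config].
#' @return the surviving rows, unchanged.
#' @export
filter_alignments <- function(alignments, cfg = filter_config()) {
  alignments %>%
    filter(identity >= cfg$min_identity) %>%
    filter(
      is.na(mate_scaffold) |
        (mate_scaffold == scaffold &
           mate_distance <= cfg$max_mate_distance &
           properly_oriented)
    ) %>%
    filter(
      ## small epsilon keeps the boundary ("within 4%") inclusive despite
      ## floating-point subtraction (0.99 - 0.95 > 0.04 in doubles)
      is.na(second_best_identity) |
        (best_identity - second_best_identity) > cfg$ambiguity_margin + 1e-9
    )
}

parse_blocks <- function(blocks) {
  lapply(strsplit(blocks, ",", fixed = TRUE), function(b) {
    m <- do.call(rbind, strsplit(b, "-", fixed = TRUE))
    matrix(as.integer(m), ncol = 2, dimnames = list(NULL, c("start", "end")))
  })
}

## attach donor/acceptor dinucleotides and infer strand from splice sites
## when the record strand is unknown; key is recomputed
annotate_candidates <- function(cand, genome) {
  n <- nrow(cand)
  donor <- character(n); acceptor <- character(n); strand <- character(n)
  for (i in seq_len(n)) {
    d <- get_subseq(genome, cand$scaffold[i], cand$start[i], cand$start[i] + 1L)
    a <- get_subseq(genome, cand$scaffold[i], cand$end[i] - 1L, cand$end[i])
    given <- if ("strand" %in% names(cand)) cand$strand[i] else NA_character_
    if (!is.na(given) && given == "+") {
      strand[i] <- "+"; donor[i] <- d; acceptor[i] <- a
    } else if (!is.na(given) && given == "-") {
      strand[i] <- "-"; donor[i] <- revcomp_dna(a); acceptor[i] <- revcomp_dna(d)
    } else if (d == "GT" && a == "AG") {
      strand[i] <- "+"; donor[i] <- d; acceptor[i] <- a
    } else if (d == "CT" && a == "AC") {
      strand[i] <- "-"; donor[i] <- revcomp_dna(a); acceptor[i] <- revcomp_dna(d)
    } else {
      strand[i] <- "*"; donor[i] <- d; acceptor[i] <- a
    }
  }
  cand$strand <- strand
  cand$donor <- donor
  cand$acceptor <- acceptor
  cand$multiplicity <- as.integer(cand$multiplicity)
  cand$key <- intron_key(cand$scaffold, cand$start, cand$end, cand$strand)
  as_tibble(cand[c("scaffold", "start", "end", "strand", "multiplicity",
                   "donor", "acceptor", "key")])
}

#' Compile intron candidates from spliced alignments
#'
#' Every gap between consecutive aligned blocks of a record is a candidate
#' intron; candidates are aggregated per identical (scaffold, start, end)
#' position and the multiplicity is the number of records crossing that
#' exact exon-exon boundary. Donor/acceptor dinucleotides are read from the
#' genome and the strand inferred from them when the alignment is
#' unstranded.
#'
#' @param alignments prefiltered alignment tibble (see
#'   [filter_alignments()]); only rows with a gap contribute.
#' @param genome named character vector of scaffold sequences.
#' @return intron-candidate tibble.
#' @export
compile_candidates <- function(alignments, genome) {
  if (nrow(alignments) == 0) {
    return(annotate_candidates(tibble(
      scaffold = character(), start = integer(), end = integer(),
      strand = NA_character_[0], multiplicity = integer()
    ), genome))
  }
  blk <- parse_blocks(alignments$blocks)
  gaps <- purrr::imap(blk, function(b, i) {
    if (nrow(b) < 2) return(NULL)
    tibble(
      read_id = alignments$read_id[i],
      scaffold = alignments$scaffold[i],
      start = b[-nrow(b), "end"] + 1L,
      end = b[-1, "start"] - 1L
    )
  })
  gaps <- bind_rows(gaps)
  if (nrow(gaps) == 0) {
    return(annotate_candidates(tibble(
      scaffold = character(), start = integer(), end = integer(),
      strand = NA_character_[0], multiplicity = integer()
    ), genome))
  }
  bad <- gaps %>%
    filter(start > end |
             start < 2L |
             end >= nchar(genome[scaffold]))
  if (nrow(bad) > 0) {
    abort(sprintf("alignment gap outside genome bounds in record '%s' (%s:%d-%d)",
                  bad$read_id[1], bad$scaffold[1], bad$start[1], bad$end[1]))
  }
  cand <- gaps %>%
    count(scaffold, start, end, name = "multiplicity") %>%
    mutate(strand = NA_character_)
  annotate_candidates(cand, genome)
}

#' Merge intron candidates from several evidence sets
#'
#' Identical keys have their multiplicities summed (evidence libraries are
#' treated as independent read sets).
#'
#' @param ... intron-candidate tibbles.
#' @return a single candidate tibble.
#' @export
merge_candidates <- function(...) {
  bind_rows(...) %>%
    group_by(scaffold, start, end, strand, donor, acceptor, key) %>%
    summarise(multiplicity = sum(multiplicity), .groups = "drop") %>%
    select(scaffold, start, end, strand, multiplicity, donor, acceptor, key) %>%
    arrange(scaffold, start, end, strand)
}

#' Contradiction counts for intron candidates
#'
#' The contradiction count of a candidate is the summed multiplicity of
#' candidates on the same scaffold that overlap its interval but are not
#' identical to it (exonic-coverage evidence is not considered).
#'
#' @param cands intron-candidate tibble.
#' @return `cands` with a `contradiction` column appended.
#' @export
contradiction_counts <- function(cands) {
  if (nrow(cands) == 0) return(mutate(cands, contradiction = integer()))
  contradiction <- integer(nrow(cands))
  for (sc in unique(cands$scaffold)) {
    idx <- which(cands$scaffold == sc)
    ir <- IRanges::IRanges(cands$start[idx], cands$end[idx])
    hits <- IRanges::findOverlaps(ir, ir)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    same <- cands$start[idx][q] == cands$start[idx][s] &
      cands$end[idx][q] == cands$end[idx][s]
    keep <- !same
    contradiction[idx] <- as.integer(tapply(
      c(cands$multiplicity[idx][s[keep]], integer(0)),
      factor(c(q[keep], integer(0)), levels = seq_along(idx)),
      sum, default = 0L
    ))
  }
  cands$contradiction <- contradiction
  cands
}

#' Filter intron candidates into a support index
#'
#' A candidate survives iff its length is within
#' `[min_intron_len, max_intron_len]`, its donor-acceptor pair is accepted,
#' and its contradiction count is at most
#' `contradiction_factor * multiplicity` (boundary inclusive).
#'
#' @param cands intron-candidate tibble (donor/acceptor annotated).
#' @param cfg a [filter_config].
#' @return the support index: the surviving candidate rows (with the
#'   `contradiction` column retained for inspection).
#' @export
filter_candidates <- function(cands, cfg = filter_config()) {
  cands <- contradiction_counts(cands)
  cands %>%
    mutate(len = end - start + 1L) %>%
    filter(
      len >= cfg$min_intron_len,
      len <= cfg$max_intron_len,
      paste0(donor, "-", acceptor) %in% cfg$accepted_splice_pairs,
      contradiction <= cfg$contradiction_factor * multiplicity
    ) %>%
    select(-len)
}

## exact-coordinate membership of intron intervals in a support index;
## strand "*" on either side matches any strand
match_support <- function(introns, idx) {
  if (nrow(introns) == 0 || nrow(idx) == 0) return(introns[0, , drop = FALSE])
  introns %>%
    inner_join(
      idx %>% select(scaffold, start, end, idx_strand = strand, multiplicity),
      by = c("scaffold", "start", "end"),
      relationship = "many-to-many"
    ) %>%
    filter(idx_strand == "*" | strand == "*" | idx_strand == strand) %>%
    distinct(across(all_of(names(introns))), multiplicity)
}

#' Supported introns of transcripts
#'
#' Returns the subset of the transcripts' introns present in the support
#' index at the exact same coordinates (off-by-one positions do not match).
#' Strand-unknown index entries match either strand.
#'
#' @param models a [gene_models] tibble (or a subset of its transcripts).
#' @param idx support index from [filter_candidates()].
#' @return tibble of supported introns with their index multiplicity.
#' @export
supported_introns <- function(models, idx) {
  match_support(transcript_introns(models), idx)
}
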