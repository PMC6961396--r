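## Small sequence and interval helpers shared across modules.
## Coordinates are 1-based closed throughout the package (the GFF3 and
## IRanges convention); an intron of length L spans end - start + 1 = L bases.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`. `N` is preserved.
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @keywords internal
#' @noRd
revcomp_dna <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", x))
}

#' @noRd
revcomp_rna <- function(x) {
  stringi::stri_reverse(chartr("ACGUacgu", "UGCAugca", x))
}

#' @noRd
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @noRd
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' Canonical string key for an intron
#'
#' @param scaffold,start,end,strand vectors describing intron intervals
#'   (1-based closed). `strand` may be `"+"`, `"-"` or `"*"` (unknown).
#' @return character vector `"scaffold:start-end(strand)"`.
#' @export
intron_key <- function(scaffold, start, end, strand = "*") {
  sprintf("%s:%d-%d(%s)", scaffold, as.integer(start), as.integer(end), strand)
}

#' Extract a subsequence from a genome
#'
#' @param genome named character vector of scaffold sequences
#'   (see [read_genome_fasta()]).
#' @param scaffold scaffold name.
#' @param start,end 1-based closed coordinates.
#' @return the subsequence as an upper-case string.
#' @export
get_subseq <- function(genome, scaffold, start, end) {
  if (!scaffold %in% names(genome)) {
    abort(sprintf("scaffold '%s' not present in genome", scaffold))
  }
  n <- nchar(genome[[scaffold]])
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 1L) || any(end > n) || any(start > end)) {
    abort(sprintf(
      "coordinates %d-%d outside scaffold '%s' (length %d)",
      start, end, scaffold, n
    ))
  }
  substr(genome[[scaffold]], start, end)
}

## deterministic local RNG scope: runs `expr` under `seed` and restores
## the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

## random DNA string(s)
rand_dna <- function(n) {
  vapply(n, function(k) {
    paste(sample(DNA_BASES, k, replace = TRUE), collapse = "")
  }, character(1))
}

stop_codons <- c("TAA", "TAG", "TGA")

## the 61 sense codons
sense_codons <- local({
  all <- as.vector(outer(
    as.vector(outer(DNA_BASES, DNA_BASES, paste0)), DNA_BASES, paste0
  ))
  setdiff(all, stop_codons)
})

## split a string into codons (length must be a multiple of 3)
codon_split <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
}
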