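## Readers and writers for the standard formats the pipeline touches.
## GFF3 parsing is delegated to rtracklayer; writing is done here so the
## output is canonical and byte-stable (fixed column formatting, fixed
## record order), which makes read -> write -> read the identity.

#' Read gene models from a GFF3 file
#'
#' Understands `gene`, `mRNA`/`transcript`, `exon`, `CDS`,
#' `five_prime_UTR` and `three_prime_UTR` features linked by `ID`/`Parent`
#' attributes. Unknown feature types are skipped with a warning; features
#' whose `Parent` cannot be resolved are reported as orphans and dropped.
#'
#' @param path path to a GFF3 file.
#' @return a [gene_models] tibble.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ## cheap structural pre-scan so malformed lines are reported by number
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- body[which(nfield != 9L)[1]]
    abort(sprintf("malformed GFF3 line %d in %s (expected 9 tab-separated fields)",
                  bad, path))
  }
  g <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent")
  ))
  g$type <- as.character(g$type)
  g$seqid <- as.character(g$seqid)
  g$strand <- as.character(g$strand)

  known <- c("gene", "mRNA", "transcript", FEATURE_TYPES)
  unknown <- setdiff(unique(g$type), known)
  if (length(unknown) > 0) {
    warn(paste0("ignoring unknown GFF3 feature type(s): ",
                paste(unknown, collapse = ", ")))
  }

  genes <- g[g$type == "gene", , drop = FALSE]
  mrnas <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  segs <- g[g$type %in% FEATURE_TYPES, , drop = FALSE]

  mrna_parent <- vapply(mrnas$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  orphan_tx <- mrnas$ID[!mrna_parent %in% genes$ID | is.na(mrna_parent)]
  if (length(orphan_tx) > 0) {
    warn(paste0("orphan transcript(s) without a gene parent dropped: ",
                paste(orphan_tx, collapse = ", ")))
  }
  keep <- mrna_parent %in% genes$ID
  tx2gene <- tibble(
    transcript_id = as.character(mrnas$ID[keep]),
    gene_id = mrna_parent[keep]
  )

  if (nrow(segs) > 0) {
    parents <- segs$Parent
    rows <- rep(seq_len(nrow(segs)), lengths(parents))
    seg_long <- tibble(
      transcript_id = as.character(unlist(parents)),
      type = segs$type[rows],
      scaffold = segs$seqid[rows],
      strand = segs$strand[rows],
      start = segs$start[rows],
      end = segs$end[rows]
    )
    orphan <- setdiff(unique(seg_long$transcript_id), tx2gene$transcript_id)
    if (length(orphan) > 0) {
      warn(paste0("orphan feature(s) with unresolved Parent dropped: ",
                  paste(orphan, collapse = ", ")))
      seg_long <- seg_long %>% filter(transcript_id %in% tx2gene$transcript_id)
    }
    out <- seg_long %>% left_join(tx2gene, by = "transcript_id")
  } else {
    out <- tibble(
      transcript_id = character(), type = character(), scaffold = character(),
      strand = character(), start = integer(), end = integer(),
      gene_id = character()
    )
  }
  gene_models(out)
}

format_gff3_attr <- function(id = NULL, parent = NULL) {
  parts <- c(
    if (!is.null(id)) paste0("ID=", id),
    if (!is.null(parent)) paste0("Parent=", parent)
  )
  paste(parts, collapse = ";")
}

#' Write gene models to a GFF3 file
#'
#' Output is canonical: genes ordered by (scaffold, start, gene id),
#' transcripts by id, features in the order exon, CDS, UTR; CDS phase is
#' recomputed from the cumulative coding length in transcript orientation.
#' Writing the result of [read_gff3()] reproduces the file byte for byte.
#'
#' @param models a [gene_models] tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  models <- gene_models(models)  # revalidate + canonical order
  if (nrow(models) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gene_tbl <- models %>%
    group_by(gene_id, scaffold, strand) %>%
    summarise(start = min(start), end = max(end), .groups = "drop") %>%
    arrange(scaffold, start, gene_id)
  gidx <- split(seq_len(nrow(models)), models$gene_id)
  m_tx <- models$transcript_id
  m_type <- models$type
  m_start <- models$start
  m_end <- models$end
  out <- vector("list", nrow(gene_tbl))
  for (gi in seq_len(nrow(gene_tbl))) {
    g_id <- gene_tbl$gene_id[gi]
    sc <- gene_tbl$scaffold[gi]
    str <- gene_tbl$strand[gi]
    lines <- paste(sc, ".", "gene", gene_tbl$start[gi], gene_tbl$end[gi],
                   ".", str, ".", format_gff3_attr(id = g_id), sep = "\t")
    rows <- gidx[[g_id]]
    for (tx in sort(unique(m_tx[rows]))) {
      trows <- rows[m_tx[rows] == tx]
      lines <- c(lines, paste(
        sc, ".", "mRNA", min(m_start[trows]), max(m_end[trows]), ".",
        str, ".", format_gff3_attr(id = tx, parent = g_id), sep = "\t"
      ))
      for (ft in FEATURE_TYPES) {
        frows <- trows[m_type[trows] == ft]
        if (length(frows) == 0) next
        frows <- frows[order(m_start[frows])]
        phase <- rep(".", length(frows))
        if (ft == "CDS") {
          ord <- if (str == "-") rev(seq_along(frows)) else seq_along(frows)
          lens <- m_end[frows] - m_start[frows] + 1L
          cum <- cumsum(c(0L, lens[ord][-length(ord)]))
          phase[ord] <- as.character((3L - cum %% 3L) %% 3L)
        }
        lines <- c(lines, paste(
          sc, ".", ft, m_start[frows], m_end[frows], ".", str, phase,
          format_gff3_attr(parent = tx), sep = "\t"
        ))
      }
    }
    out[[gi]] <- lines
  }
  writeLines(c("##gff-version 3", unlist(out)), path)
  invisible(path)
}

#' Read a genome from a FASTA file
#'
#' @param path path to a (possibly multi-record) FASTA file.
#' @return named character vector of upper-case sequences, one per scaffold.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate FASTA record name(s): ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  if (any(Biostrings::width(ss) == 0)) {
    abort("empty FASTA record(s)")
  }
  setNames(toupper(as.character(ss)), nm)
}

#' Read RNA (or mixed-alphabet) sequences from a FASTA file
#'
#' Like [read_genome_fasta()] but preserving `U`, for mature miRNA and
#' UTR FASTA files.
#'
#' @param path path to the FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_rna_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate FASTA record name(s): ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  if (any(Biostrings::width(ss) == 0)) abort("empty FASTA record(s)")
  setNames(toupper(as.character(ss)), nm)
}

#' Write sequences to a FASTA file
#'
#' Fixed 70-column wrapping and input record order, so output is
#' deterministic and `write(read(f))` is byte-stable on canonical files.
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a per-gene rescue-evidence table
#'
#' Tab-separated file with columns `gene_id`, `has_homolog`, `has_go_term`
#' (0/1 or logical) and `fpkm`. Genes absent from the table default to
#' no evidence (`FALSE`, `FALSE`, `0`) when queried via [rescue_for_genes()].
#'
#' @param path path to the TSV file.
#' @return tibble with one row per gene.
#' @export
read_rescue_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("gene_id", "has_homolog", "has_go_term", "fpkm")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("rescue table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- x %>%
    transmute(
      gene_id = as.character(gene_id),
      has_homolog = as.logical(as.integer(has_homolog)),
      has_go_term = as.logical(as.integer(has_go_term)),
      fpkm = as.numeric(fpkm)
    )
  if (any(is.na(x$fpkm)) || any(x$fpkm < 0)) {
    abort("rescue table: fpkm must be a non-negative number")
  }
  x
}

#' Resolve rescue evidence for a set of genes
#'
#' @param gene_ids character vector of gene ids.
#' @param rescue a tibble from [read_rescue_table()] (or `NULL`).
#' @return tibble with one row per requested gene; genes without a table
#'   entry get the default record (no homolog, no GO term, FPKM 0) and are
#'   reported with a message.
#' @export
rescue_for_genes <- function(gene_ids, rescue = NULL) {
  base <- tibble(gene_id = as.character(gene_ids))
  if (is.null(rescue) || nrow(rescue) == 0) {
    miss <- gene_ids
    out <- base %>% mutate(has_homolog = FALSE, has_go_term = FALSE, fpkm = 0)
  } else {
    out <- base %>% left_join(rescue, by = "gene_id")
    miss <- out$gene_id[is.na(out$fpkm)]
    out <- out %>% mutate(
      has_homolog = coalesce(has_homolog, FALSE),
      has_go_term = coalesce(has_go_term, FALSE),
      fpkm = coalesce(fpkm, 0)
    )
  }
  if (length(miss) > 0) {
    inform(sprintf("%d gene(s) without rescue-table entry use the default record",
                   length(miss)))
  }
  out
}

#' Read intron hints from a GFF file
#'
#' Parses AUGUSTUS-hints-style records (`feature == "intron"`, attribute
#' `mult=N`) into intron candidates. Donor/acceptor dinucleotides are read
#' from the genome; candidate strand is taken from the record when given and
#' otherwise inferred from the splice sites (`GT..AG` implies `+`,
#' `CT..AC` implies `-`; unresolvable candidates keep strand `"*"`).
#' Hints from multiple files can be combined with [merge_candidates()].
#'
#' @param path path to the hints GFF.
#' @param genome named character vector of scaffold sequences.
#' @return intron-candidate tibble (`scaffold`, `start`, `end`, `strand`,
#'   `multiplicity`, `donor`, `acceptor`, `key`).
#' @export
read_intron_hints <- function(path, genome) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(annotate_candidates(tibble(
      scaffold = character(), start = integer(), end = integer(),
      strand = character(), multiplicity = integer()
    ), genome))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L)) {
    abort(sprintf("malformed hints line %d in %s", which(lengths(f) != 9L)[1], path))
  }
  f <- do.call(rbind, f)
  keep <- f[, 3] == "intron"
  f <- f[keep, , drop = FALSE]
  mult <- suppressWarnings(as.integer(sub(".*mult=([0-9]+).*", "\\1", f[, 9])))
  mult[!grepl("mult=", f[, 9])] <- 1L
  cand <- tibble(
    scaffold = f[, 1],
    start = as.integer(f[, 4]),
    end = as.integer(f[, 5]),
    strand = ifelse(f[, 7] %in% c("+", "-"), f[, 7], NA_character_),
    multiplicity = mult
  )
  annotate_candidates(cand, genome)
}

#' Write intron candidates as a hints GFF
#'
#' @param cands intron-candidate tibble.
#' @param path output path.
#' @param source value for the GFF source column.
#' @return `path`, invisibly.
#' @export
write_intron_hints <- function(cands, path, source = "reannotr") {
  cands <- cands %>% arrange(scaffold, start, end, strand)
  lines <- paste(
    cands$scaffold, source, "intron", cands$start, cands$end, ".",
    ifelse(cands$strand %in% c("+", "-"), cands$strand, "."), ".",
    paste0("src=E;mult=", cands$multiplicity),
    sep = "\t"
  )
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
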