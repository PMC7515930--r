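# Phylogenomic supermatrix construction: concatenate per-gene alignments
# over a shared taxon set, strip terminal stop-codon columns from in-frame
# protein-coding alignments, and emit PHYLIP/NEXUS matrices with partition
# definitions (NEXUS charsets and RAxML-style plain text).

#' Strip the terminal stop-codon column triplet from an aligned CDS
#'
#' The final codon triplet of columns is removed when every taxon with
#' non-gap characters there carries a stop codon (TAA/TAG under translation
#' table 5); otherwise the alignment is returned unchanged with a warning.
#'
#' @param alignment Named character vector taxon -> aligned CDS; all equal
#'   length, length divisible by 3.
#' @return The (possibly shortened) alignment.
#' @export
strip_stop_codons <- function(alignment) {
  len <- unique(nchar(alignment))
  stopifnot(length(len) == 1)
  if (len %% 3 != 0) stop("alignment length is not a multiple of 3")
  last <- toupper(substr(alignment, len - 2, len))
  informative <- grepl("[ACGTN]", last)
  if (!any(informative)) return(alignment)
  if (all(last[informative] %in% c("TAA", "TAG")))
    return(substr(alignment, 1, len - 3))
  warning("final codon column-triplet is not a stop for every taxon; left unchanged",
          call. = FALSE)
  alignment
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' @param alignments Named list gene -> named character vector
#'   (taxon -> aligned sequence); each alignment internally equal-length.
#' @param taxa Taxon labels for the matrix rows; defaults to the union over
#'   genes, in first-appearance order. A taxon missing from a gene is filled
#'   with gap characters.
#' @param strip_stops Apply [strip_stop_codons()] to alignments of
#'   protein-coding genes (recognized by canonical name) first.
#' @return A `supermatrix` object: list with `taxa`, `rows` (named character
#'   vector of concatenated sequences), and `partitions` (data frame `gene`,
#'   `start`, `end` 0-based half-open, `kind`).
#' @export
concatenate_alignments <- function(alignments, taxa = NULL,
                                   strip_stops = FALSE) {
  stopifnot(length(alignments) >= 1, !is.null(names(alignments)))
  if (is.null(taxa))
    taxa <- unique(unlist(lapply(alignments, names)))
  if (anyDuplicated(taxa)) stop("duplicate taxon labels: ",
                                paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  rows <- setNames(rep("", length(taxa)), taxa)
  parts <- list()
  off <- 0L
  for (g in names(alignments)) {
    al <- unlist(alignments[[g]])
    if (anyDuplicated(names(al)))
      stop(sprintf("gene %s: conflicting duplicate taxon labels", g))
    len <- unique(nchar(al))
    if (length(len) != 1)
      stop(sprintf("gene %s: aligned sequences have unequal lengths", g))
    kind <- gene_class(g)
    if (is.na(kind)) kind <- "other"
    if (strip_stops && kind == "PCG" && len %% 3 == 0) {
      al <- strip_stop_codons(al)
      len <- unique(nchar(al))
    }
    fill <- strrep("-", len)
    add <- vapply(taxa, function(tx) if (tx %in% names(al)) al[[tx]] else fill,
                  character(1))
    rows <- paste0(rows, add)
    names(rows) <- taxa
    parts[[g]] <- data.frame(gene = g, start = off, end = off + len,
                             kind = kind, stringsAsFactors = FALSE)
    off <- off + len
  }
  partitions <- do.call(rbind, parts)
  rownames(partitions) <- NULL
  structure(list(taxa = taxa, rows = rows, partitions = partitions),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d sites, %d partitions\n",
              length(x$taxa), nchar(x$rows[[1]]), nrow(x$partitions)))
  invisible(x)
}

#' Split a supermatrix back into per-gene alignments
#'
#' Inverse of [concatenate_alignments()] (modulo gap-filled rows).
#'
#' @param sm A `supermatrix`.
#' @return Named list gene -> named character vector.
#' @export
split_supermatrix <- function(sm) {
  out <- lapply(seq_len(nrow(sm$partitions)), function(i) {
    substr(sm$rows, sm$partitions$start[i] + 1L, sm$partitions$end[i])
  })
  names(out) <- sm$partitions$gene
  out
}

#' Write a supermatrix as relaxed PHYLIP
#'
#' Header `ntaxa nsites`, then one `name sequence` line per taxon (names not
#' truncated).
#'
#' @param sm A `supermatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(sm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(sm$taxa), nchar(sm$rows[[1]])), con)
  writeLines(sprintf("%s  %s", sm$taxa, sm$rows[sm$taxa]), con)
  invisible(path)
}

#' Read a relaxed PHYLIP matrix
#' @param path File written by [write_phylip()].
#' @return Named character vector taxon -> sequence.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  parts <- strsplit(trimws(body), "\\s+")
  out <- setNames(vapply(parts, `[`, character(1), 2),
                  vapply(parts, `[`, character(1), 1))
  stopifnot(length(out) == hdr[1], all(nchar(out) == hdr[2]))
  out
}

#' Write a supermatrix as NEXUS with a charset block
#'
#' The DATA block is emitted via [ape::write.nexus.data()]; a SETS block with
#' one `charset` per partition is appended.
#'
#' @param sm A `supermatrix`.
#' @param path Output path.
#' @param scheme `"by_gene"` (one charset per gene) or `"by_codon_position"`
#'   (protein-coding partitions expanded into three codon-position charsets).
#' @return `path`, invisibly.
#' @export
write_nexus <- function(sm, path, scheme = c("by_gene", "by_codon_position")) {
  scheme <- match.arg(scheme)
  seqs <- lapply(sm$rows, function(s) strsplit(tolower(s), "")[[1]])
  names(seqs) <- sm$taxa
  ape::write.nexus.data(seqs, file = path, interleaved = FALSE,
                        datablock = TRUE)
  sets <- c("begin sets;", partition_charsets(sm$partitions, scheme), "end;")
  cat(paste0(sets, "\n"), file = path, append = TRUE, sep = "")
  invisible(path)
}

# charset lines (1-based inclusive NEXUS coordinates)
partition_charsets <- function(partitions, scheme) {
  unlist(lapply(seq_len(nrow(partitions)), function(i) {
    p <- partitions[i, ]
    if (scheme == "by_codon_position" && p$kind == "PCG") {
      sprintf("  charset %s_pos%d = %d-%d\\3;", p$gene, 1:3,
              p$start + 1:3, p$end)
    } else {
      sprintf("  charset %s = %d-%d;", p$gene, p$start + 1, p$end)
    }
  }))
}

#' Write a RAxML-style partition file
#'
#' @param sm A `supermatrix`.
#' @param path Output path.
#' @param scheme See [write_nexus()].
#' @return `path`, invisibly.
#' @export
write_raxml_partitions <- function(sm, path,
                                   scheme = c("by_gene", "by_codon_position")) {
  scheme <- match.arg(scheme)
  lines <- unlist(lapply(seq_len(nrow(sm$partitions)), function(i) {
    p <- sm$partitions[i, ]
    if (scheme == "by_codon_position" && p$kind == "PCG") {
      sprintf("DNA, %s_pos%d = %d-%d\\3", p$gene, 1:3, p$start + 1:3, p$end)
    } else {
      sprintf("DNA, %s = %d-%d", p$gene, p$start + 1, p$end)
    }
  }))
  writeLines(lines, path)
  invisible(path)
}
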