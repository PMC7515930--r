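# Per-partition nucleotide composition: AT%, AT-skew, GC-skew.
#
#   AT%     = 100 * (A+T) / (A+T+G+C)
#   AT-skew = (A - T) / (A + T)
#   GC-skew = (G - C) / (G + C)
#
# N never enters any denominator. A zero denominator yields NA (never a
# fabricated 0). Whole-genome, tRNA, rRNA and control-region partitions are
# measured on the major strand; protein-coding partitions on each gene's
# sense strand, pooled by concatenation, with terminal stop codons excluded —
# the strongly negative pooled-PCG AT-skew seen in insect mitogenomes against
# a positive whole-genome skew only appears under sense-strand pooling.

#' Count bases in a nucleotide string
#'
#' @param seq Nucleotide string over `{A,C,G,T,N}`; `N` is ignored.
#' @return A `base_counts` object: named integer vector `a`, `t`, `g`, `c`.
#' @export
base_counts <- function(seq) {
  seq <- check_dna(seq)
  if (nchar(seq) == 0) {
    cnt <- c(a = 0L, t = 0L, g = 0L, c = 0L)
  } else {
    f <- Biostrings::letterFrequency(Biostrings::DNAString(seq),
                                     c("A", "T", "G", "C"))
    cnt <- c(a = f[["A"]], t = f[["T"]], g = f[["G"]], c = f[["C"]])
    storage.mode(cnt) <- "integer"
  }
  structure(cnt, class = "base_counts")
}

#' Add base counts
#' @param ... `base_counts` objects.
#' @return Field-wise sum as `base_counts`.
#' @export
sum_base_counts <- function(...) {
  xs <- list(...)
  out <- Reduce(`+`, lapply(xs, unclass))
  structure(as.integer(out), names = c("a", "t", "g", "c"),
            class = "base_counts")
}

#' AT%, AT-skew and GC-skew from base counts
#'
#' @param counts A [base_counts()] object (or named vector with `a,t,g,c`).
#' @return Named numeric vector `at_percent`, `at_skew`, `gc_skew`; a
#'   component with a zero denominator is `NA`.
#' @export
skew_stats <- function(counts) {
  a <- counts[["a"]]; t <- counts[["t"]]
  g <- counts[["g"]]; c <- counts[["c"]]
  stopifnot(all(c(a, t, g, c) >= 0))
  tot <- a + t + g + c
  c(at_percent = if (tot > 0) 100 * (a + t) / tot else NA_real_,
    at_skew    = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    gc_skew    = if (g + c > 0) (g - c) / (g + c) else NA_real_)
}

#' Extract one codon position from a sense-strand CDS
#'
#' @param cds Sense-strand CDS string, length >= 3.
#' @param pos Codon position, 1, 2 or 3.
#' @param strip_stop Remove the final complete codon first when it is a stop
#'   (TAA/TAG under translation table 5). A trailing incomplete codon is
#'   always ignored.
#' @return Concatenation of the `pos`-th base of each complete codon.
#' @export
codon_position_subsequence <- function(cds, pos, strip_stop = TRUE) {
  cds <- check_dna(cds, "CDS")
  stopifnot(nchar(cds) >= 3, pos %in% 1:3)
  n_codon <- floor(nchar(cds) / 3)
  if (strip_stop && n_codon >= 1) {
    last <- substr(cds, 3 * n_codon - 2, 3 * n_codon)
    if (last %in% mito_genetic_code()$stops) n_codon <- n_codon - 1L
  }
  if (n_codon == 0) return("")
  idx <- 3 * seq_len(n_codon) - 3 + pos
  paste(substring(cds, idx, idx), collapse = "")
}

#' Default composition partitions
#'
#' The ten partitions of the standard comparative composition table:
#' whole genome (J-strand), pooled protein-coding genes without stop codons,
#' the three codon positions, pooled tRNAs, pooled rRNAs, rrnL, rrnS, and the
#' A+T-rich region.
#'
#' @return List of partition specs (label, members, codon_position, strand
#'   policy).
#' @export
default_partitions <- function() {
  part <- function(label, members, codon_position = NA_integer_,
                   strand_policy = "sense") {
    list(label = label, members = members, codon_position = codon_position,
         strand_policy = strand_policy)
  }
  list(
    part("whole_genome_J", "whole_genome", strand_policy = "major"),
    part("PCGs_no_stop", PCG_NAMES),
    part("codon_pos1", PCG_NAMES, 1L),
    part("codon_pos2", PCG_NAMES, 2L),
    part("codon_pos3", PCG_NAMES, 3L),
    part("tRNAs", TRNA_NAMES, strand_policy = "major"),
    part("rRNAs", RRNA_NAMES, strand_policy = "major"),
    part("rrnL", "rrnL", strand_policy = "major"),
    part("rrnS", "rrnS", strand_policy = "major"),
    part("AT_rich", CONTROL_REGION_NAME, strand_policy = "major")
  )
}

# pooled sequence of one partition
partition_sequence <- function(a, spec) {
  if (identical(spec$members, "whole_genome")) return(a$genome$sequence)
  present <- feature_names(a)
  members <- intersect(present, spec$members)  # keep genome order
  missing <- setdiff(spec$members, present)
  if (length(missing))
    stop(sprintf("partition '%s': missing feature(s) %s", spec$label,
                 paste(missing, collapse = ", ")))
  seqs <- vapply(members, function(nm) {
    f <- get_feature(a, nm)
    if (identical(spec$strand_policy, "major")) {
      s <- extract_feature_sequence(a, nm)
      if (f$strand == "N") s <- revcomp(s)   # back to major-strand reading
      s
    } else {
      extract_feature_sequence(a, nm)
    }
  }, character(1))
  if (!is.na(spec$codon_position)) {
    seqs <- vapply(seqs, codon_position_subsequence, character(1),
                   pos = spec$codon_position, strip_stop = TRUE)
  } else if (all(gene_class(members) == "PCG")) {
    # pooled PCG partition: drop terminal stops
    seqs <- vapply(seqs, strip_terminal_stop, character(1))
  }
  paste(seqs, collapse = "")
}

strip_terminal_stop <- function(cds) {
  n_codon <- floor(nchar(cds) / 3)
  if (n_codon >= 1) {
    last <- substr(cds, 3 * n_codon - 2, 3 * n_codon)
    if (last %in% mito_genetic_code()$stops)
      return(substr(cds, 1, 3 * n_codon - 3))
  }
  substr(cds, 1, 3 * n_codon)
}

#' Composition table for one annotated genome
#'
#' One row per partition, in partition order, with raw (unrounded) values.
#' Use [format_composition()] for display at the conventional precision.
#'
#' @param a An [annotation_set()].
#' @param partitions List of partition specs; see [default_partitions()].
#' @return Data frame `partition`, `length`, `at_percent`, `at_skew`,
#'   `gc_skew`.
#' @export
composition_table <- function(a, partitions = default_partitions()) {
  rows <- lapply(partitions, function(spec) {
    s <- partition_sequence(a, spec)
    st <- skew_stats(base_counts(s))
    data.frame(partition = spec$label, length = nchar(s),
               at_percent = st[["at_percent"]], at_skew = st[["at_skew"]],
               gc_skew = st[["gc_skew"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Format a composition table at conventional reporting precision
#'
#' AT% to 1 decimal place, skews to 3, `NA` rendered as `"NA"`.
#'
#' @param tab Output of [composition_table()].
#' @return Data frame of character columns.
#' @export
format_composition <- function(tab) {
  fmt <- function(x, d) ifelse(is.na(x), "NA", formatC(round(x, d), format = "f", digits = d))
  data.frame(partition = tab$partition, length = tab$length,
             at_percent = fmt(tab$at_percent, 1),
             at_skew = fmt(tab$at_skew, 3),
             gc_skew = fmt(tab$gc_skew, 3), stringsAsFactors = FALSE)
}

#' Comparative composition matrix across genomes
#'
#' @param sets Named list of [annotation_set()] objects (names = genome
#'   labels).
#' @param partitions Partition specs, see [default_partitions()].
#' @return Long-format data frame with a `genome` column.
#' @export
composition_matrix <- function(sets, partitions = default_partitions()) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  out <- lapply(names(sets), function(nm) {
    cbind(genome = nm, composition_table(sets[[nm]], partitions))
  })
  do.call(rbind, out)
}
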