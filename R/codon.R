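# Codon usage under the invertebrate mitochondrial genetic code: codon
# counting, relative synonymous codon usage (RSCU, Sharp & Li: observed count
# divided by the mean count of its synonymous family), start/stop codon
# classification, absent codons, and amino-acid usage ranking.

ALL_CODONS <- {
  b <- c("T", "C", "A", "G")
  paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
}

#' Count codons across a set of sense-strand CDSs
#'
#' Only complete codons are counted; a trailing incomplete codon is ignored.
#'
#' @param cds_set Named character vector (or list) of sense-strand CDSs,
#'   gene -> sequence.
#' @param code Genetic code from [mito_genetic_code()].
#' @param exclude_stop Exclude each CDS's terminal codon when it is a stop.
#' @return A `codon_counts` object: list with `pooled` (named integer vector
#'   over all 64 codons), `per_gene` (matrix gene x codon), and `total`.
#' @export
count_codons <- function(cds_set, code = mito_genetic_code(),
                         exclude_stop = TRUE) {
  cds_set <- unlist(as.list(cds_set))
  stopifnot(length(cds_set) >= 1, all(nchar(cds_set) >= 3))
  per_gene <- t(vapply(cds_set, function(cds) {
    cds <- check_dna(cds, "CDS")
    n <- floor(nchar(cds) / 3)
    codons <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
    if (exclude_stop && codons[n] %in% code$stops) codons <- codons[-n]
    tab <- table(factor(codons, levels = ALL_CODONS))
    as.integer(tab)
  }, integer(64)))
  colnames(per_gene) <- ALL_CODONS
  pooled <- colSums(per_gene)
  storage.mode(pooled) <- "integer"
  structure(list(pooled = pooled, per_gene = per_gene,
                 total = sum(pooled)), class = "codon_counts")
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c = count(c) * family_size / sum of counts over c's
#' synonymous family. Within each family the RSCU values sum to the family
#' size; a family with zero total yields `NA` for its codons. Stop codons are
#' not assigned RSCU values.
#'
#' @param counts A [count_codons()] result, or a named numeric vector of
#'   codon counts.
#' @param code Genetic code from [mito_genetic_code()].
#' @return Data frame `codon`, `aa` (one-letter), `aa3`, `count`, `rscu`,
#'   ordered by amino acid then codon.
#' @export
rscu <- function(counts, code = mito_genetic_code()) {
  cnt <- if (inherits(counts, "codon_counts")) counts$pooled else counts
  stopifnot(!is.null(names(cnt)), all(cnt >= 0))
  fam <- code$families
  fam$count <- as.numeric(cnt[fam$codon])
  fam$count[is.na(fam$count)] <- 0
  fam_tot <- tapply(fam$count, fam$aa, sum)
  tot <- as.numeric(fam_tot[fam$aa])
  fam$rscu <- ifelse(tot > 0, fam$count * fam$family_size / tot, NA_real_)
  fam$aa3 <- aa_three_letter(fam$aa)
  fam <- fam[order(fam$aa, fam$codon), c("codon", "aa", "aa3", "count", "rscu")]
  rownames(fam) <- NULL
  fam
}

#' Codons absent from a set of protein-coding genes
#'
#' A codon is "absent" when its pooled count across the CDS set is zero,
#' terminal stop codons excluded. Stop codons themselves are not reported.
#'
#' @param counts A [count_codons()] result.
#' @param code Genetic code from [mito_genetic_code()].
#' @return Data frame `codon`, `aa3` of unused sense codons.
#' @export
absent_codons <- function(counts, code = mito_genetic_code()) {
  stopifnot(inherits(counts, "codon_counts"))
  sense <- setdiff(ALL_CODONS, code$stops)
  absent <- sense[counts$pooled[sense] == 0]
  data.frame(codon = absent, aa3 = aa_three_letter(unname(code$map[absent])),
             stringsAsFactors = FALSE)
}

#' Start and stop codon report for annotated protein-coding genes
#'
#' The start codon is the first complete codon of the sense CDS;
#' `canonical_start` is true iff it matches ATN. The stop codon is the final
#' complete codon when it is TAA or TAG; a CDS whose length is not a multiple
#' of 3 is reported with the trailing bases as a truncated stop (e.g. `"T-"`),
#' and a final sense codon is flagged non-canonical.
#'
#' @param a An [annotation_set()] with PCG features.
#' @param code Genetic code from [mito_genetic_code()].
#' @return Data frame `gene`, `start_codon`, `canonical_start`, `stop_codon`,
#'   `stop_type` (`"complete"`, `"truncated"`, or `"non-canonical"`).
#' @export
start_stop_report <- function(a, code = mito_genetic_code()) {
  pcgs <- intersect(feature_names(a), PCG_NAMES)
  if (!length(pcgs)) stop("annotation set contains no protein-coding genes")
  rows <- lapply(pcgs, function(nm) {
    cds <- extract_feature_sequence(a, nm)
    if (nchar(cds) < 6) stop(sprintf("CDS of %s is shorter than 6 nt", nm))
    start <- substr(cds, 1, 3)
    n <- floor(nchar(cds) / 3)
    tail_len <- nchar(cds) - 3 * n
    if (tail_len > 0) {
      stop_codon <- paste0(substr(cds, 3 * n + 1, nchar(cds)),
                           strrep("-", 3 - tail_len))
      stop_type <- "truncated"
    } else {
      stop_codon <- substr(cds, nchar(cds) - 2, nchar(cds))
      stop_type <- if (stop_codon %in% c("TAA", "TAG")) "complete" else "non-canonical"
    }
    data.frame(gene = nm, start_codon = start,
               canonical_start = grepl("^AT[ACGT]$", start),
               stop_codon = stop_codon, stop_type = stop_type,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Amino-acid usage ranking
#'
#' Total usage per amino acid (stop codons excluded), descending; ties broken
#' by the amino acid's one-letter code.
#'
#' @param counts A [count_codons()] result.
#' @param code Genetic code from [mito_genetic_code()].
#' @return Data frame `aa`, `aa3`, `count`, ordered most- to least-used.
#' @export
amino_acid_ranking <- function(counts, code = mito_genetic_code()) {
  cnt <- if (inherits(counts, "codon_counts")) counts$pooled else counts
  fam <- code$families
  use <- tapply(as.numeric(cnt[fam$codon]), fam$aa, sum)
  use[is.na(use)] <- 0
  out <- data.frame(aa = names(use), aa3 = aa_three_letter(names(use)),
                    count = as.numeric(use), stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$aa), ]
  out <- out[out$count > 0, ]
  rownames(out) <- NULL
  out
}

#' Pooled sense CDS sequences of the protein-coding genes
#'
#' @param a An [annotation_set()].
#' @return Named character vector gene -> sense CDS.
#' @export
pcg_cds_set <- function(a) {
  pcgs <- intersect(feature_names(a), PCG_NAMES)
  vapply(pcgs, extract_feature_sequence, character(1), a = a)
}
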