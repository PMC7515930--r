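# Gene architecture: junction analysis (overlaps and intergenic spacers on
# the circle) and gene-order comparison against the ancestral insect
# arrangement, including the trnD/trnK translocation characteristic of
# Acridomorpha. Junctions are computed between features consecutive in
# major-strand start order regardless of coding strand.

#' Junctions between consecutive features on the circular genome
#'
#' For features ordered by major-strand start, the gap to the next feature is
#' `next_start - this_end` (negative = overlap, 0 = abutting, positive =
#' intergenic spacer). The wraparound junction from the last feature back to
#' the first is included. Features named in `exclude` are dropped before
#' junctions are formed (their two flanking features then become adjacent).
#' By default nothing is dropped: the control region's flanking junctions
#' are listed here and excluded from intergenic min/max statistics in
#' [junction_summary()] instead.
#'
#' @param a An [annotation_set()] with at least two features.
#' @param exclude Character vector of feature names to drop.
#' @return Data frame `upstream`, `downstream`, `gap`.
#' @export
junctions <- function(a, exclude = character(0)) {
  feats <- a$features[!feature_names(a) %in% exclude]
  if (length(feats) < 2) stop("need at least two features to form junctions")
  L <- a$genome$length
  starts <- vapply(feats, feature_start, integer(1))
  lens <- vapply(feats, feature_length, integer(1))
  nm <- vapply(feats, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate feature names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  ord <- order(starts)
  starts <- starts[ord]; lens <- lens[ord]; nm <- nm[ord]
  ends <- starts + lens                      # may exceed L for wrapping features
  n <- length(nm)
  gap <- c(starts[-1], starts[1] + L) - ends
  data.frame(upstream = nm, downstream = c(nm[-1], nm[1]),
             gap = as.integer(gap), stringsAsFactors = FALSE)
}

#' Summarize overlaps and intergenic regions
#'
#' Junctions touching a feature in `exclude` (by default the control region,
#' which is reported separately and would otherwise dominate "longest IGR")
#' are left out of the statistics.
#'
#' @param jn Output of [junctions()].
#' @param exclude Feature names whose junctions are excluded from the
#'   statistics.
#' @return List with `igr` (positive-gap junctions), `overlaps`
#'   (negative-gap junctions with `length = -gap`), and min/max statistics.
#' @export
junction_summary <- function(jn, exclude = CONTROL_REGION_NAME) {
  jn <- jn[!(jn$upstream %in% exclude | jn$downstream %in% exclude), ,
           drop = FALSE]
  igr <- jn[jn$gap > 0, , drop = FALSE]
  ovl <- jn[jn$gap < 0, , drop = FALSE]
  ovl$length <- -ovl$gap
  list(igr = igr, overlaps = ovl,
       igr_range = if (nrow(igr)) range(igr$gap) else c(NA_integer_, NA_integer_),
       overlap_range = if (nrow(ovl)) range(ovl$length) else c(NA_integer_, NA_integer_),
       longest_igr = if (nrow(igr)) igr[which.max(igr$gap), ] else NULL)
}

#' Construct a gene order
#'
#' @param name Canonical symbols in circular major-strand order.
#' @param strand Matching strand vector of `"J"`/`"N"`.
#' @return A `gene_order` data frame.
#' @export
gene_order <- function(name, strand) {
  stopifnot(length(name) == length(strand), all(strand %in% c("J", "N")),
            !anyDuplicated(name))
  structure(data.frame(name = name, strand = strand, stringsAsFactors = FALSE),
            class = c("gene_order", "data.frame"))
}

#' Gene order of an annotation set
#'
#' @param a An [annotation_set()].
#' @param exclude Names excluded from the order (default: control region).
#' @return A [gene_order()].
#' @export
observed_gene_order <- function(a, exclude = CONTROL_REGION_NAME) {
  feats <- a$features[!feature_names(a) %in% exclude]
  gene_order(vapply(feats, `[[`, character(1), "name"),
             vapply(feats, `[[`, character(1), "strand"))
}

# rotate order so that `anchor` comes first
rotate_order <- function(ord, anchor) {
  i <- match(anchor, ord$name)
  if (is.na(i)) stop("anchor not in order")
  idx <- c(i:nrow(ord), seq_len(i - 1))[seq_len(nrow(ord))]
  ord[idx, , drop = FALSE]
}

#' Compare a gene order to a reference (rotation-invariant)
#'
#' Both orders are rotated to a common anchor (the first reference symbol),
#' then differences are classified: `adjacent_swap` (two neighbouring symbols
#' exchanged), `translocation` (one symbol whose removal from both orders
#' makes the rest identical), `strand_flip` (same position and symbol,
#' opposite strand), and `other` for residual differences.
#'
#' @param order A [gene_order()], e.g. from [observed_gene_order()].
#' @param reference Reference [gene_order()]; default
#'   [ancestral_gene_order()].
#' @return Data frame `type`, `genes`; zero rows iff the orders are identical
#'   up to rotation.
#' @export
compare_gene_order <- function(order, reference = ancestral_gene_order()) {
  if (!setequal(order$name, reference$name)) {
    miss <- setdiff(reference$name, order$name)
    extra <- setdiff(order$name, reference$name)
    stop(sprintf("symbol sets differ; missing: %s; extra: %s",
                 paste(miss, collapse = ","), paste(extra, collapse = ",")))
  }
  anchor <- reference$name[1]
  obs <- rotate_order(order, anchor)
  ref <- rotate_order(reference, anchor)
  n <- nrow(ref)
  events <- list()
  add <- function(type, genes)
    events[[length(events) + 1L]] <<- data.frame(type = type, genes = genes,
                                                 stringsAsFactors = FALSE)

  # strand flips at name-matched positions (independent of position moves)
  common_strand <- merge(obs, ref, by = "name", suffixes = c(".obs", ".ref"))
  flips <- common_strand$name[common_strand$strand.obs != common_strand$strand.ref]
  for (g in sort(flips)) add("strand_flip", g)

  o <- obs$name; r <- ref$name
  guard <- 0
  while (any(o != r) && (guard <- guard + 1) <= n) {
    p <- which(o != r)[1]
    # adjacent swap: the two neighbouring symbols are exchanged
    if (p < n && o[p] == r[p + 1] && o[p + 1] == r[p]) {
      add("adjacent_swap", paste(r[p], r[p + 1], sep = ","))
      o[c(p, p + 1)] <- r[c(p, p + 1)]
      next
    }
    # single-symbol translocation: removing one symbol aligns everything else
    moved <- NULL
    for (g in unique(c(o[p], r[p]))) {
      if (identical(o[o != g], r[r != g])) { moved <- g; break }
    }
    if (!is.null(moved)) {
      add("translocation", moved)
      o <- r
      next
    }
    add("other", paste(o[p], "vs", r[p]))
    o[p] <- r[p]
  }
  if (!length(events))
    return(data.frame(type = character(0), genes = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Census of features by class and strand
#'
#' @param a An [annotation_set()].
#' @return Named list class -> list(J = character vector, N = character
#'   vector), in genome order.
#' @export
strand_census <- function(a) {
  nm <- feature_names(a)
  kl <- vapply(a$features, `[[`, character(1), "klass")
  st <- vapply(a$features, `[[`, character(1), "strand")
  out <- lapply(c(PCG = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                  control_region = "control_region"), function(k) {
    list(J = nm[kl == k & st == "J"], N = nm[kl == k & st == "N"])
  })
  out
}

#' Render a gene order as a signed-symbol line
#'
#' N-strand genes are suffixed `(-)`, e.g. `trnI trnQ(-) trnM ND2 ...`.
#'
#' @param ord A [gene_order()].
#' @return Character scalar.
#' @export
format_gene_order <- function(ord) {
  paste(ifelse(ord$strand == "N", paste0(ord$name, "(-)"), ord$name),
        collapse = " ")
}
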