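# tRNA cloverleaf secondary structure: pair classification (canonical /
# wobble G-U / mismatch subtypes), a deterministic heuristic folder, a
# ground-truth template generator, and cross-genome conservation comparison.
# All structure work is in the RNA alphabet; DNA input is transcribed first.

# canonical cloverleaf geometry used by both the folder and the template
CLOVER <- list(acc_len = 7L, dhu_len = c(4L, 3L), ac_len = 5L,
               tpc_len = c(5L, 4L, 3L), ac_loop = 7L)

rna_pairable <- function(b1, b2, allow_gu = TRUE) {
  p <- paste0(b1, b2)
  p %in% c("AU", "UA", "GC", "CG") | (allow_gu & p %in% c("GU", "UG"))
}

#' Classify the base pairs of a cloverleaf structure
#'
#' Each pair is assigned exactly one class: canonical (A-U, G-C), wobble
#' (G-U), or a mismatch subtype (A-A, A-G, A-C, U-C, U-U, other).
#' Classification is unordered (U-G counts as G-U). Non-canonical pairs are
#' the wobble pairs plus all mismatches.
#'
#' @param struct A `cloverleaf` structure (see [fold_cloverleaf()]), or any
#'   list with `sequence` (RNA string) and `pairs` (two-column index matrix,
#'   1-based) and optionally `arm` labels per pair.
#' @return List with `counts` (named vector over classes), `total`,
#'   `non_canonical`, and `by_arm` (class x arm table when arm labels are
#'   present).
#' @export
classify_pairs <- function(struct) {
  s <- seq_chars(struct$sequence)
  pr <- struct$pairs
  if (is.null(pr) || nrow(pr) == 0) {
    cls <- character(0)
  } else {
    if (any(pr < 1 | pr > length(s))) stop("pair index out of range")
    b1 <- s[pr[, 1]]; b2 <- s[pr[, 2]]
    key <- vapply(seq_along(b1), function(k)
      paste(sort(c(b1[k], b2[k])), collapse = "-"), character(1))
    cls <- c("A-U" = "canonical", "C-G" = "canonical", "G-U" = "wobble",
             "A-A" = "A-A", "A-G" = "A-G", "A-C" = "A-C",
             "C-U" = "U-C", "U-U" = "U-U")[key]
    cls[is.na(cls)] <- "other"
  }
  lev <- c("canonical", "wobble", "A-A", "A-G", "A-C", "U-C", "U-U", "other")
  counts <- table(factor(cls, levels = lev))
  by_arm <- if (!is.null(struct$arm) && length(cls))
    table(factor(cls, levels = lev), struct$arm) else NULL
  list(counts = c(counts), total = length(cls),
       non_canonical = length(cls) - unname(counts[["canonical"]]),
       by_arm = by_arm)
}

# extend a stem from an outer pair inward, admitting canonical/G-U pairs and
# at most max_mismatch mismatched positions; returns included pair indices
extend_stem <- function(s, i0, j0, max_len, max_mismatch, direction = 1L) {
  pairs <- NULL
  mm <- 0L
  for (k in seq_len(max_len) - 1L) {
    i <- i0 + direction * k
    j <- j0 - direction * k
    if (i >= j || i < 1 || j > length(s)) break
    ok <- rna_pairable(s[i], s[j])
    if (!ok) {
      if (mm + 1L > max_mismatch) break
      mm <- mm + 1L
    }
    pairs <- rbind(pairs, c(i, j))
  }
  pairs
}

# search a window for the best stem-loop of the given arm lengths.
# Candidates are ranked by arm length, then number of properly pairing
# positions, then closeness to the canonical cloverleaf geometry
# (pref_start / pref_loop), then leftmost start; deterministic throughout.
# Returns NULL when nothing satisfies the mismatch budget.
best_stem <- function(s, starts, lens, loops, max_mismatch,
                      arm3_end_range = NULL, pref_start = NA_integer_,
                      pref_loop = NA_integer_) {
  best <- NULL
  better <- function(cand, best) {
    if (is.null(best)) return(TRUE)
    for (f in c("L", "valid")) {
      if (cand[[f]] != best[[f]]) return(cand[[f]] > best[[f]])
    }
    if (!is.na(pref_start) && cand$dstart != best$dstart)
      return(cand$dstart < best$dstart)
    if (!is.na(pref_loop) && cand$dloop != best$dloop)
      return(cand$dloop < best$dloop)
    cand$i < best$i
  }
  for (L in lens) {
    for (i in starts) {
      for (l in loops) {
        j <- i + 2L * L + l - 1L           # arm3 end
        if (j > length(s)) next
        if (!is.null(arm3_end_range) && !(j %in% arm3_end_range)) next
        idx5 <- i:(i + L - 1L)
        idx3 <- j:(j - L + 1L)
        ok <- rna_pairable(s[idx5], s[idx3])
        if (sum(!ok) > max_mismatch) next
        cand <- list(pairs = cbind(idx5, idx3), L = L, valid = sum(ok),
                     i = i, dstart = abs(i - pref_start),
                     dloop = abs(l - pref_loop))
        if (better(cand, best)) best <- cand
      }
    }
    if (!is.null(best)) break   # prefer the longer arm length outright
  }
  best
}

#' Heuristic cloverleaf folding
#'
#' A deterministic best-effort folder: anchors the anticodon loop (from the
#' given anticodon or by scanning for the best 5-bp anticodon stem), then
#' builds the acceptor stem (7 bp from the molecule ends), the DHU arm
#' (3-4 bp starting 1-5 nt after the acceptor 5' arm), and the TPsiC arm
#' (3-5 bp whose 3' arm abuts the acceptor 3' arm within 2 nt), admitting
#' canonical and G-U pairs plus at most `max_mismatch` mismatched positions
#' per stem. Arms that cannot be formed are reported in `incomplete_arms`
#' rather than invented; a structure with no feasible anticodon stem is
#' flagged `unfoldable` with whatever partial arms were found.
#'
#' @param seq tRNA sequence (DNA or RNA alphabet), 50-100 nt.
#' @param anticodon Optional anticodon 3-mer.
#' @param max_mismatch Mismatched positions tolerated per stem.
#' @return A `cloverleaf` object: `sequence` (RNA), `pairs` (two-column
#'   matrix), `arm` (label per pair: acceptor/DHU/anticodon/TPsiC),
#'   `anticodon_start`, `incomplete_arms`, `unfoldable`.
#' @export
fold_cloverleaf <- function(seq, anticodon = NULL, max_mismatch = 1L) {
  rna <- dna_to_rna(toupper(seq))
  if (!grepl("^[ACGUN]+$", rna)) stop("invalid tRNA sequence")
  n <- nchar(rna)
  if (n < 50 || n > 100) stop("tRNA sequence length must be in [50, 100]")
  s <- seq_chars(rna)
  incomplete <- character(0)

  # acceptor stem: 7 bp from the molecule ends inward
  acc <- extend_stem(s, 1L, n, CLOVER$acc_len, max_mismatch)
  if (is.null(acc) || nrow(acc) < CLOVER$acc_len) incomplete <- c(incomplete, "acceptor")

  # anticodon anchor: loop of 7 with the anticodon at its centre
  ac_starts <- if (!is.null(anticodon)) {
    ac <- dna_to_rna(toupper(anticodon))
    stopifnot(nchar(ac) == 3)
    as.integer(gregexpr(ac, rna, fixed = TRUE)[[1]])
  } else {
    seq.int(18L, max(18L, n - 18L))
  }
  ac_starts <- ac_starts[ac_starts >= 18 & ac_starts <= n - 15]
  best_ac <- NULL
  for (p in ac_starts) {                     # p = anticodon start
    ls <- p - 2L; le <- p + 4L               # 7-nt loop bounds
    st <- extend_stem(s, ls - 1L, le + 1L, CLOVER$ac_len, max_mismatch,
                      direction = -1L)
    if (is.null(st) || nrow(st) < 3) next
    valid <- sum(rna_pairable(s[st[, 1]], s[st[, 2]]))
    cand <- list(p = p, pairs = st, valid = valid,
                 dist = abs((p + 1L) - (n + 1) / 2))
    if (is.null(best_ac) || cand$valid > best_ac$valid ||
        (cand$valid == best_ac$valid && cand$dist < best_ac$dist) ||
        (cand$valid == best_ac$valid && cand$dist == best_ac$dist &&
         cand$p < best_ac$p))
      best_ac <- cand
  }
  if (is.null(best_ac)) {
    return(structure(list(sequence = rna,
                          pairs = if (is.null(acc)) matrix(integer(0), 0, 2) else acc,
                          arm = rep("acceptor", if (is.null(acc)) 0 else nrow(acc)),
                          anticodon_start = NA_integer_,
                          incomplete_arms = c(incomplete, "anticodon"),
                          unfoldable = TRUE), class = "cloverleaf"))
  }
  ac_pairs <- best_ac$pairs
  colnames(ac_pairs) <- NULL
  p <- best_ac$p
  ac_arm5_start <- min(ac_pairs[, 1])

  # DHU arm: canonically starts 2 nt after the acceptor 5' arm (position
  # 10) with an ~8-nt loop; starts 1-4 nt after the arm are admitted
  dhu_window <- seq.int(CLOVER$acc_len + 2L, CLOVER$acc_len + 5L)
  dhu <- best_stem(s, starts = dhu_window, lens = CLOVER$dhu_len,
                   loops = 3:9, max_mismatch = max_mismatch,
                   pref_start = CLOVER$acc_len + 3L, pref_loop = 8L)
  if (!is.null(dhu) && max(dhu$pairs) >= ac_arm5_start) dhu <- NULL
  if (is.null(dhu)) incomplete <- c(incomplete, "DHU")

  # TPsiC arm: its 3' arm canonically abuts the acceptor 3' arm; placements
  # one or two nt short are tried only when the abutting one fails
  ac_arm3_end <- max(ac_pairs[, 2])
  tpc <- NULL
  if (ac_arm3_end + 1L <= n - CLOVER$acc_len - 8L) {
    for (tgt in (n - CLOVER$acc_len):(n - CLOVER$acc_len - 2L)) {
      tpc <- best_stem(s, starts = seq.int(ac_arm3_end + 1L,
                                           n - CLOVER$acc_len),
                       lens = CLOVER$tpc_len, loops = 3:9,
                       max_mismatch = max_mismatch,
                       arm3_end_range = tgt, pref_loop = 7L)
      if (!is.null(tpc) && min(tpc$pairs) <= ac_arm3_end) tpc <- NULL
      if (!is.null(tpc)) break
    }
  }
  if (is.null(tpc)) incomplete <- c(incomplete, "TPsiC")

  pairs <- rbind(if (!is.null(acc)) acc,
                 if (!is.null(dhu)) dhu$pairs,
                 ac_pairs,
                 if (!is.null(tpc)) tpc$pairs)
  arm <- c(rep("acceptor", if (is.null(acc)) 0 else nrow(acc)),
           rep("DHU", if (is.null(dhu)) 0 else nrow(dhu$pairs)),
           rep("anticodon", nrow(ac_pairs)),
           rep("TPsiC", if (is.null(tpc)) 0 else nrow(tpc$pairs)))
  colnames(pairs) <- c("i", "j")
  structure(list(sequence = rna, pairs = pairs, arm = arm,
                 anticodon_start = p, incomplete_arms = incomplete,
                 unfoldable = FALSE), class = "cloverleaf")
}

#' Generate a perfect cloverleaf template with known pairing
#'
#' Builds a 71-nt tRNA from the canonical geometry (7-bp acceptor, 4-bp DHU,
#' 5-bp anticodon, 5-bp TPsiC stems), with stem pairs drawn from the
#' Watson-Crick set and all loops/spacers set to A, so the planted pairing is
#' the unique well-formed cloverleaf. Ground truth for folder tests and for
#' planting known mismatches.
#'
#' @param anticodon Anticodon 3-mer (RNA alphabet).
#' @param seed Integer seed for the stem draws.
#' @return A `cloverleaf` object with the planted `pairs`/`arm` annotation.
#' @export
cloverleaf_template <- function(anticodon = "GAU", seed = 1L) {
  wc <- list(c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G"))
  with_seed(seed, {
    n <- 71L
    s <- rep("A", n)
    put <- function(i5, j3, k) {
      for (t in seq_len(k)) {
        pr <- wc[[sample.int(4L, 1L)]]
        s[i5 + t - 1L] <<- pr[1]
        s[j3 - t + 1L] <<- pr[2]
      }
      cbind(i5:(i5 + k - 1L), j3:(j3 - k + 1L))
    }
    acc <- put(1L, 71L, 7L)
    dhu <- put(10L, 25L, 4L)
    ac <- put(27L, 43L, 5L)
    tpc <- put(48L, 64L, 5L)
    ac3 <- seq_chars(dna_to_rna(toupper(anticodon)))
    s[34:36] <- ac3
    pairs <- rbind(acc, dhu, ac, tpc)
    colnames(pairs) <- c("i", "j")
    structure(list(sequence = paste(s, collapse = ""), pairs = pairs,
                   arm = c(rep("acceptor", 7), rep("DHU", 4),
                           rep("anticodon", 5), rep("TPsiC", 5)),
                   anticodon_start = 34L, incomplete_arms = character(0),
                   unfoldable = FALSE), class = "cloverleaf")
  })
}

## ---------------------------------------------------------------------------
## conservation comparison

#' Global alignment of two short sequences
#'
#' Needleman-Wunsch with match +1, mismatch -1, gap -2 and a deterministic
#' traceback preferring diagonal, then the gap in the first sequence.
#'
#' @param s1,s2 Sequences (character scalars).
#' @return List `score`, `substitutions`, `indels`, `aligned1`, `aligned2`.
#' @export
align_global <- function(s1, s2) {
  a <- seq_chars(toupper(s1)); b <- seq_chars(toupper(s2))
  n <- length(a); m <- length(b)
  gap <- -2; mat <- 1; mis <- -1
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * 0:n
  S[1, ] <- gap * 0:m
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, mat, mis)
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(S[i, j] + sub[j], S[i, j + 1] + gap,
                             S[i + 1, j] + gap)
    }
  }
  # traceback: diagonal first, then up (gap in s2), then left (gap in s1)
  i <- n; j <- m
  a1 <- character(0); a2 <- character(0)
  subs <- 0L; ind <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (a[i] == b[j]) mat else mis)) {
      a1 <- c(a[i], a1); a2 <- c(b[j], a2)
      if (a[i] != b[j]) subs <- subs + 1L
      i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      a1 <- c(a[i], a1); a2 <- c("-", a2)
      ind <- ind + 1L
      i <- i - 1
    } else {
      a1 <- c("-", a1); a2 <- c(b[j], a2)
      ind <- ind + 1L
      j <- j - 1
    }
  }
  list(score = S[n + 1, m + 1], substitutions = subs, indels = ind,
       aligned1 = paste(a1, collapse = ""), aligned2 = paste(a2, collapse = ""))
}

#' Cross-genome tRNA conservation comparison
#'
#' Pairwise global alignment ([align_global()]) of each tRNA across genomes;
#' substitutions and indels are summed over all genome pairs sharing the
#' tRNA, and tRNAs are ranked from most to least conserved (fewest total
#' differences first; ties broken by name).
#'
#' @param structs Named list (genome -> named list/vector tRNA -> sequence).
#' @return Data frame `trna`, `n_pairs`, `substitutions`, `indels`, `total`,
#'   sorted most-conserved first. tRNAs present in fewer than two genomes are
#'   dropped with a warning.
#' @export
compare_trna_across_genomes <- function(structs) {
  stopifnot(length(structs) >= 2)
  all_trna <- unique(unlist(lapply(structs, names)))
  rows <- list()
  for (tr in all_trna) {
    seqs <- unlist(lapply(structs, function(g)
      if (tr %in% names(g)) g[[tr]] else NULL))
    if (length(seqs) < 2) {
      warning(sprintf("tRNA %s present in fewer than two genomes; excluded", tr),
              call. = FALSE)
      next
    }
    subs <- 0L; ind <- 0L; np <- 0L
    for (i in seq_len(length(seqs) - 1)) {
      for (j in (i + 1):length(seqs)) {
        al <- align_global(seqs[[i]], seqs[[j]])
        subs <- subs + al$substitutions
        ind <- ind + al$indels
        np <- np + 1L
      }
    }
    rows[[tr]] <- data.frame(trna = tr, n_pairs = np, substitutions = subs,
                             indels = ind, total = subs + ind,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$total, out$trna), ]
  rownames(out) <- NULL
  out
}

#' Write a cloverleaf structure as annotated dot-bracket
#'
#' @param struct A `cloverleaf` object.
#' @return Character vector of three lines: sequence, dot-bracket, arm code
#'   (`a`cceptor, `d`HU, `c` anticodon, `t` TPsiC).
#' @export
dot_bracket <- function(struct) {
  n <- nchar(struct$sequence)
  db <- rep(".", n)
  armc <- rep(".", n)
  code <- c(acceptor = "a", DHU = "d", anticodon = "c", TPsiC = "t")
  if (nrow(struct$pairs)) {
    db[struct$pairs[, 1]] <- "("
    db[struct$pairs[, 2]] <- ")"
    armc[struct$pairs[, 1]] <- code[struct$arm]
    armc[struct$pairs[, 2]] <- code[struct$arm]
  }
  c(struct$sequence, paste(db, collapse = ""), paste(armc, collapse = ""))
}
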