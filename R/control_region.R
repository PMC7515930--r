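# Structural features of the A+T-rich (control) region: interrupted poly-T
# stretches, stem-loop inverted repeats, tandem repeats (a self-contained
# detector playing the role an external tandem-repeat finder plays in most
# annotation pipelines), cross-species conserved blocks, and simple motif
# scans. All coordinates reported to the user are 0-based offsets within the
# control-region string, so every report re-extracts its own substring.

#' Find interrupted poly-T stretches
#'
#' A T-stretch is a maximal window whose first and last positions are T, with
#' at most `max_interruptions` internal non-T positions and total length at
#' least `min_len` (this formalizes "a poly-T run with a few inserted bases").
#' Windows nested in a longer reported window are suppressed; results are
#' left-to-right and deterministic.
#'
#' @param cr Control-region nucleotide string (major strand).
#' @param min_len Minimum window length (>= 3).
#' @param max_interruptions Maximum internal non-T positions.
#' @return Data frame `start` (0-based), `length`, `n_interruptions`.
#' @export
find_t_stretches <- function(cr, min_len = 9, max_interruptions = 2) {
  cr <- check_dna(cr, "control region")
  stopifnot(min_len >= 3)
  s <- seq_chars(cr)
  n <- length(s)
  is_t <- s == "T"
  t_pos <- which(is_t)
  non_t <- which(!is_t)
  if (!length(t_pos)) return(empty_tstretch())
  cum_non <- cumsum(!is_t)
  cand <- list()
  for (i in t_pos) {
    # furthest right end allowing <= max_interruptions non-T strictly inside
    after <- non_t[non_t > i]
    j_max <- if (length(after) > max_interruptions) after[max_interruptions + 1] - 1L else n
    # last T within reach
    j <- max(t_pos[t_pos <= j_max])
    if (j - i + 1 >= min_len) {
      ints <- cum_non[j] - cum_non[i]
      cand[[length(cand) + 1L]] <- c(start = i, end = j, ints = ints)
    }
  }
  if (!length(cand)) return(empty_tstretch())
  m <- do.call(rbind, cand)
  m <- m[order(m[, "start"]), , drop = FALSE]
  keep <- m[, "end"] > c(-1, cummax(m[, "end"]))[seq_len(nrow(m))]
  m <- m[keep, , drop = FALSE]
  data.frame(start = m[, "start"] - 1L,
             length = m[, "end"] - m[, "start"] + 1L,
             n_interruptions = m[, "ints"], row.names = NULL)
}

empty_tstretch <- function()
  data.frame(start = integer(0), length = integer(0),
             n_interruptions = integer(0))

# integer base codes A=1, C=2, G=3, T=4 (N=5): complements sum to 5, the
# G-T wobble is the unique pair summing to 7
base_codes <- function(s) match(seq_chars(s), c("A", "C", "G", "T", "N"))

# DNA pairing used by the stem-loop finder
dna_pairable <- function(b1, b2, allow_gu = FALSE) {
  p <- paste0(b1, b2)
  p %in% c("AT", "TA", "GC", "CG") | (allow_gu & p %in% c("GT", "TG"))
}

code_pairable <- function(c1, c2, allow_gu = FALSE) {
  s <- c1 + c2
  s == 5L | (allow_gu & s == 7L & c1 != 5L & c2 != 5L)
}

#' Find stem-loop structures (inverted repeats)
#'
#' Scans every possible loop placement and extends the flanking arms outward
#' while they pair (Watson-Crick by default, G-T wobble with `allow_gu`),
#' tolerating at most `max_mismatch` internal mismatched positions per stem;
#' the outermost pair always pairs. All maximal stems of length at least
#' `min_stem` with loop length inside `loop_range` are reported, sorted by
#' stem length (descending) then position.
#'
#' @param cr Control-region nucleotide string.
#' @param min_stem Minimum stem length in bp (>= 4).
#' @param loop_range Length-2 vector `(min, max)` of admissible loop lengths
#'   (minimum 3).
#' @param allow_gu Admit G-T (wobble) arm pairings.
#' @param max_mismatch Internal mismatched positions tolerated per stem.
#' @return Data frame `arm5_start`, `arm3_start` (0-based), `stem_len`,
#'   `loop_len`, `n_mismatch`.
#' @export
find_stem_loops <- function(cr, min_stem = 8, loop_range = c(3, 8),
                            allow_gu = FALSE, max_mismatch = 0) {
  cr <- check_dna(cr, "control region")
  stopifnot(min_stem >= 4, loop_range[1] >= 3)
  s <- base_codes(cr)
  n <- length(s)
  out <- list()
  for (a in seq_len(n)) {            # loop start (1-based)
    for (l in loop_range[1]:loop_range[2]) {
      le <- a + l - 1L
      if (le + 1L > n || a - 1L < 1L) next
      k <- 0L; mm <- 0L; mism_at <- integer(0)
      while (a - k - 1L >= 1L && le + k + 1L <= n) {
        ok <- code_pairable(s[a - k - 1L], s[le + k + 1L], allow_gu)
        if (!ok) {
          if (mm + 1L > max_mismatch) break
          mm <- mm + 1L
          mism_at <- c(mism_at, k + 1L)
        }
        k <- k + 1L
      }
      # trim outer mismatches: outermost pair must pair
      while (k > 0L && k %in% mism_at) {
        mism_at <- setdiff(mism_at, k)
        k <- k - 1L
      }
      if (k >= min_stem)
        out[[length(out) + 1L]] <- c(arm5_start = a - k - 1L,
                                     arm3_start = le, stem_len = k,
                                     loop_len = l, n_mismatch = length(mism_at))
    }
  }
  if (!length(out))
    return(data.frame(arm5_start = integer(0), arm3_start = integer(0),
                      stem_len = integer(0), loop_len = integer(0),
                      n_mismatch = integer(0)))
  m <- unique(as.data.frame(do.call(rbind, out)))
  m <- m[order(-m$stem_len, m$arm5_start, m$loop_len), ]
  rownames(m) <- NULL
  m
}

#' Find tandem repeats
#'
#' A self-contained tandem-repeat detector: for every candidate period the
#' sequence is compared against itself shifted by that period; maximal
#' segments whose shifted identity stays at or above `min_identity` become
#' candidate arrays, which are then scored against a majority consensus of
#' their copies. Overlapping calls (including period harmonics) are resolved
#' by the highest `copies x identity`, ties by the smaller period then the
#' leftmost start.
#'
#' @param cr Control-region nucleotide string.
#' @param min_period,max_period Period bounds in bp (`min_period >= 2`;
#'   `max_period` is clamped to `len(cr)/2`).
#' @param min_copies Minimum copy number (fractional final copies count).
#' @param min_identity Minimum percent identity of the copies against their
#'   consensus.
#' @return Data frame `start` (0-based), `end` (0-based exclusive), `period`,
#'   `copies`, `identity`, `consensus`.
#' @export
find_tandem_repeats <- function(cr, min_period = 5, max_period = 200,
                                min_copies = 2, min_identity = 70) {
  cr <- check_dna(cr, "control region")
  s <- seq_chars(cr)
  n <- length(s)
  stopifnot(min_period >= 2)
  max_period <- min(max_period, floor(n / 2))
  cand <- list()
  thr <- min_identity / 100
  for (p in min_period:max_period) {
    m <- s[seq_len(n - p)] == s[seq_len(n - p) + p]
    segs <- high_identity_segments(m, thr, min_len = max(p * (min_copies - 1), 4),
                                   gap_max = max(2L, p %/% 3L))
    for (sg in segs) {
      start <- sg[1]; len <- sg[2]
      rr <- refine_repeat(s, start, len + p, p, thr)
      if (is.null(rr)) next
      if (rr$copies >= min_copies && rr$identity >= min_identity)
        cand[[length(cand) + 1L]] <- list(
          start = rr$start - 1L, end = rr$start - 1L + rr$len, period = p,
          copies = rr$copies, identity = rr$identity,
          consensus = rr$consensus)
    }
  }
  if (!length(cand))
    return(data.frame(start = integer(0), end = integer(0),
                      period = integer(0), copies = numeric(0),
                      identity = numeric(0), consensus = character(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(cand, as.data.frame, stringsAsFactors = FALSE))
  df$score <- df$copies * df$identity
  df <- df[order(-df$score, df$period, df$start), ]
  keep <- rep(FALSE, nrow(df))
  for (i in seq_len(nrow(df))) {
    ovl <- keep & (df$start < df$end[i]) & (df$end > df$start[i])
    if (!any(ovl)) keep[i] <- TRUE
  }
  df <- df[keep, ]
  df <- df[order(df$start), setdiff(names(df), "score")]
  rownames(df) <- NULL
  df
}

# maximal segments of a logical match vector with identity >= thr, grown
# greedily over its run-length encoding; a mismatch run is absorbed only
# when it is short (<= gap_max, i.e. a point mutation inside an array, not
# the end of one) and the segment identity stays above threshold
high_identity_segments <- function(m, thr, min_len, gap_max = 2L) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  i <- 1L
  nr <- length(r$lengths)
  while (i <= nr) {
    if (!r$values[i]) { i <- i + 1L; next }
    seg_start <- starts[i]
    matches <- r$lengths[i]
    total <- r$lengths[i]
    j <- i
    while (j + 2L <= nr &&
           r$lengths[j + 1L] <= gap_max &&
           (matches + r$lengths[j + 2L]) /
           (total + r$lengths[j + 1L] + r$lengths[j + 2L]) >= thr) {
      matches <- matches + r$lengths[j + 2L]
      total <- total + r$lengths[j + 1L] + r$lengths[j + 2L]
      j <- j + 2L
    }
    if (total >= min_len && matches / total >= thr)
      segs[[length(segs) + 1L]] <- c(seg_start, total)
    i <- j + 1L
  }
  segs
}

# score a candidate repeat region against its majority consensus and trim
# low-identity end chunks (one period at a time) so the call does not absorb
# lookalike flanking background
refine_repeat <- function(s, start, region_len, p, thr) {
  for (pass in 1:3) {
    region <- s[start:(start + region_len - 1L)]
    cons <- majority_consensus(region, p)
    m <- region == cons[((seq_len(region_len) - 1L) %% p) + 1L]
    trimmed <- FALSE
    while (region_len >= 2L * p && mean(m[seq_len(p)]) < thr) {
      start <- start + p
      region_len <- region_len - p
      m <- m[-seq_len(p)]
      trimmed <- TRUE
    }
    while (region_len >= 2L * p &&
           mean(m[(region_len - p + 1L):region_len]) < thr) {
      m <- m[seq_len(region_len - p)]
      region_len <- region_len - p
      trimmed <- TRUE
    }
    if (!trimmed) break
  }
  if (region_len < 2L * p) return(NULL)
  region <- s[start:(start + region_len - 1L)]
  cons <- majority_consensus(region, p)
  ident <- 100 * mean(region == cons[((seq_len(region_len) - 1L) %% p) + 1L])
  list(start = start, len = region_len, copies = region_len / p,
       identity = ident, consensus = paste(cons, collapse = ""))
}

# per-position majority consensus of the copies of a repeat region
# (ties broken alphabetically, deterministic)
majority_consensus <- function(region, p) {
  bases <- c("A", "C", "G", "T", "N")
  code <- match(region, bases)
  vapply(seq_len(p), function(k) {
    cnt <- tabulate(code[seq(k, length(region), by = p)], 5L)
    bases[which.max(cnt)]
  }, character(1))
}

#' Find conserved blocks across control regions
#'
#' Ungapped seed-and-extend: exact `k`-mer seeds shared by all species anchor
#' per-species offsets, which are extended in both directions while the
#' block's mean identity against its per-column majority consensus stays at
#' or above `min_identity`. Blocks are labeled `E1`, `E2`, ... left to right
#' on the first species.
#'
#' @param crs Named list/vector of control-region strings (>= 2 species).
#' @param min_block Minimum block length in bp.
#' @param min_identity Minimum mean percent identity to the block consensus.
#' @param k Seed k-mer length.
#' @return List of blocks; each is a list with `label`, `length`,
#'   `identity`, `consensus`, and `starts` (named 0-based offsets per
#'   species). Also see [conserved_block_table()].
#' @export
find_conserved_blocks <- function(crs, min_block = 15, min_identity = 90,
                                  k = 8) {
  stopifnot(length(crs) >= 2, !is.null(names(crs)))
  crs <- vapply(crs, check_dna, character(1))
  sp <- names(crs)
  codes <- lapply(crs, base_codes)
  lens <- vapply(codes, length, integer(1))
  kmers <- lapply(crs, function(x) {
    n <- nchar(x)
    if (n < k) return(character(0))
    substring(x, 1:(n - k + 1), k:n)
  })
  ref_km <- kmers[[1]]
  if (!length(ref_km)) return(list())
  # k-mer -> positions index per non-reference species; a k-mer common in
  # A+T-rich sequence occurs many times, so each seed is anchored at the
  # occurrence with the best local agreement with the reference, not the
  # first one
  idx <- lapply(sp[-1], function(s2) split(seq_along(kmers[[s2]]), kmers[[s2]]))
  names(idx) <- sp[-1]
  present <- Reduce(`&`, lapply(idx, function(ix) ref_km %in% names(ix)))
  local_score <- function(ref_start, s2, pos, span = 10L) {
    offs <- (-span):(k - 1L + span)
    ok <- ref_start + offs >= 1L & ref_start + offs <= lens[1] &
          pos + offs >= 1L & pos + offs <= lens[[s2]]
    sum(codes[[1]][ref_start + offs[ok]] == codes[[s2]][pos + offs[ok]])
  }
  cand <- list()
  seen <- character(0)                       # extended-coordinate dedupe
  for (i in which(present)) {
    anchor <- vapply(sp[-1], function(s2) {
      pos <- idx[[s2]][[ref_km[i]]]
      if (length(pos) > 30L) pos <- pos[seq_len(30L)]
      sc <- vapply(pos, local_score, numeric(1), ref_start = i, s2 = s2)
      pos[which.max(sc)]                     # ties: leftmost occurrence
    }, integer(1))
    starts <- c(i, anchor)                   # 1-based per species
    names(starts) <- sp
    ext <- extend_block(codes, starts, k, lens, min_identity / 100)
    if (ext$len >= min_block) {
      key <- paste(c(ext$starts, ext$len), collapse = ":")
      if (!key %in% seen) {
        seen <- c(seen, key)
        cand[[length(cand) + 1L]] <- list(
          starts = ext$starts - 1L, length = ext$len,
          identity = 100 * ext$identity,
          consensus = paste(ext$consensus, collapse = ""))
      }
    }
  }
  if (!length(cand)) return(list())
  # resolve overlapping candidates: longest (then highest-identity,
  # leftmost) first; a candidate sharing more than half of either footprint
  # with a kept block is dropped
  ord <- order(-vapply(cand, `[[`, numeric(1), "length"),
               -vapply(cand, `[[`, numeric(1), "identity"),
               vapply(cand, function(b) b$starts[[1]], numeric(1)))
  cand <- cand[ord]
  blocks <- list()
  for (b in cand) {
    clash <- any(vapply(blocks, function(kept) {
      o <- min(b$starts[[1]] + b$length, kept$starts[[1]] + kept$length) -
           max(b$starts[[1]], kept$starts[[1]])
      o > 0.5 * min(b$length, kept$length)
    }, logical(1)))
    if (!clash) blocks[[length(blocks) + 1L]] <- b
  }
  ord <- order(vapply(blocks, function(b) b$starts[[1]], numeric(1)))
  blocks <- blocks[ord]
  for (i in seq_along(blocks)) blocks[[i]]$label <- paste0("E", i)
  blocks
}

# grow an ungapped multi-species block from seed offsets; the running mean
# column identity (majority base fraction) must stay at or above thr
extend_block <- function(codes, starts, k, lens, thr) {
  nsp <- length(starts)
  col_id <- function(off) {
    cnt <- tabulate(vapply(seq_len(nsp), function(s)
      codes[[s]][starts[s] + off], integer(1)), 5L)
    max(cnt) / nsp
  }
  k <- as.integer(k)
  lo <- 0L; hi <- k - 1L
  id_sum <- sum(vapply(lo:hi, col_id, numeric(1)))
  ncol <- k
  repeat {                                   # right
    nxt <- hi + 1L
    if (any(starts + nxt > lens)) break
    ci <- col_id(nxt)
    if ((id_sum + ci) / (ncol + 1L) < thr) break
    id_sum <- id_sum + ci; ncol <- ncol + 1L; hi <- nxt
  }
  repeat {                                   # left
    nxt <- lo - 1L
    if (any(starts + nxt < 1L)) break
    ci <- col_id(nxt)
    if ((id_sum + ci) / (ncol + 1L) < thr) break
    id_sum <- id_sum + ci; ncol <- ncol + 1L; lo <- nxt
  }
  bases <- c("A", "C", "G", "T", "N")
  consensus <- vapply(lo:hi, function(off) {
    cnt <- tabulate(vapply(seq_len(nsp), function(s)
      codes[[s]][starts[s] + off], integer(1)), 5L)
    bases[which.max(cnt)]
  }, character(1))
  list(starts = starts + lo, len = ncol, identity = id_sum / ncol,
       consensus = consensus)
}

#' Tabulate conserved blocks
#'
#' @param blocks Output of [find_conserved_blocks()].
#' @return Data frame with `label`, `length`, `identity`, `consensus` and one
#'   `start_<species>` column per species (0-based).
#' @export
conserved_block_table <- function(blocks) {
  if (!length(blocks))
    return(data.frame(label = character(0), length = integer(0),
                      identity = numeric(0), consensus = character(0),
                      stringsAsFactors = FALSE))
  sp <- names(blocks[[1]]$starts)
  base <- data.frame(
    label = vapply(blocks, `[[`, character(1), "label"),
    length = vapply(blocks, `[[`, numeric(1), "length"),
    identity = vapply(blocks, `[[`, numeric(1), "identity"),
    consensus = vapply(blocks, `[[`, character(1), "consensus"),
    stringsAsFactors = FALSE)
  for (s in sp)
    base[[paste0("start_", s)]] <-
      vapply(blocks, function(b) unname(b$starts[s]), numeric(1))
  base
}

#' Scan for canonical control-region flanking motifs
#'
#' Presence scans for the "TATA" motif near the 5' end and the "G(A)nT"
#' motif (G, one or more A, then T) near the 3' end; absence is reported as
#' such, never imputed.
#'
#' @param cr Control-region nucleotide string.
#' @param window Window size at each end.
#' @return List `tata_5prime`, `ga_n_t_3prime` (logicals).
#' @export
motif_scan <- function(cr, window = 50) {
  cr <- check_dna(cr, "control region")
  n <- nchar(cr)
  w <- min(window, n)
  list(tata_5prime = grepl("TATA", substr(cr, 1, w), fixed = TRUE),
       ga_n_t_3prime = grepl("GA+T", substr(cr, n - w + 1, n)))
}

#' Annotated text rendering of a control region
#'
#' Renders the sequence in 60-column lines with a marker line boxing
#' T-stretches (`^`) and underlining tandem repeats (`~`).
#'
#' @param cr Control-region nucleotide string.
#' @param tstretches Output of [find_t_stretches()].
#' @param repeats Output of [find_tandem_repeats()].
#' @return Character vector of alternating sequence/marker lines.
#' @export
render_control_region <- function(cr, tstretches = find_t_stretches(cr),
                                  repeats = find_tandem_repeats(cr)) {
  n <- nchar(cr)
  marks <- rep(" ", n)
  if (nrow(repeats))
    for (i in seq_len(nrow(repeats)))
      marks[(repeats$start[i] + 1):repeats$end[i]] <- "~"
  if (nrow(tstretches))
    for (i in seq_len(nrow(tstretches)))
      marks[(tstretches$start[i] + 1):(tstretches$start[i] + tstretches$length[i])] <- "^"
  out <- character(0)
  for (p in seq(1, n, by = 60)) {
    q <- min(p + 59, n)
    out <- c(out, substr(cr, p, q),
             paste(marks[p:q], collapse = ""))
  }
  out
}
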