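# Shared fixtures: all built in code, deterministic under fixed seeds.

# random DNA with given base probabilities
rand_dna <- function(n, probs = c(A = .3, C = .2, G = .2, T = .3)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# a tiny annotation set: features tiling (or not) a small genome
tiny_annotation <- function(seq, feats) {
  g <- genome(seq, id = "TINY", organism = "Testum exemplare")
  annotation_set(g, feats)
}

# minimal GenBank flat-file text for a 60-bp circular genome with a plus
# feature, a complement feature, and an origin-spanning join
write_tiny_genbank <- function(path) {
  seq60 <- paste0("ATGAAATTTCCCGGGAAATTTATGCCCAAATTTGGGCCCAAATTTATATATGCGCGCAT")
  seq60 <- paste0(seq60, "A")  # 60 bp
  stopifnot(nchar(seq60) == 60)
  lines <- c(
    "LOCUS       TINYREC 60 bp    DNA     circular   INV",
    "DEFINITION  Testum exemplare mitochondrion, partial toy record.",
    "  ORGANISM  Testum exemplare",
    "FEATURES             Location/Qualifiers",
    "     tRNA            1..10",
    "                     /gene=\"trnI\"",
    "     tRNA            complement(11..20)",
    "                     /gene=\"trnQ\"",
    "     tRNA            join(55..60,1..4)",
    "                     /gene=\"trnM\"",
    "ORIGIN",
    sprintf("%9d %s %s %s %s %s %s", 1,
            substr(tolower(seq60), 1, 10), substr(tolower(seq60), 11, 20),
            substr(tolower(seq60), 21, 30), substr(tolower(seq60), 31, 40),
            substr(tolower(seq60), 41, 50), substr(tolower(seq60), 51, 60)),
    "//")
  writeLines(lines, path)
  seq60
}

# mirror an annotation set: reverse-complement the genome and flip every
# feature's strand and coordinates
mirror_annotation <- function(a) {
  L <- a$genome$length
  g2 <- genome(revcomp(a$genome$sequence), id = a$genome$id,
               organism = a$genome$organism, circular = a$genome$circular)
  feats <- lapply(a$features, function(f) {
    sp <- cbind(L - f$spans[, 2], L - f$spans[, 1])
    sp <- sp[rev(seq_len(nrow(sp))), , drop = FALSE]
    feature(f$name, sp, strand = if (f$strand == "J") "N" else "J",
            klass = f$klass, canonical = f$canonical)
  })
  annotation_set(g2, feats)
}

# rotate a circular annotation set so position `k` (0-based) becomes the new
# origin; only valid when no feature crosses position k
rotate_annotation <- function(a, k) {
  L <- a$genome$length
  s <- a$genome$sequence
  g2 <- genome(paste0(substr(s, k + 1, L), substr(s, 1, k)),
               id = a$genome$id, organism = a$genome$organism)
  feats <- lapply(a$features, function(f) {
    sp <- (f$spans - k) %% L
    # a span that now wraps the origin becomes two spans
    if (nrow(sp) == 1 && sp[1, 2] <= sp[1, 1] && sp[1, 2] != 0) {
      sp <- rbind(c(sp[1, 1], L), c(0, sp[1, 2]))
    } else if (nrow(sp) == 1 && sp[1, 2] == 0) {
      sp[1, 2] <- L
    } else if (nrow(sp) == 2) {
      # previously wrapping feature may become contiguous
      if (sp[1, 2] %% L == sp[2, 1]) sp <- cbind(sp[1, 1], sp[2, 2])
      if (any(sp == 0) && nrow(sp) == 2 && sp[2, 2] == 0) sp[2, 2] <- L
    }
    feature(f$name, sp, strand = f$strand, klass = f$klass,
            canonical = f$canonical)
  })
  annotation_set(g2, feats)
}

# planted control region pair used by the recovery battery: one CR carrying
# a T-stretch, stem-loop, tandem repeat and conserved block, a second CR
# sharing the block at a different offset
planted_cr_pair <- function(seed, noise = 0) {
  set.seed(seed)
  n <- 560
  s <- strsplit(random_seq_exact(n, 0.86, 0.15, -0.15), "")[[1]]
  put <- function(off, str) {
    ch <- strsplit(str, "")[[1]]
    s[(off + 1):(off + length(ch))] <<- ch
    c(off, length(ch))
  }
  ts <- put(60, "TTTTCTTTTCTTT")
  arm <- random_seq_exact(12, 0.6)
  sl <- put(200, paste0(arm, random_seq_exact(6, 0.8), revcomp(arm)))
  unit <- random_seq_exact(7, 0.75, 0.1, -0.1)
  tr <- put(330, substr(strrep(unit, 7), 1, 38))
  blk <- random_seq_exact(30, 0.8)
  b1 <- put(460, blk)
  cr1 <- paste(s, collapse = "")
  s2 <- strsplit(random_seq_exact(n, 0.86, 0.15, -0.15), "")[[1]]
  s2[101:130] <- strsplit(blk, "")[[1]]
  cr2 <- paste(s2, collapse = "")
  mut <- function(x) {
    if (noise == 0) return(x)
    ch <- strsplit(x, "")[[1]]
    hit <- which(runif(length(ch)) < noise)
    for (i in hit) ch[i] <- sample(setdiff(c("A", "T", "G", "C"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  list(cr1 = mut(cr1), cr2 = mut(cr2), ts = ts, sl = sl, tr = tr,
       b1 = b1, b2 = c(100, 30), unit = unit, copies = 38 / 7)
}

# interval overlap in bp
interval_overlap <- function(a_start, a_len, b_start, b_len)
  max(0, min(a_start + a_len, b_start + b_len) - max(a_start, b_start))

# run all four detectors on a planted pair and report which plants were
# recovered (criteria documented in the methods vignette)
recovery_trial <- function(seed, noise = 0) {
  x <- planted_cr_pair(seed, noise)
  res <- c(t_stretch = FALSE, stem_loop = FALSE, tandem_repeat = FALSE,
           block = FALSE)
  ts <- find_t_stretches(x$cr1, min_len = 9, max_interruptions = 4)
  if (nrow(ts))
    res["t_stretch"] <- any(mapply(interval_overlap, ts$start, ts$length,
                                   MoreArgs = list(b_start = x$ts[1],
                                                   b_len = x$ts[2])) >=
                            0.6 * x$ts[2])
  sl <- find_stem_loops(x$cr1, min_stem = 10, loop_range = c(3, 8),
                        max_mismatch = 3)
  if (nrow(sl))
    res["stem_loop"] <- any(mapply(function(a5, a3, st)
      interval_overlap(a5, a3 + st - a5, x$sl[1], x$sl[2]) >= 0.6 * x$sl[2],
      sl$arm5_start, sl$arm3_start, sl$stem_len))
  tr <- find_tandem_repeats(x$cr1, min_period = 5, max_period = 40,
                            min_copies = 2, min_identity = 70)
  tr7 <- tr[tr$period == 7, , drop = FALSE]
  if (nrow(tr7)) {
    o <- mapply(function(s0, e0) interval_overlap(s0, e0 - s0, x$tr[1], x$tr[2]),
                tr7$start, tr7$end)
    res["tandem_repeat"] <- if (noise == 0) any(abs(o / 7 - x$copies) <= 0.5)
                            else any(o >= 0.7 * x$tr[2])
  }
  bl <- find_conserved_blocks(c(sp1 = x$cr1, sp2 = x$cr2), min_block = 20,
                              min_identity = 85, k = 6)
  if (length(bl))
    res["block"] <- any(vapply(bl, function(b)
      interval_overlap(b$starts[["sp1"]], b$length, x$b1[1], x$b1[2]) >=
        0.8 * x$b1[2] &&
      interval_overlap(b$starts[["sp2"]], b$length, x$b2[1], x$b2[2]) >=
        0.8 * x$b2[2],
      logical(1)))
  res
}
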