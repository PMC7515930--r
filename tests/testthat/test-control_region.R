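# brute-force T-stretch oracle: enumerate every window, keep valid maximal
tstretch_oracle <- function(s, min_len, max_int) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  valid <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (ch[i] != "T" || ch[j] != "T" || j - i + 1 < min_len) next
    ints <- if (j > i + 1) sum(ch[(i + 1):(j - 1)] != "T") else 0
    if (ints <= max_int) valid[[length(valid) + 1]] <- c(i, j, ints)
  }
  if (!length(valid)) return(empty <- data.frame(start = integer(0),
                                                 length = integer(0),
                                                 n_interruptions = integer(0)))
  m <- do.call(rbind, valid)
  keep <- vapply(seq_len(nrow(m)), function(r) {
    !any(m[, 1] <= m[r, 1] & m[, 2] >= m[r, 2] &
         (m[, 1] != m[r, 1] | m[, 2] != m[r, 2]))
  }, logical(1))
  m <- m[keep, , drop = FALSE]
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(start = m[, 1] - 1L, length = m[, 2] - m[, 1] + 1L,
             n_interruptions = m[, 3])
}

test_that("T-stretch detection matches the brute-force oracle", {
  ts <- find_t_stretches("AATTTTTTTTTTTAA", min_len = 5, max_interruptions = 0)
  expect_identical(nrow(ts), 1L)
  expect_identical(ts$length, 11L)
  expect_identical(ts$start, 2L)

  ts2 <- find_t_stretches("TTTTCTTTCTTT", min_len = 10, max_interruptions = 2)
  expect_identical(nrow(ts2), 1L)
  expect_identical(ts2$length, 12L)
  expect_identical(ts2$n_interruptions, 2L)

  expect_identical(nrow(find_t_stretches("ACACACA")), 0L)

  set.seed(401)
  for (i in 1:15) {
    s <- rand_dna(80, probs = c(A = .2, C = .1, G = .1, T = .6))
    got <- find_t_stretches(s, min_len = 6, max_interruptions = 2)
    want <- tstretch_oracle(s, 6, 2)
    expect_equal(got, want, ignore_attr = TRUE, info = paste("case", i))
  }
})

test_that("reported T-stretches satisfy their own predicate", {
  set.seed(402)
  for (i in 1:10) {
    s <- rand_dna(200, probs = c(A = .25, C = .1, G = .1, T = .55))
    ts <- find_t_stretches(s, min_len = 8, max_interruptions = 3)
    for (r in seq_len(nrow(ts))) {
      w <- substr(s, ts$start[r] + 1, ts$start[r] + ts$length[r])
      ch <- strsplit(w, "")[[1]]
      expect_identical(ch[1], "T")
      expect_identical(ch[length(ch)], "T")
      expect_identical(sum(ch != "T"), ts$n_interruptions[r])
      expect_lte(sum(ch != "T"), 3L)
    }
  }
})

test_that("stem-loops: planted palindromes, G-T wobble, negative control", {
  s <- paste0(strrep("G", 12), "AAAA", strrep("C", 12))
  sl <- find_stem_loops(s, min_stem = 12, loop_range = c(3, 8))
  expect_identical(sl$stem_len[1], 12L)
  expect_identical(sl$loop_len[1], 4L)
  expect_identical(sl$arm5_start[1], 0L)

  # one G-T arm pairing: detected at full length only when wobble is allowed
  arm5 <- "GATCGATCGGGT"
  arm3 <- revcomp(arm5)
  arm3 <- paste0("G", substr(arm3, 2, 12))   # partner of terminal T becomes G
  s2 <- paste0("AA", arm5, "ATATA", arm3, "AA")
  sl_gu <- find_stem_loops(s2, min_stem = 12, loop_range = c(3, 8),
                           allow_gu = TRUE)
  expect_true(any(sl_gu$stem_len >= 12))
  sl_wc <- find_stem_loops(s2, min_stem = 12, loop_range = c(3, 8),
                           allow_gu = FALSE)
  expect_false(any(sl_wc$stem_len >= 12))
  expect_true(any(find_stem_loops(s2, min_stem = 11,
                                  loop_range = c(3, 8))$stem_len == 11))

  # shuffled sequences of the same composition essentially never carry a
  # 12-bp perfect stem
  set.seed(403)
  hits <- 0
  for (i in 1:20) {
    sh <- paste(sample(strsplit(s2, "")[[1]]), collapse = "")
    hits <- hits + (nrow(find_stem_loops(sh, min_stem = 12,
                                         loop_range = c(3, 8))) > 0)
  }
  expect_lte(hits, 1)
})

test_that("reported stem-loops re-extract arms that pair", {
  set.seed(404)
  x <- planted_cr_pair(99)
  sl <- find_stem_loops(x$cr1, min_stem = 10, loop_range = c(3, 8))
  expect_gt(nrow(sl), 0)
  ch <- strsplit(x$cr1, "")[[1]]
  for (r in seq_len(min(nrow(sl), 5))) {
    a5 <- (sl$arm5_start[r] + 1):(sl$arm5_start[r] + sl$stem_len[r])
    a3 <- (sl$arm3_start[r] + sl$stem_len[r]):(sl$arm3_start[r] + 1)
    pairs <- paste0(ch[a5], ch[a3])
    ok <- pairs %in% c("AT", "TA", "GC", "CG")
    expect_identical(sum(!ok), sl$n_mismatch[r])
  }
})

test_that("tandem repeats: exact, substituted, planted, rotation-tolerant", {
  tr <- find_tandem_repeats("ACGTACGTACGTACGT", min_period = 2,
                            max_period = 8, min_copies = 2, min_identity = 70)
  expect_identical(tr$period[1], 4L)
  expect_equal(tr$copies[1], 4)
  expect_equal(tr$identity[1], 100)

  tr2 <- find_tandem_repeats("ACGTACGTACGTAAGT", min_period = 2,
                             max_period = 8, min_copies = 2, min_identity = 70)
  expect_identical(tr2$period[1], 4L)
  expect_equal(tr2$copies[1], 4)
  expect_gte(tr2$identity[1], 90)

  x <- planted_cr_pair(7)
  tr3 <- find_tandem_repeats(x$cr1, min_period = 5, max_period = 40)
  hit <- tr3[tr3$period == 7, , drop = FALSE]
  expect_gt(nrow(hit), 0)
  o <- mapply(function(s0, e0) interval_overlap(s0, e0 - s0, x$tr[1], x$tr[2]),
              hit$start, hit$end)
  expect_true(any(abs(o / 7 - x$copies) <= 0.5))
  # the consensus is a rotation of the planted unit
  best <- hit[which.max(o), ]
  rotations <- vapply(1:7, function(k)
    paste0(substr(x$unit, k, 7), substr(x$unit, 1, k - 1)), character(1))
  expect_true(best$consensus %in% rotations)
})

test_that("reported repeats re-extract arrays matching their consensus", {
  x <- planted_cr_pair(12)
  tr <- find_tandem_repeats(x$cr1, min_period = 5, max_period = 40)
  ch <- strsplit(x$cr1, "")[[1]]
  for (r in seq_len(nrow(tr))) {
    region <- ch[(tr$start[r] + 1):tr$end[r]]
    cons <- strsplit(tr$consensus[r], "")[[1]]
    ident <- 100 * mean(region == cons[((seq_along(region) - 1) %% tr$period[r]) + 1])
    expect_equal(ident, tr$identity[r])
    expect_gte(ident, 70)
    expect_equal(tr$copies[r], length(region) / tr$period[r])
  }
})

test_that("conserved blocks: identical pair, planted block, negative control", {
  set.seed(405)
  s <- rand_dna(100)
  bl <- find_conserved_blocks(c(a = s, b = s), min_block = 20,
                              min_identity = 90)
  expect_length(bl, 1)
  expect_identical(bl[[1]]$length, 100L)
  expect_identical(unname(bl[[1]]$starts), c(0L, 0L))
  expect_equal(bl[[1]]$identity, 100)
  expect_identical(bl[[1]]$label, "E1")

  blk <- rand_dna(30)
  s1 <- paste0(rand_dna(40), blk, rand_dna(50))
  s2 <- paste0(rand_dna(90), blk, rand_dna(10))
  bl2 <- find_conserved_blocks(c(a = s1, b = s2), min_block = 25,
                               min_identity = 90)
  expect_gte(length(bl2), 1)
  hit <- Filter(function(b)
    interval_overlap(b$starts[["a"]], b$length, 40, 30) >= 25 &&
    interval_overlap(b$starts[["b"]], b$length, 90, 30) >= 25, bl2)
  expect_length(hit, 1)

  r1 <- rand_dna(300); r2 <- rand_dna(300)
  expect_length(find_conserved_blocks(c(a = r1, b = r2), min_block = 25,
                                      min_identity = 90), 0)
})

test_that("motif scans report presence and absence plainly", {
  cr <- paste0("AATATAAA", strrep("C", 50), "GGAAAATCC")
  mo <- motif_scan(cr, window = 10)
  expect_true(mo$tata_5prime)
  expect_true(mo$ga_n_t_3prime)
  mo2 <- motif_scan(strrep("C", 60), window = 20)
  expect_false(mo2$tata_5prime)
  expect_false(mo2$ga_n_t_3prime)
})

test_that("the annotated rendering marks T-stretches and repeats", {
  x <- planted_cr_pair(3)
  out <- render_control_region(x$cr1)
  expect_equal(length(out) %% 2, 0)
  expect_true(any(grepl("\\^", out)))
})
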