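test_that("pair classification is unordered and complete", {
  st <- list(sequence = "GU", pairs = cbind(1L, 2L))
  cl <- classify_pairs(st)
  expect_identical(unname(cl$counts[["wobble"]]), 1L)
  expect_identical(cl$non_canonical, 1L)

  st2 <- list(sequence = "UG", pairs = cbind(1L, 2L))
  expect_identical(classify_pairs(st2)$counts[["wobble"]], 1L)

  acc <- list(sequence = paste0(strrep("G", 7), strrep("C", 7)),
              pairs = cbind(1:7, 14:8))
  cl2 <- classify_pairs(acc)
  expect_identical(unname(cl2$counts[["canonical"]]), 7L)
  expect_identical(cl2$non_canonical, 0L)
  expect_identical(cl2$total, 7L)

  mix <- list(sequence = "AUGUAAUCUUCC",
              pairs = cbind(c(1L, 3L, 5L, 7L, 9L), c(2L, 4L, 6L, 8L, 10L)))
  cl3 <- classify_pairs(mix)
  expect_identical(cl3$total, 5L)
  expect_identical(sum(cl3$counts), 5L)
  expect_error(classify_pairs(list(sequence = "AU", pairs = cbind(1L, 9L))),
               "out of range")
})

test_that("the folder recovers a perfect cloverleaf template exactly", {
  for (seed in c(1, 5, 9)) {
    tpl <- cloverleaf_template(seed = seed)
    f <- fold_cloverleaf(tpl$sequence,
                         anticodon = substr(tpl$sequence, 34, 36))
    key <- function(p) sort(paste(p[, 1], p[, 2]))
    expect_identical(key(f$pairs), key(tpl$pairs))
    expect_length(f$incomplete_arms, 0)
    expect_false(f$unfoldable)
    cl <- classify_pairs(f)
    expect_identical(unname(cl$counts[["canonical"]]), 21L)
  }
})

test_that("a planted stem mutation is recovered as the right mismatch class", {
  tpl <- cloverleaf_template(seed = 3)
  s <- strsplit(tpl$sequence, "")[[1]]
  # force the middle anticodon-stem pair to U-U (a planted mismatch)
  acs <- which(tpl$arm == "anticodon")[3]
  p <- tpl$pairs[acs, ]
  s[p[1]] <- "U"; s[p[2]] <- "U"
  f <- fold_cloverleaf(paste(s, collapse = ""),
                       anticodon = substr(tpl$sequence, 34, 36))
  key <- function(p) sort(paste(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2])))
  expect_identical(key(f$pairs), key(tpl$pairs))   # same topology
  cl <- classify_pairs(f)
  expect_identical(unname(cl$counts[["U-U"]]), 1L)
  expect_identical(cl$non_canonical, 1L)
})

test_that("templates with one mismatch per stem keep their stem boundaries", {
  set.seed(301)
  for (rep in 1:20) {
    tpl <- cloverleaf_template(seed = 400 + rep)
    s <- strsplit(tpl$sequence, "")[[1]]
    # mutate one inner pair position in one randomly chosen stem
    arm <- sample(c("acceptor", "DHU", "anticodon", "TPsiC"), 1)
    idx <- which(tpl$arm == arm)
    inner <- idx[-c(1)]                     # keep the outermost pair intact
    p <- tpl$pairs[sample(inner, 1), ]
    s[p[1]] <- sample(setdiff(c("A", "C", "G", "U"), s[p[1]]), 1)
    f <- fold_cloverleaf(paste(s, collapse = ""),
                         anticodon = substr(tpl$sequence, 34, 36))
    key <- function(pr) sort(paste(pr[, 1], pr[, 2]))
    expect_identical(key(f$pairs), key(tpl$pairs), label = paste("rep", rep))
  }
})

test_that("a truncated 58-nt molecule is flagged with an incomplete TPsiC arm", {
  tpl <- cloverleaf_template(seed = 8)
  # drop the TPsiC arm region (positions 48..60), keeping 58 nt
  s <- paste0(substr(tpl$sequence, 1, 47), substr(tpl$sequence, 61, 71))
  expect_identical(nchar(s), 58L)
  f <- fold_cloverleaf(s, anticodon = substr(tpl$sequence, 34, 36))
  expect_true("TPsiC" %in% f$incomplete_arms)
})

test_that("sequences outside the tRNA size range are rejected", {
  expect_error(fold_cloverleaf(strrep("A", 30)), "length")
  expect_error(fold_cloverleaf(strrep("A", 200)), "length")
})

test_that("global alignment counts differences and matches the score oracle", {
  al <- align_global("ACGT", "ACGT")
  expect_identical(c(al$substitutions, al$indels), c(0L, 0L))
  al2 <- align_global("ACGT", "ACGA")
  expect_identical(c(al2$substitutions, al2$indels), c(1L, 0L))
  al3 <- align_global("ACGT", "ACGGT")
  expect_identical(c(al3$substitutions, al3$indels), c(0L, 1L))

  set.seed(302)
  for (i in 1:10) {
    a <- rand_dna(sample(20:60, 1)); b <- rand_dna(sample(20:60, 1))
    mine <- align_global(a, b)$score
    oracle <- Biostrings::pairwiseAlignment(
      a, b, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE),
      gapOpening = 0, gapExtension = 2)
    expect_equal(mine, Biostrings::score(oracle))
  }
})

test_that("cross-genome tRNA comparison ranks by conservation", {
  structs <- list(
    g1 = c(trnF = "GCGGAUUUAGCUCAGUUGGG", trnG = "AAACCCUUUGGG",
           trnK = "AAAAUUUUCCCC"),
    g2 = c(trnF = "GCGGAUUUAGCUCAGUUGGG", trnG = "AAACCCAUUUGGG",
           trnK = "AAAAUUAUCGCC"),
    g3 = c(trnF = "GCGGAUUUAGCUCAGUUGGG", trnW = "AAAAGGGGCCCC"))
  expect_silent(compare_trna_across_genomes(structs[1:2]))
  expect_warning(out <- compare_trna_across_genomes(structs),
                 "fewer than two genomes")
  expect_identical(out$trna[1], "trnF")
  expect_identical(out$total[out$trna == "trnF"], 0L)
  expect_identical(out$indels[out$trna == "trnG"], 1L)
  expect_true(out$total[out$trna == "trnK"] >= 2)
})

test_that("dot-bracket rendering is consistent with the pairing", {
  tpl <- cloverleaf_template(seed = 2)
  db <- dot_bracket(tpl)
  expect_identical(nchar(db[2]), nchar(tpl$sequence))
  expect_identical(sum(strsplit(db[2], "")[[1]] == "("), nrow(tpl$pairs))
})
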