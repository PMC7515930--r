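code <- mito_genetic_code()

test_that("translation table 5 has the invertebrate mitochondrial structure", {
  fam <- code$families
  expect_identical(sort(code$stops), c("TAA", "TAG"))
  expect_identical(unname(fam$family_size[fam$codon == "TTA"]), 6L)  # Leu
  expect_identical(unname(fam$family_size[fam$codon == "AGA"]), 8L)  # Ser incl AGN
  expect_identical(sort(fam$codon[fam$aa == "M"]), c("ATA", "ATG"))
  expect_identical(unname(code$map[["TGA"]]), "W")
})

test_that("codon counting handles stops and incomplete codons", {
  ct <- count_codons(c(g = "ATGAAATAA"), exclude_stop = TRUE)
  expect_identical(unname(ct$pooled[c("ATG", "AAA", "TAA")]), c(1L, 1L, 0L))
  expect_identical(ct$total, 2L)
  ct2 <- count_codons(c(g = "ATGATG"))
  expect_identical(unname(ct2$pooled["ATG"]), 2L)
  # trailing incomplete codon ignored; stop kept when exclude_stop = FALSE
  ct3 <- count_codons(c(g = "ATGAAATAAT"), exclude_stop = FALSE)
  expect_identical(ct3$total, 3L)
  expect_identical(unname(ct3$pooled["TAA"]), 1L)
  # pooled equals the sum of per-gene rows
  ct4 <- count_codons(c(a = "ATGATG", b = "ATGAAA"))
  expect_equal(unname(colSums(ct4$per_gene)), unname(as.numeric(ct4$pooled)))
})

test_that("rscu matches a brute-force family normalization oracle", {
  r <- rscu(count_codons(c(g = paste0("AAAAAAAAA", "AAG"))), code)
  expect_equal(r$rscu[r$codon == "AAA"], 1.5)
  expect_equal(r$rscu[r$codon == "AAG"], 0.5)

  set.seed(201)
  for (i in 1:30) {
    cnt <- setNames(rpois(64, lambda = sample(c(0.5, 3, 20), 1)),
                    mitocomp:::ALL_CODONS)
    r <- rscu(cnt, code)
    # oracle: per codon, count * family size / family total
    for (j in sample(nrow(r), 8)) {
      fam_codons <- code$families$codon[code$families$aa == r$aa[j]]
      tot <- sum(cnt[fam_codons])
      expected <- if (tot == 0) NA_real_ else
        unname(cnt[r$codon[j]] * length(fam_codons) / tot)
      expect_equal(r$rscu[j], expected)
    }
    # family-sum invariant
    sums <- as.numeric(tapply(r$rscu, r$aa, sum))
    sizes <- as.numeric(tapply(r$rscu, r$aa, length))
    ok <- !is.na(sums)
    expect_equal(sums[ok], sizes[ok])
  }
})

test_that("uniform families give RSCU exactly 1", {
  cnt <- setNames(rep(7L, 64), mitocomp:::ALL_CODONS)
  r <- rscu(cnt, code)
  expect_true(all(r$rscu == 1))
})

test_that("start/stop classification follows ATN and TAA/TAG conventions", {
  mk <- function(cds, strand = "J") {
    tiny_annotation(if (strand == "J") cds else revcomp(cds),
                    list(feature("ND3", c(0, nchar(cds)), strand = strand)))
  }
  r <- start_stop_report(mk("ATGAAATAA"))
  expect_identical(r$start_codon, "ATG")
  expect_true(r$canonical_start)
  expect_identical(r$stop_codon, "TAA")
  expect_identical(r$stop_type, "complete")

  r <- start_stop_report(mk("ATTAAATAG"))
  expect_identical(r$start_codon, "ATT")
  expect_true(r$canonical_start)
  expect_identical(r$stop_codon, "TAG")

  r <- start_stop_report(mk("ACCAAATAA"))       # non-ATN start, reported as-is
  expect_false(r$canonical_start)
  expect_identical(r$start_codon, "ACC")

  r <- start_stop_report(mk("ATGAAAAAAT"))      # truncated stop
  expect_identical(r$stop_codon, "T--")
  expect_identical(r$stop_type, "truncated")

  r <- start_stop_report(mk("ATGAAACAT", strand = "N"))
  expect_identical(r$start_codon, "ATG")        # sense-strand codon

  expect_error(start_stop_report(mk("ATGT")), "shorter than 6")
})

test_that("amino-acid ranking is descending with deterministic ties", {
  cnt <- setNames(rep(0L, 64), mitocomp:::ALL_CODONS)
  cnt[c("TTA", "ATT", "TTT")] <- c(5L, 3L, 1L)
  r <- amino_acid_ranking(cnt, code)
  expect_identical(r$aa3, c("Leu", "Ile", "Phe"))
  expect_identical(r$count, c(5, 3, 1))
  # empty counts -> empty ranking
  r0 <- amino_acid_ranking(setNames(rep(0L, 64), mitocomp:::ALL_CODONS), code)
  expect_identical(nrow(r0), 0L)
  # tie broken by one-letter code
  cnt[c("TTA", "ATT", "TTT")] <- c(2L, 2L, 2L)
  r <- amino_acid_ranking(cnt, code)
  expect_identical(r$aa, c("F", "I", "L"))
  # total usage equals total codon count
  ct <- count_codons(c(g = "ATGAAATTTCCCTAA"))
  rk <- amino_acid_ranking(ct, code)
  expect_identical(sum(rk$count), as.numeric(ct$total))
})

test_that("translation reproduces a known peptide and matches Biostrings", {
  set.seed(202)
  sense <- code$families
  for (i in 1:10) {
    pep <- paste(sample(unique(sense$aa), 25, replace = TRUE), collapse = "")
    cds <- paste(vapply(strsplit(pep, "")[[1]], function(aa)
      sample(sense$codon[sense$aa == aa], 1), character(1)), collapse = "")
    expect_identical(translate_cds(cds, code), pep)
    oracle <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds), genetic.code = Biostrings::getGeneticCode("5"),
      no.init.codon = TRUE))
    expect_identical(translate_cds(cds, code), oracle)
  }
})

test_that("absent codons are those with pooled zero count, stops excluded", {
  ct <- count_codons(c(g = "ATGAAATAA"))
  ab <- absent_codons(ct, code)
  expect_false(any(c("ATG", "AAA") %in% ab$codon))
  expect_false(any(code$stops %in% ab$codon))
  expect_identical(nrow(ab), 60L)   # 62 sense codons, 2 used
})
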