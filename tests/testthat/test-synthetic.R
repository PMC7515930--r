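test_that("generation is byte-identical for a fixed seed", {
  g1 <- generate_genome(default_genome_spec(seed = 81))
  g2 <- generate_genome(default_genome_spec(seed = 81))
  expect_identical(g1$annotation$genome$sequence, g2$annotation$genome$sequence)
  expect_identical(g1$manifest, g2$manifest)
  g3 <- generate_genome(default_genome_spec(seed = 82))
  expect_false(identical(g1$annotation$genome$sequence,
                         g3$annotation$genome$sequence))
})

test_that("the default genome meets its headline composition contract", {
  gen <- generate_genome(default_genome_spec(seed = 83))
  tab <- composition_table(gen$annotation)
  wg <- tab[tab$partition == "whole_genome_J", ]
  expect_gte(wg$at_percent, 75.5)
  expect_lte(wg$at_percent, 77.5)
  cr <- tab[tab$partition == "AT_rich", ]
  expect_gte(cr$at_percent, 85.5)
  expect_lte(cr$at_percent, 87.5)
  expect_gt(tab$at_percent[tab$partition == "codon_pos3"], 90)
})

test_that("exact-count sequence synthesis hits its targets exactly", {
  set.seed(84)
  for (i in 1:10) {
    n <- sample(300:900, 1)
    at <- runif(1, 0.5, 0.9); sk <- runif(1, -0.3, 0.3); gk <- runif(1, -0.3, 0.3)
    s <- random_seq_exact(n, at, sk, gk)
    cnt <- base_counts(s)
    atn <- as.integer(round(at * n))
    expect_identical(cnt[["a"]] + cnt[["t"]], atn)
    expect_identical(cnt[["a"]], as.integer(round(atn * (1 + sk) / 2)))
  }
  expect_error(random_seq_exact(10, 1.4), "at_frac")
})

test_that("manifests record exact realized truth", {
  gen <- generate_genome(default_genome_spec(seed = 85))
  a <- gen$annotation; m <- gen$manifest
  expect_identical(m$genome_length, a$genome$length)
  # planted features re-extract their recorded sequences
  for (p in m$planted) {
    got <- substr(a$genome$sequence, p$abs_start + 1, p$abs_start + p$length)
    expect_identical(got, p$sequence)
  }
  # the planted repeat really has its period
  tr <- m$planted$tandem_repeat
  reg <- strsplit(tr$sequence, "")[[1]]
  expect_true(all(reg == strsplit(strrep(tr$unit, 6), "")[[1]][seq_along(reg)]))
  # feature coordinate table matches the annotation
  nm <- vapply(a$features, function(f) f$name, character(1))
  expect_identical(m$features$name, nm)
})

test_that("generate_cds realizes the bias and appends a stop", {
  s <- generate_cds(9, seed = 86)
  expect_identical(nchar(s), 12L)
  expect_true(substr(s, 10, 12) %in% c("TAA", "TAG"))

  code <- mito_genetic_code()
  # uniform bias within each family -> all RSCU within 1 +/- 0.05
  fam <- code$families
  bias <- setNames(rep(0, 64), mitocomp:::ALL_CODONS)
  for (aa in unique(fam$aa)) {
    cods <- fam$codon[fam$aa == aa]
    bias[cods] <- 1 / length(cods) / length(unique(fam$aa))
  }
  cds <- generate_cds(3 * 30000, bias = bias, seed = 87)
  r <- rscu(count_codons(c(g = cds)), code)
  expect_true(all(abs(r$rscu - 1) <= 0.05, na.rm = TRUE))

  # bias concentrated on TTA pushes RSCU(TTA) towards the Leu family size
  bias2 <- bias
  leu <- fam$codon[fam$aa == "L"]
  bias2[leu] <- c(0.9, rep(0.1 / 5, 5))[order(leu != "TTA")] * sum(bias[leu])
  cds2 <- generate_cds(3 * 30000, bias = bias2, seed = 88)
  r2 <- rscu(count_codons(c(g = cds2)), code)
  expect_gt(r2$rscu[r2$codon == "TTA"], 5.2)
})

test_that("realized RSCU converges to the bias-implied values with length", {
  code <- mito_genetic_code()
  bias <- default_codon_bias()
  implied <- rscu(setNames(bias * 1e9, names(bias)), code)
  dev <- vapply(c(300, 3000, 30000), function(n_codon) {
    cds <- generate_cds(3 * n_codon, bias = bias, seed = 89)
    r <- rscu(count_codons(c(g = cds)), code)
    max(abs(r$rscu - implied$rscu), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(dev) <= 0))
  expect_lte(dev[3], 0.05)
})

test_that("infeasible specs are rejected before generation", {
  sp <- default_genome_spec(seed = 90)
  sp$targets$AT_rich <- c(1.2, 0, 0)
  expect_error(generate_genome(sp), "at_frac|<=")
  expect_error(genome_spec(sp$gene_order, sp$lengths[-1], sp$targets,
                           sp$codon_bias), "lengths missing")
  bad_len <- sp$lengths; bad_len["ND2"] <- 1000
  expect_error(genome_spec(sp$gene_order, bad_len, sp$targets, sp$codon_bias),
               "multiples of 3")
})

test_that("spec JSON round-trips to identical generation", {
  spec <- default_genome_spec(seed = 91)
  path <- withr::local_tempfile(fileext = ".json")
  write_genome_spec(spec, path)
  spec2 <- read_genome_spec(path)
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec2)
  expect_identical(g1$annotation$genome$sequence, g2$annotation$genome$sequence)
})

test_that("study sets share their planted conserved block", {
  st <- generate_study_set(3, seed = 92)
  expect_length(st$sets, 3)
  for (m in st$manifests) {
    expect_identical(m$planted$block$sequence, st$block_seq)
  }
  # and the study genomes differ elsewhere
  expect_false(identical(st$sets[[1]]$genome$sequence,
                         st$sets[[2]]$genome$sequence))
})
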