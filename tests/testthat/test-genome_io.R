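test_that("gene names normalize onto the canonical vocabulary", {
  cases <- list(
    c("COI", "COXI"), c("cox1", "COXI"), c("COIII", "COXIII"),
    c("16S ribosomal RNA", "rrnL"), c("12S rRNA", "rrnS"),
    c("NADH dehydrogenase subunit 4L", "ND4L"), c("nad5", "ND5"),
    c("cytochrome b", "CYTB"), c("ATPase8", "ATP8"),
    c("trnL2", "trnL_UUR"), c("trnL(CUN)", "trnL_CUN"),
    c("trnS1", "trnS_AGN"), c("tRNA-Ser (UCN)", "trnS_UCN"),
    c("tRNA-Met", "trnM"), c("trnA", "trnA"),
    c("D-loop", "AT_rich"), c("control region", "AT_rich"))
  for (cs in cases) expect_identical(normalize_gene_name(cs[1]), cs[2])
  # leucine/serine disambiguation from the anticodon: TAA reads UUA (a UUR
  # codon), TAG reads CUN; GCT reads AGC (an AGN codon)
  expect_identical(normalize_gene_name("tRNA-Leu", anticodon = "TAA"), "trnL_UUR")
  expect_identical(normalize_gene_name("tRNA-Leu", anticodon = "TAG"), "trnL_CUN")
  expect_identical(normalize_gene_name("tRNA-Ser", anticodon = "GCT"), "trnS_AGN")
  expect_identical(normalize_gene_name("tRNA-Leu"), NA_character_)
  expect_identical(normalize_gene_name("hypothetical protein"), NA_character_)
})

test_that("GenBank coordinates convert to 0-based half-open with wraparound", {
  path <- withr::local_tempfile(fileext = ".gb")
  seq60 <- write_tiny_genbank(path)
  a <- read_genbank(path)
  expect_s3_class(a, "annotation_set")
  expect_identical(a$genome$sequence, seq60)
  expect_true(a$genome$circular)

  f1 <- get_feature(a, "trnI")          # "1..10" plus strand
  expect_identical(unname(f1$spans[1, ]), c(0L, 10L))
  expect_identical(f1$strand, "J")

  f2 <- get_feature(a, "trnQ")          # complement(11..20)
  expect_identical(f2$strand, "N")
  expect_identical(extract_feature_sequence(a, "trnQ"),
                   revcomp(substr(seq60, 11, 20)))

  f3 <- get_feature(a, "trnM")          # join(55..60,1..4) across the origin
  expect_identical(nrow(f3$spans), 2L)
  expect_identical(unname(f3$spans[1, ]), c(54L, 60L))
  expect_identical(unname(f3$spans[2, ]), c(0L, 4L))
  expect_identical(feature_length(f3), 10L)
  expect_identical(extract_feature_sequence(a, "trnM"),
                   paste0(substr(seq60, 55, 60), substr(seq60, 1, 4)))
})

test_that("unmappable feature names are retained with a warning, not guessed", {
  path <- withr::local_tempfile(fileext = ".gb")
  lines <- c("LOCUS       X 24 bp DNA circular INV",
             "  ORGANISM  Testum exemplare",
             "FEATURES             Location/Qualifiers",
             "     tRNA            1..12",
             "                     /gene=\"mystery-rna\"",
             "ORIGIN",
             "        1 atgaaatttc ccgggaaatt tatg", "//")
  writeLines(lines, path)
  expect_warning(a <- read_genbank(path), "not mappable")
  f <- a$features[[1]]
  expect_identical(f$name, "mystery-rna")
  expect_false(f$canonical)
  expect_identical(f$klass, "tRNA")
})

test_that("a record without ORIGIN sequence is a parse error", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 10 bp", "FEATURES", "//"), path)
  expect_error(read_genbank(path), "ORIGIN")
})

test_that("extraction honours strand and sense", {
  a <- tiny_annotation("ATGCCC", list(
    feature("trnI", c(0, 3), strand = "J"),
    feature("trnQ", c(0, 3), strand = "N")))
  expect_identical(extract_feature_sequence(a, "trnI"), "ATG")
  expect_identical(extract_feature_sequence(a, "trnQ"), "CAT")
  expect_error(extract_feature_sequence(a, "trnM"), "not present")
})

test_that("feature-table TSV and GenBank writers round-trip exactly", {
  gen <- generate_genome(default_genome_spec(seed = 21))
  a <- gen$annotation
  sig <- function(x) vapply(x$features, function(f)
    paste(f$name, f$klass, f$strand, paste(f$spans, collapse = ","), sep = "|"),
    character(1))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(a, tsv)
  b <- read_feature_table(tsv, a$genome)
  expect_identical(sig(b), sig(a))

  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(a, gb)
  c2 <- read_genbank(gb)
  expect_identical(c2$genome$sequence, a$genome$sequence)
  expect_identical(c2$genome$organism, a$genome$organism)
  expect_identical(sig(c2), sig(a))
})

test_that("sense sequences are invariant under genome mirroring", {
  gen <- generate_genome(default_genome_spec(seed = 22))
  a <- gen$annotation
  m <- mirror_annotation(a)
  for (nm in feature_names(a)[c(1, 5, 12, 25, 38)])
    expect_identical(extract_feature_sequence(m, nm),
                     extract_feature_sequence(a, nm))
})

test_that("duplicate names and out-of-range spans are rejected", {
  g <- genome("ATGCATGCAT")
  f <- feature("trnI", c(0, 4))
  expect_error(annotation_set(g, list(f, f)), "duplicate")
  expect_error(annotation_set(g, list(feature("trnI", c(5, 12)))),
               "extends past")
  expect_error(genome("ATXG"), "invalid characters")
})

test_that("a missing control region is inferred next to rrnS with a warning", {
  set.seed(31)
  parts <- c(rand_dna(60), rand_dna(100), rand_dna(300))
  g <- genome(paste(parts, collapse = ""), id = "NOCr")
  feats <- list(feature("trnV", c(0, 60), strand = "N"),
                feature("rrnS", c(60, 160), strand = "N"))
  a <- annotation_set(g, feats)
  expect_warning(b <- mitocomp:::infer_control_region(a), "AT_rich")
  cr <- get_feature(b, "AT_rich")
  expect_identical(unname(cr$spans[1, ]), c(160L, 460L))
})
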