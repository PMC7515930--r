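# Canonical gene vocabulary for the 37-gene insect mitogenome, name
# normalization, the ancestral insect gene order, and the invertebrate
# mitochondrial genetic code (NCBI translation table 5).

PCG_NAMES <- c("ATP6", "ATP8", "COXI", "COXII", "COXIII", "CYTB",
               "ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6")
RRNA_NAMES <- c("rrnL", "rrnS")
TRNA_NAMES <- c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH",
                "trnI", "trnK", "trnL_CUN", "trnL_UUR", "trnM", "trnN",
                "trnP", "trnQ", "trnR", "trnS_AGN", "trnS_UCN", "trnT",
                "trnV", "trnW", "trnY")
CONTROL_REGION_NAME <- "AT_rich"

#' Canonical mitochondrial gene symbols
#'
#' The 37 gene symbols (13 protein-coding genes, 22 tRNAs, 2 rRNAs) plus the
#' `AT_rich` control region, as used throughout the package.
#'
#' @param with_control_region Include `"AT_rich"`.
#' @return Character vector of canonical symbols.
#' @export
canonical_gene_names <- function(with_control_region = FALSE) {
  out <- c(PCG_NAMES, RRNA_NAMES, TRNA_NAMES)
  if (with_control_region) out <- c(out, CONTROL_REGION_NAME)
  out
}

#' Feature class of a canonical gene symbol
#'
#' @param name Canonical symbol(s).
#' @return `"PCG"`, `"tRNA"`, `"rRNA"`, `"control_region"`, or `NA` for
#'   unknown symbols.
#' @export
gene_class <- function(name) {
  vapply(name, function(n) {
    if (n %in% PCG_NAMES) "PCG"
    else if (n %in% TRNA_NAMES) "tRNA"
    else if (n %in% RRNA_NAMES) "rRNA"
    else if (identical(n, CONTROL_REGION_NAME)) "control_region"
    else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# one-letter <-> three-letter amino acid names (plus * for stop)
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Stop")

aa_three_letter <- function(aa1) unname(AA3[aa1])

# amino-acid synonym table used when normalizing "tRNA-Leu"-style names
AA3_TO_TRNA <- c(ala = "trnA", arg = "trnR", asn = "trnN", asp = "trnD",
                 cys = "trnC", gln = "trnQ", glu = "trnE", gly = "trnG",
                 his = "trnH", ile = "trnI", lys = "trnK", met = "trnM",
                 phe = "trnF", pro = "trnP", thr = "trnT", trp = "trnW",
                 tyr = "trnY", val = "trnV")

#' Normalize a raw gene name onto the canonical vocabulary
#'
#' Heterogeneous sources write the same gene many ways (COI/COX1/cox1,
#' 16S/rrnL, tRNA-Leu/trnL2). This maps a raw name (and, for the ambiguous
#' leucine/serine tRNAs, an optional anticodon) onto the 37-symbol canonical
#' vocabulary, case-insensitively and deterministically.
#'
#' @param raw Raw name from an annotation (gene, product, or note text).
#' @param anticodon Optional anticodon 3-mer (DNA or RNA alphabet), used to
#'   disambiguate `trnL` and `trnS` when the name alone cannot.
#' @return A canonical symbol, or `NA_character_` when the name is not
#'   mappable (never a silent guess).
#' @export
normalize_gene_name <- function(raw, anticodon = NULL) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  s <- tolower(trimws(raw))
  compact <- gsub("[^a-z0-9]", "", s)

  # control region
  if (grepl("d-?loop|control *region|a\\+?t[- ]*rich|at_rich|atrich", s))
    return(CONTROL_REGION_NAME)

  # rRNAs
  if (grepl("^(rrnl|16s|lrrna|lsu)", compact) ||
      grepl("large subunit ribosomal|16s ribosomal", s))
    return("rrnL")
  if (grepl("^(rrns|12s|srrna|ssu)", compact) ||
      grepl("small subunit ribosomal|12s ribosomal", s))
    return("rrnS")

  # protein-coding genes
  pcg <- c(coxi = "COXI", coxii = "COXII", coxiii = "COXIII",
           cox1 = "COXI", cox2 = "COXII", cox3 = "COXIII",
           coi = "COXI", coii = "COXII", coiii = "COXIII",
           co1 = "COXI", co2 = "COXII", co3 = "COXIII",
           cob = "CYTB", cytb = "CYTB", cytochromeb = "CYTB",
           atp6 = "ATP6", atp8 = "ATP8", atpase6 = "ATP6", atpase8 = "ATP8",
           nd1 = "ND1", nd2 = "ND2", nd3 = "ND3", nd4 = "ND4",
           nd4l = "ND4L", nd5 = "ND5", nd6 = "ND6",
           nad1 = "ND1", nad2 = "ND2", nad3 = "ND3", nad4 = "ND4",
           nad4l = "ND4L", nad5 = "ND5", nad6 = "ND6",
           ndh1 = "ND1", ndh2 = "ND2", ndh3 = "ND3", ndh4 = "ND4",
           ndh4l = "ND4L", ndh5 = "ND5", ndh6 = "ND6")
  if (compact %in% names(pcg)) return(unname(pcg[compact]))
  # common long forms ("cytochrome c oxidase subunit I", "NADH dehydrogenase subunit 4L")
  if (grepl("cytochrome *c *oxidase", s)) {
    sub <- regmatches(s, regexpr("(subunit *)?(i{1,3}|[123])$", s))
    n <- c(i = "COXI", ii = "COXII", iii = "COXIII",
           `1` = "COXI", `2` = "COXII", `3` = "COXIII")
    key <- gsub("subunit *", "", sub)
    if (length(key) == 1 && key %in% names(n)) return(unname(n[key]))
  }
  if (grepl("cytochrome *b", s)) return("CYTB")
  if (grepl("nadh *dehydrogenase", s)) {
    key <- regmatches(s, regexpr("[1-6]l?$", s))
    if (length(key) == 1) {
      nm <- paste0("ND", toupper(key))
      if (nm %in% PCG_NAMES) return(nm)
    }
  }
  if (grepl("atp *synthase", s)) {
    key <- regmatches(s, regexpr("[68]$", s))
    if (length(key) == 1) return(paste0("ATP", key))
  }

  # tRNAs: canonical forms first (trnA, trnL1, trnL(UUR), trnS2, ...)
  m <- regmatches(compact, regexpr("^trna?([a-z])([12]?)(uur|cun|agn|ucn|uuu)?", compact))
  trna_from <- function(letter, tag) {
    letter <- toupper(letter)
    base <- paste0("trn", letter)
    if (letter == "L") {
      if (tag %in% c("uur", "2")) return("trnL_UUR")
      if (tag %in% c("cun", "1")) return("trnL_CUN")
      return(disambiguate_ls("L", anticodon))
    }
    if (letter == "S") {
      if (tag %in% c("agn", "1")) return("trnS_AGN")
      if (tag %in% c("ucn", "2")) return("trnS_UCN")
      return(disambiguate_ls("S", anticodon))
    }
    if (base %in% TRNA_NAMES) base else NA_character_
  }
  # "trnA" (alanine) lowercases to the generic "trna"; only the bare generic
  # spelling "tRNA"/"TRNA" is refused here
  if (length(m) == 1 && !(compact == "trna" && raw %in% c("tRNA", "TRNA", "trna"))) {
    g <- regmatches(compact,
                    regexec("^trna?([a-z])([12]?)(uur|cun|agn|ucn)?", compact))[[1]]
    # avoid matching e.g. "trnaala" letter 'a' then junk: accept only if the
    # remainder is empty or a family tag
    rest <- sub("^trna?[a-z][12]?(uur|cun|agn|ucn)?", "", compact)
    if (!nzchar(rest) && g[2] %in% letters)
      return(trna_from(g[2], paste0(g[3], g[4])))
  }
  # product-style names: "tRNA-Leu", "transfer RNA-Ser (UCN)"
  if (grepl("trna|transfer *rna", s)) {
    aa <- regmatches(s, regexpr("ala|arg|asn|asp|cys|gln|glu|gly|his|ile|leu|lys|met|phe|pro|ser|thr|trp|tyr|val", s))
    if (length(aa) == 1) {
      tag <- regmatches(compact, regexpr("uur|cun|agn|ucn", compact))
      tag <- if (length(tag)) tag else ""
      if (aa == "leu") {
        if (tag == "uur") return("trnL_UUR")
        if (tag == "cun") return("trnL_CUN")
        return(disambiguate_ls("L", anticodon))
      }
      if (aa == "ser") {
        if (tag == "agn") return("trnS_AGN")
        if (tag == "ucn") return("trnS_UCN")
        return(disambiguate_ls("S", anticodon))
      }
      return(unname(AA3_TO_TRNA[aa]))
    }
  }
  NA_character_
}

# resolve trnL / trnS from an anticodon: the anticodon's reverse complement is
# the codon it reads, whose family decides UUR/CUN (Leu) or AGN/UCN (Ser)
disambiguate_ls <- function(letter, anticodon) {
  if (is.null(anticodon)) return(NA_character_)
  ac <- toupper(rna_to_dna(anticodon))
  if (!grepl("^[ACGT]{3}$", ac)) return(NA_character_)
  codon <- revcomp(ac)
  if (letter == "L") {
    if (substr(codon, 1, 2) == "TT") return("trnL_UUR")   # TTA/TTG
    if (substr(codon, 1, 2) == "CT") return("trnL_CUN")
    return(NA_character_)
  }
  if (letter == "S") {
    if (substr(codon, 1, 2) == "AG") return("trnS_AGN")
    if (substr(codon, 1, 2) == "TC") return("trnS_UCN")
    return(NA_character_)
  }
  NA_character_
}

#' Ancestral insect mitochondrial gene order
#'
#' The putative ancestral arrangement of the 37 genes (control region
#' excluded), as found in *Drosophila yakuba* and most insects, on the major
#' (J) strand in circular order starting from `trnI`. Grasshopper lineages of
#' Acridomorpha differ from it by the trnD/trnK translocation.
#'
#' @return A `gene_order` object: data frame with columns `name` and `strand`.
#' @export
ancestral_gene_order <- function() {
  nm <- c("trnI", "trnQ", "trnM", "ND2", "trnW", "trnC", "trnY", "COXI",
          "trnL_UUR", "COXII", "trnK", "trnD", "ATP8", "ATP6", "COXIII",
          "trnG", "ND3", "trnA", "trnR", "trnN", "trnS_AGN", "trnE", "trnF",
          "ND5", "trnH", "ND4", "ND4L", "trnT", "trnP", "ND6", "CYTB",
          "trnS_UCN", "ND1", "trnL_CUN", "rrnL", "trnV", "rrnS")
  n_strand <- c("trnQ", "trnC", "trnY", "trnF", "ND5", "trnH", "ND4", "ND4L",
                "trnP", "ND1", "trnL_CUN", "rrnL", "trnV", "rrnS")
  gene_order(nm, ifelse(nm %in% n_strand, "N", "J"))
}

#' Invertebrate mitochondrial genetic code (translation table 5)
#'
#' Wraps NCBI translation table 5 from [Biostrings::getGeneticCode()] into the
#' structure the codon-usage functions need: the codon-to-amino-acid map, the
#' stop-codon set, and the synonymous-family table. Under this code AGA/AGG
#' encode Ser (8-codon serine family), TGA encodes Trp, and ATA encodes Met.
#'
#' @return A list with elements `map` (named character vector codon -> one
#'   letter amino acid, `*` for stop), `stops` (character vector), and
#'   `families` (data frame `codon`, `aa`, `family_size`).
#' @export
mito_genetic_code <- function() {
  map <- Biostrings::getGeneticCode("5")
  stops <- names(map)[map == "*"]
  sense <- map[map != "*"]
  fam_size <- table(sense)
  families <- data.frame(codon = names(sense),
                         aa = unname(sense),
                         family_size = as.integer(fam_size[sense]),
                         stringsAsFactors = FALSE)
  list(map = map, stops = stops, families = families)
}

#' Translate a sense-strand CDS under translation table 5
#'
#' @param cds Sense-strand nucleotide string; trailing incomplete codon is
#'   ignored.
#' @param code Genetic code from [mito_genetic_code()].
#' @return Amino-acid string (one-letter, `*` for stop).
#' @export
translate_cds <- function(cds, code = mito_genetic_code()) {
  cds <- check_dna(cds, "CDS")
  n <- floor(nchar(cds) / 3)
  if (n == 0) return("")
  codons <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- code$map[codons]
  aa[is.na(aa)] <- "X"   # codons containing N
  paste(aa, collapse = "")
}
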