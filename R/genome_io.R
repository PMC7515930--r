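# Annotated-mitogenome containers and I/O: GenBank flat files, FASTA, and a
# simple tab-separated feature table. Internal coordinates are 0-based
# half-open on the major (J) strand; GenBank's 1-based inclusive coordinates
# are converted at the boundary. A feature wrapping the circular origin is
# represented as exactly two spans, never a negative coordinate.

#' Construct a mitogenome object
#'
#' @param sequence Major (J) strand nucleotide string over `{A,C,G,T,N}`.
#' @param id Accession or label.
#' @param organism Organism name.
#' @param circular Is the molecule circular?
#' @return A `mito_genome` object.
#' @export
genome <- function(sequence, id = "genome", organism = "", circular = TRUE) {
  sequence <- check_dna(sequence, "genome sequence")
  if (nchar(sequence) == 0) stop("genome sequence must be non-empty")
  structure(list(id = id, organism = organism, sequence = sequence,
                 circular = isTRUE(circular), length = nchar(sequence)),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s (%s), %d bp, %s\n", x$id,
              if (nzchar(x$organism)) x$organism else "unknown organism",
              x$length, if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Construct an annotated feature
#'
#' @param name Canonical gene symbol (see [canonical_gene_names()]) or a raw
#'   name when `canonical = FALSE`.
#' @param spans Two-column matrix (or single `c(start, end)`) of 0-based
#'   half-open intervals on the major strand; two rows only when wrapping the
#'   origin.
#' @param strand `"J"` (major) or `"N"` (minority).
#' @param klass Feature class; inferred from `name` when `NULL`.
#' @param anticodon Optional anticodon 3-mer for tRNAs (DNA alphabet).
#' @param canonical Whether `name` is from the canonical vocabulary.
#' @return A `mito_feature` object.
#' @export
feature <- function(name, spans, strand = "J", klass = NULL,
                    anticodon = NULL, canonical = TRUE) {
  if (is.null(dim(spans))) spans <- matrix(spans, ncol = 2, byrow = TRUE)
  spans <- matrix(as.integer(spans), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  stopifnot(nrow(spans) >= 1, all(spans[, 1] < spans[, 2]),
            all(spans >= 0), strand %in% c("J", "N"), nrow(spans) <= 2)
  if (is.null(klass)) klass <- gene_class(name)
  if (is.na(klass)) stop(sprintf("cannot infer feature class for '%s'", name))
  stopifnot(klass %in% c("PCG", "tRNA", "rRNA", "control_region"))
  if (canonical && !name %in% canonical_gene_names(TRUE))
    stop(sprintf("'%s' is not a canonical gene symbol", name))
  if (canonical && !identical(gene_class(name), klass) && !is.na(gene_class(name)))
    stop(sprintf("class '%s' inconsistent with name '%s'", klass, name))
  structure(list(name = name, klass = klass, strand = strand, spans = spans,
                 anticodon = if (is.null(anticodon)) NA_character_ else toupper(anticodon),
                 canonical = isTRUE(canonical)),
            class = "mito_feature")
}

#' Total length of a feature (sum of its spans)
#' @param f A `mito_feature`.
#' @return Integer length in bp.
#' @export
feature_length <- function(f) sum(f$spans[, 2] - f$spans[, 1])

# circular start of a feature: start of its first span
feature_start <- function(f) f$spans[1, 1]

#' Construct an annotation set
#'
#' @param genome A [genome()] object.
#' @param features List of [feature()] objects; stored ordered by first-span
#'   start. Duplicate canonical names are rejected, and every span must lie
#'   within `[0, genome$length)`.
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(genome, features) {
  stopifnot(inherits(genome, "mito_genome"),
            all(vapply(features, inherits, logical(1), "mito_feature")))
  nm <- vapply(features, `[[`, character(1), "name")
  dup <- nm[duplicated(nm) & nm %in% canonical_gene_names(TRUE)]
  if (length(dup)) stop("duplicate canonical feature names: ",
                        paste(unique(dup), collapse = ", "))
  for (f in features) {
    if (any(f$spans[, 2] > genome$length))
      stop(sprintf("feature '%s' extends past genome length %d",
                   f$name, genome$length))
  }
  ord <- order(vapply(features, feature_start, integer(1)))
  structure(list(genome = genome, features = features[ord]),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  print(x$genome)
  kl <- table(vapply(x$features, `[[`, character(1), "klass"))
  cat(sprintf("  %d features (%s)\n", length(x$features),
              paste(names(kl), kl, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Feature names of an annotation set (in genome order)
#' @param a An `annotation_set`.
#' @return Character vector.
#' @export
feature_names <- function(a) vapply(a$features, `[[`, character(1), "name")

#' Look up a feature by canonical name
#' @param a An `annotation_set`.
#' @param name Canonical symbol.
#' @return The `mito_feature`.
#' @export
get_feature <- function(a, name) {
  i <- match(name, feature_names(a))
  if (is.na(i)) stop(sprintf("feature '%s' not present in annotation set", name))
  a$features[[i]]
}

#' Extract a feature's sense-strand sequence
#'
#' Concatenates the feature's spans in order on the major strand; for
#' N-strand features the reverse complement is returned so the result reads
#' 5'->3' on the coding sense.
#'
#' @param a An `annotation_set`.
#' @param name Canonical symbol of a feature in `a`.
#' @return Nucleotide string.
#' @export
extract_feature_sequence <- function(a, name) {
  f <- get_feature(a, name)
  parts <- substring(a$genome$sequence, f$spans[, 1] + 1L, f$spans[, 2])
  s <- paste(parts, collapse = "")
  if (f$strand == "N") revcomp(s) else s
}

## ---------------------------------------------------------------------------
## GenBank flat file I/O

# parse a GenBank location string into spans (0-based half-open) + strand
parse_gb_location <- function(loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "J"
  if (grepl("^complement\\(", loc)) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  spans <- t(vapply(parts, function(p) {
    if (grepl("\\.\\.", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else {
      ab <- rep(as.integer(p), 2)
    }
    c(ab[1] - 1L, ab[2])
  }, integer(2)))
  dimnames(spans) <- list(NULL, c("start", "end"))
  list(spans = spans, strand = strand)
}

# extract a quoted or bare qualifier value
gb_qualifier <- function(quals, key) {
  hit <- grep(paste0("^/", key, "="), quals, value = TRUE)
  if (!length(hit)) return(NA_character_)
  v <- sub(paste0("^/", key, "="), "", hit[1])
  gsub("^\"|\"$", "", v)
}

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Parses LOCUS/ORGANISM/FEATURES/ORIGIN, converts 1-based inclusive
#' coordinates to the internal 0-based half-open convention, maps
#' complement-strand features to strand `"N"`, represents origin-spanning
#' `join()` locations as two spans, and normalizes gene names onto the
#' canonical vocabulary via [normalize_gene_name()]. Features whose names
#' cannot be mapped are retained with their class inferred from the feature
#' key and flagged non-canonical, with a warning. If no control region is
#' annotated (D-loop, or a misc_feature mentioning "A+T" / "control region"),
#' the largest unannotated gap adjacent to `rrnS` is labeled `AT_rich` with a
#' warning.
#'
#' @param path Path to a GenBank flat file.
#' @return An [annotation_set()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1])),
                                    "\\s+")[[1]][1] else basename(path)
  circular <- length(locus) && grepl("circular", locus[1], ignore.case = TRUE)
  org_line <- grep("^ {0,4}ORGANISM", lines, value = TRUE)
  organism <- if (length(org_line)) trimws(sub("^ *ORGANISM *", "", org_line[1])) else ""

  io <- grep("^ORIGIN", lines)
  if (!length(io)) stop("GenBank record has no ORIGIN sequence: ", path)
  iend <- grep("^//", lines)
  iend <- if (length(iend)) iend[iend > io[1]][1] else length(lines) + 1L
  seq_lines <- lines[(io[1] + 1L):(iend - 1L)]
  sequence <- toupper(gsub("[0-9[:space:]/]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("GenBank record has an empty ORIGIN sequence: ", path)
  g <- genome(sequence, id = id, organism = organism, circular = circular)

  ifeat <- grep("^FEATURES", lines)
  feats <- list()
  if (length(ifeat)) {
    block <- lines[(ifeat[1] + 1L):(io[1] - 1L)]
    starts <- grep("^ {5}\\S", block)
    for (k in seq_along(starts)) {
      from <- starts[k]
      to <- if (k < length(starts)) starts[k + 1] - 1L else length(block)
      entry <- block[from:to]
      key <- sub("^ {5}(\\S+).*$", "\\1", entry[1])
      if (!key %in% c("CDS", "tRNA", "rRNA", "misc_feature", "D-loop", "gene"))
        next
      # location may continue over lines until the first qualifier
      qstart <- grep("^ +/", entry)
      loc_lines <- entry[seq_len(if (length(qstart)) qstart[1] - 1L else length(entry))]
      loc <- paste(c(sub("^ {5}\\S+ +", "", loc_lines[1]),
                     trimws(loc_lines[-1])), collapse = "")
      quals <- trimws(entry[if (length(qstart)) qstart[1]:length(entry) else integer(0)])
      pl <- parse_gb_location(loc)

      gene_q <- gb_qualifier(quals, "gene")
      product_q <- gb_qualifier(quals, "product")
      note_q <- gb_qualifier(quals, "note")
      ac_q <- gb_qualifier(quals, "anticodon")
      anticodon <- if (!is.na(ac_q)) {
        m <- regmatches(ac_q, regexpr("seq:[acgtuACGTU]{3}", ac_q))
        if (length(m)) toupper(rna_to_dna(sub("seq:", "", m))) else NULL
      } else NULL

      if (key %in% c("D-loop") ||
          (key == "misc_feature" &&
           grepl("a\\+t|control region|at.rich", paste(note_q, product_q),
                 ignore.case = TRUE))) {
        feats[[length(feats) + 1L]] <- feature(
          CONTROL_REGION_NAME, pl$spans, strand = pl$strand,
          klass = "control_region")
        next
      }

      raw <- c(gene_q, product_q, note_q)
      raw <- raw[!is.na(raw)]
      if (!length(raw)) next
      canon <- NA_character_
      for (r in raw) {
        canon <- normalize_gene_name(r, anticodon = anticodon)
        if (!is.na(canon)) break
      }
      klass_from_key <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA")[key]
      if (is.na(canon)) {
        if (key == "gene") next  # bare unidentifiable gene line
        warning(sprintf("feature name '%s' not mappable to canonical vocabulary; retained as-is",
                        raw[1]), call. = FALSE)
        feats[[length(feats) + 1L]] <- feature(
          raw[1], pl$spans, strand = pl$strand,
          klass = unname(klass_from_key), anticodon = anticodon,
          canonical = FALSE)
      } else {
        kl <- gene_class(canon)
        feats[[length(feats) + 1L]] <- feature(
          canon, pl$spans, strand = pl$strand, klass = kl,
          anticodon = anticodon)
      }
    }
  }

  # prefer typed features (CDS/tRNA/rRNA) over duplicate plain 'gene' entries:
  # keep the first occurrence of each canonical name with a known class, in
  # the order typed features were emitted above (gene lines never carry class
  # information beyond the name, so duplicates are identical in coordinates)
  nm <- vapply(feats, `[[`, character(1), "name")
  feats <- feats[!duplicated(nm)]

  a <- annotation_set(g, feats)
  if (!CONTROL_REGION_NAME %in% feature_names(a))
    a <- infer_control_region(a)
  a
}

# label the largest unannotated gap adjacent to rrnS as the control region
infer_control_region <- function(a) {
  if (!"rrnS" %in% feature_names(a)) return(a)
  occ <- occupancy_gaps(a)
  if (!nrow(occ)) return(a)
  rs <- get_feature(a, "rrnS")
  adj <- occ[occ$start == rs$spans[nrow(rs$spans), 2] |
             occ$end == rs$spans[1, 1] |
             (occ$end == a$genome$length & rs$spans[1, 1] == 0), , drop = FALSE]
  cand <- if (nrow(adj)) adj else occ
  big <- cand[which.max(cand$end - cand$start), ]
  warning("no annotated control region; labeling the largest unannotated gap adjacent to rrnS as AT_rich",
          call. = FALSE)
  cr <- feature(CONTROL_REGION_NAME, c(big$start, big$end), strand = "J",
                klass = "control_region")
  annotation_set(a$genome, c(a$features, list(cr)))
}

# unannotated gaps on the linearized major strand
occupancy_gaps <- function(a) {
  L <- a$genome$length
  cov <- rep(FALSE, L)
  for (f in a$features)
    for (r in seq_len(nrow(f$spans)))
      cov[(f$spans[r, 1] + 1L):f$spans[r, 2]] <- TRUE
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[!r$values], end = ends[!r$values])
}

#' Write an annotation set as a GenBank-style flat file
#'
#' Emits LOCUS, ORGANISM, a FEATURES table (gene/CDS/tRNA/rRNA/D-loop keys
#' with 1-based inclusive locations, `complement()` for N-strand features and
#' `join()` across the origin) and the ORIGIN sequence. Round-trips through
#' [read_genbank()].
#'
#' @param a An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(a, path) {
  g <- a$genome
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("LOCUS       %s %d bp    DNA     %s   INV", g$id, g$length,
     if (g$circular) "circular" else "linear")
  wl("DEFINITION  %s mitochondrion, complete genome.",
     if (nzchar(g$organism)) g$organism else g$id)
  wl("  ORGANISM  %s", g$organism)
  wl("FEATURES             Location/Qualifiers")
  for (f in a$features) {
    locs <- sprintf("%d..%d", f$spans[, 1] + 1L, f$spans[, 2])
    loc <- if (length(locs) > 1) sprintf("join(%s)", paste(locs, collapse = ",")) else locs
    if (f$strand == "N") loc <- sprintf("complement(%s)", loc)
    key <- switch(f$klass, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  control_region = "D-loop")
    wl("     %-16s%s", key, loc)
    if (f$klass != "control_region") wl("                     /gene=\"%s\"", f$name)
    if (f$klass == "control_region")
      wl("                     /note=\"A+T-rich region; control region\"")
    if (f$klass == "tRNA" && !is.na(f$anticodon))
      wl("                     /anticodon=\"(pos:complement,aa:Xxx,seq:%s)\"",
         tolower(f$anticodon))
  }
  wl("ORIGIN")
  s <- tolower(g$sequence)
  pos <- seq(1, nchar(s), by = 60)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59, nchar(s)))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    wl("%9d %s", p, paste(groups, collapse = " "))
  }
  wl("//")
  invisible(path)
}

## ---------------------------------------------------------------------------
## FASTA and feature-table TSV

#' Read a FASTA file
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70)
  invisible(path)
}

#' Write an annotation set's feature table as TSV
#'
#' Columns `name`, `klass`, `strand`, `start`, `end` (0-based half-open), one
#' row per span with the rows of a feature consecutive.
#'
#' @param a An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(a, path) {
  rows <- do.call(rbind, lapply(a$features, function(f) {
    data.frame(name = f$name, klass = f$klass, strand = f$strand,
               start = f$spans[, 1], end = f$spans[, 2],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table TSV back into features
#'
#' @param path TSV written by [write_feature_table()].
#' @param genome A [genome()] the features annotate.
#' @return An [annotation_set()].
#' @export
read_feature_table <- function(path, genome) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "klass", "strand", "start", "end") %in% names(tab)))
  # rows of one feature are consecutive: group by runs of identical names
  run_id <- cumsum(c(TRUE, tab$name[-1] != tab$name[-nrow(tab)]))
  grp <- split(tab, run_id)
  feats <- lapply(grp, function(d) {
    feature(d$name[1], cbind(d$start, d$end), strand = d$strand[1],
            klass = d$klass[1],
            canonical = d$name[1] %in% canonical_gene_names(TRUE))
  })
  annotation_set(genome, unname(feats))
}
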