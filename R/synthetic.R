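# Synthetic annotated mitogenomes with exact ground truth. Base and codon
# sampling realize EXACT target counts (largest-remainder apportionment of
# n*p followed by a seeded permutation), so the truth manifest can record
# realized composition and planted-feature coordinates that downstream
# statistics and detectors must reproduce exactly, not approximately.

# internal tally kept independent of the composition module
tally_bases <- function(s) {
  ch <- seq_chars(s)
  c(a = sum(ch == "A"), t = sum(ch == "T"),
    g = sum(ch == "G"), c = sum(ch == "C"))
}

#' Random sequence with exact composition
#'
#' Realizes the exact base counts implied by `(at_frac, at_skew, gc_skew)`
#' via largest-remainder rounding, then permutes them under the current RNG
#' state.
#'
#' @param n Length in bp.
#' @param at_frac Target A+T fraction in `[0, 1]`.
#' @param at_skew,gc_skew Target skews in `[-1, 1]`.
#' @return Nucleotide string of length `n`.
#' @export
random_seq_exact <- function(n, at_frac, at_skew = 0, gc_skew = 0) {
  stopifnot(n >= 0, at_frac >= 0, at_frac <= 1,
            abs(at_skew) <= 1, abs(gc_skew) <= 1)
  if (n == 0) return("")
  atn <- round(at_frac * n)
  a <- round(atn * (1 + at_skew) / 2)
  t <- atn - a
  gcn <- n - atn
  g <- round(gcn * (1 + gc_skew) / 2)
  cc <- gcn - g
  paste(sample(rep(c("A", "T", "G", "C"), c(a, t, g, cc))), collapse = "")
}

#' Default codon-bias weights
#'
#' Sense-codon sampling weights under translation table 5, built as the
#' product of position-specific base weights chosen to emulate the codon
#' composition of grasshopper mitochondrial protein-coding genes: moderate
#' A+T with a G excess at position 1, T-rich position 2 (the hydrophobic
#' amino-acid signature), and an extremely A+T-rich third position. Stop
#' codons have weight zero.
#'
#' @param position_probs 3 x 4 matrix of base weights (rows = codon
#'   positions, columns `A`, `T`, `G`, `C`).
#' @param code Genetic code from [mito_genetic_code()].
#' @return Named numeric vector over the 64 codons summing to 1.
#' @export
default_codon_bias <- function(position_probs = rbind(
                                 c(A = 0.33, T = 0.35, G = 0.20, C = 0.12),
                                 c(A = 0.20, T = 0.46, G = 0.14, C = 0.20),
                                 c(A = 0.455, T = 0.475, G = 0.03, C = 0.04)),
                               code = mito_genetic_code()) {
  stopifnot(nrow(position_probs) == 3,
            all(c("A", "T", "G", "C") %in% colnames(position_probs)))
  w <- vapply(ALL_CODONS, function(cd) {
    ch <- seq_chars(cd)
    position_probs[1, ch[1]] * position_probs[2, ch[2]] *
      position_probs[3, ch[3]]
  }, numeric(1))
  w[code$stops] <- 0
  w / sum(w)
}

#' Generate a sense-strand CDS from codon-bias weights
#'
#' Codon counts are the exact apportionment of `length/3` to the bias
#' weights (stop codons excluded internally); the codons are then permuted
#' and a terminal stop appended, so the realized codon usage is the
#' bias-implied usage up to rounding.
#'
#' @param length Coding length in bp (multiple of 3), excluding the stop.
#' @param bias Named weights over codons, see [default_codon_bias()].
#' @param code Genetic code from [mito_genetic_code()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param stop_codon Terminal stop codon appended.
#' @return Sense CDS string of `length + 3` bp.
#' @export
generate_cds <- function(length, bias = default_codon_bias(),
                         code = mito_genetic_code(), seed = NULL,
                         stop_codon = "TAA") {
  stopifnot(length %% 3 == 0, length >= 3, stop_codon %in% code$stops)
  gen <- function() {
    w <- bias[!names(bias) %in% code$stops]
    w <- w[w > 0]
    counts <- apportion(length %/% 3, w)
    codons <- sample(rep(names(w), counts))
    paste0(paste(codons, collapse = ""), stop_codon)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Construct a synthetic genome specification
#'
#' @param gene_order A [gene_order()] of the 37 genes (control region
#'   appended automatically after the last gene).
#' @param lengths Named integer vector of feature lengths in bp; PCG lengths
#'   include the terminal stop and must be multiples of 3.
#' @param targets Named list of composition targets
#'   `c(at, at_skew, gc_skew)` for `tRNA`, `rRNA` (split `rrnL`/`rrnS`),
#'   `AT_rich`, and `igr` filler.
#' @param codon_bias Codon weights for the protein-coding genes.
#' @param igr Named integer vector: intergenic gap inserted AFTER the named
#'   feature (unlisted features get 0).
#' @param start_codons Named overrides of the first codon per PCG (default
#'   `ATG`).
#' @param cr_planted List describing the planted control-region features;
#'   see [default_genome_spec()] for the shape. Set an element to `NULL` to
#'   plant nothing of that kind.
#' @param id,organism Genome metadata.
#' @param seed Integer seed making generation fully reproducible.
#' @return A `genome_spec` object.
#' @export
genome_spec <- function(gene_order, lengths, targets, codon_bias,
                        igr = integer(0), start_codons = character(0),
                        cr_planted = list(), id = "SYN1",
                        organism = "Synthetica exempli", seed = 1L) {
  stopifnot(inherits(gene_order, "gene_order"),
            all(gene_order$name %in% canonical_gene_names()),
            nrow(gene_order) == length(unique(gene_order$name)))
  need <- c(gene_order$name, CONTROL_REGION_NAME)
  missing <- setdiff(need, names(lengths))
  if (length(missing)) stop("lengths missing for: ", paste(missing, collapse = ", "))
  stopifnot(all(lengths > 0))
  pcg <- intersect(gene_order$name, PCG_NAMES)
  if (any(lengths[pcg] %% 3 != 0))
    stop("PCG lengths must be multiples of 3 (start..stop inclusive)")
  for (tg in targets) stopifnot(tg[1] >= 0, tg[1] <= 1, abs(tg[2]) <= 1,
                                abs(tg[3]) <= 1)
  structure(list(gene_order = gene_order, lengths = lengths,
                 targets = targets, codon_bias = codon_bias, igr = igr,
                 start_codons = start_codons, cr_planted = cr_planted,
                 id = id, organism = organism, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Default synthetic genome specification
#'
#' Emulates a typical grasshopper mitogenome: ~15.8 kb, the ancestral insect
#' gene order with trnD and trnK swapped (the Acridomorpha translocation),
#' whole-genome A+T around 76.5%, a ~1 kb A+T-rich region at ~86.5% A+T
#' carrying a planted interrupted T-stretch (11 T with two C insertions), a
#' 12-bp-stem stem-loop, and a period-7 tandem repeat, plus a 16-bp
#' intergenic spacer at the trnS(UCN)/ND1 junction.
#'
#' @param seed Integer seed.
#' @param id,organism Genome metadata.
#' @param block_seq Optional conserved-block sequence to plant in the
#'   control region (shared across genomes of a study set).
#' @return A `genome_spec`.
#' @export
default_genome_spec <- function(seed = 1L, id = "SYN1",
                                organism = "Synthetica exempli",
                                block_seq = NULL) {
  anc <- ancestral_gene_order()
  nm <- anc$name
  ik <- match("trnK", nm); id2 <- match("trnD", nm)
  nm[c(ik, id2)] <- nm[c(id2, ik)]           # the trnD/trnK translocation
  ord <- gene_order(nm, anc$strand[match(nm, anc$name)])

  pcg_len <- c(ND2 = 1023, COXI = 1539, COXII = 684, ATP8 = 159, ATP6 = 675,
               COXIII = 789, ND3 = 354, ND5 = 1722, ND4 = 1341, ND4L = 297,
               ND6 = 522, CYTB = 1137, ND1 = 939)
  trna_len <- setNames(rep(66L, 22), TRNA_NAMES)
  trna_len["trnP"] <- 58L
  lengths <- c(pcg_len, trna_len, rrnL = 1325L, rrnS = 795L, AT_rich = 1080L)

  targets <- list(tRNA = c(0.74, 0.01, 0.10),
                  rrnL = c(0.775, -0.17, 0.22),
                  rrnS = c(0.745, -0.11, 0.21),
                  AT_rich = c(0.875, 0.15, -0.15),
                  igr = c(0.76, 0.10, -0.10))

  igr <- c(trnS_UCN = 16L, trnY = 2L, COXII = 1L, trnE = 3L, ND4L = 2L,
           rrnS = 0L, trnW = 1L)

  cr_planted <- list(
    t_stretch = list(offset = 100L, pattern = "TTTTCTTTTCTTT"),
    stem_loop = list(offset = 300L, stem = 12L, loop = 6L),
    tandem_repeat = list(offset = 500L, period = 7L, copies = 5.5),
    block = if (!is.null(block_seq)) list(offset = 760L, sequence = block_seq))

  genome_spec(ord, lengths, targets, default_codon_bias(), igr = igr,
              start_codons = c(COXI = "ATG"), cr_planted = cr_planted,
              id = id, organism = organism, seed = seed)
}

# build the control-region string and the realized planted-feature records
build_control_region <- function(len, target, planted) {
  cr <- seq_chars(random_seq_exact(len, target[1], target[2], target[3]))
  realized <- list()
  put <- function(offset, str, what, extra = list()) {
    ch <- seq_chars(str)
    stopifnot(offset + length(ch) <= len)
    cr[(offset + 1):(offset + length(ch))] <<- ch
    realized[[what]] <<- c(list(offset = offset, length = length(ch),
                                sequence = str), extra)
  }
  if (!is.null(planted$t_stretch)) {
    ts <- planted$t_stretch
    put(ts$offset, ts$pattern, "t_stretch",
        list(n_interruptions = sum(seq_chars(ts$pattern) != "T")))
  }
  if (!is.null(planted$stem_loop)) {
    sl <- planted$stem_loop
    arm <- paste(sample(c("A", "T", "G", "C"), sl$stem, replace = TRUE,
                        prob = c(.35, .35, .15, .15)), collapse = "")
    loop <- random_seq_exact(sl$loop, 0.8)
    put(sl$offset, paste0(arm, loop, revcomp(arm)), "stem_loop",
        list(stem = sl$stem, loop = sl$loop, arm5 = arm))
  }
  if (!is.null(planted$tandem_repeat)) {
    tr <- planted$tandem_repeat
    unit <- if (!is.null(tr$unit)) tr$unit else
      random_seq_exact(tr$period, 0.75, 0.1, -0.1)
    nb <- floor(tr$period * tr$copies)
    arr <- substr(strrep(unit, ceiling(tr$copies) + 1L), 1, nb)
    put(tr$offset, arr, "tandem_repeat",
        list(period = tr$period, copies = nb / tr$period, unit = unit))
  }
  if (!is.null(planted$block)) {
    bl <- planted$block
    put(bl$offset, bl$sequence, "block")
  }
  list(sequence = paste(cr, collapse = ""), realized = realized)
}

#' Generate a synthetic annotated mitogenome with ground truth
#'
#' Deterministic for a fixed spec (the spec's `seed` governs every draw).
#' Protein-coding genes are generated from the codon bias with the requested
#' start codon and a TAA/TAG stop; tRNA/rRNA/intergenic/control-region
#' segments realize their composition targets exactly on the major strand;
#' N-strand genes are inserted as the reverse complement of their generated
#' sense sequence; planted control-region features overwrite their footprint
#' and the manifest records post-overwrite truth.
#'
#' @param spec A [genome_spec()].
#' @return List with `annotation` (an [annotation_set()]) and `manifest`
#'   (spec echo, feature coordinates, planted-feature records with
#'   control-region-relative and absolute coordinates, and exact realized
#'   base counts per composition partition).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, generate_genome_impl(spec))
}

generate_genome_impl <- function(spec) {
  ord <- spec$gene_order
  feats <- list()
  pieces <- character(0)
  sense_seqs <- list()        # per-feature sense sequence (ground truth)
  cursor <- 0L
  cr_info <- NULL

  emit <- function(name, strand, major_seq) {
    len <- nchar(major_seq)
    feats[[length(feats) + 1L]] <<- feature(
      name, c(cursor, cursor + len), strand = strand,
      klass = gene_class(name))
    pieces[length(pieces) + 1L] <<- major_seq
    cursor <<- cursor + len
  }
  gap_after <- function(name) {
    gp <- if (name %in% names(spec$igr)) spec$igr[[name]] else 0L
    if (gp > 0) {
      tg <- spec$targets$igr
      pieces[length(pieces) + 1L] <<- random_seq_exact(gp, tg[1], tg[2], tg[3])
      cursor <<- cursor + gp
    }
  }

  for (i in seq_len(nrow(ord))) {
    nm <- ord$name[i]; st <- ord$strand[i]
    kl <- gene_class(nm)
    len <- spec$lengths[[nm]]
    if (kl == "PCG") {
      cds <- generate_cds(len - 3L, bias = spec$codon_bias,
                          stop_codon = "TAA")
      start <- if (nm %in% names(spec$start_codons))
        spec$start_codons[[nm]] else "ATG"
      cds <- paste0(start, substr(cds, 4, nchar(cds)))
      sense_seqs[[nm]] <- cds
      emit(nm, st, if (st == "N") revcomp(cds) else cds)
    } else {
      tg <- if (kl == "tRNA") spec$targets$tRNA else spec$targets[[nm]]
      s <- random_seq_exact(len, tg[1], tg[2], tg[3])   # major-strand footprint
      sense_seqs[[nm]] <- if (st == "N") revcomp(s) else s
      emit(nm, st, s)
    }
    gap_after(nm)
  }
  # control region after the final gene, before wrapping to the first
  cr <- build_control_region(spec$lengths[[CONTROL_REGION_NAME]],
                             spec$targets$AT_rich, spec$cr_planted)
  cr_start <- cursor
  emit(CONTROL_REGION_NAME, "J", cr$sequence)
  sense_seqs[[CONTROL_REGION_NAME]] <- cr$sequence

  g <- genome(paste(pieces, collapse = ""), id = spec$id,
              organism = spec$organism, circular = TRUE)
  a <- annotation_set(g, feats)

  planted <- lapply(cr$realized, function(p) {
    p$abs_start <- cr_start + p$offset
    p
  })

  manifest <- list(
    id = spec$id, seed = spec$seed, genome_length = g$length,
    features = data.frame(
      name = vapply(feats, `[[`, character(1), "name"),
      strand = vapply(feats, `[[`, character(1), "strand"),
      start = vapply(feats, function(f) f$spans[1, 1], integer(1)),
      end = vapply(feats, function(f) f$spans[nrow(f$spans), 2], integer(1)),
      stringsAsFactors = FALSE),
    planted = planted,
    partition_counts = manifest_partition_counts(sense_seqs, g$sequence, ord))
  list(annotation = a, manifest = manifest)
}

# exact realized base counts per default partition, tallied directly from
# the generated strings (independently of the composition module)
manifest_partition_counts <- function(sense_seqs, genome_seq, ord) {
  pcg <- intersect(ord$name, PCG_NAMES)
  cds_nostop <- vapply(pcg, function(nm) {
    s <- sense_seqs[[nm]]
    substr(s, 1, nchar(s) - 3L)              # generator always ends in a stop
  }, character(1))
  pos_seq <- function(p) paste(vapply(cds_nostop, function(s) {
    idx <- seq.int(p, nchar(s), by = 3L)
    paste(substring(s, idx, idx), collapse = "")
  }, character(1)), collapse = "")
  major_of <- function(nm) {
    s <- sense_seqs[[nm]]
    st <- ord$strand[match(nm, ord$name)]
    if (!is.na(st) && st == "N") revcomp(s) else s
  }
  trna <- paste(vapply(intersect(ord$name, TRNA_NAMES), major_of,
                       character(1)), collapse = "")
  rrna <- paste(vapply(intersect(ord$name, RRNA_NAMES), major_of,
                       character(1)), collapse = "")
  list(
    whole_genome_J = tally_bases(genome_seq),
    PCGs_no_stop = tally_bases(paste(cds_nostop, collapse = "")),
    codon_pos1 = tally_bases(pos_seq(1L)),
    codon_pos2 = tally_bases(pos_seq(2L)),
    codon_pos3 = tally_bases(pos_seq(3L)),
    tRNAs = tally_bases(trna),
    rRNAs = tally_bases(rrna),
    rrnL = tally_bases(major_of("rrnL")),
    rrnS = tally_bases(major_of("rrnS")),
    AT_rich = tally_bases(sense_seqs[[CONTROL_REGION_NAME]]))
}

#' Generate a comparative study set of synthetic genomes
#'
#' `n` genomes from [default_genome_spec()] with per-genome seeds derived
#' from `seed`, all sharing one planted conserved-block sequence in their
#' control regions (so cross-species block discovery has ground truth).
#'
#' @param n Number of genomes.
#' @param seed Integer master seed.
#' @return List with `sets` (named list of annotation sets), `manifests`,
#'   and `block_seq`.
#' @export
generate_study_set <- function(n = 4, seed = 1L) {
  block_seq <- with_seed(seed * 1000L + 7L, random_seq_exact(40, 0.8, 0.1, -0.1))
  out <- lapply(seq_len(n), function(i) {
    sp <- default_genome_spec(seed = seed * 100L + i,
                              id = sprintf("SYN%03d", i),
                              organism = sprintf("Synthetica exempli %d", i),
                              block_seq = block_seq)
    generate_genome(sp)
  })
  names(out) <- vapply(out, function(x) x$annotation$genome$id, character(1))
  list(sets = lapply(out, `[[`, "annotation"),
       manifests = lapply(out, `[[`, "manifest"),
       block_seq = block_seq)
}

#' Write / read a genome spec as JSON
#'
#' @param spec A `genome_spec`.
#' @param path File path.
#' @return `read_genome_spec()` returns a `genome_spec`;
#'   `write_genome_spec()` returns `path` invisibly.
#' @export
write_genome_spec <- function(spec, path) {
  x <- unclass(spec)
  x$gene_order <- as.data.frame(spec$gene_order)
  # named atomic vectors must become JSON objects, not arrays
  for (f in c("lengths", "codon_bias", "igr", "start_codons"))
    x[[f]] <- as.list(x[[f]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_genome_spec
#' @export
read_genome_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  targets <- lapply(x$targets, as.numeric)
  cr <- x$cr_planted
  genome_spec(gene_order(x$gene_order$name, x$gene_order$strand),
              lengths = unlist(x$lengths), targets = targets,
              codon_bias = unlist(x$codon_bias),
              igr = unlist(x$igr), start_codons = unlist(x$start_codons),
              cr_planted = cr, id = x$id, organism = x$organism,
              seed = x$seed)
}
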