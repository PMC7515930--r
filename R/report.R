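# Comparative multi-genome reporting: the command-level entry points behind
# the mitocomp command-line script. Each writes its tables as TSV with a
# machine-readable JSON mirror, logs to stderr, and returns its results
# invisibly so the same functions serve interactive use.

log_msg <- function(...) message(sprintf(...))

write_tsv_json <- function(df, out_dir, name) {
  tsv <- file.path(out_dir, paste0(name, ".tsv"))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(df, file.path(out_dir, paste0(name, ".json")),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(tsv)
}

# accept annotation sets or paths to GenBank files
resolve_inputs <- function(inputs) {
  if (!length(inputs)) stop("no input genomes given")
  sets <- lapply(inputs, function(x) {
    if (inherits(x, "annotation_set")) x
    else if (is.character(x) && file.exists(x)) read_genbank(x)
    else stop("input must be an annotation_set or a path to a GenBank file")
  })
  nm <- names(sets)
  auto <- vapply(sets, function(a) a$genome$id, character(1))
  out <- if (is.null(nm)) auto else ifelse(nzchar(nm), nm, auto)
  names(sets) <- make.unique(out, sep = "_")
  sets
}

#' Comparative composition / codon-usage report
#'
#' Emits, for one or more annotated genomes: the comparative composition
#' matrix (partitions x genomes), per-genome RSCU tables, the start/stop
#' codon report, absent codons, the junction report, and the strand census.
#'
#' @param inputs List of [annotation_set()] objects or GenBank file paths.
#' @param out_dir Output directory (created if needed).
#' @param raw Emit full-precision values; otherwise AT% is rendered to 1
#'   decimal and skews to 3, the conventional reporting precision.
#' @return Invisibly, a list with all computed tables.
#' @export
run_stats <- function(inputs, out_dir = ".", raw = FALSE) {
  sets <- resolve_inputs(inputs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  comp <- composition_matrix(sets)
  comp_out <- if (raw) comp else {
    cbind(genome = comp$genome, format_composition(comp[-1]))
  }
  write_tsv_json(comp_out, out_dir, "composition")

  rscu_tabs <- lapply(names(sets), function(nm) {
    counts <- count_codons(pcg_cds_set(sets[[nm]]))
    cbind(genome = nm, rscu(counts))
  })
  write_tsv_json(do.call(rbind, rscu_tabs), out_dir, "rscu")

  absent <- do.call(rbind, lapply(names(sets), function(nm) {
    ab <- absent_codons(count_codons(pcg_cds_set(sets[[nm]])))
    if (nrow(ab)) cbind(genome = nm, ab) else NULL
  }))
  if (is.null(absent))
    absent <- data.frame(genome = character(0), codon = character(0),
                         aa3 = character(0))
  write_tsv_json(absent, out_dir, "absent_codons")

  ss <- do.call(rbind, lapply(names(sets), function(nm)
    cbind(genome = nm, start_stop_report(sets[[nm]]))))
  write_tsv_json(ss, out_dir, "start_stop")

  jn <- do.call(rbind, lapply(names(sets), function(nm)
    cbind(genome = nm, junctions(sets[[nm]]))))
  write_tsv_json(jn, out_dir, "junctions")

  census <- do.call(rbind, lapply(names(sets), function(nm) {
    sc <- strand_census(sets[[nm]])
    do.call(rbind, lapply(names(sc), function(k)
      data.frame(genome = nm, klass = k,
                 J = paste(sc[[k]]$J, collapse = ","),
                 N = paste(sc[[k]]$N, collapse = ","),
                 n_J = length(sc[[k]]$J), n_N = length(sc[[k]]$N),
                 stringsAsFactors = FALSE)))
  }))
  write_tsv_json(census, out_dir, "strand_census")

  ranking <- do.call(rbind, lapply(names(sets), function(nm)
    cbind(genome = nm, amino_acid_ranking(count_codons(pcg_cds_set(sets[[nm]]))))))
  write_tsv_json(ranking, out_dir, "amino_acid_ranking")

  log_msg("stats: %d genome(s), outputs in %s", length(sets), out_dir)
  invisible(list(composition = comp, rscu = rscu_tabs, absent = absent,
                 start_stop = ss, junctions = jn, census = census,
                 ranking = ranking))
}

#' Control-region feature report
#'
#' Per-genome T-stretch, stem-loop and tandem-repeat listings, conserved
#' blocks across genomes (when two or more control regions are available),
#' and an annotated text rendering. Genomes lacking a control region get a
#' warning and are skipped; the rest are still processed.
#'
#' @param inputs List of [annotation_set()] objects or GenBank file paths.
#' @param out_dir Output directory.
#' @param min_stem,loop_range,allow_gu,max_mismatch Stem-loop parameters,
#'   see [find_stem_loops()].
#' @param min_period,max_period,min_copies,min_identity Tandem-repeat
#'   parameters, see [find_tandem_repeats()].
#' @param min_block,block_identity Conserved-block parameters, see
#'   [find_conserved_blocks()].
#' @param tstretch_min_len,tstretch_max_int T-stretch parameters.
#' @return Invisibly, a list of per-genome reports plus `blocks`.
#' @export
run_control_region <- function(inputs, out_dir = ".",
                               tstretch_min_len = 9, tstretch_max_int = 2,
                               min_stem = 8, loop_range = c(3, 8),
                               allow_gu = FALSE, max_mismatch = 0,
                               min_period = 5, max_period = 200,
                               min_copies = 2, min_identity = 70,
                               min_block = 15, block_identity = 90) {
  sets <- resolve_inputs(inputs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  crs <- list()
  per_genome <- list()
  for (nm in names(sets)) {
    a <- sets[[nm]]
    if (!CONTROL_REGION_NAME %in% feature_names(a)) {
      warning(sprintf("genome %s: no control region found; skipped", nm),
              call. = FALSE)
      next
    }
    cr <- extract_feature_sequence(a, CONTROL_REGION_NAME)
    crs[[nm]] <- cr
    ts <- find_t_stretches(cr, tstretch_min_len, tstretch_max_int)
    sl <- find_stem_loops(cr, min_stem, loop_range, allow_gu, max_mismatch)
    tr <- find_tandem_repeats(cr, min_period, max_period, min_copies,
                              min_identity)
    mo <- motif_scan(cr)
    per_genome[[nm]] <- list(t_stretches = ts, stem_loops = sl,
                             tandem_repeats = tr, motifs = mo)
    if (nrow(ts)) write_tsv_json(cbind(genome = nm, ts), out_dir,
                                 paste0("tstretch_", nm))
    if (nrow(sl)) write_tsv_json(cbind(genome = nm, sl), out_dir,
                                 paste0("stemloop_", nm))
    if (nrow(tr)) write_tsv_json(cbind(genome = nm, tr), out_dir,
                                 paste0("repeats_", nm))
    writeLines(render_control_region(cr, ts, tr),
               file.path(out_dir, paste0("cr_annotated_", nm, ".txt")))
  }
  blocks <- if (length(crs) >= 2)
    find_conserved_blocks(crs, min_block = min_block,
                          min_identity = block_identity)
  else list()
  if (length(blocks))
    write_tsv_json(conserved_block_table(blocks), out_dir, "conserved_blocks")
  log_msg("control-region: %d genome(s) scanned, %d conserved block(s)",
          length(crs), length(blocks))
  invisible(c(per_genome, list(blocks = blocks)))
}

#' Build and write a supermatrix from a directory of alignments
#'
#' Reads every `*.fasta`/`*.fa` per-gene alignment in `align_dir` (file stem
#' = gene name), concatenates, and writes relaxed PHYLIP, NEXUS (with
#' charsets) and a RAxML-style partition file.
#'
#' @param align_dir Directory of aligned FASTA files.
#' @param out_prefix Output path prefix.
#' @param strip_stops Strip terminal stop-codon columns from in-frame PCG
#'   alignments.
#' @param scheme Partition scheme, see [write_nexus()].
#' @return Invisibly, the `supermatrix`.
#' @export
run_supermatrix <- function(align_dir, out_prefix = "supermatrix",
                            strip_stops = TRUE, scheme = "by_gene") {
  files <- list.files(align_dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  if (!length(files)) stop("no FASTA alignments found in ", align_dir)
  alignments <- lapply(files, read_fasta)
  names(alignments) <- sub("\\.(fa|fasta)$", "", basename(files))
  sm <- concatenate_alignments(alignments, strip_stops = strip_stops)
  write_phylip(sm, paste0(out_prefix, ".phy"))
  write_nexus(sm, paste0(out_prefix, ".nex"), scheme = scheme)
  write_raxml_partitions(sm, paste0(out_prefix, ".partitions.txt"),
                         scheme = scheme)
  log_msg("supermatrix: %d taxa, %d sites, %d partitions",
          length(sm$taxa), nchar(sm$rows[[1]]), nrow(sm$partitions))
  invisible(sm)
}

#' Simulate a synthetic genome and write it to disk
#'
#' @param out_prefix Output path prefix; writes `<prefix>.gb`,
#'   `<prefix>.fasta`, `<prefix>.features.tsv` and `<prefix>.manifest.json`.
#' @param spec A [genome_spec()]; default [default_genome_spec()] under
#'   `seed`.
#' @param seed Seed used when `spec` is not given.
#' @return Invisibly, the `generate_genome()` result.
#' @export
run_simulate <- function(out_prefix = "synthetic", spec = NULL, seed = 1L) {
  if (is.null(spec))
    spec <- default_genome_spec(seed = seed, id = sprintf("SYN%03d", seed))
  gen <- generate_genome(spec)
  a <- gen$annotation
  write_genbank(a, paste0(out_prefix, ".gb"))
  write_fasta(setNames(a$genome$sequence, a$genome$id),
              paste0(out_prefix, ".fasta"))
  write_feature_table(a, paste0(out_prefix, ".features.tsv"))
  jsonlite::write_json(gen$manifest, paste0(out_prefix, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  log_msg("simulate: %s (%d bp) written to %s.*", a$genome$id,
          a$genome$length, out_prefix)
  invisible(gen)
}
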