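# Low-level sequence helpers shared across modules. Sequences are plain
# uppercase character scalars over {A,C,G,T,N}; Biostrings does the heavy
# lifting where it applies.

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' Validate a nucleotide string
#'
#' Uppercases `seq` and errors on any character outside `{A,C,G,T,N}`.
#' @param seq Character scalar.
#' @param what Label used in error messages.
#' @return The validated, uppercased sequence.
#' @export
check_dna <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    stop(sprintf("%s contains invalid characters: %s", what,
                 paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")))
  }
  seq
}

# split a sequence into single characters
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# DNA -> RNA alphabet (used by the tRNA module for reporting)
dna_to_rna <- function(x) chartr("Tt", "Uu", x)
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

# run thunk under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# largest-remainder apportionment of n items to probabilities p (sums to n)
apportion <- function(n, p) {
  stopifnot(n >= 0, all(p >= 0), sum(p) > 0)
  p <- p / sum(p)
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    frac <- raw - k
    # deterministic tie-break: larger fraction first, then earlier index
    ord <- order(-frac, seq_along(frac))
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1L
  }
  as.integer(k)
}
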