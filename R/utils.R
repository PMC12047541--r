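# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a parent seed and a stream name
#'
#' All stochastic steps in the package draw their randomness from one global
#' seed via named child streams, so that individual pipeline stages are
#' reproducible in isolation.
#'
#' @param seed Integer parent seed.
#' @param stream Character stream name (e.g. `"reads"`, `"dedup"`).
#' @return An integer seed, deterministic in `(seed, stream)`, < 2^31.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # polynomial hash of the stream name folded with the parent seed
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483563
  as.integer(h %% 2147483563) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# reverse complement of a plain character vector of DNA strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# vectorised substring over one long string (1-based inclusive)
substr_vec <- function(s, start, end) {
  substring(s, start, end)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Benjamini-Hochberg wrapper kept in one place
bh_fdr <- function(p) stats::p.adjust(p, method = "BH")
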