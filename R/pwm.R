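BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' Holds per-position base probabilities (and raw counts where available),
#' background frequencies, the derived log-odds matrix, and a calling
#' threshold. Probabilities are normalised per position.
#'
#' @param mat 4 x w numeric matrix (rows A, C, G, T) of counts or
#'   probabilities.
#' @param name Motif name.
#' @param bkg Background base frequencies (named, sums to 1).
#' @param pseudocount Added to counts before normalisation (default 0.5 total
#'   per position, split by background).
#' @param threshold Log-odds calling threshold; if `NULL`, set to the score
#'   whose match p-value under the background model is `threshold_pval`.
#' @param threshold_pval Match p-value used to derive the default threshold.
#' @return Object of class `pwm`.
#' @export
pwm <- function(mat, name = "motif",
                bkg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                pseudocount = 0.5, threshold = NULL, threshold_pval = 1e-4) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L && ncol(mat) == 4L) mat <- t(mat)
  stopifnot(nrow(mat) == 4L, ncol(mat) >= 4L, all(mat >= 0))
  rownames(mat) <- BASES
  bkg <- bkg[BASES] / sum(bkg[BASES])
  counts <- NULL
  if (any(mat > 1) || any(abs(colSums(mat) - 1) > 1e-6)) {
    counts <- mat
    mat <- sweep(mat + pseudocount * bkg, 2, colSums(mat) + pseudocount, "/")
  }
  prob <- sweep(mat, 2, colSums(mat), "/")
  lo <- log2(sweep(pmax(prob, 1e-10), 1, bkg, "/"))
  obj <- structure(list(name = name, prob = prob, counts = counts, bkg = bkg,
                        logodds = lo, width = ncol(prob), threshold = NA_real_),
                   class = "pwm")
  obj$threshold <- if (!is.null(threshold)) threshold else
    pwm_score_threshold(obj, threshold_pval)
  obj
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, call threshold %.2f bits, consensus %s\n",
              x$name, x$width, x$threshold, pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (modal base per position)
#' @param x A [pwm()].
#' @export
pwm_consensus <- function(x) paste(BASES[apply(x$prob, 2, which.max)], collapse = "")

#' Information content per position of a probability matrix
#'
#' IC(j) = 2 + sum_b f_bj log2 f_bj (bits), the small-sample-uncorrected
#' Schneider information content over a uniform background.
#'
#' @param prob 4 x w probability matrix.
#' @return Numeric vector of per-position information content in bits.
#' @export
pwm_ic <- function(prob) {
  apply(prob, 2, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
}

#' Log-odds score threshold for a given match p-value
#'
#' Computes the exact distribution of the motif score of a random background
#' sequence by per-position convolution of the (discretised) log-odds values
#' and returns the smallest score `s` with `P(score >= s) <= pval`.
#'
#' @param x A [pwm()].
#' @param pval Match p-value (default 1e-4).
#' @param step Discretisation step in bits.
#' @export
pwm_score_threshold <- function(x, pval = 1e-4, step = 0.001) {
  lo <- round(x$logodds / step)
  # distribution over discretised scores: named vector prob[score]
  dist <- c(`0` = 1)
  for (j in seq_len(ncol(lo))) {
    s <- as.numeric(names(dist))
    new <- tapply(rep(dist, each = 4L) * rep(x$bkg, length(dist)),
                  rep(s, each = 4L) + rep(lo[, j], length(dist)), sum)
    dist <- new
  }
  sc <- as.numeric(names(dist))
  o <- order(sc, decreasing = TRUE)
  tail_p <- cumsum(dist[o])
  i <- which(tail_p <= pval)
  thr <- if (length(i)) sc[o][max(i)] else max(sc) + 1
  thr * step
}

#' Score every offset of a sequence against a PWM, both strands
#'
#' @param x A [pwm()].
#' @param seq DNA string (length >= motif width).
#' @return data.frame with `offset` (1-based start of the motif in `seq`),
#'   `strand`, `score`.
#' @export
pwm_score_all <- function(x, seq) {
  w <- x$width
  L <- nchar(seq)
  if (L < w) return(data.frame(offset = integer(), strand = character(),
                               score = numeric()))
  b <- match(strsplit(toupper(seq), "")[[1]], BASES)
  n <- L - w + 1L
  idx <- outer(seq_len(n) - 1L, seq_len(w), `+`)    # n x w base positions
  base <- matrix(b[idx], nrow = n)
  sc_f <- sc_r <- rep(NA_real_, n)
  ok <- !apply(is.na(base), 1, any)
  if (any(ok)) {
    lo <- x$logodds
    # forward strand
    sc_f[ok] <- rowSums(matrix(lo[cbind(as.vector(base[ok, , drop = FALSE]),
                                        rep(seq_len(w), each = sum(ok)))],
                               nrow = sum(ok)))
    # reverse strand: complement bases, reverse positions
    comp <- 5L - base
    sc_r[ok] <- rowSums(matrix(lo[cbind(as.vector(comp[ok, , drop = FALSE]),
                                        rep(w:1, each = sum(ok)))],
                               nrow = sum(ok)))
  }
  data.frame(offset = rep(seq_len(n), 2L),
             strand = rep(c("+", "-"), each = n),
             score = c(sc_f, sc_r))
}

#' Read PWMs from a JASPAR-format text file
#'
#' Accepts the JASPAR 2020+ flavour: a `>ID name` header line followed by four
#' rows `A [ 4 19 0 ... ]` (brackets optional).
#'
#' @param path File path.
#' @param ... Passed to [pwm()].
#' @return Named list of [pwm()] objects.
#' @export
read_jaspar <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stopf("no JASPAR records ('>' headers) in %s", path)
  out <- list()
  for (s in starts) {
    name <- trimws(sub("^>\\s*", "", lines[s]))
    name <- gsub("\\s+", "_", name)
    rows <- lines[(s + 1L):(s + 4L)]
    row_nums <- lapply(rows, function(r) {
      r2 <- sub("^\\s*[ACGTacgt]", "", r)
      as.numeric(regmatches(r2, gregexpr("-?[0-9.]+", r2))[[1]])
    })
    if (length(unique(lengths(row_nums))) != 1L)
      stopf("JASPAR record '%s': ragged matrix rows", name)
    mat <- do.call(rbind, row_nums)
    bases <- toupper(substr(trimws(rows), 1L, 1L))
    if (!all(sort(bases) == BASES)) stopf("JASPAR record '%s': expected A/C/G/T rows", name)
    rownames(mat) <- bases
    out[[name]] <- pwm(mat[BASES, , drop = FALSE], name = name, ...)
  }
  out
}

#' Read PWMs from a MEME minimal-format file
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections and
#' the file-level `Background letter frequencies` line if present.
#'
#' @param path File path.
#' @param ... Passed to [pwm()].
#' @return Named list of [pwm()] objects.
#' @export
read_meme <- function(path, ...) {
  lines <- readLines(path)
  bkg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bl <- grep("^Background letter frequencies", lines)
  if (length(bl) && bl[1] < length(lines)) {
    toks <- strsplit(trimws(lines[bl[1] + 1L]), "\\s+")[[1]]
    if (length(toks) >= 8L) {
      v <- as.numeric(toks[c(2, 4, 6, 8)])
      names(v) <- toupper(toks[c(1, 3, 5, 7)])
      if (!anyNA(v)) bkg <- v[BASES]
    }
  }
  starts <- grep("^MOTIF\\s", lines)
  if (!length(starts)) stopf("no MOTIF blocks in %s", path)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(sub("^MOTIF\\s+", "", lines[s])), "\\s+")[[1]][1]
    h <- grep("^letter-probability matrix", lines[s:length(lines)])[1] + s - 1L
    if (is.na(h)) stopf("MOTIF %s: no letter-probability matrix", name)
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
    rows <- lines[(h + 1L):(h + w)]
    mat <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4]),
                    numeric(4)))
    out[[name]] <- pwm(t(mat), name = name, bkg = bkg, ...)
  }
  out
}

#' Write an ICM / count matrix as a tab-separated file
#' @param mat 4 x w matrix (rows A,C,G,T).
#' @param path Output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  utils::write.table(cbind(base = rownames(mat), as.data.frame(mat)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
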