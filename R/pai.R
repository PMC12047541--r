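# Predictor-agnostic variant prioritisation: predicted allelic imbalance
# (pAI) and in silico saturation mutagenesis. A CoveragePredictor is a list
# with class "coverage_predictor": $predict(seq) -> non-negative scalar
# (summed predicted coverage over the window), $window (bp), $name.

#' Toy PWM-energy coverage predictor
#'
#' Occupancy of a window is the Boltzmann-weighted sum of PWM log-odds scores
#' over all offsets and strands: `sum exp(lambda * score)`. Deterministic,
#' strictly positive, and motif-driven — the ground-truth predictor used to
#' exercise the pAI and saturation-mutagenesis machinery without a trained
#' network. External sequence-to-coverage models can be plugged in by
#' wrapping their per-window summed prediction in the same interface.
#'
#' @param x A [pwm()].
#' @param lambda Inverse-temperature scaling of log-odds scores (default 0.7).
#' @param window Prediction window length in bp (default 256).
#' @return A `coverage_predictor`.
#' @export
pwm_energy_predictor <- function(x, lambda = 0.7, window = 256L) {
  force(x); force(lambda)
  predict_fn <- function(seq) {
    sc <- pwm_score_all(x, seq)$score
    sc <- sc[!is.na(sc)]
    if (!length(sc)) return(0)
    sum(exp(lambda * sc))
  }
  structure(list(predict = predict_fn, window = as.integer(window),
                 name = sprintf("pwm-energy(%s, lambda=%g)", x$name, lambda)),
            class = "coverage_predictor")
}

#' Constant coverage predictor (for calibration checks)
#' @param value Constant prediction (default 1).
#' @param window Window length.
#' @export
constant_predictor <- function(value = 1, window = 256L) {
  structure(list(predict = function(seq) value, window = as.integer(window),
                 name = "constant"),
            class = "coverage_predictor")
}

#' @export
print.coverage_predictor <- function(x, ...) {
  cat(sprintf("coverage predictor: %s (window %d bp)\n", x$name, x$window))
  invisible(x)
}

# fixed-length window centered on a variant for one allele (alt windows are
# rebuilt through the haplotype machinery and re-centered on the variant)
allele_window <- function(g, v, allele, window) {
  half <- window %/% 2L
  L <- nchar(g[[v$chrom]])
  ws <- v$pos - half + 1L; we <- ws + window - 1L
  if (allele == 0L) return(substr(g[[v$chrom]], max(1L, ws), min(L, we)))
  pad <- nchar(v$ref) + nchar(v$alt) + 4L
  bs <- max(1L, ws - pad); be <- min(L, we + pad)
  hap <- haplotype_sequence(g, v$chrom, bs, be, v[, c("pos", "ref", "alt")], 1L)
  vc <- hap$ref_to_hap[v$pos - bs + 1L]
  as_ <- vc - (v$pos - ws)
  substr(hap$seq, max(1L, as_), min(nchar(hap$seq), as_ + window - 1L))
}

#' Predicted allelic imbalance (pAI) for variants
#'
#' For each variant, the predictor scores a fixed-length window centered on
#' the variant for the reference and the alternative allele;
#' `pAI = pred(ref) / (pred(ref) + pred(alt))`. Equal predictions give
#' exactly 0.5; a zero total is undefined and reported `NA`.
#'
#' @param predictor A `coverage_predictor`.
#' @param genome See [load_genome()].
#' @param variants data.frame (`chrom`, `pos`, `ref`, `alt`).
#' @return data.frame: `variant_id`, `pred_ref`, `pred_alt`, `pai`.
#' @export
predict_pai <- function(predictor, genome, variants) {
  g <- load_genome(genome)
  variants <- validate_variants(variants)
  out <- data.frame(variant_id = variants$id, pred_ref = NA_real_,
                    pred_alt = NA_real_, pai = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    pr <- predictor$predict(allele_window(g, v, 0L, predictor$window))
    pa <- predictor$predict(allele_window(g, v, 1L, predictor$window))
    out$pred_ref[i] <- pr; out$pred_alt[i] <- pa
    out$pai[i] <- if (pr + pa > 0) pr / (pr + pa) else NA_real_
  }
  out
}

#' Rank a peak's variants by predicted effect size
#'
#' Descending `|pAI - 0.5|`; ties broken by distance to the peak summit, then
#' by coordinate. Rank 1 is the top-predicted (candidate causal) variant.
#'
#' @param pai_table Output of [predict_pai()] with added `region_id`, `pos`
#'   and (optionally) `summit_distance` columns.
#' @return `pai_table` with a `rank` column, ordered within region.
#' @export
rank_variants <- function(pai_table) {
  stopifnot(all(c("region_id", "pai", "pos") %in% names(pai_table)))
  sd_ <- pai_table$summit_distance %||% rep(0, nrow(pai_table))
  if (is.null(pai_table$summit_distance)) pai_table$summit_distance <- sd_
  parts <- split(seq_len(nrow(pai_table)), pai_table$region_id)
  pai_table$rank <- NA_integer_
  for (ix in parts) {
    o <- order(-abs(pai_table$pai[ix] - 0.5), pai_table$summit_distance[ix],
               pai_table$pos[ix])
    pai_table$rank[ix[o]] <- seq_along(ix)
  }
  pai_table[order(pai_table$region_id, pai_table$rank), , drop = FALSE]
}

#' Direction agreement between predicted and measured allelic imbalance
#'
#' A prediction is correct when `pAI - 0.5` and `ref_bias - 0.5` share sign.
#' The strong set requires both absolute deviations above
#' `strong_threshold`.
#'
#' @param pai_table Output of [predict_pai()].
#' @param results CHT result table (`variant_id`, `ref_bias`).
#' @param strong_threshold Deviation-from-0.5 cutoff for the strong set
#'   (default 0.1).
#' @return List: `fraction` (agreement over all shared variants with defined
#'   directions), `fraction_strong`, `strong` (strong-set table), `table`.
#' @export
direction_agreement <- function(pai_table, results, strong_threshold = 0.1) {
  m <- merge(pai_table, results[, c("variant_id", "ref_bias")],
             by = "variant_id")
  m <- m[!is.na(m$pai) & m$pai != 0.5 & m$ref_bias != 0.5, , drop = FALSE]
  m$correct <- sign(m$pai - 0.5) == sign(m$ref_bias - 0.5)
  strong <- m[abs(m$pai - 0.5) > strong_threshold &
                abs(m$ref_bias - 0.5) > strong_threshold, , drop = FALSE]
  list(fraction = if (nrow(m)) mean(m$correct) else NA_real_,
       fraction_strong = if (nrow(strong)) mean(strong$correct) else NA_real_,
       strong = strong, table = m)
}

#' In silico saturation mutagenesis around a position
#'
#' Every base at every position within `center +/- flank` is substituted in
#' turn and the mutated window is scored with the predictor. Scores are
#' normalised by the mean of their absolute values; deltas subtract the
#' reference-base score at each position (so the reference base's delta is
#' exactly zero), and the per-position importance is the sum of absolute
#' deltas.
#'
#' @param predictor A `coverage_predictor`.
#' @param genome See [load_genome()].
#' @param chrom,center Window center (1-based).
#' @param flank Bases on each side (default 75: a 151-position scan).
#' @return Object of class `satmut`: `positions` (genomic), `ref_base`,
#'   `raw`, `norm` (position x base matrices), `delta`, `importance`,
#'   `skipped` (positions with non-ACGT reference base).
#' @export
saturation_mutagenesis <- function(predictor, genome, chrom, center,
                                   flank = 75L) {
  g <- load_genome(genome)
  L <- nchar(g[[chrom]])
  win <- predictor$window
  half <- win %/% 2L
  ws <- center - half + 1L; we <- ws + win - 1L
  if (ws < 1L || we > L)
    stopf("prediction window [%d,%d] off contig '%s' (length %d)", ws, we, chrom, L)
  seq0 <- substr(g[[chrom]], ws, we)
  positions <- (center - flank):(center + flank)
  n <- length(positions)
  raw <- matrix(NA_real_, n, 4L, dimnames = list(NULL, BASES))
  ref_base <- substring(seq0, positions - ws + 1L, positions - ws + 1L)
  skipped <- !(ref_base %in% BASES)
  for (i in seq_len(n)) {
    if (skipped[i]) next
    off <- positions[i] - ws + 1L
    for (b in BASES) {
      s <- seq0
      substr(s, off, off) <- b
      raw[i, b] <- predictor$predict(s)
    }
  }
  norm <- raw / mean(abs(raw), na.rm = TRUE)
  delta <- norm
  for (i in seq_len(n)) {
    if (skipped[i]) { delta[i, ] <- NA_real_; next }
    delta[i, ] <- norm[i, ] - norm[i, ref_base[i]]
  }
  importance <- rowSums(abs(delta))
  importance[skipped] <- NA_real_
  structure(list(chrom = chrom, center = center, flank = flank,
                 positions = positions, ref_base = ref_base,
                 raw = raw, norm = norm, delta = delta,
                 importance = importance, skipped = skipped),
            class = "satmut")
}

#' @export
print.satmut <- function(x, ...) {
  cat(sprintf("saturation mutagenesis %s:%d +/-%d bp: max importance %.3g at %s:%d\n",
              x$chrom, x$center, x$flank, max(x$importance, na.rm = TRUE),
              x$chrom, x$positions[which.max(x$importance)]))
  invisible(x)
}

#' @export
plot.satmut <- function(x, ...) {
  plot(x$positions, x$importance, type = "h",
       xlab = sprintf("position on %s", x$chrom),
       ylab = "importance (sum |delta|)", ...)
  graphics::abline(v = x$center, lty = 3, col = "red3")
  invisible(x)
}
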