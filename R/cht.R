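# Combined haplotype test: joint beta-binomial (allele-specific) and
# beta-negative-binomial (read-depth) likelihood sharing one effect parameter
# p = beta/(alpha+beta), the probability that a read comes from the
# ALT-carrying haplotype.

#' Beta-binomial log-likelihood
#'
#' Mean-overdispersion parameterisation: shapes `a = p(1-rho)/rho`,
#' `b = (1-p)(1-rho)/rho`, so `rho -> 0` recovers the binomial exactly (the
#' `rho = 0` branch evaluates the binomial pmf).
#'
#' @param k Successes (ALT-haplotype reads), vectorised.
#' @param n Trials (allele-specific reads), vectorised.
#' @param p Success probability in (0,1).
#' @param rho Overdispersion in `[0, 1)`.
#' @return Sum of log-likelihood contributions.
#' @export
bb_loglik <- function(k, n, p, rho) {
  if (p <= 0 || p >= 1 || rho < 0 || rho >= 1) stopf("bb_loglik: parameters out of range")
  if (any(k < 0) || any(k > n)) stopf("bb_loglik: require 0 <= k <= n")
  if (rho == 0) return(sum(stats::dbinom(k, n, p, log = TRUE)))
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

#' (Beta-)negative-binomial log-likelihood for region read depth
#'
#' Negative binomial with mean `mu` and size (inverse-dispersion) `phi`;
#' `phi = Inf` evaluates the Poisson pmf exactly (variance -> mean limit).
#' An optional beta layer on the NB success probability (`rho_extra > 0`,
#' concentration `(1-rho_extra)/rho_extra`) gives the beta-negative-binomial.
#'
#' @param t Observed total counts (non-negative integers), vectorised.
#' @param mu Expected totals (> 0), vectorised.
#' @param phi Dispersion size parameter (> 0, possibly `Inf`).
#' @param rho_extra Beta-layer overdispersion in `[0, 1)`; 0 = plain NB.
#' @return Sum of log-likelihood contributions.
#' @export
bnb_loglik <- function(t, mu, phi, rho_extra = 0) {
  if (any(t < 0) || any(mu <= 0) || phi <= 0 || rho_extra < 0 || rho_extra >= 1)
    stopf("bnb_loglik: parameters out of range")
  if (is.infinite(phi)) return(sum(stats::dpois(t, mu, log = TRUE)))
  if (rho_extra == 0) return(sum(stats::dnbinom(t, size = phi, mu = mu, log = TRUE)))
  p0 <- phi / (phi + mu)
  cc <- (1 - rho_extra) / rho_extra
  a <- p0 * cc; b <- (1 - p0) * cc
  sum(lchoose(t + phi - 1, t) + lbeta(a + phi, b + t) - lbeta(a, b))
}

# random draws from the depth model (used by the generator and in tests)
rbnb <- function(n, mu, phi, rho_extra = 0) {
  if (is.infinite(phi)) return(stats::rpois(n, mu))
  if (rho_extra == 0) return(stats::rnbinom(n, size = phi, mu = mu))
  p0 <- phi / (phi + mu)
  cc <- (1 - rho_extra) / rho_extra
  pr <- stats::rbeta(n, p0 * cc, (1 - p0) * cc)
  stats::rnbinom(n, size = phi, prob = pr)
}

# expected depth of sample with dosage g under effect p: mu = E ((2-g)(1-p) + g p)
mu_depth <- function(E, g, p) pmax(E * ((2 - g) * (1 - p) + g * p), 1e-9)

cht_loglik <- function(p, dat, rho_as, phi_bnb, use_as = TRUE, use_bnb = TRUE) {
  ll <- 0
  if (use_as) {
    het <- dat$g == 1L & (dat$as_ref + dat$as_alt) > 0L
    if (any(het))
      ll <- ll + bb_loglik(dat$as_alt[het], dat$as_ref[het] + dat$as_alt[het],
                           p, rho_as)
  }
  if (use_bnb)
    ll <- ll + bnb_loglik(dat$T, mu_depth(dat$E, dat$g, p), phi_bnb)
  ll
}

#' Fit the combined haplotype test for one region/variant pair
#'
#' The allele-specific component is a beta-binomial over heterozygous samples
#' (`k` = reads on the ALT-carrying haplotype, `n` = allele-specific reads);
#' the depth component is a negative-binomial over all samples with mean
#' `E_i ((2-g_i)(1-p) + g_i p)` for `g_i` ALT copies. Both share the effect
#' parameter `p`; the null constrains `p = 0.5` (`alpha = beta`), the
#' alternative maximises over `p` by bounded one-dimensional optimisation.
#' Significance is a likelihood-ratio test on 1 df.
#'
#' @param dat data.frame for one test: columns `sample`, `g` (0/1/2 ALT
#'   copies), `T` (total count), `E` (expected count), `as_ref`, `as_alt`.
#' @param rho_as Beta-binomial overdispersion.
#' @param phi_bnb Depth dispersion (NB size).
#' @param component `"full"`, `"as"` or `"bnb"`.
#' @param p_bounds Clamp for the effect parameter.
#' @return List of class `cht_fit` (`alpha`, `beta`, `ref_bias`, `AI`,
#'   `lrt_stat`, `p_value`, log-likelihoods, `converged`, `n_het`), or `NULL`
#'   when the chosen component carries no information (no het sample with
#'   allele-specific reads and no genotype contrast in depth).
#' @export
fit_cht <- function(dat, rho_as = 0.01, phi_bnb = 20, component = "full",
                    p_bounds = c(1e-6, 1 - 1e-6)) {
  component <- match.arg(component, c("full", "as", "bnb"))
  use_as <- component != "bnb"; use_bnb <- component != "as"
  n_het <- sum(dat$g == 1L & (dat$as_ref + dat$as_alt) > 0L)
  depth_contrast <- length(unique(dat$g[dat$g != 1L])) > 1L || (n_het > 0L && any(dat$g != 1L))
  info_as <- use_as && n_het > 0L
  info_bnb <- use_bnb && length(unique(dat$g)) > 1L
  if (!info_as && !info_bnb) return(NULL)
  # drop the uninformative side so the optimiser sees only signal-bearing terms
  use_as <- info_as; use_bnb <- use_bnb && info_bnb

  f <- function(p) cht_loglik(p, dat, rho_as, phi_bnb, use_as, use_bnb)
  ll_null <- f(0.5)
  opt <- try(stats::optimize(f, interval = p_bounds, maximum = TRUE,
                             tol = 1e-8), silent = TRUE)
  if (inherits(opt, "try-error") || !is.finite(opt$objective)) {
    p_hat <- 0.5; ll_alt <- ll_null; converged <- FALSE
  } else {
    converged <- TRUE
    if (opt$objective >= ll_null) {
      p_hat <- opt$maximum; ll_alt <- opt$objective
    } else { p_hat <- 0.5; ll_alt <- ll_null }
  }
  lrt <- max(0, 2 * (ll_alt - ll_null))
  pv <- if (!converged) 1 else stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
  if (!converged) p_hat <- 0.5
  s <- max(sum(dat$as_ref + dat$as_alt), 1L)       # alpha+beta count scale
  structure(list(alpha = s * (1 - p_hat), beta = s * p_hat,
                 p = p_hat, ref_bias = 1 - p_hat,
                 AI = abs(0.5 - (1 - p_hat)),
                 ll_null = ll_null, ll_alt = ll_alt,
                 lrt_stat = lrt, p_value = pv,
                 converged = converged, n_het = n_het,
                 component = component),
            class = "cht_fit")
}

#' @export
print.cht_fit <- function(x, ...) {
  cat(sprintf("CHT fit (%s): ref_bias = %.3f, AI = %.3f, LRT = %.2f, p = %.3g%s\n",
              x$component, x$ref_bias, x$AI, x$lrt_stat, x$p_value,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Estimate genome-wide dispersions under the null
#'
#' Maximum-likelihood estimates with the effect fixed at `p = 0.5`
#' (`alpha = beta`) across all region tests: the beta-binomial overdispersion
#' from all heterozygous allele-specific observations, the depth dispersion
#' from all (T, E) pairs. Deterministic given the data.
#'
#' @param counts Long count table (see [region_counts()]): columns `g`, `T`,
#'   `E`, `as_ref`, `as_alt`, `region_id`.
#' @param min_regions Minimum distinct regions for estimation (default 50);
#'   fewer falls back to `defaults` with a warning.
#' @param defaults Fallback `c(rho_as=, phi_bnb=)`.
#' @return Named list `rho_as`, `phi_bnb`.
#' @export
estimate_dispersions <- function(counts, min_regions = 50,
                                 defaults = c(rho_as = 0.01, phi_bnb = 20)) {
  n_reg <- length(unique(counts$region_id))
  if (n_reg < min_regions) {
    warnf("only %d regions (< %d); using default dispersions", n_reg, min_regions)
    return(as.list(defaults))
  }
  het <- counts$g == 1L & (counts$as_ref + counts$as_alt) > 0L
  rho <- if (any(het)) {
    k <- counts$as_alt[het]; n <- counts$as_ref[het] + counts$as_alt[het]
    stats::optimize(function(r) bb_loglik(k, n, 0.5, r),
                    interval = c(1e-6, 0.8), maximum = TRUE, tol = 1e-7)$maximum
  } else defaults[["rho_as"]]
  ok <- counts$E > 0
  phi <- stats::optimize(function(lp) bnb_loglik(counts$T[ok], counts$E[ok], exp(lp)),
                         interval = log(c(1e-2, 1e6)), maximum = TRUE,
                         tol = 1e-7)$maximum
  list(rho_as = rho, phi_bnb = exp(phi))
}

#' Run the combined haplotype test over a count table
#'
#' The main fitting entry point. For every (region, test variant) pair in the
#' count table it fits the null and alternative models and reports the full
#' CHT together with its allele-specific-only and depth-only component tests,
#' with Benjamini-Hochberg FDR per component across all tested variants.
#' `permute = TRUE` shuffles genotype labels across samples independently for
#' every test variant (seeded) while leaving the counts fixed, and randomises
#' the haplotype orientation of the allele-specific counts — the empirical
#' null used for calibration.
#'
#' @param counts Long count table: columns `region_id`, `variant_id`,
#'   `sample`, `g`, `T`, `E`, `as_ref`, `as_alt` (see [region_counts()]).
#' @param dispersions Optional list `rho_as`, `phi_bnb`; estimated from the
#'   data via [estimate_dispersions()] when `NULL`.
#' @param permute Permute genotypes (empirical null)?
#' @param seed Seed for the permutation stream.
#' @return Object of class `cht_scan`: a results data.frame (one row per
#'   region/variant; columns `p_value`, `p_as`, `p_bnb`, `fdr`, `fdr_as`,
#'   `fdr_bnb`, `alpha`, `beta`, `ref_bias`, `AI`, `lrt_stat`, `n_het`, ...)
#'   plus the dispersions used.
#' @export
cht <- function(counts, dispersions = NULL, permute = FALSE, seed = 1L) {
  need <- c("region_id", "variant_id", "sample", "g", "T", "E", "as_ref", "as_alt")
  if (!all(need %in% names(counts)))
    stopf("count table must have columns: %s", paste(need, collapse = ", "))
  if (is.null(dispersions)) dispersions <- estimate_dispersions(counts)
  key <- paste(counts$region_id, counts$variant_id, sep = "\r")
  groups <- split(seq_len(nrow(counts)), key)

  res <- vector("list", length(groups))
  pseed <- child_seed(seed, "permute")
  for (gi in seq_along(groups)) {
    dat <- counts[groups[[gi]], , drop = FALSE]
    if (permute) {
      dat <- with_seed(pseed + gi, {
        pi_ <- sample.int(nrow(dat))
        d <- dat
        d$g <- dat$g[pi_]
        flip <- sample(c(TRUE, FALSE), nrow(dat), replace = TRUE)
        ar <- ifelse(flip, dat$as_alt, dat$as_ref)
        aa <- ifelse(flip, dat$as_ref, dat$as_alt)
        d$as_ref <- ar; d$as_alt <- aa
        d
      })
    }
    full <- fit_cht(dat, dispersions$rho_as, dispersions$phi_bnb, "full")
    if (is.null(full)) next
    fas <- fit_cht(dat, dispersions$rho_as, dispersions$phi_bnb, "as")
    fbn <- fit_cht(dat, dispersions$rho_as, dispersions$phi_bnb, "bnb")
    res[[gi]] <- data.frame(
      region_id = dat$region_id[1L], variant_id = dat$variant_id[1L],
      n_samples = nrow(dat), n_het = full$n_het,
      alpha = full$alpha, beta = full$beta,
      ref_bias = full$ref_bias, AI = full$AI,
      ll_null = full$ll_null, ll_alt = full$ll_alt,
      lrt_stat = full$lrt_stat, p_value = full$p_value,
      p_as = if (is.null(fas)) NA_real_ else fas$p_value,
      p_bnb = if (is.null(fbn)) NA_real_ else fbn$p_value,
      converged = full$converged,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(res) || !nrow(res)) stopf("no informative region tests")
  res$fdr <- bh_fdr(res$p_value)
  res$fdr_as <- bh_fdr(res$p_as)
  res$fdr_bnb <- bh_fdr(res$p_bnb)
  rownames(res) <- NULL
  structure(list(results = res, dispersions = dispersions,
                 permuted = permute, seed = seed,
                 n_samples = length(unique(counts$sample))),
            class = "cht_scan")
}

#' @rdname cht
#' @param ... Passed to [cht()].
#' @export
run_cht <- function(counts, ...) cht(counts, ...)

#' @export
print.cht_scan <- function(x, ...) {
  r <- x$results
  cat(sprintf("Combined haplotype test%s: %d region/variant tests, %d samples\n",
              if (x$permuted) " (permuted genotypes)" else "", nrow(r),
              x$n_samples))
  cat(sprintf("  dispersions: rho_as = %.4g, phi_bnb = %.4g\n",
              x$dispersions$rho_as, x$dispersions$phi_bnb))
  sig <- significant_set(x)
  cat(sprintf("  significant (FDR < 0.01 & AI > 0.1): %d variants\n",
              nrow(sig$variants)))
  invisible(x)
}

#' @export
summary.cht_scan <- function(object, fdr_threshold = 0.01, min_ai = 0.1, ...) {
  r <- object$results
  sig <- significant_set(object, fdr_threshold, min_ai)
  out <- list(n_tests = nrow(r), n_het_median = stats::median(r$n_het),
              dispersions = object$dispersions, permuted = object$permuted,
              n_significant = nrow(sig$variants),
              ai_quantiles = stats::quantile(r$AI, c(.5, .9, .99)),
              p_quantiles = stats::quantile(r$p_value, c(.01, .1, .5)))
  class(out) <- "summary.cht_scan"
  out
}

#' @export
print.summary.cht_scan <- function(x, ...) {
  cat(sprintf("CHT scan%s: %d tests, median het samples %g\n",
              if (x$permuted) " (permuted)" else "", x$n_tests, x$n_het_median))
  cat(sprintf("  rho_as = %.4g, phi_bnb = %.4g\n",
              x$dispersions$rho_as, x$dispersions$phi_bnb))
  cat(sprintf("  significant variants: %d\n", x$n_significant))
  cat("  AI quantiles (50/90/99%):",
      paste(sprintf("%.3f", x$ai_quantiles), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.cht_scan <- function(object, ...) {
  r <- object$results
  stats::setNames(r$ref_bias - 0.5, r$variant_id)
}

#' QQ plot of CHT p-values against the uniform distribution
#' @param x A `cht_scan`.
#' @param which Components to draw.
#' @param ... Passed to `plot`.
#' @export
plot.cht_scan <- function(x, which = c("p_value", "p_as", "p_bnb"), ...) {
  r <- x$results
  cols <- c(p_value = "darkorange2", p_as = "steelblue", p_bnb = "grey40")
  n <- nrow(r)
  exp_q <- -log10(stats::ppoints(n))
  plot(exp_q, sort(-log10(r$p_value)), pch = 20, col = cols[["p_value"]],
       xlab = "expected -log10(p)", ylab = "observed -log10(p)",
       main = if (x$permuted) "CHT (permuted genotypes)" else "CHT", ...)
  for (w in setdiff(which, "p_value")) {
    pv <- r[[w]][!is.na(r[[w]])]
    graphics::points(-log10(stats::ppoints(length(pv))), sort(-log10(pv)),
                     pch = 20, col = cols[[w]])
  }
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = which, col = cols[which], pch = 20,
                   bty = "n")
  invisible(x)
}

#' Significant variants and imbalanced peaks
#'
#' A variant is significant when `fdr < fdr_threshold` and `AI > min_ai`; a
#' peak (region) is imbalanced when it has at least one significant variant.
#' The per-peak top variant is the minimum-p variant (ties broken by larger
#' AI, then leftmost coordinate).
#'
#' @param scan A `cht_scan` (or its results data.frame).
#' @param fdr_threshold FDR cutoff (default 0.01).
#' @param min_ai Allelic-imbalance cutoff (default 0.1).
#' @param component Which p-value/FDR column to gate on.
#' @param variants Optional variant table (`id`, `pos`) for coordinate
#'   tie-breaks.
#' @return List: `variants` (significant rows), `peaks` (one row per
#'   imbalanced region with its top variant).
#' @export
significant_set <- function(scan, fdr_threshold = 0.01, min_ai = 0.1,
                            component = c("full", "as", "bnb"),
                            variants = NULL) {
  component <- match.arg(component)
  r <- if (inherits(scan, "cht_scan")) scan$results else scan
  fcol <- switch(component, full = "fdr", as = "fdr_as", bnb = "fdr_bnb")
  sig <- r[!is.na(r[[fcol]]) & r[[fcol]] < fdr_threshold & r$AI > min_ai, ,
           drop = FALSE]
  if (!is.null(variants)) {
    sig$pos <- variants$pos[match(sig$variant_id, variants$id)]
  } else {
    sig$pos <- suppressWarnings(as.integer(sub("^[^:]*:(\\d+):.*$", "\\1",
                                               sig$variant_id)))
  }
  peaks <- do.call(rbind, lapply(split(sig, sig$region_id), function(d) {
    o <- order(d$p_value, -d$AI, d$pos)
    d[o[1L], , drop = FALSE]
  }))
  list(variants = sig, peaks = peaks)
}

#' Direction concordance between two CHT result tables
#'
#' For variants significant in both tables, a variant is concordant when both
#' reference-allele biases fall on the same side of 0.5. Also reports the
#' Spearman correlation of signed imbalance over all shared variants.
#'
#' @param a,b `cht_scan` objects or result data.frames.
#' @param fdr_threshold,min_ai Significance gates applied to each table.
#' @return List: `fraction` (NA when no variant is significant in both),
#'   `n_shared_significant`, `spearman`, `table`.
#' @export
cht_concordance <- function(a, b, fdr_threshold = 0.01, min_ai = 0.1) {
  ra <- if (inherits(a, "cht_scan")) a$results else a
  rb <- if (inherits(b, "cht_scan")) b$results else b
  shared <- merge(ra[, c("variant_id", "ref_bias", "fdr", "AI")],
                  rb[, c("variant_id", "ref_bias", "fdr", "AI")],
                  by = "variant_id", suffixes = c("_a", "_b"))
  rho <- if (nrow(shared) >= 3L)
    stats::cor(shared$ref_bias_a, shared$ref_bias_b, method = "spearman")
  else NA_real_
  sig <- shared[shared$fdr_a < fdr_threshold & shared$AI_a > min_ai &
                  shared$fdr_b < fdr_threshold & shared$AI_b > min_ai &
                  shared$ref_bias_a != 0.5 & shared$ref_bias_b != 0.5, ,
                drop = FALSE]
  frac <- if (nrow(sig)) mean(sign(sig$ref_bias_a - 0.5) ==
                                sign(sig$ref_bias_b - 0.5)) else NA_real_
  list(fraction = frac, n_shared_significant = nrow(sig), spearman = rho,
       table = shared)
}

#' Relative region read counts (percent of expected)
#' @param counts Long count table.
#' @return `counts` with a `rel_count = 100 * T / E` column.
#' @export
relative_region_counts <- function(counts) {
  counts$rel_count <- 100 * counts$T / counts$E
  counts
}
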