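# Combined haplotype test: likelihood components, fitting, dispersions,
# permutation null, significance sets.

test_that("beta-binomial log-likelihood has exact binomial limit and symmetry", {
  expect_equal(bb_loglik(5, 10, 0.5, 0), log(252 / 1024), tolerance = 1e-9)
  expect_equal(bb_loglik(3, 10, 0.3, 0.1), bb_loglik(7, 10, 0.7, 0.1),
               tolerance = 1e-12)
  expect_error(bb_loglik(5, 10, 1.2, 0), "range")
  expect_error(bb_loglik(11, 10, 0.5, 0), "k <= n")
})

test_that("beta-binomial matches an independent mixture-integral oracle", {
  # oracle: integrate dbinom(k,n,q) against the Beta(a,b) mixing density
  oracle <- function(k, n, p, rho) {
    a <- p * (1 - rho) / rho; b <- (1 - p) * (1 - rho) / rho
    log(stats::integrate(function(q) stats::dbinom(k, n, q) *
                           stats::dbeta(q, a, b),
                         0, 1, rel.tol = 1e-12)$value)
  }
  for (case in list(c(3, 10, 0.5, 0.1), c(0, 12, 0.3, 0.2),
                    c(40, 60, 0.6, 0.05))) {
    expect_equal(bb_loglik(case[1], case[2], case[3], case[4]),
                 oracle(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-7)
  }
})

test_that("depth likelihood has exact Poisson limit and a proper pmf", {
  expect_equal(bnb_loglik(4, 4, Inf), stats::dpois(4, 4, log = TRUE),
               tolerance = 1e-9)
  # pmf sums to 1 for the beta-negative-binomial layer
  ll <- vapply(0:3000, function(t) bnb_loglik(t, 10, 5, rho_extra = 0.05),
               numeric(1))
  expect_equal(sum(exp(ll)), 1, tolerance = 1e-6)
  # NB branch agrees with stats::dnbinom
  expect_equal(bnb_loglik(7, 10, 3), stats::dnbinom(7, size = 3, mu = 10,
                                                    log = TRUE))
})

test_that("draws from the depth model recover their mean", {
  set.seed(42)
  x <- aschip:::rbnb(20000, mu = 50, phi = 10)
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 50), 4 * se)
})

test_that("perfectly balanced data fit to zero imbalance", {
  dat <- data.frame(sample = paste0("s", 1:6), g = c(0, 1, 1, 1, 2, 2),
                    T = 100L, E = 100, as_ref = c(0, 50, 50, 50, 0, 0),
                    as_alt = c(0, 50, 50, 50, 0, 0))
  f <- fit_cht(dat)
  expect_equal(f$AI, 0, tolerance = 1e-4)
  expect_equal(f$ref_bias, 0.5, tolerance = 1e-4)
  expect_gt(f$p_value, 0.9)
  expect_true(f$converged)
})

test_that("a strong reference bias is recovered with the documented summaries", {
  # 75:25 allele-specific reads in each of 4 het samples, depths consistent
  dat <- data.frame(sample = paste0("s", 1:4), g = 1L, T = 100L, E = 100,
                    as_ref = 75L, as_alt = 25L)
  f <- fit_cht(dat, rho_as = 0.001)
  expect_equal(f$ref_bias, 0.75, tolerance = 0.02)
  expect_equal(f$AI, 0.25, tolerance = 0.02)
  expect_equal(f$alpha / (f$alpha + f$beta), f$ref_bias, tolerance = 1e-9)
  expect_lt(f$p_value, 1e-6)
  expect_gte(f$lrt_stat, 0)
})

test_that("uninformative tests are skipped, not forced to p = 1", {
  dat <- data.frame(sample = "s1", g = 2L, T = 100L, E = 100,
                    as_ref = 0L, as_alt = 0L)
  expect_null(fit_cht(dat))
})

test_that("the shared effect is recovered within 0.05 at depth 2000", {
  counts <- simulate_region_counts(n_regions = 30, n_samples = 8,
                                   depth = 2000, as_depth = 2000,
                                   p_true = 0.7, rho_as = 0.01, phi_bnb = 50,
                                   seed = 9)
  scan <- cht(counts, dispersions = list(rho_as = 0.01, phi_bnb = 50))
  p_hat <- 1 - scan$results$ref_bias     # fitted ALT-haplotype probability
  expect_true(all(abs(p_hat - 0.7) < 0.05))
  expect_lt(abs(mean(p_hat) - 0.7), 0.01)
})

test_that("null-model dispersion estimation recovers generating values", {
  low <- simulate_region_counts(n_regions = 150, n_samples = 8, depth = 300,
                                as_depth = 300, p_true = 0.5, rho_as = 0,
                                phi_bnb = 1e5, seed = 5)
  est <- estimate_dispersions(low)
  expect_lt(est$rho_as, 0.02)
  hi <- simulate_region_counts(n_regions = 150, n_samples = 8, depth = 300,
                               as_depth = 300, p_true = 0.5, rho_as = 0.2,
                               phi_bnb = 20, seed = 6)
  est2 <- estimate_dispersions(hi)
  expect_gt(est2$rho_as, 0.15)
  expect_lt(est2$rho_as, 0.25)
  # sufficiency: duplicating every region leaves the estimates unchanged
  dup <- rbind(hi, transform(hi, region_id = paste0(region_id, "b")))
  est3 <- estimate_dispersions(dup)
  expect_equal(est3$rho_as, est2$rho_as, tolerance = 1e-5)
  expect_equal(est3$phi_bnb, est2$phi_bnb, tolerance = 1e-3)
})

test_that("identical data and seed give identical result tables", {
  counts <- simulate_region_counts(n_regions = 40, seed = 3)
  s1 <- cht(counts, dispersions = list(rho_as = 0.01, phi_bnb = 20),
            permute = TRUE, seed = 11)
  s2 <- cht(counts, dispersions = list(rho_as = 0.01, phi_bnb = 20),
            permute = TRUE, seed = 11)
  expect_identical(s1$results, s2$results)
})

test_that("permuted-genotype p-values are uniform on null data", {
  counts <- simulate_region_counts(n_regions = 300, n_samples = 10,
                                   depth = 400, as_depth = 150,
                                   p_true = 0.5, rho_as = 0.02, phi_bnb = 30,
                                   seed = 13)
  scan <- cht(counts, dispersions = list(rho_as = 0.02, phi_bnb = 30),
              permute = TRUE, seed = 13)
  ks <- stats::ks.test(scan$results$p_value, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("the full test is at least as powerful as the AS-only component", {
  # both a depth and an allele-specific effect present
  counts <- simulate_region_counts(n_regions = 150, n_samples = 8,
                                   depth = 300, as_depth = 60, p_true = 0.6,
                                   rho_as = 0.02, phi_bnb = 30, seed = 21)
  scan <- cht(counts, dispersions = list(rho_as = 0.02, phi_bnb = 30))
  power_full <- mean(scan$results$fdr < 0.05)
  power_as <- mean(scan$results$fdr_as < 0.05, na.rm = TRUE)
  expect_gte(power_full, power_as)
})

test_that("detection rate rises with true imbalance and read depth", {
  pow <- function(p, depth) {
    counts <- simulate_region_counts(n_regions = 100, n_samples = 8,
                                     depth = depth, as_depth = depth / 4,
                                     p_true = p, rho_as = 0.02, phi_bnb = 30,
                                     seed = 31)
    scan <- cht(counts, dispersions = list(rho_as = 0.02, phi_bnb = 30))
    mean(scan$results$fdr < 0.05 & scan$results$AI > 0.05)
  }
  expect_lte(pow(0.55, 400), pow(0.7, 400))
  expect_lte(pow(0.7, 80), pow(0.7, 800))
})

test_that("AS-only p-values agree with an exact beta-binomial test", {
  # single het sample, no depth contrast: LRT vs exact two-sided tail
  exact_two_sided <- function(k, n, rho) {
    pm <- vapply(0:n, function(i) exp(bb_loglik(i, n, 0.5, rho)), numeric(1))
    sum(pm[pm <= pm[k + 1] * (1 + 1e-12)])
  }
  for (case in list(c(k = 330, n = 600), c(k = 260, n = 600))) {
    dat <- data.frame(sample = "s1", g = 1L, T = 100L, E = 100,
                      as_ref = case["n"] - case["k"], as_alt = case["k"])
    f <- fit_cht(dat, rho_as = 0.01, component = "as")
    pe <- exact_two_sided(case[["k"]], case[["n"]], 0.01)
    expect_lt(abs(f$p_value - pe) / pe, 0.1)
  }
})

test_that("significance gates and peak collapse follow the definitions", {
  r <- data.frame(region_id = c("r1", "r1", "r1", "r2"),
                  variant_id = c("c:100:A:T", "c:200:A:T", "c:300:A:T",
                                 "c:900:A:T"),
                  p_value = c(1e-6, 1e-6, 1e-3, 0.5),
                  fdr = c(0.005, 0.005, 0.005, 0.6),
                  AI = c(0.2, 0.3, 0.15, 0.4),
                  ref_bias = c(0.7, 0.2, 0.65, 0.9))
  sig <- significant_set(r)
  expect_equal(nrow(sig$variants), 3L)       # all three r1 variants pass
  expect_equal(nrow(sig$peaks), 1L)          # one imbalanced peak
  # top variant: min p, tie broken by larger AI
  expect_equal(sig$peaks$variant_id, "c:200:A:T")
  # AI gate: small AI is not significant even at tiny FDR
  r2 <- transform(r, AI = 0.05)
  expect_equal(nrow(significant_set(r2)$variants), 0L)
})

test_that("direction concordance is 1 for identical and 0 for mirrored results", {
  r <- data.frame(variant_id = sprintf("v%d", 1:20),
                  ref_bias = seq(0.2, 0.8, length.out = 20),
                  fdr = 0.001, AI = 0.3)
  expect_equal(cht_concordance(r, r)$fraction, 1)
  mirror <- transform(r, ref_bias = 1 - ref_bias)
  expect_equal(cht_concordance(r, mirror)$fraction, 0)
  expect_equal(cht_concordance(r, r)$spearman, 1)
})

test_that("relative region counts are percentages of expectation", {
  counts <- data.frame(T = c(50, 200), E = c(100, 100))
  expect_equal(relative_region_counts(counts)$rel_count, c(50, 200))
})
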