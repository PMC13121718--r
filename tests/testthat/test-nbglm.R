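test_that("size factors follow the median-of-ratios closed form", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), 3, 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors_median_of_ratios(m)), c(1, 1))
  m2 <- m; m2[, 2] <- 2 * m2[, 1]
  sf <- size_factors_median_of_ratios(m2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  m3 <- rbind(c(0, 5), c(4, 0))
  dimnames(m3) <- list(c("g1", "g2"), c("a", "b"))
  expect_error(size_factors_median_of_ratios(m3), "positive")
})

test_that("intercept-only NB fit matches the closed-form estimate", {
  set.seed(61)
  # Poisson limit: closed form log(sum y / sum s) holds for any offsets
  y <- rpois(20, 80)
  s <- runif(20, 0.5, 2)
  f <- fit_nb_glm(y, matrix(1, 20, 1), offsets = log(s), alpha = 0)
  expect_equal(unname(f$coefficients), log(sum(y) / sum(s)), tolerance = 1e-8)
  # equal size factors: holds at any dispersion
  y2 <- rnbinom(20, size = 5, mu = 60)
  s2 <- rep(1.7, 20)
  f2 <- fit_nb_glm(y2, matrix(1, 20, 1), offsets = log(s2), alpha = 0.2)
  expect_equal(unname(f2$coefficients), log(sum(y2) / sum(s2)),
               tolerance = 1e-8)
})

test_that("all-zero genes are flagged unconverged rather than fitted", {
  f <- fit_nb_glm(rep(0L, 10), matrix(1, 10, 1))
  expect_false(f$converged)
  expect_equal(f$log_likelihood, -Inf)
})

test_that("NB coefficients and likelihood agree with an independent GLM fit", {
  skip_if_not_installed("MASS")
  set.seed(62)
  x <- rep(c(0, 1), each = 12)
  y <- rnbinom(24, size = 10, mu = 100 * exp(0.7 * x))
  f <- fit_nb_glm(y, cbind(int = 1, x = x), alpha = 0.1)
  g <- stats::glm(y ~ x, family = MASS::negative.binomial(theta = 10))
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(f$log_likelihood,
               sum(dnbinom(y, size = 10, mu = fitted(g), log = TRUE)),
               tolerance = 1e-6)
})

test_that("NB log-likelihood converges to Poisson as dispersion vanishes", {
  set.seed(63)
  y <- rpois(50, 40)
  mu <- rep(40, 50)
  ll_nb <- sum(dnbinom(y, size = 1 / 1e-8, mu = mu, log = TRUE))
  ll_pois <- sum(dpois(y, mu, log = TRUE))
  expect_equal(ll_nb, ll_pois, tolerance = 1e-4)
})

test_that("coefficient recovery is unbiased at moderate sample size", {
  set.seed(64)
  n <- 200
  x <- rep(c(0, 1), each = n / 2)
  beta <- c(log(300), 0.8)
  est <- t(replicate(40, {
    y <- rnbinom(n, size = 20, mu = exp(beta[1] + beta[2] * x))
    fit_nb_glm(y, cbind(1, x), alpha = 0.05)$coefficients
  }))
  expect_lt(max(abs(colMeans(est) - beta)), 0.05)
})

test_that("dispersion estimates recover truth and hit the floor for Poisson data", {
  set.seed(65)
  X <- matrix(1, 20, 1)
  a_nb <- replicate(300, {
    y <- rnbinom(20, size = 10, mu = 500)
    ntve:::estimate_dispersion_one(y, X, rep(0, 20))
  })
  expect_gt(median(a_nb), 0.07)
  expect_lt(median(a_nb), 0.13)
  a_pois <- replicate(200, {
    y <- rpois(20, 500)
    ntve:::estimate_dispersion_one(y, X, rep(0, 20))
  })
  expect_gte(mean(a_pois < 0.01), 0.9)
  # constant counts: no overdispersion signal
  expect_lt(ntve:::estimate_dispersion_one(rep(7L, 12), matrix(1, 12, 1),
                                           rep(0, 12)), 1e-4)
})

test_that("the LRT statistic is the chi-squared quantile map", {
  f <- list(log_likelihood = -100)
  r <- list(log_likelihood = -100)
  out <- lrt(f, r, 1)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  out2 <- lrt(list(log_likelihood = -100 + 3.841 / 2),
              list(log_likelihood = -100), 1)
  expect_equal(out2$p_value, 0.05, tolerance = 1e-3)
})

test_that("natural spline basis satisfies boundary and reproduction properties", {
  times <- seq(0, 6, by = 0.25)
  K <- 4
  B <- natural_cubic_spline_basis(times, K = K)
  expect_equal(dim(B), c(length(times), K))
  # natural condition: linear (zero second difference) beyond the boundary
  # knots, and second derivative vanishing at the boundary itself
  fb <- function(t) {
    splines::ns(t, knots = attr(B, "knots"),
                Boundary.knots = attr(B, "Boundary.knots"))
  }
  for (k in seq_len(K)) {
    out_lo <- fb(c(-2, -1, 0))[, k]
    out_hi <- fb(c(6, 7, 8))[, k]
    expect_lt(abs(diff(diff(out_lo))), 1e-8)
    expect_lt(abs(diff(diff(out_hi))), 1e-8)
  }
  # intercept + basis reproduces any function built from the same basis
  coefs <- c(2, -1, 0.5, 1.5)
  yfun <- 3 + drop(B %*% coefs)
  fit <- lm.fit(cbind(1, B), yfun)
  expect_lt(max(abs(fit$residuals)), 1e-10)
  # K = 1: single monotone basis over the range
  B1 <- natural_cubic_spline_basis(times, K = 1)
  expect_true(all(diff(B1[, 1]) >= -1e-12))
})

test_that("one-vs-rest test finds a strong lineage effect and permutation destroys it", {
  set.seed(66)
  nrep <- c(3, 6)
  lab <- rep(c("rest", "target"), nrep)
  # 40 null genes + 10 with a strong lineage effect (natural-log beta1 = 2)
  mu <- matrix(500, 50, 9)
  mu[41:50, lab == "target"] <- 500 * exp(2)
  vals <- matrix(rnbinom(length(mu), size = 20, mu = mu), 50,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:9)))
  res <- one_vs_rest_lrt(vals, lab, target = "target",
                         size_factors = rep(1, 9))
  expect_true(all(res$p_adjusted[41:50] < 0.05))
  expect_gt(min(res$lfc[41:50]), 1)          # log2 of e^2 is ~2.89
  # permuting labels of a significant gene destroys significance on average
  g <- vals[45, ]
  perm_p <- replicate(60, {
    pl <- sample(lab)
    r <- one_vs_rest_lrt(matrix(g, 1, dimnames = list("g", names(g))),
                         pl, target = "target", size_factors = rep(1, 9))
    r$p_value
  })
  expect_gt(median(perm_p), 0.1)
})

test_that("trajectory test ignores constant offsets but finds spline deviations", {
  cfg0 <- timecourse_config(fraction_lineage_specific = 0,
                            fraction_constant_shift = 0.5,
                            constant_shift_effect = 1, seed = 67)
  sim0 <- simulate_timecourse_counts(cfg0, n_genes = 150)
  m <- sim0$counts$sample_meta
  res0 <- lineage_spline_lrt(sim0$counts, m$lineage, m$time_days,
                             target = cfg0$lineages[1], K = 4)
  expect_lt(mean(res0$p_value < 0.05, na.rm = TRUE), 0.09)
  cfg1 <- timecourse_config(fraction_lineage_specific = 0.2,
                            fraction_constant_shift = 0.2,
                            spline_effect_size = 1.5, seed = 68)
  sim1 <- simulate_timecourse_counts(cfg1, n_genes = 150)
  m1 <- sim1$counts$sample_meta
  res1 <- lineage_spline_lrt(sim1$counts, m1$lineage, m1$time_days,
                             target = cfg1$lineages[1], K = 4)
  cls <- sim1$truth$effect_class
  expect_gt(mean(res1$p_adjusted[cls == "delta"] < 0.05, na.rm = TRUE), 0.8)
  # two-axis classification: beta1-only genes light up the offset test only
  ovr <- one_vs_rest_lrt(sim1$counts, m1$lineage, target = cfg1$lineages[1])
  b1 <- cls == "beta1"
  expect_gt(mean(ovr$p_adjusted[b1] < 0.05, na.rm = TRUE), 0.8)
  expect_lt(mean(res1$p_adjusted[b1] < 0.05, na.rm = TRUE), 0.2)
})

test_that("time-course spline test is calibrated on constant genes and detects dynamics", {
  cfg0 <- timecourse_config(lineages = c("cm", "cm2"), time_points = 0:9,
                            fraction_lineage_specific = 0,
                            fraction_constant_shift = 0, gamma_sd = 0,
                            seed = 69)
  sim0 <- simulate_timecourse_counts(cfg0, n_genes = 200)
  m <- sim0$counts$sample_meta
  keep <- m$lineage == "cm"
  res0 <- timecourse_spline_lrt(sim0$counts$values[, keep],
                                m$time_days[keep], m$replicate[keep], K = 4)
  expect_lt(mean(res0$p_value < 0.05, na.rm = TRUE), 0.09)
  expect_true(all(res0$df == 4))
  # sinusoidal genes: one cycle, amplitude 1 log unit
  set.seed(70)
  tt <- rep(0:9, each = 3)
  repl <- rep(1:3, 10)
  mu <- 500 * exp(sin(2 * pi * tt / 9))
  vals <- t(replicate(60, rnbinom(30, size = 20, mu = mu)))
  dimnames(vals) <- list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:30))
  res1 <- timecourse_spline_lrt(vals, tt, repl, K = 4,
                                size_factors = rep(1, 30))
  expect_gt(mean(res1$p_adjusted < 0.05, na.rm = TRUE), 0.9)
})

test_that("Wald interval tests follow the stated tail arithmetic", {
  fit <- structure(list(coefficients = c(int = 1, eff = 1 * log(2)),
                        standard_errors = c(int = 0.1, eff = 0.1 * log(2)),
                        converged = TRUE), class = "nb_fit")
  # |beta| equal to theta: greaterAbs z = 0, p = 1
  w <- wald_test(fit, "eff", alternative = "greaterAbs", theta = 1)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)
  # lessAbs at beta = 0: both one-sided tails equal Phi(-theta/se)
  fit0 <- structure(list(coefficients = c(int = 1, eff = 0),
                         standard_errors = c(int = 0.1, eff = 0.1 * log(2)),
                         converged = TRUE), class = "nb_fit")
  w2 <- wald_test(fit0, "eff", alternative = "lessAbs", theta = 1)
  expect_equal(w2$p_value, pnorm(-10), tolerance = 1e-26)
  w3 <- wald_test(fit0, "eff", alternative = "standard")
  expect_equal(w3$p_value, 1)
})

test_that("BH adjustment equals its brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  set.seed(71)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("shrinkage pulls noisy estimates toward zero, never inflates", {
  set.seed(72)
  lfc <- rnorm(200, 0, 1)
  se <- runif(200, 0.01, 2)
  shr <- shrink_lfc(lfc, se)
  expect_true(all(abs(shr) <= abs(lfc) + 1e-12))
  # tiny SE: shrunken ~ raw; huge SE: shrunken ~ 0
  precise <- shrink_lfc(c(lfc, 2), c(se, 1e-6))
  expect_equal(precise[201], 2, tolerance = 1e-3)
  vague <- shrink_lfc(c(lfc, 2), c(se, 100))
  expect_lt(abs(vague[201]), 0.01)
})

test_that("Wald intervals achieve nominal coverage on simulated effects", {
  sim <- simulate_two_condition(300, c(15, 15), true_lfc = rep(1 / log(2), 300),
                                dispersion = 0.05, base_mean = 300, seed = 73)
  de <- nb_wald_de(sim$counts, sim$counts$sample_meta$condition, ref = "ref",
                   size_factors = rep(1, 30))
  est <- de$lfc * log(2); se <- de$se * log(2)
  cover <- mean(abs(est - 1) <= 1.96 * se, na.rm = TRUE)
  expect_gt(cover, 0.9)
  expect_lt(cover, 0.99)
  expect_lt(abs(mean(est, na.rm = TRUE) - 1), 0.05)
})
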