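test_that("null OLS fit matches the normal equations", {
  set.seed(1)
  X <- cbind(1, matrix(rnorm(20), 10, 2))
  y <- rnorm(10)
  fit <- fit_null_ols(y, X)
  expect_equal(fit$coef, drop(solve(crossprod(X), crossprod(X, y))),
               ignore_attr = TRUE)
  expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-10)
  # perfect fit
  y2 <- X %*% c(1, 2, -1)
  f2 <- fit_null_ols(drop(y2), X)
  expect_equal(f2$sigma2, 0, tolerance = 1e-20)
  # intercept only: residuals are centered y
  f3 <- fit_null_ols(y, matrix(1, 10, 1))
  expect_equal(f3$residuals, y - mean(y))
  expect_error(fit_null_ols(y, cbind(X, X[, 2])), "rank-deficient")
})

test_that("chi-square mixture tail matches survival functions", {
  expect_equal(pvalue_chi2_mixture(qchisq(0.95, 1), 1), 0.05,
               tolerance = 1e-6)
  expect_equal(pvalue_chi2_mixture(qchisq(0.95, 2), c(1, 1)), 0.05,
               tolerance = 1e-6)
  x <- 4.2
  expect_equal(pvalue_chi2_mixture(2 * x, 2),
               pvalue_chi2_mixture(x, 1), tolerance = 1e-6)
  expect_error(pvalue_chi2_mixture(1, c(0, -1)), "invalid eigenvalues")
  # saddlepoint fallback tracks the exact tail into deep territory
  for (q in c(60, 120)) {
    expect_equal(log(saddlepoint_pvalue(q, 1)),
                 pchisq(q, 1, lower.tail = FALSE, log.p = TRUE),
                 tolerance = 0.05)
  }
  lam <- c(2.5, 1.2, 0.4)
  expect_equal(saddlepoint_pvalue(15, lam),
               pvalue_chi2_mixture(15, lam), tolerance = 0.02)
})

test_that("kernel score test reduces to the single-variant test", {
  set.seed(2)
  n <- 150
  X <- h_design(n)
  g <- rbinom(n, 2, 0.1)
  y <- rnorm(n)
  null <- fit_null_ols(y, X)
  sv <- single_variant_test(null, g)
  sc <- score_test(null, phi_linear(matrix(g, ncol = 1), 1))
  expect_equal(sc$p, sv$p, tolerance = 1e-7)
  # scale invariance: phi * 2 gives identical p
  phi <- phi_linear(h_geno(n, 4, 0.2, 3), rep(1, 4))
  phi2 <- kernel_factor(phi$matrix * 2, phi$labels, phi$design)
  expect_equal(score_test(null, phi)$p, score_test(null, phi2)$p,
               tolerance = 1e-8)
})

test_that("REML estimates respect the boundary and recover signal", {
  set.seed(4)
  n <- 300
  X <- h_design(n)
  G <- h_geno(n, 5, 0.3, 5)
  phi <- phi_linear(G, rep(1, 5))
  # boundary mass under the null
  zero_frac <- mean(replicate(60, {
    fit <- fit_lmm_reml(rnorm(n), X, phi)
    fit$sigma2_g == 0
  }))
  expect_gte(zero_frac, 0.35)
  # alternative >= null restricted log-likelihood, always
  for (i in 1:5) {
    fit <- fit_lmm_reml(rnorm(n), X, phi)
    expect_gte(fit$loglik, fit$loglik_null - 1e-10)
  }
  # recovery when signal dominates
  K <- tcrossprod(phi$matrix)
  sig_g <- 4
  ok <- replicate(60, {
    y <- drop(X %*% c(1, 0.5)) +
      drop(t(chol(sig_g * K + diag(1, n))) %*% rnorm(n))
    fit <- fit_lmm_reml(y, X, phi)
    fit$sigma2_g / sig_g > 0.33 && fit$sigma2_g / sig_g < 3
  })
  expect_gte(mean(ok), 0.85)
})

test_that("RLRT statistic is a boundary-respecting likelihood ratio", {
  set.seed(6)
  n <- 120
  X <- h_design(n)
  phi <- phi_linear(h_geno(n, 4, 0.25, 7), rep(1, 4))
  y <- rnorm(n)
  s <- rlrt_stat(y, X, phi)
  expect_gte(s, 0)
  # location invariance given an intercept
  expect_equal(rlrt_stat(y + 100, X, phi), s, tolerance = 1e-6)
  # zero exactly when the variance estimate hits the boundary
  fit <- fit_lmm_reml(y, X, phi)
  if (fit$sigma2_g == 0) expect_equal(s, 0)
})

test_that("the exact RLRT null sampler is deterministic in the seed", {
  n <- 100
  X <- h_design(n)
  phi <- phi_linear(h_geno(n, 5, 0.2, 8), rep(1, 5))
  s1 <- sample_rlrt_null(phi, X, n_samples = 200, seed = 42)
  s2 <- sample_rlrt_null(phi, X, n_samples = 200, seed = 42)
  expect_identical(s1, s2)
  s3 <- sample_rlrt_null(phi, X, n_samples = 200, seed = 43)
  expect_false(identical(s1, s3))
  expect_true(all(s1 >= 0))
  # substantial point mass at zero for small kernels
  expect_gte(mean(s1 == 0), 0.3)
})

test_that("null mixture fitting handles degenerate and duplicated input", {
  mix0 <- fit_null_mixture(rep(0, 2000))
  expect_equal(mix0$pi, 1)
  expect_true(mix0$degenerate)
  expect_equal(mixture_pvalue(c(0, 1, 5), mix0), c(1, 1, 1))
  set.seed(9)
  stats <- ifelse(runif(5000) < 0.5, 0, rchisq(5000, 1))
  m1 <- fit_null_mixture(stats)
  m2 <- fit_null_mixture(rep(stats, 2))
  expect_equal(m1$pi, m2$pi)
  expect_equal(m1$a, m2$a, tolerance = 0.02)
  expect_equal(m1$d, m2$d, tolerance = 0.02)
  expect_warning(fit_null_mixture(c(0, 1, 2)), "fewer than 1000")
})

test_that("mixture p-values follow the fitted survival function", {
  mix <- structure(list(pi = 0.5, a = 1, d = 1, degenerate = FALSE),
                   class = "null_mixture")
  expect_equal(mixture_pvalue(0, mix), 1)
  expect_equal(mixture_pvalue(qchisq(0.95, 1), mix), 0.025,
               tolerance = 1e-6)
  mix2 <- structure(list(pi = 0, a = 1, d = 2, degenerate = FALSE),
                    class = "null_mixture")
  expect_equal(mixture_pvalue(qchisq(0.95, 2), mix2), 0.05,
               tolerance = 1e-6)
  # monotone decreasing in the statistic
  p <- mixture_pvalue(seq(0.1, 10, by = 0.1), mix)
  expect_true(all(diff(p) < 0))
})

test_that("sLRT triggers the RLRT only below the threshold", {
  set.seed(10)
  n <- 200
  X <- h_design(n)
  G <- h_geno(n, 5, 0.2, 11)
  phi <- phi_linear(G, rep(1, 5))
  y <- rnorm(n)
  fit <- slrt(y, X, phi, t = 1e-6, seed = 1)   # essentially never triggers
  expect_false(fit$lrt_triggered)
  expect_equal(fit$final_p, fit$score_p)
  expect_null(fit$null_stats)
  fit2 <- slrt(y, X, phi, t = 0.999999, n_null = 50, seed = 1)
  expect_true(fit2$lrt_triggered)
  expect_equal(length(fit2$null_stats), 50L)
  expect_true(is.na(fit2$final_p))   # awaits pooled finalization
  mix <- suppressWarnings(fit_null_mixture(fit2$null_stats))
  fit3 <- slrt(y, X, phi, t = 0.999999, n_null = 50, seed = 1,
               mixture = mix)
  expect_false(is.na(fit3$final_p))
  expect_output(print(fit2), "RLRT triggered")
})

test_that("Cauchy combination behaves like the CCT", {
  expect_equal(cauchy_combine(c(0.5, 0.5)), 0.5)
  for (p in c(0.9, 0.3, 0.01, 1e-8)) {
    expect_equal(cauchy_combine(rep(p, 4)), p, tolerance = 1e-10)
  }
  expect_equal(cauchy_combine(c(0.02, 0.5)), 0.0398433216,
               tolerance = 1e-6)
  # stable far tail: combining tiny p-values stays near p/k
  expect_equal(cauchy_combine(c(1e-40, 0.5)), 2e-40, tolerance = 0.01)
  expect_warning(cauchy_combine(c(0, 0.5)), "clipped")
  # weights shift the combination toward the up-weighted p
  expect_lt(cauchy_combine(c(0.01, 0.5), weights = c(0.9, 0.1)),
            cauchy_combine(c(0.01, 0.5), weights = c(0.1, 0.9)))
})

test_that("single-variant effect estimates match covariate-adjusted OLS", {
  set.seed(12)
  n <- 20
  X <- cbind(1, rnorm(n))
  g <- rbinom(n, 2, 0.3)
  y <- 0.4 * g + rnorm(n)
  null <- fit_null_ols(y, X)
  res <- single_variant_test(null, g)
  ref <- lm(y ~ X[, 2] + g)
  expect_equal(res$beta, unname(coef(ref)["g"]), tolerance = 1e-8)
  expect_error(single_variant_test(null, rep(0, n)), "monomorphic")
})

test_that("genomic inflation factor is calibrated and monotone", {
  expect_equal(lambda_gc(rep(0.5, 10)), 1.0)
  set.seed(13)
  p <- runif(5e4)
  expect_equal(lambda_gc(p), 1.0, tolerance = 0.03)
  expect_gt(lambda_gc(p * 0.5), lambda_gc(p))
})

test_that("per-gene seeds are deterministic and label-separated", {
  s1 <- gene_seed(7, "GENE1", "missense.kernel")
  expect_identical(s1, gene_seed(7, "GENE1", "missense.kernel"))
  expect_false(s1 == gene_seed(7, "GENE1", "missense.gbvc"))
  expect_false(s1 == gene_seed(8, "GENE1", "missense.kernel"))
  seeds <- vapply(sprintf("G%03d", 1:500),
                  function(g) gene_seed(1, g, "x"), 1L)
  expect_true(all(seeds >= 1 & seeds <= 2^31 - 1))
})
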