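#' Fit the null fixed-effects model
#'
#' Ordinary least squares fit of the covariate-only model, the null of the
#' variance-component test (sigma^2_g = 0). Stores the QR factorization so
#' vectors can be projected onto the orthogonal complement of the
#' covariate space.
#'
#' @param y numeric response (already transformed, no missing values).
#' @param X n x q covariate design matrix including an intercept column.
#' @return object of class `null_model` with elements `coef`, `residuals`,
#'   `sigma2` (residual variance with divisor n - q), `n`, `q`, `qr`.
#' @export
fit_null_ols <- function(y, X) {
  stopifnot(is.numeric(y), is.matrix(X), nrow(X) == length(y),
            nrow(X) > ncol(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    nm <- colnames(X)
    nm <- if (is.null(nm)) paste0("col", drop) else nm[drop]
    stop("rank-deficient design: collinear columns ",
         paste(nm, collapse = ", "))
  }
  coef <- qr.coef(qrX, y)
  r <- qr.resid(qrX, y)
  n <- length(y); q <- ncol(X)
  structure(list(coef = coef, residuals = r,
                 sigma2 = sum(r * r) / (n - q),
                 n = n, q = q, qr = qrX, X = X),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("null model: n = %d, q = %d covariates, sigma2_e = %.4g\n",
              x$n, x$q, x$sigma2))
  invisible(x)
}

# project a vector/matrix onto the orthogonal complement of span(X)
.project_resid <- function(null, M) qr.resid(null$qr, M)

#' Tail probability of a mixture of chi-squares
#'
#' P(sum_s lambda_s chi^2_1 > q) by Davies' method (accuracy 1e-7, up to
#' 1e6 integration terms); when Davies returns an invalid or non-positive
#' value, a Kuonen saddlepoint approximation is used instead.
#'
#' @param q observed statistic.
#' @param lambdas mixture weights (eigenvalues); at least one must be
#'   positive.
#' @param floor lower bound applied to the returned p (default 1e-300).
#' @return p-value in (0, 1\].
#' @export
pvalue_chi2_mixture <- function(q, lambdas, floor = 1e-300) {
  lambdas <- lambdas[lambdas > 0]
  if (!length(lambdas)) stop("invalid eigenvalues: none positive")
  if (q <= 0) return(1)
  if (length(lambdas) == 1L) {   # single component: exact chi-square tail
    p <- stats::pchisq(q / lambdas, df = 1, lower.tail = FALSE)
    return(max(min(p, 1), floor))
  }
  davies <- function(tol) tryCatch(
    suppressWarnings(mgcv::psum.chisq(q, lb = lambdas, tol = tol,
                                      nlim = 1e6)),
    error = function(e) NA_real_)
  # adaptive precision: a fast pass (abs error <= 2e-5) suffices for
  # clearly non-significant p; anything smaller is recomputed at the full
  # 1e-7 accuracy
  p <- davies(2e-5)
  if (!is.finite(p) || p < 0.1) p <- davies(1e-7)
  if (!is.finite(p) || p <= 0 || p > 1) p <- saddlepoint_pvalue(q, lambdas)
  max(min(p, 1), floor)
}

#' Saddlepoint tail approximation for chi-square mixtures
#'
#' Lugannani-Rice / Kuonen saddlepoint approximation to
#' P(sum lambda_s chi^2_1 > q). Used as fallback when numerical inversion
#' of the characteristic function fails.
#'
#' @inheritParams pvalue_chi2_mixture
#' @return approximate p-value.
#' @export
saddlepoint_pvalue <- function(q, lambdas) {
  lambdas <- lambdas[lambdas > 0]
  mu <- sum(lambdas)
  if (abs(q - mu) < 1e-10 * mu) return(0.5)
  K  <- function(t) -0.5 * sum(log1p(-2 * t * lambdas))
  K1 <- function(t) sum(lambdas / (1 - 2 * t * lambdas))
  K2 <- function(t) 2 * sum(lambdas^2 / (1 - 2 * t * lambdas)^2)
  tmax <- 1 / (2 * max(lambdas)) - 1e-12
  tmin <- if (q > mu) 0 else -1e3 / min(lambdas)
  root <- tryCatch(
    stats::uniroot(function(t) K1(t) - q, lower = tmin, upper = tmax,
                   tol = 1e-12)$root,
    error = function(e) NA_real_)
  if (!is.finite(root)) return(if (q > mu) 1e-300 else 1)
  w <- sign(root) * sqrt(max(2 * (root * q - K(root)), 0))
  v <- root * sqrt(K2(root))
  if (abs(w) < 1e-8) return(0.5)
  p <- stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
  max(min(p, 1), 1e-300)
}

# eigenvalues (and projections) of t(phi) P phi, shared by score test,
# REML fit and the RLRT null sampler; truncation at 1e-10 * max
.kernel_spectrum <- function(null, phi_mat) {
  Pphi <- .project_resid(null, phi_mat)
  A <- crossprod(Pphi)
  eg <- eigen(A, symmetric = TRUE)
  keep <- eg$values > 1e-10 * max(eg$values, 0)
  if (!any(keep)) return(NULL)
  list(mu = eg$values[keep], V = eg$vectors[, keep, drop = FALSE])
}

#' Variance-component score test
#'
#' Score test of H0: sigma^2_g = 0 against sigma^2_g > 0 in the mixed
#' model y ~ N(X alpha, sigma^2_e I + sigma^2_g phi phi^T). The statistic
#' is Q = r^T phi phi^T r / sigma2_e with r the null-model residuals; its
#' null law is the mixture sum_s lambda_s chi^2_1 over the eigenvalues of
#' phi^T P phi, evaluated with [pvalue_chi2_mixture()].
#'
#' @param null a `null_model` from [fit_null_ols()].
#' @param phi a `kernel_factor` (centered).
#' @return list with `stat` and `p`.
#' @export
score_test <- function(null, phi) {
  phi_mat <- if (inherits(phi, "kernel_factor")) phi$matrix else as.matrix(phi)
  if (ncol(phi_mat) == 0L) stop("degenerate kernel: no columns")
  sp <- .kernel_spectrum(null, phi_mat)
  if (is.null(sp)) stop("degenerate kernel: numerically zero after centering")
  u <- crossprod(phi_mat, null$residuals)
  stat <- sum(u * u) / null$sigma2
  list(stat = stat, p = pvalue_chi2_mixture(stat, sp$mu))
}

#' REML fit of the single-kernel linear mixed model
#'
#' Maximizes the restricted likelihood of
#' y ~ N(X alpha, sigma^2_e I + sigma^2_g phi phi^T) over
#' (sigma^2_e, sigma^2_g >= 0). Using the spectral decomposition of
#' phi^T P phi the profile restricted log-likelihood reduces to a 1-D
#' search over the variance ratio h = sigma^2_g / sigma^2_e, scanned on a
#' log grid and refined with Brent's method.
#'
#' @param y response vector.
#' @param X covariate matrix with intercept.
#' @param phi a `kernel_factor`.
#' @return object of class `lmm_fit`: `sigma2_e`, `sigma2_g`, `h`,
#'   `loglik` (restricted), `loglik_null`, `converged`.
#' @export
fit_lmm_reml <- function(y, X, phi) {
  null <- fit_null_ols(y, X)
  phi_mat <- if (inherits(phi, "kernel_factor")) phi$matrix else as.matrix(phi)
  sp <- .kernel_spectrum(null, phi_mat)
  if (is.null(sp)) stop("degenerate kernel: numerically zero after centering")
  mu <- sp$mu
  r <- null$residuals
  # u_s = projections of the whitened residual on the kernel eigendirections
  u2 <- as.numeric(crossprod(sp$V, crossprod(phi_mat, r)))^2 / mu
  rss <- sum(r * r)
  nq <- null$n - null$q
  # -2 * restricted profile log-likelihood (up to constants)
  f <- function(h) {
    s2 <- (sum(u2 / (1 + h * mu)) + rss - sum(u2)) / nq
    nq * log(s2) + sum(log1p(h * mu))
  }
  hs <- 10^seq(-8, 8, length.out = 81) / max(mu)
  vals <- c(f(0), vapply(hs, f, 0))
  i <- which.min(vals)
  if (i == 1L) {
    opt <- stats::optimize(f, c(0, hs[1]))
    h_hat <- if (opt$objective < vals[1]) opt$minimum else 0
  } else {
    lo <- if (i == 2L) 0 else hs[i - 2L]
    hi <- if (i == length(vals)) hs[length(hs)] else hs[i]
    h_hat <- stats::optimize(f, c(lo, hi))$minimum
    if (f(0) <= f(h_hat)) h_hat <- 0
  }
  s2e <- (sum(u2 / (1 + h_hat * mu)) + rss - sum(u2)) / nq
  const <- -0.5 * nq * (1 + log(2 * pi))
  ll_alt <- const - 0.5 * (nq * log(s2e) + sum(log1p(h_hat * mu)))
  ll_null <- const - 0.5 * nq * log(rss / nq)
  structure(list(sigma2_e = s2e, sigma2_g = h_hat * s2e, h = h_hat,
                 loglik = max(ll_alt, ll_null), loglik_null = ll_null,
                 converged = TRUE, mu = mu),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "REML fit: sigma2_e = %.4g, sigma2_g = %.4g, restricted logLik = %.4f\n",
    x$sigma2_e, x$sigma2_g, x$loglik))
  invisible(x)
}

#' Restricted likelihood-ratio statistic
#'
#' Twice the difference between the restricted log-likelihood of the
#' alternative model (sigma^2_g free) and the null (sigma^2_g = 0);
#' exactly zero when the REML estimate sits on the boundary.
#'
#' @inheritParams fit_lmm_reml
#' @return non-negative statistic.
#' @export
rlrt_stat <- function(y, X, phi) {
  fit <- fit_lmm_reml(y, X, phi)
  max(0, 2 * (fit$loglik - fit$loglik_null))
}

#' Sample the exact finite-sample RLRT null distribution
#'
#' Draws from the exact null law of the restricted likelihood-ratio
#' statistic for testing sigma^2_g = 0 (Crainiceanu-Ruppert construction):
#' with mu_s the nonzero eigenvalues of phi^T P phi and independent
#' chi-square draws w_s, each sample is the supremum over the variance
#' ratio lambda of
#' \deqn{(n-q) \log(1 + N(\lambda)/D(\lambda)) - \sum_s \log(1+\lambda\mu_s)}
#' where N and D are the weighted chi-square sums of the construction. The
#' supremum is taken over a log-spaced grid including 0 and sharpened with
#' a vectorized golden-section refinement around the per-draw argmax.
#'
#' @param phi a `kernel_factor`.
#' @param X covariate matrix.
#' @param n_samples number of null statistics (default 100 per gene).
#' @param seed RNG seed (required for reproducibility).
#' @param grid_points number of positive grid points (default 128).
#' @return numeric vector of `n_samples` non-negative statistics.
#' @export
sample_rlrt_null <- function(phi, X, n_samples = 100, seed,
                             grid_points = 128) {
  stopifnot(n_samples >= 1)
  if (missing(seed)) stop("an explicit seed is required")
  phi_mat <- if (inherits(phi, "kernel_factor")) phi$matrix else as.matrix(phi)
  n <- nrow(phi_mat); q <- ncol(X)
  sp <- .kernel_spectrum(list(qr = qr(X)), phi_mat)
  if (is.null(sp)) stop("degenerate kernel: no nonzero eigenvalues")
  mu <- sp$mu
  K <- length(mu); nq <- n - q
  set.seed(as.integer(seed %% .Machine$integer.max))
  W <- matrix(stats::rchisq(n_samples * K, df = 1), n_samples, K)
  extra <- if (nq - K > 0) stats::rchisq(n_samples, df = nq - K) else
    numeric(n_samples)

  crit_scalar <- function(lam) {
    # shared lambda across draws: two matrix-vector products
    a <- 1 + lam * mu
    N <- drop(W %*% (lam * mu / a))
    D <- drop(W %*% (1 / a)) + extra
    nq * log1p(N / D) - sum(log(a))
  }

  grid <- c(0, 10^seq(-5, 5, length.out = grid_points) / max(mu))
  vals <- matrix(0, n_samples, length(grid))
  for (k in seq_along(grid)[-1]) vals[, k] <- crit_scalar(grid[k])
  best <- max.col(vals, ties.method = "first")
  stat <- vals[cbind(seq_len(n_samples), best)]

  # vectorized golden-section refinement on log-lambda inside the
  # per-draw bracket around the grid argmax (draws at argmax 0 stay 0)
  pos <- best > 1L
  if (any(pos)) {
    lg <- log(grid[-1])           # log of the positive grid points
    L <- length(lg)
    step <- lg[2] - lg[1]
    j <- best[pos] - 1L           # index into lg of the per-draw argmax
    lo <- ifelse(j == 1L, lg[1] - step, lg[pmax(j - 1L, 1L)])
    hi <- ifelse(j == L, lg[L] + step, lg[pmin(j + 1L, L)])
    gr <- (sqrt(5) - 1) / 2
    idx <- which(pos)
    Wp <- W[idx, , drop = FALSE]; ep <- extra[idx]
    sub_crit <- function(loglam) {
      lam <- exp(loglam)
      A <- 1 + outer(lam, mu)
      N <- rowSums(Wp * outer(lam, mu) / A)
      D <- rowSums(Wp / A) + ep
      nq * log1p(N / D) - rowSums(log(A))
    }
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- sub_crit(x1); f2 <- sub_crit(x2)
    for (it in seq_len(24)) {
      move1 <- f1 < f2
      lo[move1] <- x1[move1]; x1[move1] <- x2[move1]; f1[move1] <- f2[move1]
      x2[move1] <- lo[move1] + gr * (hi[move1] - lo[move1])
      hi[!move1] <- x2[!move1]; x2[!move1] <- x1[!move1]
      f2[!move1] <- f1[!move1]
      x1[!move1] <- hi[!move1] - gr * (hi[!move1] - lo[!move1])
      fnew <- sub_crit(ifelse(move1, x2, x1))
      f2[move1] <- fnew[move1]; f1[!move1] <- fnew[!move1]
    }
    stat[idx] <- pmax(stat[idx], pmax(f1, f2))
  }
  pmax(stat, 0)
}

#' Fit the pooled parametric RLRT null mixture
#'
#' Fits the mixture pi * chi^2_0 + (1 - pi) * a * chi^2_d to pooled
#' simulated RLRT null statistics. pi is the observed fraction of (near)
#' zero statistics; (a, d) are fitted by least squares between the log
#' empirical survival probabilities and the log model survival function
#' over the top-decile order statistics (log-quantile regression on the
#' 10\% largest statistics).
#'
#' @param statistics pooled null statistics (>= 1000 recommended; a
#'   warning is issued below that).
#' @param top_fraction fraction of largest statistics used for the (a, d)
#'   fit (default 0.1).
#' @param eps_zero statistics at or below this count as zero (default
#'   1e-8).
#' @return object of class `null_mixture`: `pi`, `a`, `d`, `n_statistics`,
#'   `degenerate` (TRUE when all statistics are zero).
#' @export
fit_null_mixture <- function(statistics, top_fraction = 0.1,
                             eps_zero = 1e-8) {
  stopifnot(length(statistics) >= 1, all(statistics >= 0))
  n <- length(statistics)
  if (n < 1000) warning("fewer than 1000 pooled statistics; ",
                        "mixture fit may be unstable")
  pi_hat <- mean(statistics <= eps_zero)
  if (pi_hat >= 1) {
    return(structure(list(pi = 1, a = 1, d = 1, n_statistics = n,
                          degenerate = TRUE), class = "null_mixture"))
  }
  s <- sort(statistics, decreasing = TRUE)
  k <- max(ceiling(top_fraction * n), 2L)
  top <- s[seq_len(k)]
  emp_surv <- (seq_len(k) - 0.5) / n
  pos <- statistics[statistics > eps_zero]
  d0 <- max(2 * mean(pos)^2 / max(stats::var(pos), 1e-12), 0.05)
  a0 <- max(mean(pos) / d0, 1e-3)
  obj <- function(par) {
    a <- exp(par[1]); d <- exp(par[2])
    mod <- log1p(-pi_hat) +
      stats::pchisq(top / a, df = d, lower.tail = FALSE, log.p = TRUE)
    sum((log(emp_surv) - mod)^2)
  }
  fit <- stats::optim(c(log(a0), log(d0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  structure(list(pi = pi_hat, a = exp(fit$par[1]), d = exp(fit$par[2]),
                 n_statistics = n, degenerate = FALSE),
            class = "null_mixture")
}

#' @export
print.null_mixture <- function(x, ...) {
  cat(sprintf(
    "null mixture: pi = %.3f, a = %.3f, d = %.3f (fit on %d statistics)\n",
    x$pi, x$a, x$d, x$n_statistics))
  invisible(x)
}

#' P-value from a fitted null mixture
#'
#' Survival probability of a statistic under the fitted mixture
#' pi * chi^2_0 + (1 - pi) * a * chi^2_d: a zero statistic returns 1,
#' otherwise (1 - pi) * S_chi2_d(stat / a), floored at `floor`.
#'
#' @param stat non-negative statistic (vectorized).
#' @param mixture a `null_mixture`.
#' @param eps_zero zero threshold matching the fit.
#' @param floor minimum p (default 1e-300).
#' @return p-value(s) in (0, 1\].
#' @export
mixture_pvalue <- function(stat, mixture, eps_zero = 1e-8, floor = 1e-300) {
  stopifnot(inherits(mixture, "null_mixture"), all(stat >= 0))
  if (isTRUE(mixture$degenerate)) return(rep(1, length(stat)))
  p <- (1 - mixture$pi) *
    stats::pchisq(stat / mixture$a, df = mixture$d, lower.tail = FALSE)
  p[stat <= eps_zero] <- 1
  pmin(pmax(p, floor), 1)
}

#' Two-stage score/restricted-likelihood-ratio test (sLRT)
#'
#' Runs the variance-component score test for one gene; if its p-value is
#' at or above the trigger threshold `t`, the score p is final. Below the
#' threshold, the restricted likelihood-ratio statistic is computed and
#' `n_null` exact null statistics are sampled; the final p-value is filled
#' in later from the pooled null mixture (see [pool_and_finalize()]), or
#' immediately when `mixture` is supplied.
#'
#' @param y response vector.
#' @param X covariate matrix with intercept.
#' @param phi a `kernel_factor`.
#' @param t trigger threshold on the score p (default 0.1).
#' @param n_null null statistics sampled per triggered gene (default 100).
#' @param seed RNG seed for the null sampler.
#' @param mixture optional `null_mixture` for immediate finalization.
#' @return object of class `slrt_fit`: `score_stat`, `score_p`,
#'   `lrt_triggered`, `rlrt_stat`, `null_stats`, `final_p` (NA while
#'   awaiting pooled finalization).
#' @export
slrt <- function(y, X, phi, t = 0.1, n_null = 100, seed = 1,
                 mixture = NULL) {
  stopifnot(t > 0, t < 1)
  null <- fit_null_ols(y, X)
  sc <- score_test(null, phi)
  out <- list(score_stat = sc$stat, score_p = sc$p,
              lrt_triggered = sc$p < t, rlrt_stat = NA_real_,
              null_stats = NULL, final_p = sc$p)
  if (out$lrt_triggered) {
    out$rlrt_stat <- rlrt_stat(y, X, phi)
    out$null_stats <- sample_rlrt_null(phi, X, n_samples = n_null,
                                       seed = seed)
    out$final_p <- if (!is.null(mixture)) {
      mixture_pvalue(out$rlrt_stat, mixture)
    } else NA_real_
  }
  structure(out, class = "slrt_fit")
}

#' @export
print.slrt_fit <- function(x, ...) {
  cat(sprintf("sLRT: score stat = %.4g, score p = %.3g\n",
              x$score_stat, x$score_p))
  if (x$lrt_triggered) {
    cat(sprintf("  RLRT triggered: stat = %.4g, %d null statistics, %s\n",
                x$rlrt_stat, length(x$null_stats),
                if (is.na(x$final_p)) "final p pending pooled null" else
                  sprintf("final p = %.3g", x$final_p)))
  } else {
    cat(sprintf("  not triggered; final p = score p = %.3g\n", x$final_p))
  }
  invisible(x)
}

#' Cauchy combination of dependent p-values
#'
#' Combines p-values with the Cauchy combination test:
#' T = sum_i w_i tan((0.5 - p_i) pi), p = 0.5 - arctan(T)/pi. Valid under
#' arbitrary dependence; identical inputs return the same value. P-values
#' below 1e-15 enter through the numerically stable tail form
#' 1/(pi * p_i), and very large T returns 1/(pi * T).
#'
#' @param p_values vector of p-values in (0, 1); values exactly 0 or 1 are
#'   clipped into the open interval with a warning.
#' @param weights optional non-negative weights (default equal); they are
#'   normalized to sum to 1.
#' @return combined p-value.
#' @export
cauchy_combine <- function(p_values, weights = NULL) {
  k <- length(p_values)
  stopifnot(k >= 1)
  if (any(p_values <= 0 | p_values >= 1)) {
    warning("p-values at 0 or 1 clipped to the open interval")
    p_values <- pmin(pmax(p_values, 1e-300), 1 - 1e-16)
  }
  if (is.null(weights)) weights <- rep(1 / k, k)
  stopifnot(length(weights) == k, all(weights >= 0))
  weights <- weights / sum(weights)
  # tail forms below 1e-6 / above its reciprocal keep tiny p-values exact
  stat <- ifelse(p_values < 1e-6, 1 / (p_values * pi),
                 tan((0.5 - p_values) * pi))
  T <- sum(weights * stat)
  if (T > 1 / (1e-6 * pi)) return(1 / (pi * T))
  max(min(0.5 - atan(T) / pi, 1), 1e-300)
}

#' Single-variant score test
#'
#' Score test of one genotype column against the null model, with effect
#' size and standard error from the regression of the residualized
#' phenotype on the residualized genotype (effect on the transformed
#' phenotype scale).
#'
#' @param null a `null_model`.
#' @param g dosage n-vector (missing mean-imputed; must have at least one
#'   carrier).
#' @return list with `beta`, `se`, `stat` (chi-square, 1 df), `p`.
#' @export
single_variant_test <- function(null, g) {
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  if (stats::var(g) == 0) stop("monomorphic genotype: no carriers")
  gt <- .project_resid(null, g)
  gg <- sum(gt * gt)
  if (gg <= 1e-12) stop("genotype collinear with covariates")
  r <- null$residuals
  beta <- sum(gt * r) / gg
  stat <- sum(gt * r)^2 / (null$sigma2 * gg)
  res2 <- sum((r - beta * gt)^2) / (null$n - null$q - 1)
  se <- sqrt(res2 / gg)
  list(beta = beta, se = se, stat = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Genomic inflation factor
#'
#' lambda_GC: the median chi-square (1 df) quantile of the observed
#' p-values divided by the theoretical null median (0.4549364).
#'
#' @param p_values vector of p-values in (0, 1\].
#' @return numeric scalar; 1 under perfect calibration.
#' @export
lambda_gc <- function(p_values) {
  stopifnot(length(p_values) >= 1, all(p_values > 0), all(p_values <= 1))
  chi <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Deterministic per-gene seed
#'
#' Derives a reproducible, order-independent seed for one gene and test
#' label from the master seed via a rolling string hash, so genome-wide
#' runs give identical results regardless of gene processing order.
#'
#' @param master_seed integer master seed.
#' @param gene_id gene identifier.
#' @param label test label (e.g. "missense.kernel.cat").
#' @return integer seed in \[1, 2^31 - 2\].
#' @export
gene_seed <- function(master_seed, gene_id, label = "") {
  s <- paste0(gene_id, ":", label)
  h <- as.double(master_seed) %% 2147483647
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h) + 1L
}
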