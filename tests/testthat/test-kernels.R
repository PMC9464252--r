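test_that("max-weight collapsing takes the largest carried weight", {
  G <- rbind(c(1, 2, 0), c(0, 0, 0), c(0, 1, 1), c(2, 0, 0))
  w <- c(0.8, 1.0, 0.3)
  expect_equal(collapse_max(G, w), c(1.0, 0, 1.0, 0.8))
  expect_equal(collapse_max(G, rep(1, 3)),
               as.numeric(rowSums(G >= 1) > 0))  # pLOF carrier indicator
  expect_error(collapse_max(matrix(numeric(0), 4, 0), numeric(0)),
               "empty gene")
})

test_that("linear kernel factor is the weighted centered dosage matrix", {
  G <- h_geno(50, 4, maf = 0.3)
  phi <- phi_linear(G, rep(1, 4))
  expect_equal(phi$matrix, sweep(G, 2, colMeans(G)),
               ignore_attr = TRUE)
  expect_true(phi$centered)
  expect_warning(phi0 <- phi_linear(G, c(1, 0, 1, 1)), "zero-weight")
  expect_equal(ncol(phi0$matrix), 3L)
  # score-test p invariant to scaling all weights by a constant
  X <- h_design(50)
  set.seed(9); y <- rnorm(50)
  null <- fit_null_ols(y, X)
  w <- c(0.2, 0.9, 0.5, 0.7)
  p1 <- score_test(null, phi_linear(G, w))$p
  p2 <- score_test(null, phi_linear(G, w * 3.7))$p
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("local collapsing sums weighted columns per amino-acid position", {
  G <- h_geno(60, 4, maf = 0.25, seed = 4)
  w <- c(0.9, 0.8, 1, 0.6)
  # all positions distinct: identical to the linear kernel
  phi_d <- phi_local_collapse(G, w, aa_positions = c(5, 9, 12, 20))
  phi_l <- phi_linear(G, w)
  expect_equal(phi_d$matrix, phi_l$matrix, ignore_attr = TRUE)
  # two variants at one position, both weight 1: column is the sum
  phi_g <- phi_local_collapse(G[, 1:2], c(1, 1), aa_positions = c(7, 7))
  Gc <- sweep(G[, 1:2], 2, colMeans(G[, 1:2]))
  expect_equal(as.numeric(phi_g$matrix), Gc[, 1] + Gc[, 2])
  expect_equal(phi_g$labels, "7")
  expect_error(phi_local_collapse(G, w, aa_positions = c(1, NA, 2, 3)),
               "invalid input")
  # a singleton position behaves as the single variant: equal score p
  X <- h_design(60); set.seed(10); y <- rnorm(60)
  null <- fit_null_ols(y, X)
  p_pos <- score_test(null, phi_local_collapse(G[, 1, drop = FALSE], 0.7,
                                               aa_positions = 99))$p
  p_sv <- single_variant_test(null, G[, 1])$p
  expect_equal(p_pos, p_sv, tolerance = 1e-8)
})

test_that("RBP similarity combines cosine and Gaussian position kernels", {
  expect_equal(position_similarity(0), 1)
  expect_equal(position_similarity(50), 0.5)
  expect_equal(position_similarity(100), 0.0625)
  expect_equal(position_similarity(100), 0.5^(100^2 / 50^2))

  set.seed(6)
  m <- 12
  G <- h_geno(80, m, maf = 0.2, seed = 6)
  V <- matrix(rnorm(m * 8), m, 8)
  pos <- sort(sample(1000:2000, m))
  w <- runif(m, 0.3, 1)
  phi <- phi_rbp(G, w, V, pos)
  S <- attr(phi, "S")
  # brute-force elementwise product of independently computed Q and R
  for (i in 1:m) for (j in 1:m) {
    q_ij <- sum(V[i, ] * V[j, ]) / sqrt(sum(V[i, ]^2) * sum(V[j, ]^2))
    r_ij <- exp(log(0.5) / 50^2 * (pos[i] - pos[j])^2)
    expect_equal(S[i, j], q_ij * r_ij, tolerance = 1e-12)
  }
  expect_equal(diag(S), rep(1, m), ignore_attr = TRUE)
  # antiparallel effect vectors at distance 0 have similarity -1
  V2 <- rbind(c(1, 0.5, rep(0, 6)), -c(1, 0.5, rep(0, 6)))
  S2 <- attr(phi_rbp(h_geno(40, 2, 0.3, 7), c(1, 1), V2, c(500, 500)), "S")
  expect_equal(S2[1, 2], -1)
  expect_error(phi_rbp(G, w, matrix(0, m, 8), pos), "zero RBP effect")
})

test_that("kernel matrices are positive semidefinite for every design", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 40; m <- 6
    G <- h_geno(n, m, maf = 0.3, seed = rep)
    w <- runif(m, 0.2, 1)
    fs <- list(
      phi_linear(G, w),
      phi_local_collapse(G, w, aa_positions = sample(1:3, m, TRUE)),
      phi_rbp(G, w, matrix(rnorm(m * 8), m), sort(sample(1:300, m)))
    )
    for (phi in fs) {
      K <- tcrossprod(phi$matrix)
      ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-8 * max(ev))
    }
  }
  # duplicated position + effect vector: singular S handled by the ridge
  V <- matrix(rep(c(1, 0.2, rep(0, 6)), 3), 3, byrow = TRUE)
  G3 <- h_geno(40, 3, 0.3, 21)
  expect_s3_class(phi_rbp(G3, rep(1, 3), V, c(100, 100, 100)),
                  "kernel_factor")
})

test_that("pLOF concatenation appends one centered burden column", {
  G <- h_geno(50, 3, maf = 0.3, seed = 8)
  phi <- phi_linear(G, rep(1, 3))
  burden <- as.numeric(rbinom(50, 1, 0.3))
  phi2 <- concat_plof(phi, burden)
  expect_equal(ncol(phi2$matrix), 4L)
  expect_equal(tail(phi2$labels, 1), "pLOF")
  expect_equal(phi2$matrix[, 4], burden - mean(burden))
  # all-zero burden: dropped
  expect_equal(ncol(concat_plof(phi, rep(0, 50))$matrix), 3L)
  # empty factor plus burden: burden column alone
  empty <- kernel_factor(matrix(numeric(0), 50, 0), character(0), "linear")
  solo <- concat_plof(empty, burden)
  expect_equal(ncol(solo$matrix), 1L)
  expect_equal(solo$labels, "pLOF")
  # missing pLOF set: unchanged, flagged
  same <- concat_plof(phi, NULL)
  expect_true(isTRUE(attr(same, "plof_missing")))
  expect_equal(same$matrix, phi$matrix)
})
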