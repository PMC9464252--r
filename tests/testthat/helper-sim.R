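# small fixtures shared across test files; everything is generated in code

h_geno <- function(n, m, maf = 0.2, seed = 1) {
  set.seed(seed)
  G <- matrix(rbinom(n * m, 2L, maf), n, m)
  colnames(G) <- sprintf("1:%d:A:C", seq_len(m) * 100L)
  G
}

h_design <- function(n, q = 2, seed = 2) {
  set.seed(seed)
  cbind(intercept = 1, matrix(rnorm(n * (q - 1)), n))
}

# brute-force HWE exact oracle via log-factorials (independent of the
# recurrence used by hwe_exact)
h_hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  n1 <- min(nA, na)
  if (n1 == 0) return(1)
  hets <- seq(n1 %% 2, n1, by = 2)
  logp <- sapply(hets, function(h) {
    hom1 <- (n1 - h) / 2; hom2 <- (max(nA, na) - h) / 2
    lfactorial(n) - lfactorial(hom1) - lfactorial(h) - lfactorial(hom2) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  })
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- pr[hets == nAa]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# brute-force two-sided Fisher oracle by hypergeometric enumeration
h_fisher_oracle <- function(a, b, c, d) {
  # table rows (a, b) / (c, d); condition on margins
  m1 <- a + b; m2 <- c + d; k <- a + c
  xs <- max(0, k - m2):min(k, m1)
  pr <- dhyper(xs, m1, m2, k)
  obs <- dhyper(a, m1, m2, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# a small raw annotation table covering all four categories
h_raw_annotations <- function() {
  raw <- data.frame(
    variant_id = sprintf("1:%d:A:C", 1:8 * 100L),
    gene_id = c("G1", "G1", "G1", "G1", "G2", "G2", "G2", "G2"),
    category = c("pLOF", "missense", "missense", "missense",
                 "splice", "splice", "rbp", "rbp"),
    strand = c("+", "+", "+", "+", "+", "+", "+", "-"),
    sift = c(NA, 0.1, 0.4, 0.2, NA, NA, NA, NA),
    polyphen = c(NA, 0.9, 0.9, 0.8, NA, NA, NA, NA),
    aa_position = c(NA, 10L, 10L, 42L, NA, NA, NA, NA),
    delta_ag = c(NA, NA, NA, NA, 0.1, 0.05, NA, NA),
    delta_al = c(NA, NA, NA, NA, 0, 0.02, NA, NA),
    delta_dg = c(NA, NA, NA, NA, 0, 0.01, NA, NA),
    delta_dl = c(NA, NA, NA, NA, 0.05, 0.03, NA, NA),
    is_plof = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  for (k in 1:8) {
    raw[[paste0("rbp_ref_", k)]] <- ifelse(raw$category == "rbp", 0.2, NA)
    raw[[paste0("rbp_alt_", k)]] <- ifelse(raw$category == "rbp",
                                           c(rep(0.2, 6), 0.55, 0.45), NA)
  }
  raw
}
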