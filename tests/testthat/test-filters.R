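test_that("minor allele frequency folds and handles missingness", {
  # 21 heterozygous carriers among 182,288 individuals
  g <- c(rep(1, 21), rep(0, 182288 - 21))
  maf <- minor_allele_frequency(g)
  expect_equal(maf, 21 / (2 * 182288))
  expect_equal(sprintf("%.3f%%", 100 * maf), "0.006%")
  expect_equal(minor_allele_frequency(rep(0, 10)), 0)
  expect_equal(minor_allele_frequency(c(2, 2, 0, 0)), 0.5)
  expect_equal(minor_allele_frequency(c(2, 2, 2, 0)), 0.25)  # folded
  expect_equal(minor_allele_frequency(c(1, NA, 0, 1)), 2 / 6)
  expect_error(minor_allele_frequency(c(NA_real_, NA_real_)),
               "undefined MAF")
})

test_that("HWE exact test matches brute-force enumeration", {
  expect_equal(hwe_exact(50, 0, 0), 1.0)
  # frozen from the enumeration oracle: all-heterozygote table, n = 50
  expect_equal(hwe_exact(0, 50, 0), 1.2412467283e-14, tolerance = 1e-6)
  set.seed(11)
  for (i in 1:40) {
    n <- sample(3:50, 1)
    nAa <- sample(0:n, 1)
    nAA <- sample(0:(n - nAa), 1)
    naa <- n - nAa - nAA
    expect_equal(hwe_exact(nAA, nAa, naa), h_hwe_oracle(nAA, nAa, naa),
                 tolerance = 1e-10,
                 info = sprintf("table (%d,%d,%d)", nAA, nAa, naa))
  }
})

test_that("qc_filter reports every violated threshold", {
  set.seed(3)
  n <- 2000
  G <- cbind(
    common   = rbinom(n, 2, 0.1),              # MAF far above 0.1%
    lowcall  = c(rbinom(n - 250, 2, 0.0005), rep(NA, 250)),  # 87.5% calls
    hwe_bad  = c(rep(2, 15), rep(0, n - 15)),  # minor homs, no hets
    passing  = c(1, rep(0, n - 1))             # single het, MAF 0.025%
  )
  rep <- qc_filter(G)
  expect_true(grepl("common", rep$fail_reasons[1]))
  expect_true(grepl("low_call_rate", rep$fail_reasons[2]))
  expect_true(grepl("hwe", rep$fail_reasons[3]))
  expect_true(rep$pass[4])
  expect_equal(rep$fail_reasons[4], "")
  expect_equal(rep$pass, rep$fail_reasons == "")
  # a variant both common and HWE-violating lists both reasons
  G2 <- cbind(both = c(rep(2, 300), rep(0, n - 300)))
  r2 <- qc_filter(G2)
  expect_true(grepl("common", r2$fail_reasons) &&
                grepl("hwe", r2$fail_reasons))
  # boundary: exactly at the HWE threshold is retained
  p_obs <- hwe_exact(1985, 0, 15)
  r3 <- qc_filter(cbind(v = c(rep(2, 15), rep(0, n - 15))),
                  thresholds = list(maf_max = 0.5, hwe_min = p_obs,
                                    call_rate_min = 0.9))
  expect_true(r3$pass[1])
})

test_that("ancestry pruning uses two-sided Fisher tests per population", {
  counts <- data.frame(
    pop = c("EUR", "AFR", "EUR", "AFR", "EUR", "AFR"),
    variant_id = c("v1", "v1", "v2", "v2", "v3", "v3"),
    alt_count = c(10, 1, 5, 50, 4, 0),
    total = c(20000, 2000, 20000, 2000, 20000, 0))
  res <- ancestry_prune(counts, "EUR")
  # v1: same 0.05% frequency in both populations
  expect_true(res$keep[res$variant_id == "v1"])
  expect_gt(res$ancestry_p_min[res$variant_id == "v1"], 0.5)
  # v2: large deviation; frozen oracle p = 1.071235e-46 << 1e-5
  expect_false(res$keep[res$variant_id == "v2"])
  expect_equal(res$ancestry_p_min[res$variant_id == "v2"],
               h_fisher_oracle(5, 20000 - 5, 50, 2000 - 50),
               tolerance = 1e-6)
  expect_equal(res$ancestry_p_min[res$variant_id == "v2"], 1.071235e-46,
               tolerance = 1e-4)
  # v3: zero genotyped alleles in AFR
  expect_equal(res$reason[res$variant_id == "v3"], "selectively_missing")
  # two-sidedness: swapping alt/ref labels leaves p unchanged
  sw <- counts[counts$variant_id == "v2", ]
  sw$alt_count <- sw$total - sw$alt_count
  res_sw <- ancestry_prune(sw, "EUR")
  expect_equal(res_sw$ancestry_p_min,
               res$ancestry_p_min[res$variant_id == "v2"])
  expect_error(ancestry_prune(counts[counts$pop != "EUR", ], "EUR"),
               "configuration error")
})
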