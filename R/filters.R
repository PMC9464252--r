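#' Minor allele frequency of dosage vectors
#'
#' MAF is computed from minor-allele dosages in \{0, 1, 2\} over the
#' non-missing samples and folded to be at most 0.5.
#'
#' @param g numeric vector of dosages (NA = missing), or an n x m matrix
#'   (one column per variant).
#' @return numeric scalar (or length-m vector) in \[0, 0.5\].
#' @export
minor_allele_frequency <- function(g) {
  if (is.matrix(g)) return(apply(g, 2L, minor_allele_frequency))
  ok <- !is.na(g)
  if (!any(ok)) stop("undefined MAF: all dosages missing")
  af <- sum(g[ok]) / (2 * sum(ok))
  min(af, 1 - af)
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided test of Hardy-Weinberg equilibrium from genotype counts,
#' conditioning on the observed allele counts and summing the probabilities
#' of all heterozygote configurations no more likely than the observed one
#' (Wigginton-style exact test). Monomorphic sites return 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major hom, het, minor hom).
#' @return exact p-value in (0, 1\].
#' @export
hwe_exact <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("empty genotype table")
  n1 <- 2 * min(n_AA, n_aa) + n_Aa  # minor allele count
  n2 <- 2 * n - n1
  if (n1 == 0) return(1)
  # iterate over heterozygote counts with the parity of the minor count,
  # building conditional probabilities by ratio recurrence from the mode
  hets <- seq(n1 %% 2, min(n1, n2), by = 2)
  nh <- length(hets)
  pr <- numeric(nh)
  mid <- which.min(abs(hets - n1 * n2 / (n1 + n2)))  # near-modal start
  pr[mid] <- 1
  if (mid < nh) {
    for (k in mid:(nh - 1)) {
      h <- hets[k]
      hom1 <- (n1 - h) / 2; hom2 <- (n2 - h) / 2
      # P(h+2) / P(h) = 4 * hom1 * hom2 / ((h+2)(h+1))
      pr[k + 1] <- pr[k] * 4 * hom1 * hom2 / ((h + 2) * (h + 1))
    }
  }
  if (mid > 1) {
    for (k in mid:2) {
      h <- hets[k]
      hom1 <- (n1 - h) / 2; hom2 <- (n2 - h) / 2
      # P(h-2) / P(h) = h(h-1) / (4 (hom1+1)(hom2+1))
      pr[k - 1] <- pr[k] * h * (h - 1) / (4 * (hom1 + 1) * (hom2 + 1))
    }
  }
  pr <- pr / sum(pr)
  obs <- pr[hets == n_Aa]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Default variant QC thresholds
#' @return named list: `maf_max` (0.001), `hwe_min` (1e-5),
#'   `call_rate_min` (0.9).
#' @export
default_qc_thresholds <- function() {
  list(maf_max = 0.001, hwe_min = 1e-5, call_rate_min = 0.9)
}

#' Variant-level quality control
#'
#' Flags variants that are too common (MAF above `maf_max`), genotyped in
#' too few samples (call rate below `call_rate_min`) or violating
#' Hardy-Weinberg equilibrium (exact p strictly below `hwe_min`). All
#' failing reasons are reported, not just the first. Boundary behaviour:
#' a variant exactly at `maf_max` or at the HWE threshold is retained.
#'
#' @param G n x m dosage matrix (NA = missing) with variant ids as column
#'   names.
#' @param thresholds list as from [default_qc_thresholds()].
#' @return data.frame with one row per variant: `variant_id`, `maf`,
#'   `call_rate`, `hwe_p`, `pass`, `fail_reasons` (comma-joined string,
#'   empty when passing).
#' @export
qc_filter <- function(G, thresholds = default_qc_thresholds()) {
  stopifnot(is.matrix(G))
  m <- ncol(G)
  ids <- colnames(G)
  if (is.null(ids)) ids <- paste0("v", seq_len(m))
  maf <- numeric(m); call_rate <- numeric(m); hwe_p <- numeric(m)
  reasons <- character(m)
  for (j in seq_len(m)) {
    g <- G[, j]
    ok <- !is.na(g)
    call_rate[j] <- mean(ok)
    maf[j] <- if (any(ok)) minor_allele_frequency(g) else NA_real_
    gg <- g[ok]
    n_het <- sum(gg == 1)
    n_min <- sum(gg == 2)  # dosage counts the minor allele
    n_maj <- sum(gg == 0)
    hwe_p[j] <- if (length(gg)) hwe_exact(n_maj, n_het, n_min) else NA_real_
    fr <- character(0)
    if (!is.na(maf[j]) && maf[j] > thresholds$maf_max) fr <- c(fr, "common")
    if (call_rate[j] < thresholds$call_rate_min) fr <- c(fr, "low_call_rate")
    if (!is.na(hwe_p[j]) && hwe_p[j] < thresholds$hwe_min) fr <- c(fr, "hwe")
    reasons[j] <- paste(fr, collapse = ",")
  }
  data.frame(variant_id = ids, maf = maf, call_rate = call_rate,
             hwe_p = hwe_p, pass = reasons == "", fail_reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Ancestry-based variant pruning
#'
#' For each variant, compares the alternative-allele count in every
#' non-reference superpopulation against the reference population with a
#' two-sided Fisher exact test on the 2 x 2 allele-count table, and excludes
#' variants with any p below `p_min`. Variants with zero genotyped alleles
#' in any population are excluded as selectively missing.
#'
#' @param counts data.frame with columns `pop`, `variant_id`, `alt_count`,
#'   `total` (total genotyped alleles in that population).
#' @param reference_pop name of the reference population (e.g. "EUR").
#' @param p_min exclusion threshold (default 1e-5); exclusion requires
#'   p strictly below it.
#' @return data.frame per variant: `variant_id`, `ancestry_p_min`, `keep`,
#'   `reason` ("", "ancestry" or "selectively_missing").
#' @export
ancestry_prune <- function(counts, reference_pop, p_min = 1e-5) {
  stopifnot(all(c("pop", "variant_id", "alt_count", "total") %in%
                  names(counts)))
  if (!reference_pop %in% counts$pop) {
    stop("configuration error: reference population '", reference_pop,
         "' absent from counts table")
  }
  ids <- unique(counts$variant_id)
  out <- data.frame(variant_id = ids, ancestry_p_min = NA_real_,
                    keep = TRUE, reason = "", stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    tab <- counts[counts$variant_id == ids[k], , drop = FALSE]
    if (any(tab$total == 0)) {
      out$keep[k] <- FALSE
      out$reason[k] <- "selectively_missing"
      next
    }
    ref <- tab[tab$pop == reference_pop, , drop = FALSE]
    if (nrow(ref) != 1) stop("configuration error: reference population ",
                             "missing for variant ", ids[k])
    others <- tab[tab$pop != reference_pop, , drop = FALSE]
    pmin_k <- 1
    for (i in seq_len(nrow(others))) {
      m22 <- matrix(c(ref$alt_count, ref$total - ref$alt_count,
                      others$alt_count[i],
                      others$total[i] - others$alt_count[i]), nrow = 2)
      pmin_k <- min(pmin_k, stats::fisher.test(m22)$p.value)
    }
    out$ancestry_p_min[k] <- pmin_k
    if (pmin_k < p_min) {
      out$keep[k] <- FALSE
      out$reason[k] <- "ancestry"
    }
  }
  out
}
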