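#' Simulation study specification
#'
#' Describes a synthetic study: sample size, gene/variant layout, the rare
#' minor-allele-frequency spectrum, category composition, amino-acid
#' position sharing, causal architecture and covariates. The MAF law is
#' log-uniform on \[1/(2n), maf_max\], which produces the singleton-heavy
#' spectrum characteristic of exome sequencing at scale.
#'
#' @param n number of samples.
#' @param n_genes number of genes.
#' @param m_per_gene variants per gene (scalar, recycled).
#' @param maf_max upper MAF bound (default 0.001, the study-wide
#'   rare-variant inclusion threshold).
#' @param category_mix named probabilities over
#'   c(pLOF, missense, splice, rbp) for assigning variants to categories.
#' @param aa_share fraction of missense variants sharing an amino-acid
#'   position with another variant of the same gene (default 0.2).
#' @param causal_fraction fraction of a causal gene's variants with
#'   nonzero effect.
#' @param prop_negative fraction of causal effects with negative sign.
#' @param h2_gene phenotypic variance explained by a causal gene
#'   (0 = null simulation).
#' @param weight_effect_cor if TRUE, causal variants are drawn
#'   preferentially among high-weight variants.
#' @param n_covariates number of standard-normal covariates besides the
#'   intercept.
#' @param missing_rate genotype missingness rate.
#' @param n_rbp length of RBP effect vectors (default 8).
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(n = 500, n_genes = 10, m_per_gene = 10,
                     maf_max = 0.001,
                     category_mix = c(pLOF = 0.15, missense = 0.45,
                                      splice = 0.2, rbp = 0.2),
                     aa_share = 0.2, causal_fraction = 0.3,
                     prop_negative = 0, h2_gene = 0,
                     weight_effect_cor = FALSE, n_covariates = 2,
                     missing_rate = 0, n_rbp = 8L) {
  if (maf_max > 0.5) stop("config error: maf_max above 0.5")
  stopifnot(aa_share >= 0, aa_share <= 1, causal_fraction >= 0,
            causal_fraction <= 1, h2_gene >= 0, h2_gene < 1,
            prop_negative >= 0, prop_negative <= 1,
            abs(sum(category_mix) - 1) < 1e-8)
  structure(list(n = n, n_genes = n_genes, m_per_gene = m_per_gene,
                 maf_max = maf_max, category_mix = category_mix,
                 aa_share = aa_share, causal_fraction = causal_fraction,
                 prop_negative = prop_negative, h2_gene = h2_gene,
                 weight_effect_cor = weight_effect_cor,
                 n_covariates = n_covariates, missing_rate = missing_rate,
                 n_rbp = as.integer(n_rbp)),
            class = "sim_spec")
}

#' Simulate rare-variant genotypes
#'
#' Draws per-variant MAFs from the log-uniform law of the spec and
#' genotypes as binomial(2, MAF) minor-allele dosages, with optional
#' missingness. Variants are laid out on consecutive positions spaced
#' 10-200 bp apart within each gene.
#'
#' @param spec a `sim_spec`.
#' @param seed RNG seed.
#' @return list with `G` (n x m dosage matrix, NA = missing, column names
#'   = variant ids "chrom:pos:ref:alt") and `map` (data.frame: variant_id,
#'   gene_id, chrom, pos, ref, alt, strand).
#' @export
sim_genotypes <- function(spec, seed = 1) {
  set.seed(seed)
  m_per <- rep(spec$m_per_gene, length.out = spec$n_genes)
  m <- sum(m_per)
  lo <- log(1 / (2 * spec$n)); hi <- log(max(spec$maf_max, 1.01 / (2 * spec$n)))
  maf <- exp(stats::runif(m, min(lo, hi), max(lo, hi)))
  G <- matrix(stats::rbinom(spec$n * m, 2L, rep(maf, each = spec$n)),
              nrow = spec$n, ncol = m)
  if (spec$missing_rate > 0) {
    G[matrix(stats::runif(spec$n * m) < spec$missing_rate, spec$n, m)] <- NA
  }
  gene_id <- rep(sprintf("GENE%04d", seq_len(spec$n_genes)), times = m_per)
  gene_start <- cumsum(c(1e6, utils::head(m_per, -1) * 300 + 5e4))
  pos <- unlist(lapply(seq_len(spec$n_genes), function(g) {
    gene_start[g] + cumsum(sample(10:200, m_per[g], replace = TRUE))
  }))
  strand <- rep(sample(c("+", "-"), spec$n_genes, replace = TRUE),
                times = m_per)
  ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                "")
  vid <- sprintf("1:%d:%s:%s", pos, ref, alt)
  colnames(G) <- vid
  list(G = G,
       map = data.frame(variant_id = vid, gene_id = gene_id, chrom = "1",
                        pos = pos, ref = ref, alt = unname(alt),
                        strand = strand, maf_true = maf,
                        stringsAsFactors = FALSE))
}

#' Simulate a raw variant-annotation table
#'
#' Generates predictor-level columns (SIFT/PolyPhen, SpliceAI deltas, RBP
#' binding probabilities, amino-acid positions) so that the annotation
#' module processes simulated and real tables identically. Missense
#' amino-acid positions share positions at the spec's `aa_share` rate;
#' RBP effect vectors are sparse with random sign.
#'
#' @param spec a `sim_spec`.
#' @param map variant map from [sim_genotypes()].
#' @param seed RNG seed.
#' @return data.frame in the raw annotation-table layout accepted by
#'   [build_annotations()].
#' @export
sim_annotations <- function(spec, map, seed = 1) {
  set.seed(seed + 1L)
  m <- nrow(map)
  category <- sample(names(spec$category_mix), m, replace = TRUE,
                     prob = spec$category_mix)
  out <- data.frame(variant_id = map$variant_id, gene_id = map$gene_id,
                    category = category, strand = map$strand,
                    sift = NA_real_, polyphen = NA_real_,
                    aa_position = NA_integer_,
                    delta_ag = NA_real_, delta_al = NA_real_,
                    delta_dg = NA_real_, delta_dl = NA_real_,
                    is_plof = category == "pLOF",
                    stringsAsFactors = FALSE)
  for (k in seq_len(spec$n_rbp)) {
    out[[paste0("rbp_ref_", k)]] <- NA_real_
    out[[paste0("rbp_alt_", k)]] <- NA_real_
  }

  i <- which(category == "missense")
  if (length(i)) {
    out$sift[i] <- stats::rbeta(length(i), 0.5, 2)       # mostly deleterious
    out$polyphen[i] <- stats::rbeta(length(i), 2, 0.5)
    for (g in unique(map$gene_id[i])) {
      gi <- i[map$gene_id[i] == g]
      aa <- seq_along(gi) * 3L + sample(100L, 1)
      share <- stats::runif(length(gi)) < spec$aa_share & seq_along(gi) > 1
      aa[share] <- aa[pmax(which(share) - 1L, 1L)]
      out$aa_position[gi] <- aa
    }
  }

  i <- which(category == "splice")
  if (length(i)) {
    d <- matrix(stats::rbeta(length(i) * 4, 0.6, 1.2), ncol = 4)
    out[i, c("delta_ag", "delta_al", "delta_dg", "delta_dl")] <- d
    # a fraction of splice variants is dually annotated as pLOF
    out$is_plof[i] <- stats::runif(length(i)) < 0.15
  }

  i <- which(category == "rbp")
  if (length(i)) {
    for (k in seq_len(spec$n_rbp)) {
      pref <- stats::runif(length(i), 0.05, 0.6)
      shift <- ifelse(stats::runif(length(i)) < 0.3,
                      stats::runif(length(i), -0.4, 0.4), 0)
      out[[paste0("rbp_ref_", k)]][i] <- pref
      out[[paste0("rbp_alt_", k)]][i] <- pmin(pmax(pref + shift, 0), 1)
    }
  }
  out
}

#' Simulate a quantitative phenotype
#'
#' y = X alpha + G beta + epsilon. Effects beta are nonzero on a random
#' causal subset of the columns of `G_causal` with the configured sign
#' mixture, and epsilon is scaled so the causal term explains `h2_gene` of
#' the phenotypic variance. With `h2_gene = 0` the phenotype is pure null.
#'
#' @param G_causal n x m dosage matrix of the causal gene (may be NULL or
#'   have zero columns for a null phenotype).
#' @param X covariate matrix (intercept included).
#' @param spec a `sim_spec`.
#' @param seed RNG seed.
#' @param weights optional variant weights used to bias causal-variant
#'   selection when `spec$weight_effect_cor` is TRUE.
#' @return numeric phenotype vector of length n.
#' @export
sim_phenotype <- function(G_causal, X, spec, seed = 1, weights = NULL) {
  set.seed(seed + 2L)
  n <- nrow(X)
  alpha <- stats::rnorm(ncol(X), 0, 0.3)
  eta <- as.numeric(X %*% alpha)
  gen <- numeric(n)
  if (!is.null(G_causal) && ncol(G_causal) > 0 && spec$h2_gene > 0) {
    m <- ncol(G_causal)
    n_causal <- max(1L, round(spec$causal_fraction * m))
    prob <- if (spec$weight_effect_cor && !is.null(weights)) {
      weights + 0.01
    } else rep(1, m)
    causal <- sample.int(m, n_causal, prob = prob)
    beta <- abs(stats::rnorm(n_causal))
    neg <- stats::runif(n_causal) < spec$prop_negative
    beta[neg] <- -beta[neg]
    Gc <- G_causal[, causal, drop = FALSE]
    Gc[is.na(Gc)] <- 0
    gen <- as.numeric(Gc %*% beta)
    vg <- stats::var(gen)
    if (vg > 0) {
      # scale so the causal term explains h2_gene of unit total variance
      gen <- gen * sqrt(spec$h2_gene / vg)
    } else gen <- numeric(n)
  }
  eta + gen + stats::rnorm(n, 0, sqrt(max(1 - spec$h2_gene, 1e-12)))
}

#' Simulate covariates
#'
#' Intercept plus standard-normal covariates.
#'
#' @param spec a `sim_spec`.
#' @param seed RNG seed.
#' @return n x (1 + n_covariates) matrix with named columns.
#' @export
sim_covariates <- function(spec, seed = 1) {
  set.seed(seed + 3L)
  X <- cbind(1, matrix(stats::rnorm(spec$n * spec$n_covariates), spec$n))
  colnames(X) <- c("intercept",
                   if (spec$n_covariates > 0)
                     paste0("cov", seq_len(spec$n_covariates)))
  X
}

#' Simulate a complete study
#'
#' Bundles genotypes, raw annotations, covariates and one or more
#' phenotypes into the in-memory structure consumed by [run_study()];
#' optionally writes PLINK bed/bim/fam and TSV tables so the pipeline
#' ingests simulated and real data identically.
#'
#' @param spec a `sim_spec`.
#' @param seed master seed.
#' @param n_phenotypes number of phenotypes to simulate.
#' @param causal_genes character vector of gene ids carrying signal (under
#'   `spec$h2_gene`); empty for a null study.
#' @param dir optional directory; when given, files are written with
#'   prefix `sim` (see [write_plink()], [write_study_tables()]).
#' @return list with `G`, `map`, `annotations_raw`, `X`, `phenotypes`
#'   (n x n_phenotypes matrix), `sample_ids`, `spec`, `seed`.
#' @export
sim_study <- function(spec, seed = 1, n_phenotypes = 1,
                      causal_genes = character(0), dir = NULL) {
  geno <- sim_genotypes(spec, seed)
  ann <- sim_annotations(spec, geno$map, seed)
  X <- sim_covariates(spec, seed)
  pheno <- vapply(seq_len(n_phenotypes), function(k) {
    Gc <- if (length(causal_genes)) {
      geno$G[, geno$map$gene_id %in% causal_genes, drop = FALSE]
    } else NULL
    sim_phenotype(Gc, X, spec, seed = seed * 1000L + k)
  }, numeric(spec$n))
  colnames(pheno) <- paste0("pheno", seq_len(n_phenotypes))
  sample_ids <- sprintf("S%05d", seq_len(spec$n))
  rownames(geno$G) <- sample_ids
  out <- list(G = geno$G, map = geno$map, annotations_raw = ann, X = X,
              phenotypes = pheno, sample_ids = sample_ids, spec = spec,
              seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_plink(file.path(dir, "sim"), geno$G, geno$map, sample_ids)
    write_study_tables(dir, out)
  }
  out
}
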