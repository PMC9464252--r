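#' Study configuration
#'
#' Collects all tunable thresholds of the genome-wide testing procedure
#' with their default values: QC (MAF <= 0.1\%, HWE exact p >= 1e-5, call
#' rate >= 90\%), qualifying-variant thresholds (missense impact 0.8,
#' splice delta 0.1, RBP effect 0.25), the sLRT trigger threshold t = 0.1,
#' 100 simulated null statistics per triggered gene (250,000 for
#' gene-specific conditional tests), and the study-wide significance level
#' alpha = 0.05 (Bonferroni-corrected over all emitted tests).
#'
#' @param maf_max,hwe_min,call_rate_min variant QC thresholds.
#' @param missense_weight_min,splice_delta_min,rbp_effect_min qualifying
#'   thresholds.
#' @param slrt_t sLRT trigger threshold.
#' @param alpha FWER level.
#' @param n_null_per_gene null statistics per triggered gene.
#' @param n_null_conditional null statistics for conditional tests.
#' @param master_seed integer master seed; per-gene seeds derive from it.
#' @param categories variant categories to run.
#' @param int_transform apply the rank-based inverse-normal transform to
#'   phenotypes.
#' @param do_qc run variant QC before testing.
#' @param n_rbp RBP effect-vector length.
#' @return object of class `study_config`.
#' @export
study_config <- function(maf_max = 0.001, hwe_min = 1e-5,
                         call_rate_min = 0.9, missense_weight_min = 0.8,
                         splice_delta_min = 0.1, rbp_effect_min = 0.25,
                         slrt_t = 0.1, alpha = 0.05,
                         n_null_per_gene = 100,
                         n_null_conditional = 250000, master_seed = 1,
                         categories = c("pLOF", "missense", "splice",
                                        "rbp"),
                         int_transform = TRUE, do_qc = TRUE, n_rbp = 8L) {
  stopifnot(alpha > 0, alpha < 1, slrt_t > 0, slrt_t < 1,
            n_null_per_gene >= 1)
  structure(list(
    qc = list(maf_max = maf_max, hwe_min = hwe_min,
              call_rate_min = call_rate_min),
    thresholds = list(missense = missense_weight_min,
                      splice = splice_delta_min, rbp = rbp_effect_min),
    slrt_t = slrt_t, alpha = alpha, n_null_per_gene = n_null_per_gene,
    n_null_conditional = n_null_conditional, master_seed = master_seed,
    categories = categories, int_transform = int_transform, do_qc = do_qc,
    n_rbp = as.integer(n_rbp)), class = "study_config")
}

#' Rank-based inverse-normal transform
#'
#' Maps values to standard-normal quantiles by rank,
#' qnorm((rank - 0.5) / n), optionally within groups (e.g. sex-stratified
#' for bimodal phenotypes). Missing values stay missing; the transform is
#' monotone within each group.
#'
#' @param values numeric vector.
#' @param groups optional grouping factor of the same length.
#' @return transformed vector.
#' @export
inverse_normal_transform <- function(values, groups = NULL) {
  tr <- function(x) {
    ok <- !is.na(x)
    if (sum(ok) < 10) stop("fewer than 10 non-missing values in a group")
    if (stats::var(x[ok]) == 0) stop("constant phenotype cannot be ",
                                     "quantile-transformed")
    out <- rep(NA_real_, length(x))
    r <- rank(x[ok], ties.method = "average")
    out[ok] <- stats::qnorm((r - 0.5) / sum(ok))
    out
  }
  if (is.null(groups)) return(tr(values))
  stopifnot(length(groups) == length(values))
  out <- rep(NA_real_, length(values))
  for (g in unique(groups[!is.na(groups)])) {
    i <- which(groups == g)
    out[i] <- tr(values[i])
  }
  out
}

# one elementary test record
.record <- function(gene_id, category, track, design, n_variants,
                    n_carriers, sc, triggered, rlrt = NA_real_,
                    null_stats = NULL, flags = character(0)) {
  list(gene_id = gene_id, category = category, track = track,
       design = design, n_variants = n_variants, n_carriers = n_carriers,
       score_stat = sc$stat, score_p = sc$p, lrt_triggered = triggered,
       rlrt_stat = rlrt, null_stats = null_stats, rlrt_p = NA_real_,
       flags = flags)
}

.burden_factor <- function(burden) {
  b <- burden - mean(burden)
  if (sum(b * b) <= 1e-12) return(NULL)
  kernel_factor(matrix(b, ncol = 1), "burden", "collapse_max")
}

.n_carriers <- function(G) sum(rowSums(!is.na(G) & G >= 1) > 0)

#' Run all tests of one gene for one variant category
#'
#' Implements the per-category testing procedure:
#' \itemize{
#'   \item \strong{pLOF}: max-weight collapsing burden, score test only.
#'   \item \strong{missense}: score tests for the weighted burden (gbvc)
#'     and the locally collapsing kernel; if either p falls below the
#'     trigger threshold, RLRT statistics and simulated null statistics
#'     are computed for both, plus two pLOF-combined designs (joint max
#'     burden over missense and pLOF variants; concatenation of the
#'     collapsed pLOF variable to the locally collapsed factor).
#'   \item \strong{splice}: as missense with the weighted linear kernel;
#'     variants dually annotated splice + pLOF count once, as pLOF, in the
#'     joint designs.
#'   \item \strong{rbp}: kernel-only sLRT with the directional RBP kernel,
#'     run separately per strand; when pLOF variants sit in the set they
#'     are removed and the test repeated, and the pLOF-free result is
#'     reported (flagged).
#' }
#'
#' @param gene_id gene identifier.
#' @param G n x m dosage matrix restricted to the gene's QC-passing
#'   variants (columns named by variant id).
#' @param qual qualifying annotations for this gene (all categories), from
#'   [assign_qualifying()].
#' @param y transformed phenotype (no missing values).
#' @param X covariate matrix with intercept.
#' @param category one of "pLOF", "missense", "splice", "rbp".
#' @param positions named vector mapping variant id to bp position (rbp
#'   only).
#' @param config a `study_config`.
#' @param null optional pre-fitted `null_model` for (y, X); computed when
#'   absent. Passing it avoids refitting across genes.
#' @return list of test records (possibly empty when the gene has no
#'   qualifying variants of the category).
#' @export
test_gene_category <- function(gene_id, G, qual, y, X, category,
                               positions = NULL,
                               config = study_config(), null = NULL) {
  qg <- qual[qual$gene_id == gene_id, , drop = FALSE]
  avail <- intersect(qg$variant_id, colnames(G))
  qg <- qg[qg$variant_id %in% avail, , drop = FALSE]
  cat_rows <- qg[qg$category == category, , drop = FALSE]
  if (!nrow(cat_rows)) return(list())
  if (is.null(null)) null <- fit_null_ols(y, X)
  t <- config$slrt_t; n_null <- config$n_null_per_gene
  seed_for <- function(label) gene_seed(config$master_seed, gene_id,
                                        paste(category, label))
  plof_rows <- qg[qg$category == "pLOF", , drop = FALSE]

  safe_score <- function(phi) {
    tryCatch(score_test(null, phi), error = function(e) NULL)
  }
  add_rlrt <- function(rec, phi, label) {
    rec$rlrt_stat <- rlrt_stat(y, X, phi)
    rec$null_stats <- sample_rlrt_null(phi, X, n_samples = n_null,
                                       seed = seed_for(label))
    rec$lrt_triggered <- TRUE
    rec
  }

  if (category == "pLOF") {
    Gp <- G[, cat_rows$variant_id, drop = FALSE]
    phi <- .burden_factor(collapse_max(Gp, rep(1, ncol(Gp))))
    if (is.null(phi)) return(list())
    sc <- safe_score(phi)
    if (is.null(sc)) return(list())
    return(list(.record(gene_id, category, "gbvc", "cat", ncol(Gp),
                        .n_carriers(Gp), sc, FALSE)))
  }

  if (category == "rbp") {
    out <- list()
    for (st in unique(cat_rows$strand)) {
      rows <- cat_rows[cat_rows$strand == st, , drop = FALSE]
      flags <- character(0)
      if (any(rows$is_also_plof)) {
        rows <- rows[!rows$is_also_plof, , drop = FALSE]
        flags <- "plof_removed"
        if (!nrow(rows)) next
      }
      Gr <- G[, rows$variant_id, drop = FALSE]
      ev <- do.call(rbind, rows$effect_vector)
      pos <- positions[rows$variant_id]
      phi <- tryCatch(
        phi_rbp(Gr, rows$weight, ev, pos, gene_id = gene_id),
        error = function(e) NULL)
      if (is.null(phi) || ncol(phi$matrix) == 0L) next
      sc <- safe_score(phi)
      if (is.null(sc)) next
      rec <- .record(gene_id, category, "kernel", "cat", nrow(rows),
                     .n_carriers(Gr), sc, FALSE, flags = flags)
      if (sc$p < t) rec <- add_rlrt(rec, phi, paste0("kernel.cat.", st))
      rec$strand <- st
      out <- c(out, list(rec))
    }
    return(out)
  }

  # missense / splice: gbvc + kernel tracks with pLOF-combined designs.
  # Dual-annotated variants (splice + pLOF) move to the pLOF side of the
  # joint designs; the category-only tests keep them.
  Gm <- G[, cat_rows$variant_id, drop = FALSE]
  w <- cat_rows$weight
  phi_b <- .burden_factor(collapse_max(Gm, w))
  phi_k <- tryCatch({
    if (category == "missense") {
      phi_local_collapse(Gm, w, cat_rows$aa_position)
    } else {
      phi_linear(Gm, w, cat_rows$variant_id)
    }
  }, error = function(e) NULL)
  if (is.null(phi_b) || is.null(phi_k) || ncol(phi_k$matrix) == 0L) {
    return(list())
  }
  sc_b <- safe_score(phi_b); sc_k <- safe_score(phi_k)
  if (is.null(sc_b) || is.null(sc_k)) return(list())
  nv <- nrow(cat_rows); ncar <- .n_carriers(Gm)
  rec_b <- .record(gene_id, category, "gbvc", "cat", nv, ncar, sc_b, FALSE)
  rec_k <- .record(gene_id, category, "kernel", "cat", nv, ncar, sc_k,
                   FALSE)
  out <- list()
  if (min(sc_b$p, sc_k$p) < t) {
    rec_b <- add_rlrt(rec_b, phi_b, "gbvc.cat")
    rec_k <- add_rlrt(rec_k, phi_k, "kernel.cat")
    # joint designs with pLOF variants
    solo <- cat_rows[!cat_rows$is_also_plof, , drop = FALSE]
    plof_ids <- union(plof_rows$variant_id,
                      cat_rows$variant_id[cat_rows$is_also_plof])
    joint_ids <- c(solo$variant_id, plof_ids)
    Gj <- G[, joint_ids, drop = FALSE]
    wj <- c(solo$weight, rep(1, length(plof_ids)))
    phi_jb <- .burden_factor(collapse_max(Gj, wj))
    plof_burden <- if (length(plof_ids)) {
      collapse_max(G[, plof_ids, drop = FALSE], rep(1, length(plof_ids)))
    } else NULL
    phi_solo <- tryCatch({
      if (!nrow(solo)) {
        kernel_factor(matrix(numeric(0), nrow(G), 0), character(0),
                      phi_k$design)
      } else if (category == "missense") {
        phi_local_collapse(G[, solo$variant_id, drop = FALSE], solo$weight,
                           solo$aa_position)
      } else {
        phi_linear(G[, solo$variant_id, drop = FALSE], solo$weight,
                   solo$variant_id)
      }
    }, error = function(e) NULL)
    phi_jk <- if (!is.null(phi_solo)) concat_plof(phi_solo, plof_burden)
              else NULL
    if (!is.null(phi_jb)) {
      sc_jb <- safe_score(phi_jb)
      if (!is.null(sc_jb)) {
        rec_jb <- .record(gene_id, category, "gbvc", "cat_plof",
                          length(joint_ids), .n_carriers(Gj), sc_jb, FALSE)
        rec_jb <- add_rlrt(rec_jb, phi_jb, "gbvc.cat_plof")
        out <- c(out, list(rec_jb))
      }
    }
    if (!is.null(phi_jk) && ncol(phi_jk$matrix) > 0L) {
      sc_jk <- safe_score(phi_jk)
      if (!is.null(sc_jk)) {
        rec_jk <- .record(gene_id, category, "kernel", "cat_plof",
                          length(joint_ids), .n_carriers(Gj), sc_jk, FALSE)
        rec_jk <- add_rlrt(rec_jk, phi_jk, "kernel.cat_plof")
        out <- c(out, list(rec_jk))
      }
    }
  }
  c(list(rec_b, rec_k), out)
}

#' Pool null statistics and finalize p-values
#'
#' Fits one parametric null mixture per (category x track x design) group
#' from the pooled simulated RLRT statistics of all triggered genes,
#' converts every triggered record's RLRT statistic to a p-value under its
#' group mixture, and combines the category-only and category+pLOF
#' designs per gene and track with the Cauchy combination test, yielding a
#' single kernel-based and a single gbvc p-value per gene. Non-triggered
#' genes keep their score-test p.
#'
#' @param records flat list of records from [test_gene_category()] for one
#'   phenotype.
#' @param config a `study_config`.
#' @return data.frame with one row per (gene, category, track):
#'   `gene_id`, `category`, `test_type`, `n_variants`, `n_carriers`,
#'   `score_stat`, `score_p`, `rlrt_stat`, `rlrt_p`, `combined_p`,
#'   `final_p`, `lrt_triggered`, `flags`. Attribute `mixtures` carries the
#'   fitted `null_mixture` objects keyed by group.
#' @export
pool_and_finalize <- function(records, config = study_config()) {
  if (!length(records)) {
    return(structure(data.frame(), mixtures = list()))
  }
  grp_key <- vapply(records, function(r) {
    paste(r$category, r$track, r$design, sep = ".")
  }, "")
  triggered <- vapply(records, function(r) isTRUE(r$lrt_triggered), TRUE)
  mixtures <- list()
  for (g in unique(grp_key[triggered])) {
    idx <- which(grp_key == g & triggered)
    pooled <- unlist(lapply(records[idx], `[[`, "null_stats"))
    mix <- suppressWarnings(fit_null_mixture(pooled))
    mixtures[[g]] <- mix
    for (i in idx) {
      records[[i]]$rlrt_p <- mixture_pvalue(records[[i]]$rlrt_stat, mix)
    }
  }

  gene_key <- vapply(records, function(r) {
    paste(r$gene_id, r$category, r$track,
          if (is.null(r$strand)) "" else r$strand, sep = "|")
  }, "")
  keys <- unique(gene_key)
  nk <- length(keys)
  out <- list(gene_id = character(nk), category = character(nk),
              test_type = character(nk), n_variants = integer(nk),
              n_carriers = integer(nk), score_stat = numeric(nk),
              score_p = numeric(nk), rlrt_stat = numeric(nk),
              rlrt_p = numeric(nk), combined_p = numeric(nk),
              final_p = numeric(nk), lrt_triggered = logical(nk),
              flags = character(nk))
  rec_of_key <- split(seq_along(records), factor(gene_key, levels = keys))
  for (ki in seq_len(nk)) {
    rs <- records[rec_of_key[[ki]]]
    cat_rec <- rs[[which(vapply(rs, function(r) r$design == "cat", TRUE))]]
    plof_rec <- rs[vapply(rs, function(r) r$design == "cat_plof", TRUE)]
    combined_p <- NA_real_
    if (isTRUE(cat_rec$lrt_triggered)) {
      ps <- cat_rec$rlrt_p
      if (length(plof_rec)) ps <- c(ps, plof_rec[[1]]$rlrt_p)
      # zero RLRT statistics give p exactly 1; move onto the open interval
      ps <- pmin(pmax(ps, 1e-300), 1 - 1e-16)
      combined_p <- if (length(ps) > 1) cauchy_combine(ps) else ps
      final_p <- combined_p
    } else {
      final_p <- cat_rec$score_p
    }
    out$gene_id[ki] <- cat_rec$gene_id
    out$category[ki] <- cat_rec$category
    out$test_type[ki] <- cat_rec$track
    out$n_variants[ki] <- cat_rec$n_variants
    out$n_carriers[ki] <- cat_rec$n_carriers
    out$score_stat[ki] <- cat_rec$score_stat
    out$score_p[ki] <- cat_rec$score_p
    out$rlrt_stat[ki] <- cat_rec$rlrt_stat
    out$rlrt_p[ki] <- cat_rec$rlrt_p
    out$combined_p[ki] <- combined_p
    out$final_p[ki] <- final_p
    out$lrt_triggered[ki] <- isTRUE(cat_rec$lrt_triggered)
    out$flags[ki] <- paste(cat_rec$flags, collapse = ",")
  }
  structure(as.data.frame(out, stringsAsFactors = FALSE),
            mixtures = mixtures)
}

#' Bonferroni significance cutoff
#'
#' @param alpha FWER level.
#' @param n_tests total number of tests performed.
#' @return alpha / n_tests.
#' @export
bonferroni_cutoff <- function(alpha, n_tests) {
  stopifnot(n_tests >= 1, alpha > 0)
  alpha / n_tests
}

#' Conditional association test
#'
#' Re-tests a gene after conditioning on a single variant: the
#' conditioning dosage joins the covariates of a gene-specific null
#' model, the RLRT statistic is recomputed, a large gene-specific null
#' sample is drawn (default 250,000 statistics), a gene-specific mixture
#' is fitted on its top decile, and the p-value is read off that mixture.
#' A conditioning variant collinear with the covariates is dropped with a
#' warning and the unconditional p returned, flagged.
#'
#' @param y phenotype vector.
#' @param X covariate matrix with intercept.
#' @param g_cond conditioning dosage vector (most significant nearby
#'   single variant; see [choose_conditioning_variant()]).
#' @param phi a `kernel_factor` for the gene.
#' @param n_null gene-specific null statistics (default from config:
#'   250,000).
#' @param seed RNG seed.
#' @return list: `p`, `rlrt_stat`, `mixture`, `conditioned` (FALSE when
#'   the variant was dropped as collinear).
#' @export
conditional_test <- function(y, X, g_cond, phi, n_null = 250000, seed = 1) {
  g_cond[is.na(g_cond)] <- mean(g_cond, na.rm = TRUE)
  Xc <- cbind(X, cond = g_cond)
  conditioned <- TRUE
  if (qr(Xc)$rank < ncol(Xc)) {
    warning("conditioning variant collinear with covariates; dropped")
    Xc <- X
    conditioned <- FALSE
  }
  stat <- rlrt_stat(y, Xc, phi)
  nulls <- sample_rlrt_null(phi, Xc, n_samples = n_null, seed = seed)
  mix <- suppressWarnings(fit_null_mixture(nulls))
  list(p = mixture_pvalue(stat, mix), rlrt_stat = stat, mixture = mix,
       conditioned = conditioned)
}

#' Choose the conditioning variant
#'
#' Picks the most significant single variant; ties are broken by
#' proximity to the gene start position.
#'
#' @param p_values single-variant p-values.
#' @param positions variant bp positions.
#' @param gene_start gene start bp.
#' @return index of the chosen variant.
#' @export
choose_conditioning_variant <- function(p_values, positions, gene_start) {
  stopifnot(length(p_values) == length(positions), length(p_values) >= 1)
  best <- which(p_values == min(p_values))
  if (length(best) > 1) {
    best <- best[which.min(abs(positions[best] - gene_start))]
  }
  best
}

#' Run a full genome-wide study
#'
#' Full pass over a study bundle: phenotype inverse-normal transform,
#' variant QC, per-gene tests for every requested category, pooled-null
#' finalization per phenotype, Bonferroni flags over all emitted tests,
#' and the genomic inflation factor per (phenotype x category x
#' test-type) group. Fully reproducible from the master seed and
#' independent of gene processing order.
#'
#' @param study list with `G` (dosage matrix, variant-id columns), `map`
#'   (variant_id, gene_id, pos, strand), `annotations_raw`, `X`,
#'   `phenotypes` (matrix with named columns), `sample_ids` — as produced
#'   by [sim_study()] or assembled from [read_plink()] and the table
#'   readers.
#' @param config a `study_config`.
#' @return results data.frame (see [pool_and_finalize()] plus `phenotype`,
#'   `significant`, `lambda_group`); attributes `cutoff`, `n_tests`, `qc`,
#'   `mixtures`.
#' @export
run_study <- function(study, config = study_config()) {
  G <- study$G
  qc <- NULL
  if (config$do_qc) {
    qc <- qc_filter(G, config$qc)
    G <- G[, qc$pass, drop = FALSE]
  }
  ann <- build_annotations(study$annotations_raw, n_rbp = config$n_rbp)
  qual <- suppressWarnings(
    assign_qualifying(ann, thresholds = config$thresholds,
                      known_genes = unique(study$map$gene_id)))
  qual <- qual[qual$variant_id %in% colnames(G), , drop = FALSE]
  positions <- stats::setNames(study$map$pos, study$map$variant_id)
  genes <- sort(unique(qual$gene_id))

  res_all <- list()
  mixtures_all <- list()
  for (ph in colnames(study$phenotypes)) {
    y_raw <- study$phenotypes[, ph]
    ok <- !is.na(y_raw) & stats::complete.cases(study$X)
    y <- y_raw[ok]
    if (config$int_transform) y <- inverse_normal_transform(y)
    X <- study$X[ok, , drop = FALSE]
    Gp <- G[ok, , drop = FALSE]
    null <- fit_null_ols(y, X)
    col_of <- match(qual$variant_id, colnames(Gp))
    records <- vector("list", length(genes))
    for (gi in seq_along(genes)) {
      gene <- genes[gi]
      sel <- which(qual$gene_id == gene & !is.na(col_of))
      if (!length(sel)) next
      Gg <- Gp[, col_of[sel], drop = FALSE]
      qual_g <- qual[sel, , drop = FALSE]
      recs <- lapply(config$categories, function(cat) {
        test_gene_category(gene, Gg, qual_g, y, X, cat,
                           positions = positions, config = config,
                           null = null)
      })
      records[[gi]] <- do.call(c, recs)
    }
    records <- do.call(c, records)
    res <- pool_and_finalize(records, config)
    if (nrow(res)) {
      res <- cbind(phenotype = ph, res, stringsAsFactors = FALSE)
      res_all[[ph]] <- res
      mixtures_all[[ph]] <- attr(res, "mixtures")
    }
  }
  results <- do.call(rbind, res_all)
  if (is.null(results) || !nrow(results)) {
    return(structure(data.frame(), cutoff = NA_real_, n_tests = 0L,
                     qc = qc, mixtures = mixtures_all))
  }
  rownames(results) <- NULL
  n_tests <- nrow(results)
  cutoff <- bonferroni_cutoff(config$alpha, n_tests)
  results$significant <- results$final_p < cutoff
  results$lambda_group <- NA_real_
  grp <- paste(results$phenotype, results$category, results$test_type)
  for (g in unique(grp)) {
    i <- grp == g
    results$lambda_group[i] <- lambda_gc(results$final_p[i])
  }
  structure(results, cutoff = cutoff, n_tests = n_tests, qc = qc,
            mixtures = mixtures_all)
}
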