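#' Missense impact score
#'
#' Averages the deleteriousness probabilities implied by a SIFT score and a
#' PolyPhen-2 score. SIFT reports the probability of being tolerated, so it
#' enters as `1 - sift`; PolyPhen reports the probability of being damaging
#' and enters directly. The result is the mean predicted probability of the
#' variant being deleterious and is used both to filter and to weight
#' missense variants.
#'
#' @param sift numeric vector of SIFT scores in \[0, 1\] (0 = deleterious).
#' @param polyphen numeric vector of PolyPhen-2 scores in \[0, 1\]
#'   (1 = probably damaging).
#' @param variant_id optional ids used in error messages.
#' @return numeric vector of impact scores in \[0, 1\]:
#'   `((1 - sift) + polyphen) / 2`.
#' @examples
#' impact_score(0, 1)        # 1: extreme deleterious
#' impact_score(0.2, 0.8)    # 0.8
#' @export
impact_score <- function(sift, polyphen, variant_id = NULL) {
  .check_unit_interval(sift, "sift", variant_id)
  .check_unit_interval(polyphen, "polyphen", variant_id)
  if (length(sift) != length(polyphen)) {
    stop("invalid annotation: sift and polyphen must have equal length")
  }
  ((1 - sift) + polyphen) / 2
}

#' Splice-variant weight from SpliceAI delta scores
#'
#' The weight of a predicted splice variant is the maximum of its four
#' SpliceAI delta scores (acceptor gain/loss, donor gain/loss).
#'
#' @param deltas numeric vector of length 4, or an m x 4 matrix (one row per
#'   variant), entries in \[0, 1\].
#' @param variant_id optional ids used in error messages.
#' @return numeric scalar (or length-m vector) of weights.
#' @export
splice_weight <- function(deltas, variant_id = NULL) {
  if (is.matrix(deltas)) {
    if (ncol(deltas) != 4L) {
      stop("invalid annotation: expected exactly 4 SpliceAI delta scores",
           .var_msg(variant_id))
    }
    .check_unit_interval(as.numeric(deltas), "delta", variant_id)
    return(apply(deltas, 1L, max))
  }
  if (length(deltas) != 4L) {
    stop("invalid annotation: expected exactly 4 SpliceAI delta scores",
         .var_msg(variant_id))
  }
  .check_unit_interval(deltas, "delta", variant_id)
  max(deltas)
}

#' RNA-binding-protein variant effect vector and weight
#'
#' Variant effects on RBP binding are the differences between the predicted
#' binding probabilities under the alternative and the reference allele,
#' one entry per RBP model output. The variant weight is the largest
#' absolute effect.
#'
#' @param p_alt numeric vector (length R) of binding probabilities for the
#'   alternative allele, or an m x R matrix.
#' @param p_ref matching probabilities for the reference allele.
#' @param variant_id optional ids used in error messages.
#' @return a list with `effect` (vector, or m x R matrix) with entries in
#'   \[-1, 1\], and `weight` (scalar or length-m vector), the max absolute
#'   entry per variant.
#' @export
rbp_effect <- function(p_alt, p_ref, variant_id = NULL) {
  if (is.matrix(p_alt) != is.matrix(p_ref) ||
      length(p_alt) != length(p_ref) ||
      (is.matrix(p_alt) && ncol(p_alt) != ncol(p_ref))) {
    stop("invalid annotation: p_alt and p_ref dimensions differ",
         .var_msg(variant_id))
  }
  .check_unit_interval(as.numeric(p_alt), "p_alt", variant_id)
  .check_unit_interval(as.numeric(p_ref), "p_ref", variant_id)
  v <- p_alt - p_ref
  w <- if (is.matrix(v)) apply(abs(v), 1L, max) else max(abs(v))
  list(effect = v, weight = w)
}

#' Default qualifying-variant thresholds
#'
#' Inclusion thresholds per variant category: missense variants need an
#' impact score of at least 0.8 (or rescue, see [assign_qualifying()]),
#' splice variants a maximum delta score of at least 0.1, RBP variants a
#' maximum absolute effect of at least 0.25. pLOF variants always qualify
#' with weight 1.
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(missense = 0.8, splice = 0.1, rbp = 0.25)
}

#' Build per-variant annotations from a raw annotation table
#'
#' Converts a raw annotation table (one row per variant x gene x category,
#' carrying predictor outputs) into scored annotations: category weights via
#' [impact_score()], [splice_weight()] and [rbp_effect()], pLOF weights fixed
#' at 1. Missense rows missing either SIFT or PolyPhen are dropped with a
#' warning (both scores are required for the impact score).
#'
#' @param raw data.frame with columns `variant_id`, `gene_id`, `category`
#'   (one of pLOF, missense, splice, rbp), `strand`, and per category:
#'   `sift`, `polyphen`, `aa_position` (missense); `delta_ag`, `delta_al`,
#'   `delta_dg`, `delta_dl` (splice); `rbp_ref_1..R`, `rbp_alt_1..R` (rbp);
#'   optional logical `is_plof` marking dual-annotated splice/rbp variants.
#' @param n_rbp number of RBP model outputs R (default 8).
#' @return data.frame of class `variant_annotation` with columns
#'   `variant_id`, `gene_id`, `category`, `weight`, `aa_position`, `strand`,
#'   `is_also_plof`, and a list column `effect_vector` (non-NULL for rbp
#'   rows only).
#' @export
build_annotations <- function(raw, n_rbp = 8L) {
  stopifnot(is.data.frame(raw))
  need <- c("variant_id", "gene_id", "category", "strand")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("annotation table missing columns: ",
                         paste(miss, collapse = ", "))
  cat_ok <- raw$category %in% c("pLOF", "missense", "splice", "rbp")
  if (!all(cat_ok)) stop("unknown variant category: ",
                         paste(unique(raw$category[!cat_ok]), collapse = ", "))
  key <- paste(raw$variant_id, raw$gene_id, raw$category)
  if (anyDuplicated(key)) stop("duplicated (variant, gene, category) rows")

  n <- nrow(raw)
  weight <- rep(NA_real_, n)
  aa_position <- rep(NA_integer_, n)
  effect_vector <- vector("list", n)
  keep <- rep(TRUE, n)

  i <- raw$category == "pLOF"
  weight[i] <- 1

  i <- which(raw$category == "missense")
  if (length(i)) {
    s <- raw$sift[i]; p <- raw$polyphen[i]
    ok <- is.finite(s) & is.finite(p)
    if (any(!ok)) {
      warning(sum(!ok), " missense variant(s) dropped: missing SIFT/PolyPhen")
      keep[i[!ok]] <- FALSE
    }
    weight[i[ok]] <- impact_score(s[ok], p[ok], raw$variant_id[i[ok]])
    aa_position[i] <- as.integer(raw$aa_position[i])
    if (anyNA(aa_position[i][ok])) {
      stop("invalid annotation: missense variants require aa_position")
    }
  }

  i <- which(raw$category == "splice")
  if (length(i)) {
    d <- as.matrix(raw[i, c("delta_ag", "delta_al", "delta_dg", "delta_dl")])
    weight[i] <- splice_weight(d, raw$variant_id[i])
  }

  i <- which(raw$category == "rbp")
  if (length(i)) {
    ref_cols <- paste0("rbp_ref_", seq_len(n_rbp))
    alt_cols <- paste0("rbp_alt_", seq_len(n_rbp))
    if (!all(c(ref_cols, alt_cols) %in% names(raw))) {
      stop("annotation table missing RBP probability columns for R = ", n_rbp)
    }
    eff <- rbp_effect(as.matrix(raw[i, alt_cols]), as.matrix(raw[i, ref_cols]),
                      raw$variant_id[i])
    weight[i] <- eff$weight
    ev <- eff$effect
    for (k in seq_along(i)) effect_vector[[i[k]]] <- as.numeric(ev[k, ])
  }

  is_also_plof <- if ("is_plof" %in% names(raw)) {
    as.logical(raw$is_plof) & raw$category != "pLOF"
  } else rep(FALSE, n)
  is_also_plof[is.na(is_also_plof)] <- FALSE

  out <- data.frame(variant_id = raw$variant_id, gene_id = raw$gene_id,
                    category = raw$category, weight = weight,
                    aa_position = aa_position, strand = raw$strand,
                    is_also_plof = is_also_plof, stringsAsFactors = FALSE)
  out$effect_vector <- effect_vector
  out <- out[keep, , drop = FALSE]
  class(out) <- c("variant_annotation", "data.frame")
  out
}

#' Select qualifying variants per gene and category
#'
#' Applies the category inclusion thresholds to scored annotations:
#' \itemize{
#'   \item pLOF variants always qualify (weight 1);
#'   \item missense variants qualify if their impact score is at least the
#'     missense threshold, *or* if they affect an amino-acid position at
#'     which another variant of the same gene reaches that threshold
#'     (position rescue rule);
#'   \item splice variants qualify if their weight (max delta score) meets
#'     the splice threshold;
#'   \item rbp variants qualify if their weight (max absolute effect) meets
#'     the rbp threshold.
#' }
#' The result is independent of input row order.
#'
#' @param annotations a `variant_annotation` data.frame from
#'   [build_annotations()].
#' @param thresholds named list as from [default_thresholds()].
#' @param known_genes optional character vector; variants referencing other
#'   genes are skipped with a warning.
#' @return the qualifying subset, sorted by (gene, category, variant),
#'   with attribute `n_skipped_unknown_gene`.
#' @export
assign_qualifying <- function(annotations, thresholds = default_thresholds(),
                              known_genes = NULL) {
  stopifnot(inherits(annotations, "variant_annotation") ||
            is.data.frame(annotations))
  ann <- annotations
  n_skipped <- 0L
  if (!is.null(known_genes)) {
    unknown <- !(ann$gene_id %in% known_genes)
    if (any(unknown)) {
      n_skipped <- sum(unknown)
      warning(n_skipped, " variant(s) reference unknown genes; skipped")
      ann <- ann[!unknown, , drop = FALSE]
    }
  }

  qual <- logical(nrow(ann))
  qual[ann$category == "pLOF"] <- TRUE
  qual[ann$category == "splice"] <- ann$weight[ann$category == "splice"] >=
    thresholds$splice
  qual[ann$category == "rbp"] <- ann$weight[ann$category == "rbp"] >=
    thresholds$rbp

  mis <- which(ann$category == "missense")
  if (length(mis)) {
    direct <- ann$weight[mis] >= thresholds$missense
    # rescue: any position (within gene) holding a direct-qualifying variant
    pos_key <- paste(ann$gene_id[mis], ann$aa_position[mis])
    rescued_pos <- unique(pos_key[direct])
    qual[mis] <- direct | (pos_key %in% rescued_pos)
  }

  out <- ann[qual, , drop = FALSE]
  out <- out[order(out$gene_id, out$category, out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped_unknown_gene") <- n_skipped
  out
}

.var_msg <- function(variant_id) {
  if (is.null(variant_id)) "" else paste0(" (variant ",
                                          paste(variant_id, collapse = ","),
                                          ")")
}

.check_unit_interval <- function(x, what, variant_id = NULL) {
  bad <- !is.finite(x) | x < 0 | x > 1
  if (any(bad)) {
    id <- if (!is.null(variant_id) && length(variant_id) == length(x)) {
      variant_id[bad][1]
    } else variant_id
    stop("invalid annotation: ", what, " outside [0, 1]", .var_msg(id))
  }
  invisible(TRUE)
}
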