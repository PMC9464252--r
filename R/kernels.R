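#' Kernel factor objects
#'
#' A kernel factor is the n x g matrix phi(G) whose cross-product
#' phi %*% t(phi) is the gene's kernel matrix. Columns represent variants,
#' amino-acid positions, or a collapsed pLOF burden depending on the design.
#'
#' @param matrix n x g numeric matrix.
#' @param labels length-g column labels.
#' @param design one of "collapse_max", "linear", "local_collapse", "rbp".
#' @param centered logical; TRUE once columns are mean-centered.
#' @return object of class `kernel_factor`.
#' @export
kernel_factor <- function(matrix, labels, design, centered = TRUE) {
  stopifnot(is.matrix(matrix), length(labels) == ncol(matrix))
  structure(list(matrix = matrix, labels = as.character(labels),
                 design = design, centered = centered),
            class = "kernel_factor")
}

#' @export
print.kernel_factor <- function(x, ...) {
  cat(sprintf("kernel_factor: %d x %d, design = %s, centered = %s\n",
              nrow(x$matrix), ncol(x$matrix), x$design, x$centered))
  invisible(x)
}

#' @export
dim.kernel_factor <- function(x) dim(x$matrix)

# mean-impute missing dosages per variant, then mean-center columns
.impute_mean <- function(G) {
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2L]]
  }
  G
}

.center_cols <- function(M) sweep(M, 2L, colMeans(M))

# drop numerically zero columns (constant dosage after centering)
.drop_null_cols <- function(M, labels, tol = 1e-12) {
  keep <- colSums(M * M) > tol
  list(matrix = M[, keep, drop = FALSE], labels = labels[keep])
}

#' Max-weight burden collapsing
#'
#' Collapses a gene's qualifying variants into a single burden score per
#' individual: the largest weight among the variants that individual
#' carries (dosage >= 1), or 0 for non-carriers. With all weights equal to
#' 1 (pLOF) this is the carrier indicator. Returned uncentered; centering
#' is applied by the testing layer.
#'
#' @param G n x m dosage matrix (missing values are mean-imputed first;
#'   imputed fractional dosages do not create carriers).
#' @param w length-m weights in \[0, 1\].
#' @return numeric n-vector of burden scores.
#' @export
collapse_max <- function(G, w) {
  if (!is.matrix(G) || ncol(G) == 0L) stop("empty gene: no variants")
  stopifnot(length(w) == ncol(G), all(w >= 0), all(w <= 1))
  carrier <- !is.na(G) & G >= 1
  out <- numeric(nrow(G))
  for (j in order(w)) out[carrier[, j]] <- w[j]
  out
}

#' Weighted linear kernel factor
#'
#' phi = G_c diag(sqrt(w)) where G_c is the column-mean-centered dosage
#' matrix: each variant contributes an independent, weight-scaled column.
#'
#' @param G n x m dosage matrix (missing mean-imputed).
#' @param w length-m weights; zero-weight variants are dropped with a
#'   warning.
#' @param variant_ids optional column labels.
#' @return a `kernel_factor` with design "linear".
#' @export
phi_linear <- function(G, w, variant_ids = colnames(G)) {
  if (!is.matrix(G) || ncol(G) == 0L) stop("empty gene: no variants")
  stopifnot(length(w) == ncol(G))
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(ncol(G)))
  if (any(w == 0)) {
    warning(sum(w == 0), " zero-weight variant(s) dropped")
    G <- G[, w > 0, drop = FALSE]
    variant_ids <- variant_ids[w > 0]
    w <- w[w > 0]
  }
  Gc <- .center_cols(.impute_mean(G))
  M <- sweep(Gc, 2L, sqrt(w), `*`)
  z <- .drop_null_cols(M, variant_ids)
  kernel_factor(z$matrix, z$labels, "linear")
}

#' Locally collapsing kernel factor
#'
#' Groups variants hitting the same amino-acid position of a gene and sums
#' their weighted centered dosages into one column per position:
#' phi = G_c diag(sqrt(w)) C, where the collapsing matrix C assigns
#' variant i to its position group with entry `signs[i]` (all +1 for
#' unsigned variant effect predictions). With all positions distinct this
#' reduces exactly to the weighted linear kernel.
#'
#' @param G n x m dosage matrix.
#' @param w length-m weights.
#' @param aa_positions length-m amino-acid positions (no missing values).
#' @param signs length-m effect signs in \{-1, +1\}; default all +1.
#' @return a `kernel_factor` with design "local_collapse", columns labeled
#'   by amino-acid position.
#' @export
phi_local_collapse <- function(G, w, aa_positions, signs = rep(1, ncol(G))) {
  if (!is.matrix(G) || ncol(G) == 0L) stop("empty gene: no variants")
  stopifnot(length(w) == ncol(G), length(aa_positions) == ncol(G),
            all(signs %in% c(-1, 1)))
  if (anyNA(aa_positions)) {
    stop("invalid input: missing amino-acid position for local collapsing")
  }
  keep <- w > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-weight variant(s) dropped")
    G <- G[, keep, drop = FALSE]; w <- w[keep]
    aa_positions <- aa_positions[keep]; signs <- signs[keep]
  }
  Gc <- .center_cols(.impute_mean(G))
  GW <- sweep(Gc, 2L, sqrt(w) * signs, `*`)
  groups <- sort(unique(aa_positions))
  M <- vapply(groups, function(p) {
    rowSums(GW[, aa_positions == p, drop = FALSE])
  }, numeric(nrow(G)))
  if (!is.matrix(M)) M <- matrix(M, ncol = length(groups))
  z <- .drop_null_cols(M, as.character(groups))
  kernel_factor(z$matrix, z$labels, "local_collapse")
}

#' Bandwidth of the Gaussian positional kernel
#'
#' Default bandwidth gamma = -log(0.5) / 50^2, chosen so that two variants
#' 50 bp apart have positional similarity exactly 0.5.
#' @return numeric scalar.
#' @export
rbp_gamma <- function() -log(0.5) / 50^2

#' Positional similarity between variants
#'
#' Gaussian kernel on base-pair distance: exp(-gamma d^2).
#'
#' @param distance base-pair distance(s).
#' @param gamma bandwidth (default [rbp_gamma()]).
#' @return similarity in (0, 1\].
#' @export
position_similarity <- function(distance, gamma = rbp_gamma()) {
  exp(-gamma * distance^2)
}

#' Directional RBP kernel factor
#'
#' Builds the variant-similarity matrix S = Q o R (elementwise product),
#' where Q holds cosine similarities of the variants' RBP effect vectors
#' (so aligned predicted effects are similar, opposing effects
#' anti-similar) and R holds Gaussian positional similarities
#' exp(-gamma (x_i - x_j)^2). The factor is phi = G_c diag(sqrt(w)) L with
#' L the (lower) Cholesky factor of S. If S is numerically singular, a
#' ridge of 1e-8 tr(S)/m is added and escalated tenfold up to 1e-4 tr(S)/m
#' before failing.
#'
#' @param G n x m dosage matrix.
#' @param w length-m weights.
#' @param effect_vectors m x R matrix of RBP effect vectors (no all-zero
#'   rows; zero-weight variants must be excluded upstream).
#' @param positions length-m chromosomal positions (bp).
#' @param gamma Gaussian bandwidth, default [rbp_gamma()].
#' @param gene_id used in error messages.
#' @return a `kernel_factor` with design "rbp"; attribute `S` carries the
#'   similarity matrix.
#' @export
phi_rbp <- function(G, w, effect_vectors, positions, gamma = rbp_gamma(),
                    gene_id = NULL) {
  if (!is.matrix(G) || ncol(G) == 0L) stop("empty gene: no variants")
  m <- ncol(G)
  stopifnot(length(w) == m, nrow(effect_vectors) == m,
            length(positions) == m)
  nrm <- sqrt(rowSums(effect_vectors^2))
  if (any(nrm == 0)) {
    stop("invalid input: zero RBP effect vector (exclude weight-0 variants)")
  }
  V <- effect_vectors / nrm
  Q <- tcrossprod(V)
  R <- exp(-gamma * outer(positions, positions, `-`)^2)
  S <- Q * R
  L <- .chol_ridge(S, gene_id)
  Gc <- .center_cols(.impute_mean(G))
  M <- sweep(Gc, 2L, sqrt(w), `*`) %*% L
  labels <- colnames(G)
  if (is.null(labels)) labels <- paste0("v", seq_len(m))
  z <- .drop_null_cols(M, labels)
  kf <- kernel_factor(z$matrix, z$labels, "rbp")
  attr(kf, "S") <- S
  kf
}

.chol_ridge <- function(S, gene_id = NULL) {
  m <- nrow(S)
  base_ridge <- 1e-8 * sum(diag(S)) / m
  for (ridge in c(0, base_ridge * 10^(0:4))) {
    L <- tryCatch(t(chol(S + diag(ridge, m))), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  stop("numerical kernel error: similarity matrix not positive definite",
       if (!is.null(gene_id)) paste0(" (gene ", gene_id, ")") else "")
}

#' Concatenate a collapsed pLOF burden to a kernel factor
#'
#' Appends the mean-centered pLOF burden (from [collapse_max()] over the
#' gene's pLOF variants) as an extra column labeled "pLOF", for joint
#' category + pLOF kernel tests. Variants dually annotated in the category
#' and as pLOF must be removed from the category side before building
#' `phi` (they count once, as pLOF). An all-zero burden leaves the factor
#' unchanged; an empty pLOF set returns `phi` with attribute
#' `plof_missing` set.
#'
#' @param phi a `kernel_factor` (may have zero columns).
#' @param plof_burden numeric n-vector, or NULL when the gene has no pLOF
#'   variants.
#' @return a `kernel_factor` with at most one extra column.
#' @export
concat_plof <- function(phi, plof_burden) {
  stopifnot(inherits(phi, "kernel_factor"))
  if (is.null(plof_burden) || length(plof_burden) == 0L) {
    attr(phi, "plof_missing") <- TRUE
    return(phi)
  }
  stopifnot(length(plof_burden) == nrow(phi$matrix) ||
              ncol(phi$matrix) == 0L)
  b <- plof_burden - mean(plof_burden)
  if (sum(b * b) <= 1e-12) return(phi)
  kernel_factor(cbind(phi$matrix, b), c(phi$labels, "pLOF"), phi$design)
}
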