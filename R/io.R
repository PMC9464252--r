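#' Read PLINK bed/bim/fam genotypes
#'
#' Decodes variant-major PLINK 1 binary genotypes to minor-allele dosages
#' with explicit missing values. If the A1 allele of a variant is in fact
#' the major allele in this sample, the dosage is flipped so that it
#' always counts the minor allele (MAF <= 0.5).
#'
#' @param prefix path prefix; `<prefix>.bed/.bim/.fam` must exist.
#'   Alternatively pass explicit paths via `bed`, `bim`, `fam`.
#' @param bed,bim,fam explicit file paths (override `prefix`).
#' @return list with `G` (n x m dosage matrix, NA = missing; rownames =
#'   sample ids, colnames = variant ids "chrom:pos:ref:alt") and `map`
#'   (data.frame: variant_id, gene_id = NA, chrom, pos, ref, alt,
#'   flipped).
#' @export
read_plink <- function(prefix = NULL, bed = NULL, bim = NULL, fam = NULL) {
  if (!is.null(prefix)) {
    bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
    fam <- paste0(prefix, ".fam")
  }
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop("format error: missing file ", f)
  }
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("chrom", "id", "cm", "pos",
                                            "a1", "a2"))
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam_df); m <- nrow(bim_df)
  sample_ids <- as.character(fam_df[[2]])

  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("format error: bad PLINK bed magic bytes")
  }
  if (raw[3] != as.raw(0x01)) {
    stop("format error: only variant-major bed files are supported")
  }
  bpv <- ceiling(n / 4)  # bytes per variant
  if (length(raw) - 3 != bpv * m) {
    stop("format error: bed payload does not match bim/fam dimensions")
  }
  payload <- raw[-(1:3)]
  # 2-bit codes per sample, low bits first: 00 hom A1, 01 missing,
  # 10 het, 11 hom A2; dosage counts A1
  b <- matrix(as.integer(payload), nrow = bpv)
  quarters <- matrix(0L, 4L * bpv, m)
  quarters[seq(1L, 4L * bpv, 4L), ] <- b %% 4L
  quarters[seq(2L, 4L * bpv, 4L), ] <- (b %/% 4L) %% 4L
  quarters[seq(3L, 4L * bpv, 4L), ] <- (b %/% 16L) %% 4L
  quarters[seq(4L, 4L * bpv, 4L), ] <- b %/% 64L
  quarters <- quarters[seq_len(n), , drop = FALSE]
  lookup <- c(2, NA, 1, 0)  # code 0..3 -> A1 dosage
  G <- matrix(lookup[quarters + 1L], n, m)

  flipped <- logical(m)
  for (j in seq_len(m)) {
    af <- mean(G[, j], na.rm = TRUE) / 2
    if (is.finite(af) && af > 0.5) {
      G[, j] <- 2 - G[, j]
      flipped[j] <- TRUE
    }
  }
  ref <- ifelse(flipped, bim_df$a1, bim_df$a2)
  alt <- ifelse(flipped, bim_df$a2, bim_df$a1)
  vid <- sprintf("%s:%d:%s:%s", bim_df$chrom, bim_df$pos, ref, alt)
  dimnames(G) <- list(sample_ids, vid)
  list(G = G,
       map = data.frame(variant_id = vid, gene_id = NA_character_,
                        chrom = as.character(bim_df$chrom),
                        pos = bim_df$pos, ref = ref, alt = alt,
                        flipped = flipped, stringsAsFactors = FALSE))
}

#' Write PLINK bed/bim/fam genotypes
#'
#' Writes a dosage matrix (minor-allele counts, NA = missing) as a
#' variant-major PLINK 1 fileset; A1 is the minor (counted) allele.
#'
#' @param prefix output path prefix.
#' @param G n x m dosage matrix.
#' @param map data.frame with variant_id, chrom, pos, ref, alt.
#' @param sample_ids character vector of n sample ids.
#' @return invisibly, the prefix.
#' @export
write_plink <- function(prefix, G, map, sample_ids) {
  stopifnot(nrow(map) == ncol(G), length(sample_ids) == nrow(G))
  n <- nrow(G); m <- ncol(G)
  utils::write.table(
    data.frame(map$chrom, map$variant_id, 0L, map$pos, map$alt, map$ref),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(sample_ids, sample_ids, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  code <- matrix(0L, n, m)   # dosage -> 2-bit code (A1 = alt = minor)
  code[is.na(G)] <- 1L
  code[!is.na(G) & G == 1] <- 2L
  code[!is.na(G) & G == 0] <- 3L
  bpv <- ceiling(n / 4)
  pad <- matrix(3L, 4 * bpv - n, m)  # pad as hom-major
  full <- rbind(code, pad)
  dim(full) <- c(4L, bpv * m)
  bytes <- as.raw(full[1, ] + 4L * full[2, ] + 16L * full[3, ] +
                    64L * full[4, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), bytes), con)
  invisible(prefix)
}

.read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("unreadable input: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss)) stop(path, " missing required columns: ",
                           paste(miss, collapse = ", "))
  }
  df
}

#' Read phenotype and covariate tables
#'
#' Sample-ID-keyed TSVs with headers; the two tables are joined on
#' `sample_id`. Unknown sample ids in either table (relative to
#' `sample_ids`, when supplied) are an error.
#'
#' @param pheno_path TSV with `sample_id` plus one column per phenotype.
#' @param covar_path TSV with `sample_id` plus covariate columns.
#' @param sample_ids optional reference sample ordering (e.g. from the fam
#'   file); the returned tables are aligned to it.
#' @return list with `phenotypes` (matrix), `X` (covariate matrix with
#'   intercept prepended), `sample_ids`.
#' @export
read_sample_tables <- function(pheno_path, covar_path, sample_ids = NULL) {
  ph <- .read_tsv(pheno_path, "sample_id")
  cv <- .read_tsv(covar_path, "sample_id")
  if (anyDuplicated(ph$sample_id) || anyDuplicated(cv$sample_id)) {
    stop("duplicated sample ids in phenotype or covariate table")
  }
  ids <- if (is.null(sample_ids)) ph$sample_id else sample_ids
  for (tab in list(ph, cv)) {
    unknown <- setdiff(tab$sample_id, ids)
    if (length(unknown)) stop("unknown sample ids: ",
                              paste(utils::head(unknown, 5), collapse = ", "))
  }
  ph <- ph[match(ids, ph$sample_id), , drop = FALSE]
  cv <- cv[match(ids, cv$sample_id), , drop = FALSE]
  X <- cbind(intercept = 1,
             as.matrix(cv[, setdiff(names(cv), "sample_id"), drop = FALSE]))
  pheno <- as.matrix(ph[, setdiff(names(ph), "sample_id"), drop = FALSE])
  rownames(pheno) <- ids; rownames(X) <- ids
  list(phenotypes = pheno, X = X, sample_ids = ids)
}

#' Read a raw variant-annotation TSV
#'
#' @param path TSV with header; columns as documented in
#'   [build_annotations()]; missing-value token "NA".
#' @return data.frame (raw annotations; duplicated
#'   (variant, gene, category) rows are an error).
#' @export
read_annotation_table <- function(path) {
  df <- .read_tsv(path, c("variant_id", "gene_id", "category", "strand"))
  key <- paste(df$variant_id, df$gene_id, df$category)
  if (anyDuplicated(key)) stop("duplicated variant annotation rows in ", path)
  df
}

#' Read a gene-definition TSV
#' @param path TSV with columns gene_id, chrom, start, end, strand.
#' @return data.frame.
#' @export
read_gene_table <- function(path) {
  .read_tsv(path, c("gene_id", "chrom", "start", "end", "strand"))
}

#' Write the study tables of a simulated study
#'
#' Writes phenotype, covariate, annotation and gene TSVs alongside the
#' PLINK fileset so the pipeline ingests simulated data through the same
#' readers as real data.
#'
#' @param dir output directory.
#' @param study a study bundle from [sim_study()].
#' @return invisibly, the directory.
#' @export
write_study_tables <- function(dir, study) {
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  w(data.frame(sample_id = study$sample_ids, study$phenotypes,
               check.names = FALSE), "pheno.tsv")
  w(data.frame(sample_id = study$sample_ids,
               study$X[, setdiff(colnames(study$X), "intercept"),
                       drop = FALSE], check.names = FALSE), "covar.tsv")
  w(study$annotations_raw, "annot.tsv")
  genes <- do.call(rbind, lapply(split(study$map, study$map$gene_id),
    function(d) data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
                           start = min(d$pos), end = max(d$pos),
                           strand = d$strand[1])))
  w(genes, "genes.tsv")
  invisible(dir)
}

#' Write a results table
#'
#' Writes gene-level association results as TSV with a stable column order
#' and deterministic row ordering by (phenotype, gene, category,
#' test type); p-values are written in scientific notation with 6
#' significant digits.
#'
#' @param results data.frame from [run_study()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_results <- function(results, path) {
  cols <- c("phenotype", "gene_id", "category", "test_type", "n_variants",
            "n_carriers", "score_stat", "score_p", "rlrt_stat", "rlrt_p",
            "combined_p", "final_p", "lrt_triggered", "significant",
            "lambda_group")
  out <- results[, intersect(cols, names(results)), drop = FALSE]
  if (nrow(out)) {
    out <- out[order(out$phenotype, out$gene_id, out$category,
                     out$test_type), , drop = FALSE]
    for (cc in intersect(c("score_p", "rlrt_p", "combined_p", "final_p"),
                         names(out))) {
      out[[cc]] <- ifelse(is.na(out[[cc]]), NA,
                          format(out[[cc]], digits = 7, scientific = TRUE))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
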