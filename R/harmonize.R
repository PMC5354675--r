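# Unit conversions, gene-universe intersection, variance filtering, cohort
# correlation and PCA embedding.

#' Convert RPKM to TPM
#'
#' Rescales each sample so that TPM_g = RPKM_g / sum_g(RPKM_g) * 1e6; every
#' column of the result sums to one million.
#'
#' @param x An [expression_matrix()] with unit `RPKM`.
#' @return An [expression_matrix()] with unit `TPM`.
#' @export
rpkm_to_tpm <- function(x) {
  .check(inherits(x, "expression_matrix"), "'x' must be an expression_matrix")
  .check(x$unit == "RPKM", "input unit must be RPKM")
  csum <- colSums(x$values)
  zero <- which(csum <= 0)
  if (length(zero)) {
    stop("degenerate sample: all-zero expression column: ",
         paste(colnames(x$values)[zero], collapse = ", "), call. = FALSE)
  }
  expression_matrix(sweep(x$values, 2L, csum, "/") * 1e6, unit = "TPM",
                    sample_class = x$sample_class)
}

#' Log-transform TPM values
#'
#' Computes log2(TPM/d + 1) with d = 10 for single-cell libraries (whose
#' complexity is roughly an order of magnitude below bulk, so TPM is divided
#' by 10 before the offset) and d = 1 otherwise.
#'
#' @param x An [expression_matrix()] with unit `TPM`.
#' @param single_cell_scale If `TRUE`, divide TPM by 10 before `log2(. + 1)`.
#' @return An [expression_matrix()] with unit `LOG2_TPM1`.
#' @export
to_log_tpm <- function(x, single_cell_scale = FALSE) {
  .check(inherits(x, "expression_matrix"), "'x' must be an expression_matrix")
  .check(x$unit == "TPM", "input unit must be TPM")
  .check(all(x$values >= 0), "domain error: negative TPM value")
  d <- if (single_cell_scale) 10 else 1
  expression_matrix(log2(x$values / d + 1), unit = "LOG2_TPM1",
                    sample_class = x$sample_class)
}

#' Restrict matrices to their shared gene universe
#'
#' Intersects the gene identifiers of two or more expression matrices
#' (exact-string matching) and returns each matrix restricted to the shared
#' genes in a common order (the order of the first matrix). Values are
#' untouched.
#'
#' @param ... Two or more [expression_matrix()] objects.
#' @return A list of expression matrices over the identical gene universe.
#' @export
intersect_universe <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1L]]) &&
      !inherits(mats[[1L]], "expression_matrix")) {
    mats <- mats[[1L]]
  }
  .check(length(mats) >= 2L, "need at least two matrices")
  .check(all(vapply(mats, inherits, logical(1), "expression_matrix")),
         "all inputs must be expression_matrix objects")
  shared <- Reduce(intersect, lapply(mats, genes))
  if (length(shared) == 0L) {
    stop("empty gene intersection across matrices", call. = FALSE)
  }
  shared <- genes(mats[[1L]])[genes(mats[[1L]]) %in% shared]
  lapply(mats, function(m) {
    expression_matrix(m$values[shared, , drop = FALSE], unit = m$unit,
                      sample_class = m$sample_class)
  })
}

#' Select the most variable genes
#'
#' Ranks genes by sample variance (denominator n-1) across all samples and
#' returns the top `k`; ties are broken by lexicographic gene id so the
#' selection is deterministic.
#'
#' @param x An [expression_matrix()].
#' @param k Number of genes to keep (`0 < k <=` number of genes).
#' @return Character vector of `k` gene identifiers.
#' @export
top_variance_genes <- function(x, k) {
  .check(inherits(x, "expression_matrix"), "'x' must be an expression_matrix")
  .check(.is_number(k) && k >= 1, "'k' must be a positive integer")
  .check(k <= nrow(x$values), "'k' exceeds the number of genes")
  v <- apply(x$values, 1L, stats::var)
  ord <- order(-v, rownames(x$values), method = "radix")
  rownames(x$values)[ord][seq_len(k)]
}

#' Pearson correlation of mean expression profiles
#'
#' Computes the per-gene mean of each group (on the log scale the matrices
#' carry) and returns the Pearson correlation between the two mean vectors —
#' the cohort-level similarity statistic.
#'
#' @param group_a,group_b [expression_matrix()] objects over the same gene
#'   universe, with at least three genes.
#' @return Pearson r (scalar).
#' @export
mean_profile_correlation <- function(group_a, group_b) {
  .check(identical(genes(group_a), genes(group_b)),
         "matrices must share an identical gene universe")
  .check(nrow(group_a$values) >= 3L, "need at least 3 genes")
  ma <- rowMeans(group_a$values)
  mb <- rowMeans(group_b$values)
  if (stats::sd(ma) == 0 || stats::sd(mb) == 0) {
    stop("undefined correlation: a mean profile has zero variance",
         call. = FALSE)
  }
  stats::cor(ma, mb)
}

#' Principal component embedding of samples
#'
#' Centers each gene across samples (no scaling to unit variance) and embeds
#' samples on the leading principal components. Component signs are fixed so
#' the largest-magnitude gene loading of each component is positive.
#'
#' @param x An [expression_matrix()].
#' @param genes Genes to use (e.g. from [top_variance_genes()]); default all.
#' @param n_components Number of components (>= 1, <= min(genes, samples)).
#' @return A list of class `pca_embedding` with `samples`, `coordinates`
#'   (samples x components), `loadings` (genes x components) and
#'   `explained_variance` (fraction of total variance per component).
#' @export
pca_embed <- function(x, genes = NULL, n_components = 2L) {
  .check(inherits(x, "expression_matrix"), "'x' must be an expression_matrix")
  .check(.is_number(n_components) && n_components >= 1,
         "'n_components' must be >= 1")
  v <- x$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    .check(length(missing) == 0L,
           paste("genes absent from matrix:", paste(missing, collapse = ", ")))
    v <- v[genes, , drop = FALSE]
  }
  .check(n_components <= min(dim(v)),
         "'n_components' exceeds min(genes, samples)")
  pr <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  total_var <- sum(pr$sdev^2)
  k <- n_components
  coords <- pr$x[, seq_len(k), drop = FALSE]
  loads <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loads[, j]))
    if (loads[i, j] < 0) {
      loads[, j] <- -loads[, j]
      coords[, j] <- -coords[, j]
    }
  }
  structure(list(samples = colnames(v), coordinates = coords,
                 loadings = loads,
                 explained_variance = pr$sdev[seq_len(k)]^2 / total_var),
            class = "pca_embedding")
}
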