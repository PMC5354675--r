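# Ranking of cell lines by mean transcriptome correlation to single
# malignant cells, control-matched MITF/AXL program scoring, selection of
# state-extreme cells, gene-set enrichment statistics, and kernel-density
# clustering of lines into MITF/AXL/intermediate states.

#' Rank cell lines by mean correlation to single malignant cells
#'
#' For each line, computes the Pearson correlation with every single cell
#' over all shared genes (log scale) and averages over cells. Pairs involving
#' a zero-variance profile are skipped rather than scored 0; a line with no
#' scorable pair is an error. Output is sorted by decreasing mean r with ties
#' broken by line id.
#'
#' @param cell_lines,cells [expression_matrix()] objects over the identical
#'   gene universe, on a log scale.
#' @param cell_subset Optional character vector of cell ids to restrict to
#'   (e.g. the MITF-top or AXL-top cells from [select_extreme_cells()]).
#' @return data.frame with columns `line`, `mean_r`, `n_pairs` (cells used),
#'   ordered from most to least tumour-like.
#' @export
rank_by_single_cell_correlation <- function(cell_lines, cells,
                                            cell_subset = NULL) {
  .check(identical(genes(cell_lines), genes(cells)),
         "matrices must share an identical gene universe")
  cv <- cells$values
  if (!is.null(cell_subset)) {
    missing <- setdiff(cell_subset, colnames(cv))
    .check(length(missing) == 0L,
           paste("unknown cells:", paste(missing, collapse = ", ")))
    cv <- cv[, cell_subset, drop = FALSE]
  }
  .check(ncol(cv) >= 1L, "no cells to correlate against")
  r <- suppressWarnings(stats::cor(cell_lines$values, cv))
  n_skipped <- sum(is.na(r))
  if (n_skipped > 0) {
    warning(sprintf("%d zero-variance line-cell pairs skipped", n_skipped))
  }
  mean_r <- rowMeans(r, na.rm = TRUE)
  if (anyNA(mean_r) || any(!is.finite(mean_r))) {
    stop("line with no scorable cell pair: ",
         paste(names(mean_r)[!is.finite(mean_r)], collapse = ", "),
         call. = FALSE)
  }
  n_pairs <- rowSums(!is.na(r))
  ord <- order(-mean_r, colnames(cell_lines$values), method = "radix")
  data.frame(line = colnames(cell_lines$values)[ord], mean_r = mean_r[ord],
             n_pairs = n_pairs[ord], row.names = NULL,
             stringsAsFactors = FALSE)
}

# equal-frequency expression bins for control-gene matching
.expression_bins <- function(avg, n_bins) {
  rk <- rank(avg, ties.method = "first")
  pmin(pmax(ceiling(n_bins * rk / length(avg)), 1L), n_bins)
}

#' MITF/AXL program cell scores with expression-matched controls
#'
#' Relative expression is each gene centered across cells. The raw program
#' score of a cell is the mean relative expression of the program genes; the
#' control score is the mean over a pool built by binning all genes into
#' `n_bins` equal-frequency bins of average expression and drawing
#' `n_controls` genes (with replacement) from the bin of each program gene.
#' The cell score is raw minus control, removing cell-complexity bias, and
#' `ratio_key = score_mitf - score_axl` orders cells along the MITF/AXL axis.
#'
#' @param cells An [expression_matrix()] on a log scale.
#' @param mitf_set,axl_set Character vectors of program genes; members absent
#'   from the universe are dropped with a warning.
#' @param n_bins Number of average-expression bins (default 25).
#' @param n_controls Control genes drawn per program gene (default 100).
#' @param seed Integer seed for the control draws (required).
#' @param control_pools Optional list with elements `mitf` and/or `axl` of
#'   gene ids overriding the sampled control pools.
#' @return data.frame with per-cell columns `cell`, `raw_mitf`, `raw_axl`,
#'   `control_mitf`, `control_axl`, `score_mitf`, `score_axl`, `ratio_key`.
#' @export
program_cell_scores <- function(cells, mitf_set, axl_set, n_bins = 25L,
                                n_controls = 100L, seed,
                                control_pools = NULL) {
  .check(!missing(seed), "'seed' is required for the control draws")
  v <- cells$values
  universe <- rownames(v)
  filter_set <- function(s, name) {
    kept <- intersect(s, universe)
    if (length(kept) < length(s)) {
      warning(sprintf("%d %s program genes absent from universe, dropped",
                      length(s) - length(kept), name))
    }
    .check(length(kept) >= 1L,
           sprintf("%s program set empty after universe filtering", name))
    kept
  }
  mitf_set <- filter_set(mitf_set, "MITF")
  axl_set <- filter_set(axl_set, "AXL")
  rel <- v - rowMeans(v)
  bins <- .expression_bins(rowMeans(v), n_bins)
  names(bins) <- universe
  draw_pool <- function(set) {
    unlist(lapply(set, function(g) {
      pool <- universe[bins == bins[[g]]]
      pool[sample.int(length(pool), n_controls, replace = TRUE)]
    }), use.names = FALSE)
  }
  pools <- with_seed(seed, list(mitf = draw_pool(mitf_set),
                                axl = draw_pool(axl_set)))
  if (!is.null(control_pools$mitf)) pools$mitf <- control_pools$mitf
  if (!is.null(control_pools$axl)) pools$axl <- control_pools$axl
  raw_mitf <- colMeans(rel[mitf_set, , drop = FALSE])
  raw_axl <- colMeans(rel[axl_set, , drop = FALSE])
  ctl_mitf <- colMeans(rel[pools$mitf, , drop = FALSE])
  ctl_axl <- colMeans(rel[pools$axl, , drop = FALSE])
  data.frame(cell = colnames(v), raw_mitf = raw_mitf, raw_axl = raw_axl,
             control_mitf = ctl_mitf, control_axl = ctl_axl,
             score_mitf = raw_mitf - ctl_mitf, score_axl = raw_axl - ctl_axl,
             ratio_key = (raw_mitf - ctl_mitf) - (raw_axl - ctl_axl),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the MITF-top and AXL-top extreme cells
#'
#' Returns the `k` cells with the largest `ratio_key` (MITF-top) and the `k`
#' with the smallest (AXL-top); the two sets are disjoint. If fewer than `2k`
#' cells are available, `k` is reduced to `floor(n/2)` with a warning. Ties
#' at the boundary are broken by cell id.
#'
#' @param scores Output of [program_cell_scores()].
#' @param k Number of cells per extreme (default 400).
#' @return List with character vectors `mitf_top` and `axl_top`.
#' @export
select_extreme_cells <- function(scores, k = 400L) {
  n <- nrow(scores)
  .check(n >= 2L, "need at least 2 cells")
  if (2L * k > n) {
    k <- floor(n / 2)
    warning(sprintf("fewer than 2k cells; k reduced to %d", k))
  }
  top <- scores$cell[order(-scores$ratio_key, scores$cell,
                           method = "radix")][seq_len(k)]
  bottom <- scores$cell[order(scores$ratio_key, scores$cell,
                              method = "radix")][seq_len(k)]
  list(mitf_top = top, axl_top = bottom)
}

#' Gene-set enrichment statistics
#'
#' `single_sample` mode (cell-line MITF/AXL enrichment): genes are
#' standardized across samples (Z-scores, denominator n-1; zero-SD genes get
#' Z = 0) and the statistic of a set in a sample is the one-sample t of the
#' set genes' Z values against mean zero. `two_group` mode (e.g. cell lines
#' vs tumours with pathway sets): per-gene log-fold changes between the two
#' groups are computed and the statistic of a set is the Welch two-sample t
#' comparing the set genes' fold changes to the all-gene background.
#'
#' @param expr An [expression_matrix()] on a log scale.
#' @param sets Named list of gene-id character vectors; members absent from
#'   the universe are dropped. Sets left with fewer than 2 genes are flagged
#'   degenerate (statistic `NA`).
#' @param mode `"single_sample"` or `"two_group"`.
#' @param groups For `two_group`: named vector mapping every sample to one of
#'   exactly two group labels; fold change is first group level minus second
#'   (alphabetical).
#' @return `single_sample`: sets x samples numeric matrix of t statistics
#'   (`NA` where degenerate). `two_group`: data.frame with `set`,
#'   `statistic`, `p_value`, `n_genes`.
#' @export
gene_set_enrichment <- function(expr, sets,
                                mode = c("single_sample", "two_group"),
                                groups = NULL) {
  mode <- match.arg(mode)
  v <- expr$values
  universe <- rownames(v)
  sets <- lapply(sets, intersect, universe)
  .check(all(lengths(sets) >= 1L), "a set is empty after universe filtering")
  if (mode == "single_sample") {
    mu <- rowMeans(v)
    sdv <- apply(v, 1L, stats::sd)
    z <- (v - mu) / ifelse(sdv == 0, Inf, sdv)
    out <- matrix(NA_real_, nrow = length(sets), ncol = ncol(v),
                  dimnames = list(names(sets), colnames(v)))
    for (s in seq_along(sets)) {
      zg <- z[sets[[s]], , drop = FALSE]
      k <- nrow(zg)
      if (k < 2L) {
        warning(sprintf("set '%s' has < 2 genes; statistic undefined",
                        names(sets)[s]))
        next
      }
      m <- colMeans(zg)
      sd_ <- apply(zg, 2L, stats::sd)
      stat <- m / (sd_ / sqrt(k))
      stat[sd_ == 0 & m == 0] <- 0
      stat[sd_ == 0 & m != 0] <- NA_real_  # degenerate: all set genes tied off-zero
      out[s, ] <- stat
    }
    return(out)
  }
  .check(!is.null(groups), "'groups' is required in two_group mode")
  .check(all(colnames(v) %in% names(groups)),
         "'groups' must map every sample")
  g <- groups[colnames(v)]
  lev <- sort(unique(g))
  .check(length(lev) == 2L, "exactly two groups required")
  lfc <- rowMeans(v[, g == lev[1L], drop = FALSE]) -
    rowMeans(v[, g == lev[2L], drop = FALSE])
  res <- lapply(seq_along(sets), function(s) {
    gs <- sets[[s]]
    if (length(gs) < 2L) {
      warning(sprintf("set '%s' has < 2 genes; statistic undefined",
                      names(sets)[s]))
      return(data.frame(set = names(sets)[s], statistic = NA_real_,
                        p_value = NA_real_, n_genes = length(gs)))
    }
    tt <- stats::t.test(lfc[gs], lfc)
    data.frame(set = names(sets)[s], statistic = unname(tt$statistic),
               p_value = tt$p.value, n_genes = length(gs))
  })
  do.call(rbind, res)
}

# Gaussian-kernel mean-shift in bandwidth-scaled coordinates
.mean_shift_modes <- function(y, tol = 1e-8, max_iter = 500L) {
  n <- nrow(y)
  modes <- y
  for (i in seq_len(n)) {
    pt <- y[i, ]
    for (iter in seq_len(max_iter)) {
      d2 <- colSums((t(y) - pt)^2)
      wgt <- exp(-d2 / 2)
      new_pt <- colSums(y * wgt) / sum(wgt)
      if (sum((new_pt - pt)^2) < tol^2) {
        pt <- new_pt
        break
      }
      pt <- new_pt
    }
    modes[i, ] <- pt
  }
  modes
}

#' Cluster cell lines into MITF/AXL/intermediate states
#'
#' Runs Gaussian-kernel density mode-seeking (mean shift) on the 2-D
#' (MITF enrichment, AXL enrichment) coordinates with per-axis Silverman
#' bandwidths; points converging to modes closer than one bandwidth are
#' merged into one cluster. The cluster with the highest mean MITF-AXL
#' difference is labelled `MITF`, the lowest `AXL`, and all remaining
#' clusters are pooled as `INTERMEDIATE`. With fewer than two modes, lines
#' fall back to the sign of MITF-AXL with a warning. Deterministic: no
#' internal randomness.
#'
#' @param mitf_enrichment,axl_enrichment Numeric vectors over lines; names
#'   (line ids) are taken from `mitf_enrichment` if present.
#' @return Named character vector of state labels in
#'   `{"MITF","AXL","INTERMEDIATE"}`.
#' @export
cluster_program_states <- function(mitf_enrichment, axl_enrichment) {
  .check(length(mitf_enrichment) == length(axl_enrichment),
         "enrichment vectors must have equal length")
  n <- length(mitf_enrichment)
  .check(n >= 3L, "need at least 3 lines")
  x <- cbind(mitf = as.numeric(mitf_enrichment),
             axl = as.numeric(axl_enrichment))
  ids <- names(mitf_enrichment)
  if (is.null(ids)) ids <- sprintf("line%03d", seq_len(n))
  diff_score <- x[, 1L] - x[, 2L]
  h <- apply(x, 2L, stats::sd) * n^(-1 / 6)   # Silverman, d = 2
  fallback <- function(msg) {
    warning(msg)
    lab <- ifelse(diff_score >= 0, "MITF", "AXL")
    names(lab) <- ids
    lab
  }
  if (any(h == 0)) {
    return(fallback("degenerate enrichment spread; labelling by sign of MITF-AXL"))
  }
  y <- sweep(x, 2L, h, "/")
  modes <- .mean_shift_modes(y)
  # merge modes within one bandwidth (scaled distance 1), single linkage
  cluster <- integer(n)
  centers <- NULL
  for (i in seq_len(n)) {
    assigned <- FALSE
    if (!is.null(centers)) {
      d <- sqrt(colSums((t(centers) - modes[i, ])^2))
      j <- which(d < 1)
      if (length(j)) {
        cluster[i] <- j[1L]
        assigned <- TRUE
      }
    }
    if (!assigned) {
      centers <- rbind(centers, modes[i, ])
      cluster[i] <- nrow(centers)
    }
  }
  k <- max(cluster)
  if (k < 2L) {
    return(fallback("fewer than two density modes; labelling by sign of MITF-AXL"))
  }
  means <- vapply(seq_len(k), function(cl) mean(diff_score[cluster == cl]),
                  numeric(1))
  lab <- rep("INTERMEDIATE", n)
  lab[cluster == which.max(means)] <- "MITF"
  lab[cluster == which.min(means)] <- "AXL"
  names(lab) <- ids
  lab
}

#' Assemble the per-line fidelity ranking table
#'
#' Orchestrates the full ranking: overall mean correlation to all cells,
#' state-specific mean correlations against the MITF-top/AXL-top extreme
#' cells, per-line MITF/AXL gene-set enrichment, and the kernel-density
#' state clustering.
#'
#' @param cell_lines,cells Log-scale [expression_matrix()] objects over the
#'   identical gene universe.
#' @param mitf_set,axl_set Program gene sets.
#' @param k_extreme Extreme cells per state (default 400; reduced when few
#'   cells are available).
#' @param seed Seed for the control-gene draws.
#' @return data.frame with one row per line: `line`, `mean_r_all`,
#'   `mean_r_mitf_top`, `mean_r_axl_top`, `mitf_enrichment`,
#'   `axl_enrichment`, `state`; ordered by decreasing `mean_r_all`.
#' @export
rank_cell_lines <- function(cell_lines, cells, mitf_set, axl_set,
                            k_extreme = 400L, seed = 1L) {
  scores <- program_cell_scores(cells, mitf_set, axl_set, seed = seed)
  extremes <- select_extreme_cells(scores, k = k_extreme)
  r_all <- rank_by_single_cell_correlation(cell_lines, cells)
  r_mitf <- rank_by_single_cell_correlation(cell_lines, cells,
                                            cell_subset = extremes$mitf_top)
  r_axl <- rank_by_single_cell_correlation(cell_lines, cells,
                                           cell_subset = extremes$axl_top)
  enr <- gene_set_enrichment(cell_lines,
                             list(MITF = mitf_set, AXL = axl_set),
                             mode = "single_sample")
  state <- cluster_program_states(enr["MITF", r_all$line],
                                  enr["AXL", r_all$line])
  data.frame(line = r_all$line, mean_r_all = r_all$mean_r,
             mean_r_mitf_top = r_mitf$mean_r[match(r_all$line, r_mitf$line)],
             mean_r_axl_top = r_axl$mean_r[match(r_all$line, r_axl$line)],
             mitf_enrichment = enr["MITF", r_all$line],
             axl_enrichment = enr["AXL", r_all$line],
             state = unname(state[r_all$line]), row.names = NULL,
             stringsAsFactors = FALSE)
}
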