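# Tissue-of-origin skin scoring with squared-enrichment gene weights,
# hierarchical clustering, combined origin calls, copy-number event calls,
# and assembly of the per-line genomic summary.

#' Construct a tissue-enrichment gene panel
#'
#' Holds per-gene tissue EST-enrichment (EE) weights. EE scores are squared
#' and normalised to sum to one (`scaled_ee = ee^2 / sum(ee^2)`), so strongly
#' tissue-associated genes dominate the origin score.
#'
#' @param gene Gene identifiers (unique).
#' @param ee Non-negative enrichment scores, at least one positive.
#' @return data.frame of class `tiger_panel` with columns `gene`, `ee`,
#'   `scaled_ee`.
#' @export
tiger_panel <- function(gene, ee) {
  gene <- as.character(gene)
  .check(!anyDuplicated(gene), "duplicate panel genes")
  .check(all(is.finite(ee)) && all(ee >= 0), "EE scores must be >= 0")
  .check(sum(ee^2) > 0, "at least one positive EE score required")
  out <- data.frame(gene = gene, ee = as.numeric(ee),
                    scaled_ee = ee^2 / sum(ee^2), stringsAsFactors = FALSE)
  class(out) <- c("tiger_panel", "data.frame")
  out
}

#' Weighted skin-origin scores
#'
#' Scores each sample as the sum over panel genes of expression (normalized
#' scale) times the squared-and-scaled EE weight. Panel genes absent from the
#' expression universe are dropped and the weights re-normalised (with a
#' warning) so scores stay comparable.
#'
#' @param expr An [expression_matrix()] (normalized/variance-stabilised
#'   values).
#' @param panel A [tiger_panel()].
#' @return A [score_table()] named `"TigerSkin"`.
#' @export
tiger_skin_scores <- function(expr, panel) {
  .check(inherits(panel, "tiger_panel"), "'panel' must be a tiger_panel")
  present <- panel$gene %in% rownames(expr$values)
  if (!any(present)) stop("no panel genes present in expression universe",
                          call. = FALSE)
  if (!all(present)) {
    warning(sprintf("%d panel gene(s) absent from universe; weights re-normalised",
                    sum(!present)))
    panel <- tiger_panel(panel$gene[present], panel$ee[present])
  }
  v <- expr$values[panel$gene, , drop = FALSE]
  score_table(colnames(v), colSums(v * panel$scaled_ee),
              score_name = "TigerSkin")
}

#' Hierarchical clustering of samples (Euclidean, ward.D2)
#'
#' Agglomerative clustering of samples with Euclidean distance and the
#' ward.D2 update rule: distances enter un-squared and are squared within the
#' Lance-Williams update, the convention under which merge heights are on the
#' original distance scale.
#'
#' @param expr An [expression_matrix()] with at least two samples.
#' @param genes Optional gene subset (e.g. the most variable genes).
#' @param n_cut Optional number of flat clusters to cut the tree into.
#' @return List with `hclust` (the dendrogram) and `labels` (named integer
#'   cluster memberships, `NULL` unless `n_cut` given).
#' @export
cluster_samples_hierarchical <- function(expr, genes = NULL, n_cut = NULL) {
  v <- expr$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    .check(length(missing) == 0L,
           paste("genes absent from matrix:", paste(missing, collapse = ", ")))
    v <- v[genes, , drop = FALSE]
  }
  .check(ncol(v) >= 2L, "need at least 2 samples")
  hc <- stats::hclust(stats::dist(t(v)), method = "ward.D2")
  labels <- if (!is.null(n_cut)) stats::cutree(hc, k = n_cut) else NULL
  list(hclust = hc, labels = labels)
}

#' Combine skin scores and UV calls into origin calls
#'
#' A sample is `skin_high` when its skin score is at or above the threshold;
#' `probable_melanoma` flags the high-confidence quadrant, `skin_high AND
#' uv_positive`. Samples missing either input get an `NA` call with a
#' warning. The threshold default of 95 is tied to the variance-stabilised
#' scale of the original panels; on other scales choose it from data.
#'
#' @param skin_scores A [score_table()] (e.g. from [tiger_skin_scores()]).
#' @param uv_calls data.frame from [uv_signature_call()].
#' @param skin_threshold Skin-score threshold (default 95).
#' @return data.frame with columns `sample`, `skin_score`, `uv_positive`,
#'   `skin_high`, `probable_melanoma`.
#' @export
call_probable_origin <- function(skin_scores, uv_calls, skin_threshold = 95) {
  ids <- union(skin_scores$sample, uv_calls$sample)
  skin <- skin_scores$score[match(ids, skin_scores$sample)]
  uv <- uv_calls$uv_positive[match(ids, uv_calls$sample)]
  if (anyNA(skin) || anyNA(uv)) {
    warning("samples missing a skin score or UV call get NA origin calls")
  }
  skin_high <- skin >= skin_threshold
  data.frame(sample = ids, skin_score = skin, uv_positive = uv,
             skin_high = skin_high, probable_melanoma = skin_high & uv,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call copy-number events from ploidy-corrected values
#'
#' `AMP` for values strictly above `amp_threshold`, `DEL` for values strictly
#' below `del_threshold`, `NEUTRAL` otherwise; `NA` values propagate.
#'
#' @param cn Numeric genes-by-samples matrix of ploidy-corrected copy-number
#'   values.
#' @param amp_threshold,del_threshold Event thresholds (defaults 1, -0.75).
#' @return Character matrix of the same shape with entries
#'   `AMP`/`DEL`/`NEUTRAL`/`NA`.
#' @export
call_copy_number_events <- function(cn, amp_threshold = 1,
                                    del_threshold = -0.75) {
  .check(is.matrix(cn) && is.numeric(cn), "'cn' must be a numeric matrix")
  out <- matrix(NA_character_, nrow = nrow(cn), ncol = ncol(cn),
                dimnames = dimnames(cn))
  out[!is.na(cn)] <- "NEUTRAL"
  out[!is.na(cn) & cn > amp_threshold] <- "AMP"
  out[!is.na(cn) & cn < del_threshold] <- "DEL"
  out
}

#' Assemble the per-line genomic summary
#'
#' Joins, per cell line: the MITF/AXL state cluster, the UV-signature flag,
#' the mean correlation to all malignant cells, mutation status for a gene
#' panel (`MUT` if the line has any record for the gene, `WT` if the line is
#' in the mutation table without one, `NA` if the line is absent), and
#' copy-number event calls for a gene panel (`NA` when the line or gene is
#' missing).
#'
#' @param ranking data.frame with columns `line`, `mean_r_all`, `state`
#'   (e.g. from [rank_cell_lines()]).
#' @param uv_calls data.frame from [uv_signature_call()] keyed by line id.
#' @param mutations A `mutation_table` with a `gene` column.
#' @param cn_events Character matrix from [call_copy_number_events()]
#'   (genes x lines), or `NULL`.
#' @param mutation_panel,cn_panel Character vectors of panel genes.
#' @return data.frame with one row per line: `line`, `state`, `uv_positive`,
#'   `mean_r_all`, then `mut_<gene>` and `cn_<gene>` columns.
#' @export
build_genomic_summary <- function(ranking, uv_calls, mutations,
                                  cn_events = NULL,
                                  mutation_panel = character(),
                                  cn_panel = character()) {
  .check(is.data.frame(ranking) && nrow(ranking) > 0L, "empty ranking")
  .check(all(c("line", "mean_r_all", "state") %in% names(ranking)),
         "ranking needs columns line, mean_r_all, state")
  if (length(mutation_panel)) {
    .check(!is.null(mutations$gene),
           "mutation table needs a 'gene' column for panel status")
  }
  out <- data.frame(line = ranking$line, state = ranking$state,
                    uv_positive = uv_calls$uv_positive[
                      match(ranking$line, uv_calls$sample)],
                    mean_r_all = ranking$mean_r_all,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (g in mutation_panel) {
    status <- rep(NA_character_, nrow(out))
    present <- out$line %in% mutations$sample
    mutated <- out$line %in% mutations$sample[mutations$gene == g]
    status[present] <- "WT"
    status[mutated] <- "MUT"
    out[[paste0("mut_", g)]] <- status
  }
  for (g in cn_panel) {
    call <- rep(NA_character_, nrow(out))
    if (!is.null(cn_events) && g %in% rownames(cn_events)) {
      hit <- out$line %in% colnames(cn_events)
      call[hit] <- cn_events[g, out$line[hit]]
    }
    out[[paste0("cn_", g)]] <- call
  }
  out
}
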