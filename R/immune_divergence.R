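# Differential expression between cell lines and tumours, partition of top
# DEGs by immune/stromal score correlation, the immune DEG signature value,
# and its Kaplan-Meier/log-rank survival analysis.

#' Per-gene Welch differential expression between cell lines and tumours
#'
#' For every gene, computes Welch's unequal-variance t statistic with the
#' Welch-Satterthwaite degrees of freedom, a two-sided p value, and
#' Benjamini-Hochberg adjusted p values over all tested genes. Expression is
#' expected on a log scale (`LOG2_TPM1` or `NORMALIZED`). Genes with zero
#' variance in both groups and equal means get `t = 0, p = 1`; with unequal
#' means the difference is infinitely many standard errors, so `p = 0`.
#'
#' @param cell_lines,tumours [expression_matrix()] objects over the identical
#'   gene universe, each with at least two samples.
#' @return A `data.frame` with columns `gene`, `mean_cell_line`,
#'   `mean_tumour`, `t_statistic`, `df`, `p_value`, `adjusted_p`, `rank`
#'   (1 = most significant under the [select_top_degs()] ordering).
#' @export
differential_expression <- function(cell_lines, tumours) {
  .check(identical(genes(cell_lines), genes(tumours)),
         "matrices must share an identical gene universe")
  .check(cell_lines$unit %in% c("LOG2_TPM1", "NORMALIZED") &&
           tumours$unit %in% c("LOG2_TPM1", "NORMALIZED"),
         "differential expression requires log-scale units")
  a <- cell_lines$values
  b <- tumours$values
  .check(ncol(a) >= 2L && ncol(b) >= 2L,
         "each group needs at least 2 samples")
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  degenerate <- se2 == 0
  t_stat[degenerate & (m1 == m2)] <- 0
  t_stat[degenerate & (m1 != m2)] <- sign(m1 - m2)[degenerate & (m1 != m2)] * Inf
  p <- 2 * stats::pt(-abs(t_stat), df)
  p[degenerate & (m1 == m2)] <- 1
  p[degenerate & (m1 != m2)] <- 0
  adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(a), mean_cell_line = m1, mean_tumour = m2,
                    t_statistic = t_stat, df = df, p_value = p,
                    adjusted_p = adj, row.names = NULL,
                    stringsAsFactors = FALSE)
  ord <- order(out$adjusted_p, out$p_value, -abs(out$t_statistic), out$gene,
               method = "radix")
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  out
}

#' Select the top differentially expressed genes
#'
#' Takes the `floor(fraction * m)` genes with the smallest adjusted p values.
#' Ties are broken by smaller raw p, then larger absolute t, then gene id, so
#' the selection is deterministic.
#'
#' @param deg_table Output of [differential_expression()].
#' @param fraction Fraction of the tested universe to keep (default 0.05).
#' @return Character vector of gene identifiers.
#' @export
select_top_degs <- function(deg_table, fraction = 0.05) {
  .check(is.data.frame(deg_table) && nrow(deg_table) > 0L,
         "empty DEG table")
  .check(fraction > 0 && fraction <= 1, "fraction must be in (0,1]")
  n_top <- floor(fraction * nrow(deg_table))
  .check(n_top >= 1L, "fraction selects no genes")
  deg_table$gene[order(deg_table$rank)][seq_len(n_top)]
}

#' Correlate genes with a per-sample score across tumours
#'
#' Pearson correlation of each gene's expression with the score across tumour
#' samples. Zero-variance genes get `r = 0` with a flag so the downstream
#' partition stays total.
#'
#' @param tumours An [expression_matrix()].
#' @param genes Genes to correlate (must be present).
#' @param score A [score_table()] covering all tumour samples.
#' @return data.frame with columns `gene`, `r`, `zero_variance`.
#' @export
correlate_genes_with_scores <- function(tumours, genes, score) {
  .check(inherits(score, "score_table"), "'score' must be a score_table")
  ids <- colnames(tumours$values)
  .check(length(ids) >= 3L, "need at least 3 tumours")
  .check(all(ids %in% score$sample), "score table must cover all tumours")
  missing <- setdiff(genes, rownames(tumours$values))
  .check(length(missing) == 0L,
         paste("genes absent from matrix:", paste(missing, collapse = ", ")))
  s <- score$score[match(ids, score$sample)]
  v <- tumours$values[genes, , drop = FALSE]
  sds <- apply(v, 1L, stats::sd)
  zero <- sds == 0 | stats::sd(s) == 0
  r <- rep(0, length(genes))
  if (any(!zero)) {
    r[!zero] <- as.numeric(stats::cor(t(v[!zero, , drop = FALSE]), s))
  }
  data.frame(gene = genes, r = r, zero_variance = zero, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Partition genes by immune/stromal score correlation
#'
#' Labels a gene `IMMUNE` if its immune-score correlation strictly exceeds
#' the threshold; otherwise `STROMAL` if the stromal correlation does;
#' otherwise `NEITHER`. Genes exceeding both thresholds are labelled
#' `IMMUNE` (immune precedence).
#'
#' @param r_immune,r_stromal Outputs of [correlate_genes_with_scores()] over
#'   the same genes (matched by `gene`).
#' @param threshold Strict correlation threshold (default 0.4).
#' @return data.frame with columns `gene`, `r_immune`, `r_stromal`, `label`.
#' @export
partition_degs <- function(r_immune, r_stromal, threshold = 0.4) {
  .check(setequal(r_immune$gene, r_stromal$gene),
         "immune and stromal correlation tables must cover the same genes")
  r_stromal <- r_stromal[match(r_immune$gene, r_stromal$gene), ]
  label <- ifelse(r_immune$r > threshold, "IMMUNE",
                  ifelse(r_stromal$r > threshold, "STROMAL", "NEITHER"))
  data.frame(gene = r_immune$gene, r_immune = r_immune$r,
             r_stromal = r_stromal$r, label = label, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Immune DEG values: summed per-gene Z-scores over tumours
#'
#' Standardizes each listed gene across tumours (mean 0, SD 1, denominator
#' n-1) and sums the Z-scores per tumour. Zero-SD genes contribute 0.
#'
#' @param tumours An [expression_matrix()] with at least two samples.
#' @param immune_genes Non-empty subset of the gene universe.
#' @return A [score_table()] named `"ImmuneDEG"`.
#' @export
immune_deg_values <- function(tumours, immune_genes) {
  .check(length(immune_genes) >= 1L, "empty gene list")
  .check(ncol(tumours$values) >= 2L, "need at least 2 tumours")
  missing <- setdiff(immune_genes, rownames(tumours$values))
  .check(length(missing) == 0L,
         paste("genes absent from matrix:", paste(missing, collapse = ", ")))
  v <- tumours$values[immune_genes, , drop = FALSE]
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  z <- (v - mu) / ifelse(sdv == 0, Inf, sdv)   # zero-SD rows -> 0
  score_table(colnames(v), colSums(z), score_name = "ImmuneDEG")
}

#' Median-split Kaplan-Meier and log-rank survival analysis
#'
#' Restricts to samples with both a score and survival information,
#' dichotomizes the score at the median (`HIGH` strictly above, `LOW` at or
#' below), censors events beyond the horizon, and computes Kaplan-Meier
#' curves and the two-group log-rank chi-square (1 df).
#'
#' @param values A [score_table()].
#' @param survival A [survival_records()] table.
#' @param horizon Follow-up horizon in months (default 120, i.e. ten years).
#' @return List with `groups` (sample, group), `km` (per-group product-limit
#'   estimates), `chisq`, `df`, `p`.
#' @export
survival_logrank <- function(values, survival, horizon = 120) {
  .check(inherits(values, "score_table"), "'values' must be a score_table")
  shared <- intersect(values$sample, survival$sample)
  .check(length(shared) >= 2L, "need at least 2 samples with score and survival")
  v <- values$score[match(shared, values$sample)]
  time <- survival$time[match(shared, survival$sample)]
  event <- survival$event[match(shared, survival$sample)]
  med <- stats::median(v)
  group <- ifelse(v > med, "HIGH", "LOW")
  if (length(unique(group)) < 2L) {
    stop("one group empty after median split", call. = FALSE)
  }
  event <- event & time <= horizon
  time <- pmin(time, horizon)
  groups <- data.frame(sample = shared, group = group,
                       stringsAsFactors = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata_lab <- sub("^group=", "", rep(names(fit$strata),
                                       if (is.null(fit$strata)) 0 else fit$strata))
  km <- data.frame(group = strata_lab, time = fit$time, n_risk = fit$n.risk,
                   n_event = fit$n.event, survival = fit$surv,
                   stringsAsFactors = FALSE)
  if (sum(event) == 0) {
    return(list(groups = groups, km = km, chisq = 0, df = 1L, p = 1))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- unname(sd_$chisq)
  p <- stats::pchisq(chisq, df = 1L, lower.tail = FALSE)
  list(groups = groups, km = km, chisq = chisq, df = 1L, p = p)
}
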