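# Mutation-spectrum tabulation, UV-signature classification, and
# cell-line-vs-tumour alteration-frequency comparison.

SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
CONTEXT_CLASSES <- c("DIPYRIMIDINE", "NON_DIPYRIMIDINE")

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Collapse substitutions to the pyrimidine strand and classify context
#'
#' Records with a purine reference are reverse-complemented (ref and alt
#' complemented, 5'/3' neighbours swapped and complemented) so the reference
#' is always C or T, giving the six standard collapsed substitution classes.
#' The context is `DIPYRIMIDINE` when, after the collapse, at least one
#' flanking base is a pyrimidine (C or T) — the context of UV photoproducts.
#'
#' @param records A `mutation_table` (see [mutation_records()]).
#' @return data.frame with columns `sample`, `class` (e.g. `"C>T"`) and
#'   `context`, one row per record in input order.
#' @export
normalize_substitution <- function(records) {
  ref <- records$ref
  alt <- records$alt
  five <- records$five_prime
  three <- records$three_prime
  purine <- ref %in% c("A", "G")
  if (any(purine)) {
    new_five <- unname(.COMPLEMENT[three[purine]])
    new_three <- unname(.COMPLEMENT[five[purine]])
    ref[purine] <- unname(.COMPLEMENT[records$ref[purine]])
    alt[purine] <- unname(.COMPLEMENT[records$alt[purine]])
    five[purine] <- new_five
    three[purine] <- new_three
  }
  dipyr <- five %in% c("C", "T") | three %in% c("C", "T")
  data.frame(sample = records$sample, class = paste0(ref, ">", alt),
             context = ifelse(dipyr, "DIPYRIMIDINE", "NON_DIPYRIMIDINE"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mutation spectrum per sample group
#'
#' Tabulates, per sample, the percentage of that sample's SNVs in each of the
#' 12 class-by-context cells (six pyrimidine-collapsed substitution classes
#' times dipyrimidine/non-dipyrimidine), then summarises each group by the
#' mean and standard error of those per-sample percentages.
#'
#' @param records A `mutation_table`.
#' @param group_map Named character vector mapping each record's sample to a
#'   group label. Mapped samples without records are dropped with a warning.
#' @return List with `per_sample` (data.frame: sample, group, class, context,
#'   count, percent) and `summary` (data.frame: group, class, context,
#'   mean_percent, sem, n_samples).
#' @export
mutation_spectrum <- function(records, group_map) {
  .check(all(records$sample %in% names(group_map)),
         "every record's sample must be mapped to a group")
  norm <- normalize_substitution(records)
  empty <- setdiff(names(group_map), records$sample)
  if (length(empty)) {
    warning(sprintf("%d mapped sample(s) with 0 SNVs excluded from means",
                    length(empty)))
  }
  cells <- expand.grid(class = SUBSTITUTION_CLASSES,
                       context = CONTEXT_CLASSES, stringsAsFactors = FALSE)
  key <- paste(norm$class, norm$context)
  cell_key <- paste(cells$class, cells$context)
  by_sample <- lapply(split(key, norm$sample), function(k) {
    cnt <- table(factor(k, levels = cell_key))
    data.frame(class = cells$class, context = cells$context,
               count = as.integer(cnt),
               percent = as.numeric(cnt) / length(k) * 100)
  })
  per_sample <- do.call(rbind, lapply(names(by_sample), function(s) {
    cbind(sample = s, group = unname(group_map[s]), by_sample[[s]],
          stringsAsFactors = FALSE)
  }))
  rownames(per_sample) <- NULL
  summ <- do.call(rbind, lapply(split(per_sample, per_sample$group),
                                function(d) {
    agg <- lapply(split(d$percent, paste(d$class, d$context)), function(p) {
      c(mean = mean(p),
        sem = if (length(p) > 1) stats::sd(p) / sqrt(length(p)) else 0)
    })
    agg <- agg[cell_key]
    data.frame(group = d$group[1L], class = cells$class,
               context = cells$context,
               mean_percent = vapply(agg, `[[`, numeric(1), "mean"),
               sem = vapply(agg, `[[`, numeric(1), "sem"),
               n_samples = length(unique(d$sample)),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(per_sample = per_sample, summary = summ)
}

#' UV mutational-signature calls
#'
#' For each sample, computes `f_uv`, the fraction of its SNVs that are C>T at
#' a dipyrimidine site after pyrimidine-strand collapse (denominator: all of
#' the sample's SNVs), and flags the sample UV-signature positive when
#' `f_uv > 0.6` strictly.
#'
#' @param records A `mutation_table` with at least one SNV per sample.
#' @return data.frame with columns `sample`, `n_snvs`, `f_uv`, `uv_positive`.
#' @export
uv_signature_call <- function(records) {
  .check(nrow(records) >= 1L, "no mutation records")
  norm <- normalize_substitution(records)
  qual <- norm$class == "C>T" & norm$context == "DIPYRIMIDINE"
  by <- split(qual, norm$sample)
  out <- data.frame(sample = names(by),
                    n_snvs = lengths(by),
                    f_uv = vapply(by, mean, numeric(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$uv_positive <- out$f_uv > 0.6
  out
}

#' Exact two-sided binomial comparison of alteration frequencies
#'
#' Tests whether `k` altered lines of `n` differ from a reference tumour
#' alteration rate `p0`, using the exact binomial test with the two-sided
#' minimum-likelihood rule: the p value sums the probabilities of all
#' outcomes no more likely than the observed one.
#'
#' @param k Number of altered cell lines.
#' @param n Panel size (> 0).
#' @param p0 Reference alteration rate, in (0,1).
#' @return Two-sided p value.
#' @export
compare_alteration_frequencies <- function(k, n, p0) {
  .check(.is_number(n) && n >= 1, "n must be >= 1")
  .check(.is_number(k) && k >= 0 && k <= n, "k must be in [0, n]")
  .check(.is_number(p0) && p0 > 0 && p0 < 1, "p0 must be in (0,1)")
  stats::binom.test(k, n, p = p0, alternative = "two.sided")$p.value
}
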