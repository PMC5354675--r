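# Seeded generators producing expression cohorts, single cells, cell-line
# panels, mutation catalogs and survival tables with the statistical
# structure the analysis assumes: tumours are purity-weighted mixtures of a
# malignant archetype with immune and stromal contamination, cell lines are
# pure malignant profiles, single cells come from MITF-high/AXL-high
# archetypes, SNV catalogs have a tunable dipyrimidine C>T fraction, and
# survival hazards track immune burden.

#' Parameters of the synthetic cohort generator
#'
#' @param n_genes Total genes.
#' @param n_tumours,n_cell_lines,n_single_cells Sample counts.
#' @param n_immune_genes,n_stromal_genes Sizes of the contamination blocks.
#' @param n_mitf_program,n_axl_program Sizes of the two state programs.
#' @param purity_range Interval in `[0,1]` tumour purity is drawn from.
#' @param noise_sd Log2-scale SD of multiplicative expression noise.
#' @param program_shift Log2 shift of program genes in their archetype.
#' @param uv_fraction_pos,uv_fraction_neg True dipyrimidine C>T proportions
#'   for UV-positive and UV-negative samples.
#' @param mutations_per_sample SNVs per simulated sample.
#' @param survival_hazard_ratio Hazard ratio between above/below-median
#'   immune-score groups.
#' @param seed Integer seed; fixes every draw of every generator.
#' @return A validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_genes = 2000L, n_tumours = 120L,
                          n_cell_lines = 30L, n_single_cells = 200L,
                          n_immune_genes = 100L, n_stromal_genes = 40L,
                          n_mitf_program = 50L, n_axl_program = 50L,
                          purity_range = c(0.3, 0.7), noise_sd = 0.3,
                          program_shift = 2, uv_fraction_pos = 0.75,
                          uv_fraction_neg = 0.30,
                          mutations_per_sample = 100L,
                          survival_hazard_ratio = 2, seed = 1L) {
  counts <- c(n_genes, n_tumours, n_cell_lines, n_single_cells,
              n_immune_genes, n_stromal_genes, n_mitf_program, n_axl_program,
              mutations_per_sample)
  .check(all(counts >= 1), "all counts must be positive")
  .check(length(purity_range) == 2L && purity_range[1] <= purity_range[2] &&
           purity_range[1] >= 0 && purity_range[2] <= 1,
         "purity_range must be an interval within [0,1]")
  .check(uv_fraction_pos >= 0 && uv_fraction_pos <= 1 &&
           uv_fraction_neg >= 0 && uv_fraction_neg <= 1,
         "uv fractions must lie in [0,1]")
  .check(noise_sd >= 0, "noise_sd must be >= 0")
  .check(n_immune_genes + n_stromal_genes + n_mitf_program + n_axl_program <=
           n_genes,
         "gene blocks exceed n_genes")
  structure(list(n_genes = as.integer(n_genes),
                 n_tumours = as.integer(n_tumours),
                 n_cell_lines = as.integer(n_cell_lines),
                 n_single_cells = as.integer(n_single_cells),
                 n_immune_genes = as.integer(n_immune_genes),
                 n_stromal_genes = as.integer(n_stromal_genes),
                 n_mitf_program = as.integer(n_mitf_program),
                 n_axl_program = as.integer(n_axl_program),
                 purity_range = as.numeric(purity_range),
                 noise_sd = noise_sd, program_shift = program_shift,
                 uv_fraction_pos = uv_fraction_pos,
                 uv_fraction_neg = uv_fraction_neg,
                 mutations_per_sample = as.integer(mutations_per_sample),
                 survival_hazard_ratio = survival_hazard_ratio,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

# Shared archetypes on the log2 scale, drawn under the params seed so every
# generator (tumours, cell lines, single cells) refers to the same malignant
# profile. Gene blocks are laid out deterministically at the front of the
# gene list; truth labels expose them.
.archetypes <- function(params) {
  p <- params
  gene_ids <- sprintf("g%04d", seq_len(p$n_genes))
  i_imm <- seq_len(p$n_immune_genes)
  i_str <- p$n_immune_genes + seq_len(p$n_stromal_genes)
  i_mitf <- p$n_immune_genes + p$n_stromal_genes + seq_len(p$n_mitf_program)
  i_axl <- p$n_immune_genes + p$n_stromal_genes + p$n_mitf_program +
    seq_len(p$n_axl_program)
  with_seed(p$seed, {
    base <- stats::rnorm(p$n_genes, mean = 4, sd = 2)
    mal <- base
    mal[c(i_imm, i_str)] <- base[c(i_imm, i_str)] - 3   # lineage-silent blocks
    imm <- base
    imm[i_imm] <- base[i_imm] + 3
    str_ <- base
    str_[i_str] <- base[i_str] + 3
    list(gene_ids = gene_ids, base = base, malignant = mal, immune = imm,
         stromal = str_,
         immune_genes = gene_ids[i_imm], stromal_genes = gene_ids[i_str],
         mitf_genes = gene_ids[i_mitf], axl_genes = gene_ids[i_axl])
  })
}

# log2 profile -> TPM column summing to `total`
.log_to_tpm <- function(log2_mat, total = 1e6) {
  v <- 2^log2_mat
  sweep(v, 2L, colSums(v), "/") * total
}

.noisy <- function(tpm, noise_sd, total = 1e6) {
  if (noise_sd > 0) {
    tpm <- tpm * 2^matrix(stats::rnorm(length(tpm), sd = noise_sd),
                          nrow = nrow(tpm))
  }
  sweep(tpm, 2L, colSums(tpm), "/") * total
}

#' Simulate a tumour + cell-line expression cohort
#'
#' Each tumour TPM profile is `purity * malignant + (1-purity) * w * immune +
#' (1-purity) * (1-w) * stromal` with the immune mixture weight `w` drawn
#' once per cohort, uniformly from `[0.5, 0.9]`, so immune contamination
#' dominates stromal while per-tumour admixture varies only through purity.
#' Profiles are then perturbed by multiplicative log-normal noise and
#' renormalised to TPM. Cell
#' lines are noisy copies of the pure malignant archetype. Immune/stromal
#' score tables are the mean log2(TPM+1) of the true immune/stromal gene
#' blocks per tumour — scores monotone in the respective cell fraction, which
#' is all the downstream pipeline requires of them.
#'
#' @param params A [cohort_params()].
#' @return List with `tumours`, `cell_lines` ([expression_matrix()], unit
#'   TPM), `immune_scores`, `stromal_scores` ([score_table()]), and `truth`
#'   (gene-block labels, per-tumour `purity` and immune weight `w`).
#' @export
simulate_expression_cohort <- function(params) {
  p <- params
  arch <- .archetypes(p)
  with_seed(p$seed + 1L, {
    tum_ids <- sprintf("T%03d", seq_len(p$n_tumours))
    cl_ids <- sprintf("CL%03d", seq_len(p$n_cell_lines))
    purity <- stats::runif(p$n_tumours, p$purity_range[1], p$purity_range[2])
    w <- rep(stats::runif(1L, 0.5, 0.9), p$n_tumours)
    mal_tpm <- .log_to_tpm(cbind(arch$malignant))[, 1L]
    imm_tpm <- .log_to_tpm(cbind(arch$immune))[, 1L]
    str_tpm <- .log_to_tpm(cbind(arch$stromal))[, 1L]
    tum <- vapply(seq_len(p$n_tumours), function(i) {
      purity[i] * mal_tpm + (1 - purity[i]) *
        (w[i] * imm_tpm + (1 - w[i]) * str_tpm)
    }, numeric(p$n_genes))
    tum <- .noisy(tum, p$noise_sd)
    dimnames(tum) <- list(arch$gene_ids, tum_ids)
    cl <- matrix(mal_tpm, nrow = p$n_genes, ncol = p$n_cell_lines)
    cl <- .noisy(cl, p$noise_sd)
    dimnames(cl) <- list(arch$gene_ids, cl_ids)
    tumours <- expression_matrix(tum, unit = "TPM", sample_class = "TUMOUR")
    cell_lines <- expression_matrix(cl, unit = "TPM",
                                    sample_class = "CELL_LINE")
    log_tum <- log2(tum + 1)
    immune_scores <- score_table(
      tum_ids, colMeans(log_tum[arch$immune_genes, , drop = FALSE]),
      score_name = "Immune")
    stromal_scores <- score_table(
      tum_ids, colMeans(log_tum[arch$stromal_genes, , drop = FALSE]),
      score_name = "Stromal")
    names(purity) <- tum_ids
    names(w) <- tum_ids
    list(tumours = tumours, cell_lines = cell_lines,
         immune_scores = immune_scores, stromal_scores = stromal_scores,
         truth = list(immune_genes = arch$immune_genes,
                      stromal_genes = arch$stromal_genes,
                      mitf_genes = arch$mitf_genes,
                      axl_genes = arch$axl_genes,
                      purity = purity, immune_weight = w))
  })
}

#' Simulate single malignant cells from two transcriptional archetypes
#'
#' Cells are drawn (probability 0.5 each) from a MITF-high or AXL-high
#' archetype: the malignant profile with the respective program gene block
#' elevated by `program_shift` log2 units, plus log-normal noise. Columns are
#' emitted at a x10 TPM scale (each sums to 1e7), so that
#' [to_log_tpm()]'s single-cell divide-by-10 path applies.
#'
#' @param params A [cohort_params()].
#' @return List with `cells` ([expression_matrix()], class `SINGLE_CELL`) and
#'   `truth` (archetype label `"MITF"`/`"AXL"` per cell, program gene ids).
#' @export
simulate_single_cells <- function(params) {
  p <- params
  arch <- .archetypes(p)
  with_seed(p$seed + 2L, {
    ids <- sprintf("SC%04d", seq_len(p$n_single_cells))
    state <- ifelse(stats::runif(p$n_single_cells) < 0.5, "MITF", "AXL")
    logm <- matrix(arch$malignant, nrow = p$n_genes, ncol = p$n_single_cells)
    rownames(logm) <- arch$gene_ids
    logm[arch$mitf_genes, state == "MITF"] <-
      logm[arch$mitf_genes, state == "MITF"] + p$program_shift
    logm[arch$axl_genes, state == "AXL"] <-
      logm[arch$axl_genes, state == "AXL"] + p$program_shift
    tpm <- .log_to_tpm(logm, total = 1e7)
    tpm <- .noisy(tpm, p$noise_sd, total = 1e7)
    dimnames(tpm) <- list(arch$gene_ids, ids)
    names(state) <- ids
    list(cells = expression_matrix(tpm, unit = "TPM",
                                   sample_class = "SINGLE_CELL"),
         truth = list(state = state, mitf_genes = arch$mitf_genes,
                      axl_genes = arch$axl_genes))
  })
}

#' Simulate a cell-line panel at graded distances from the malignant archetype
#'
#' Each line is the malignant archetype, optionally shifted toward the MITF
#' or AXL state, distorted by independent gene-wise log-normal noise with a
#' line-specific SD (`distortions`). Larger distortion means a line farther
#' from the archetype, giving a known ground-truth fidelity ordering.
#'
#' @param params A [cohort_params()].
#' @param distortions Numeric vector, one log2-scale noise SD per line.
#' @param states Optional vector over lines in `{"MITF","AXL","NEUTRAL"}`;
#'   default all `"NEUTRAL"` (no program shift).
#' @return List with `cell_lines` ([expression_matrix()], unit TPM) and
#'   `truth` (`distortion` and `state` per line).
#' @export
simulate_cell_line_panel <- function(params, distortions,
                                     states = NULL) {
  p <- params
  .check(all(distortions >= 0), "distortions must be >= 0")
  n <- length(distortions)
  if (is.null(states)) states <- rep("NEUTRAL", n)
  .check(length(states) == n && all(states %in% c("MITF", "AXL", "NEUTRAL")),
         "states must be MITF/AXL/NEUTRAL, one per line")
  arch <- .archetypes(p)
  with_seed(p$seed + 3L, {
    ids <- sprintf("L%03d", seq_len(n))
    logm <- matrix(arch$malignant, nrow = p$n_genes, ncol = n)
    rownames(logm) <- arch$gene_ids
    logm[arch$mitf_genes, states == "MITF"] <-
      logm[arch$mitf_genes, states == "MITF"] + p$program_shift
    logm[arch$axl_genes, states == "AXL"] <-
      logm[arch$axl_genes, states == "AXL"] + p$program_shift
    for (i in seq_len(n)) {
      if (distortions[i] > 0) {
        logm[, i] <- logm[, i] + stats::rnorm(p$n_genes, sd = distortions[i])
      }
    }
    tpm <- .log_to_tpm(logm)
    dimnames(tpm) <- list(arch$gene_ids, ids)
    truth <- data.frame(line = ids, distortion = distortions, state = states,
                        stringsAsFactors = FALSE)
    list(cell_lines = expression_matrix(tpm, unit = "TPM",
                                        sample_class = "CELL_LINE"),
         truth = truth)
  })
}

# one batch of random SNVs; uv rows are C>T with a pyrimidine flank, non-uv
# rows are rejection-sampled from everything else
.draw_snvs <- function(n, uv) {
  pick <- function(n, set) set[sample.int(length(set), n, replace = TRUE)]
  out <- data.frame(ref = character(n), alt = character(n),
                    five_prime = character(n), three_prime = character(n),
                    stringsAsFactors = FALSE)
  n_uv <- sum(uv)
  if (n_uv > 0) {
    five <- pick(n_uv, DNA_BASES)
    three <- pick(n_uv, DNA_BASES)
    # guarantee at least one pyrimidine neighbour
    fix <- !(five %in% c("C", "T")) & !(three %in% c("C", "T"))
    while (any(fix)) {
      side <- stats::runif(sum(fix)) < 0.5
      five[fix][side] <- pick(sum(side), c("C", "T"))
      three[fix][!side] <- pick(sum(!side), c("C", "T"))
      fix <- !(five %in% c("C", "T")) & !(three %in% c("C", "T"))
    }
    out$ref[uv] <- "C"; out$alt[uv] <- "T"
    out$five_prime[uv] <- five; out$three_prime[uv] <- three
  }
  n_bg <- sum(!uv)
  if (n_bg > 0) {
    need <- which(!uv)
    while (length(need)) {
      m <- length(need)
      ref <- pick(m, DNA_BASES)
      alt <- pick(m, DNA_BASES)
      redraw <- alt == ref
      while (any(redraw)) {
        alt[redraw] <- pick(sum(redraw), DNA_BASES)
        redraw <- alt == ref
      }
      five <- pick(m, DNA_BASES)
      three <- pick(m, DNA_BASES)
      cls <- normalize_substitution(
        mutation_records(rep("x", m), ref, alt, five, three))
      ok <- !(cls$class == "C>T" & cls$context == "DIPYRIMIDINE")
      idx <- need[ok]
      out$ref[idx] <- ref[ok]; out$alt[idx] <- alt[ok]
      out$five_prime[idx] <- five[ok]; out$three_prime[idx] <- three[ok]
      need <- need[!ok]
    }
  }
  # randomly report either strand to exercise strand collapse downstream
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- stats::runif(n) < 0.5
  if (any(flip)) {
    ref <- out$ref[flip]; alt <- out$alt[flip]
    five <- out$five_prime[flip]; three <- out$three_prime[flip]
    out$ref[flip] <- unname(comp[ref])
    out$alt[flip] <- unname(comp[alt])
    out$five_prime[flip] <- unname(comp[three])
    out$three_prime[flip] <- unname(comp[five])
  }
  out
}

#' Simulate somatic SNV catalogs with a tunable UV fraction
#'
#' For UV-positive samples each SNV is a dipyrimidine C>T with probability
#' `uv_fraction_pos` (and is otherwise drawn uniformly from the non-UV
#' substitution/context classes); UV-negative samples use `uv_fraction_neg`.
#' Each record is reported on a random strand, so purine-reference rows
#' exercise the pyrimidine-strand collapse.
#'
#' @param params A [cohort_params()].
#' @param n_samples Number of samples.
#' @param positive Logical vector (recycled) marking UV-positive samples.
#' @return List with `records` (a `mutation_table`) and `truth` (data.frame
#'   of `sample`, `uv_positive`).
#' @export
simulate_mutation_catalog <- function(params, n_samples,
                                      positive = TRUE) {
  p <- params
  positive <- rep_len(as.logical(positive), n_samples)
  ids <- sprintf("M%04d", seq_len(n_samples))
  with_seed(p$seed + 4L, {
    per <- p$mutations_per_sample
    frac <- ifelse(positive, p$uv_fraction_pos, p$uv_fraction_neg)
    sample_col <- rep(ids, each = per)
    uv <- stats::runif(n_samples * per) < rep(frac, each = per)
    snvs <- .draw_snvs(n_samples * per, uv)
    records <- mutation_records(sample_col, snvs$ref, snvs$alt,
                                snvs$five_prime, snvs$three_prime)
    list(records = records,
         truth = data.frame(sample = ids, uv_positive = positive,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate survival times linked to an immune score
#'
#' Draws exponential event times whose log-hazard is linear in the
#' standardized immune score, scaled so the above-median and below-median
#' score groups differ in mean log-hazard by `log(hazard_ratio)`. Baseline
#' hazard corresponds to a 60-month median survival; administrative censoring
#' is applied at `censor_time`.
#'
#' @param immune_values A [score_table()].
#' @param hazard_ratio Target group hazard ratio (1 = no association).
#' @param censor_time Administrative censoring time in months.
#' @param seed Integer seed.
#' @return A [survival_records()] table aligned with `immune_values`.
#' @export
simulate_survival <- function(immune_values, hazard_ratio = 2,
                              censor_time = 120, seed = 1L) {
  .check(inherits(immune_values, "score_table"),
         "'immune_values' must be a score_table")
  .check(hazard_ratio > 0, "hazard_ratio must be > 0")
  .check(censor_time >= 0, "censor_time must be >= 0")
  v <- immune_values$score
  n <- length(v)
  z <- if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else rep(0, n)
  hi <- z > stats::median(z)
  beta <- 0
  if (hazard_ratio != 1 && any(hi) && any(!hi)) {
    spread <- mean(z[hi]) - mean(z[!hi])
    if (spread > 0) beta <- log(hazard_ratio) / spread
  }
  lambda0 <- log(2) / 60
  with_seed(seed, {
    t_event <- stats::rexp(n, rate = lambda0 * exp(beta * z))
    event <- t_event <= censor_time
    survival_records(immune_values$sample, pmin(t_event, censor_time), event)
  })
}
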