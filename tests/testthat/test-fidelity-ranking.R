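test_that("mean single-cell correlations follow Pearson arithmetic", {
  line <- cbind(L1 = c(1, 2, 3, 4))
  cells <- cbind(c1 = c(1, 2, 3, 4), c2 = c(4, 3, 2, 1))
  rownames(line) <- rownames(cells) <- paste0("g", 1:4)
  rk <- rank_by_single_cell_correlation(toy_expression(line),
                                        toy_expression(cells,
                                                       sample_class = "SINGLE_CELL"))
  expect_equal(rk$mean_r, mean(c(1, -1)), tolerance = 1e-12)
  # identical cell: r = 1
  rk1 <- rank_by_single_cell_correlation(
    toy_expression(line),
    toy_expression(line, sample_class = "SINGLE_CELL"), "L1")
  expect_equal(rk1$mean_r, 1)
  # shift invariance: adding a constant to a line leaves its rank unchanged
  shifted <- toy_expression(line + 7)
  rk2 <- rank_by_single_cell_correlation(shifted,
                                         toy_expression(cells,
                                                        sample_class = "SINGLE_CELL"))
  expect_equal(rk2$mean_r, rk$mean_r, tolerance = 1e-12)
  expect_true(all(abs(rk$mean_r) <= 1))
})

test_that("zero-variance pairs are skipped, not scored", {
  lines <- cbind(L1 = c(1, 2, 3), L2 = c(2, 1, 3))
  cells <- cbind(c1 = c(1, 3, 2), c2 = c(2, 2, 2))
  rownames(lines) <- rownames(cells) <- paste0("g", 1:3)
  const_line <- cbind(L9 = c(5, 5, 5))
  rownames(const_line) <- paste0("g", 1:3)
  expect_warning(
    rk <- rank_by_single_cell_correlation(
      toy_expression(lines),
      toy_expression(cells, sample_class = "SINGLE_CELL")),
    "skipped")
  expect_equal(rk$n_pairs[rk$line == "L1"], 1L)
  expect_error(suppressWarnings(rank_by_single_cell_correlation(
    toy_expression(const_line),
    toy_expression(cells, sample_class = "SINGLE_CELL"))),
    "no scorable")
})

test_that("program scores vanish under self-control and are seeded", {
  p <- cohort_params(seed = 61)
  sim <- simulate_single_cells(p)
  cells <- to_log_tpm(sim$cells, single_cell_scale = TRUE)
  mitf <- sim$truth$mitf_genes
  axl <- sim$truth$axl_genes
  self <- program_cell_scores(cells, mitf, axl, seed = 1,
                              control_pools = list(mitf = mitf, axl = axl))
  expect_equal(max(abs(self$score_mitf)), 0, tolerance = 1e-12)
  expect_equal(max(abs(self$score_axl)), 0, tolerance = 1e-12)
  s1 <- program_cell_scores(cells, mitf, axl, seed = 4)
  s2 <- program_cell_scores(cells, mitf, axl, seed = 4)
  expect_identical(s1, s2)
  s3 <- program_cell_scores(cells, mitf, axl, seed = 5)
  expect_false(identical(s1$control_mitf, s3$control_mitf))
})

test_that("program score separation recovers the generator's shift", {
  p <- cohort_params(seed = 67)
  sim <- simulate_single_cells(p)
  cells <- to_log_tpm(sim$cells, single_cell_scale = TRUE)
  sc <- program_cell_scores(cells, sim$truth$mitf_genes, sim$truth$axl_genes,
                            seed = 2)
  is_mitf <- sim$truth$state[sc$cell] == "MITF"
  gap <- mean(sc$score_mitf[is_mitf]) - mean(sc$score_mitf[!is_mitf])
  se <- sqrt(var(sc$score_mitf[is_mitf]) / sum(is_mitf) +
               var(sc$score_mitf[!is_mitf]) / sum(!is_mitf))
  expect_lt(abs(gap - p$program_shift), 3 * se + 0.15)
  # ratio key separates the archetypes almost perfectly
  expect_gt(min(sc$ratio_key[is_mitf]), max(sc$ratio_key[!is_mitf]) - 0.5)
})

test_that("zero shift centres program scores at zero", {
  p <- cohort_params(program_shift = 0, seed = 71)
  sim <- simulate_single_cells(p)
  cells <- to_log_tpm(sim$cells, single_cell_scale = TRUE)
  sc <- program_cell_scores(cells, sim$truth$mitf_genes, sim$truth$axl_genes,
                            seed = 2)
  se <- sd(sc$score_mitf) / sqrt(nrow(sc))
  expect_lt(abs(mean(sc$score_mitf)), 3 * se + 0.02)
})

test_that("extreme-cell selection is disjoint, sized, and tie-stable", {
  sc <- data.frame(cell = sprintf("c%02d", 1:10),
                   ratio_key = c(3, 2, 2, 1, 0, 0, -1, -2, -2, -3))
  ex <- select_extreme_cells(sc, k = 2)
  expect_identical(ex$mitf_top, c("c01", "c02"))
  expect_identical(ex$axl_top, c("c10", "c08"))
  expect_length(intersect(ex$mitf_top, ex$axl_top), 0)
  expect_warning(ex2 <- select_extreme_cells(sc, k = 8), "reduced")
  expect_length(ex2$mitf_top, 5)
  # boundary tie broken by cell id: c02 < c03 at ratio 2
  expect_true("c02" %in% ex$mitf_top && !("c03" %in% ex$mitf_top))
})

test_that("single-sample enrichment matches the hand one-sample t", {
  # 3 samples; g1,g2 engineered so sample s3 has Z = (1, 3)
  v <- rbind(g1 = c(-1, 0, 1), g2 = c(-1, -2, 3))
  v["g1", ] <- v["g1", ] / sd(v["g1", ])       # Z row = (-1.09.., 0, 1.09)
  em <- toy_expression(v)
  z1 <- (v["g1", ] - mean(v["g1", ])) / sd(v["g1", ])
  z2 <- (v["g2", ] - mean(v["g2", ])) / sd(v["g2", ])
  stat <- gene_set_enrichment(em, list(S = c("g1", "g2")),
                              mode = "single_sample")
  for (j in 1:3) {
    z <- c(z1[j], z2[j])
    expect_equal(stat["S", j], mean(z) / (sd(z) / sqrt(2)), tolerance = 1e-12)
  }
  # all set genes at the cohort mean: statistic 0
  flat <- toy_expression(rbind(a = c(0, 0, 0), b = c(0, 0, 0),
                               c = c(1, 2, 3)))
  st <- gene_set_enrichment(flat, list(S = c("a", "b")), "single_sample")
  expect_equal(unname(st["S", ]), c(0, 0, 0))
  # set of size 1: flagged undefined
  expect_warning(st1 <- gene_set_enrichment(em, list(S = "g1"),
                                            "single_sample"), "undefined")
  expect_true(all(is.na(st1)))
})

test_that("two-group enrichment compares set fold changes to background", {
  set.seed(12)
  v <- matrix(rnorm(200), 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  grp <- setNames(rep(c("CL", "TU"), each = 5), colnames(v))
  v[1:4, grp == "CL"] <- v[1:4, grp == "CL"] + 3   # set up in group CL
  em <- toy_expression(v)
  res <- gene_set_enrichment(em, list(UP = sprintf("g%02d", 1:4),
                                      NULLSET = sprintf("g%02d", 11:16)),
                             mode = "two_group", groups = grp)
  lfc <- rowMeans(v[, grp == "CL"]) - rowMeans(v[, grp == "TU"])
  tt <- t.test(lfc[1:4], lfc)
  expect_equal(res$statistic[res$set == "UP"], unname(tt$statistic),
               tolerance = 1e-12)
  expect_gt(res$statistic[res$set == "UP"], 2)
  expect_lt(abs(res$statistic[res$set == "NULLSET"]), 2.5)
})

test_that("state clustering recovers separated blobs and degenerates safely", {
  set.seed(33)
  m <- c(rnorm(15, 3, 0.3), rnorm(15, -3, 0.3), rnorm(15, 0, 0.3))
  a <- c(rnorm(15, -3, 0.3), rnorm(15, 3, 0.3), rnorm(15, 0, 0.3))
  truth <- rep(c("MITF", "AXL", "INTERMEDIATE"), each = 15)
  lab <- cluster_program_states(m, a)
  expect_gte(ari(lab, truth), 0.8)
  expect_identical(unname(lab[1]), "MITF")
  expect_identical(unname(lab[16]), "AXL")
  # permutation invariance
  perm <- sample(45)
  lab2 <- cluster_program_states(m[perm], a[perm])
  expect_identical(unname(lab2), unname(lab[perm]))
  # duplicated single line: one mode, sign fallback
  expect_warning(lab3 <- cluster_program_states(rep(1, 5), rep(0.5, 5)),
                 "sign")
  expect_true(all(lab3 == "MITF"))
})

test_that("rank_cell_lines assembles a complete, ordered table", {
  p <- cohort_params(seed = 79, n_single_cells = 120)
  sim <- simulate_single_cells(p)
  cells <- to_log_tpm(sim$cells, single_cell_scale = TRUE)
  panel <- simulate_cell_line_panel(
    p, distortions = rep(0.4, 12),
    states = rep(c("MITF", "AXL", "NEUTRAL"), each = 4))
  lines <- to_log_tpm(panel$cell_lines)
  tab <- rank_cell_lines(lines, cells, sim$truth$mitf_genes,
                         sim$truth$axl_genes, k_extreme = 30, seed = 3)
  expect_identical(nrow(tab), 12L)
  expect_true(all(!is.na(tab$state)))
  expect_true(all(abs(c(tab$mean_r_all, tab$mean_r_mitf_top,
                        tab$mean_r_axl_top)) <= 1))
  expect_true(!is.unsorted(rev(tab$mean_r_all)))
  # MITF-state lines correlate better with MITF-top than AXL-top cells
  st <- panel$truth$state[match(tab$line, panel$truth$line)]
  expect_true(all(tab$mean_r_mitf_top[st == "MITF"] >
                    tab$mean_r_axl_top[st == "MITF"]))
  expect_true(all(tab$mean_r_axl_top[st == "AXL"] >
                    tab$mean_r_mitf_top[st == "AXL"]))
})
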