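test_that("Welch t matches the scalar oracle and handles degenerate genes", {
  a <- toy_expression(rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5), g3 = c(1, 4, 2)))
  b <- toy_expression(rbind(g1 = c(4, 5, 6), g2 = c(5, 5, 5), g3 = c(9, 9, 9)),
                      sample_prefix = "t", sample_class = "TUMOUR")
  deg <- differential_expression(a, b)
  # hand Welch on (1,2,3) vs (4,5,6): diff -3, se sqrt(2/3), df 4
  expect_equal(deg$t_statistic[1], -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(deg$df[1], 4, tolerance = 1e-12)
  tt <- t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(deg$p_value[1], tt$p.value, tolerance = 1e-12)
  # both groups constant and equal: t = 0, p = 1
  expect_equal(deg$t_statistic[2], 0)
  expect_equal(deg$p_value[2], 1)
  expect_true(all(deg$adjusted_p >= deg$p_value - 1e-15))
  expect_identical(sort(deg$rank), 1:3)
  expect_error(differential_expression(a, toy_expression(cbind(t1 = c(1, 2, 3)),
                                                         sample_class = "TUMOUR")),
               "2 samples")
})

test_that("identical groups give t = 0, p = 1 everywhere", {
  set.seed(2)
  v <- matrix(rnorm(30), 5)
  a <- toy_expression(v[, 1:3])
  b <- toy_expression(v[, 1:3], sample_prefix = "t", sample_class = "TUMOUR")
  deg <- differential_expression(a, b)
  expect_true(all(deg$t_statistic == 0))
  expect_true(all(deg$p_value == 1))
})

test_that("BH adjustment equals the hand step-up rule", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_oracle(p), rep(0.04, 4))
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  # exhaustive small grid + seeded random vectors, lengths 1..8
  grid <- c(0.001, 0.02, 0.2, 0.5, 0.97, 1)
  for (m in 1:3) {
    combos <- do.call(expand.grid, rep(list(grid), m))
    for (i in seq_len(nrow(combos))) {
      pv <- as.numeric(combos[i, ])
      expect_equal(p.adjust(pv, "BH"), bh_oracle(pv), tolerance = 1e-14)
    }
  }
  set.seed(8)
  for (m in 4:8) {
    for (rep_ in 1:50) {
      pv <- runif(m)
      expect_equal(p.adjust(pv, "BH"), bh_oracle(pv), tolerance = 1e-14)
    }
  }
})

test_that("top-DEG selection takes floor(fraction*m) with deterministic ties", {
  fake <- data.frame(gene = sprintf("g%05d", 1:20460),
                     p_value = rep(0.5, 20460),
                     adjusted_p = rep(0.5, 20460),
                     t_statistic = rep(1, 20460))
  fake$rank <- order(order(fake$adjusted_p, fake$p_value,
                           -abs(fake$t_statistic), fake$gene))
  expect_length(select_top_degs(fake), 1023L)
  small <- fake[1:100, ]
  small$rank <- 1:100
  expect_length(select_top_degs(small), 5L)
  # all-equal adjusted p: ties resolved by gene id
  expect_identical(select_top_degs(small, 0.05), sprintf("g%05d", 1:5))
  expect_error(select_top_degs(fake[0, ]), "empty")
})

test_that("gene-score correlations match closed forms and flag zero variance", {
  v <- rbind(match_ = c(1, 3, 2, 4), neg = -c(1, 3, 2, 4),
             lin = c(1, 2, 3, 4), flat = c(2, 2, 2, 2))
  tum <- toy_expression(v, sample_class = "TUMOUR")
  sc <- score_table(colnames(tum$values), c(1, 3, 2, 4))
  res <- correlate_genes_with_scores(tum, rownames(v), sc)
  expect_equal(res$r[1], 1)
  expect_equal(res$r[2], -1)
  expect_equal(res$r[3], 0.8)
  expect_equal(res$r[4], 0)
  expect_identical(res$zero_variance, c(FALSE, FALSE, FALSE, TRUE))
  expect_error(correlate_genes_with_scores(
    toy_expression(v[, 1:2], sample_class = "TUMOUR"), "lin",
    score_table(paste0("s", 1:2), 1:2)), "3 tumours")
})

test_that("DEG partition applies strict thresholds with immune precedence", {
  ri <- data.frame(gene = c("a", "b", "c", "d"), r = c(0.5, 0.4, 0.6, 0.1))
  rs <- data.frame(gene = c("a", "b", "c", "d"), r = c(0.1, 0.9, 0.6, 0.45))
  part <- partition_degs(ri, rs)
  expect_identical(part$label, c("IMMUNE", "STROMAL", "IMMUNE", "STROMAL"))
  # boundary: exactly 0.4 is not IMMUNE
  expect_identical(part$label[2], "STROMAL")
  none <- partition_degs(data.frame(gene = "x", r = 0.2),
                         data.frame(gene = "x", r = 0.3))
  expect_identical(none$label, "NEITHER")
})

test_that("immune DEG values are summed per-gene Z-scores", {
  v <- rbind(g1 = c(2, 0), g2 = c(4, 2), flat = c(7, 7))
  tum <- toy_expression(v, sample_class = "TUMOUR")
  out <- immune_deg_values(tum, c("g1", "g2"))
  # each gene Z = (+0.707..., -0.707...): sums are (sqrt(2), -sqrt(2))
  expect_equal(out$score, c(sqrt(2), -sqrt(2)), tolerance = 1e-12)
  # zero-SD genes contribute nothing
  out2 <- immune_deg_values(tum, c("g1", "g2", "flat"))
  expect_equal(out2$score, out$score)
  # Z rows mean 0 / summed columns 0 within 1e-9
  set.seed(5)
  big <- toy_expression(matrix(rnorm(200), 20), sample_class = "TUMOUR")
  vals <- immune_deg_values(big, rownames(big$values))
  expect_lt(abs(sum(vals$score)), 1e-9)
  expect_error(immune_deg_values(tum, character(0)), "empty")
})

test_that("single gene at the cohort mean scores zero", {
  tum <- toy_expression(rbind(g1 = c(1, 2, 3)), sample_class = "TUMOUR")
  out <- immune_deg_values(tum, "g1")
  expect_equal(out$score[2], 0)
})

test_that("log-rank reproduces the two-subject hand computation", {
  vals <- score_table(c("A", "B"), c(2, 1))   # A is HIGH
  surv <- survival_records(c("A", "B"), c(1, 2), c(TRUE, TRUE))
  res <- survival_logrank(vals, surv)
  expect_identical(res$groups$group[res$groups$sample == "A"], "HIGH")
  expect_equal(res$chisq, 1.0, tolerance = 1e-12)
  expect_equal(res$p, pchisq(1, 1, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("log-rank degenerates correctly", {
  # identical survival in both groups: chi-square 0, p 1
  vals <- score_table(paste0("s", 1:6), c(1, 1, 1, 2, 2, 2))
  surv <- survival_records(paste0("s", 1:6), rep(c(3, 5, 8), 2),
                           rep(TRUE, 6))
  res <- survival_logrank(vals, surv)
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  # all censored: no information, chi-square 0
  surv2 <- survival_records(paste0("s", 1:6), rep(10, 6), rep(FALSE, 6))
  res2 <- survival_logrank(vals, surv2)
  expect_equal(res2$chisq, 0)
  expect_equal(res2$p, 1)
  # ties at the median go LOW; all-equal scores leave HIGH empty
  vals3 <- score_table(paste0("s", 1:6), rep(1, 6))
  expect_error(survival_logrank(vals3, surv), "empty")
})

test_that("events beyond the horizon are censored at the horizon", {
  vals <- score_table(paste0("s", 1:4), c(1, 1, 2, 2))
  surv <- survival_records(paste0("s", 1:4), c(50, 200, 60, 180),
                           rep(TRUE, 4))
  res <- survival_logrank(vals, surv, horizon = 120)
  expect_true(all(res$km$time <= 120))
  expect_equal(sum(res$km$n_event), 2)
})
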