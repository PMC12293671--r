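fixture3 <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))

test_that("the normality gate routes by per-group Shapiro-Wilk", {
  set.seed(101)
  gauss <- list(control = rnorm(17), no_DR = rnorm(14),
                NPDR = rnorm(18), PDR = rnorm(20))
  expect_identical(normality_gate(gauss), "anova")
  # heavily skewed group flips the branch in the vast majority of draws
  kw_hits <- 0L
  for (s in 1:50) {
    set.seed(s)
    g <- list(a = rnorm(17), b = rnorm(14), c = rnorm(18),
              d = exp(rnorm(18, sd = 1)))
    if (normality_gate(g) == "kruskal_wallis") kw_hits <- kw_hits + 1L
  }
  expect_gte(kw_hits, 45L)
  expect_warning(br <- normality_gate(list(a = rep(1, 5), b = rep(2, 5))),
                 "constant")
  expect_identical(br, "kruskal_wallis")
  expect_error(normality_gate(list(a = 1:2, b = 1:5)), "n >= 3")
})

test_that("one-way ANOVA reproduces textbook sums of squares and df", {
  # group sizes 17/14/18/20 -> df (3, 65)
  set.seed(3)
  g <- list(a = rnorm(17), b = rnorm(14), c = rnorm(18), d = rnorm(20))
  res <- one_way_anova(g)
  expect_equal(unname(res$df), c(3, 65))
  # hand-worked fixture: SSB = 6 (df 2), SSW = 6 (df 6) -> F = 3
  res2 <- one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
  expect_equal(res2$statistic, 3)
  expect_equal(unname(res2$df), c(2, 6))
  # two identical groups: F = 0, p = 1
  res3 <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p_value, 1)
  expect_error(one_way_anova(list(a = rep(1, 3), b = rep(2, 3))), "variance")
})

test_that("Kruskal-Wallis matches hand rank arithmetic", {
  res <- kruskal_wallis(fixture3)
  # ranks 1..9, no ties: H = 12/(N(N+1)) * sum n (Rbar - (N+1)/2)^2 = 7.2
  expect_equal(res$statistic, 7.2)
  expect_equal(res$df, 2)
  # permuting the groups leaves H unchanged
  expect_equal(kruskal_wallis(fixture3[c(3, 1, 2)])$statistic, 7.2)
  # four groups -> df 3
  set.seed(8)
  g4 <- list(a = rnorm(17), b = rnorm(14), c = rnorm(18), d = rnorm(20))
  expect_equal(kruskal_wallis(g4)$df, 3)
  expect_error(kruskal_wallis(list(a = rep(1, 3), b = rep(1, 3))), "identical")
})

test_that("Dunn's test matches the mean-rank z oracle with Bonferroni capping", {
  res <- dunn_posthoc(fixture3)
  expect_equal(nrow(res), 3L)
  # hand oracle for pair (a, c): Rbar = 2 vs 8, V0 = N(N+1)/12 = 7.5
  z_ac <- (2 - 8) / sqrt(7.5 * (1 / 3 + 1 / 3))
  p_ac <- 2 * pnorm(-abs(z_ac))
  row <- res[res$group_a == "a" & res$group_b == "c", ]
  expect_equal(row$z, z_ac)
  expect_equal(row$adjusted_p, min(1, 3 * p_ac))
  # capping at 1
  set.seed(2)
  flat <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10), d = rnorm(10))
  resf <- dunn_posthoc(flat)
  expect_equal(nrow(resf), 6L)
  expect_true(all(resf$adjusted_p <= 1))
  expect_true(all(resf$adjusted_p >= resf$p_value))
  # tie correction: duplicated values still give finite z
  tied <- list(a = c(1, 1, 2, 3), b = c(2, 2, 3, 4), c = c(5, 5, 6, 7))
  expect_true(all(is.finite(dunn_posthoc(tied)$z)))
})

test_that("rank-based tests are invariant under positive scaling", {
  set.seed(31)
  g <- list(a = rnorm(8), b = rnorm(9) + 1, c = rnorm(7) - 0.5)
  gs <- lapply(g, function(v) v * 1000)
  expect_equal(kruskal_wallis(gs)$statistic, kruskal_wallis(g)$statistic)
  expect_equal(dunn_posthoc(gs)$adjusted_p, dunn_posthoc(g)$adjusted_p)
})

test_that("Tukey's test uses the studentized range on pooled variance", {
  set.seed(14)
  eq <- list(a = rnorm(10))
  eq$b <- eq$a + 1e-6  # equal-mean groups up to numerical dust
  res <- tukey_posthoc(eq)
  expect_gt(res$adjusted_p, 0.99)
  g4 <- list(a = rnorm(17), b = rnorm(14), c = rnorm(18), d = rnorm(20))
  expect_equal(nrow(tukey_posthoc(g4)), 6L)
  # balanced 3-group: rejection iff observed q exceeds q(0.05; 3, 6) = 4.34
  bal <- list(a = c(1.1, 0.9, 1.0), b = c(1.2, 1.05, 1.15), c = c(2.3, 2.5, 2.1))
  res3 <- tukey_posthoc(bal)
  values <- unlist(bal); gf <- rep(names(bal), each = 3)
  mse <- sum(tapply(values, gf, function(v) sum((v - mean(v))^2))) / 6
  for (i in seq_len(nrow(res3))) {
    qa <- abs(mean(bal[[res3$group_a[i]]]) - mean(bal[[res3$group_b[i]]])) /
      sqrt(mse / 3)
    expect_identical(res3$adjusted_p[i] < 0.05, qa > 4.34)
  }
  expect_error(tukey_posthoc(list(a = rep(1, 3), b = rep(1, 3))), "variance")
})

test_that("Spearman correlation matches rank arithmetic", {
  expect_equal(spearman_correlation(1:8, (1:8)^2)$rho, 1)
  expect_equal(spearman_correlation(1:8, -(1:8))$rho, -1)
  # 6 d^2 / (n (n^2 - 1)) on {(1,2),(2,1),(3,4),(4,3)}: rho = 0.6
  res <- spearman_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$rho, 0.6)
  expect_equal(res$n, 4L)
  # t approximation agrees with the closed form
  expect_equal(res$p_value, 2 * pt(-0.6 * sqrt(2 / (1 - 0.36)), 2))
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_correlation(1:3, 3:1), "at least 4")
})

test_that("the full comparison gates post hoc tests on omnibus significance", {
  tab <- generate_cohort(cohort_spec(seed = 5))
  cmp <- run_full_comparison(tab, c("fd", "wlr", "faz_area_mm2"))
  expect_s3_class(cmp, "cohort_comparison")
  # strong built-in group effects: FD and WLR run post hocs with 6 pairs
  expect_equal(nrow(cmp$results$fd$posthoc), 6L)
  expect_equal(nrow(cmp$results$wlr$posthoc), 6L)
  long <- comparison_table(cmp)
  expect_true(all(c("parameter", "adjusted_p") %in% names(long)))
  expect_error(run_full_comparison(tab, "nope"), "missing columns")
  # parameter with no group effect skips the post hoc stage
  set.seed(6)
  tab$flat <- rnorm(nrow(tab))
  cmp2 <- run_full_comparison(tab, "flat")
  expect_null(cmp2$results$flat$posthoc)
})
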