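test_that("Welch t: identity, separation, antisymmetry, invariance", {
  expect_error(welch_t(c(1, 1, 1), c(2, 2, 2)), "zero variance")

  a <- c(4.1, 5.2, 6.3, 5.5)
  same <- welch_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  sep <- welch_t(c(1, 2, 3), c(11, 12, 13))
  expect_gt(abs(sep$statistic), 10)
  expect_lt(sep$p_value, 0.001)

  set.seed(5)
  b <- rnorm(7, 1)
  expect_equal(welch_t(a, b)$statistic, -welch_t(b, a)$statistic)
  expect_equal(welch_t(a, b)$p_value, welch_t(b, a)$p_value)
  # shared shift and scale leave t unchanged
  expect_equal(welch_t(3 * a + 10, 3 * b + 10)$statistic,
               welch_t(a, b)$statistic, tolerance = 1e-12)
})

test_that("Welch p agrees with a permutation oracle on small samples", {
  set.seed(404)
  for (k in 1:3) {
    a <- rnorm(8, 0, 1)
    b <- rnorm(8, 0.8, 1.3)
    p_w <- welch_t(a, b)$p_value
    p_perm <- perm_welch_p(a, b, n_perm = 4000, seed = k)
    expect_lt(abs(p_w - p_perm), 0.04)
  }
})

test_that("summary-based Welch t reproduces the published site contrasts", {
  expect_equal(welch_t_from_summary(5, 1, 12, 5, 1, 12)$statistic, 0)

  # time within two body-lengths: t(22) = -2.69
  tip <- welch_t_from_summary(174.2, 11.26, 12, 219.4, 12.45, 12)
  expect_equal(tip$statistic, -2.69, tolerance = 0.005)
  expect_equal(tip$df, 22)

  # inter-individual distance: printed t = 2.384 from rounded summaries
  iid <- welch_t_from_summary(165.1, 15.49, 12, 121.1, 10.09, 12)
  expect_equal(iid$statistic, 2.38, tolerance = 0.005)

  # distance traveled: t(22) = 3.40, p = 0.003
  dst <- welch_t_from_summary(4316.9, 372.09, 12, 2547.1, 363.56, 12)
  expect_equal(dst$statistic, 3.40, tolerance = 0.005)
  expect_lt(abs(dst$p_value - 0.003), 0.0005)
})

test_that("Pillai's trace matches hand scatter arithmetic on a balanced toy", {
  # balanced 2 x 2 with 3 observations per cell, 2 responses
  pop <- rep(c("p1", "p2"), each = 6)
  sex <- rep(rep(c("m", "f"), each = 3), 2)
  set.seed(99)
  y <- cbind(c(1, 2, 3, 4, 5, 6, 2, 3, 4, 8, 9, 10),
             c(0.5, 0.1, 0.4, 1.5, 1.1, 1.4, 0.2, 0.6, 0.4, 2.2, 2.6, 2.4))
  res <- shape_manova(y, pop, sex)

  # hand computation: cell means, balanced-design effect scatter matrices
  cell <- paste(pop, sex)
  grand <- colMeans(y)
  mp <- rowsum(y, pop) / 6
  ms <- rowsum(y, sex) / 6
  mc <- rowsum(y, cell) / 3
  h_pop <- 6 * crossprod(sweep(mp, 2, grand))
  h_sex <- 6 * crossprod(sweep(ms, 2, grand))
  e <- crossprod(y - mc[cell, ])
  h_int <- crossprod(sweep(mc, 2, grand)) * 3 - h_pop - h_sex
  pillai_hand <- function(h) sum(diag(h %*% solve(h + e)))
  expect_equal(res$population$statistic, pillai_hand(h_pop), tolerance = 1e-12)
  expect_equal(res$sex$statistic, pillai_hand(h_sex), tolerance = 1e-12)
  expect_equal(res$population_x_sex$statistic, pillai_hand(h_int),
               tolerance = 1e-12)

  # and the full statistic/df/p agree with the reference implementation
  fit <- stats::manova(y ~ factor(pop) * factor(sex))
  sm <- summary(fit, test = "Pillai")$stats
  expect_equal(res$population$statistic, unname(sm[1, "Pillai"]),
               tolerance = 1e-12)
  expect_equal(res$population$p_value, unname(sm[1, "Pr(>F)"]),
               tolerance = 1e-9)
  expect_equal(res$population_x_sex$p_value, unname(sm[3, "Pr(>F)"]),
               tolerance = 1e-9)
})

test_that("MANOVA on unbalanced data uses Type II scatter (car cross-check)", {
  set.seed(17)
  n <- c(25, 9, 18, 30)
  pop <- rep(rep(c("p1", "p2"), 2), n)
  sex <- rep(c("m", "m", "f", "f"), n)
  y <- matrix(rnorm(sum(n) * 3), ncol = 3)
  y[pop == "p2", 1] <- y[pop == "p2", 1] + 2
  res <- shape_manova(y, pop, sex)
  ref <- car::Manova(stats::lm(y ~ factor(pop) * factor(sex)), type = 2)
  ref_sum <- summary(ref, multivariate = TRUE)$multivariate.tests
  get_pillai <- function(term) ref_sum[[term]]$SSPH
  for (term in c("factor(pop)", "factor(sex)", "factor(pop):factor(sex)")) {
    h <- ref_sum[[term]]$SSPH
    e <- ref_sum[[term]]$SSPE
    pill <- sum(diag(h %*% solve(h + e)))
    mine <- switch(term, "factor(pop)" = res$population,
                   "factor(sex)" = res$sex,
                   res$population_x_sex)
    expect_equal(mine$statistic, pill, tolerance = 1e-10)
  }

  sepd <- shape_manova(y, pop, sex)
  expect_lt(sepd$population$p_value, 0.001)
})

test_that("two-way ANOVA + Tukey: hand SS on a balanced design, planted cell", {
  # balanced 2 x 2, 4 per cell
  pop <- rep(c("p1", "p2"), each = 8)
  sex <- rep(rep(c("f", "m"), each = 4), 2)
  y <- c(5, 6, 7, 8,   6, 7, 8, 9,
         7, 8, 9, 10,  12, 13, 14, 15)
  out <- ratio_anova_tukey(y, pop, sex)
  cell <- paste(pop, sex)
  grand <- mean(y)
  ss_pop <- 8 * sum((tapply(y, pop, mean) - grand)^2)
  ss_sex <- 8 * sum((tapply(y, sex, mean) - grand)^2)
  ss_cells <- 4 * sum((tapply(y, cell, mean) - grand)^2)
  ss_int <- ss_cells - ss_pop - ss_sex
  ss_err <- sum((y - tapply(y, cell, mean)[cell])^2)
  f_hand <- function(ss, df1) (ss / df1) / (ss_err / 12)
  expect_equal(out$anova$population$statistic, f_hand(ss_pop, 1),
               tolerance = 1e-10)
  expect_equal(out$anova$sex$statistic, f_hand(ss_sex, 1), tolerance = 1e-10)
  expect_equal(out$anova$population_x_sex$statistic, f_hand(ss_int, 1),
               tolerance = 1e-10)

  # Tukey flags the p2:m cell against all others
  tk <- out$tukey
  rows <- grepl("p2:m", tk$comparison)
  expect_true(all(tk$p_adj[rows] < 0.05))
  # and agrees with the reference studentized-range computation
  ref <- TukeyHSD(aov(y ~ interaction(pop, sex, sep = ":")))
  expect_equal(sort(tk$p_adj), sort(unname(ref[[1]][, "p adj"])),
               tolerance = 1e-10)

  expect_error(ratio_anova_tukey(y[1:12], pop[1:12], sex[1:12]), "empty cell")
})

test_that("signed-rank test: exact enumeration, ties, symmetry, direction", {
  # posterior = anterior + 1 elementwise, n = 10: one-sided p = 1/1024
  ant <- c(10, 12, 13, 15, 17, 20, 22, 25, 30, 31)
  res <- paired_wilcoxon(ant + 1, ant, alternative = "greater")
  expect_true(res$exact)
  expect_equal(res$p_value, 1 / 1024)
  expect_equal(res$statistic, 55)

  # random pairs, n = 8: exact two-sided p equals the full 2^8 enumeration
  set.seed(77)
  for (k in 1:5) {
    d <- round(rnorm(8, 0.3, 1), 1)
    d <- d[d != 0]
    if (length(d) < 5) next
    mine <- paired_wilcoxon(d, rep(0, length(d)))
    expect_equal(mine$p_value, enum_signed_rank(d), tolerance = 1e-12)
  }
  # ties handled by average ranks in both paths
  d_tied <- c(1, 1, -1, 2, 2, 3, -2)
  expect_equal(paired_wilcoxon(d_tied, rep(0, 7))$p_value,
               enum_signed_rank(d_tied), tolerance = 1e-12)

  # no-ties case agrees with the reference exact implementation
  d2 <- c(0.8, -0.4, 1.9, 2.7, -1.2, 0.6, 3.1, -2.3, 1.4)
  expect_equal(paired_wilcoxon(d2, rep(0, 9))$p_value,
               wilcox.test(d2, exact = TRUE)$p.value, tolerance = 1e-12)

  # antisymmetric differences sit at the null center
  d_sym <- c(1.5, -1.5, 2.5, -2.5, 3.5, -3.5)
  res_sym <- paired_wilcoxon(d_sym, rep(0, 6))
  expect_equal(res_sym$statistic, 6 * 7 / 4)
  expect_gt(res_sym$p_value, 0.99)

  expect_error(paired_wilcoxon(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)),
               "all differences")

  # invariance under odd monotone transforms of the differences
  d3 <- c(0.2, 0.5, -0.1, 1.2, 0.9, -0.7, 0.3)
  cube <- function(x) x^3
  expect_equal(paired_wilcoxon(cube(d3), rep(0, 7))$statistic,
               paired_wilcoxon(d3, rep(0, 7))$statistic)
  expect_equal(paired_wilcoxon(7 * d3, rep(0, 7))$p_value,
               paired_wilcoxon(d3, rep(0, 7))$p_value)
})

test_that("large-n signed-rank path uses the corrected normal approximation", {
  set.seed(88)
  d <- rnorm(40, 0.4)
  mine <- paired_wilcoxon(d, rep(0, 40))
  expect_false(mine$exact)
  ref <- wilcox.test(d, correct = TRUE, exact = FALSE)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Kruskal-Wallis matches the tie-corrected hand formula", {
  # 6-value worked example with ties
  vals <- c(1, 2, 2, 3, 5, 5)
  grp <- c("a", "a", "b", "b", "c", "c")
  res <- kruskal_wallis(vals, grp)
  expect_equal(res$statistic, kw_hand(vals, grp), tolerance = 1e-12)
  expect_equal(res$df, 2)

  # maximal separation for n = (3, 3): H at its maximum over assignments
  res_max <- kruskal_wallis(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  all_h <- apply(combn(6, 3), 2, function(idx) {
    g <- rep("b", 6); g[idx] <- "a"
    kw_hand(1:6, g)
  })
  expect_equal(res_max$statistic, max(all_h), tolerance = 1e-12)

  # monotone-transform invariance
  set.seed(6)
  v <- rnorm(15); g <- rep(c("a", "b", "c"), 5)
  expect_equal(kruskal_wallis(exp(v), g)$statistic,
               kruskal_wallis(v, g)$statistic, tolerance = 1e-12)

  expect_error(kruskal_wallis(rep(3, 6), grp), "identical")
})
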