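#' Test-result container
#' @noRd
test_result <- function(test, statistic, df, p_value, effect_direction = NA,
                        n_per_group = NULL, extra = NULL) {
  structure(
    c(list(test = test, statistic = unname(statistic), df = unname(df),
           p_value = unname(p_value), effect_direction = effect_direction,
           n_per_group = n_per_group), extra),
    class = "shoal_test")
}

#' @export
print.shoal_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, df = %s, p = %.4g%s\n",
              x$test, x$statistic,
              paste(signif(x$df, 5), collapse = ", "), x$p_value,
              if (!is.na(x$effect_direction[1]))
                paste0(", direction: ", x$effect_direction) else ""))
  invisible(x)
}

#' Welch two-sample t test
#'
#' Unequal-variance t test between two samples (tank means in the behavioral
#' analyses). A thin wrapper around [stats::t.test()] returning the package's
#' result container with the effect direction spelled out.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @param label_a,label_b Group labels used in the direction field.
#' @return A `shoal_test` with `statistic` (t), `df` (Welch-Satterthwaite),
#'   `p_value` (two-sided), `effect_direction`.
#' @export
welch_t <- function(sample_a, sample_b, label_a = "a", label_b = "b") {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("welch_t: each sample needs n >= 2", call. = FALSE)
  }
  if (var(sample_a) == 0 && var(sample_b) == 0) {
    stop("welch_t: zero variance in both samples", call. = FALSE)
  }
  ht <- t.test(sample_a, sample_b, var.equal = FALSE)
  test_result("welch_t", ht$statistic, ht$parameter, ht$p.value,
              effect_direction = if (mean(sample_a) >= mean(sample_b))
                paste(label_a, ">", label_b) else paste(label_a, "<", label_b),
              n_per_group = c(length(sample_a), length(sample_b)))
}

#' Welch t statistic from printed summaries
#'
#' Recomputes a two-sample t statistic from published means, standard errors
#' of the mean, and group sizes: `t = (m_a - m_b) / sqrt(sem_a^2 + sem_b^2)`.
#' Both the pooled df (`n_a + n_b - 2`, the convention used when reporting
#' `t(22)` for 12 tanks per site) and the Welch-Satterthwaite df are
#' returned.
#'
#' @param mean_a,mean_b Group means.
#' @param sem_a,sem_b Standard errors of the mean (must be > 0).
#' @param n_a,n_b Group sizes (must be >= 2).
#' @return A `shoal_test`; `df` is the pooled df, `df_welch` the
#'   Welch-Satterthwaite approximation.
#' @examples
#' welch_t_from_summary(174.2, 11.26, 12, 219.4, 12.45, 12)$statistic
#' @export
welch_t_from_summary <- function(mean_a, sem_a, n_a, mean_b, sem_b, n_b) {
  if (sem_a <= 0 || sem_b <= 0) stop("welch_t_from_summary: sems must be > 0",
                                     call. = FALSE)
  if (n_a < 2L || n_b < 2L) stop("welch_t_from_summary: n must be >= 2",
                                 call. = FALSE)
  se2 <- sem_a^2 + sem_b^2
  t_stat <- (mean_a - mean_b) / sqrt(se2)
  df_welch <- se2^2 / (sem_a^4 / (n_a - 1) + sem_b^4 / (n_b - 1))
  p <- 2 * pt(-abs(t_stat), df_welch)
  test_result("welch_t_from_summary", t_stat, n_a + n_b - 2, p,
              effect_direction = if (mean_a >= mean_b) "a > b" else "a < b",
              n_per_group = c(n_a, n_b),
              extra = list(df_welch = df_welch))
}

#' Pillai's trace MANOVA for a two-factor crossed design
#'
#' Multivariate analysis of variance of shape scores on Population, Sex, and
#' their interaction, computed from between/within scatter matrices with
#' Type II sums of squares and cross-products (each main effect adjusted for
#' the other, the interaction adjusted for both), against the residual
#' scatter of the full interaction model. Pillai's trace and its standard F
#' approximation are reported per term.
#'
#' @param scores n x q numeric matrix of responses (shape PC scores retaining
#'   `min_variance` of the shape variance when built via
#'   [manova_scores()]).
#' @param population,sex Factor-like vectors of length n.
#' @return A list of `shoal_test` objects, one per term
#'   (`population`, `sex`, `population_x_sex`).
#' @export
shape_manova <- function(scores, population, sex) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  q <- ncol(scores)
  population <- factor(population)
  sex <- factor(sex)
  if (nlevels(population) < 2L || nlevels(sex) < 2L) {
    stop("shape_manova: both factors need at least 2 levels", call. = FALSE)
  }
  if (n <= q + nlevels(population) * nlevels(sex) - 1L) {
    stop("shape_manova: more specimens than response dimensions required; ",
         "reduce the retained shape axes", call. = FALSE)
  }
  rss_mat <- function(formula_rhs) {
    mm <- stats::model.matrix(formula_rhs, data.frame(population, sex))
    qr_fit <- qr(mm)
    res <- qr.resid(qr_fit, scores)
    crossprod(res)
  }
  e_full <- rss_mat(~ population * sex)
  df_error <- n - qr(stats::model.matrix(~ population * sex,
                                         data.frame(population, sex)))$rank
  terms <- list(
    population = list(h = rss_mat(~ sex) - rss_mat(~ population + sex),
                      df = nlevels(population) - 1L),
    sex = list(h = rss_mat(~ population) - rss_mat(~ population + sex),
               df = nlevels(sex) - 1L),
    population_x_sex = list(
      h = rss_mat(~ population + sex) - e_full,
      df = (nlevels(population) - 1L) * (nlevels(sex) - 1L))
  )
  out <- lapply(names(terms), function(nm) {
    h <- terms[[nm]]$h
    df_h <- terms[[nm]]$df
    ev <- tryCatch(
      Re(eigen(solve(h + e_full, h), only.values = TRUE)$values),
      error = function(e) stop(
        "shape_manova: singular scatter matrix; reduce the response dimension",
        call. = FALSE))
    pillai <- sum(pmax(pmin(ev, 1), 0))
    s <- min(df_h, q)
    m <- (abs(df_h - q) - 1) / 2
    nn <- (df_error - q - 1) / 2
    df1 <- s * (2 * m + s + 1)
    df2 <- s * (2 * nn + s + 1)
    f_stat <- (pillai / (s - pillai)) * (df2 / df1)
    p <- pf(f_stat, df1, df2, lower.tail = FALSE)
    test_result(paste0("manova_pillai_", nm), pillai, c(df1, df2), p,
                extra = list(f_approx = f_stat, term_df = df_h,
                             error_df = df_error, n_responses = q))
  })
  names(out) <- names(terms)
  out
}

#' Shape scores retained for MANOVA
#'
#' PC scores covering at least `min_variance` of the shape variance; the
#' response set used by [shape_manova()].
#'
#' @param analysis A `shape_analysis` with PC scores.
#' @param min_variance Cumulative variance fraction to retain (default 0.99).
#' @return Matrix of retained scores.
#' @export
manova_scores <- function(analysis, min_variance = 0.99) {
  stopifnot(inherits(analysis, "shape_analysis"))
  if (is.null(analysis$pc_scores)) analysis <- shape_pca(analysis)
  k <- which(cumsum(analysis$variance_explained) >= min_variance)[1L]
  analysis$pc_scores[, seq_len(k), drop = FALSE]
}

#' Two-way ANOVA with Tukey HSD on the body-size ratio
#'
#' Two-way analysis of variance of the posterior/anterior area ratio on
#' Population, Sex, and their interaction, with Type II sums of squares
#' (the sex ratios differ strongly between sites, so the design is
#' unbalanced), plus Tukey's honestly-significant-difference comparisons of
#' the four Population x Sex cell means (Tukey-Kramer for unequal cells).
#'
#' @param ratio Numeric response, one value per fish.
#' @param population,sex Factor-like vectors.
#' @return List with `anova` (a list of `shoal_test` per term, Type II) and
#'   `tukey` (data frame of pairwise cell comparisons).
#' @export
ratio_anova_tukey <- function(ratio, population, sex) {
  population <- factor(population)
  sex <- factor(sex)
  cells <- table(population, sex)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("ratio_anova_tukey: empty cell %s:%s",
                 rownames(cells)[empty[1L]], colnames(cells)[empty[2L]]),
         call. = FALSE)
  }
  dat <- data.frame(ratio = ratio, population = population, sex = sex)
  fit <- aov(ratio ~ population * sex, data = dat)
  a2 <- car::Anova(fit, type = 2)
  terms <- c("population", "sex", "population:sex")
  res_row <- which(rownames(a2) == "Residuals")
  tests <- lapply(terms, function(tm) {
    r <- which(rownames(a2) == tm)
    test_result(paste0("anova_", sub(":", "_x_", tm)),
                a2$`F value`[r], c(a2$Df[r], a2$Df[res_row]),
                a2$`Pr(>F)`[r],
                extra = list(sum_sq = a2$`Sum Sq`[r], ss_type = "II"))
  })
  names(tests) <- sub(":", "_x_", terms)
  cell <- interaction(population, sex, sep = ":")
  tk <- TukeyHSD(aov(ratio ~ cell, data = data.frame(ratio, cell)))$cell
  tukey <- data.frame(comparison = rownames(tk), tk, row.names = NULL)
  names(tukey) <- c("comparison", "diff", "lwr", "upr", "p_adj")
  list(anova = tests, tukey = tukey)
}

#' Wilcoxon signed-rank test for paired region areas
#'
#' Paired signed-rank test (posterior vs anterior body-region area). Zero
#' differences are dropped, tied absolute differences receive average ranks,
#' and the null distribution of the positive-rank sum is obtained by exact
#' enumeration (a sign-convolution over the realized ranks, valid with ties)
#' for up to `exact_max` retained pairs, otherwise by the normal
#' approximation with continuity correction and tie-corrected variance.
#'
#' @param posterior,anterior Paired numeric vectors, equal length >= 5.
#' @param exact_max Largest n for which the exact distribution is enumerated
#'   (default 25).
#' @param alternative `"two.sided"`, `"greater"` (posterior > anterior), or
#'   `"less"`.
#' @return A `shoal_test` with `statistic` = V (sum of ranks of positive
#'   differences), `p_value`, and `exact` flag.
#' @export
paired_wilcoxon <- function(posterior, anterior, exact_max = 25,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(posterior) != length(anterior) || length(posterior) < 5L) {
    stop("paired_wilcoxon: paired vectors of equal length >= 5 required",
         call. = FALSE)
  }
  d <- posterior - anterior
  d <- d[d != 0]
  n <- length(d)
  if (!n) stop("paired_wilcoxon: all differences are zero", call. = FALSE)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of V over the 2^n equiprobable sign assignments, by
    # convolution on the doubled (integer) rank scale
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    probs <- numeric(tot + 1L)  # index = doubled rank sum + 1
    probs[1L] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), probs[seq_len(tot + 1L - rk)])
      probs <- (probs + shifted) / 2
    }
    v2 <- as.integer(round(2 * v))
    p_le <- sum(probs[seq_len(v2 + 1L)])
    p_ge <- sum(probs[(v2 + 1L):(tot + 1L)])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- switch(alternative,
                two.sided = (abs(v - mu) - 0.5) / sqrt(sigma2),
                greater = (v - mu - 0.5) / sqrt(sigma2),
                less = (mu - v - 0.5) / sqrt(sigma2))
    p <- if (alternative == "two.sided") 2 * pnorm(-z) else pnorm(-z)
    p <- min(1, max(0, p))
    exact <- FALSE
  }
  test_result("wilcoxon_signed_rank", v, NA_real_, p,
              effect_direction = if (v >= n * (n + 1) / 4)
                "posterior > anterior" else "posterior < anterior",
              n_per_group = n,
              extra = list(exact = exact, alternative = alternative))
}

#' Kruskal-Wallis test on standard length
#'
#' Rank-based comparison of a numeric endpoint across groups with the
#' standard tie correction; a wrapper around [stats::kruskal.test()].
#'
#' @param values Numeric vector.
#' @param group Factor-like vector of group labels.
#' @return A `shoal_test` with `statistic` = H, chi-squared df, and p.
#' @export
kruskal_wallis <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("kruskal_wallis: need >= 2 groups",
                                call. = FALSE)
  if (length(unique(values)) == 1L) {
    stop("kruskal_wallis: all values identical", call. = FALSE)
  }
  ht <- kruskal.test(values, group)
  test_result("kruskal_wallis", ht$statistic, ht$parameter, ht$p.value,
              n_per_group = as.integer(table(group)))
}
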