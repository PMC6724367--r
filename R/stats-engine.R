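#' Select a two-sample test from distribution diagnostics
#'
#' Implements the test-selection decision tree: each group is checked for
#' normality (Shapiro-Wilk) and the pair for variance homogeneity (Levene's
#' test). Both groups normal and homogeneous variances: Student's t.
#' Both normal, heterogeneous: Welch's t. Any group non-normal, homogeneous:
#' Mann-Whitney U. Any non-normal, heterogeneous: bootstrap randomization
#' t-test.
#'
#' @param a,b Numeric samples (each n >= 3; Shapiro-Wilk is undefined
#'   below that).
#' @param diag_alpha Alpha for both diagnostic tests (default 0.05).
#' @param levene_center Centering for Levene's test: `"mean"` (default,
#'   the classic SPSS-style test) or `"median"` (Brown-Forsythe).
#' @return A list: `test_name` (one of `student_t`, `welch_t`,
#'   `mann_whitney`, `randomization_t`), `shapiro_p` (length-2), `levene_p`,
#'   `normal`, `homogeneous`.
#' @export
select_test <- function(a, b, diag_alpha = 0.05,
                        levene_center = c("mean", "median")) {
  levene_center <- match.arg(levene_center)
  a <- .check_numeric(a, "a"); b <- .check_numeric(b, "b")
  .assert(length(a) >= 3 && length(b) >= 3,
          "each group needs n >= 3 (Shapiro-Wilk undefined below that)",
          class = "wolbtiter_insufficient_data")
  shapiro_p <- vapply(list(a, b), function(x) {
    if (var(x) == 0) return(0)  # a point mass is maximally non-normal
    shapiro.test(x)$p.value
  }, numeric(1))
  grp <- factor(rep(c("a", "b"), c(length(a), length(b))))
  centerfun <- if (levene_center == "mean") mean else median
  lev <- car::leveneTest(c(a, b), grp, center = centerfun)
  levene_p <- lev[["Pr(>F)"]][1]
  if (is.na(levene_p)) levene_p <- 1  # both groups constant: no evidence either way
  normal <- all(shapiro_p > diag_alpha)
  homogeneous <- levene_p > diag_alpha
  test_name <- if (normal) {
    if (homogeneous) "student_t" else "welch_t"
  } else {
    if (homogeneous) "mann_whitney" else "randomization_t"
  }
  list(test_name = test_name,
       shapiro_p = c(a = shapiro_p[1], b = shapiro_p[2]),
       levene_p = levene_p, normal = normal, homogeneous = homogeneous,
       diag_alpha = diag_alpha)
}

.new_titer_test <- function(test_name, statistic, p_value, n, diagnostics,
                            extra = list()) {
  structure(c(list(test_name = test_name, statistic = unname(statistic),
                   p_value = unname(p_value), n = n,
                   shapiro_p = diagnostics$shapiro_p %||% c(a = NA_real_, b = NA_real_),
                   levene_p = diagnostics$levene_p %||% NA_real_,
                   alpha_used = diagnostics$diag_alpha %||% NA_real_),
              extra),
            class = "titer_test")
}

#' @export
print.titer_test <- function(x, ...) {
  cat(sprintf("<titer_test> %s: statistic = %.4g, two-tailed p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  if (!all(is.na(x$shapiro_p)))
    cat(sprintf("  diagnostics: Shapiro p = %.3g / %.3g, Levene p = %.3g (alpha %.2g)\n",
                x$shapiro_p[1], x$shapiro_p[2], x$levene_p, x$alpha_used))
  invisible(x)
}

#' @method tidy titer_test
#' @export
tidy.titer_test <- function(x, ...) {
  tibble::tibble(test_name = x$test_name, statistic = x$statistic,
                 p_value = x$p_value,
                 n_a = x$n[1], n_b = if (length(x$n) > 1) x$n[2] else NA_integer_,
                 shapiro_p_a = x$shapiro_p[1], shapiro_p_b = x$shapiro_p[2],
                 levene_p = x$levene_p)
}

#' @method glance titer_test
#' @export
glance.titer_test <- tidy.titer_test

# Mann-Whitney U with the package-wide p-value rule: exact when the combined
# sample size is <= 20 with no ties, else normal approximation with tie and
# continuity correction.
.mw_test <- function(a, b) {
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && (length(a) + length(b)) <= 20
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Compare two groups with the decision-tree-selected test
#'
#' Runs [select_test()] and applies the chosen two-sample test, two-tailed.
#' Deterministic given `seed` when the randomization test is selected.
#'
#' @inheritParams select_test
#' @param reps Bootstrap replicates for the randomization test.
#' @param seed Seed for the randomization test (ignored otherwise).
#' @param randomization_method Null construction for the randomization
#'   test; see [randomization_t_test()].
#' @return A `titer_test` object: `test_name`, `statistic`, two-tailed
#'   `p_value`, per-group diagnostics, group sizes.
#' @export
compare_two_groups <- function(a, b, diag_alpha = 0.05, reps = 10000,
                               seed = NULL, levene_center = c("mean", "median"),
                               randomization_method = c("bootstrap", "permutation")) {
  a <- .check_numeric(a, "a"); b <- .check_numeric(b, "b")
  n <- c(a = length(a), b = length(b))
  if (var(a) == 0 && var(b) == 0) {
    # no within-group variation at all: any location test is degenerate
    .assert(mean(a) == mean(b),
            "both groups are constant with different values: no valid test applies",
            class = "wolbtiter_degenerate_data")
    return(.new_titer_test("student_t", 0, 1, n,
                           list(shapiro_p = c(a = 0, b = 0), levene_p = 1,
                                diag_alpha = diag_alpha)))
  }
  sel <- select_test(a, b, diag_alpha, levene_center)
  res <- switch(sel$test_name,
    student_t = {
      tt <- t.test(a, b, var.equal = TRUE)
      list(statistic = unname(tt$statistic), p = tt$p.value)
    },
    welch_t = {
      tt <- t.test(a, b)
      list(statistic = unname(tt$statistic), p = tt$p.value)
    },
    mann_whitney = .mw_test(a, b),
    randomization_t = {
      rt <- randomization_t_test(a, b, reps = reps, seed = seed,
                                 method = randomization_method)
      list(statistic = rt$statistic, p = rt$p_value)
    })
  .new_titer_test(sel$test_name, res$statistic, res$p, n, sel,
                  extra = if (sel$test_name == "randomization_t")
                    list(reps = reps, seed = seed) else list())
}

#' Data-frame interface to the two-group comparison
#'
#' @param data A data frame with a value column and a two-level condition
#'   column.
#' @param value,condition Column names (strings or bare names via `{{ }}`
#'   is not required; strings are fine).
#' @param ... Passed to [compare_two_groups()].
#' @return A `titer_test`.
#' @export
compare_conditions <- function(data, value, condition, ...) {
  data <- tibble::as_tibble(data)
  .assert(all(c(value, condition) %in% names(data)),
          "`value`/`condition` columns not found in `data`")
  v <- data[[value]]; g <- data[[condition]]
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- factor(g[keep])
  .assert(nlevels(g) == 2, "`condition` must have exactly two levels")
  compare_two_groups(v[g == levels(g)[1]], v[g == levels(g)[2]], ...)
}

#' Bootstrap randomization t-test
#'
#' Resampling estimate of the two-tailed p-value for a location difference
#' when neither normality nor variance homogeneity holds. The observed
#' statistic is Welch's t. The null is built by centering both groups to the
#' pooled mean and resampling each group with replacement (`"bootstrap"`,
#' default), or by permuting group labels (`"permutation"`). The p-value is
#' `(1 + #{|t*| >= |t_obs|}) / (1 + reps)`, which is a valid (slightly
#' conservative) Monte-Carlo p-value.
#'
#' @param a,b Numeric samples.
#' @param reps Number of resamples (>= 100).
#' @param seed RNG seed for reproducibility.
#' @param method Null construction (see above).
#' @return A `titer_test` with `test_name = "randomization_t"`.
#' @export
randomization_t_test <- function(a, b, reps = 10000, seed = NULL,
                                 method = c("bootstrap", "permutation")) {
  method <- match.arg(method)
  a <- .check_numeric(a, "a"); b <- .check_numeric(b, "b")
  .assert(reps >= 100, "`reps` must be at least 100")
  .assert(var(a) > 0 || var(b) > 0,
          "zero variance in both groups: randomization test degenerate",
          class = "wolbtiter_degenerate_data")
  na <- length(a); nb <- length(b)
  obs <- .welch_stat(a, b)$statistic
  tstar <- .with_seed(seed, {
    if (method == "bootstrap") {
      gm <- mean(c(a, b))
      ac <- a - mean(a) + gm
      bc <- b - mean(b) + gm
      A <- matrix(ac[sample.int(na, na * reps, replace = TRUE)], na)
      B <- matrix(bc[sample.int(nb, nb * reps, replace = TRUE)], nb)
    } else {
      pool <- c(a, b)
      idx <- vapply(seq_len(reps), function(i) sample.int(na + nb),
                    integer(na + nb))
      A <- matrix(pool[idx[seq_len(na), ]], na)
      B <- matrix(pool[idx[na + seq_len(nb), ]], nb)
    }
    n1 <- nrow(A); n2 <- nrow(B)
    m1 <- colMeans(A); m2 <- colMeans(B)
    v1 <- pmax((colSums(A * A) - n1 * m1^2) / (n1 - 1), 0)
    v2 <- pmax((colSums(B * B) - n2 * m2^2) / (n2 - 1), 0)
    (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
  })
  # non-finite resampled statistics (all-tied draws) count as exceedances:
  # conservative, keeps the p-value valid
  exceed <- !is.finite(tstar) | abs(tstar) >= abs(obs)
  p <- (1 + sum(exceed)) / (1 + reps)
  .new_titer_test("randomization_t", obs, p, c(a = na, b = nb),
                  list(), extra = list(reps = reps, seed = seed,
                                       method = method))
}

#' Kruskal-Wallis rank ANOVA across three or more groups
#'
#' Non-parametric comparison across developmental stages (or any >= 3
#' groups): tie-corrected H statistic with a chi-square p-value on k - 1
#' degrees of freedom. All values identical across groups gives H = 0,
#' p = 1 (no evidence, not an error).
#'
#' @param groups A named or unnamed list of numeric samples (>= 3 groups,
#'   each n >= 2), or a data frame plus `value`/`group` column names.
#' @param value,group Column names when `groups` is a data frame.
#' @return A `titer_test` with `test_name = "kruskal_wallis"`.
#' @export
kruskal_wallis <- function(groups, value = "value", group = "condition") {
  if (is.data.frame(groups)) {
    groups <- split(groups[[value]], groups[[group]])
  }
  .assert(is.list(groups) && length(groups) >= 3, "need at least 3 groups")
  .assert(all(vapply(groups, length, integer(1)) >= 2),
          "each group needs n >= 2")
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1) {
    return(.new_titer_test("kruskal_wallis", 0, 1,
                           vapply(groups, length, integer(1)), list(),
                           extra = list(df = length(groups) - 1)))
  }
  kt <- kruskal.test(groups)
  .new_titer_test("kruskal_wallis", unname(kt$statistic), kt$p.value,
                  vapply(groups, length, integer(1)), list(),
                  extra = list(df = unname(kt$parameter)))
}
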