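#' Empirical power at one subsample size
#'
#' One point of the subsampling power procedure: draw `n` values with
#' replacement independently from each of two titer datasets, test the two
#' subsamples two-tailed, repeat, and report the proportion of iterations
#' with p below `alpha`. Subsamples with zero variance in both groups carry
#' no information and count as non-significant.
#'
#' @param a,b Source titer datasets (non-empty numeric).
#' @param n Subsample size per group (>= 2).
#' @param iterations Number of subsample iterations (default 10000).
#' @param alpha Two-tailed significance level (default 0.01).
#' @param test `"auto"` (default: selected once from the full datasets via
#'   [select_test()], restricted to the t-variants and Mann-Whitney — a
#'   randomization-test selection maps to Welch's t),
#'   `"auto_per_iteration"` (re-run the normality/variance diagnostics on
#'   every subsample pair and dispatch per iteration), or one of
#'   `"student_t"`, `"welch_t"`, `"mann_whitney"`.
#' @param diag_alpha Diagnostic alpha for per-iteration selection.
#' @param seed RNG seed; identical inputs and seed give identical results.
#' @return One-row tibble: `n`, `test`, `proportion_significant`, `mc_se`
#'   (binomial Monte-Carlo standard error), `n_significant`, `iterations`,
#'   `alpha`.
#' @export
power_at_n <- function(a, b, n, iterations = 10000, alpha = 0.01,
                       test = "auto", diag_alpha = 0.05, seed = NULL) {
  a <- .check_numeric(a, "a"); b <- .check_numeric(b, "b")
  .assert(n >= 2, "`n` must be >= 2")
  .assert(iterations >= 1, "`iterations` must be >= 1")
  .assert(alpha > 0 && alpha < 1, "`alpha` must lie in (0, 1)")
  test <- .resolve_power_test(a, b, test)
  p <- .with_seed(seed, {
    A <- matrix(a[sample.int(length(a), n * iterations, replace = TRUE)], n)
    B <- matrix(b[sample.int(length(b), n * iterations, replace = TRUE)], n)
    switch(test,
           student_t = .t_p_cols(A, B, var_equal = TRUE),
           welch_t = .t_p_cols(A, B, var_equal = FALSE),
           mann_whitney = .mw_p_cols(A, B),
           auto_per_iteration = .auto_iter_p_cols(A, B, diag_alpha))
  })
  nsig <- sum(!is.na(p) & p < alpha)
  prop <- nsig / iterations
  tibble::tibble(n = as.integer(n), test = test,
                 proportion_significant = prop,
                 mc_se = sqrt(prop * (1 - prop) / iterations),
                 n_significant = nsig,
                 iterations = as.integer(iterations), alpha = alpha)
}

.resolve_power_test <- function(a, b, test) {
  choices <- c("auto", "auto_per_iteration", "student_t", "welch_t",
               "mann_whitney")
  test <- match.arg(test, choices)
  if (test != "auto") return(test)
  sel <- select_test(a, b)$test_name
  if (sel == "randomization_t") sel <- "welch_t"  # too costly for the inner loop
  sel
}

# Per-iteration decision-tree dispatch on subsample columns. Mirrors
# select_test() with the randomization branch mapped to Welch's t (the
# decision-tree concretization used throughout the subsampling procedure).
# Subsamples too small for Shapiro-Wilk (n < 3) use Welch's t.
.auto_iter_p_cols <- function(A, B, diag_alpha) {
  it <- ncol(A)
  if (nrow(A) < 3 || nrow(B) < 3) return(.t_p_cols(A, B, var_equal = FALSE))
  swp <- function(M) apply(M, 2, function(col) {
    if (var(col) == 0) 0 else shapiro.test(col)$p.value
  })
  normal <- swp(A) > diag_alpha & swp(B) > diag_alpha
  lev <- vapply(seq_len(it), function(j) .levene_p2(A[, j], B[, j]),
                numeric(1))
  hom <- is.na(lev) | lev > diag_alpha
  p <- rep(NA_real_, it)
  grp_s <- normal & hom
  grp_w <- !hom  # Welch for heterogeneous variances, normal or not
  grp_m <- !normal & hom
  if (any(grp_s)) p[grp_s] <- .t_p_cols(A[, grp_s, drop = FALSE],
                                        B[, grp_s, drop = FALSE], TRUE)
  if (any(grp_w)) p[grp_w] <- .t_p_cols(A[, grp_w, drop = FALSE],
                                        B[, grp_w, drop = FALSE], FALSE)
  if (any(grp_m)) p[grp_m] <- .mw_p_cols(A[, grp_m, drop = FALSE],
                                         B[, grp_m, drop = FALSE])
  p
}

#' Subsampling power curve over a range of sample sizes
#'
#' Vectorizes [power_at_n()] over `n_range` with an independent seeded
#' stream per subsample size.
#'
#' @inheritParams power_at_n
#' @param n_range Integer subsample sizes (default `2:35`).
#' @param test_policy `"auto_once"` (default: one test chosen from the full
#'   datasets and reused at every n and iteration),
#'   `"auto_per_iteration"` (diagnostics re-run on every subsample), or
#'   `"fixed"` (use `test`).
#' @param test Test for `test_policy = "fixed"`.
#' @return A tibble of class `power_curve` (one row per n) with the
#'   configuration in `attr(, "config")`.
#' @export
power_curve <- function(a, b, n_range = 2:35, iterations = 10000,
                        alpha = 0.01,
                        test_policy = c("auto_once", "auto_per_iteration",
                                        "fixed"),
                        test = "welch_t", seed = NULL) {
  test_policy <- match.arg(test_policy)
  a <- .check_numeric(a, "a"); b <- .check_numeric(b, "b")
  .assert(length(n_range) >= 1 && all(n_range >= 2),
          "`n_range` must contain sizes >= 2")
  resolved <- switch(test_policy,
                     auto_once = .resolve_power_test(a, b, "auto"),
                     auto_per_iteration = "auto_per_iteration",
                     fixed = .resolve_power_test(a, b, test))
  rows <- purrr::map(seq_along(n_range), function(i) {
    power_at_n(a, b, n_range[i], iterations = iterations, alpha = alpha,
               test = resolved,
               seed = if (is.null(seed)) NULL else seed + i)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- list(n_range = as.integer(n_range),
                              iterations = as.integer(iterations),
                              alpha = alpha, test_policy = test_policy,
                              test = resolved, seed = seed)
  class(out) <- c("power_curve", class(out))
  out
}

#' Smallest subsample size reaching a target power
#'
#' First crossing of the power curve above `target`; `NA` when the curve
#' never reaches it.
#'
#' @param curve A [power_curve()] result (or any tibble with `n` and
#'   `proportion_significant`).
#' @param target Target proportion of significant outcomes, in (0, 1].
#' @return Smallest `n` with proportion >= target, or `NA_integer_`.
#' @export
min_n_for_power <- function(curve, target) {
  .assert(is.numeric(target) && length(target) == 1 && target > 0 && target <= 1,
          "`target` must lie in (0, 1]")
  .assert(all(c("n", "proportion_significant") %in% names(curve)),
          "`curve` must carry columns n and proportion_significant")
  ord <- order(curve$n)
  hit <- which(curve$proportion_significant[ord] >= target)
  if (!length(hit)) return(NA_integer_)
  as.integer(curve$n[ord][hit[1]])
}

#' @method autoplot power_curve
#' @export
autoplot.power_curve <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n,
                                       y = .data$proportion_significant)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(0, .data$proportion_significant - 3 * .data$mc_se),
      ymax = pmin(1, .data$proportion_significant + 3 * .data$mc_se)),
      alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = cfg$alpha %||% object$alpha[1],
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "subsample size n per group",
                  y = sprintf("proportion significant (two-tailed p < %.3g)",
                              cfg$alpha %||% object$alpha[1]),
                  title = sprintf("Subsampling power (%s, %d iterations per n)",
                                  cfg$test %||% object$test[1],
                                  cfg$iterations %||% object$iterations[1])) +
    ggplot2::theme_minimal()
}

#' @export
plot.power_curve <- function(x, ...) print(autoplot(x, ...))
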