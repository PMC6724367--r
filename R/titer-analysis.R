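# Condition-level analyses of per-ovariole titer tables.
#
# The record schema is one row per ovariole:
#   ovariole, acquisition_order, condition,
#   gsc_single, gsc_cluster_total, gsc_cluster_cells, stage4, stage10
# (missing measurements are NA).

.titer_stages <- c("gsc_single", "stage4", "stage10")

#' Summarize titer by condition and developmental stage
#'
#' Per condition x stage: sample size, median titer, percent-of-control
#' (100 * median / control median), and a decision-tree two-sample test
#' against the control condition.
#'
#' @param records Ovariole record tibble (see file header for the schema).
#' @param control Control condition label; `NULL` (or a label absent from
#'   the data, with a warning) yields summaries without percent/tests.
#' @param stages Stage columns to summarize (default
#'   `gsc_single`, `stage4`, `stage10`).
#' @param diag_alpha Diagnostic alpha for test selection.
#' @param seed Seed for randomization tests, if selected.
#' @return Tibble: `condition`, `stage`, `n`, `median`,
#'   `percent_of_control`, `test_name`, `statistic`, `p_value` (test fields
#'   `NA` for the control itself and when no control is available).
#' @export
summarize_condition <- function(records, control = NULL,
                                stages = .titer_stages, diag_alpha = 0.05,
                                seed = NULL) {
  records <- tibble::as_tibble(records)
  .assert("condition" %in% names(records), "`records` needs a condition column")
  stages <- intersect(stages, names(records))
  .assert(length(stages) >= 1, "no stage columns found in `records`")
  long <- tidyr::pivot_longer(records, dplyr::all_of(stages),
                              names_to = "stage", values_to = "titer") |>
    dplyr::filter(!is.na(.data$titer))
  have_control <- !is.null(control) && control %in% long$condition
  if (!is.null(control) && !have_control)
    warning(sprintf("control condition '%s' not present: summaries without tests",
                    control))
  smry <- long |>
    dplyr::group_by(.data$condition, .data$stage) |>
    dplyr::summarise(n = dplyr::n(), median = median(.data$titer),
                     .groups = "drop")
  smry$percent_of_control <- NA_real_
  smry$test_name <- NA_character_
  smry$statistic <- NA_real_
  smry$p_value <- NA_real_
  if (have_control) {
    for (i in seq_len(nrow(smry))) {
      ctrl_med <- smry$median[smry$condition == control &
                                smry$stage == smry$stage[i]]
      if (length(ctrl_med) == 1)
        smry$percent_of_control[i] <- 100 * smry$median[i] / ctrl_med
      if (smry$condition[i] != control) {
        ctrl <- long$titer[long$condition == control &
                             long$stage == smry$stage[i]]
        trt <- long$titer[long$condition == smry$condition[i] &
                            long$stage == smry$stage[i]]
        if (length(ctrl) >= 3 && length(trt) >= 3) {
          tst <- compare_two_groups(trt, ctrl, diag_alpha = diag_alpha,
                                    seed = seed)
          smry$test_name[i] <- tst$test_name
          smry$statistic[i] <- tst$statistic
          smry$p_value[i] <- tst$p_value
        }
      }
    }
  }
  dplyr::arrange(smry, factor(.data$stage, levels = stages), .data$condition)
}

#' Per-cell titer of a stem-cell cluster
#'
#' Divides each cluster's total nucleoid count by the number of cells
#' scored in the cluster (2-4 putative germline stem cells per ovariole).
#'
#' @param cluster_total Total count per cluster (vectorized).
#' @param n_cells Cells per cluster (>= 1).
#' @return Real-valued per-cell titer(s).
#' @export
per_cell_cluster_titer <- function(cluster_total, n_cells) {
  cluster_total <- .check_numeric(cluster_total, "cluster_total")
  .assert(is.numeric(n_cells) && all(is.finite(n_cells)),
          "`n_cells` must be numeric")
  .assert(all(n_cells >= 1), "`n_cells` must be >= 1")
  cluster_total / n_cells
}

#' Cross-stage titer regressions within ovarioles
#'
#' Ordinary least-squares regression of each later stage's titer on each
#' earlier stage's, across ovarioles: does early titer predict late titer
#' in the same ovariole? R-squared is orientation-invariant; slopes are for
#' the later-on-earlier orientation.
#'
#' @param records Ovariole record tibble.
#' @param stages Ordered stage columns (earliest first).
#' @return Tibble: `predictor`, `response`, `n`, `slope`, `intercept`,
#'   `r_squared`, `error` (a message when that pair could not be fit; other
#'   pairs are still computed).
#' @export
cross_stage_regression <- function(records, stages = .titer_stages) {
  records <- tibble::as_tibble(records)
  stages <- intersect(stages, names(records))
  .assert(length(stages) >= 2, "need at least two stage columns")
  pairs <- utils::combn(stages, 2)
  out <- purrr::map(seq_len(ncol(pairs)), function(k) {
    xs <- pairs[1, k]; ys <- pairs[2, k]  # earlier predicts later
    x <- records[[xs]]; y <- records[[ys]]
    ok <- !is.na(x) & !is.na(y)
    row <- tibble::tibble(predictor = xs, response = ys, n = sum(ok),
                          slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, error = NA_character_)
    if (sum(ok) < 3) {
      row$error <- "fewer than 3 complete records"
    } else if (var(x[ok]) == 0) {
      row$error <- "zero predictor variance"
    } else {
      fit <- lm(y[ok] ~ x[ok])
      row$slope <- unname(coef(fit)[2])
      row$intercept <- unname(coef(fit)[1])
      row$r_squared <- 1 - sum(residuals(fit)^2) /
        sum((y[ok] - mean(y[ok]))^2)
    }
    row
  })
  dplyr::bind_rows(out)
}

#' Acquisition-order drift check
#'
#' Compares titers of the first `k` against the last `k` samples in
#' acquisition order within one condition: photobleaching, staining-round
#' or imaging-session drift shows up as a first-half/last-half difference.
#'
#' @param records Ovariole records for a single condition, carrying
#'   `acquisition_order` (unique, no NA) and the stage column `value`.
#' @param value Stage column to test (e.g. `"gsc_single"`).
#' @param k Group size for each half (default `floor(n / 2)`, at most n/2).
#' @param alpha Drift-flag significance level (default 0.05).
#' @param diag_alpha,seed Passed to [compare_two_groups()].
#' @return One-row tibble: `n`, `k`, `median_first`, `median_last`,
#'   `test_name`, `statistic`, `p_value`, `drift`.
#' @export
acquisition_drift <- function(records, value, k = NULL, alpha = 0.05,
                              diag_alpha = 0.05, seed = NULL) {
  records <- tibble::as_tibble(records)
  .assert("acquisition_order" %in% names(records) &&
            !anyNA(records$acquisition_order),
          "`records` must carry a complete acquisition_order column")
  .assert(!anyDuplicated(records$acquisition_order),
          "acquisition_order must be unique within a session")
  .assert(value %in% names(records), sprintf("no column '%s'", value))
  records <- records[!is.na(records[[value]]), ]
  n <- nrow(records)
  k <- k %||% floor(n / 2)
  .assert(k >= 3 && 2 * k <= n, "`k` must satisfy 3 <= k <= n/2")
  ord <- order(records$acquisition_order)
  v <- records[[value]][ord]
  first <- v[seq_len(k)]; last <- v[seq.int(n - k + 1, n)]
  tst <- compare_two_groups(first, last, diag_alpha = diag_alpha, seed = seed)
  tibble::tibble(n = n, k = k,
                 median_first = median(first), median_last = median(last),
                 test_name = tst$test_name, statistic = tst$statistic,
                 p_value = tst$p_value, drift = tst$p_value < alpha)
}

#' Condition medians, violin-style overview plot
#'
#' @param records Ovariole record tibble.
#' @param stages Stage columns to include.
#' @return A ggplot: per-stage titer distributions by condition on a log
#'   scale.
#' @export
plot_titer_by_condition <- function(records, stages = .titer_stages) {
  records <- tibble::as_tibble(records)
  stages <- intersect(stages, names(records))
  long <- tidyr::pivot_longer(records, dplyr::all_of(stages),
                              names_to = "stage", values_to = "titer") |>
    dplyr::filter(!is.na(.data$titer))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$titer)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::stat_summary(fun = median, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~ stage, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "titer (nucleoids or copies)") +
    ggplot2::theme_minimal()
}
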