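test_that("condition summaries report medians, percent-of-control and tests", {
  rec <- tibble::tibble(ovariole = 1:8,
                        acquisition_order = 1:8,
                        condition = rep(c("ctl", "trt"), each = 4),
                        stage10 = c(100, 110, 120, 130, 30, 40, 50, 60))
  s <- summarize_condition(rec, control = "ctl")
  ctl <- s[s$condition == "ctl", ]; trt <- s[s$condition == "trt", ]
  expect_equal(ctl$median, 115)
  expect_equal(ctl$percent_of_control, 100)
  expect_equal(trt$percent_of_control, 100 * 45 / 115)
  expect_false(is.na(trt$p_value))
  expect_true(is.na(ctl$p_value))
  # single condition, identical values: median, no test
  one <- tibble::tibble(condition = "only", stage4 = rep(7, 5))
  s1 <- summarize_condition(one)
  expect_equal(s1$median, 7)
  expect_true(is.na(s1$test_name))
  expect_warning(summarize_condition(one, control = "missing"), "not present")
})

test_that("percent-of-control is scale invariant and medians match a sort-based oracle", {
  set.seed(60)
  rec <- tibble::tibble(condition = rep(c("ctl", "trt"), each = 10),
                        stage4 = rlnorm(20, 5, 0.5),
                        stage10 = rlnorm(20, 8, 0.4))
  s1 <- summarize_condition(rec, control = "ctl")
  rec2 <- dplyr::mutate(rec, stage4 = stage4 * 13, stage10 = stage10 * 13)
  s2 <- summarize_condition(rec2, control = "ctl")
  expect_equal(s1$percent_of_control, s2$percent_of_control)
  for (i in seq_len(nrow(s1))) {
    vals <- rec[[s1$stage[i]]][rec$condition == s1$condition[i]]
    expect_equal(s1$median[i], oracle_median(vals))
  }
})

test_that("cluster per-cell titers divide totals by cells scored", {
  expect_equal(per_cell_cluster_titer(120, 2), 60)
  expect_equal(per_cell_cluster_titer(77, 1), 77)
  expect_equal(per_cell_cluster_titer(c(90, 120), c(3, 4)), c(30, 30))
  expect_error(per_cell_cluster_titer(120, 0), ">= 1")
})

test_that("cross-stage regressions fit per pair and survive degenerate pairs", {
  rec <- tibble::tibble(gsc_single = c(10, 20, 30, 40),
                        stage4 = c(100, 200, 300, 400),
                        stage10 = c(1000, 2000, 3000, 4000))
  r <- cross_stage_regression(rec)
  expect_equal(nrow(r), 3)
  expect_true(all(abs(r$r_squared - 1) < 1e-12))
  set.seed(61)
  rec2 <- tibble::tibble(gsc_single = rnorm(30, 60, 10),
                         stage4 = rnorm(30, 1000, 200),
                         stage10 = rnorm(30, 20000, 4000))
  r2 <- cross_stage_regression(rec2)
  for (i in seq_len(3)) {
    o <- oracle_ols(rec2[[r2$predictor[i]]], rec2[[r2$response[i]]])
    expect_equal(r2$slope[i], o$slope, tolerance = 1e-9)
    expect_equal(r2$r_squared[i], o$r_squared, tolerance = 1e-9)
  }
  rec3 <- tibble::tibble(gsc_single = rep(5, 10), stage4 = rnorm(10),
                         stage10 = rnorm(10))
  r3 <- cross_stage_regression(rec3)
  expect_match(r3$error[r3$predictor == "gsc_single"][1], "variance")
  expect_true(all(is.na(r3$error[r3$predictor == "stage4"])))
})

test_that("acquisition drift flags trends but not stationary noise", {
  rec0 <- tibble::tibble(acquisition_order = 1:16,
                         gsc_single = rep(c(50, 60, 55, 45), 4))
  d0 <- acquisition_drift(rec0, "gsc_single", k = 4)
  expect_false(d0$drift)
  # identical halves: p = 1
  rec1 <- tibble::tibble(acquisition_order = 1:12,
                         gsc_single = rep(c(10, 20, 30, 40, 50, 60), 2))
  d1 <- acquisition_drift(rec1, "gsc_single", k = 6)
  expect_equal(d1$p_value, 1)
  # injected linear trend is detected in most seeds
  hits <- vapply(1:20, function(s) {
    set.seed(s + 300)
    rec <- tibble::tibble(acquisition_order = 1:30,
                          gsc_single = 100 - 2.5 * (1:30) + rnorm(30, 0, 8))
    acquisition_drift(rec, "gsc_single", k = 10, alpha = 0.01)$drift
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # stationary data flags at roughly the nominal rate
  null_hits <- vapply(1:200, function(s) {
    set.seed(s + 600)
    rec <- tibble::tibble(acquisition_order = 1:24,
                          gsc_single = rnorm(24, 100, 15))
    acquisition_drift(rec, "gsc_single", k = 8, alpha = 0.05)$drift
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(mean(null_hits), 0.05 + 3 * se)
  expect_error(acquisition_drift(tibble::tibble(gsc_single = 1:10),
                                 "gsc_single"), "acquisition_order")
})

test_that("synthetic supplementary tables carry their published summary statistics", {
  g <- synthetic_germline_titers(seed = 1)
  expect_equal(median(g$gsc_single), 61.5)
  expect_equal(median(g$stage4), 1140)
  expect_equal(median(g$stage10), 22500)
  pc <- per_cell_cluster_titer(g$gsc_cluster_total, g$gsc_cluster_cells)
  expect_equal(median(pc), 58.9)
  expect_equal(t.test(g$gsc_single, pc)$p.value, 0.878, tolerance = 1e-6)
  r2 <- cross_stage_regression(g)
  expect_equal(r2$r_squared, c(0.108, 0.084, 0.159), tolerance = 1e-9)
  m <- synthetic_method_comparison(seed = 1)
  expect_equal(oracle_ols(m$manual, m$auto)$r_squared, 0.854,
               tolerance = 1e-9)
  expect_equal(t.test(m$manual, m$auto, var.equal = TRUE)$p.value, 0.896,
               tolerance = 1e-9)
  d <- synthetic_diet_titers(seed = 1)
  med <- function(col, cond) median(d[[col]][d$condition == cond])
  expect_equal(med("gsc_single", "un-enriched"), 79)
  expect_equal(med("gsc_single", "yeast-enriched"), 55)
  expect_equal(med("stage10", "yeast-enriched") /
                 med("stage10", "un-enriched"), 8240 / 22900)
  expect_equal(t.test(d$gsc_single[d$condition == "un-enriched"],
                      d$gsc_single[d$condition == "yeast-enriched"])$p.value,
               0.017, tolerance = 1e-6)
  rif <- synthetic_rifampicin_qpcr(seed = 1)
  tr <- rif$truth
  expect_equal(median(tr$true_copies[tr$treatment == "rifampicin"]) /
                 median(tr$true_copies[tr$treatment == "DMSO"]), 0.29,
               tolerance = 1e-12)
})
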