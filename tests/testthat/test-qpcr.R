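test_that("standard-curve fitting matches closed forms and the OLS oracle", {
  pts <- data.frame(known_copies = c(1e2, 1e4, 1e6), ct = c(30, 20, 10))
  expect_warning(cv <- fit_standard_curve(pts), "efficiency")
  expect_equal(cv$slope, -5)
  expect_equal(cv$intercept, 40)
  expect_equal(cv$r_squared, 1)
  expect_equal(cv$efficiency, 10^0.2 - 1, tolerance = 1e-12)
  set.seed(2)
  noisy <- data.frame(known_copies = 10^(2:8),
                      ct = 36 - 3.32 * (2:8) + rnorm(7, 0, 0.2))
  cvn <- suppressWarnings(fit_standard_curve(noisy))
  o <- oracle_ols(log10(noisy$known_copies), noisy$ct)
  expect_equal(cvn$slope, o$slope, tolerance = 1e-9)
  expect_equal(cvn$intercept, o$intercept, tolerance = 1e-9)
  expect_error(fit_standard_curve(pts[1:2, ]),
               class = "wolbtiter_insufficient_data")
  bad <- data.frame(known_copies = c(1e2, 1e4, 1e6), ct = c(10, 20, 30))
  expect_error(suppressWarnings(fit_standard_curve(bad)),
               class = "wolbtiter_invalid_curve")
})

test_that("Ct conversion inverts the curve and is strictly decreasing", {
  cv <- structure(list(slope = -5, intercept = 40, r_squared = 1,
                       efficiency = 10^0.2 - 1, n_points = 3),
                  class = "standard_curve")
  expect_equal(ct_to_copies(cv, 40), 1)
  expect_equal(ct_to_copies(cv, 20), 1e4)
  expect_equal(ct_to_copies(cv, NA_real_), 0)
  cts <- seq(38, 8, by = -0.5)
  expect_true(all(diff(ct_to_copies(cv, cts)) > 0))
  # round trip over 6 decades with perfect-doubling chemistry
  g <- plate_ground_truth(data.frame(sample = paste0("s", 1:6), gene = "wsp",
                                     true_copies = 10^(1:6)),
                          efficiency = 1, ct_noise_sd = 0)
  pl <- make_qpcr_plate(g)
  cv2 <- fit_standard_curve(pl$standards)
  est <- quantify_plate(pl$samples, pl$standards)
  expect_equal(sort(est$copies_per_reaction), 10^(1:6), tolerance = 1e-9)
  expect_equal(ct_to_copies(cv2, cv2$intercept), 1, tolerance = 1e-12)
})

test_that("replicate aggregation handles sentinels and schema violations", {
  cv <- structure(list(slope = -1 / log10(2), intercept = 35, r_squared = 1,
                       efficiency = 1, n_points = 4),
                  class = "standard_curve")
  w <- tibble::tibble(sample = "s1", gene = "wsp", ct = c(25, 25, 25))
  expect_equal(summarize_sample(w, cv)$copies_per_reaction,
               ct_to_copies(cv, 25))
  w2 <- tibble::tibble(sample = "s1", gene = "wsp", ct = c(25, 26, NA))
  s2 <- summarize_sample(w2, cv)
  expect_equal(s2$n_sentinel, 1L)
  expect_true(s2$infected)
  expect_equal(s2$copies_per_reaction,
               median(ct_to_copies(cv, c(25, 26))))
  s3 <- summarize_sample(tibble::tibble(sample = "s1", gene = "wsp",
                                        ct = c(NA_real_, NA_real_)), cv)
  expect_equal(s3$copies_per_reaction, 0)
  expect_false(s3$infected)
  expect_error(summarize_sample(tibble::tibble(sample = c("s1", "s2"),
                                               gene = "wsp", ct = c(20, 21)),
                                cv),
               class = "wolbtiter_schema_error")
  # mean aggregation differs from median with an outlier replicate
  w4 <- tibble::tibble(sample = "s1", gene = "wsp", ct = c(25, 25, 20))
  expect_gt(summarize_sample(w4, cv, "mean")$copies_per_reaction,
            summarize_sample(w4, cv, "median")$copies_per_reaction)
})

test_that("relative ratios expose the endoreplication confounder", {
  expect_equal(relative_ratio(0, 10), 0)
  expect_equal(relative_ratio(7, 7), 1)
  expect_error(relative_ratio(5, 0), class = "wolbtiter_undefined_ratio")
  wsp <- 2e4; host <- 1e3
  base <- relative_ratio(wsp, host)
  # rescaling both estimates leaves the ratio unchanged
  expect_equal(relative_ratio(3 * wsp, 3 * host), base)
  # a 1.7x rise in host copies at constant symbiont load drops the ratio
  # by 1/1.7 even though absolute abundance did not change
  expect_equal(relative_ratio(wsp, 1.7 * host), base / 1.7)
})

test_that("infection calls match plate ground truth", {
  expect_false(classify_infection(c(NA_real_, NA_real_)))
  expect_true(classify_infection(c(NA, 24)))
  vp <- synthetic_validation_plate(seed = 6)
  wsp <- vp$plate$samples[vp$plate$samples$gene == "wsp", ]
  calls <- tapply(wsp$ct, wsp$sample, classify_infection)
  truth <- vp$truth[vp$truth$gene == "wsp", ]
  expect_equal(as.logical(calls[truth$sample]), truth$infected)
})

test_that("source extrapolation applies the dilution arithmetic", {
  expect_equal(extrapolate_source_copies(123, 10, 10, 1, 1), 123)
  expect_equal(extrapolate_source_copies(1000, 2, 100, 10, 5), 1e5)
  expect_error(extrapolate_source_copies(10, 0, 100, 1, 5), "positive")
  # noise-free recovery of a known per-fly truth
  per_fly <- 4.3e7; flies <- 5; extract <- 100; template <- 2; dil <- 10
  per_rxn <- per_fly * flies / dil / (extract / template)
  expect_equal(extrapolate_source_copies(per_rxn, template, extract, dil,
                                         flies), per_fly)
})

test_that("noisy plates recover copy numbers within the Monte-Carlo bound", {
  # Independent oracle for the attainable precision: median over replicates
  # of copies under Ct noise sd 0.25 with slope -3.32 has relative error
  # distribution simulable directly from the noise model.
  set.seed(40)
  slope <- -1 / log10(2)
  rel_err <- replicate(2000, {
    est <- median(10^(rnorm(3, 0, 0.25) / abs(slope)))
    abs(est - 1)
  })
  bound <- quantile(rel_err, 0.99)
  errs <- vapply(1:60, function(s) {
    truth <- data.frame(sample = "s1", gene = "wsp", true_copies = 5e4)
    g <- plate_ground_truth(truth, efficiency = 1, ct_noise_sd = 0.25,
                            seed = s)
    pl <- make_qpcr_plate(g)
    est <- quantify_plate(pl$samples, pl$standards)
    abs(est$copies_per_reaction - 5e4) / 5e4
  }, numeric(1))
  expect_lt(median(errs), bound)
})
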