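#' Ground truth for a synthetic qPCR plate
#'
#' Describes the true state a synthetic plate is generated from: per-sample,
#' per-gene template copy numbers, the amplification efficiency of the
#' chemistry, and the Ct measurement noise.
#'
#' @param true_copies A data frame with columns `sample`, `gene`,
#'   `true_copies` (non-negative; 0 marks an uninfected sample for a
#'   symbiont-specific gene) and optionally `treatment`.
#' @param efficiency Per-cycle amplification efficiency E in (0, 1.5]
#'   (1 = perfect doubling).
#' @param intercept Ct at a single template copy (default 35).
#' @param ct_noise_sd Gaussian sd of Ct measurement noise (>= 0).
#' @param seed RNG seed.
#' @return An object of class `plate_ground_truth`.
#' @export
plate_ground_truth <- function(true_copies, efficiency = 1, intercept = 35,
                               ct_noise_sd = 0, seed = 1L) {
  true_copies <- tibble::as_tibble(true_copies)
  .assert(all(c("sample", "gene", "true_copies") %in% names(true_copies)),
          "`true_copies` needs columns sample, gene, true_copies")
  .assert(all(true_copies$true_copies >= 0), "true copy numbers must be >= 0")
  .assert(efficiency > 0 && efficiency <= 1.5, "`efficiency` must lie in (0, 1.5]")
  .assert(ct_noise_sd >= 0, "`ct_noise_sd` must be >= 0")
  if (!"treatment" %in% names(true_copies)) true_copies$treatment <- NA_character_
  structure(list(true_copies = true_copies, efficiency = efficiency,
                 intercept = intercept, ct_noise_sd = ct_noise_sd,
                 seed = seed),
            class = "plate_ground_truth")
}

#' Simulate a qPCR plate from ground truth
#'
#' Generates threshold-cycle values through the log-linear amplification
#' model `Ct = intercept + slope * log10(copies)` with
#' `slope = -1 / log10(1 + efficiency)` and additive Gaussian Ct noise.
#' Zero-copy wells never amplify and carry the no-amplification sentinel
#' (`NA` Ct). The emitted dilution series, fitted with
#' [fit_standard_curve()], inverts the model: with zero noise the fit
#' recovers slope and intercept exactly.
#'
#' @param ground A [plate_ground_truth()].
#' @param dilution_series Known plasmid copy numbers for the standard curve;
#'   must be positive, with >= 3 points spanning >= 2 decades.
#' @param n_replicates Technical replicates per sample well (default 3).
#' @param plate Plate identifier.
#' @param flies_per_sample Recorded provenance: flies homogenized per sample
#'   (default 5).
#' @return A list with `standards` (tibble `gene, known_copies, ct`) and
#'   `samples` (tibble `plate, well, sample, gene, treatment, replicate, ct`;
#'   `NA` ct = no amplification) plus a `flies_per_sample` attribute.
#' @export
make_qpcr_plate <- function(ground, dilution_series = 10^(2:7),
                            n_replicates = 3, plate = "P1",
                            flies_per_sample = 5) {
  .assert(inherits(ground, "plate_ground_truth"),
          "`ground` must be a plate_ground_truth")
  .assert(all(dilution_series > 0),
          "dilution series copy numbers must be positive")
  .assert(length(dilution_series) >= 3, "need >= 3 dilution points")
  .assert(log10(max(dilution_series) / min(dilution_series)) >= 2,
          "dilution series must span at least 2 decades")
  slope <- -1 / log10(1 + ground$efficiency)
  .with_seed(ground$seed, {
    std_ct <- ground$intercept + slope * log10(dilution_series)
    genes <- unique(ground$true_copies$gene)
    standards <- tidyr::crossing(gene = genes,
                                 known_copies = sort(dilution_series,
                                                     decreasing = TRUE))
    standards$ct <- ground$intercept + slope * log10(standards$known_copies) +
      rnorm(nrow(standards), 0, ground$ct_noise_sd)

    samples <- tidyr::uncount(ground$true_copies, n_replicates, .id = "replicate")
    samples$plate <- plate
    samples$well <- sprintf("%s_%s_%s_r%d", plate, samples$sample,
                            samples$gene, samples$replicate)
    samples$ct <- ifelse(
      samples$true_copies > 0,
      ground$intercept + slope * log10(pmax(samples$true_copies, 1e-300)) +
        rnorm(nrow(samples), 0, ground$ct_noise_sd),
      NA_real_)
    samples <- dplyr::select(samples, "plate", "well", "sample", "gene",
                             "treatment", "replicate", "ct")
    out <- list(standards = standards, samples = samples)
    attr(out, "flies_per_sample") <- flies_per_sample
    out
  })
}

#' Generate a synthetic titer dataset
#'
#' Draws `n` titer values with a prescribed theoretical median and
#' dispersion, emulating per-sample nucleoid counts or copy-number
#' estimates. For `"lognormal"`, values are `rlnorm(n, log(median),
#' dispersion)` so the theoretical median equals `median` and `dispersion`
#' is the log-scale sd; for `"normal"`, mean = `median` and `dispersion` is
#' the sd. `dispersion = 0` degenerates to `n` copies of the median.
#'
#' @param median Target theoretical median (> 0).
#' @param dispersion Spread parameter (>= 0; units depend on `distribution`).
#' @param n Number of values (>= 1).
#' @param distribution `"lognormal"` (default; titers are right-skewed,
#'   positive counts) or `"normal"`.
#' @param seed RNG seed.
#' @return Numeric vector of length `n`.
#' @export
make_titer_dataset <- function(median, dispersion, n,
                               distribution = c("lognormal", "normal"),
                               seed = 1L) {
  distribution <- match.arg(distribution)
  .assert(median > 0, "`median` must be positive")
  .assert(dispersion >= 0, "`dispersion` must be >= 0")
  .assert(n >= 1, "`n` must be >= 1")
  if (dispersion == 0) return(rep(median, n))
  .with_seed(seed, switch(distribution,
    lognormal = rlnorm(n, meanlog = log(median), sdlog = dispersion),
    normal = rnorm(n, mean = median, sd = dispersion)))
}
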