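#' Fit a qPCR standard curve
#'
#' Least-squares fit of threshold cycle against log10 template copies over a
#' plasmid dilution series: `Ct = intercept + slope * log10(copies)`. The
#' amplification efficiency is derived as `E = 10^(-1/slope) - 1` (perfect
#' doubling: slope -3.3219, E = 1).
#'
#' @param points Data frame with columns `known_copies` (> 0) and `ct`, one
#'   row per dilution point; >= 3 points spanning >= 2 decades.
#' @param qc_efficiency Acceptable efficiency band; a warning is raised
#'   outside it (default `c(0.9, 1.1)`).
#' @param qc_r_squared Minimum R^2 before a warning (default 0.98).
#' @return An object of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `n_points`.
#' @export
fit_standard_curve <- function(points, qc_efficiency = c(0.9, 1.1),
                               qc_r_squared = 0.98) {
  points <- tibble::as_tibble(points)
  .assert(all(c("known_copies", "ct") %in% names(points)),
          "`points` needs columns known_copies and ct")
  .assert(nrow(points) >= 3, "need at least 3 dilution points",
          class = "wolbtiter_insufficient_data")
  .assert(all(points$known_copies > 0), "known copy numbers must be positive")
  .assert(all(is.finite(points$ct)), "Ct values must be finite")
  .assert(log10(max(points$known_copies) / min(points$known_copies)) >= 2,
          "dilution series must span at least 2 log10 decades")
  x <- log10(points$known_copies)
  fit <- lm(points$ct ~ x)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  .assert(slope < 0,
          "fitted slope is non-negative: not a valid amplification curve",
          class = "wolbtiter_invalid_curve")
  r2 <- 1 - sum(residuals(fit)^2) / sum((points$ct - mean(points$ct))^2)
  eff <- 10^(-1 / slope) - 1
  if (eff < qc_efficiency[1] || eff > qc_efficiency[2])
    warning(sprintf("amplification efficiency %.3f outside QC band [%.2f, %.2f]",
                    eff, qc_efficiency[1], qc_efficiency[2]))
  if (r2 < qc_r_squared)
    warning(sprintf("standard curve R^2 = %.4f below QC minimum %.2f",
                    r2, qc_r_squared))
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency = eff, n_points = nrow(points)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> Ct = %.4f %+.4f * log10(copies)  (n = %d)\n",
              x$intercept, x$slope, x$n_points))
  cat(sprintf("  R^2 = %.5f, efficiency = %.1f%%\n",
              x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, efficiency = x$efficiency,
                 n_points = x$n_points)
}

#' Convert threshold cycles to absolute copy numbers
#'
#' Inverts the standard curve: `copies = 10^((ct - intercept) / slope)`.
#' The no-amplification sentinel (`NA` Ct) converts to 0 copies.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param ct Numeric Ct values (`NA` = no amplification).
#' @return Copies per reaction (same length as `ct`).
#' @export
ct_to_copies <- function(curve, ct) {
  .assert(inherits(curve, "standard_curve"), "`curve` must be a standard_curve")
  out <- 10^((ct - curve$intercept) / curve$slope)
  out[is.na(ct)] <- 0
  out
}

#' Aggregate technical replicates into a copy-number estimate
#'
#' Converts each replicate Ct of one sample/gene to copies and aggregates.
#' Sentinel (non-amplifying) replicates are excluded from the aggregate and
#' recorded; if every replicate is sentinel the sample is called uninfected
#' with 0 copies.
#'
#' @param wells Tibble of wells for a single sample and gene (columns
#'   `sample`, `gene`, `ct`; extra columns pass through the schema check).
#' @param curve Standard curve for that gene.
#' @param aggregation `"median"` (default; robust to single outlier wells)
#'   or `"mean"`.
#' @return One-row tibble: `sample`, `gene`, `copies_per_reaction`,
#'   `n_replicates`, `n_sentinel`, `aggregation`, `infected`.
#' @export
summarize_sample <- function(wells, curve, aggregation = c("median", "mean")) {
  aggregation <- match.arg(aggregation)
  wells <- tibble::as_tibble(wells)
  .assert(all(c("sample", "gene", "ct") %in% names(wells)),
          "`wells` needs columns sample, gene, ct")
  .assert(nrow(wells) >= 1, "no wells supplied")
  .assert(length(unique(wells$sample)) == 1 && length(unique(wells$gene)) == 1,
          "wells mix samples or genes: summarize one sample+gene at a time",
          class = "wolbtiter_schema_error")
  sentinel <- is.na(wells$ct)
  if (all(sentinel)) {
    copies <- 0
  } else {
    reps <- ct_to_copies(curve, wells$ct[!sentinel])
    copies <- if (aggregation == "median") median(reps) else mean(reps)
  }
  tibble::tibble(sample = wells$sample[1], gene = wells$gene[1],
                 copies_per_reaction = copies,
                 n_replicates = nrow(wells), n_sentinel = sum(sentinel),
                 aggregation = aggregation, infected = !all(sentinel))
}

#' Quantify every sample/gene on a plate
#'
#' Fits one standard curve per gene from the plate's dilution series and
#' aggregates each sample's technical replicates into absolute copy numbers.
#'
#' @param samples Well table (`plate, well, sample, gene, treatment,
#'   replicate, ct`; `NA` ct = no amplification).
#' @param standards Dilution-series table (`gene, known_copies, ct`).
#' @param aggregation As in [summarize_sample()].
#' @return Tibble of copy estimates, one row per sample x gene, carrying the
#'   sample's `treatment` label.
#' @export
quantify_plate <- function(samples, standards,
                           aggregation = c("median", "mean")) {
  aggregation <- match.arg(aggregation)
  samples <- tibble::as_tibble(samples)
  standards <- tibble::as_tibble(standards)
  curves <- standards |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_map(~ fit_standard_curve(.x), .keep = FALSE)
  names(curves) <- sort(unique(standards$gene))
  samples |>
    dplyr::group_by(.data$sample, .data$gene) |>
    dplyr::group_modify(function(w, key) {
      .assert(key$gene %in% names(curves),
              sprintf("no standard curve for gene '%s' on this plate", key$gene))
      est <- summarize_sample(dplyr::mutate(w, sample = key$sample,
                                            gene = key$gene),
                              curves[[key$gene]], aggregation)
      est$treatment <- w$treatment[1] %||% NA_character_
      dplyr::select(est, -"sample", -"gene")
    }) |>
    dplyr::ungroup()
}

#' Relative titer as a target/reference copy ratio
#'
#' Ratio of symbiont-gene copies (wsp) to host-gene copies (rpl32) for one
#' sample. Note the denominator is *not* a constant per cell: host gene
#' copy number shifts with tissue ploidy, which is exactly the confounder
#' absolute quantification avoids.
#'
#' @param wsp,rpl32 One-row copy-estimate tibbles from [summarize_sample()]
#'   (same sample), or bare numerics.
#' @return The copy ratio (0 when the symbiont copies are 0).
#' @export
relative_ratio <- function(wsp, rpl32) {
  get1 <- function(x, name) {
    if (is.data.frame(x)) {
      .assert(nrow(x) == 1 && "copies_per_reaction" %in% names(x),
              paste0("`", name, "` must be a one-row copy estimate"))
      x$copies_per_reaction
    } else .check_numeric(x, name)
  }
  if (is.data.frame(wsp) && is.data.frame(rpl32))
    .assert(wsp$sample == rpl32$sample,
            "numerator and denominator come from different samples")
  num <- get1(wsp, "wsp"); den <- get1(rpl32, "rpl32")
  .assert(all(den > 0),
          "reference-gene copies are 0: relative ratio undefined",
          class = "wolbtiter_undefined_ratio")
  num / den
}

#' Classify a sample as infected from its symbiont-gene wells
#'
#' A sample is infected iff any technical replicate amplifies (numeric Ct
#' below `max_ct`); samples whose symbiont-gene wells are all sentinel are
#' uninfected.
#'
#' @param wells Well tibble (or a bare Ct vector) for one sample's
#'   symbiont-gene reactions.
#' @param max_ct Maximum cycle treated as genuine amplification (default 35).
#' @return Logical.
#' @export
classify_infection <- function(wells, max_ct = 35) {
  ct <- if (is.data.frame(wells)) wells$ct else wells
  .assert(length(ct) >= 1, "need at least one well")
  any(!is.na(ct) & ct < max_ct)
}

#' Back-extrapolate reaction copies to the source animal
#'
#' Scales copies detected in one qPCR reaction up to copies per fly:
#' `copies * (extract_volume / template_volume) * dilution_factor /
#' flies_per_sample`.
#'
#' @param copies_per_reaction Copies detected in the reaction (>= 0).
#' @param template_volume_ul Template volume loaded per reaction (> 0).
#' @param extract_volume_ul Total DNA extract volume (> 0).
#' @param dilution_factor Fold dilution of the extract before loading (> 0).
#' @param flies_per_sample Animals homogenized per sample (> 0, default 5).
#' @return Estimated copies per fly.
#' @export
extrapolate_source_copies <- function(copies_per_reaction, template_volume_ul,
                                      extract_volume_ul, dilution_factor = 1,
                                      flies_per_sample = 5) {
  .assert(all(copies_per_reaction >= 0), "copies must be >= 0")
  .assert(template_volume_ul > 0 && extract_volume_ul > 0 &&
            dilution_factor > 0 && flies_per_sample > 0,
          "volumes, dilution factor and flies per sample must be positive")
  copies_per_reaction * (extract_volume_ul / template_volume_ul) *
    dilution_factor / flies_per_sample
}
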