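#' Threshold a stack into foreground puncta
#'
#' Separates bright nucleoid puncta from background by global thresholding,
#' optionally after excluding masked regions. The threshold actually applied
#' is always returned for provenance.
#'
#' @param stack An [image_stack()] or `(z, y, x)` array.
#' @param masks Optional exclusion masks (logical `(z, y, x)` array, or a
#'   single plane broadcast across z). Masked voxels are removed from both the
#'   threshold computation and the foreground.
#' @param policy Threshold policy: `"otsu"` (default; Otsu's method on the
#'   pooled intensity histogram), `"fixed"` (use `value` as the threshold), or
#'   `"percentile"` (threshold at the `value` quantile of unmasked
#'   intensities, `value` in (0, 1)).
#' @param value Threshold for `"fixed"`, quantile for `"percentile"`.
#' @return A list with `binary` (logical `(z, y, x)` array, foreground =
#'   intensity strictly above threshold) and `threshold_used`.
#' @export
binarize_stack <- function(stack, masks = NULL,
                           policy = c("otsu", "fixed", "percentile"),
                           value = NULL) {
  policy <- match.arg(policy)
  vox <- .as_voxels(stack)
  d <- dim(vox)
  m <- .normalize_masks(masks, d)
  vals <- if (is.null(m)) as.vector(vox) else vox[!m]
  if (length(vals) == 0) {
    # every voxel excluded: empty foreground, threshold undefined
    warning("all voxels are masked: foreground is empty")
    return(list(binary = array(FALSE, d), threshold_used = NA_real_))
  }
  rng <- range(vals)
  thr <- switch(policy,
    fixed = {
      .assert(is.numeric(value) && length(value) == 1,
              "`value` must give the fixed threshold")
      .assert(value >= rng[1] && value <= rng[2],
              "fixed threshold lies outside the stack's intensity range")
      value
    },
    percentile = {
      .assert(is.numeric(value) && length(value) == 1 && value > 0 && value < 1,
              "`value` must be a quantile in (0, 1)")
      as.numeric(quantile(vals, value, names = FALSE))
    },
    otsu = {
      if (rng[2] - rng[1] <= 0) {
        warning("constant image: Otsu threshold is degenerate; foreground is empty")
        rng[2]
      } else {
        sc <- (vals - rng[1]) / (rng[2] - rng[1])
        t01 <- EBImage::otsu(EBImage::Image(matrix(sc, ncol = 1)),
                             range = c(0, 1), levels = 256L)
        rng[1] + t01 * (rng[2] - rng[1])
      }
    })
  binary <- vox > thr
  if (!is.null(m)) binary[m] <- FALSE
  list(binary = binary, threshold_used = thr)
}

#' Locate the Z-center of a sample
#'
#' For a roughly football-shaped egg chamber, the focal plane showing the
#' largest sample width (foreground area) marks the Z-center. Ties break
#' toward the lower (earlier-acquired) plane index.
#'
#' @param binary_stack Binary `(z, y, x)` array.
#' @return 1-based plane index of the widest plane.
#' @export
find_z_center <- function(binary_stack) {
  bin <- .as_voxels(binary_stack) > 0
  areas <- apply(bin, 1, sum)
  .assert(sum(areas) > 0, "no foreground voxels: cannot locate a sample",
          class = "wolbtiter_no_sample")
  which.max(areas)  # which.max already breaks ties toward the lower index
}

.new_puncta_result <- function(per_plane_counts, planes_used, total_raw,
                               total_reported, redundancy_fraction, method,
                               threshold_used, z_center = NA_integer_) {
  structure(list(per_plane_counts = as.integer(per_plane_counts),
                 planes_used = planes_used,
                 total_raw = as.integer(total_raw),
                 total_reported = total_reported,
                 redundancy_fraction = redundancy_fraction,
                 method = method, threshold_used = threshold_used,
                 z_center = z_center),
            class = "puncta_result")
}

#' @export
print.puncta_result <- function(x, ...) {
  cat(sprintf("<puncta_result> method %s: total_raw %d, total_reported %s\n",
              x$method, x$total_raw, format(x$total_reported)))
  cat(sprintf("  planes used: %s; threshold %.4g\n",
              if (length(x$planes_used)) paste(range(x$planes_used), collapse = "-") else "none",
              x$threshold_used))
  if (!is.na(x$redundancy_fraction %||% NA))
    cat(sprintf("  inter-plane redundancy: %.3f\n", x$redundancy_fraction))
  invisible(x)
}

#' @method tidy puncta_result
#' @export
tidy.puncta_result <- function(x, ...) {
  tibble::tibble(plane_index = x$planes_used,
                 count = x$per_plane_counts)
}

#' @method glance puncta_result
#' @export
glance.puncta_result <- function(x, ...) {
  tibble::tibble(method = x$method,
                 total_raw = x$total_raw,
                 total_reported = x$total_reported,
                 n_planes = length(x$planes_used),
                 z_center = x$z_center,
                 redundancy_fraction = x$redundancy_fraction %||% NA_real_,
                 threshold_used = x$threshold_used)
}

#' Quantify a stack by full-volume 3D counting
#'
#' The computational analog of manual scoring across all focal planes: every
#' 3D-connected punctum is counted exactly once, however many planes it
#' spans. Suited to early-stage samples (single stem cells, early cysts)
#' where every plane is scored.
#'
#' @inheritParams binarize_stack
#' @param connectivity 3D connectivity, 6 or 26 (default).
#' @param min_size_vox Minimum component volume (default 2 voxels).
#' @return A `puncta_result` with `method = "manual_3d"`; per-plane counts
#'   credit each component to the first plane it appears in, so they sum to
#'   the 3D total. `total_reported` equals `total_raw` (no doubling).
#' @export
quantify_stack_3d <- function(stack, masks = NULL, policy = "otsu",
                              value = NULL, connectivity = 26,
                              min_size_vox = 2) {
  bz <- binarize_stack(stack, masks, policy, value)
  lab <- .label_cc(bz$binary, connectivity)
  per_plane <- .per_plane_3d(lab, min_size_vox)
  total <- sum(per_plane)
  .new_puncta_result(per_plane, seq_len(dim(bz$binary)[1]), total, total,
                     NULL, "manual_3d", bz$threshold_used)
}

#' Quantify a late-stage (stage-10) cyst by half-depth doubling
#'
#' The semi-automated convention for large stage-10 egg chambers: particles
#' are counted per focal plane from the Z-center (widest plane) down through
#' half the sample's Z-depth, and the summed count is doubled, assuming
#' Z-symmetry of the roughly football-shaped chamber.
#'
#' @inheritParams binarize_stack
#' @param connectivity 2D connectivity per plane, 4 or 8 (default).
#' @param min_size_px Minimum particle area per plane (default 2).
#' @param z_center Optional explicit Z-center plane; default locates it with
#'   [find_z_center()].
#' @param half Which half of the chamber to count: `"lower"` (default,
#'   Z-center towards the bottom of the acquisition) or `"upper"`.
#' @param redundancy_correct If `TRUE`, multiply the doubled total by
#'   `1 - redundancy_fraction` to remove puncta counted in two adjacent
#'   planes. By default redundancy is only *reported*, not subtracted.
#' @param redundancy_fraction Optional externally estimated redundancy
#'   fraction; when `NULL` and correction is requested it is estimated from
#'   the counted planes via [estimate_plane_redundancy()].
#' @return A `puncta_result` with `method = "semi_auto_2d"`;
#'   `total_reported = 2 * total_raw` (optionally redundancy-corrected).
#' @export
quantify_stage10_cyst <- function(stack, masks = NULL, policy = "otsu",
                                  value = NULL, connectivity = 8,
                                  min_size_px = 2, z_center = NULL,
                                  half = c("lower", "upper"),
                                  redundancy_correct = FALSE,
                                  redundancy_fraction = NULL) {
  half <- match.arg(half)
  bz <- binarize_stack(stack, masks, policy, value)
  bin <- bz$binary
  nz <- dim(bin)[1]
  areas <- apply(bin, 1, sum)
  if (sum(areas) == 0) {
    # nothing left (e.g. fully masked): an empty but valid result
    return(.new_puncta_result(integer(0), integer(0), 0L, 0,
                              redundancy_fraction, "semi_auto_2d",
                              bz$threshold_used))
  }
  zc <- z_center %||% find_z_center(bin)
  .assert(zc >= 1 && zc <= nz, "`z_center` is outside the stack")
  z_lo <- min(which(areas > 0)); z_hi <- max(which(areas > 0))
  .assert(zc >= z_lo && zc <= z_hi, "stack does not span the Z-center")
  planes <- if (half == "lower") zc:z_hi else zc:z_lo
  .assert(length(planes) >= 1,
          "stack too shallow to contain a half-depth below the Z-center")
  counts <- vapply(planes, function(i)
    count_particles_2d(bin[i, , ], connectivity, min_size_px), integer(1))
  total_raw <- sum(counts)
  total <- 2 * total_raw
  if (redundancy_correct) {
    if (is.null(redundancy_fraction)) {
      pr <- estimate_plane_redundancy(bin, plane_pairs = cbind(head(planes, -1) ,
                                                               tail(planes, -1)),
                                      connectivity = connectivity,
                                      min_size_px = min_size_px)
      redundancy_fraction <- pr$fraction
    }
    total <- total * (1 - redundancy_fraction)
  }
  .new_puncta_result(counts, planes, total_raw, total, redundancy_fraction,
                     "semi_auto_2d", bz$threshold_used, zc)
}

#' Estimate inter-plane count redundancy
#'
#' Fraction of particles in the second plane of each adjacent plane pair
#' whose signal overlaps a particle in the first plane by at least
#' `overlap_min_px` pixels — i.e. puncta that per-plane counting would score
#' twice. A 1-pixel overlap is never counted; `overlap_min_px` pixels always
#' is.
#'
#' @param binary_stack Binary `(z, y, x)` array.
#' @param plane_pairs Two-column matrix of adjacent plane index pairs
#'   (first, second). Default: all adjacent pairs in the stack.
#' @param overlap_min_px Minimum pixel overlap to call redundancy (default 2).
#' @param connectivity,min_size_px As in [count_particles_2d()].
#' @return A one-row tibble: `fraction`, `n_examined`, `n_overlapping`,
#'   `overlap_min_px`. Errors if no particles are examined (the fraction is
#'   undefined, not zero).
#' @export
estimate_plane_redundancy <- function(binary_stack, plane_pairs = NULL,
                                      overlap_min_px = 2, connectivity = 8,
                                      min_size_px = 2) {
  bin <- .as_voxels(binary_stack) > 0
  nz <- dim(bin)[1]
  if (is.null(plane_pairs)) {
    .assert(nz >= 2, "need at least two planes to assess redundancy")
    plane_pairs <- cbind(seq_len(nz - 1), 2:nz)
  }
  plane_pairs <- matrix(as.integer(plane_pairs), ncol = 2)
  .assert(all(plane_pairs >= 1 & plane_pairs <= nz),
          "plane pair indices out of range")
  .assert(all(abs(plane_pairs[, 2] - plane_pairs[, 1]) == 1),
          "plane pairs must be adjacent planes")
  n_total <- 0L; n_red <- 0L
  for (k in seq_len(nrow(plane_pairs))) {
    lab1 <- .label_cc(bin[plane_pairs[k, 1], , ], connectivity)
    lab2 <- .label_cc(bin[plane_pairs[k, 2], , ], connectivity)
    sz1 <- if (any(lab1 > 0)) tabulate(lab1[lab1 > 0]) else integer(0)
    sz2 <- if (any(lab2 > 0)) tabulate(lab2[lab2 > 0]) else integer(0)
    if (length(sz1)) lab1[lab1 %in% which(sz1 < min_size_px)] <- 0L
    if (length(sz2)) lab2[lab2 %in% which(sz2 < min_size_px)] <- 0L
    comps2 <- setdiff(unique(as.vector(lab2)), 0L)
    n_total <- n_total + length(comps2)
    if (!length(comps2)) next
    both <- lab1 > 0 & lab2 > 0
    if (any(both)) {
      ov <- table(lab2[both], lab1[both])
      hit <- rownames(ov)[apply(ov, 1, max) >= overlap_min_px]
      n_red <- n_red + length(hit)
    }
  }
  .assert(n_total > 0,
          "no particles examined: redundancy fraction is undefined",
          class = "wolbtiter_undefined_fraction")
  tibble::tibble(fraction = n_red / n_total, n_examined = n_total,
                 n_overlapping = n_red, overlap_min_px = overlap_min_px)
}

#' Compare manual and semi-automated counts
#'
#' Ordinary least-squares regression of semi-automated counts on manual
#' counts from the same regions, plus a two-sample comparison of the two
#' count distributions through the test-selection decision tree.
#'
#' @param manual,auto Paired count vectors of equal length (n >= 3).
#' @param diag_alpha Diagnostic alpha for test selection (default 0.05).
#' @param seed Optional seed (used only if the randomization test is
#'   selected).
#' @return An object of class `method_comparison`: `slope`, `intercept`,
#'   `r_squared`, `n`, and `test` (a [compare_two_groups()] result).
#' @export
compare_counting_methods <- function(manual, auto, diag_alpha = 0.05,
                                     seed = NULL) {
  manual <- .check_numeric(manual, "manual")
  auto <- .check_numeric(auto, "auto")
  .assert(length(manual) == length(auto), "count vectors must be paired")
  .assert(length(manual) >= 3, "need at least 3 paired counts")
  .assert(var(manual) > 0, "manual counts have zero variance: regression undefined")
  fit <- lm(auto ~ manual)
  r2 <- 1 - sum(residuals(fit)^2) / sum((auto - mean(auto))^2)
  test <- compare_two_groups(manual, auto, diag_alpha = diag_alpha, seed = seed)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, n = length(manual), test = test),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> n = %d: auto = %.4g + %.4g * manual, R^2 = %.3f\n",
              x$n, x$intercept, x$slope, x$r_squared))
  cat(sprintf("  distribution comparison: %s, p = %.3g\n",
              x$test$test_name, x$test$p_value))
  invisible(x)
}

#' @method glance method_comparison
#' @export
glance.method_comparison <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n = x$n,
                 test_name = x$test$test_name, p_value = x$test$p_value)
}
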