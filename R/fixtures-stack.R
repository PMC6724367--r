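#' Generate a synthetic confocal stack with known ground truth
#'
#' Renders a 3D z-stack emulating DNA-stained ovarian tissue: bright
#' sub-resolution puncta (bacterial nucleoids) over optional large, dim host
#' nuclei, plus additive Gaussian noise. Every placed object is reported in
#' the returned ground truth, so downstream counting can be checked exactly.
#'
#' Puncta are rendered as isotropic Gaussian intensity profiles with
#' `sigma = punctum_radius_px / 2`. With `z_profile = "gaussian"` the profile
#' extends across planes in z; with `"planar"` each punctum is confined to a
#' single focal plane (emulating nucleoids smaller than the z-step), except
#' for a `straddle_fraction` of puncta rendered identically on two adjacent
#' planes — the plane-straddling signals that per-plane counting scores
#' twice.
#'
#' @param shape `(z, y, x)` voxel counts.
#' @param n_puncta Number of puncta to place (>= 0).
#' @param punctum_radius_px Punctum radius in pixels (Gaussian sigma is half
#'   of this).
#' @param min_separation_px Minimum pairwise 3D center distance. Must exceed
#'   `2 * punctum_radius_px` for strict separation.
#' @param centers Optional pre-chosen integer `(z, y, x)` center matrix;
#'   overrides random placement (no separation check is applied).
#' @param nuclei Optional host-nucleus spec:
#'   `list(n =, radius_px =, intensity =)`. Nuclei are rendered dimmer than
#'   puncta so a single global threshold can separate the two.
#' @param amplitude Peak punctum intensity above background (default 1000).
#' @param background Constant background level (default 100).
#' @param noise_sd Additive Gaussian noise sigma (default 0); negative values
#'   after noise are clipped to 0.
#' @param z_profile `"gaussian"` (3D profile; default) or `"planar"`.
#' @param straddle_fraction Fraction of planar puncta duplicated onto the
#'   next plane (default 0; ignored for `z_profile = "gaussian"`).
#' @param z_step_um Z-spacing metadata (default 1.5).
#' @param seed RNG seed; identical arguments give bit-identical stacks.
#' @param max_tries Placement attempts per punctum before giving up.
#'
#' @return A list with `stack` (an [image_stack()]) and `truth`, a list of
#'   `punctum_centers` (tibble `z, y, x, straddles`), `punctum_radius_px`,
#'   `nuclei_centers`, and `seed`.
#' @export
make_stack <- function(shape = c(21, 128, 128), n_puncta = 50,
                       punctum_radius_px = 2,
                       min_separation_px = 3 * punctum_radius_px,
                       centers = NULL, nuclei = NULL,
                       amplitude = 1000, background = 100, noise_sd = 0,
                       z_profile = c("gaussian", "planar"),
                       straddle_fraction = 0, z_step_um = 1.5, seed = 1L,
                       max_tries = 200L) {
  z_profile <- match.arg(z_profile)
  .assert(length(shape) == 3 && all(shape >= 1), "`shape` must be positive (z, y, x)")
  .assert(n_puncta >= 0, "`n_puncta` must be >= 0")
  .assert(noise_sd >= 0, "`noise_sd` must be >= 0")
  .assert(straddle_fraction >= 0 && straddle_fraction <= 1,
          "`straddle_fraction` must lie in [0, 1]")
  shape <- as.integer(shape)

  .with_seed(seed, {
    if (is.null(centers)) {
      centers <- .place_centers(shape, n_puncta, min_separation_px,
                                margin = ceiling(punctum_radius_px * 2 + 1),
                                planar = z_profile == "planar",
                                max_tries = max_tries)
    } else {
      centers <- matrix(as.integer(centers), ncol = 3)
      n_puncta <- nrow(centers)
    }
    straddles <- rep(FALSE, n_puncta)
    if (z_profile == "planar" && straddle_fraction > 0 && n_puncta > 0) {
      n_str <- round(straddle_fraction * n_puncta)
      cand <- which(centers[, 1] < shape[1])
      straddles[sample(cand, min(n_str, length(cand)))] <- TRUE
    }

    vox <- array(background, shape)
    sigma <- punctum_radius_px / 2
    if (n_puncta > 0) {
      for (i in seq_len(n_puncta)) {
        vox <- .render_punctum(vox, centers[i, ], amplitude, sigma,
                               planar = z_profile == "planar",
                               straddle = straddles[i])
      }
    }
    nuclei_centers <- NULL
    if (!is.null(nuclei) && (nuclei$n %||% 0) > 0) {
      nuclei_centers <- .place_centers(shape, nuclei$n,
                                       min_separation_px = nuclei$radius_px,
                                       margin = 1L, planar = FALSE,
                                       max_tries = max_tries)
      for (i in seq_len(nrow(nuclei_centers))) {
        vox <- .render_punctum(vox, nuclei_centers[i, ],
                               nuclei$intensity %||% (amplitude / 4),
                               nuclei$radius_px / 2, planar = FALSE,
                               straddle = FALSE)
      }
    }
    if (noise_sd > 0) {
      vox <- vox + array(rnorm(length(vox), 0, noise_sd), shape)
      vox[vox < 0] <- 0
    }
    truth <- list(
      punctum_centers = tibble::tibble(z = centers[, 1], y = centers[, 2],
                                       x = centers[, 3], straddles = straddles),
      punctum_radius_px = punctum_radius_px,
      nuclei_centers = nuclei_centers,
      seed = seed)
    list(stack = image_stack(vox, z_step_um = z_step_um), truth = truth)
  })
}

# Rejection-sample integer centers with a minimum pairwise 3D distance.
.place_centers <- function(shape, n, min_separation_px, margin, planar,
                           max_tries) {
  if (n == 0) return(matrix(integer(0), ncol = 3))
  lo <- pmin(1L + margin, shape)
  hi <- pmax(shape - margin, lo)
  if (planar) { lo[1] <- 1L; hi[1] <- shape[1] }
  .assert(all(hi >= lo), "stack too small for the requested punctum radius")
  centers <- matrix(0L, n, 3)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    .assert(tries <= max_tries * n,
            sprintf("could not place %d puncta at separation %.3g: capacity exceeded",
                    n, min_separation_px),
            class = "wolbtiter_capacity_error")
    cand <- vapply(1:3, function(j) sample(lo[j]:hi[j], 1L), integer(1))
    if (placed > 0) {
      d2 <- colSums((t(centers[seq_len(placed), , drop = FALSE]) - cand)^2)
      if (min(d2) < min_separation_px^2) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  centers
}

# Add one Gaussian-profile punctum (or dim nucleus blob) in place.
.render_punctum <- function(vox, center, amplitude, sigma, planar, straddle) {
  d <- dim(vox)
  w <- max(1L, ceiling(3 * sigma))
  ys <- max(1L, center[2] - w):min(d[2], center[2] + w)
  xs <- max(1L, center[3] - w):min(d[3], center[3] + w)
  prof2d <- outer((ys - center[2])^2, (xs - center[3])^2, "+")
  prof2d <- amplitude * exp(-prof2d / (2 * sigma^2))
  if (planar) {
    zs <- center[1]
    if (straddle && center[1] < d[1]) zs <- c(zs, center[1] + 1L)
    for (z in zs) vox[z, ys, xs] <- vox[z, ys, xs] + prof2d
  } else {
    zs <- max(1L, center[1] - w):min(d[1], center[1] + w)
    for (z in zs) {
      gz <- exp(-(z - center[1])^2 / (2 * sigma^2))
      vox[z, ys, xs] <- vox[z, ys, xs] + gz * prof2d
    }
  }
  vox
}

#' Generate a Z-symmetric stage-10-like fixture stack
#'
#' Places an even number of plane-confined puncta in mirrored pairs around a
#' central plane (with no punctum on the center plane itself), so the
#' half-depth-doubling convention of [quantify_stage10_cyst()] recovers the
#' ground-truth total exactly on noise-free renders. Placement guarantees
#' that any two puncta either sit at least `min_separation_px` apart in the
#' image plane or at least two planes apart in z, so neither per-plane 2D
#' counting nor 26-connected 3D counting merges them.
#'
#' @inheritParams make_stack
#' @param n_puncta Even total punctum count.
#' @param z_center Center plane index; default the middle plane.
#' @return As [make_stack()]; `truth` additionally carries `z_center`.
#' @export
make_stage10_stack <- function(shape = c(21, 160, 160), n_puncta = 100,
                               punctum_radius_px = 2,
                               min_separation_px = 3 * punctum_radius_px,
                               amplitude = 1000, background = 100,
                               noise_sd = 0, z_center = NULL, seed = 1L,
                               max_tries = 200L) {
  .assert(n_puncta %% 2 == 0, "`n_puncta` must be even (mirrored pairs)")
  shape <- as.integer(shape)
  zc <- as.integer(z_center %||% ((shape[1] + 1) %/% 2))
  half_depth <- min(zc - 1L, shape[1] - zc)
  .assert(half_depth >= 1, "stack too shallow for a symmetric stage-10 fixture")
  margin <- ceiling(punctum_radius_px * 2 + 1)

  centers <- .with_seed(seed, {
    n_half <- n_puncta %/% 2
    out <- matrix(0L, n_puncta, 3)
    placed <- 0L; tries <- 0L
    while (placed < n_half) {
      tries <- tries + 1L
      .assert(tries <= max_tries * n_half,
              "could not place puncta at the requested separation: capacity exceeded",
              class = "wolbtiter_capacity_error")
      cand <- c(sample((zc + 1L):(zc + half_depth), 1L),
                sample((1L + margin):(shape[2] - margin), 1L),
                sample((1L + margin):(shape[3] - margin), 1L))
      mirror <- c(2L * zc - cand[1], cand[2], cand[3])
      prev <- out[seq_len(2L * placed), , drop = FALSE]
      ok <- TRUE
      for (p in list(cand, mirror)) {
        if (!nrow(prev)) break
        dxy2 <- (prev[, 2] - p[2])^2 + (prev[, 3] - p[3])^2
        dz <- abs(prev[, 1] - p[1])
        if (any(dxy2 < min_separation_px^2 & dz < 2)) { ok <- FALSE; break }
      }
      if (!ok) next
      out[2L * placed + 1L, ] <- cand
      out[2L * placed + 2L, ] <- mirror
      placed <- placed + 1L
    }
    out
  })
  res <- make_stack(shape = shape, centers = centers,
                    punctum_radius_px = punctum_radius_px,
                    amplitude = amplitude, background = background,
                    noise_sd = noise_sd, z_profile = "planar",
                    seed = seed + 1L)
  res$truth$z_center <- zc
  res$truth$seed <- seed
  res
}

#' Write stack ground truth as JSON
#'
#' Companion to [write_stack()]: serializes the ground-truth object of
#' [make_stack()] in a plain JSON layout (`punctum_centers` as records,
#' 1-based indices).
#'
#' @param truth Ground-truth list from [make_stack()].
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(punctum_centers = truth$punctum_centers,
              punctum_radius_px = truth$punctum_radius_px,
              nuclei_centers = if (is.null(truth$nuclei_centers)) NULL else
                as.data.frame(truth$nuclei_centers),
              seed = truth$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
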