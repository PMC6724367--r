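#' Confocal image stack
#'
#' A lightweight container for a 3D grayscale confocal z-stack. Voxels are
#' stored as a numeric array with dimensions `(z, y, x)`; plane `i` is the
#' `y` by `x` matrix `voxels[i, , ]`. Plane 1 is the top of the acquisition
#' (stacks are acquired top to bottom). All indices in this package are
#' 1-based.
#'
#' @param voxels 3D numeric array `(z, y, x)` of non-negative finite
#'   intensities, or a single `y` by `x` matrix (treated as a one-plane stack).
#' @param z_step_um Z-spacing between focal planes in micrometres. Defaults to
#'   1.5, the acquisition interval the counting conventions here assume.
#' @param pixel_size_um Optional lateral pixel size in micrometres.
#' @param channel Label for the imaged channel (default `"DNA"`, i.e. a DNA
#'   stain in which bacterial nucleoids appear as bright puncta).
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, z_step_um = 1.5, pixel_size_um = NULL,
                        channel = "DNA") {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, dim(voxels)))
  .assert(is.array(voxels) && length(dim(voxels)) == 3,
          "`voxels` must be a (z, y, x) array or a single-plane matrix")
  .assert(all(is.finite(voxels)) && all(voxels >= 0),
          "stack intensities must be finite and non-negative")
  .assert(is.numeric(z_step_um) && length(z_step_um) == 1 && z_step_um > 0,
          "`z_step_um` must be a positive scalar")
  structure(list(voxels = voxels, z_step_um = z_step_um,
                 pixel_size_um = pixel_size_um, channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d plane(s) of %d x %d px, z-step %.2g um, channel %s\n",
              d[1], d[2], d[3], x$z_step_um, x$channel))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

.as_voxels <- function(stack) {
  if (inherits(stack, "image_stack")) return(stack$voxels)
  if (is.matrix(stack)) return(array(stack, c(1L, dim(stack))))
  .assert(is.array(stack) && length(dim(stack)) == 3,
          "expected an `image_stack`, a (z, y, x) array, or a matrix")
  stack
}

#' Read and write multi-page TIFF stacks
#'
#' `read_stack()` loads a multi-page grayscale TIFF as an [image_stack()];
#' `write_stack()` writes one out as 16-bit multi-page TIFF. Intensities are
#' rescaled by `scale` on write (TIFF storage is \[0, 1\]) and back on read.
#'
#' @param path File path.
#' @param scale Intensity corresponding to full scale (default `2^16 - 1`).
#' @param ... Passed on to [image_stack()].
#' @return `read_stack()` returns an `image_stack`; `write_stack()` returns
#'   `path` invisibly.
#' @export
read_stack <- function(path, scale = 65535, ...) {
  planes <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(planes)) planes <- list(planes)
  planes <- lapply(planes, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # collapse accidental RGB
    p * scale
  })
  vox <- array(0, c(length(planes), nrow(planes[[1]]), ncol(planes[[1]])))
  for (i in seq_along(planes)) vox[i, , ] <- planes[[i]]
  image_stack(vox, ...)
}

#' @rdname read_stack
#' @param stack An `image_stack` (or bare array).
#' @export
write_stack <- function(stack, path, scale = 65535) {
  vox <- .as_voxels(stack)
  planes <- lapply(seq_len(dim(vox)[1]),
                   function(i) pmin(pmax(vox[i, , ] / scale, 0), 1))
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read per-plane exclusion masks
#'
#' Masks mark voxels to *exclude* from counting (follicle cells, host nuclei,
#' staining debris) — the programmatic stand-in for manual image clean-up.
#' Any non-zero mask pixel is excluded.
#'
#' @param path Multi-page TIFF of binary masks (one page, broadcast to all
#'   planes, or one page per plane).
#' @return A logical `(z, y, x)` array.
#' @export
read_masks <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  planes <- lapply(planes, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p > 0
  })
  out <- array(FALSE, c(length(planes), nrow(planes[[1]]), ncol(planes[[1]])))
  for (i in seq_along(planes)) out[i, , ] <- planes[[i]]
  out
}

# Normalize masks to a logical (z, y, x) array matching `d`, broadcasting a
# single plane across z. Masks are exclusion masks and must be binary.
.normalize_masks <- function(masks, d) {
  if (is.null(masks)) return(NULL)
  if (is.matrix(masks)) masks <- array(masks, c(1L, dim(masks)))
  .assert(is.array(masks) && length(dim(masks)) == 3, "masks must be per-plane matrices")
  dm <- dim(masks)
  .assert(all(dm[2:3] == d[2:3]), "mask planes must match the stack's y/x size")
  .assert(dm[1] == d[1] || dm[1] == 1L,
          "mask plane count must equal the stack depth or 1 (broadcast)")
  vals <- unique(as.vector(masks))
  .assert(all(vals %in% c(0, 1, TRUE, FALSE)), "masks must be strictly binary")
  m <- array(as.logical(masks), dm)
  if (dm[1] == 1L && d[1] > 1L) {
    m2 <- array(FALSE, d)
    for (i in seq_len(d[1])) m2[i, , ] <- m[1, , ]
    m <- m2
  }
  m
}

#' Smooth a stack plane-by-plane
#'
#' Light 2D Gaussian smoothing applied independently to each focal plane,
#' useful before thresholding noisy stacks: sub-resolution puncta survive a
#' sub-pixel-scale blur while uncorrelated sensor noise is strongly
#' suppressed. Smoothing is optional and never applied implicitly.
#'
#' @param stack An [image_stack()] or `(z, y, x)` array.
#' @param sigma Gaussian sigma in pixels (default 0.8).
#' @return An `image_stack` with smoothed voxels (metadata preserved).
#' @export
smooth_stack <- function(stack, sigma = 0.8) {
  vox <- .as_voxels(stack)
  .assert(sigma > 0, "`sigma` must be positive")
  sm <- vox
  for (i in seq_len(dim(vox)[1])) {
    sm[i, , ] <- EBImage::gblur(vox[i, , ], sigma = sigma)
  }
  sm[sm < 0] <- 0
  if (inherits(stack, "image_stack")) {
    out <- stack; out$voxels <- sm; out
  } else {
    image_stack(sm)
  }
}
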