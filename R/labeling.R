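# Connected-component labeling on binary planes/stacks.
#
# Labeling runs on the foreground voxels only: neighbor pairs are found by
# matching shifted linear indices, and components come from
# igraph::components() on the resulting adjacency graph. This supports the
# particle-analysis connectivities (4/8 in 2D, 6/26 in 3D) uniformly.

.half_offsets <- function(ndim, connectivity) {
  if (ndim == 2) {
    .assert(connectivity %in% c(4, 8), "2D connectivity must be 4 or 8")
    offs <- rbind(c(1, 0), c(0, 1))
    if (connectivity == 8) offs <- rbind(offs, c(1, 1), c(1, -1))
  } else {
    .assert(connectivity %in% c(6, 26), "3D connectivity must be 6 or 26")
    if (connectivity == 6) {
      offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    } else {
      g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
      keep <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
        (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
      offs <- unname(g[keep, , drop = FALSE])
    }
  }
  offs
}

# Label connected components of a binary matrix (2D) or array (3D).
# Returns an integer array of the same shape; 0 = background.
.label_cc <- function(bin, connectivity) {
  d <- dim(bin)
  ndim <- length(d)
  lab <- array(0L, d)
  idx <- which(bin)
  nf <- length(idx)
  if (nf == 0L) return(lab)
  co <- arrayInd(idx, d)
  offs <- .half_offsets(ndim, connectivity)
  mult <- cumprod(c(1, d[-ndim]))
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[k, ], "+")
    ok <- rep(TRUE, nf)
    for (j in seq_len(ndim)) ok <- ok & nb[, j] >= 1L & nb[, j] <= d[j]
    if (!any(ok)) next
    lin <- as.integer((nb[ok, , drop = FALSE] - 1) %*% mult) + 1L
    hit <- match(lin, idx)
    keep <- !is.na(hit)
    from <- c(from, which(ok)[keep])
    to <- c(to, hit[keep])
  }
  if (length(from)) {
    g <- igraph::make_graph(rbind(from, to), n = nf, directed = FALSE)
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_len(nf)
  }
  lab[idx] <- as.integer(memb)
  lab
}

#' Count particles in a binary focal plane
#'
#' 2D connected-component particle analysis: the number of connected
#' foreground regions with at least `min_size_px` pixels.
#'
#' @param plane A binary (logical or 0/1) matrix.
#' @param connectivity 4 (edge neighbors) or 8 (edge + diagonal; default,
#'   the usual particle-analysis convention).
#' @param min_size_px Minimum particle area in pixels (default 2, suppressing
#'   single-pixel noise).
#' @return Integer particle count (0 for an empty plane).
#' @export
count_particles_2d <- function(plane, connectivity = 8, min_size_px = 2) {
  .assert(is.matrix(plane), "`plane` must be a matrix")
  .assert(all(plane %in% c(0, 1, TRUE, FALSE)), "`plane` must be binary")
  lab <- .label_cc(plane > 0, connectivity)
  if (!any(lab > 0L)) return(0L)
  sizes <- tabulate(lab[lab > 0L])
  sum(sizes >= min_size_px)
}

#' Count puncta in a binary 3D stack
#'
#' 3D connected-component counting — the computational analog of scoring each
#' punctum once across all focal planes it appears in (a human scorer does
#' not double-count a bacterium visible in two adjacent planes).
#'
#' @param binary_stack Binary `(z, y, x)` array.
#' @param connectivity 6 (face neighbors) or 26 (face + edge + corner;
#'   default).
#' @param min_size_vox Minimum component volume in voxels (default 2).
#' @return Integer punctum count.
#' @export
count_puncta_3d <- function(binary_stack, connectivity = 26, min_size_vox = 2) {
  bin <- .as_voxels(binary_stack) > 0
  lab <- .label_cc(bin, connectivity)
  if (!any(lab > 0L)) return(0L)
  sizes <- tabulate(lab[lab > 0L])
  sum(sizes >= min_size_vox)
}

# Per-plane attribution of 3D components: each component is credited to the
# first (topmost) plane it appears in, so the per-plane counts sum to the
# 3D total.
.per_plane_3d <- function(lab3, min_size_vox) {
  d <- dim(lab3)
  out <- integer(d[1])
  if (!any(lab3 > 0L)) return(out)
  sizes <- tabulate(lab3[lab3 > 0L])
  keep <- which(sizes >= min_size_vox)
  if (!length(keep)) return(out)
  idx <- which(lab3 > 0L)
  z <- ((idx - 1L) %% d[1]) + 1L
  labv <- lab3[idx]
  first_z <- tapply(z, labv, min)
  first_z <- first_z[as.character(keep)]
  tab <- table(factor(first_z, levels = seq_len(d[1])))
  as.integer(tab)
}
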