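make_binary_stack <- function(planes) {
  # planes: list of y-by-x 0/1 matrices -> intensity image_stack (0/1000)
  vox <- array(0, c(length(planes), nrow(planes[[1]]), ncol(planes[[1]])))
  for (i in seq_along(planes)) vox[i, , ] <- planes[[i]] * 1000
  image_stack(vox)
}

disk_plane <- function(ny, nx, centers, radius = 2) {
  m <- matrix(0L, ny, nx)
  for (k in seq_len(nrow(centers))) {
    ys <- pmax(1, centers[k, 1] - radius):pmin(ny, centers[k, 1] + radius)
    xs <- pmax(1, centers[k, 2] - radius):pmin(nx, centers[k, 2] + radius)
    d2 <- outer((ys - centers[k, 1])^2, (xs - centers[k, 2])^2, "+")
    m[ys, xs][d2 <= radius^2] <- 1L
  }
  m
}

test_that("thresholding respects masks and policies", {
  r <- make_stack(shape = c(7, 64, 64), n_puncta = 12, seed = 3)
  bz <- binarize_stack(r$stack, policy = "percentile", value = 0.98)
  expect_gt(sum(bz$binary), 0)
  # mask covering one punctum removes it from the foreground
  ctr <- r$truth$punctum_centers
  mask <- array(FALSE, dim(r$stack$voxels))
  mask[, pmax(1, ctr$y[1] - 6):pmin(64, ctr$y[1] + 6),
       pmax(1, ctr$x[1] - 6):pmin(64, ctr$x[1] + 6)] <- TRUE
  bm <- binarize_stack(r$stack, masks = mask, policy = "fixed", value = 500)
  expect_false(any(bm$binary[, ctr$y[1], ctr$x[1]]))
  n_mask <- count_puncta_3d(bm$binary)
  n_full <- count_puncta_3d(binarize_stack(r$stack, policy = "fixed",
                                           value = 500)$binary)
  expect_equal(n_full, 12L)
  expect_equal(n_mask, 11L)
  expect_error(binarize_stack(r$stack, policy = "fixed", value = 1e9),
               "outside")
})

test_that("masking never increases and higher thresholds never grow the foreground", {
  for (seed in c(1, 4)) {
    r <- make_stack(shape = c(9, 56, 56), n_puncta = 25, noise_sd = 80,
                    seed = seed)
    a1 <- sum(binarize_stack(r$stack, policy = "fixed", value = 300)$binary)
    a2 <- sum(binarize_stack(r$stack, policy = "fixed", value = 500)$binary)
    expect_lte(a2, a1)
    mask <- array(FALSE, dim(r$stack$voxels)); mask[, 1:28, ] <- TRUE
    cm <- count_puncta_3d(binarize_stack(r$stack, masks = mask,
                                         policy = "fixed", value = 500)$binary)
    cf <- count_puncta_3d(binarize_stack(r$stack, policy = "fixed",
                                         value = 500)$binary)
    expect_lte(cm, cf)
  }
})

test_that("2D particle counting matches definition cases and a flood-fill oracle", {
  centers <- as.matrix(expand.grid(seq(5, 95, 10), seq(5, 95, 10)))
  expect_equal(count_particles_2d(disk_plane(100, 100, centers)), 100L)
  # two blobs touching only diagonally
  m <- matrix(0L, 8, 8); m[2:3, 2:3] <- 1L; m[4:5, 4:5] <- 1L
  expect_equal(count_particles_2d(m, connectivity = 8), 1L)
  expect_equal(count_particles_2d(m, connectivity = 4), 2L)
  # size filter
  m2 <- matrix(0L, 8, 8); m2[2, 2] <- 1L; m2[5:6, 5:6] <- 1L
  expect_equal(count_particles_2d(m2, min_size_px = 2), 1L)
  expect_equal(count_particles_2d(m2, min_size_px = 1), 2L)
  # random planes vs brute-force flood fill
  for (seed in 1:4) {
    set.seed(seed)
    rnd <- matrix(runif(30 * 30) < 0.3, 30, 30)
    for (conn in c(4, 8)) {
      expect_equal(count_particles_2d(rnd, connectivity = conn,
                                      min_size_px = 1),
                   oracle_component_count(rnd, conn))
    }
  }
})

test_that("3D counting matches ground truth, the flood-fill oracle, and the plane-splitting bound", {
  r <- make_stack(shape = c(13, 120, 120), n_puncta = 100,
                  punctum_radius_px = 2, min_separation_px = 7, seed = 6)
  bz <- binarize_stack(r$stack, policy = "fixed", value = 400)
  expect_equal(count_puncta_3d(bz$binary), 100L)
  sum2d <- sum(vapply(seq_len(13), function(i)
    count_particles_2d(bz$binary[i, , ]), integer(1)))
  expect_gte(sum2d, count_puncta_3d(bz$binary))
  expect_equal(count_puncta_3d(array(FALSE, c(3, 5, 5))), 0L)
  for (seed in 1:3) {
    set.seed(seed)
    rnd <- array(runif(10 * 12 * 12) < 0.2, c(10, 12, 12))
    for (conn in c(6, 26)) {
      expect_equal(count_puncta_3d(rnd, connectivity = conn,
                                   min_size_vox = 1),
                   oracle_component_count(rnd, conn))
    }
  }
})

test_that("the Z-center is the widest plane, ties toward the top", {
  # ellipsoidal foreground over 21 planes: symmetric, widest in the middle
  planes <- lapply(1:21, function(z) {
    r <- sqrt(max(0, 1 - ((z - 11) / 10)^2)) * 20
    disk_plane(60, 60, cbind(30, 30), radius = max(r, 0.1))
  })
  expect_equal(find_z_center(make_binary_stack(planes)$voxels > 0), 11)
  one <- array(TRUE, c(1, 4, 4))
  expect_equal(find_z_center(one), 1)
  expect_error(find_z_center(array(FALSE, c(3, 4, 4))),
               class = "wolbtiter_no_sample")
  for (seed in 1:5) {
    set.seed(seed)
    areas <- sample(0:50, 9, replace = TRUE)
    if (all(areas == 0)) areas[3] <- 5
    pl <- lapply(areas, function(a) {
      m <- matrix(0L, 12, 12); m[which(seq_len(144) <= a)] <- 1L; m
    })
    bin <- make_binary_stack(pl)$voxels > 0
    expect_equal(find_z_center(bin), which.max(areas))
  }
})

test_that("half-depth doubling follows the counting convention", {
  # per-plane counts 10 / 12 / 8 below the Z-center -> reported 60
  pl <- list(matrix(0L, 80, 80),
             disk_plane(80, 80, as.matrix(expand.grid(seq(6, 76, 8)[1:5], c(10, 30))))[, ],
             disk_plane(80, 80, as.matrix(expand.grid(seq(6, 76, 8)[1:6], c(20, 50)))),
             disk_plane(80, 80, as.matrix(expand.grid(seq(6, 76, 8)[1:4], c(40, 60)))))
  st <- make_binary_stack(pl)
  q <- quantify_stage10_cyst(st, policy = "fixed", value = 500, z_center = 2)
  expect_equal(q$per_plane_counts, c(10L, 12L, 8L))
  expect_equal(q$total_raw, 30L)
  expect_equal(q$total_reported, 60)
  expect_equal(q$method, "semi_auto_2d")
  expect_equal(sum(q$per_plane_counts), q$total_raw)
})

test_that("symmetric stage-10 fixtures are recovered exactly and fully masked stacks give zero", {
  s <- make_stage10_stack(shape = c(19, 140, 140), n_puncta = 120, seed = 8)
  q <- quantify_stage10_cyst(s$stack, policy = "fixed", value = 400,
                             z_center = s$truth$z_center)
  expect_equal(q$total_reported, 120)
  mask <- array(TRUE, dim(s$stack$voxels))
  expect_warning(qm <- quantify_stage10_cyst(s$stack, masks = mask,
                                             policy = "fixed", value = 400),
                 "masked")
  expect_equal(qm$total_reported, 0)
  # a sample that does not span the requested Z-center is an error
  shallow <- array(0, c(4, 20, 20)); shallow[1, 5:8, 5:8] <- 1000
  expect_error(quantify_stage10_cyst(image_stack(shallow), policy = "fixed",
                                     value = 500, z_center = 3),
               "span")
})

test_that("redundancy correction subtracts the estimated double-count fraction", {
  r <- make_stack(shape = c(10, 150, 150), n_puncta = 200, z_profile = "planar",
                  straddle_fraction = 0.1, min_separation_px = 8, seed = 13)
  bz <- binarize_stack(r$stack, policy = "fixed", value = 400)
  q0 <- quantify_stage10_cyst(r$stack, policy = "fixed", value = 400,
                              z_center = 1)
  qc <- quantify_stage10_cyst(r$stack, policy = "fixed", value = 400,
                              z_center = 1, redundancy_correct = TRUE)
  expect_lt(qc$total_reported, q0$total_reported)
  expect_equal(qc$total_reported,
               q0$total_reported * (1 - qc$redundancy_fraction))
})

test_that("plane redundancy follows the overlap definition", {
  full <- disk_plane(40, 40, as.matrix(expand.grid(c(10, 30), c(10, 30))))
  ident <- array(FALSE, c(2, 40, 40))
  ident[1, , ] <- full > 0; ident[2, , ] <- full > 0
  expect_equal(estimate_plane_redundancy(ident)$fraction, 1)
  disj <- ident
  disj[2, , ] <- FALSE
  disj[2, 36:38, 36:38] <- TRUE
  expect_equal(estimate_plane_redundancy(disj)$fraction, 0)
  # 1-pixel overlap not counted, 2-pixel overlap counted
  p1 <- matrix(0L, 10, 10); p1[2:3, 2:3] <- 1L
  p2 <- matrix(0L, 10, 10); p2[3:4, 3:4] <- 1L   # overlaps p1 at exactly 1 px
  st <- array(FALSE, c(2, 10, 10)); st[1, , ] <- p1 > 0; st[2, , ] <- p2 > 0
  expect_equal(estimate_plane_redundancy(st, min_size_px = 1)$fraction, 0)
  p3 <- matrix(0L, 10, 10); p3[2:3, 3:4] <- 1L   # overlaps p1 at 2 px
  st[2, , ] <- p3 > 0
  expect_equal(estimate_plane_redundancy(st, min_size_px = 1)$fraction, 1)
  expect_error(estimate_plane_redundancy(array(FALSE, c(2, 5, 5))),
               class = "wolbtiter_undefined_fraction")
})

test_that("method comparison reduces to OLS plus a distribution test", {
  x <- c(10, 20, 30, 40, 55)
  id <- compare_counting_methods(x, x)
  expect_equal(id$slope, 1)
  expect_equal(id$r_squared, 1)
  expect_equal(id$test$p_value, 1)
  set.seed(9)
  manual <- rnorm(40, 200, 40)
  auto <- 0.95 * manual + rnorm(40, 5, 12)
  mc <- compare_counting_methods(manual, auto)
  o <- oracle_ols(manual, auto)
  expect_equal(mc$slope, o$slope, tolerance = 1e-9)
  expect_equal(mc$intercept, o$intercept, tolerance = 1e-9)
  expect_equal(mc$r_squared, o$r_squared, tolerance = 1e-9)
  expect_error(compare_counting_methods(rep(5, 10), rnorm(10)), "variance")
})

test_that("stacks round-trip through 16-bit TIFF with their masks", {
  r <- make_stack(shape = c(4, 24, 24), n_puncta = 5, seed = 2)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_stack(r$stack, tf)
  back <- read_stack(tf)
  expect_equal(dim(back$voxels), dim(r$stack$voxels))
  expect_lt(max(abs(back$voxels - r$stack$voxels)), 1.01)  # 16-bit rounding
  mf <- withr::local_tempfile(fileext = ".tif")
  mask <- array(0, c(4, 24, 24)); mask[, 1:10, ] <- 1
  tiff::writeTIFF(lapply(1:4, function(i) mask[i, , ]), mf)
  m <- read_masks(mf)
  expect_identical(m, mask > 0)
})
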