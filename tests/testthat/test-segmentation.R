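make_sphere_volume <- function(n = 13, radius = 5, value = 1, center = NULL) {
  if (is.null(center)) center <- rep((n + 1) / 2, 3)
  vol <- array(0, c(n, n, n))
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (sum((c(i, j, k) - center)^2) <= radius^2) vol[i, j, k] <- value
  }
  vol
}

test_that("box smoothing is a mean filter with reflected borders", {
  # fixed point on a constant volume
  const <- array(3.7, c(4, 5, 6))
  expect_equal(smooth_box3(const), const)
  # impulse response: a 27-value voxel becomes a 3x3x3 block of ones
  v <- array(0, c(5, 5, 5)); v[3, 3, 3] <- 27
  s <- smooth_box3(v)
  expect_equal(s[2:4, 2:4, 2:4], array(1, c(3, 3, 3)))
  expect_equal(sum(s), 27)
  # random volume equals the brute-force 27-neighbour oracle
  set.seed(11)
  r <- array(runif(5 * 5 * 5), c(5, 5, 5))
  expect_equal(smooth_box3(r), brute_box3(r), tolerance = 1e-12)
  # non-cubic shape too
  r2 <- array(runif(4 * 7 * 3), c(4, 7, 3))
  expect_equal(smooth_box3(r2), brute_box3(r2), tolerance = 1e-12)
  expect_error(smooth_box3(matrix(1, 3, 3)), class = "pp_dim_error")
})

test_that("reporter segmentation recovers analytic sphere volumes", {
  vs <- c(x = 1, y = 1, z = 1)
  lv <- seg_levels(low = 0.2, high = 0.6, prey = 0.5)
  # everything below the low level: both masks empty
  flat <- array(0.1, c(10, 10, 10))
  seg <- segment_reporter(flat, lv, vs)
  expect_identical(nrow(seg$cell$table), 0L)
  expect_identical(nrow(seg$phagosome$table), 0L)
  # a radius-5 sphere above the high level on zero background
  vol <- make_sphere_volume(13, radius = 5, value = 1)
  seg <- segment_reporter(vol, lv, vs)
  expect_identical(nrow(seg$phagosome$table), 1L)
  analytic <- 4 / 3 * pi * 5^3
  expect_lt(abs(seg$phagosome$table$volume_um3 - analytic) / analytic, 0.05)
  # phagosome voxels always nest inside cell voxels
  expect_true(all(seg$cell$labels[seg$phagosome$labels > 0] > 0))
})

test_that("component labelling matches an independent flood fill", {
  set.seed(5)
  vol <- array(0, c(12, 12, 8))
  vol[2:4, 2:4, 2:3] <- 1
  vol[8:11, 7:10, 5:7] <- 1
  vol[1, 12, 8] <- 1  # 1-voxel speck, removed by the size filter
  lv <- seg_levels(low = 0.2, high = 0.5, prey = 0.5)
  seg <- segment_reporter(vol, lv, c(x = 1, y = 1, z = 1), min_size = 5)
  oracle_sizes <- brute_flood_sizes(vol > 0.5, 26)
  expect_identical(sort(seg$phagosome$table$n_voxels),
                   sort(as.integer(oracle_sizes[oracle_sizes >= 5])))
  # 6-connectivity: diagonal-only contact separates components
  diagonal <- array(0, c(4, 4, 4))
  diagonal[1:2, 1:2, 1:2] <- 1
  diagonal[3:4, 3:4, 3:4] <- 1
  lab26 <- segment_prey(diagonal, 0.5, c(x = 1, y = 1, z = 1),
                        connectivity = 26, min_size = 1)
  lab6 <- segment_prey(diagonal, 0.5, c(x = 1, y = 1, z = 1),
                       connectivity = 6, min_size = 1)
  expect_identical(nrow(lab26$table), 1L)
  expect_identical(nrow(lab6$table), 2L)
})

test_that("prey segmentation handles empty and saturated thresholds", {
  vs <- c(x = 0.5, y = 0.5, z = 1.5)
  empty <- array(0, c(8, 8, 4))
  expect_identical(nrow(segment_prey(empty + 0.01, 0.5, vs)$table), 0L)
  vol <- make_sphere_volume(9, 3)
  expect_identical(nrow(segment_prey(vol, max(vol) + 1, vs)$table), 0L)
  # volumes convert through the anisotropic voxel size
  lab <- segment_prey(vol, 0.5, vs)
  expect_equal(lab$table$volume_um3, lab$table$n_voxels * prod(vs))
})

test_that("inside/outside prey volumes conserve total volume exactly", {
  vs <- c(x = 1, y = 1, z = 1)
  sphere <- make_sphere_volume(13, radius = 5)
  prey <- segment_prey(sphere, 0.5, vs)
  # fully internal: outside zero, flagged, infinite ratio
  cell_all <- segment_prey(array(1, dim(sphere)), 0.5, vs)
  io <- inside_outside_ratio(prey, cell_all)
  expect_identical(io$outside_um3, 0)
  expect_true(io$fully_internal)
  expect_identical(io$ratio, Inf)
  # fully external: ratio zero
  cell_none <- segment_prey(array(0, dim(sphere)), 0.5, vs)
  io0 <- inside_outside_ratio(prey, cell_none)
  expect_identical(io0$ratio, 0)
  expect_equal(io0$outside_um3, io0$total_um3)
  # half-engulfed: a planar cell boundary through the sphere centre
  # (centre placed between voxel columns so the plane bisects it exactly)
  sphere <- make_sphere_volume(14, radius = 5, center = c(7, 7.5, 7))
  prey <- segment_prey(sphere, 0.5, vs)
  half <- array(0, dim(sphere)); half[, 1:7, ] <- 1
  cell_half <- segment_prey(half, 0.5, vs)
  ioh <- inside_outside_ratio(prey, cell_half)
  analytic_half <- 4 / 3 * pi * 5^3 / 2
  expect_lt(abs(ioh$inside_um3 - analytic_half) / analytic_half, 0.05)
  expect_lt(abs(ioh$outside_um3 - analytic_half) / analytic_half, 0.05)
  expect_lt(abs(ioh$ratio - 1), 0.1)
  # conservation holds exactly in every configuration
  for (io_i in list(io, io0, ioh)) {
    expect_identical(io_i$inside_um3 + io_i$outside_um3, io_i$total_um3)
  }
  expect_error(
    inside_outside_ratio(prey, segment_prey(array(0, c(3, 3, 3)), 0.5, vs)),
    class = "pp_shape_error")
})

test_that("automatic levels separate known populations at SNR 8", {
  set.seed(42)
  n <- 24
  truth_class <- array(0L, c(n, n, n))
  truth_class[3:10, 3:10, 3:10] <- 1L     # cell-level block
  truth_class[15:20, 15:20, 15:20] <- 2L  # phagosome-level block
  means <- c(0.05, 0.45, 1)[truth_class + 1L]
  vol <- array(means + rnorm(n^3, 0, 1 / 8), dim(truth_class))
  sm <- smooth_box3(vol)
  lv <- auto_levels(sm)
  expect_s3_class(lv, "pp_seg_levels")
  expect_gt(lv$high, lv$low)
  called <- (sm > lv$low) + (sm > lv$high)
  # evaluate away from the blurred class boundaries (1-voxel shell)
  interior <- array(TRUE, dim(truth_class))
  interior[2:11, 2:11, 2:11] <- FALSE; interior[4:9, 4:9, 4:9] <- TRUE
  interior[14:21, 14:21, 14:21] <- FALSE; interior[16:19, 16:19, 16:19] <- TRUE
  expect_lt(mean(called[interior] != truth_class[interior]), 0.01)
  # two-population (prey) case
  truth2 <- array(0L, c(n, n, n)); truth2[5:16, 5:16, 5:16] <- 1L
  vol2 <- array(c(0.05, 1)[truth2 + 1L] + rnorm(n^3, 0, 1 / 8), dim(truth2))
  thr <- otsu_levels(vol2, n_classes = 2)
  expect_lt(mean((vol2 > thr) != truth2), 0.01)
  expect_error(seg_levels(low = 0.5, high = 0.4, prey = 0.3),
               class = "pp_config_error")
})
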