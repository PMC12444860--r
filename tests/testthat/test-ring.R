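test_that("ring pixel sets equal the brute-force scan in both modes", {
  withr::with_seed(7, {
    for (mode in c("annulus", "disc")) {
      for (rep in 1:3) {
        ctr <- runif(2, 12, 28)
        spec <- ring_spec(radius = 6, half_width = 1.5, mode = mode)
        px <- ring_pixels(ctr, spec, c(41, 41))
        oracle <- brute_ring_scan(matrix(0, 41, 41), ctr, 6, 1.5, 21, mode)
        got <- paste(px$row, px$col)
        want <- paste(oracle$pixels$row, oracle$pixels$col)
        expect_setequal(got, want)
        expect_false(attr(px, "clipped"))
      }
    }
  })
})

test_that("a unit-radius ring includes the four pixel neighbours", {
  spec <- ring_spec(radius = 1, half_width = 0.999)
  px <- ring_pixels(c(10, 10), spec, c(21, 21))
  got <- paste(px$row, px$col)
  for (nb in list(c(10, 11), c(12, 11), c(11, 10), c(11, 12))) {
    expect_true(paste(nb[1], nb[2]) %in% got)
  }
})

test_that("rings at the image corner are clipped and flagged", {
  spec <- ring_spec(radius = 6, half_width = 1.5)
  px_corner <- ring_pixels(c(0, 0), spec, c(41, 41))
  px_full <- ring_pixels(c(20, 20), spec, c(41, 41))
  expect_lt(nrow(px_corner), nrow(px_full))
  expect_true(attr(px_corner, "clipped"))
})

test_that("angular profiles are exact on uniform and random planes", {
  spec <- ring_spec(radius = 6, half_width = 1.5)
  # uniform field: every sector mean and the ring mean equal the constant
  prof <- angular_profile(matrix(2.5, 41, 41), c(20, 20), spec)
  expect_equal(prof$sector_means, rep(2.5, 21))
  expect_equal(prof$ring_mean, 2.5)
  # random plane: oracle equality at 1e-9 relative tolerance
  withr::with_seed(21, {
    plane <- matrix(runif(41 * 41), 41, 41)
    ctr <- c(17.3, 22.8)
    prof <- angular_profile(plane, ctr, spec)
    oracle <- brute_ring_scan(plane, ctr, 6, 1.5, 21)
    expect_equal(prof$ring_mean, oracle$ring_mean, tolerance = 1e-9)
    expect_equal(prof$sector_means, oracle$sector_means, tolerance = 1e-9)
  })
  expect_error(angular_profile(matrix(0, 3, 3), c(200, 200), spec),
               class = "pp_geometry_error")
})

test_that("a pore in the shell is confined to the overlapping sectors", {
  spec <- ring_spec(radius = 6, half_width = 1.5)
  pore_start <- 2 * pi * 5 / 21  # aligned with sector boundaries
  img <- shell_plane(pore_start = pore_start, pore_width = pi / 3)
  prof <- angular_profile(img, c(20, 20), spec)
  in_pore <- seq_len(21) %in% 6:7  # 60 deg ~ 3.5 sectors; 6 and 7 are fully in
  expect_true(all(prof$sector_means[in_pore] < 0.2))
  clean <- prof$sector_means[!seq_len(21) %in% 5:9]
  expect_true(all(clean > 0.5))
})

test_that("rotating the pore by one sector width permutes the sector means", {
  spec <- ring_spec(radius = 6, half_width = 1.5)
  step <- 2 * pi / 21
  a <- angular_profile(shell_plane(pore_start = 3 * step), c(20, 20), spec)
  b <- angular_profile(shell_plane(pore_start = 4 * step), c(20, 20), spec)
  # b's profile is a's shifted by one sector, within the pixel-binning
  # tolerance of ~3 pixels per sector at this radius
  shifted <- c(a$sector_means[21], a$sector_means[-21])
  expect_lt(max(abs(b$sector_means - shifted)), 0.15)
  # and one sector is the best cyclic shift of all
  mismatch <- purrr::map_dbl(0:20, function(k) {
    sum(abs(b$sector_means -
              a$sector_means[(seq_len(21) - 1 - k) %% 21 + 1]))
  })
  expect_identical(which.min(mismatch) - 1L, 1L)
})

test_that("kymographs index frames and planes correctly", {
  cfg <- noise_free(tiny_config(p_pulse = 0))
  sim <- simulate_cohort(cfg)
  tr <- truth_tracks(sim$truth)
  one <- tr[1, ]
  s1 <- build_kymograph(one, sim$movies[[1]], ring_spec(radius = 3))
  expect_identical(dim(s1$sectors), c(1L, 21L))
  bad <- one; bad$frame <- 999L
  expect_error(build_kymograph(bad, sim$movies[[1]], ring_spec(radius = 3)),
               class = "pp_index_error")
  # annulus sees the bright membrane; a disc dilutes it with the dim interior
  s_ann <- build_kymograph(tr, sim$movies[[1]], ring_spec(radius = 3))
  s_disc <- build_kymograph(tr, sim$movies[[1]],
                            ring_spec(radius = 3, mode = "disc"))
  i_peak <- which.max(s_ann$ring_mean)
  expect_gte(s_ann$ring_mean[i_peak], s_disc$ring_mean[i_peak])
})

test_that("the low-pass filter is a centred sliding mean with mirrored ends", {
  withr::with_seed(3, {
    s <- phagopulse:::new_ring_series(
      "t", 1:30, matrix(runif(30 * 21), 30, 21), runif(30), 30, "raw")
    id1 <- lowpass(s, 1)
    expect_equal(id1$ring_mean, s$ring_mean)
    expect_equal(id1$sectors, s$sectors)
    const <- phagopulse:::new_ring_series(
      "c", 1:10, matrix(2, 10, 21), rep(2, 10), 30, "raw")
    expect_equal(lowpass(const, 5)$ring_mean, rep(2, 10))
    f <- lowpass(s, 5)
    expect_equal(f$ring_mean, brute_sliding_mean(s$ring_mean, 5),
                 tolerance = 1e-12)
    expect_equal(f$sectors[, 4], brute_sliding_mean(s$sectors[, 4], 5),
                 tolerance = 1e-12)
    expect_error(lowpass(s, 4), class = "pp_config_error")
    expect_error(lowpass(s, 31), class = "pp_config_error")
  })
})

test_that("normalisation maps each track onto [0, 1] and is idempotent", {
  sec <- matrix(c(10, 20, 30, 25), 4, 21)
  s <- phagopulse:::new_ring_series("t", 1:4, sec, c(10, 20, 30, 25), 30, "raw")
  n1 <- normalize_tracks(s)
  expect_equal(min(n1$sectors, n1$ring_mean), 0)
  expect_equal(max(n1$sectors, n1$ring_mean), 1)
  expect_equal(n1$ring_mean[2], 0.5)  # midpoint of [10, 30]
  n2 <- normalize_tracks(n1)
  expect_equal(n2$sectors, n1$sectors)
  expect_equal(n2$ring_mean, n1$ring_mean)
  # constant tracks are flagged, not divided by zero
  cs <- phagopulse:::new_ring_series("c", 1:5, matrix(7, 5, 21), rep(7, 5),
                                     30, "raw")
  nc <- normalize_tracks(cs)
  expect_true(nc$flags$constant)
  expect_true(all(nc$ring_mean == 0))
})

test_that("alignment at time zero reproduces brute-force column statistics", {
  mk <- function(id, frames, vals) {
    phagopulse:::new_ring_series(id, frames,
                                 matrix(vals, length(vals), 21), vals, 30,
                                 "normalized")
  }
  # a single track: mean is the track, sd is zero
  one <- align_and_average(mk("a", 5:9, c(1, 2, 3, 2, 1)))
  expect_equal(one$summary$mean, c(1, 2, 3, 2, 1))
  expect_equal(one$summary$sd, rep(0, 5))
  expect_equal(one$summary$n, rep(1, 5))
  # two identical tracks offset in absolute time collapse after alignment
  two <- align_and_average(list(mk("a", 5:9, c(1, 2, 3, 2, 1)),
                                mk("b", 11:15, c(1, 2, 3, 2, 1))))
  expect_equal(two$summary$mean, c(1, 2, 3, 2, 1))
  expect_equal(two$summary$sd, rep(0, 5))
  expect_true(all(purrr::map_int(two$aligned, function(s) s$frames[1]) == 0L))
  # nine ragged random tracks vs direct column statistics
  withr::with_seed(14, {
    lens <- sample(6:12, 9, replace = TRUE)
    tracks <- purrr::imap(lens, function(l, i) {
      mk(paste0("t", i), seq(10 + i, len = l), runif(l))
    })
    got <- align_and_average(tracks)
    mat <- matrix(NA_real_, max(lens), 9)
    for (j in 1:9) mat[seq_len(lens[j]), j] <- tracks[[j]]$ring_mean
    expect_equal(got$summary$mean, rowMeans(mat, na.rm = TRUE))
    want_sd <- apply(mat, 1, function(r) {
      r <- r[!is.na(r)]; if (length(r) <= 1) 0 else sd(r)
    })
    expect_equal(got$summary$sd, want_sd)
    expect_equal(got$summary$n, rowSums(!is.na(mat)))
  })
})
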