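fake_calls <- function(neutrophil, pulsing, latency = NA_real_,
                       n_pulses = ifelse(pulsing, 1L, 0L)) {
  out <- tibble::tibble(
    track_id = sprintf("t%03d", seq_along(neutrophil)),
    neutrophil = neutrophil, pulsing = pulsing,
    n_pulses = n_pulses, latency_min = latency)
  class(out) <- c("pp_calls", class(out))
  out
}

test_that("per-neutrophil pulsing fractions aggregate as hand computation", {
  # every phagosome pulsing
  s1 <- pulsing_summary(fake_calls(c(1, 1, 2), c(TRUE, TRUE, TRUE),
                                   latency = c(5, 7, 9)))
  expect_equal(s1$summary$mean_pct_pulsing, 100)
  expect_equal(s1$summary$pct_neutrophils_pulsing, 100)
  # fractions 0% and 50% -> mean 25%, half of neutrophils pulsing
  s2 <- pulsing_summary(fake_calls(c(1, 1, 2, 2), c(FALSE, FALSE, TRUE, FALSE),
                                   latency = c(NA, NA, 8, NA)))
  expect_equal(s2$summary$mean_pct_pulsing, 25)
  expect_equal(s2$summary$pct_neutrophils_pulsing, 50)
  expect_equal(s2$summary$pooled_pct_pulsing, 25)
  expect_equal(s2$summary$latency_mean_min, 8)
  # aggregation matches a brute-force recomputation on a random cohort
  withr::with_seed(77, {
    nb <- rep(1:30, times = sample(1:8, 30, replace = TRUE))
    calls <- fake_calls(nb, runif(length(nb)) < 0.3)
    s <- pulsing_summary(calls)
    frac <- sapply(split(calls$pulsing, calls$neutrophil), mean) * 100
    expect_equal(s$summary$mean_pct_pulsing, mean(frac))
    expect_equal(s$summary$sd_pct_pulsing, sd(frac))
    expect_equal(s$summary$pct_neutrophils_pulsing, 100 * mean(frac > 0))
  })
})

test_that("the summary estimator recovers a generative pulse probability", {
  withr::with_seed(123, {
    p <- 0.124
    nb <- rep(seq_len(400), times = pmin(rgeom(400, 1 / 3) + 1, 25))
    calls <- fake_calls(nb, runif(length(nb)) < p)
    s <- pulsing_summary(calls)
    se <- sd(s$per_neutrophil$pct_pulsing) / sqrt(nrow(s$per_neutrophil))
    expect_lt(abs(s$summary$mean_pct_pulsing - 100 * p), 3 * se)
  })
})

test_that("burden correlation is Spearman with midranks", {
  expect_equal(burden_correlation(
    tibble::tibble(n_bacteria = 1:6, n_pulsing = (1:6)^2))$rho, 1)
  expect_equal(burden_correlation(
    tibble::tibble(n_bacteria = 1:3, n_pulsing = 3:1))$rho, -1)
  withr::with_seed(8, {
    rec <- tibble::tibble(n_bacteria = sample(1:10, 50, replace = TRUE),
                          n_pulsing = sample(0:4, 50, replace = TRUE))
    got <- burden_correlation(rec)
    want <- suppressWarnings(
      stats::cor.test(rec$n_bacteria, rec$n_pulsing, method = "spearman"))
    expect_equal(got$rho, unname(want$estimate), tolerance = 1e-12)
    expect_gt(got$p_value, 0); expect_lt(got$p_value, 1)
  })
  expect_warning(burden_correlation(
    tibble::tibble(n_bacteria = rep(2, 5), n_pulsing = 1:5)))
  expect_error(burden_correlation(
    tibble::tibble(n_bacteria = 1:2, n_pulsing = 1:2)),
    class = "pp_config_error")
})

test_that("relative change divides by the baseline and excludes zero baselines", {
  ser <- tibble::tibble(
    object = rep(c("a", "b", "z"), each = 3),
    timepoint = rep(c(0, 10, 60), 3),
    intensity = c(4, 4, 4, 10, 5, 8, 0, 1, 2))
  expect_warning(rc <- relative_change(ser, baseline = 0), "zero baseline")
  a <- rc$per_object[rc$per_object$object == "a", ]
  expect_equal(a$rel_change, c(1, 1, 1))
  b <- rc$per_object[rc$per_object$object == "b", ]
  expect_equal(b$rel_change[b$timepoint == 10], 0.5)
  expect_false("z" %in% rc$per_object$object)
  expect_error(relative_change(ser, baseline = 99), class = "pp_config_error")
})

test_that("pulsing phagosomes keep their prey reporter brighter at 10 min", {
  # generator pH model: sealed phagosomes dim after engulfment, pulsing ones
  # (held near tissue pH by re-opening) do not
  n_fov <- 10
  cfg <- sim_config(shape = c(x = 24, y = 24, z = 7), n_frames = 26,
                    n_neutrophils = n_fov, phagosomes_fixed = 1,
                    p_pulse = 0.5, p_leak = 0, latency_mean_min = 20,
                    engulf_window_frames = c(2L, 2L), seed = 15)
  rows <- purrr::map_dfr(seq_len(n_fov), function(fov) {
    sim <- simulate_movie(cfg, fov)
    det <- detect_centroids(sim$movie, "prey")
    ph <- sim$truth$phagosomes
    e <- ph$engulf_frame[1]
    tibble::tibble(
      object = sprintf("fov%03d", fov),
      class = ifelse(ph$pulsing[1], "pulsing", "non_pulsing"),
      timepoint = c(0, 10),
      intensity = c(det$mean_intensity[det$frame == e][1],
                    det$mean_intensity[det$frame == e + 20][1]))
  })
  expect_setequal(unique(rows$class), c("pulsing", "non_pulsing"))
  rc <- relative_change(rows, baseline = 0)
  at10 <- rc$by_class[rc$by_class$timepoint == 10, ]
  expect_gt(at10$mean[at10$class == "pulsing"],
            at10$mean[at10$class == "non_pulsing"])
})

test_that("dye classification recovers generative leak fractions at n = 2000", {
  for (p in c(0.05, 0.2, 0.5)) {
    cfg <- sim_config(shape = c(x = 20, y = 20, z = 7), n_frames = 12,
                      n_neutrophils = 2000, phagosomes_fixed = 1,
                      p_leak = p, seed = round(1000 * p))
    dc <- simulate_dye_cohort(cfg, dye_add_frame = 5)
    expect_identical(nrow(dc$intensities), 2000L)
    dp <- dye_positive_fraction(dc$intensities)
    se <- sqrt(p * (1 - p) / 2000)
    expect_lt(abs(dp$fraction_pct - 100 * p), 3 * 100 * se)
    # balanced accuracy against the generator flags
    truth_flag <- dc$truth$phagosomes$dye_positive[
      match(dc$intensities$object,
            sprintf("fov%03d_ph%03d", dc$truth$phagosomes$fov,
                    dc$truth$phagosomes$phagosome))]
    bal <- mean(c(mean(dp$labels$dye_positive[truth_flag]),
                  mean(!dp$labels$dye_positive[!truth_flag])))
    expect_gte(bal, 0.95)
  }
  # degenerate inputs
  flat <- tibble::tibble(object = letters[1:5], pre_mean = 0.02,
                         post_mean = 0.02)
  expect_equal(dye_positive_fraction(flat, threshold = 0.1)$fraction_pct, 0)
})

test_that("peri-bacterial shell voxels match a brute-force distance oracle", {
  vs <- c(x = 0.25, y = 0.25, z = 0.5)
  vol <- array(1, c(14, 14, 8))
  mask <- array(0, c(14, 14, 8)); mask[6:8, 6:8, 4:5] <- 1
  prey <- segment_prey(mask, 0.5, vs)
  # uniform indicator, reference at the same level: ratio 1
  r1 <- dcf_shell_ratio(vol, prey, shell_um = 0.5, reference = rep(1, 5))
  expect_equal(r1$ratio, 1)
  expect_false(r1$flagged)
  # brute-force voxel set: min Euclidean distance to the mask in um
  d <- dim(vol)
  in_shell_oracle <- array(FALSE, d)
  midx <- which(mask > 0, arr.ind = TRUE)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] > 0) next
    dd <- sqrt((((midx[, 1] - i) * vs["y"])^2 +
                  ((midx[, 2] - j) * vs["x"])^2 +
                  ((midx[, 3] - k) * vs["z"])^2))
    in_shell_oracle[i, j, k] <- min(dd) <= 0.5
  }
  expect_identical(r1$shell_voxels, sum(in_shell_oracle))
  # a ROS-bright shell four times the reference level
  vol4 <- array(0.1, d)
  vol4[in_shell_oracle] <- 0.4
  r4 <- dcf_shell_ratio(vol4, prey, shell_um = 0.5, reference = rep(0.1, 4))
  expect_equal(r4$ratio, 4)
  expect_error(dcf_shell_ratio(vol, prey, shell_um = 0,
                               reference = 1), class = "pp_config_error")
})

test_that("group comparisons agree with hand-ranked statistics", {
  withr::with_seed(2, {
    # identical groups: statistics at the null centre
    df0 <- tibble::tibble(value = rep(1:10, 2),
                          group = rep(c("a", "b"), each = 10))
    r0 <- compare_groups(df0, tests = c("kruskal", "wilcox"))
    expect_gt(r0$p_value[r0$method == "kruskal_wallis"], 0.9)
    # strong separation: p below 1e-6
    df1 <- tibble::tibble(value = c(rnorm(50), rnorm(50, 10)),
                          group = rep(c("a", "b"), each = 50))
    r1 <- compare_groups(df1, tests = c("t", "wilcox"))
    expect_true(all(r1$p_value < 1e-6))
    # Kruskal-Wallis H on a toy 3-group set equals the hand-ranked formula
    vals <- c(1, 3, 5, 2, 4, 6, 10, 12, 11)
    grp <- rep(c("a", "b", "c"), each = 3)
    r <- rank(vals); n <- length(vals)
    hand_h <- 12 / (n * (n + 1)) *
      sum(tapply(r, grp, function(g) length(g) * mean(g)^2)) - 3 * (n + 1)
    rk <- compare_groups(tibble::tibble(value = vals, group = grp),
                         tests = "kruskal")
    expect_equal(rk$statistic, hand_h, tolerance = 1e-12)
    # Dunn z tests come Holm-adjusted and flag nothing valid-sized
    rd <- compare_groups(tibble::tibble(value = vals, group = grp),
                         tests = "dunn")
    expect_true(all(rd$p_adjusted >= rd$p_value))
    # undersized groups are flagged for the t-test
    rsmall <- compare_groups(
      tibble::tibble(value = c(1, 2, 3), group = c("a", "a", "b")),
      tests = "t")
    expect_true(rsmall$flagged)
  })
})

test_that("event tallies reproduce printed percentages with exact CIs", {
  t1 <- tally_statistics(tibble::tibble(name = "reopen", numerator = 27,
                                        denominator = 138, digits = 1))
  expect_identical(t1$pct, 19.6)
  t2 <- tally_statistics(tibble::tibble(name = "none", numerator = 0,
                                        denominator = 10, digits = 1))
  expect_identical(t2$pct, 0)
  expect_equal(t2$ci_lo_pct, 0)
  expect_equal(t2$ci_hi_pct, 30.8, tolerance = 0.1)
  t3 <- tally_statistics(tibble::tibble(name = "all", numerator = 31,
                                        denominator = 31, digits = 0))
  expect_identical(t3$pct, 100)
  expect_error(tally_statistics(tibble::tibble(name = "bad", numerator = 1,
                                               denominator = 0)),
               class = "pp_config_error")
  expect_error(tally_statistics(tibble::tibble(name = "bad", numerator = 5,
                                               denominator = 3)),
               class = "pp_config_error")
})

test_that("the packaged event-tally fixture matches its recorded percentages", {
  tal <- read_event_tally()
  stats <- tally_statistics(tal)
  expect_identical(stats$pct, tal$expected_pct)
})
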