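# a surge-then-decay backbone with optional pulse bumps, in [0, 1]
toy_trace <- function(n = 40, pulses = list()) {
  x <- c(0.6, 1, 0.7, 0.45, 0.3, 0.22, rep(0.15, n - 6))
  for (p in pulses) {
    i <- p[["at"]]
    x[i - 1] <- x[i - 1] + p[["h"]] / 2
    x[i] <- x[i] + p[["h"]]
    x[i + 1] <- x[i + 1] + p[["h"]] / 2
  }
  pmin(x, 1)
}

test_that("monotone decay after the surge yields zero pulses", {
  ev <- detect_pulses(toy_trace())
  expect_identical(nrow(ev), 0L)
  # a trace that never drops below the fade threshold has no pulse window
  ev2 <- detect_pulses(rep(0.9, 20))
  expect_identical(nrow(ev2), 0L)
})

test_that("isolated bumps are reported with consistent event geometry", {
  tr <- toy_trace(40, list(c(at = 15, h = 0.5), c(at = 30, h = 0.6)))
  ev <- detect_pulses(tr)
  expect_identical(ev$peak, c(15L, 30L))
  expect_true(all(ev$onset <= ev$peak & ev$peak <= ev$end))
  expect_true(all(ev$amplitude > 0 & ev$amplitude <= 1))
  expect_true(all(ev$prominence <= ev$amplitude))
  expect_equal(ev$duration, ev$end - ev$onset)
})

test_that("of two close maxima the higher is kept, the earlier on ties", {
  base <- rep(0.1, 30)
  mk <- function(h1, h2) {
    x <- base
    x[1:3] <- c(0.9, 1, 0.6)  # surge
    x[14] <- h1; x[16] <- h2  # two maxima 2 frames apart (< min_separation 3)
    x
  }
  ev_hi_first <- detect_pulses(mk(0.7, 0.5))
  expect_identical(ev_hi_first$peak, 14L)
  ev_hi_second <- detect_pulses(mk(0.5, 0.7))
  expect_identical(ev_hi_second$peak, 16L)
  ev_tie <- detect_pulses(mk(0.6, 0.6))
  expect_identical(ev_tie$peak, 14L)
})

test_that("pulse count is monotone non-increasing in the prominence threshold", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      x <- toy_trace(60)
      for (k in 1:4) {
        at <- sample(10:58, 1)
        x[at] <- min(x[at] + runif(1, 0.05, 0.8), 1)
      }
      x <- pmin(pmax(x + rnorm(60, 0, 0.02), 0), 1)
      counts <- purrr::map_int(seq(0, 1, by = 0.1), function(pm) {
        nrow(detect_pulses(x, pulse_params(prominence_min = pm)))
      })
      expect_true(all(diff(counts) <= 0))
    }
  })
})

test_that("detection is deterministic and validates its input", {
  tr <- toy_trace(40, list(c(at = 20, h = 0.6)))
  expect_identical(detect_pulses(tr), detect_pulses(tr))
  expect_error(detect_pulses(tr * 2), class = "pp_state_error")
  expect_error(detect_pulses(c(0.1, 0.2, 0.3)), class = "pp_state_error")
  raw <- phagopulse:::new_ring_series("t", 1:10, matrix(0.5, 10, 21),
                                      rep(0.5, 10), 30, "raw")
  expect_error(detect_pulses(raw), class = "pp_state_error")
})

test_that("noise-free scheduled pulses are recovered at the logged frames", {
  cfg <- noise_free(sim_config(
    shape = c(x = 24, y = 24, z = 7), n_frames = 90, n_neutrophils = 4,
    phagosomes_fixed = 1, p_pulse = 1, pulse_count_fixed = 3, p_open = 0,
    latency_mean_min = 6, latency_sd_min = 1, channels = "reporter", seed = 2))
  cc <- call_simulated_cohort(cfg)
  expect_true(all(cc$calls$n_pulses == 3))
  for (i in seq_len(nrow(cc$calls))) {
    det <- cc$calls$pulses[[i]]$peak_frame
    expect_true(all(abs(det - cc$calls$true_peaks[[i]]) <= 1))
  }
})

test_that("per-phagosome metrics: latency, flags, and the 18-pulse extreme", {
  # no pulses: flag false, latency undefined
  s <- phagopulse:::new_ring_series("t", 1:40, matrix(toy_trace(), 40, 21),
                                    toy_trace(), 30, "normalized")
  cc <- call_phagosome(s)
  expect_false(cc$pulsing)
  expect_true(is.na(cc$latency_min))
  # first pulse scheduled at 10 min arrives within one frame interval
  cfg <- noise_free(sim_config(
    shape = c(x = 24, y = 24, z = 7), n_frames = 80, n_neutrophils = 3,
    phagosomes_fixed = 1, p_pulse = 1, pulse_count_fixed = 1,
    latency_mean_min = 10, latency_sd_min = 0, channels = "reporter",
    p_open = 0, seed = 6))
  cc2 <- call_simulated_cohort(cfg)
  expect_true(all(cc2$calls$true_latency_min == 10))
  expect_true(all(abs(cc2$calls$latency_min - 10) <= 0.5))
  # 18 well-separated scheduled pulses are all counted
  cfg18 <- noise_free(sim_config(
    shape = c(x = 24, y = 24, z = 7), n_frames = 260, n_neutrophils = 1,
    phagosomes_fixed = 1, p_pulse = 1, pulse_count_fixed = 18,
    latency_mean_min = 6, latency_sd_min = 0.5, pulse_gap_mean_min = 0.01,
    engulf_window_frames = c(2L, 2L), channels = "reporter", p_open = 0,
    seed = 10))
  cc18 <- call_simulated_cohort(cfg18)
  expect_identical(cc18$calls$true_n_pulses, 18L)
  expect_identical(cc18$calls$n_pulses, 18L)
})

test_that("mean detected count equals the scheduled count on noise-free cohorts", {
  for (k in 1:3) {
    cfg <- noise_free(sim_config(
      shape = c(x = 24, y = 24, z = 7), n_frames = 80, n_neutrophils = 4,
      phagosomes_fixed = 1, p_pulse = 1, pulse_count_fixed = k,
      latency_mean_min = 6, latency_sd_min = 1, channels = "reporter",
      seed = 40 + k))
    cc <- call_simulated_cohort(cfg)
    expect_equal(mean(cc$calls$n_pulses), k)
  }
})

test_that("the operating-point sweep scores detectors against the log", {
  cfg <- noise_free(sim_config(
    shape = c(x = 24, y = 24, z = 7), n_frames = 90, n_neutrophils = 6,
    phagosomes_fixed = 1, p_pulse = 0.5, pulse_count_fixed = 2, p_open = 0,
    latency_mean_min = 6, latency_sd_min = 1, channels = "reporter", seed = 12))
  cc <- call_simulated_cohort(cfg, keep_series = TRUE)
  grid <- tidyr::expand_grid(prominence_min = c(0.2, 0.99),
                             fade_threshold = 0.4, min_separation = 3)
  res <- sweep_operating_point(cc$series, cc$truth, grid)
  expect_true(all(diff(res$f1) <= 0))
  best <- res[res$prominence_min == 0.2, ]
  expect_equal(best$f1, 1)
  # an unreachable prominence threshold recalls nothing
  worst <- res[res$prominence_min == 0.99, ]
  expect_equal(worst$recall, 0)
  expect_error(sweep_operating_point(cc$series, cc$truth, grid[0, ]),
               class = "pp_config_error")
})
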