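#' Profile and call a simulated cohort from ground-truth tracks
#'
#' Validation workflow for the profiling and pulse-calling stages in
#' isolation: simulates each field of view, takes the generator's own tracks
#' (bypassing segmentation and linking), builds ring kymographs on the
#' reporter channel, low-pass filters, normalises, and calls pulses with the
#' engulfment frame taken from the log. Fields of view are processed one at a
#' time, so arbitrarily large cohorts fit in memory.
#'
#' @param config a [sim_config()].
#' @param spec a [ring_spec()]; the default radius (3 px) matches the
#'   rendered 1 um membrane at 0.33 um pixels.
#' @param params a [pulse_params()].
#' @param window low-pass window, frames.
#' @return List: `calls` (a `pp_calls` tibble joined with the ground truth
#'   per phagosome: `true_pulsing`, `true_n_pulses`, `true_latency_min`,
#'   `true_peaks`, `leaky`, `neutrophil`), `truth` (combined `pp_truth`),
#'   and `series` (the normalised ring series, kept only when
#'   `keep_series = TRUE`).
#' @param keep_series keep the per-track normalised series (memory!).
#' @export
call_simulated_cohort <- function(config, spec = ring_spec(radius = 3),
                                  params = pulse_params(), window = 5,
                                  keep_series = FALSE) {
  stopifnot(inherits(config, "pp_sim_config"))
  all_calls <- vector("list", config$n_neutrophils)
  all_truth <- vector("list", config$n_neutrophils)
  all_series <- list()
  for (fov in seq_len(config$n_neutrophils)) {
    sim <- simulate_movie(config, fov)
    tr <- truth_tracks(sim$truth)
    ph <- sim$truth$phagosomes
    calls <- purrr::map_dfr(seq_len(nrow(ph)), function(i) {
      id <- sprintf("fov%03d_ph%03d", fov, ph$phagosome[i])
      s <- build_kymograph(tr[tr$track_id == id, ], sim$movie, spec)
      s <- normalize_tracks(lowpass(s, window))
      if (keep_series) all_series[[id]] <<- s
      cc <- call_phagosome(s, engulf_frame = ph$engulf_frame[i],
                           params = params)
      cc$neutrophil <- fov
      cc$phagosome <- ph$phagosome[i]
      cc$true_pulsing <- ph$pulsing[i]
      cc$true_n_pulses <- ph$n_pulses[i]
      cc$true_latency_min <- ph$latency_min[i]
      cc$true_peaks <- ph$pulse_peaks[i]
      cc$leaky <- ph$leaky[i]
      cc
    })
    all_calls[[fov]] <- calls
    all_truth[[fov]] <- sim$truth
  }
  calls <- dplyr::bind_rows(all_calls)
  class(calls) <- c("pp_calls", class(calls))
  truth <- combine_truth(all_truth, config)
  list(calls = calls, truth = truth,
       series = if (keep_series) all_series else NULL)
}

#' Simulate a dye-accumulation cohort and measure mask dye intensities
#'
#' Emulates the fluid-phase dye experiment: movies are simulated, the dye
#' channel is added at `dye_add_frame`, and the mean dye intensity within
#' each segmented bacterial mask is measured before and after addition
#' ([measure_dye()]). Fields of view are streamed.
#'
#' @param config a [sim_config()].
#' @param dye_add_frame frame at which the dye is added.
#' @return List: `intensities` (tibble from [measure_dye()], one row per
#'   matched phagosome) and `truth` (with `dye_positive` flags updated).
#' @export
simulate_dye_cohort <- function(config, dye_add_frame) {
  stopifnot(inherits(config, "pp_sim_config"))
  ints <- vector("list", config$n_neutrophils)
  truths <- vector("list", config$n_neutrophils)
  for (fov in seq_len(config$n_neutrophils)) {
    sim <- simulate_movie(config, fov)
    movie <- add_dye_channel(sim$movie, sim$truth, dye_add_frame)
    ints[[fov]] <- measure_dye(movie, sim$truth, dye_add_frame)
    truths[[fov]] <- sim$truth
  }
  truth <- dye_positive_truth(combine_truth(truths, config), dye_add_frame)
  list(intensities = dplyr::bind_rows(ints), truth = truth)
}
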