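#' Pulse detection parameters
#'
#' A pulse is a brief, high-amplitude re-surge of normalised ring-mean
#' fluorescence after the initial closure surge has faded. The detector is
#' deterministic: the closure surge (from the start of the trace until it
#' first drops below `fade_threshold`) is excluded, then local maxima with
#' topographic prominence at least `prominence_min` and peak-to-peak
#' separation at least `min_separation` frames are reported as pulses.
#'
#' @param prominence_min minimum topographic prominence, normalised units.
#' @param fade_threshold normalised level whose first downward crossing ends
#'   the closure-surge exclusion window.
#' @param min_separation minimum separation between accepted peaks, frames.
#' @return A `pp_pulse_params` list.
#' @export
pulse_params <- function(prominence_min = 0.2, fade_threshold = 0.4,
                         min_separation = 3) {
  if (prominence_min < 0 || prominence_min > 1) {
    abort("prominence_min must be in [0, 1]", class = "pp_config_error")
  }
  if (fade_threshold <= 0 || fade_threshold >= 1) {
    abort("fade_threshold must be in (0, 1)", class = "pp_config_error")
  }
  if (min_separation < 1) {
    abort("min_separation must be >= 1 frame", class = "pp_config_error")
  }
  structure(list(prominence_min = prominence_min,
                 fade_threshold = fade_threshold,
                 min_separation = min_separation),
            class = "pp_pulse_params")
}

# min-max rescale to [0, 1]; constant input maps to zero
rescale01 <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi > lo) (x - lo) / (hi - lo) else rep(0, length(x))
}

# local maxima: strictly above the previous value, at least the next
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# topographic prominence of peak i on trace x, with base positions
peak_prominence <- function(x, i) {
  n <- length(x)
  # walk left until a strictly higher value (or the start)
  lo <- i
  j <- i - 1
  left_min <- x[i]; left_base <- i
  while (j >= 1 && x[j] <= x[i]) {
    if (x[j] < left_min) { left_min <- x[j]; left_base <- j }
    j <- j - 1
  }
  j <- i + 1
  right_min <- x[i]; right_base <- i
  while (j <= n && x[j] <= x[i]) {
    if (x[j] < right_min) { right_min <- x[j]; right_base <- j }
    j <- j + 1
  }
  base <- max(left_min, right_min)
  list(prominence = x[i] - base, left_base = left_base, right_base = right_base)
}

#' Detect pulses on a normalised ring-mean trace
#'
#' @param trace numeric vector in `[0, 1]` (a normalised ring-mean time
#'   series) or a normalised `pp_ring_series`.
#' @param params a [pulse_params()] object.
#' @return Tibble of pulse events ordered by time: `onset`, `peak`, `end`
#'   (1-based indices into the trace, `onset <= peak <= end`), `amplitude`
#'   (trace value at the peak), `prominence`, `duration` (frames,
#'   `end - onset`). Deterministic for fixed inputs; among peaks closer than
#'   `min_separation` the higher one is kept, ties broken to the earlier.
#' @export
detect_pulses <- function(trace, params = pulse_params()) {
  if (inherits(trace, "pp_ring_series")) {
    if (!trace$state %in% c("normalized", "aligned")) {
      abort("series must be normalised before pulse detection",
            class = "pp_state_error")
    }
    # thresholds are defined on the ring-mean trace's own [0, 1] span:
    # joint sector/ring-mean normalisation leaves the ring mean compressed
    trace <- rescale01(trace$ring_mean)
  }
  stopifnot(inherits(params, "pp_pulse_params"))
  if (length(trace) < 5) {
    abort("trace must have at least 5 frames", class = "pp_state_error")
  }
  if (any(trace < -1e-6 | trace > 1 + 1e-6)) {
    abort("trace is not normalised to [0, 1]", class = "pp_state_error")
  }
  empty <- tibble(onset = integer(0), peak = integer(0), end = integer(0),
                  amplitude = numeric(0), prominence = numeric(0),
                  duration = integer(0))
  fade <- which(trace < params$fade_threshold)
  if (length(fade) == 0) return(empty)
  fade_idx <- fade[1]
  peaks <- local_maxima(trace)
  peaks <- peaks[peaks > fade_idx]
  if (length(peaks) == 0) return(empty)

  # min-separation suppression over all maxima (before the prominence filter,
  # so raising prominence_min can only shrink the accepted set)
  ord <- peaks[order(-trace[peaks], peaks)]
  accepted <- integer(0)
  for (p in ord) {
    if (all(abs(p - accepted) >= params$min_separation)) {
      accepted <- c(accepted, p)
    }
  }
  accepted <- sort(accepted)
  if (length(accepted) == 0) return(empty)

  prom <- purrr::map(accepted, function(p) peak_prominence(trace, p))
  keep <- purrr::map_dbl(prom, "prominence") >= params$prominence_min
  accepted <- accepted[keep]
  prom <- prom[keep]
  if (length(accepted) == 0) return(empty)
  # onset/end: where the trace last/first crosses half prominence below the
  # peak — the rise/fall flanks, not the (noise-determined) minimum of a long
  # flat valley
  onset <- integer(length(accepted)); end <- integer(length(accepted))
  for (i in seq_along(accepted)) {
    pk <- accepted[i]; pr <- prom[[i]]
    lvl <- trace[pk] - 0.5 * pr$prominence
    j <- pk
    while (j > pr$left_base && trace[j - 1] > lvl) j <- j - 1
    onset[i] <- max(j - 1, pr$left_base, fade_idx)
    j <- pk
    while (j < pr$right_base && trace[j + 1] > lvl) j <- j + 1
    end[i] <- min(j + 1, pr$right_base)
  }
  tibble(
    onset = pmin(onset, accepted),
    peak = accepted,
    end = pmax(end, accepted),
    amplitude = trace[accepted],
    prominence = purrr::map_dbl(prom, "prominence"),
    duration = as.integer(pmax(end, accepted) - pmin(onset, accepted))
  )
}

#' Call pulses on one phagosome track
#'
#' Runs [detect_pulses()] on a normalised ring series and derives the
#' per-phagosome metrics: pulsing flag, pulse count, and first-pulse latency
#' in minutes from the engulfment frame (time zero of an aligned track).
#'
#' @param series a normalised `pp_ring_series`.
#' @param engulf_frame engulfment frame; defaults to the track's first frame.
#' @param params a [pulse_params()] object.
#' @return One-row tibble: `track_id`, `engulf_frame`, `n_pulses`, `pulsing`,
#'   `latency_min` (NA when not pulsing), `low_confidence` (track shorter
#'   than 10 frames after the fade), `pulses` (list column of pulse events
#'   with absolute frames and minutes).
#' @export
call_phagosome <- function(series, engulf_frame = NULL,
                           params = pulse_params()) {
  stopifnot(inherits(series, "pp_ring_series"))
  if (is.null(series$frame_interval_s) || !is.finite(series$frame_interval_s)) {
    abort("series lacks time calibration (frame interval)",
          class = "pp_config_error")
  }
  engulf_frame <- engulf_frame %||% series$frames[1]
  dt_min <- series$frame_interval_s / 60
  ev <- detect_pulses(series, params)
  trace <- rescale01(series$ring_mean)
  fade <- which(trace < params$fade_threshold)
  post_fade <- if (length(fade)) length(trace) - fade[1] + 1 else 0
  ev$onset_frame <- series$frames[ev$onset]
  ev$peak_frame <- series$frames[ev$peak]
  ev$end_frame <- series$frames[ev$end]
  ev$onset_min <- (ev$onset_frame - engulf_frame) * dt_min
  ev$duration_min <- ev$duration * dt_min
  tibble(
    track_id = series$track_id,
    engulf_frame = engulf_frame,
    n_pulses = nrow(ev),
    pulsing = nrow(ev) >= 1,
    latency_min = if (nrow(ev)) ev$onset_min[1] else NA_real_,
    low_confidence = post_fade < 10,
    pulses = list(ev)
  )
}

#' Call pulses across a cohort of tracks
#'
#' @param series_list list of normalised `pp_ring_series`.
#' @param params a [pulse_params()] object.
#' @param engulf_frames optional named vector of engulfment frames keyed by
#'   track id.
#' @return A `pp_calls` tibble, one row per track (see [call_phagosome()]).
#' @export
call_cohort <- function(series_list, params = pulse_params(),
                        engulf_frames = NULL) {
  out <- purrr::map_dfr(series_list, function(s) {
    ef <- if (!is.null(engulf_frames)) engulf_frames[[s$track_id]] else NULL
    call_phagosome(s, engulf_frame = ef, params = params)
  })
  class(out) <- c("pp_calls", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.pp_calls <- function(x, ...) {
  tidyr::unnest(dplyr::select(x, "track_id", "pulses"), "pulses")
}

#' @exportS3Method generics::glance
glance.pp_calls <- function(x, ...) {
  tibble(
    n_tracks = nrow(x),
    n_pulsing = sum(x$pulsing),
    pct_pulsing = 100 * mean(x$pulsing),
    mean_pulses_when_pulsing = if (any(x$pulsing)) {
      mean(x$n_pulses[x$pulsing])
    } else NA_real_,
    latency_mean_min = if (any(x$pulsing)) {
      mean(x$latency_min[x$pulsing])
    } else NA_real_,
    latency_sd_min = if (sum(x$pulsing) > 1) {
      sd(x$latency_min[x$pulsing])
    } else NA_real_
  )
}

#' Sweep detector operating points against ground truth
#'
#' Scores a parameter grid on a labelled synthetic cohort: a detected pulse
#' whose peak lies within `match_tol` frames of a scheduled pulse peak counts
#' as a true positive (one-to-one matching, nearest first).
#'
#' @param series_list list of normalised `pp_ring_series` whose track ids
#'   follow the [truth_tracks()] convention (`fovNNN_phNNN`), or any ids
#'   resolvable via `matches`.
#' @param truth a `pp_truth` log.
#' @param grid tibble of parameter sets with columns `prominence_min`,
#'   `fade_threshold`, `min_separation`.
#' @param match_tol matching tolerance, frames.
#' @param matches optional tibble `track_id`, `fov`, `phagosome` mapping
#'   tracks to truth objects.
#' @return The grid with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`
#'   columns, sorted by decreasing F1.
#' @export
sweep_operating_point <- function(series_list, truth, grid, match_tol = 2,
                                  matches = NULL) {
  if (is.null(grid) || nrow(grid) == 0) {
    abort("parameter grid is empty", class = "pp_config_error")
  }
  truth_peaks <- function(track_id) {
    if (!is.null(matches)) {
      m <- matches[matches$track_id == track_id, ]
      if (nrow(m) == 0) return(integer(0))
      r <- truth$phagosomes[truth$phagosomes$fov == m$fov[1] &
                              truth$phagosomes$phagosome == m$phagosome[1], ]
    } else {
      p <- regmatches(track_id, regexec("fov([0-9]+)_ph([0-9]+)", track_id))[[1]]
      if (length(p) != 3) return(integer(0))
      r <- truth$phagosomes[truth$phagosomes$fov == as.integer(p[2]) &
                              truth$phagosomes$phagosome == as.integer(p[3]), ]
    }
    if (nrow(r) == 0) integer(0) else r$pulse_peaks[[1]]
  }
  scheduled <- purrr::map(series_list, function(s) truth_peaks(s$track_id))

  res <- purrr::pmap_dfr(grid, function(prominence_min, fade_threshold,
                                        min_separation, ...) {
    par <- pulse_params(prominence_min, fade_threshold, min_separation)
    tp <- fp <- fn <- 0
    for (i in seq_along(series_list)) {
      s <- series_list[[i]]
      ev <- detect_pulses(s, par)
      det <- s$frames[ev$peak]
      sch <- scheduled[[i]]
      used <- logical(length(sch))
      hits <- 0
      for (d in det) {
        dd <- abs(sch - d); dd[used] <- Inf
        if (length(dd) && min(dd) <= match_tol) {
          used[which.min(dd)] <- TRUE
          hits <- hits + 1
        }
      }
      tp <- tp + hits
      fp <- fp + length(det) - hits
      fn <- fn + sum(!used)
    }
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (isTRUE(precision + recall > 0)) {
      2 * precision * recall / (precision + recall)
    } else 0
    tibble(prominence_min = prominence_min, fade_threshold = fade_threshold,
           min_separation = min_separation, tp = tp, fp = fp, fn = fn,
           precision = precision, recall = recall, f1 = f1)
  })
  dplyr::arrange(res, dplyr::desc(.data$f1))
}
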