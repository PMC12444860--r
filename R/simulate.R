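#' @title Ground-truthed synthetic movie generation
#' @name simulate_cohort
#'
#' @description
#' `simulate_cohort()` generates one two-channel 3D time-lapse movie per
#' neutrophil (field of view) together with a ground-truth event log, so every
#' downstream stage (segmentation, tracking, ring profiling, pulse calling,
#' cohort statistics) can be validated against known truth.
#' `simulate_movie()` generates a single field of view; cohorts are composed
#' of per-FOV generators seeded deterministically from `(config$seed, fov)`,
#' so FOVs can be generated independently (and streamed) with bit-identical
#' results.
#'
#' Each phagosome is rendered as a spherical membrane shell with a Gaussian
#' cross-section plus a solid prey sphere inside. The reporter amplitude
#' follows a closure surge (linear rise, exponential fade to a plateau) with
#' optional scheduled pulses; open intervals cut an azimuthal pore sector out
#' of the shell; the prey brightness follows a pH map (dim while the sealed
#' phagosome is alkaline, bright during open intervals).
#'
#' @param config a [sim_config()] object.
#' @param fov field-of-view (neutrophil) index, `1..config$n_neutrophils`.
#' @return `simulate_movie()`: a list with elements `movie` ([new_movie()])
#'   and `truth` (a `pp_truth` log for that FOV). `simulate_cohort()`: a list
#'   with `movies` (list of `pp_movie`) and `truth` (combined `pp_truth`).
#' @examples
#' cfg <- sim_config(n_neutrophils = 1, phagosomes_fixed = 1, p_pulse = 1,
#'                   pulse_count_fixed = 2, n_frames = 60, seed = 42)
#' sim <- simulate_cohort(cfg)
#' sim$truth$phagosomes$n_pulses
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "pp_sim_config"))
  fovs <- purrr::map(seq_len(config$n_neutrophils),
                     function(i) simulate_movie(config, i))
  truth <- combine_truth(purrr::map(fovs, "truth"), config)
  list(movies = purrr::map(fovs, "movie"), truth = truth)
}

#' @rdname simulate_cohort
#' @export
simulate_movie <- function(config, fov = 1L) {
  stopifnot(inherits(config, "pp_sim_config"))
  sched <- with_seed(fov_seed(config$seed, fov, 1L),
                     schedule_fov(config, fov))
  movie <- render_fov(config, sched, fov)
  list(movie = movie, truth = combine_truth(list(sched$truth), config))
}

# deterministic per-FOV, per-stream seed below 2^31
fov_seed <- function(seed, fov, stream) {
  (as.double(seed) * 1000003 + as.double(fov) * 7919 +
     as.double(stream) * 104729) %% 2147483629
}

combine_truth <- function(truths, config) {
  structure(
    list(
      phagosomes = dplyr::bind_rows(purrr::map(truths, function(t) t$phagosomes)),
      neutrophils = dplyr::bind_rows(purrr::map(truths, function(t) t$neutrophils)),
      config = config
    ),
    class = "pp_truth"
  )
}

#' @export
print.pp_truth <- function(x, ...) {
  cat(sprintf("<pp_truth> %d neutrophil(s), %d phagosome(s), %d pulsing, %d leaky\n",
              nrow(x$neutrophils), nrow(x$phagosomes),
              sum(x$phagosomes$pulsing), sum(x$phagosomes$leaky)))
  invisible(x)
}

rtrunc <- function(draw, lo, hi) {
  for (i in 1:10000) {
    x <- draw()
    if (x >= lo && x <= hi) return(x)
  }
  abort("truncated draw failed to land in its support", class = "pp_config_error")
}

# ---- event scheduling -------------------------------------------------------

schedule_fov <- function(config, fov) {
  dt_min <- config$frame_interval_s / 60
  nf <- config$n_frames

  n_ph <- if (!is.null(config$phagosomes_fixed)) {
    as.integer(config$phagosomes_fixed)
  } else {
    rtrunc(function() rgeom(1, 1 / config$phagosome_mean) + 1L,
           config$phagosome_range[1], config$phagosome_range[2])
  }

  geom <- place_phagosomes(config, n_ph, fov)

  lp <- lognormal_params(config$latency_mean_min, config$latency_sd_min)
  rise <- config$pulse_rise_frames

  ph <- purrr::map(seq_len(n_ph), function(i) {
    engulf <- sample(seq(config$engulf_window_frames[1],
                         config$engulf_window_frames[2]), 1)
    pulsing <- runif(1) < config$p_pulse
    leaky <- runif(1) < config$p_leak
    onsets <- integer(0); peaks <- integer(0)
    open_iv <- matrix(integer(0), ncol = 2)
    pore_angles <- numeric(0); outcomes <- character(0)
    latency <- NA_real_
    if (pulsing) {
      n_want <- if (!is.null(config$pulse_count_fixed)) {
        as.integer(config$pulse_count_fixed)
      } else {
        rtrunc(function() 1L + rpois(1, config$pulse_count_mean - 1),
               config$pulse_count_range[1], config$pulse_count_range[2])
      }
      lat_draw <- max(rlnorm(1, lp$meanlog, lp$sdlog), config$latency_floor_min)
      o <- engulf + max(round(lat_draw / dt_min), 1)
      while (length(onsets) < n_want && (o + rise) <= nf - 1) {
        onsets <- c(onsets, as.integer(o))
        gap <- max(round(rexp(1, 1 / config$pulse_gap_mean_min) / dt_min),
                   config$pulse_min_gap_frames)
        o <- o + gap
      }
      peaks <- onsets + rise
      if (length(onsets) > 0) {
        latency <- (onsets[1] - engulf) * dt_min
        for (j in seq_along(onsets)) {
          if (runif(1) < config$p_open) {
            open_iv <- rbind(open_iv,
                             c(onsets[j],
                               min(onsets[j] + config$open_interval_frames - 1L, nf)))
            pore_angles <- c(pore_angles, runif(1, 0, 2 * pi))
            outcomes <- c(outcomes,
                          sample(c("recaptured", "released", "transferred"),
                                 1, prob = c(29, 1, 1) / 31))
          }
        }
      } else {
        pulsing <- FALSE  # nothing fit within the movie
      }
    }
    if (leaky) {
      # unsealed phagosome: open for its whole observed lifetime
      open_iv <- rbind(open_iv, c(engulf, nf))
      pore_angles <- c(pore_angles, runif(1, 0, 2 * pi))
    }
    tibble(
      fov = fov, neutrophil = fov, phagosome = i,
      x_um = geom$centers[i, 1], y_um = geom$centers[i, 2],
      z_um = geom$centers[i, 3],
      radius_um = config$phagosome_radius_um,
      engulf_frame = engulf, pulsing = pulsing,
      n_pulses = length(onsets),
      pulse_onsets = list(onsets), pulse_peaks = list(peaks),
      latency_min = latency,
      open_intervals = list(open_iv), pore_angles = list(pore_angles),
      outcomes = list(outcomes),
      leaky = leaky, dye_positive = FALSE
    )
  })
  phagosomes <- dplyr::bind_rows(ph)

  drift_dir <- if (config$drift_px_per_frame > 0) runif(1, 0, 2 * pi) else 0
  phagosomes$drift_dx_px <- config$drift_px_per_frame * cos(drift_dir)
  phagosomes$drift_dy_px <- config$drift_px_per_frame * sin(drift_dir)

  neutrophil <- tibble(
    fov = fov, neutrophil = fov,
    n_bacteria = n_ph,  # one bacterium per phagosome
    n_phagosomes = n_ph,
    cell_x_um = geom$cell_center[1], cell_y_um = geom$cell_center[2],
    cell_z_um = geom$cell_center[3], cell_radius_um = geom$r_cell
  )

  list(truth = list(phagosomes = phagosomes, neutrophils = neutrophil),
       geom = geom)
}

place_phagosomes <- function(config, n_ph, fov) {
  vs <- config$voxel_size
  fov_um <- as.numeric(config$shape) * as.numeric(vs[c("x", "y", "z")])
  r_ph <- config$phagosome_radius_um
  s <- config$min_separation_um
  cell_center <- fov_um / 2
  r_cell_max <- min(fov_um[1], fov_um[2]) / 2 - 0.5
  r_cell <- min(max(3.5, r_ph + 0.5 + (s / 2) * sqrt(n_ph / 0.4)), r_cell_max)
  z_lim <- fov_um[3] / 2 - r_ph - 2 * config$shell_sigma_um

  repeat {
    r_place <- r_cell - r_ph - 0.2
    centers <- matrix(NA_real_, n_ph, 3)
    ok <- TRUE
    for (i in seq_len(n_ph)) {
      placed <- FALSE
      for (try in 1:4000) {
        # uniform in the placement sphere, z clamped to the axial field
        p <- runif(3, -1, 1) * r_place
        if (sum(p^2) > r_place^2) next
        if (abs(p[3]) > z_lim) next
        if (i > 1) {
          dxy <- sqrt((centers[seq_len(i - 1), 1] - (cell_center[1] + p[1]))^2 +
                        (centers[seq_len(i - 1), 2] - (cell_center[2] + p[2]))^2)
          if (any(dxy < s)) next
        }
        centers[i, ] <- cell_center + p
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) break
    if (r_cell >= r_cell_max) {
      abort(sprintf(
        "placement of phagosome %d of neutrophil %d exceeds image bounds",
        which(is.na(centers[, 1]))[1], fov), class = "pp_generation_error")
    }
    r_cell <- min(r_cell + 0.4, r_cell_max)
  }
  list(centers = centers, cell_center = cell_center, r_cell = r_cell)
}

# ---- intensity schedules ----------------------------------------------------

# reporter amplitude per frame: closure surge + scheduled pulses
reporter_amplitude <- function(config, engulf, onsets, n_frames) {
  dt <- config$frame_interval_s
  rise <- config$pulse_rise_frames
  t <- seq_len(n_frames)
  amp <- numeric(n_frames)
  peak0 <- engulf + rise
  ramp <- t >= engulf & t < peak0
  amp[ramp] <- config$surge_amplitude * (t[ramp] - engulf + 1) / (rise + 1)
  dec <- t >= peak0
  amp[dec] <- config$surge_amplitude *
    (config$fade_plateau + (1 - config$fade_plateau) *
       exp(-(t[dec] - peak0) * dt / config$fade_tau_s))
  for (o in onsets) {
    pk <- o + rise
    a <- config$pulse_amplitude * config$surge_amplitude
    ramp <- t >= o & t < pk
    amp[ramp] <- amp[ramp] + a * (t[ramp] - o + 1) / (rise + 1)
    dec <- t >= pk
    amp[dec] <- amp[dec] + a * exp(-(t[dec] - pk) * dt / config$pulse_tau_s)
  }
  amp
}

# prey (pH reporter) brightness factor per frame
prey_brightness <- function(config, engulf, open_mask, pulsing, leaky, n_frames) {
  pm <- config$ph_map
  dt_min <- config$frame_interval_s / 60
  t_min <- (seq_len(n_frames) - engulf) * dt_min
  b <- rep(pm$pre, n_frames)
  after <- t_min >= 0
  if (pulsing || leaky) {
    b[after] <- pm$pulsing
  } else {
    dip <- pmin(pmax((t_min - pm$dip_start_min) /
                       (pm$dip_full_min - pm$dip_start_min), 0), 1)
    rec <- pmin(pmax((t_min - pm$recover_start_min) /
                       (pm$recover_full_min - pm$recover_start_min), 0), 1)
    lvl <- pm$pre + dip * (pm$alkaline - pm$pre) +
      rec * (pm$recovered - pm$alkaline)
    b[after] <- lvl[after]
  }
  b[open_mask] <- pm$open
  b
}

open_state <- function(open_iv, pore_angles, n_frames) {
  mask <- logical(n_frames)
  angle <- rep(NA_real_, n_frames)
  if (nrow(open_iv) > 0) {
    for (j in seq_len(nrow(open_iv))) {
      idx <- seq(open_iv[j, 1], min(open_iv[j, 2], n_frames))
      mask[idx] <- TRUE
      angle[idx] <- pore_angles[j]
    }
  }
  list(mask = mask, angle = angle)
}

# ---- voxel rendering --------------------------------------------------------

# sparse profile of one object: linear 3-D indices, values, xy azimuth
sphere_profile <- function(center_um, shape, vs, radius, sigma, solid,
                           z_scale = 1) {
  ext <- radius + 4 * sigma
  ext_z <- ext / z_scale
  yr <- which(abs((seq_len(shape["y"]) - 1) * vs["y"] - center_um[2]) <= ext)
  xr <- which(abs((seq_len(shape["x"]) - 1) * vs["x"] - center_um[1]) <= ext)
  zr <- which(abs((seq_len(shape["z"]) - 1) * vs["z"] - center_um[3]) <= ext_z)
  if (!length(yr) || !length(xr) || !length(zr)) {
    return(list(idx = integer(0), val = numeric(0), angle = numeric(0)))
  }
  dy <- (yr - 1) * vs["y"] - center_um[2]
  dx <- (xr - 1) * vs["x"] - center_um[1]
  dz <- ((zr - 1) * vs["z"] - center_um[3]) * z_scale
  ny <- length(yr); nx <- length(xr); nz <- length(zr)
  d2 <- outer(outer(dy^2, dx^2, "+"), dz^2, "+")
  d <- sqrt(d2)
  val <- if (solid) {
    ifelse(d <= radius, 1, exp(-(d - radius)^2 / (2 * sigma^2)))
  } else {
    exp(-(d - radius)^2 / (2 * sigma^2))
  }
  ang2d <- atan2(matrix(dy, ny, nx), matrix(dx, ny, nx, byrow = TRUE)) %% (2 * pi)
  angle <- array(ang2d, c(ny, nx, nz))
  iy <- rep(yr, times = nx * nz)
  ix <- rep(rep(xr, each = ny), times = nz)
  iz <- rep(zr, each = ny * nx)
  idx <- iy + (ix - 1L) * shape["y"] + (iz - 1L) * shape["y"] * shape["x"]
  keep <- val > 1e-4
  list(idx = as.integer(idx[keep]), val = as.numeric(val)[keep],
       angle = as.numeric(angle)[keep])
}

render_fov <- function(config, sched, fov) {
  shp <- c(y = unname(config$shape["y"]), x = unname(config$shape["x"]),
           z = unname(config$shape["z"]))
  shape <- c(x = unname(config$shape["x"]), y = unname(config$shape["y"]),
             z = unname(config$shape["z"]))
  vs <- config$voxel_size
  nf <- config$n_frames
  chans <- config$channels
  nc <- length(chans)
  vol_n <- prod(shape)
  arr <- array(config$background,
               c(shape[["y"]], shape[["x"]], shape[["z"]], nc, nf))

  geom <- sched$geom
  ph <- sched$truth$phagosomes
  rep_ch <- match("reporter", chans)
  prey_ch <- match("prey", chans)
  drift <- config$drift_px_per_frame > 0

  # neutrophil cytoplasm on the reporter channel
  if (!is.na(rep_ch) && !drift) {
    cell_idx <- which(cell_mask_volume(geom$cell_center, geom$r_cell, shape, vs))
    for (t in seq_len(nf)) {
      off <- ((t - 1L) * nc + (rep_ch - 1L)) * vol_n
      arr[off + cell_idx] <- arr[off + cell_idx] + config$cell_intensity
    }
  }

  pore_halfwidth <- config$pore_angle_deg / 180 * pi / 2
  zsc <- config$shell_sigma_um / max(config$shell_sigma_um, config$z_psf_um)

  per_ph <- purrr::map(seq_len(nrow(ph)), function(i) {
    r <- ph[i, ]
    os <- open_state(r$open_intervals[[1]], r$pore_angles[[1]], nf)
    list(
      center = c(r$x_um, r$y_um, r$z_um),
      amp = reporter_amplitude(config, r$engulf_frame, r$pulse_onsets[[1]], nf),
      brightness = prey_brightness(config, r$engulf_frame, os$mask,
                                   r$pulsing, r$leaky, nf),
      engulf = r$engulf_frame, open = os,
      drift_v = c(r$drift_dx_px * vs["x"], r$drift_dy_px * vs["y"])
    )
  })

  for (i in seq_along(per_ph)) {
    p <- per_ph[[i]]
    shell <- NULL; prey <- NULL
    if (!drift) {
      shell <- sphere_profile(p$center, shape, vs, config$phagosome_radius_um,
                              config$shell_sigma_um, solid = FALSE,
                              z_scale = zsc)
      prey <- sphere_profile(p$center, shape, vs, config$prey_radius_um,
                             config$shell_sigma_um, solid = TRUE,
                             z_scale = zsc)
    }
    for (t in seq_len(nf)) {
      if (t < p$engulf) next
      if (drift) {
        ctr <- p$center + c(p$drift_v * (t - 1), 0)
        shell <- sphere_profile(ctr, shape, vs, config$phagosome_radius_um,
                                config$shell_sigma_um, solid = FALSE,
                                z_scale = zsc)
        prey <- sphere_profile(ctr, shape, vs, config$prey_radius_um,
                               config$shell_sigma_um, solid = TRUE,
                               z_scale = zsc)
      }
      if (!is.na(rep_ch) && p$amp[t] > 1e-8 && length(shell$idx)) {
        val <- shell$val
        if (p$open$mask[t]) {
          # azimuthal pore: sector of the shell at background
          da <- (shell$angle - p$open$angle[t] + pi) %% (2 * pi) - pi
          val <- val * as.numeric(abs(da) > pore_halfwidth)
        }
        off <- ((t - 1L) * nc + (rep_ch - 1L)) * vol_n
        arr[off + shell$idx] <- arr[off + shell$idx] + p$amp[t] * val
      }
      if (!is.na(prey_ch) && length(prey$idx)) {
        off <- ((t - 1L) * nc + (prey_ch - 1L)) * vol_n
        arr[off + prey$idx] <- arr[off + prey$idx] +
          config$prey_amplitude * p$brightness[t] * prey$val
      }
    }
  }

  if (drift && !is.na(rep_ch)) {
    for (t in seq_len(nf)) {
      ctr <- geom$cell_center + c(per_ph[[1]]$drift_v * (t - 1), 0)
      cell <- cell_mask_volume(ctr, geom$r_cell, shape, vs)
      arr[, , , rep_ch, t] <- arr[, , , rep_ch, t] +
        as.numeric(cell) * config$cell_intensity
    }
  }

  arr <- add_camera_noise(arr, config, fov_seed(config$seed, fov, 2L))

  new_movie(arr, chans, vs, config$frame_interval_s, fov = fov)
}

cell_mask_volume <- function(center_um, r_cell, shape, vs) {
  dy2 <- ((seq_len(shape["y"]) - 1) * vs["y"] - center_um[2])^2
  dx2 <- ((seq_len(shape["x"]) - 1) * vs["x"] - center_um[1])^2
  dz2 <- ((seq_len(shape["z"]) - 1) * vs["z"] - center_um[3])^2
  outer(outer(dy2, dx2, "+"), dz2, "+") <= r_cell^2
}

add_camera_noise <- function(arr, config, seed) {
  read_sd <- if (is.finite(config$snr)) config$surge_amplitude / config$snr else 0
  if (read_sd == 0 && config$shot_factor == 0) return(arr)
  with_seed(seed, {
    z <- rnorm(length(arr))
    if (config$shot_factor > 0) {
      arr + z * sqrt(read_sd^2 + config$shot_factor * pmax(arr, 0))
    } else {
      arr + z * read_sd
    }
  })
}

# ---- dye channel ------------------------------------------------------------

#' Add an extracellular-dye channel to a simulated movie
#'
#' Emulates adding a membrane-impermeable fluid-phase dye to the medium while
#' imaging: extracellular voxels gain dye intensity from `dye_add_frame`
#' onward, and the interiors of leaky (unsealed) phagosomes accumulate dye,
#' but only during/after an open interval at or after the addition frame.
#'
#' @param movie a `pp_movie` from [simulate_movie()] with reporter and prey
#'   channels.
#' @param truth the matching `pp_truth` log.
#' @param dye_add_frame 1-based frame at which dye is added.
#' @return A `pp_movie` with an appended `"dye"` channel. The updated
#'   per-phagosome dye-positive flags are available via
#'   [dye_positive_truth()].
#' @export
add_dye_channel <- function(movie, truth, dye_add_frame) {
  stopifnot(inherits(movie, "pp_movie"), inherits(truth, "pp_truth"))
  if (!all(c("reporter", "prey") %in% movie$channels)) {
    abort("movie must carry reporter and prey channels before dye addition",
          class = "pp_format_error")
  }
  if ("dye" %in% movie$channels) {
    abort("movie already has a dye channel", class = "pp_format_error")
  }
  nf <- n_frames(movie)
  if (dye_add_frame < 1 || dye_add_frame > nf) {
    abort(sprintf("dye_add_frame %d outside movie duration 1..%d",
                  dye_add_frame, nf), class = "pp_index_error")
  }
  config <- truth$config
  d <- unname(dim(movie$data))
  shape <- c(x = d[2], y = d[1], z = d[3])
  vs <- movie$voxel_size
  fov <- movie$fov
  nb <- truth$neutrophils[truth$neutrophils$fov == fov, ]
  ph <- truth$phagosomes[truth$phagosomes$fov == fov, ]

  dye <- array(config$background, c(d[1], d[2], d[3], 1, nf))
  extra <- !cell_mask_volume(
    c(nb$cell_x_um, nb$cell_y_um, nb$cell_z_um),
    nb$cell_radius_um + 0.3, shape, vs)
  for (t in seq(dye_add_frame, nf)) {
    dye[, , , 1, t] <- dye[, , , 1, t] + as.numeric(extra) * config$dye_amplitude
  }
  vol_n <- prod(shape)
  for (i in seq_len(nrow(ph))) {
    r <- ph[i, ]
    iv <- r$open_intervals[[1]]
    if (!r$leaky || nrow(iv) == 0) next
    starts <- iv[iv[, 2] >= dye_add_frame, 1, drop = TRUE]
    if (!length(starts)) next
    t0 <- max(dye_add_frame, min(starts))
    interior <- sphere_profile(
      c(r$x_um, r$y_um, r$z_um), shape, vs,
      r$radius_um, config$shell_sigma_um / 2, solid = TRUE,
      z_scale = config$shell_sigma_um /
        max(config$shell_sigma_um, config$z_psf_um))
    for (t in seq(t0, nf)) {
      fill <- config$dye_amplitude *
        (1 - exp(-(t - t0 + 1) / config$dye_tau_frames))
      off <- (t - 1L) * vol_n
      dye[off + interior$idx] <- dye[off + interior$idx] + fill * interior$val
    }
  }
  dye <- add_camera_noise(dye, config, fov_seed(config$seed, fov, 3L))

  out <- array(0, c(d[1], d[2], d[3], d[4] + 1, nf))
  out[, , , seq_len(d[4]), ] <- movie$data
  out[, , , d[4] + 1, ] <- dye
  new_movie(out, c(movie$channels, "dye"), vs, movie$frame_interval_s,
            offset_min = movie$offset_min, fov = fov)
}

#' Ground-truth dye-positive flags after dye addition
#'
#' A phagosome is dye-positive when it is leaky and has an open interval at or
#' after the dye-addition frame.
#'
#' @param truth a `pp_truth` log.
#' @param dye_add_frame 1-based frame at which dye was added.
#' @return The `pp_truth` with its `dye_positive` column updated.
#' @export
dye_positive_truth <- function(truth, dye_add_frame) {
  truth$phagosomes$dye_positive <- purrr::map2_lgl(
    truth$phagosomes$leaky, truth$phagosomes$open_intervals,
    function(lk, iv) lk && nrow(iv) > 0 && any(iv[, 2] >= dye_add_frame))
  truth
}

#' Ground-truth tracks for simulated phagosomes
#'
#' Converts the generator log into a track table (one row per phagosome per
#' frame from engulfment to the end of the movie), bypassing segmentation and
#' linking. Useful for validating the profiling and pulse-calling stages in
#' isolation.
#'
#' @param truth a `pp_truth` log.
#' @return A `pp_tracks` tibble (see [link_detections()]).
#' @export
truth_tracks <- function(truth) {
  cfg <- truth$config
  vs <- cfg$voxel_size
  rows <- purrr::map(seq_len(nrow(truth$phagosomes)), function(i) {
    r <- truth$phagosomes[i, ]
    frames <- seq(r$engulf_frame, cfg$n_frames)
    tibble(
      track_id = sprintf("fov%03d_ph%03d", r$fov, r$phagosome),
      fov = r$fov, frame = frames,
      x_um = r$x_um + r$drift_dx_px * vs["x"] * (frames - 1),
      y_um = r$y_um + r$drift_dy_px * vs["y"] * (frames - 1),
      z_um = r$z_um,
      gap = FALSE, source = "truth"
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pp_tracks", class(out))
  out
}
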