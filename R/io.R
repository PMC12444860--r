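#' Write a movie as multi-page TIFF with OME-style sidecar metadata
#'
#' Voxel data are stored as 32-bit float pages in TCZYX page order, min-max
#' scaled into `[0, 1]` (a requirement of TIFF float storage here); the
#' affine scale, axis sizes, channel names, physical voxel sizes and frame
#' interval are recorded in an OME-style XML sidecar (`<basename>.ome.xml`)
#' written next to the TIFF, so reading the pair back restores calibrated
#' intensities to 32-bit float precision.
#'
#' @param movie a `pp_movie`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "pp_movie"))
  d <- dim(movie$data)
  lo <- min(movie$data); hi <- max(movie$data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- vector("list", d[5] * d[4] * d[3])
  p <- 0L
  for (t in seq_len(d[5])) for (ch in seq_len(d[4])) for (z in seq_len(d[3])) {
    p <- p + 1L
    pages[[p]] <- (movie$data[, , z, ch, t] - lo) / scale
  }
  atomic_write(path, function(tmp) {
    tiff::writeTIFF(pages, tmp, bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
  })
  xml <- xml2::xml_new_root("OME")
  img <- xml2::xml_add_child(xml, "Image", ID = "Image:0")
  px <- xml2::xml_add_child(
    img, "Pixels", DimensionOrder = "XYZCT", Type = "float",
    SizeX = d[2], SizeY = d[1], SizeZ = d[3], SizeC = d[4], SizeT = d[5],
    PhysicalSizeX = movie$voxel_size[["x"]],
    PhysicalSizeY = movie$voxel_size[["y"]],
    PhysicalSizeZ = movie$voxel_size[["z"]], PhysicalSizeUnit = "um",
    TimeIncrement = movie$frame_interval_s, TimeIncrementUnit = "s")
  for (i in seq_along(movie$channels)) {
    xml2::xml_add_child(px, "Channel", ID = sprintf("Channel:0:%d", i - 1),
                        Name = movie$channels[i])
  }
  xml2::xml_add_child(xml, "ScaleOffset", Offset = lo, Scale = scale,
                      AcquisitionOffsetMin = movie$offset_min)
  atomic_write(sidecar_path(path), function(tmp) {
    xml2::write_xml(xml, tmp)
  })
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".ome.xml")

#' Read a movie from TIFF (+ OME-style sidecar) or with explicit calibration
#'
#' Without the sidecar the file's axes and physical calibration are unknown;
#' they must then be supplied explicitly (`voxel_size`, `frame_interval_s`,
#' `n_z`, `channels`) — voxel units are never assumed silently.
#'
#' @param path TIFF path.
#' @param voxel_size,frame_interval_s,n_z,channels calibration overrides used
#'   when no sidecar is present.
#' @return A `pp_movie`.
#' @export
read_movie <- function(path, voxel_size = NULL, frame_interval_s = NULL,
                       n_z = NULL, channels = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("movie file not found: %s", path), class = "pp_io_error")
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) {
                      abort(sprintf("truncated or unreadable TIFF: %s",
                                    conditionMessage(e)), class = "pp_io_error")
                    })
  if (is.matrix(pages)) pages <- list(pages)
  sc <- sidecar_path(path)
  lo <- 0; scale <- 1; offset_min <- 0
  if (file.exists(sc)) {
    xml <- xml2::read_xml(sc)
    px <- xml2::xml_find_first(xml, ".//Pixels")
    if (inherits(px, "xml_missing")) {
      abort("sidecar lacks a Pixels element", class = "pp_parse_error")
    }
    gi <- function(a) as.integer(xml2::xml_attr(px, a))
    gn <- function(a) as.numeric(xml2::xml_attr(px, a))
    nx <- gi("SizeX"); ny <- gi("SizeY"); n_z <- gi("SizeZ")
    nc <- gi("SizeC"); nt <- gi("SizeT")
    voxel_size <- c(x = gn("PhysicalSizeX"), y = gn("PhysicalSizeY"),
                    z = gn("PhysicalSizeZ"))
    frame_interval_s <- gn("TimeIncrement")
    channels <- xml2::xml_attr(xml2::xml_find_all(px, ".//Channel"), "Name")
    so <- xml2::xml_find_first(xml, ".//ScaleOffset")
    if (!inherits(so, "xml_missing")) {
      lo <- as.numeric(xml2::xml_attr(so, "Offset"))
      scale <- as.numeric(xml2::xml_attr(so, "Scale"))
      offset_min <- as.numeric(xml2::xml_attr(so, "AcquisitionOffsetMin"))
    }
    if (any(is.na(voxel_size)) || is.na(frame_interval_s)) {
      abort("sidecar missing physical calibration (PhysicalSizeX/Y/Z, TimeIncrement)",
            class = "pp_calibration_error")
    }
  } else {
    if (is.null(voxel_size) || is.null(frame_interval_s) ||
        is.null(n_z) || is.null(channels)) {
      abort(paste("no OME sidecar found and no calibration override supplied;",
                  "refusing to assume pixel units"),
            class = "pp_calibration_error")
    }
    nc <- length(channels)
    nt <- length(pages) / (nc * n_z)
    if (nt != round(nt)) {
      abort(sprintf(
        "ambiguous axes: %d pages do not factor into %d channel(s) x %d slice(s)",
        length(pages), nc, n_z), class = "pp_format_error")
    }
    nt <- as.integer(nt)
    ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  }
  if (length(pages) != nt * nc * n_z) {
    abort(sprintf("truncated TIFF: expected %d pages (T%d x C%d x Z%d), found %d",
                  nt * nc * n_z, nt, nc, n_z, length(pages)),
          class = "pp_io_error")
  }
  arr <- array(0, c(ny, nx, n_z, nc, nt))
  p <- 0L
  for (t in seq_len(nt)) for (ch in seq_len(nc)) for (z in seq_len(n_z)) {
    p <- p + 1L
    arr[, , z, ch, t] <- pages[[p]] * scale + lo
  }
  new_movie(arr, channels, voxel_size, frame_interval_s, offset_min = offset_min)
}

# ---- pipeline configuration -------------------------------------------------

pipeline_defaults <- function() {
  list(
    segmentation = list(connectivity = 26, min_size = 5,
                        reporter_per_frame = FALSE,
                        levels = NULL),  # NULL = auto (multi-level Otsu)
    tracking = list(channel = "prey", max_displacement = 2, max_gap = 2,
                    min_track_len = 20),
    ring = list(radius = 3, half_width = 1.5, sectors = 21,
                mode = "annulus", plane = "nearest"),
    lowpass_window = 5,
    pulse = list(prominence_min = 0.2, fade_threshold = 0.4,
                 min_separation = 3),
    out_dir = NULL,
    log_level = "info"
  )
}

#' Build a validated pipeline configuration
#'
#' @param sim a [sim_config()] describing the cohort to simulate, or `NULL`
#'   when analysing movies from disk.
#' @param movie_paths character vector of TIFF paths (used when `sim` is
#'   `NULL`).
#' @param ... overrides of the default stage parameter blocks
#'   (`segmentation`, `tracking`, `ring`, `lowpass_window`, `pulse`,
#'   `out_dir`, `log_level`); unknown keys are rejected.
#' @return A `pp_pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, movie_paths = NULL, ...) {
  cfg <- pipeline_defaults()
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) {
    abort(sprintf("unknown pipeline configuration key(s): %s",
                  paste(bad, collapse = ", ")), class = "pp_config_error")
  }
  for (k in names(dots)) {
    if (is.list(cfg[[k]]) && is.list(dots[[k]])) {
      badk <- setdiff(names(dots[[k]]), names(cfg[[k]]))
      if (length(badk)) {
        abort(sprintf("unknown key(s) in '%s' block: %s", k,
                      paste(badk, collapse = ", ")), class = "pp_config_error")
      }
      cfg[[k]][names(dots[[k]])] <- dots[[k]]
    } else {
      cfg[[k]] <- dots[[k]]
    }
  }
  if (is.null(sim) && is.null(movie_paths)) {
    abort("either `sim` or `movie_paths` must be given", class = "pp_config_error")
  }
  cfg$sim <- sim
  cfg$movie_paths <- movie_paths
  # validate nested specs early
  do.call(ring_spec, cfg$ring)
  do.call(pulse_params, cfg$pulse)
  structure(cfg, class = "pp_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys anywhere in the file are rejected by name.
#'
#' @param path YAML file.
#' @return A `pp_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known_top <- c("sim", "movie_paths", "segmentation", "tracking", "ring",
                 "lowpass_window", "pulse", "out_dir", "log_level")
  bad <- setdiff(names(y), known_top)
  if (length(bad)) {
    abort(sprintf("unknown configuration key(s): %s", paste(bad, collapse = ", ")),
          class = "pp_config_error")
  }
  sim <- NULL
  if (!is.null(y$sim)) {
    bad <- setdiff(names(y$sim), names(formals(sim_config)))
    if (length(bad)) {
      abort(sprintf("unknown key(s) in 'sim' block: %s",
                    paste(bad, collapse = ", ")), class = "pp_config_error")
    }
    args <- y$sim
    for (k in c("shape", "voxel_size")) {
      if (!is.null(args[[k]])) args[[k]] <- unlist(args[[k]])
    }
    for (k in c("phagosome_range", "pulse_count_range", "engulf_window_frames")) {
      if (!is.null(args[[k]])) args[[k]] <- unlist(args[[k]])
    }
    if (!is.null(args$channels)) args$channels <- unlist(args$channels)
    sim <- do.call(sim_config, args)
  }
  extra <- y[setdiff(names(y), c("sim", "movie_paths"))]
  do.call(pipeline_config,
          c(list(sim = sim, movie_paths = y$movie_paths), extra))
}

#' The packaged cohort-defaults pipeline configuration
#'
#' The reference conditions the package is calibrated on: per-phagosome
#' pulse probability 12.4%, latency 10.5 +/- 12.49 min, dye-leak probability
#' 20.1%, 1-25 phagosomes per neutrophil, SNR 8. The ring radius (3 px)
#' matches the rendered 1 um membrane radius at the default 0.33 um pixels.
#'
#' @param ... overrides passed to the `sim` block (e.g. `n_neutrophils`,
#'   `seed`).
#' @return A `pp_pipeline_config`.
#' @export
cohort_defaults <- function(...) {
  path <- system.file("extdata", "cohort_defaults.yaml", package = "phagopulse")
  cfg <- read_pipeline_config(path)
  dots <- list(...)
  if (length(dots)) {
    sim_args <- cfg$sim
    class(sim_args) <- NULL
    sim_args[names(dots)] <- dots
    cfg$sim <- do.call(sim_config, sim_args)
  }
  cfg
}

pp_log <- function(cfg_level, level, fmt, ...) {
  ranks <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (ranks[[level]] >= ranks[[cfg_level %||% "info"]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
}

# ---- the orchestrator -------------------------------------------------------

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate (optional) -> segment -> track ->
#' profile -> call -> stats — streaming one field of view at a time, writes
#' every stage's table under `out_dir`, and records a run manifest (config
#' hash, seed, package version). Reruns with the same configuration
#' reproduce all outputs bit-identically.
#'
#' @param config a [pipeline_config()].
#' @return A `pp_pipeline_result` list: `calls`, `tracks`, `summary`
#'   ([pulsing_summary()] object), `burden`, `aligned`, `object_tables`,
#'   `out_dir`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pp_pipeline_config"))
  out_dir <- config$out_dir %||% file.path(tempdir(), "phagopulse_run")
  dir.create(file.path(out_dir, "kymographs"), recursive = TRUE,
             showWarnings = FALSE)
  lvl <- config$log_level
  manifest <- list(
    package = "phagopulse",
    version = as.character(utils::packageVersion("phagopulse")),
    config_hash = rlang::hash(unclass(config)),
    seed = if (!is.null(config$sim)) config$sim$seed else NA,
    status = "running", failed_stage = NA
  )
  write_manifest <- function() {
    atomic_write(file.path(out_dir, "manifest.json"), function(tmp) {
      jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, null = "null")
    })
  }
  write_manifest()

  n_fov <- if (!is.null(config$sim)) config$sim$n_neutrophils else length(config$movie_paths)
  spec <- do.call(ring_spec, config$ring)
  par <- do.call(pulse_params, config$pulse)
  seg <- config$segmentation
  trk <- config$tracking

  all_calls <- list(); all_tracks <- list(); all_series <- list()
  all_objects <- list()
  stage <- "simulate"
  res <- tryCatch({
    for (fov in seq_len(n_fov)) {
      stage <- "simulate"
      if (!is.null(config$sim)) {
        sim <- simulate_movie(config$sim, fov)
        movie <- sim$movie
        truth_fov <- sim$truth
      } else {
        movie <- read_movie(config$movie_paths[fov])
        movie$fov <- fov
        truth_fov <- NULL
      }
      pp_log(lvl, "info", "FOV %d/%d: %d frames", fov, n_fov, n_frames(movie))

      stage <- "segment"
      nf <- n_frames(movie)
      ref_frame <- nf  # all objects engulfed by the end of the movie
      rep_sm <- smooth_box3(movie_frame(movie, ref_frame, "reporter"))
      prey_sm <- smooth_box3(movie_frame(movie, ref_frame, trk$channel))
      levels <- if (is.null(seg$levels)) {
        auto_levels(rep_sm, prey_sm, robust = TRUE)
      } else {
        do.call(seg_levels, seg$levels)
      }
      rep_seg <- segment_reporter(rep_sm, levels, movie$voxel_size,
                                  seg$connectivity, seg$min_size, ref_frame)
      detections <- detect_centroids(
        movie, trk$channel,
        level = if (is.null(seg$levels)) NULL else levels$prey,
        connectivity = seg$connectivity, min_size = seg$min_size)
      vox_vol <- prod(movie$voxel_size)
      objects <- dplyr::bind_rows(
        dplyr::mutate(rep_seg$cell$table, what = "cell", fov = fov),
        dplyr::mutate(rep_seg$phagosome$table, what = "phagosome", fov = fov),
        dplyr::mutate(detections, what = "prey", fov = fov,
                      channel = trk$channel,
                      volume_um3 = .data$n_voxels * vox_vol))
      all_objects[[fov]] <- objects

      stage <- "track"
      tracks <- link_detections(detections, trk$max_displacement, trk$max_gap)
      if (nrow(tracks)) {
        tracks$track_id <- sprintf("fov%03d_%s", fov, tracks$track_id)
        tracks$fov <- fov
      }
      keep_ids <- tracks |>
        dplyr::count(.data$track_id) |>
        dplyr::filter(.data$n >= trk$min_track_len) |>
        dplyr::pull(.data$track_id)
      tracks_kept <- tracks[tracks$track_id %in% keep_ids, ]
      all_tracks[[fov]] <- tracks

      stage <- "profile"
      series <- purrr::map(keep_ids, function(id) {
        s <- build_kymograph(tracks_kept[tracks_kept$track_id == id, ],
                             movie, spec, channel = "reporter")
        normalize_tracks(lowpass(s, config$lowpass_window))
      })

      stage <- "call"
      calls <- if (length(series)) call_cohort(series, par) else NULL
      if (!is.null(calls)) {
        calls$neutrophil <- fov
        calls$fov <- fov
        calls$n_bacteria <- if (!is.null(truth_fov)) {
          truth_fov$neutrophils$n_bacteria[1]
        } else NA_integer_
        all_calls[[fov]] <- calls
      }
      all_series <- c(all_series, series)
    }

    stage <- "stats"
    calls <- dplyr::bind_rows(all_calls)
    class(calls) <- c("pp_calls", class(calls))
    tracks <- dplyr::bind_rows(all_tracks)
    summary <- pulsing_summary(calls)
    burden <- if (!anyNA(calls$n_bacteria) && nrow(summary$per_neutrophil) >= 3) {
      rec <- dplyr::distinct(calls, .data$neutrophil, .data$n_bacteria) |>
        dplyr::left_join(summary$per_neutrophil, by = "neutrophil")
      tryCatch(burden_correlation(rec), warning = function(w) NULL)
    } else NULL
    aligned <- align_and_average(all_series)

    stage <- "write"
    frame_dt <- if (!is.null(config$sim)) config$sim$frame_interval_s else NA_real_
    readr::write_csv(
      dplyr::mutate(tracks, t_seconds = (.data$frame - 1) * frame_dt,
                    .after = "frame"),
      file.path(out_dir, "tracks.csv"))
    readr::write_csv(dplyr::select(calls, -"pulses"),
                     file.path(out_dir, "calls.csv"))
    readr::write_csv(tidy(calls), file.path(out_dir, "pulses.csv"))
    readr::write_csv(dplyr::bind_rows(all_objects),
                     file.path(out_dir, "objects.csv"))
    readr::write_csv(aligned$summary, file.path(out_dir, "aligned_mean_sd.csv"))
    kymo_index <- purrr::map_chr(all_series, function(s) {
      f <- file.path(out_dir, "kymographs", paste0(s$track_id, ".csv"))
      readr::write_csv(as_tibble(s), f)
      f
    })
    atomic_write(file.path(out_dir, "summary.json"), function(tmp) {
      jsonlite::write_json(list(
        pulsing = as.list(summary$summary),
        per_neutrophil = summary$per_neutrophil,
        pulse_count_dist = summary$pulse_count_dist,
        burden = if (!is.null(burden)) as.list(burden) else NULL
      ), tmp, auto_unbox = TRUE, digits = NA, null = "null")
    })

    structure(list(calls = calls, tracks = tracks, summary = summary,
                   burden = burden, aligned = aligned,
                   object_tables = dplyr::bind_rows(all_objects),
                   series = all_series,
                   kymograph_index = kymo_index,
                   out_dir = out_dir, manifest = manifest),
              class = "pp_pipeline_result")
  }, error = function(e) {
    manifest$status <<- "failed"
    manifest$failed_stage <<- stage
    write_manifest()
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)), class = "pp_pipeline_error", parent = e)
  })
  manifest$status <- "ok"
  res$manifest <- manifest
  write_manifest()
  res
}

#' @export
print.pp_pipeline_result <- function(x, ...) {
  cat(sprintf("<pp_pipeline_result> %d track(s) across %d FOV(s); outputs in %s\n",
              length(unique(x$tracks$track_id)),
              length(unique(x$tracks$fov)), x$out_dir))
  print(x$summary)
  invisible(x)
}

#' Write a human-readable and machine-readable cohort report
#'
#' @param result a `pp_pipeline_result`.
#' @param path output path stem; writes `<path>.json` and `<path>.txt`.
#' @param fixture optional event tally tibble (see [read_event_tally()]);
#'   when present, computed tally percentages are echoed against it.
#' @return Invisibly, the report list.
#' @export
write_report <- function(result, path, fixture = NULL) {
  s <- result$summary$summary
  notices <- character(0)
  if (s$n_phagosomes == 0) notices <- c(notices, "zero phagosomes analysed")
  if (s$n_neutrophils == 0) notices <- c(notices, "zero-denominator: no neutrophils")
  fixture_cmp <- NULL
  if (!is.null(fixture)) {
    ts <- tally_statistics(fixture)
    fixture_cmp <- dplyr::mutate(
      ts, expected_pct = fixture$expected_pct %||% NA_real_,
      match = .data$pct == .data$expected_pct)
  }
  report <- list(
    summary = as.list(s),
    per_neutrophil = result$summary$per_neutrophil,
    pulse_count_dist = result$summary$pulse_count_dist,
    burden = if (!is.null(result$burden)) as.list(result$burden) else NULL,
    kymograph_index = result$kymograph_index,
    fixture_comparison = fixture_cmp,
    notices = notices
  )
  atomic_write(paste0(path, ".json"), function(tmp) {
    jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null")
  })
  atomic_write(paste0(path, ".txt"), function(tmp) {
    con <- file(tmp, "w"); on.exit(close(con))
    writeLines(c(
      "phagopulse cohort report",
      sprintf("neutrophils: %d; phagosomes: %d", s$n_neutrophils, s$n_phagosomes),
      sprintf("pulsing phagosomes per neutrophil: %.1f +/- %.1f %%",
              s$mean_pct_pulsing, s$sd_pct_pulsing),
      sprintf("neutrophils with >=1 pulsing phagosome: %.1f %%",
              s$pct_neutrophils_pulsing),
      if (is.finite(s$latency_mean_min %||% NA)) {
        sprintf("first-pulse latency: %.1f +/- %.1f min",
                s$latency_mean_min, s$latency_sd_min %||% 0)
      },
      if (length(notices)) paste("NOTICE:", notices)
    ), con)
  })
  invisible(report)
}
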