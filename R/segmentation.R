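#' 3D box smoothing
#'
#' Smooths a single-channel 3D volume with a 3x3x3 mean (box) kernel,
#' implemented as three separable running-mean passes. Borders are handled by
#' symmetric reflection, so a constant volume is a fixed point of the filter.
#'
#' @param volume numeric 3-D array.
#' @return Numeric array of the same shape.
#' @export
smooth_box3 <- function(volume) {
  if (length(dim(volume)) != 3L) {
    abort("smooth_box3() expects a 3-D volume", class = "pp_dim_error")
  }
  .box_smooth3_cpp(as.numeric(volume), as.integer(dim(volume)))
}

#' Multi-level Otsu thresholds
#'
#' Picks `n_classes - 1` intensity thresholds maximising the between-class
#' variance of a histogram of `x` (exhaustive search over bin boundaries).
#' Used for automatic level selection: three classes on the reporter channel
#' (background / cell / phagosome) and two on the prey channel.
#'
#' @param x numeric vector or array of intensities.
#' @param n_classes number of classes (2 or 3).
#' @param n_bins histogram resolution.
#' @return Numeric vector of `n_classes - 1` increasing thresholds.
#' @export
otsu_levels <- function(x, n_classes = 2, n_bins = 128) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) abort("cannot threshold a constant volume",
                            class = "pp_config_error")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(pmin(pmax(findInterval(x, breaks, all.inside = TRUE), 1),
                     n_bins), n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  total_w <- w[n_bins]; total_m <- m[n_bins]
  css <- function(i, j) {
    # between-class contribution of bins (i, j]
    wi <- w[j] - if (i > 0) w[i] else 0
    if (wi == 0) return(0)
    mi <- m[j] - if (i > 0) m[i] else 0
    mi^2 / wi
  }
  if (n_classes == 2) {
    best <- -Inf; bi <- 1
    for (i in seq_len(n_bins - 1)) {
      v <- css(0, i) + css(i, n_bins)
      if (v > best) { best <- v; bi <- i }
    }
    return(breaks[bi + 1])
  }
  if (n_classes != 3) abort("n_classes must be 2 or 3", class = "pp_config_error")
  best <- -Inf; bi <- c(1, 2)
  for (i in seq_len(n_bins - 2)) {
    a <- css(0, i)
    for (j in seq(i + 1, n_bins - 1)) {
      v <- a + css(i, j) + css(j, n_bins)
      if (v > best) { best <- v; bi <- c(i, j) }
    }
  }
  breaks[bi + 1]
}

#' Segmentation levels for the two-channel analysis
#'
#' Holds the intensity levels used for volumetric segmentation: a low level
#' for the whole neutrophil and a high level for the phagosome on the
#' reporter channel, and a single level for the bacteria on the prey channel.
#'
#' @param low,high reporter-channel levels (`high > low`).
#' @param prey prey-channel level.
#' @param method `"auto"` (multi-level Otsu) or `"fixed"`.
#' @return A `pp_seg_levels` list.
#' @export
seg_levels <- function(low, high, prey, method = c("fixed", "auto")) {
  method <- match.arg(method)
  if (!is.finite(low) || !is.finite(high) || high <= low) {
    abort("high level must exceed low level", class = "pp_config_error")
  }
  structure(list(low = low, high = high, prey = prey, method = method),
            class = "pp_seg_levels")
}

#' Automatic level selection from smoothed reference-frame volumes
#'
#' Default: 3-class multi-level Otsu on the reporter histogram gives the
#' (low, high) pair, a single Otsu gives the prey level. With
#' `robust = TRUE` (used by the pipeline, where background dominates the
#' volume and a global multi-level Otsu would split the background mode)
#' the levels are found hierarchically: low = Otsu of the whole volume,
#' high = Otsu of the supra-low intensities, prey = [detection_level()].
#'
#' @param reporter smoothed reporter-channel 3-D volume.
#' @param prey smoothed prey-channel 3-D volume (or `NULL`).
#' @param robust use the hierarchical rule for background-dominated volumes.
#' @return A [seg_levels()] object with `method = "auto"`.
#' @export
auto_levels <- function(reporter, prey = NULL, robust = FALSE) {
  if (robust) {
    low <- otsu_levels(reporter, n_classes = 2)
    hi_vals <- reporter[reporter > low]
    high <- if (length(hi_vals) > 30 && diff(range(hi_vals)) > 0) {
      max(otsu_levels(hi_vals, n_classes = 2), low * 1.001)
    } else low * 1.001
    pl <- if (!is.null(prey)) detection_level(prey) else NA_real_
    return(seg_levels(low, high, pl, method = "auto"))
  }
  lv <- otsu_levels(reporter, n_classes = 3)
  pl <- if (!is.null(prey)) otsu_levels(prey, n_classes = 2) else NA_real_
  seg_levels(lv[1], lv[2], pl, method = "auto")
}

new_label_volume <- function(labels, channel, frame, voxel_size, intensity) {
  tab <- label_table(labels, voxel_size, intensity, channel, frame)
  structure(list(labels = labels, channel = channel, frame = frame,
                 voxel_size = voxel_size, table = tab),
            class = "pp_labels")
}

#' @export
print.pp_labels <- function(x, ...) {
  cat(sprintf("<pp_labels> channel %s, frame %s: %d object(s)\n",
              x$channel, x$frame, nrow(x$table)))
  invisible(x)
}

label_table <- function(labels, voxel_size, intensity, channel, frame) {
  vox_vol <- prod(voxel_size)
  k <- max(labels)
  if (k == 0) {
    return(tibble(frame = integer(0), label = integer(0),
                  channel = character(0), n_voxels = integer(0),
                  volume_um3 = numeric(0), x_um = numeric(0),
                  y_um = numeric(0), z_um = numeric(0),
                  mean_intensity = numeric(0)))
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  d <- dim(labels)
  iy <- (idx - 1) %% d[1] + 1
  ix <- ((idx - 1) %/% d[1]) %% d[2] + 1
  iz <- (idx - 1) %/% (d[1] * d[2]) + 1
  n_vox <- tabulate(lab, k)
  tibble(
    frame = frame, label = seq_len(k), channel = channel,
    n_voxels = n_vox,
    volume_um3 = n_vox * vox_vol,
    x_um = as.numeric(tapply((ix - 1) * voxel_size["x"], lab, mean)),
    y_um = as.numeric(tapply((iy - 1) * voxel_size["y"], lab, mean)),
    z_um = as.numeric(tapply((iz - 1) * voxel_size["z"], lab, mean)),
    mean_intensity = as.numeric(tapply(intensity[idx], lab, mean))
  )
}

label_mask <- function(mask, connectivity, min_size) {
  lab <- .label3d_cpp(mask, as.integer(dim(mask)), as.integer(connectivity))
  if (min_size > 1 && max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], max(lab))
    keep <- which(sizes >= min_size)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  lab
}

#' Two-level reporter-channel segmentation
#'
#' Thresholds a smoothed reporter volume at a low level (whole neutrophil)
#' and a high level (phagosome) and labels the connected components of each
#' mask. Because the two masks come from nested thresholds of the same
#' volume, every phagosome voxel lies inside a cell component.
#'
#' @param frame smoothed single-channel 3-D volume (see [smooth_box3()]).
#' @param levels a [seg_levels()] object.
#' @param voxel_size named numeric `c(x=, y=, z=)` in micrometres.
#' @param connectivity 26 (default) or 6.
#' @param min_size minimum object size, voxels.
#' @param frame_index frame number recorded in the object table.
#' @return List with elements `cell` and `phagosome`, each a `pp_labels`
#'   object carrying the integer label volume and a per-object tibble
#'   (label, voxel count, volume in um^3, centroid in um, mean intensity).
#' @export
segment_reporter <- function(frame, levels, voxel_size,
                             connectivity = 26, min_size = 5,
                             frame_index = NA_integer_) {
  stopifnot(inherits(levels, "pp_seg_levels"))
  if (length(dim(frame)) != 3L) {
    abort("segment_reporter() expects a 3-D volume", class = "pp_dim_error")
  }
  cell_lab <- label_mask(frame > levels$low, connectivity, min_size)
  ph_lab <- label_mask(frame > levels$high, connectivity, min_size)
  list(
    cell = new_label_volume(cell_lab, "reporter", frame_index, voxel_size, frame),
    phagosome = new_label_volume(ph_lab, "reporter", frame_index, voxel_size, frame)
  )
}

#' Single-level prey-channel segmentation
#'
#' @param frame smoothed prey-channel 3-D volume.
#' @param level intensity threshold.
#' @inheritParams segment_reporter
#' @return A `pp_labels` object.
#' @export
segment_prey <- function(frame, level, voxel_size,
                         connectivity = 26, min_size = 5,
                         frame_index = NA_integer_) {
  if (length(dim(frame)) != 3L) {
    abort("segment_prey() expects a 3-D volume", class = "pp_dim_error")
  }
  lab <- label_mask(frame > level, connectivity, min_size)
  new_label_volume(lab, "prey", frame_index, voxel_size, frame)
}

#' Inside/outside bacterial volume ratio
#'
#' For each prey (bacterium) component, measures the volume lying inside
#' versus outside the cell mask. Inside and outside volumes always sum
#' exactly to the component volume. A component entirely inside the cell is
#' reported with an infinite ratio and flagged `fully_internal`.
#'
#' @param prey a `pp_labels` object for the prey channel.
#' @param cell a `pp_labels` object for the cell (low reporter level).
#' @return Tibble with one row per prey component: `label`, `inside_um3`,
#'   `outside_um3`, `total_um3`, `ratio`, `fully_internal`.
#' @export
inside_outside_ratio <- function(prey, cell) {
  stopifnot(inherits(prey, "pp_labels"), inherits(cell, "pp_labels"))
  if (!identical(dim(prey$labels), dim(cell$labels))) {
    abort("prey and cell label volumes must share geometry",
          class = "pp_shape_error")
  }
  vox_vol <- prod(prey$voxel_size)
  k <- max(prey$labels)
  if (k == 0) {
    return(tibble(label = integer(0), inside_um3 = numeric(0),
                  outside_um3 = numeric(0), total_um3 = numeric(0),
                  ratio = numeric(0), fully_internal = logical(0)))
  }
  idx <- which(prey$labels > 0)
  lab <- prey$labels[idx]
  inside <- cell$labels[idx] > 0
  n_in <- tabulate(lab[inside], k)
  n_tot <- tabulate(lab, k)
  n_out <- n_tot - n_in
  tibble(
    label = seq_len(k),
    inside_um3 = n_in * vox_vol,
    outside_um3 = n_out * vox_vol,
    total_um3 = n_tot * vox_vol,
    ratio = ifelse(n_out == 0, Inf, n_in / n_out),
    fully_internal = n_out == 0
  )
}
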