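#' Ring geometry specification
#'
#' Defines the ring used to extract membrane fluorescence around a tracked
#' phagosome centroid: all pixels within a ring of the given radius are
#' extracted, and their intensities are binned into angular sectors (21
#' directions by default) to show whether the signal is uniform around the
#' ring or higher on one side.
#'
#' "Within a ring of radius r" admits two readings; both are provided. The
#' default `annulus` mode takes pixels whose centre distance lies within
#' `half_width` of `radius`, capturing the membrane the reporter decorates;
#' `disc` mode takes all pixels up to `radius`.
#'
#' @param radius ring radius in pixels (default 6).
#' @param half_width annulus half-width in pixels (default 1.5; ignored in
#'   disc mode).
#' @param sectors number of angular sectors (default 21). Sector k covers
#'   angles `[2*pi*(k-1)/sectors, 2*pi*k/sectors)`, measured with the image
#'   y-axis pointing down.
#' @param mode `"annulus"` or `"disc"`.
#' @param plane plane selection rule for 3-D movies: `"nearest"` (z-slice
#'   nearest the centroid) or `"maxproj3"` (maximum projection of the three
#'   nearest slices, for low-SNR data).
#' @return A `pp_ring_spec` list.
#' @export
ring_spec <- function(radius = 6, half_width = 1.5, sectors = 21,
                      mode = c("annulus", "disc"),
                      plane = c("nearest", "maxproj3")) {
  mode <- match.arg(mode)
  plane <- match.arg(plane)
  if (radius <= 0) abort("ring radius must be > 0", class = "pp_config_error")
  if (sectors < 1) abort("need at least one sector", class = "pp_config_error")
  if (mode == "annulus" && half_width >= radius) {
    abort("annulus half-width must be smaller than the radius",
          class = "pp_config_error")
  }
  structure(list(radius = radius, half_width = half_width, sectors = sectors,
                 mode = mode, plane = plane),
            class = "pp_ring_spec")
}

#' Pixels belonging to a ring around a centre
#'
#' Membership uses the exact Euclidean distance from the (sub-pixel) centre;
#' the centre is never rounded. Pixels falling outside the image are dropped
#' and the result is flagged as clipped.
#'
#' @param center numeric `c(x, y)` centre in 0-based pixel coordinates.
#' @param spec a [ring_spec()].
#' @param dim image plane dimensions `c(rows, cols)` (or a matrix, whose
#'   dimensions are used).
#' @return Tibble with columns `row`, `col` (1-based pixel indices), `dx`,
#'   `dy`, `r` (pixels) and `angle` (radians in `[0, 2*pi)`, y down), with
#'   attribute `clipped` set when part of the ring fell outside the plane.
#' @export
ring_pixels <- function(center, spec, dim) {
  stopifnot(inherits(spec, "pp_ring_spec"))
  if (is.matrix(dim)) dim <- base::dim(dim)
  nr <- dim[1]; nc <- dim[2]
  cx <- center[1]; cy <- center[2]
  r_out <- if (spec$mode == "annulus") spec$radius + spec$half_width else spec$radius
  r_in <- if (spec$mode == "annulus") spec$radius - spec$half_width else 0
  rows <- seq(max(1, floor(cy + 1 - r_out)), min(nr, ceiling(cy + 1 + r_out)))
  cols <- seq(max(1, floor(cx + 1 - r_out)), min(nc, ceiling(cx + 1 + r_out)))
  clipped <- (cy + 1 - r_out < 1) || (cy + 1 + r_out > nr) ||
    (cx + 1 - r_out < 1) || (cx + 1 + r_out > nc)
  if (!length(rows) || !length(cols)) {
    out <- tibble(row = integer(0), col = integer(0), dx = numeric(0),
                  dy = numeric(0), r = numeric(0), angle = numeric(0))
    attr(out, "clipped") <- TRUE
    return(out)
  }
  grid <- expand.grid(row = rows, col = cols)
  dx <- grid$col - 1 - cx
  dy <- grid$row - 1 - cy
  r <- sqrt(dx^2 + dy^2)
  keep <- r >= r_in & r <= r_out
  angle <- atan2(dy[keep], dx[keep]) %% (2 * pi)
  out <- tibble(row = grid$row[keep], col = grid$col[keep],
                dx = dx[keep], dy = dy[keep], r = r[keep], angle = angle)
  attr(out, "clipped") <- clipped
  out
}

#' Angular intensity profile on one plane
#'
#' Bins the ring pixels into equal angular sectors and reports the mean
#' intensity per sector plus the overall ring mean. The ring mean is the mean
#' over all ring pixels, not the mean of sector means. Empty sectors (only
#' possible for very small rings) are filled by circular linear interpolation
#' from their neighbours and flagged.
#'
#' @param plane numeric matrix (one image plane, rows = y).
#' @param center numeric `c(x, y)` in 0-based pixel coordinates.
#' @param spec a [ring_spec()].
#' @return List: `sector_means` (length `spec$sectors`), `ring_mean`,
#'   `interpolated` (logical per sector), `clipped`.
#' @export
angular_profile <- function(plane, center, spec) {
  pix <- ring_pixels(center, spec, dim(plane))
  if (nrow(pix) == 0) {
    abort("ring contains no pixels (degenerate geometry)",
          class = "pp_geometry_error")
  }
  vals <- plane[cbind(pix$row, pix$col)]
  k <- pmin(floor(pix$angle / (2 * pi / spec$sectors)) + 1L, spec$sectors)
  sums <- tapply(vals, factor(k, levels = seq_len(spec$sectors)), mean)
  means <- as.numeric(sums)
  interp <- is.na(means)
  if (any(interp)) {
    means <- fill_circular(means)
  }
  list(sector_means = means, ring_mean = mean(vals),
       interpolated = interp, clipped = attr(pix, "clipped"))
}

# circular linear interpolation of NA runs
fill_circular <- function(x) {
  n <- length(x)
  ok <- which(!is.na(x))
  if (length(ok) == 0) return(rep(0, n))
  for (i in which(is.na(x))) {
    d_prev <- (i - ok - 1) %% n; d_next <- (ok - i - 1) %% n
    prev <- ok[which.min(d_prev)]; nxt <- ok[which.min(d_next)]
    dp <- (i - prev) %% n; dn <- (nxt - i) %% n
    if (dp + dn == 0) x[i] <- x[prev]
    else x[i] <- (x[prev] * dn + x[nxt] * dp) / (dp + dn)
  }
  x
}

new_ring_series <- function(track_id, frames, sectors, ring_mean,
                            frame_interval_s, state, flags = list()) {
  structure(list(track_id = track_id, frames = frames, sectors = sectors,
                 ring_mean = ring_mean, frame_interval_s = frame_interval_s,
                 state = state, flags = flags),
            class = "pp_ring_series")
}

#' @export
print.pp_ring_series <- function(x, ...) {
  cat(sprintf("<pp_ring_series> track %s: %d frame(s) x %d sector(s), state %s\n",
              x$track_id, length(x$frames), ncol(x$sectors), x$state))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.pp_ring_series <- function(x, ...) {
  s <- as_tibble(as.data.frame(x$sectors))
  names(s) <- sprintf("s%02d", seq_len(ncol(x$sectors)))
  dplyr::bind_cols(
    tibble(track_id = x$track_id, frame = x$frames,
           t_min = (x$frames - x$frames[1]) * x$frame_interval_s / 60,
           ring_mean = x$ring_mean),
    s)
}

#' Build a ring kymograph for one track
#'
#' For each track point, selects the image plane by the spec's plane rule
#' (default: the z-slice nearest the centroid), computes the angular profile
#' at the (x, y) centroid and stacks the rows by frame, producing a
#' frames-by-sectors kymograph plus the per-frame ring mean.
#'
#' @param track a `pp_tracks` tibble containing a single track.
#' @param movie the `pp_movie` the track was measured in.
#' @param spec a [ring_spec()].
#' @param channel channel to profile (default `"reporter"`).
#' @return A `pp_ring_series` (state `"raw"`).
#' @export
build_kymograph <- function(track, movie, spec = ring_spec(),
                            channel = "reporter") {
  stopifnot(inherits(movie, "pp_movie"))
  ids <- unique(track$track_id)
  if (length(ids) != 1) {
    abort("build_kymograph() expects exactly one track", class = "pp_config_error")
  }
  track <- dplyr::arrange(track, .data$frame)
  nt <- n_frames(movie)
  bad <- track$frame[track$frame < 1 | track$frame > nt]
  if (length(bad)) {
    abort(sprintf("track frame %d outside movie time range", bad[1]),
          class = "pp_index_error")
  }
  vs <- movie$voxel_size
  nz <- dim(movie$data)[3]
  n <- nrow(track)
  ch <- if (is.character(channel)) match(channel, movie$channels) else channel
  if (is.na(ch)) abort("channel not present in movie", class = "pp_format_error")
  stack <- movie$data[, , , ch, , drop = FALSE]  # one copy for the whole track
  sectors <- matrix(NA_real_, n, spec$sectors)
  ring_mean <- numeric(n)
  clipped <- logical(n)
  for (i in seq_len(n)) {
    t_i <- track$frame[i]
    zi <- min(max(round(track$z_um[i] / vs["z"]) + 1, 1), nz)
    plane <- if (spec$plane == "maxproj3") {
      zr <- seq(max(1, zi - 1), min(nz, zi + 1))
      apply(stack[, , zr, 1, t_i, drop = FALSE], c(1, 2), max)
    } else {
      stack[, , zi, 1, t_i]
    }
    prof <- angular_profile(plane,
                            c(track$x_um[i] / vs["x"], track$y_um[i] / vs["y"]),
                            spec)
    sectors[i, ] <- prof$sector_means
    ring_mean[i] <- prof$ring_mean
    clipped[i] <- prof$clipped
  }
  new_ring_series(ids, track$frame, sectors, ring_mean,
                  movie$frame_interval_s, "raw",
                  flags = list(clipped = clipped))
}

# centred moving average with symmetric-reflected ends
moving_avg_reflect <- function(x, window) {
  n <- length(x)
  h <- (window - 1) / 2
  if (h == 0) return(x)
  xp <- c(rev(x[seq_len(h)]), x, rev(x[seq(n - h + 1, n)]))
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))[h + seq_len(n)]
}

#' Low-pass filter a ring profile series
#'
#' Centred moving average along time, applied independently to each sector
#' trace and to the ring mean, with symmetric reflection at the ends.
#' `window = 1` is the identity.
#'
#' @param series a `pp_ring_series`.
#' @param window odd window length in frames (default 5).
#' @return The filtered series (state `"filtered"`).
#' @export
lowpass <- function(series, window = 5) {
  stopifnot(inherits(series, "pp_ring_series"))
  if (window < 1 || window %% 2 == 0) {
    abort("window must be odd and >= 1", class = "pp_config_error")
  }
  if (window > length(series$frames)) {
    abort("window longer than the series", class = "pp_config_error")
  }
  series$sectors <- apply(series$sectors, 2, moving_avg_reflect, window = window)
  if (length(series$frames) == 1) series$sectors <- matrix(series$sectors, nrow = 1)
  series$ring_mean <- moving_avg_reflect(series$ring_mean, window)
  series$state <- "filtered"
  series
}

#' Min-max normalise ring profile series per track
#'
#' Per track, subtracts the track minimum and divides by the resulting
#' maximum so values lie in `[0, 1]`. A single minimum/maximum is taken
#' jointly over all sector values and the ring mean of the track. Constant
#' tracks are mapped to zero and flagged.
#'
#' @param series a `pp_ring_series` or a list of them.
#' @return Series (or list) in state `"normalized"`.
#' @export
normalize_tracks <- function(series) {
  if (inherits(series, "pp_ring_series")) return(normalize_one(series))
  purrr::map(series, normalize_one)
}

normalize_one <- function(s) {
  lo <- min(s$sectors, s$ring_mean)
  hi <- max(s$sectors, s$ring_mean)
  if (hi > lo) {
    s$sectors <- (s$sectors - lo) / (hi - lo)
    s$ring_mean <- (s$ring_mean - lo) / (hi - lo)
    s$flags$constant <- FALSE
  } else {
    s$sectors[] <- 0
    s$ring_mean[] <- 0
    s$flags$constant <- TRUE
  }
  s$state <- "normalized"
  s
}

#' Align tracks at time zero and average
#'
#' Shifts every series so its first frame becomes time 0 (the engulfment
#' frame for tracks that start at engulfment) and computes the per-time-index
#' mean and standard deviation of the ring mean over the tracks present at
#' that index. Ragged ends are handled by counting only contributing tracks.
#'
#' @param series a `pp_ring_series` or list of them.
#' @return List with `aligned` (the series, re-indexed, state `"aligned"`)
#'   and `summary`, a tibble `t_index` (frames since track start), `t_min`,
#'   `mean`, `sd` (0 where a single track contributes), `n`.
#' @export
align_and_average <- function(series) {
  if (inherits(series, "pp_ring_series")) series <- list(series)
  if (length(series) == 0) abort("need at least one series", class = "pp_config_error")
  aligned <- purrr::map(series, function(s) {
    s$frames <- s$frames - s$frames[1]
    s$state <- "aligned"
    s
  })
  max_len <- max(purrr::map_int(aligned, function(s) length(s$frames)))
  mat <- matrix(NA_real_, max_len, length(aligned))
  for (j in seq_along(aligned)) {
    mat[seq_along(aligned[[j]]$ring_mean), j] <- aligned[[j]]$ring_mean
  }
  n <- rowSums(!is.na(mat))
  mu <- rowMeans(mat, na.rm = TRUE)
  sdv <- apply(mat, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) <= 1) 0 else sd(r)
  })
  dt <- series[[1]]$frame_interval_s
  list(aligned = aligned,
       summary = tibble(t_index = seq_len(max_len) - 1L,
                        t_min = (seq_len(max_len) - 1) * dt / 60,
                        mean = mu, sd = sdv, n = n))
}
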