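#' Multi-channel 3D time-lapse movie container
#'
#' A `pp_movie` wraps a 5-D voxel array together with its physical
#' calibration. The logical axis order is time, channel, z, y, x; internally
#' the array is stored with dimensions `(y, x, z, channel, time)` so that a
#' single channel volume of one frame is a contiguous block and each `[y, x]`
#' plane is an image-oriented matrix (y pointing down).
#'
#' @param data numeric array with dimensions `(y, x, z, channel, time)`.
#' @param channels character vector of unique channel names, e.g.
#'   `c("reporter", "prey")`.
#' @param voxel_size named numeric `c(x=, y=, z=)`, micrometres per voxel.
#' @param frame_interval_s time between frames, seconds.
#' @param offset_min acquisition start relative to infection, minutes
#'   (metadata only).
#' @param fov field-of-view index within a cohort (metadata only).
#'
#' @return A `pp_movie` object.
#' @export
new_movie <- function(data, channels, voxel_size, frame_interval_s,
                      offset_min = 0, fov = NA_integer_) {
  if (length(dim(data)) != 5L) {
    abort("`data` must be a 5-D array (y, x, z, channel, time)", class = "pp_format_error")
  }
  if (dim(data)[4] != length(channels)) {
    abort("number of channels does not match dim(data)[4]", class = "pp_format_error")
  }
  if (anyDuplicated(channels)) abort("channel names must be unique", class = "pp_format_error")
  voxel_size <- voxel_size[c("x", "y", "z")]
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    abort("voxel sizes must be positive and named x, y, z", class = "pp_config_error")
  }
  if (!is.finite(frame_interval_s) || frame_interval_s <= 0) {
    abort("frame interval must be positive", class = "pp_config_error")
  }
  structure(
    list(data = data, channels = channels, voxel_size = voxel_size,
         frame_interval_s = frame_interval_s, offset_min = offset_min,
         fov = fov),
    class = "pp_movie"
  )
}

#' @export
print.pp_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<pp_movie> %d frame(s) x %d channel(s) [%s], %d x %d x %d voxels (y,x,z)\n",
    d[5], d[4], paste(x$channels, collapse = ", "), d[1], d[2], d[3]))
  cat(sprintf("  voxel size %.3g x %.3g x %.3g um, frame interval %.3g s\n",
              x$voxel_size["x"], x$voxel_size["y"], x$voxel_size["z"],
              x$frame_interval_s))
  invisible(x)
}

#' Extract one channel volume of one frame
#'
#' @param movie a [new_movie()] object.
#' @param frame 1-based frame index.
#' @param channel channel name or index.
#' @return 3-D array `(y, x, z)`.
#' @export
movie_frame <- function(movie, frame, channel) {
  stopifnot(inherits(movie, "pp_movie"))
  nt <- dim(movie$data)[5]
  if (frame < 1 || frame > nt) {
    abort(sprintf("frame %d outside movie time range 1..%d", frame, nt),
          class = "pp_index_error")
  }
  if (is.character(channel)) {
    channel <- match(channel, movie$channels)
    if (is.na(channel)) {
      abort("channel not present in movie", class = "pp_format_error")
    }
  }
  movie$data[, , , channel, frame, drop = TRUE]
}

#' @export
dim.pp_movie <- function(x) dim(x$data)

#' Number of frames in a movie
#' @param movie a [new_movie()] object.
#' @export
n_frames <- function(movie) dim(movie$data)[5]
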