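#' Per-frame object detection for tracking
#'
#' Smooths and segments one channel of every frame and returns the component
#' centroids, the raw material for [link_detections()]. The prey channel is
#' the default detection channel: bacteria stay bright while the membrane
#' reporter fades between pulses, so prey-based detections keep phagosome
#' identity alive over the whole movie.
#'
#' @param movie a `pp_movie`.
#' @param channel channel to detect on.
#' @param level intensity threshold; `NULL` picks a single Otsu level from
#'   the smoothed first frame containing signal.
#' @param connectivity,min_size passed to [segment_prey()].
#' @return Tibble: `frame`, `label`, `x_um`, `y_um`, `z_um`, `n_voxels`,
#'   `mean_intensity`.
#' @export
detect_centroids <- function(movie, channel = "prey", level = NULL,
                             connectivity = 26, min_size = 5) {
  stopifnot(inherits(movie, "pp_movie"))
  nf <- n_frames(movie)
  d <- dim(movie$data)
  ch <- if (is.character(channel)) match(channel, movie$channels) else channel
  if (is.na(ch)) abort("channel not present in movie", class = "pp_format_error")
  stack <- movie$data[, , , ch, , drop = TRUE]
  if (nf == 1) dim(stack) <- c(d[1], d[2], d[3], 1)
  dim4 <- c(d[1], d[2], d[3], nf)
  sm <- .box_smooth3_batch_cpp(as.numeric(stack), as.integer(dim4))
  if (is.null(level)) {
    # objects can be dim in part of the movie (pH-dependent brightness):
    # take the lowest workable level across sample frames
    cand <- unique(pmax(1, ceiling(nf * c(1 / 3, 2 / 3, 1))))
    lv <- purrr::map_dbl(cand, function(t) {
      fr <- sm[, , , t, drop = TRUE]
      dim(fr) <- d[1:3]
      detection_level(fr)
    })
    level <- if (all(!is.finite(lv))) Inf else min(lv[is.finite(lv)])
  }
  lab <- .label3d_batch_cpp(sm > level, as.integer(dim4),
                            as.integer(connectivity))
  idx <- which(lab > 0)
  empty <- tibble(frame = integer(0), label = integer(0), x_um = numeric(0),
                  y_um = numeric(0), z_um = numeric(0), n_voxels = integer(0),
                  mean_intensity = numeric(0))
  if (!length(idx)) return(empty)
  fsz <- prod(d[1:3])
  fr <- (idx - 1) %/% fsz + 1
  i3 <- (idx - 1) %% fsz
  iy <- i3 %% d[1]
  ix <- (i3 %/% d[1]) %% d[2]
  iz <- i3 %/% (d[1] * d[2])
  l <- lab[idx]
  max_lab <- max(l)
  key <- (fr - 1) * max_lab + l
  n_vox <- tabulate(key, nf * max_lab)
  keep_key <- which(n_vox >= min_size)
  if (!length(keep_key)) return(empty)
  vs <- movie$voxel_size
  sx <- rowsum(ix * vs[["x"]], key)
  sy <- rowsum(iy * vs[["y"]], key)
  sz <- rowsum(iz * vs[["z"]], key)
  si <- rowsum(sm[idx], key)
  keys_present <- as.numeric(rownames(sx))
  m <- match(keep_key, keys_present)
  nv <- n_vox[keep_key]
  out <- tibble(
    frame = as.integer((keep_key - 1) %/% max_lab + 1),
    label = as.integer((keep_key - 1) %% max_lab + 1),
    x_um = sx[m] / nv, y_um = sy[m] / nv, z_um = sz[m] / nv,
    n_voxels = as.integer(nv), mean_intensity = si[m] / nv
  )
  dplyr::arrange(out, .data$frame, .data$label)
}

#' Robust spot-detection threshold for sparse bright objects
#'
#' A plain Otsu threshold fails when the foreground occupies a tiny fraction
#' of the volume (it splits the background mode instead). This rule first
#' floors the histogram at `median + k * mad` of the smoothed volume, then
#' applies Otsu to the supra-floor intensities only, and returns the larger
#' of the two. Returns `Inf` (no detections) when nothing rises above the
#' floor.
#'
#' @param volume smoothed single-channel 3-D volume.
#' @param k noise-floor multiplier (default 4).
#' @param min_voxels minimum number of supra-floor voxels required to
#'   attempt thresholding.
#' @return A single detection level.
#' @export
detection_level <- function(volume, k = 4, min_voxels = 30) {
  med <- median(volume)
  floor_level <- med + k * stats::mad(volume)
  v <- volume[volume > floor_level]
  if (length(v) < min_voxels || diff(range(v)) == 0) return(Inf)
  max(otsu_levels(v, n_classes = 2), floor_level)
}

#' Link per-frame detections into tracks
#'
#' Frame-to-frame one-to-one assignment minimising total Euclidean
#' displacement in micrometres (anisotropy honoured), solved exactly with
#' the Hungarian algorithm. Links longer than `max_displacement` are
#' forbidden; unmatched detections start new tracks; tracks unseen for more
#' than `max_gap` frames terminate. Gaps up to `max_gap` frames are closed by
#' linear interpolation and flagged.
#'
#' @param detections tibble with columns `frame`, `x_um`, `y_um`, `z_um`
#'   (e.g. from [detect_centroids()]).
#' @param max_displacement maximum per-frame displacement, micrometres.
#' @param max_gap maximum number of missed frames bridged within a track.
#' @return A `pp_tracks` tibble: `track_id`, `frame`, `x_um`, `y_um`, `z_um`,
#'   `gap` (TRUE for interpolated points), `source = "builtin"`. Frames are
#'   strictly increasing within a track, one detection per frame.
#' @export
link_detections <- function(detections, max_displacement = 2, max_gap = 2) {
  if (max_displacement <= 0) {
    abort("max_displacement must be > 0", class = "pp_config_error")
  }
  cols <- c("frame", "x_um", "y_um", "z_um")
  if (nrow(detections) == 0) {
    out <- tibble(track_id = character(0), frame = integer(0),
                  x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                  gap = logical(0), source = character(0))
    class(out) <- c("pp_tracks", class(out))
    return(out)
  }
  stopifnot(all(cols %in% names(detections)))
  detections <- dplyr::arrange(detections, .data$frame)
  frames <- sort(unique(detections$frame))
  det_by_frame <- split(detections[cols], detections$frame)

  # active track state: per-track growing list of point rows
  pts <- list()        # track -> list of c(frame, x, y, z, gap)
  last_pos <- list()   # track -> c(frame, x, y, z)
  active <- integer(0)

  for (f in frames) {
    det <- det_by_frame[[as.character(f)]]
    if (length(active)) {
      seen <- vapply(last_pos[active], function(p) p[1], numeric(1))
      active <- active[seen >= f - max_gap - 1]
    }
    nd <- nrow(det); na <- length(active)
    assigned_det <- rep(FALSE, nd)
    if (na > 0 && nd > 0) {
      lp <- matrix(unlist(last_pos[active]), nrow = na, byrow = TRUE)
      cost <- sqrt(outer(lp[, 2], det$x_um, "-")^2 +
                     outer(lp[, 3], det$y_um, "-")^2 +
                     outer(lp[, 4], det$z_um, "-")^2)
      big <- 1e9
      cost[cost > max_displacement] <- big
      match_col <- .hungarian_cpp(cost, big)
      for (i in seq_len(na)) {
        j <- match_col[i]
        if (is.na(j)) next
        tr <- active[i]
        prev <- last_pos[[tr]]
        gap_n <- f - prev[1] - 1
        if (gap_n > 0) {
          # close the gap by linear interpolation, flagged
          w <- seq_len(gap_n) / (gap_n + 1)
          for (g in seq_len(gap_n)) {
            pts[[tr]][[length(pts[[tr]]) + 1]] <-
              c(prev[1] + g,
                prev[2] + w[g] * (det$x_um[j] - prev[2]),
                prev[3] + w[g] * (det$y_um[j] - prev[3]),
                prev[4] + w[g] * (det$z_um[j] - prev[4]), 1)
          }
        }
        pts[[tr]][[length(pts[[tr]]) + 1]] <-
          c(f, det$x_um[j], det$y_um[j], det$z_um[j], 0)
        last_pos[[tr]] <- c(f, det$x_um[j], det$y_um[j], det$z_um[j])
        assigned_det[j] <- TRUE
      }
    }
    for (j in which(!assigned_det)) {
      id <- length(pts) + 1L
      pts[[id]] <- list(c(f, det$x_um[j], det$y_um[j], det$z_um[j], 0))
      last_pos[[id]] <- c(f, det$x_um[j], det$y_um[j], det$z_um[j])
      active <- c(active, id)
    }
  }

  mat <- do.call(rbind, purrr::flatten(pts))
  n_per <- vapply(pts, length, integer(1))
  out <- tibble(
    track_id = sprintf("track%04d", rep(seq_along(pts), n_per)),
    frame = as.integer(mat[, 1]),
    x_um = mat[, 2], y_um = mat[, 3], z_um = mat[, 4],
    gap = mat[, 5] == 1,
    source = "builtin"
  )
  class(out) <- c("pp_tracks", class(out))
  out
}

#' Read TrackMate XML tracks
#'
#' Parses the Spots and Tracks sections of a TrackMate file into the package
#' track table. Spot positions are in physical units (micrometres) as stored
#' by TrackMate; the image calibration must be present in the
#' `Settings/ImageData` element.
#'
#' @param path path to a TrackMate XML file.
#' @return A `pp_tracks` tibble with `source = "trackmate"` and track IDs
#'   preserved from the file.
#' @export
read_trackmate <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(sprintf("malformed TrackMate XML (%s): %s", path, conditionMessage(e)),
          class = "pp_parse_error")
  })
  model <- xml2::xml_find_first(doc, ".//Model")
  if (inherits(model, "xml_missing")) {
    abort("TrackMate XML missing element path /TrackMate/Model",
          class = "pp_parse_error")
  }
  img <- xml2::xml_find_first(doc, ".//Settings/ImageData")
  if (inherits(img, "xml_missing")) {
    abort("TrackMate XML missing element path /TrackMate/Settings/ImageData",
          class = "pp_parse_error")
  }
  for (at in c("pixelwidth", "pixelheight", "voxeldepth")) {
    if (is.na(xml2::xml_attr(img, at))) {
      abort(sprintf("TrackMate ImageData missing calibration attribute '%s'", at),
            class = "pp_parse_error")
    }
  }
  spots <- xml2::xml_find_all(model, ".//AllSpots//Spot")
  if (length(spots) == 0) {
    abort("TrackMate XML missing element path Model/AllSpots/Spot",
          class = "pp_parse_error")
  }
  spot_tab <- tibble(
    id = xml2::xml_attr(spots, "ID"),
    frame = as.integer(xml2::xml_attr(spots, "FRAME")),
    x_um = as.numeric(xml2::xml_attr(spots, "POSITION_X")),
    y_um = as.numeric(xml2::xml_attr(spots, "POSITION_Y")),
    z_um = as.numeric(xml2::xml_attr(spots, "POSITION_Z"))
  )
  tracks <- xml2::xml_find_all(model, ".//AllTracks/Track")
  if (length(tracks) == 0) {
    abort("TrackMate XML missing element path Model/AllTracks/Track",
          class = "pp_parse_error")
  }
  out <- purrr::map_dfr(tracks, function(tr) {
    tid <- xml2::xml_attr(tr, "TRACK_ID")
    edges <- xml2::xml_find_all(tr, ".//Edge")
    ids <- unique(c(xml2::xml_attr(edges, "SPOT_SOURCE_ID"),
                    xml2::xml_attr(edges, "SPOT_TARGET_ID")))
    pts <- spot_tab[spot_tab$id %in% ids, ]
    pts <- dplyr::arrange(pts, .data$frame)
    dplyr::mutate(dplyr::select(pts, -"id"),
                  track_id = paste0("trackmate_", tid),
                  gap = FALSE, source = "trackmate")
  })
  out <- dplyr::select(out, "track_id", "frame", "x_um", "y_um", "z_um",
                       "gap", "source")
  class(out) <- c("pp_tracks", class(out))
  out
}

#' Match built tracks to ground-truth phagosomes
#'
#' Assigns each track to the nearest ground-truth phagosome (median track
#' position vs. truth centre, Hungarian assignment), used to score tracking
#' and pulse detection against the generator log.
#'
#' @param tracks a `pp_tracks` tibble for one FOV.
#' @param truth a `pp_truth` log.
#' @param fov FOV index the tracks belong to.
#' @param max_distance_um maximum centre distance for a valid match.
#' @return Tibble: `track_id`, `phagosome`, `distance_um`.
#' @export
match_tracks_to_truth <- function(tracks, truth, fov,
                                  max_distance_um = 2) {
  ph <- truth$phagosomes[truth$phagosomes$fov == fov, ]
  ids <- unique(tracks$track_id)
  if (length(ids) == 0 || nrow(ph) == 0) {
    return(tibble(track_id = character(0), phagosome = integer(0),
                  distance_um = numeric(0)))
  }
  pos <- t(vapply(ids, function(id) {
    p <- tracks[tracks$track_id == id, ]
    c(median(p$x_um), median(p$y_um), median(p$z_um))
  }, numeric(3)))
  cost <- outer(seq_along(ids), seq_len(nrow(ph)), Vectorize(function(i, j) {
    sqrt(sum((pos[i, ] - c(ph$x_um[j], ph$y_um[j], ph$z_um[j]))^2))
  }))
  big <- 1e9
  cost[cost > max_distance_um] <- big
  m <- .hungarian_cpp(cost, big)
  keep <- !is.na(m)
  tibble(track_id = ids[keep], phagosome = ph$phagosome[m[keep]],
         distance_um = cost[cbind(which(keep), m[keep])])
}
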