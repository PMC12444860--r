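# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive results with naive loops, separate from the package
# implementations they check.

# 27-neighbour mean with symmetric (edge-duplicating) reflection
brute_box3 <- function(vol) {
  d <- dim(vol)
  refl <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  out <- vol
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    s <- 0
    for (a in -1:1) for (b in -1:1) for (cc in -1:1) {
      s <- s + vol[refl(i + a, d[1]), refl(j + b, d[2]), refl(k + cc, d[3])]
    }
    out[i, j, k] <- s / 27
  }
  out
}

# queue-based flood fill, 26- or 6-connectivity; returns per-component sizes
# in discovery order
brute_flood_sizes <- function(mask, connectivity = 26) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  sizes <- integer(0)
  nb <- expand.grid(a = -1:1, b = -1:1, cc = -1:1)
  nb <- nb[!(nb$a == 0 & nb$b == 0 & nb$cc == 0), ]
  if (connectivity == 6) nb <- nb[abs(nb$a) + abs(nb$b) + abs(nb$cc) == 1, ]
  for (s1 in seq_len(d[1])) for (s2 in seq_len(d[2])) for (s3 in seq_len(d[3])) {
    if (!mask[s1, s2, s3] || seen[s1, s2, s3]) next
    queue <- list(c(s1, s2, s3)); seen[s1, s2, s3] <- TRUE; n <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]; n <- n + 1
      for (r in seq_len(nrow(nb))) {
        q <- p + c(nb$a[r], nb$b[r], nb$cc[r])
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && !seen[q[1], q[2], q[3]]) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    sizes <- c(sizes, n)
  }
  sizes
}

# full-plane scan applying the ring radius predicate
brute_ring_scan <- function(plane, center, radius, half_width, sectors,
                            mode = "annulus") {
  nr <- nrow(plane); nc <- ncol(plane)
  r_out <- if (mode == "annulus") radius + half_width else radius
  r_in <- if (mode == "annulus") radius - half_width else 0
  vals <- c(); ang <- c(); rows <- c(); cols <- c()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    dx <- (j - 1) - center[1]; dy <- (i - 1) - center[2]
    r <- sqrt(dx^2 + dy^2)
    if (r >= r_in && r <= r_out) {
      vals <- c(vals, plane[i, j])
      ang <- c(ang, atan2(dy, dx) %% (2 * pi))
      rows <- c(rows, i); cols <- c(cols, j)
    }
  }
  k <- pmin(floor(ang / (2 * pi / sectors)) + 1, sectors)
  sect <- sapply(seq_len(sectors), function(s) {
    if (any(k == s)) mean(vals[k == s]) else NA_real_
  })
  list(ring_mean = mean(vals), sector_means = sect,
       pixels = data.frame(row = rows, col = cols))
}

# centred sliding mean with mirrored ends
brute_sliding_mean <- function(x, w) {
  h <- (w - 1) / 2
  n <- length(x)
  xp <- c(rev(x[seq_len(h)]), x, rev(x[seq(n - h + 1, n)]))
  sapply(seq_len(n), function(i) mean(xp[i:(i + w - 1)]))
}

# minimal assignment cost by explicit enumeration of permutations
brute_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(ncol(cost)))) {
    s <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    best <- min(best, s)
  }
  best
}

# Gaussian ring phantom, optionally with a pore sector at background
shell_plane <- function(n = 41, cx = 20, cy = 20, radius = 6, amp = 1,
                        sigma = 1.2, pore_start = NULL, pore_width = pi / 3) {
  img <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dx <- (j - 1) - cx; dy <- (i - 1) - cy
    r <- sqrt(dx^2 + dy^2)
    v <- amp * exp(-(r - radius)^2 / (2 * sigma^2))
    if (!is.null(pore_start)) {
      a <- atan2(dy, dx) %% (2 * pi)
      da <- (a - pore_start) %% (2 * pi)
      if (da < pore_width) v <- 0
    }
    img[i, j] <- v
  }
  img
}

# hand-written TrackMate XML fixture: one track, three spots
trackmate_fixture <- function(path, with_tracks = TRUE, with_calibration = TRUE) {
  spots <- paste0(
    '<SpotsInFrame frame="0">',
    '<Spot ID="101" FRAME="0" POSITION_X="1.5" POSITION_Y="2.5" POSITION_Z="3.0"/>',
    '</SpotsInFrame>',
    '<SpotsInFrame frame="1">',
    '<Spot ID="102" FRAME="1" POSITION_X="1.7" POSITION_Y="2.6" POSITION_Z="3.0"/>',
    '</SpotsInFrame>',
    '<SpotsInFrame frame="2">',
    '<Spot ID="103" FRAME="2" POSITION_X="1.9" POSITION_Y="2.7" POSITION_Z="3.1"/>',
    '</SpotsInFrame>')
  tracks <- if (with_tracks) {
    paste0('<AllTracks><Track TRACK_ID="7" NUMBER_SPOTS="3">',
           '<Edge SPOT_SOURCE_ID="101" SPOT_TARGET_ID="102"/>',
           '<Edge SPOT_SOURCE_ID="102" SPOT_TARGET_ID="103"/>',
           '</Track></AllTracks>')
  } else ""
  calib <- if (with_calibration) {
    '<ImageData pixelwidth="0.33" pixelheight="0.33" voxeldepth="1.5"/>'
  } else '<ImageData/>'
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<TrackMate version="7.0.0">',
    '<Model spatialunits="micron"><AllSpots>', spots, '</AllSpots>',
    tracks, '</Model>',
    '<Settings>', calib, '</Settings>',
    '</TrackMate>')
  writeLines(xml, path)
  path
}

# compact simulation configs used across tests
tiny_config <- function(...) {
  sim_config(shape = c(x = 28, y = 28, z = 7), n_frames = 40,
             n_neutrophils = 1, phagosomes_fixed = 1, seed = 1, ...)
}
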