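#' Per-neutrophil pulsing summary
#'
#' Aggregates phagosome call records to the statistics the analysis reports
#' per neutrophil: the mean and s.d. of the percentage of pulsing phagosomes
#' within a neutrophil (each neutrophil weighted equally), the percentage of
#' phagocytic neutrophils with at least one pulsing phagosome, first-pulse
#' latency mean and s.d. over pulsing phagosomes, and the pulse-count
#' distribution. The pooled per-phagosome rate is also emitted, clearly
#' labelled, since the two weightings differ.
#'
#' @param calls a `pp_calls` tibble (one row per phagosome track) with a
#'   `neutrophil` column identifying the neutrophil of each track.
#' @return A `pp_pulsing_summary` list with `per_neutrophil` (tibble:
#'   `neutrophil`, `n_phagosomes`, `n_pulsing`, `pct_pulsing`), `summary`
#'   (one row; see [glance()]), and `pulse_count_dist` (tibble `n_pulses`,
#'   `n_phagosomes`). Neutrophils with zero phagosomes cannot appear in
#'   `calls` and are therefore excluded by construction; a `dropped`
#'   attribute records any `NA`-neutrophil tracks that were excluded.
#' @export
pulsing_summary <- function(calls) {
  if (!"neutrophil" %in% names(calls)) {
    abort("calls must carry a `neutrophil` column", class = "pp_config_error")
  }
  dropped <- sum(is.na(calls$neutrophil))
  calls <- calls[!is.na(calls$neutrophil), ]
  if (nrow(calls) == 0) {
    abort("no phagosome records to summarise", class = "pp_config_error")
  }
  per <- calls |>
    dplyr::group_by(.data$neutrophil) |>
    dplyr::summarise(n_phagosomes = dplyr::n(),
                     n_pulsing = sum(.data$pulsing), .groups = "drop") |>
    dplyr::mutate(pct_pulsing = 100 * .data$n_pulsing / .data$n_phagosomes)
  lat <- calls$latency_min[calls$pulsing]
  summary <- tibble(
    n_neutrophils = nrow(per),
    n_phagosomes = nrow(calls),
    mean_pct_pulsing = mean(per$pct_pulsing),
    sd_pct_pulsing = if (nrow(per) > 1) sd(per$pct_pulsing) else 0,
    pct_neutrophils_pulsing = 100 * mean(per$n_pulsing >= 1),
    pooled_pct_pulsing = 100 * mean(calls$pulsing),
    latency_mean_min = if (length(lat)) mean(lat) else NA_real_,
    latency_sd_min = if (length(lat) > 1) sd(lat) else NA_real_
  )
  dist <- calls |>
    dplyr::filter(.data$pulsing) |>
    dplyr::count(.data$n_pulses, name = "n_phagosomes")
  out <- structure(list(per_neutrophil = per, summary = summary,
                        pulse_count_dist = dist),
                   class = "pp_pulsing_summary")
  attr(out, "dropped") <- dropped
  out
}

#' @export
print.pp_pulsing_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<pp_pulsing_summary> %d neutrophils, %d phagosomes\n",
           "  pulsing phagosomes per neutrophil: %.1f +/- %.1f %%\n",
           "  neutrophils with >=1 pulsing phagosome: %.1f %%\n"),
    s$n_neutrophils, s$n_phagosomes, s$mean_pct_pulsing, s$sd_pct_pulsing,
    s$pct_neutrophils_pulsing))
  if (is.finite(s$latency_mean_min %||% NA)) {
    cat(sprintf("  first-pulse latency: %.1f +/- %.1f min\n",
                s$latency_mean_min, s$latency_sd_min))
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.pp_pulsing_summary <- function(x, ...) x$summary

#' @exportS3Method generics::tidy
tidy.pp_pulsing_summary <- function(x, ...) x$per_neutrophil

#' Spearman correlation between bacterial burden and pulsing
#'
#' Spearman's rank correlation (midranks for ties) between the number of
#' bacteria per neutrophil and the number of pulsing phagosomes per
#' neutrophil, with a two-sided t-approximation p-value.
#'
#' @param records tibble with columns `n_bacteria` and `n_pulsing` (one row
#'   per neutrophil).
#' @return One-row tibble: `rho`, `p_value`, `n`.
#' @export
burden_correlation <- function(records) {
  x <- records$n_bacteria; y <- records$n_pulsing
  n <- length(x)
  if (n < 3) abort("need at least 3 neutrophils", class = "pp_config_error")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warn("burden correlation undefined: constant column")
    return(tibble(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), n - 2)
  }
  tibble(rho = rho, p_value = p, n = n)
}

#' Relative intensity change versus a baseline timepoint
#'
#' For each object, divides the intensity at every timepoint by the
#' intensity at the baseline timepoint (relative change, dimensionless).
#' Objects with zero baseline are excluded and reported in the `excluded`
#' attribute.
#'
#' @param series tibble with columns `object`, `timepoint`, `intensity` and
#'   optionally `class` (e.g. pulsing / non-pulsing).
#' @param baseline the baseline timepoint label (must be present).
#' @return List with `per_object` (tibble `object`, `class?`, `timepoint`,
#'   `rel_change`) and `by_class` (group mean, sd, n per class x timepoint;
#'   `NULL` when no `class` column).
#' @export
relative_change <- function(series, baseline) {
  if (!baseline %in% series$timepoint) {
    abort("baseline timepoint not present", class = "pp_config_error")
  }
  base <- series |>
    dplyr::filter(.data$timepoint == baseline) |>
    dplyr::select("object", baseline_intensity = "intensity")
  excluded <- base$object[base$baseline_intensity == 0]
  if (length(excluded)) {
    warn(sprintf("%d object(s) excluded: zero baseline", length(excluded)))
  }
  per <- series |>
    dplyr::inner_join(base, by = "object") |>
    dplyr::filter(.data$baseline_intensity > 0) |>
    dplyr::mutate(rel_change = .data$intensity / .data$baseline_intensity) |>
    dplyr::select(-"intensity", -"baseline_intensity")
  by_class <- NULL
  if ("class" %in% names(series)) {
    by_class <- per |>
      dplyr::group_by(.data$class, .data$timepoint) |>
      dplyr::summarise(mean = mean(.data$rel_change),
                       sd = if (dplyr::n() > 1) sd(.data$rel_change) else 0,
                       n = dplyr::n(), .groups = "drop")
  }
  out <- list(per_object = per, by_class = by_class)
  attr(out, "excluded") <- excluded
  out
}

#' Dye-accumulation classification of phagosomes
#'
#' Classifies phagosomes as dye-positive when their post-addition mean dye
#' intensity exceeds a threshold: either a fixed value or the pre-addition
#' background mean plus `k` background standard deviations (default k = 3).
#'
#' @param intensities tibble with one row per phagosome: `object`,
#'   `pre_mean` (mean dye intensity before addition), `post_mean` (after).
#' @param k threshold multiplier for the background rule.
#' @param threshold optional fixed threshold overriding the background rule.
#' @return List: `fraction_pct` (percent positive), `threshold`, `labels`
#'   (tibble `object`, `post_mean`, `dye_positive`), `n`.
#' @export
dye_positive_fraction <- function(intensities, k = 3, threshold = NULL) {
  stopifnot(all(c("object", "pre_mean", "post_mean") %in% names(intensities)))
  if (nrow(intensities) == 0) {
    abort("no phagosome intensities supplied", class = "pp_state_error")
  }
  if (any(!is.finite(intensities$post_mean))) {
    abort("post-addition intensities missing (no frames after dye addition?)",
          class = "pp_state_error")
  }
  if (is.null(threshold)) {
    bg <- intensities$pre_mean
    threshold <- mean(bg) + k * sd(bg)
  }
  labels <- tibble(object = intensities$object,
                   post_mean = intensities$post_mean,
                   dye_positive = intensities$post_mean > threshold)
  list(fraction_pct = 100 * mean(labels$dye_positive),
       threshold = threshold, labels = labels, n = nrow(labels))
}

#' Measure per-phagosome dye intensities in a simulated movie
#'
#' Reproduces the mask-based dye measurement: bacteria are segmented on the
#' prey channel and the mean dye intensity within each bacterial mask is
#' measured before and after the dye-addition frame. Masks are matched to
#' ground-truth phagosomes by centroid.
#'
#' @param movie a `pp_movie` with a `"dye"` channel (see [add_dye_channel()]).
#' @param truth the matching `pp_truth` log.
#' @param dye_add_frame frame at which dye was added.
#' @param n_measure number of frames averaged at each end (pre = the frames
#'   just before addition, post = the movie's final frames).
#' @return Tibble: `object` (global phagosome id), `fov`, `phagosome`,
#'   `pre_mean`, `post_mean`.
#' @export
measure_dye <- function(movie, truth, dye_add_frame, n_measure = 3) {
  stopifnot(inherits(movie, "pp_movie"), "dye" %in% movie$channels)
  nf <- n_frames(movie)
  fov <- movie$fov
  ph <- truth$phagosomes[truth$phagosomes$fov == fov, ]
  pre_frames <- seq(max(1, dye_add_frame - n_measure), max(1, dye_add_frame - 1))
  post_frames <- seq(max(dye_add_frame, nf - n_measure + 1), nf)
  sm <- smooth_box3(movie_frame(movie, nf, "prey"))  # all objects engulfed by then
  level <- detection_level(sm)
  lab <- segment_prey(sm, level, movie$voxel_size, frame_index = nf)
  # only bacteria inside the neutrophil are measured: clip each mask to the
  # cell interior so it cannot touch the extracellular dye pool
  nb_row <- truth$neutrophils[truth$neutrophils$fov == fov, ]
  d3 <- unname(dim(lab$labels))
  inside <- cell_mask_volume(
    c(nb_row$cell_x_um, nb_row$cell_y_um, nb_row$cell_z_um),
    nb_row$cell_radius_um, c(x = d3[2], y = d3[1], z = d3[3]),
    movie$voxel_size)
  lab$labels[!inside] <- 0L
  if (nrow(lab$table) == 0) {
    return(tibble(object = character(0), fov = integer(0),
                  phagosome = integer(0), pre_mean = numeric(0),
                  post_mean = numeric(0)))
  }
  # match labels to truth phagosomes by centroid
  cost <- outer(seq_len(nrow(lab$table)), seq_len(nrow(ph)),
                Vectorize(function(i, j) {
                  sqrt((lab$table$x_um[i] - ph$x_um[j])^2 +
                         (lab$table$y_um[i] - ph$y_um[j])^2 +
                         (lab$table$z_um[i] - ph$z_um[j])^2)
                }))
  big <- 1e9
  cost[cost > 2] <- big
  m <- .hungarian_cpp(cost, big)
  mask_mean <- function(frames, label) {
    idx <- which(lab$labels == label)
    mean(purrr::map_dbl(frames, function(t) {
      mean(movie_frame(movie, t, "dye")[idx])
    }))
  }
  rows <- purrr::map_dfr(which(!is.na(m)), function(i) {
    tibble(object = sprintf("fov%03d_ph%03d", fov, ph$phagosome[m[i]]),
           fov = fov, phagosome = ph$phagosome[m[i]],
           pre_mean = mask_mean(pre_frames, i),
           post_mean = mask_mean(post_frames, i))
  })
  rows
}

#' Peri-bacterial shell intensity ratio
#'
#' Quantifies an indicator channel in a thin shell around each segmented
#' bacterium (default 0.5 um, honouring anisotropic voxel sizes) and reports
#' its mean divided by the mean signal of reference (non-infected) phagocytes.
#'
#' @param volume indicator-channel 3-D volume.
#' @param prey a `pp_labels` object for the bacteria.
#' @param shell_um shell radius in micrometres (default 0.5).
#' @param reference numeric vector of reference phagocyte intensities.
#' @return Tibble: `label`, `shell_mean`, `shell_voxels`, `ratio`,
#'   `flagged` (TRUE when the shell is empty after clipping).
#' @export
dcf_shell_ratio <- function(volume, prey, shell_um = 0.5, reference) {
  stopifnot(inherits(prey, "pp_labels"))
  if (shell_um <= 0) abort("shell radius must be > 0", class = "pp_config_error")
  if (length(reference) == 0 || !all(is.finite(reference))) {
    abort("reference intensity set must be non-empty", class = "pp_config_error")
  }
  if (!identical(dim(volume), dim(prey$labels))) {
    abort("volume and labels must share geometry", class = "pp_shape_error")
  }
  vs <- prey$voxel_size
  d <- dim(volume)
  ref_mean <- mean(reference)
  purrr::map_dfr(seq_len(max(prey$labels, 0)), function(lb) {
    idx <- which(prey$labels == lb)
    iy <- (idx - 1) %% d[1] + 1
    ix <- ((idx - 1) %/% d[1]) %% d[2] + 1
    iz <- (idx - 1) %/% (d[1] * d[2]) + 1
    # candidate voxels in the dilated bounding box
    ry <- seq(max(1, min(iy) - ceiling(shell_um / vs["y"])),
              min(d[1], max(iy) + ceiling(shell_um / vs["y"])))
    rx <- seq(max(1, min(ix) - ceiling(shell_um / vs["x"])),
              min(d[2], max(ix) + ceiling(shell_um / vs["x"])))
    rz <- seq(max(1, min(iz) - ceiling(shell_um / vs["z"])),
              min(d[3], max(iz) + ceiling(shell_um / vs["z"])))
    cand <- expand.grid(y = ry, x = rx, z = rz)
    cidx <- cand$y + (cand$x - 1) * d[1] + (cand$z - 1) * d[1] * d[2]
    in_mask <- prey$labels[cidx] == lb
    # min Euclidean distance (um) from each candidate to the mask
    d2 <- outer(((cand$x - 1) * vs["x"]), ((ix - 1) * vs["x"]), "-")^2 +
      outer(((cand$y - 1) * vs["y"]), ((iy - 1) * vs["y"]), "-")^2 +
      outer(((cand$z - 1) * vs["z"]), ((iz - 1) * vs["z"]), "-")^2
    mind <- sqrt(apply(d2, 1, min))
    shell_idx <- cidx[!in_mask & mind <= shell_um]
    if (length(shell_idx) == 0) {
      tibble(label = lb, shell_mean = NA_real_, shell_voxels = 0L,
             ratio = NA_real_, flagged = TRUE)
    } else {
      sm <- mean(volume[shell_idx])
      tibble(label = lb, shell_mean = sm, shell_voxels = length(shell_idx),
             ratio = sm / ref_mean, flagged = FALSE)
    }
  })
}

#' Group comparison tests
#'
#' Standard comparisons for summary tables: Kruskal-Wallis across all groups
#' (with Dunn post-hoc pairwise z tests, Holm-adjusted), pairwise
#' Mann-Whitney, and unpaired Welch t-tests. The bespoke science lives
#' upstream; this is reporting plumbing over `stats` routines.
#'
#' @param df tibble with a value column and a group column.
#' @param value,group column names (strings).
#' @param tests subset of `c("kruskal", "dunn", "wilcox", "t")`.
#' @return Tidy tibble: `method`, `comparison`, `statistic`, `p_value`,
#'   `p_adjusted`, `n`, `flagged` (too-small groups for a t-test).
#' @export
compare_groups <- function(df, value = "value", group = "group",
                           tests = c("kruskal", "dunn", "wilcox", "t")) {
  v <- df[[value]]; g <- factor(df[[group]])
  if (nlevels(g) < 2) abort("need at least 2 groups", class = "pp_config_error")
  tests <- match.arg(tests, several.ok = TRUE)
  out <- list()
  if ("kruskal" %in% tests) {
    kt <- stats::kruskal.test(v, g)
    out$kruskal <- tibble(method = "kruskal_wallis", comparison = "all",
                          statistic = unname(kt$statistic),
                          p_value = kt$p.value, p_adjusted = NA_real_,
                          n = length(v), flagged = FALSE)
  }
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  if ("dunn" %in% tests) {
    out$dunn <- dunn_test(v, g)
  }
  if ("wilcox" %in% tests) {
    out$wilcox <- purrr::map_dfr(pairs, function(p) {
      a <- v[g == p[1]]; b <- v[g == p[2]]
      wt <- suppressWarnings(stats::wilcox.test(a, b))
      tibble(method = "mann_whitney", comparison = paste(p, collapse = " vs "),
             statistic = unname(wt$statistic), p_value = wt$p.value,
             p_adjusted = NA_real_, n = length(a) + length(b), flagged = FALSE)
    })
  }
  if ("t" %in% tests) {
    out$t <- purrr::map_dfr(pairs, function(p) {
      a <- v[g == p[1]]; b <- v[g == p[2]]
      if (length(a) < 2 || length(b) < 2) {
        return(tibble(method = "t_test", comparison = paste(p, collapse = " vs "),
                      statistic = NA_real_, p_value = NA_real_,
                      p_adjusted = NA_real_, n = length(a) + length(b),
                      flagged = TRUE))
      }
      tt <- stats::t.test(a, b)
      tibble(method = "t_test", comparison = paste(p, collapse = " vs "),
             statistic = unname(tt$statistic), p_value = tt$p.value,
             p_adjusted = NA_real_, n = length(a) + length(b), flagged = FALSE)
    })
  }
  dplyr::bind_rows(out)
}

# Dunn's pairwise z tests on joint ranks with tie correction, Holm-adjusted
dunn_test <- function(v, g) {
  r <- rank(v)
  n <- length(v)
  ties <- table(v)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  s2 <- n * (n + 1) / 12 - tie_corr
  lv <- levels(g)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(p) {
    ra <- r[g == p[1]]; rb <- r[g == p[2]]
    z <- (mean(ra) - mean(rb)) /
      sqrt(s2 * (1 / length(ra) + 1 / length(rb)))
    tibble(method = "dunn", comparison = paste(p, collapse = " vs "),
           statistic = z, p_value = 2 * stats::pnorm(-abs(z)),
           n = length(ra) + length(rb), flagged = FALSE)
  })
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "holm")
  res[, c("method", "comparison", "statistic", "p_value", "p_adjusted",
          "n", "flagged")]
}

#' Percentages with exact binomial confidence intervals for event tallies
#'
#' Converts numerator/denominator event counts (e.g. re-openings visualised
#' per pulse examined) into percentages at a chosen printed precision with
#' Clopper-Pearson 95% confidence intervals.
#'
#' @param tally tibble with columns `name`, `numerator`, `denominator` and
#'   optionally `digits` (decimal places for the printed percentage,
#'   default 1).
#' @return Tibble: `name`, `numerator`, `denominator`, `pct` (rounded to
#'   `digits`), `ci_lo_pct`, `ci_hi_pct`.
#' @export
tally_statistics <- function(tally) {
  stopifnot(all(c("name", "numerator", "denominator") %in% names(tally)))
  if (any(tally$denominator <= 0)) {
    abort("tally denominators must be > 0", class = "pp_config_error")
  }
  if (any(tally$numerator > tally$denominator | tally$numerator < 0)) {
    abort("tally numerators must lie in [0, denominator]",
          class = "pp_config_error")
  }
  digits <- if ("digits" %in% names(tally)) tally$digits else rep(1L, nrow(tally))
  purrr::pmap_dfr(list(tally$name, tally$numerator, tally$denominator, digits),
                  function(nm, num, den, dg) {
                    ci <- stats::binom.test(num, den)$conf.int
                    tibble(name = nm, numerator = num, denominator = den,
                           pct = round(100 * num / den, dg),
                           ci_lo_pct = 100 * ci[1], ci_hi_pct = 100 * ci[2])
                  })
}

#' Read a packaged or external event-tally file
#'
#' @param path path to a YAML tally file; the default is the packaged
#'   transcription of the reference in vivo event counts.
#' @return Tibble suitable for [tally_statistics()].
#' @export
read_event_tally <- function(path = system.file("extdata", "event_tallies.yaml",
                                                package = "phagopulse")) {
  y <- yaml::read_yaml(path)
  purrr::map_dfr(y$tallies, function(e) {
    tibble(name = e$name, numerator = e$numerator,
           denominator = e$denominator, digits = e$digits %||% 1L,
           expected_pct = e$expected_pct %||% NA_real_)
  })
}
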