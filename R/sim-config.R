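#' Simulation configuration for synthetic phagosome movies
#'
#' Builds and validates the parameter set for the ground-truthed movie
#' generator. The defaults describe the cohort the package treats as its
#' reference condition: neutrophils carrying 1-25 bacteria-bearing phagosomes
#' whose membrane reporter surges at cup closure, fades exponentially, and on
#' a 12.4% subset re-surges in pulses starting a median of ~10.5 min after
#' engulfment (up to 18 pulses, typically four); 20.1% of phagosomes are
#' "leaky" (unsealed, able to accumulate extracellular dye).
#'
#' @param shape named integer vector `c(x=, y=, z=)`, image size in voxels.
#' @param voxel_size named numeric `c(x=, y=, z=)`, micrometres per voxel.
#'   The default 1.5 um z step matches spinning-disk z-stacks of tissue;
#'   the xy size (0.33 um) is a documented convention for a 40x EM-CCD setup.
#' @param frame_interval_s seconds between frames.
#' @param n_frames movie duration in frames (>= 2).
#' @param n_neutrophils number of neutrophils; one field of view (movie) is
#'   generated per neutrophil.
#' @param phagosome_mean mean of the (truncated geometric) phagosomes-per-
#'   neutrophil distribution.
#' @param phagosome_range inclusive support of the phagosome count.
#' @param phagosomes_fixed if not `NULL`, every neutrophil gets exactly this
#'   many phagosomes (overrides the distribution).
#' @param p_pulse per-phagosome probability of being a pulsing phagosome.
#' @param pulse_count_mean mean pulses per pulsing phagosome; counts are drawn
#'   as `1 + Poisson(pulse_count_mean - 1)` truncated to `pulse_count_range`
#'   (mode near 4 at the default).
#' @param pulse_count_range inclusive support of the pulse count.
#' @param pulse_count_fixed if not `NULL`, fixed pulses per pulsing phagosome.
#' @param latency_mean_min,latency_sd_min mean and s.d. (minutes) of the
#'   first-pulse latency; drawn from a lognormal moment-matched to these.
#' @param latency_floor_min minimum realisable latency (minutes): a pulse is
#'   re-recruitment after the closure surge has faded, so it cannot precede
#'   the fade.
#' @param pulse_gap_mean_min mean gap (minutes) between successive pulses.
#' @param pulse_min_gap_frames minimum gap between pulse onsets, frames.
#' @param p_open per-pulse probability that the phagosome visibly re-opens
#'   (a pore is rendered) during the pulse.
#' @param open_interval_frames duration of a pulse-associated open interval.
#' @param pore_angle_deg angular width of the rendered pore sector.
#' @param p_leak per-phagosome probability of being unsealed ("leaky"):
#'   leaky phagosomes carry an open interval spanning their whole lifetime
#'   and accumulate extracellular dye once it is added.
#' @param surge_amplitude closure-surge amplitude (arbitrary units).
#' @param fade_tau_s exponential fade time constant, seconds.
#' @param fade_plateau residual membrane signal after fading, as a fraction
#'   of the surge amplitude.
#' @param pulse_amplitude pulse amplitude relative to the closure surge.
#' @param pulse_rise_frames linear rise time of surge and pulses, frames.
#' @param pulse_tau_s pulse decay time constant, seconds.
#' @param phagosome_radius_um phagosome (membrane shell) radius.
#' @param shell_sigma_um Gaussian cross-section of the rendered shell.
#' @param prey_radius_um radius of the solid prey (bacterium) sphere.
#' @param z_psf_um axial blur scale (um): objects are rendered with an
#'   axially elongated profile emulating the axial PSF plus slab integration
#'   of a confocal z-step, so sub-slice objects remain visible between
#'   slices.
#' @param prey_amplitude prey channel amplitude at neutral (tissue) pH.
#' @param ph_map list mapping phagosome state to prey-channel brightness
#'   factors; see Details.
#' @param cell_intensity cytoplasmic reporter intensity of the neutrophil.
#' @param background camera background level (all channels).
#' @param min_separation_um minimum in-plane (xy) distance between phagosome
#'   centres, chosen so objects stay separable after 3x3x3 smoothing at the
#'   anisotropic z step.
#' @param drift_px_per_frame constant-velocity drift of the whole cell,
#'   xy pixels per frame (0 = static).
#' @param snr closure-surge amplitude divided by the additive (read) noise
#'   standard deviation; `Inf` disables read noise.
#' @param shot_factor scale of the signal-dependent (Poisson-like) noise
#'   variance; 0 disables it.
#' @param engulf_window_frames inclusive frame window for engulfment times.
#' @param channels channels to render, subset of
#'   `c("reporter", "prey")` (a dye channel is added by [add_dye_channel()]).
#' @param dye_amplitude extracellular dye intensity after addition.
#' @param dye_tau_frames time constant (frames) of dye influx into leaky
#'   phagosomes.
#' @param seed integer seed fixing all randomness end-to-end.
#'
#' @details
#' The prey channel emulates a pH reporter on the bacteria: brightness is
#' `ph_map$pre` before engulfment, dips towards `ph_map$alkaline` while the
#' phagosome is sealed and alkaline (reaching the dip at `dip_full_min`
#' minutes post engulfment and recovering to `recovered` between
#' `recover_start_min` and `recover_full_min`), stays near `ph_map$pulsing`
#' on pulsing or leaky phagosomes, and equals `ph_map$open` during open
#' intervals.
#'
#' @return A validated `pp_sim_config` list.
#' @export
sim_config <- function(shape = c(x = 68L, y = 68L, z = 12L),
                       voxel_size = c(x = 0.33, y = 0.33, z = 1.5),
                       frame_interval_s = 30,
                       n_frames = 120L,
                       n_neutrophils = 4L,
                       phagosome_mean = 3,
                       phagosome_range = c(1L, 25L),
                       phagosomes_fixed = NULL,
                       p_pulse = 0.124,
                       pulse_count_mean = 4,
                       pulse_count_range = c(1L, 18L),
                       pulse_count_fixed = NULL,
                       latency_mean_min = 10.5,
                       latency_sd_min = 12.49,
                       latency_floor_min = 5,
                       pulse_gap_mean_min = 5,
                       pulse_min_gap_frames = 10L,
                       p_open = 0.196,
                       open_interval_frames = 3L,
                       pore_angle_deg = 60,
                       p_leak = 0.201,
                       surge_amplitude = 1,
                       fade_tau_s = 90,
                       fade_plateau = 0.25,
                       pulse_amplitude = 0.8,
                       pulse_rise_frames = 2L,
                       pulse_tau_s = 90,
                       phagosome_radius_um = 1,
                       shell_sigma_um = 0.25,
                       prey_radius_um = 0.5,
                       z_psf_um = 0.5,
                       prey_amplitude = 1.6,
                       ph_map = list(pre = 1, alkaline = 0.6, open = 1,
                                     pulsing = 0.95, recovered = 0.9,
                                     dip_start_min = 2, dip_full_min = 10,
                                     recover_start_min = 30,
                                     recover_full_min = 60),
                       cell_intensity = 0.12,
                       background = 0.02,
                       min_separation_um = 2.5,
                       drift_px_per_frame = 0,
                       snr = 8,
                       shot_factor = 0.01,
                       engulf_window_frames = c(2L, 8L),
                       channels = c("reporter", "prey"),
                       dye_amplitude = 0.6,
                       dye_tau_frames = 2,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pp_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(msg, class = "pp_config_error")
  chk(length(cfg$shape) == 3 && all(cfg$shape >= 4),
      "shape must give x, y, z sizes of at least 4 voxels")
  names(cfg$shape) <- c("x", "y", "z")
  chk(all(cfg$voxel_size > 0), "voxel sizes must be > 0")
  names(cfg$voxel_size) <- c("x", "y", "z")
  chk(cfg$frame_interval_s > 0, "frame interval must be > 0")
  chk(cfg$n_frames >= 2, "duration must be at least 2 frames")
  chk(cfg$n_neutrophils >= 1, "need at least one neutrophil")
  for (p in c("p_pulse", "p_open", "p_leak")) {
    chk(is.numeric(cfg[[p]]) && length(cfg[[p]]) == 1 &&
          cfg[[p]] >= 0 && cfg[[p]] <= 1,
        sprintf("%s must be a probability in [0, 1]", p))
  }
  chk(cfg$phagosome_mean > 0, "phagosome_mean must be > 0")
  chk(length(cfg$phagosome_range) == 2 &&
        cfg$phagosome_range[1] >= 1 &&
        diff(cfg$phagosome_range) >= 0,
      "phagosome_range must be an increasing pair with minimum >= 1")
  chk(is.null(cfg$phagosomes_fixed) ||
        (cfg$phagosomes_fixed >= 1), "phagosomes_fixed must be >= 1")
  chk(cfg$pulse_count_mean >= 1, "pulse_count_mean must be >= 1")
  chk(length(cfg$pulse_count_range) == 2 && cfg$pulse_count_range[1] >= 1 &&
        diff(cfg$pulse_count_range) >= 0,
      "pulse_count_range must be an increasing pair with minimum >= 1")
  chk(cfg$latency_mean_min > 0 && cfg$latency_sd_min >= 0,
      "latency distribution parameters must be positive")
  chk(cfg$latency_floor_min >= 0, "latency_floor_min must be >= 0")
  chk(cfg$pulse_gap_mean_min > 0, "pulse_gap_mean_min must be > 0")
  chk(cfg$open_interval_frames >= 1, "open_interval_frames must be >= 1")
  chk(cfg$pore_angle_deg > 0 && cfg$pore_angle_deg < 360,
      "pore_angle_deg must be in (0, 360)")
  chk(cfg$fade_tau_s > 0 && cfg$pulse_tau_s > 0, "time constants must be > 0")
  chk(cfg$fade_plateau >= 0 && cfg$fade_plateau < 1,
      "fade_plateau must be in [0, 1)")
  chk(cfg$surge_amplitude > 0, "surge_amplitude must be > 0")
  chk(cfg$pulse_amplitude > 0, "pulse_amplitude must be > 0")
  chk(cfg$phagosome_radius_um > 0 && cfg$shell_sigma_um > 0 &&
        cfg$prey_radius_um > 0, "geometry radii must be > 0")
  chk(cfg$z_psf_um > 0, "z_psf_um must be > 0")
  chk(cfg$prey_radius_um < cfg$phagosome_radius_um,
      "prey must fit inside the phagosome")
  chk(cfg$min_separation_um > 0, "min_separation_um must be > 0")
  chk(cfg$snr > 0, "snr must be > 0 (use Inf for no read noise)")
  chk(cfg$shot_factor >= 0, "shot_factor must be >= 0")
  chk(length(cfg$engulf_window_frames) == 2 &&
        cfg$engulf_window_frames[1] >= 1 &&
        cfg$engulf_window_frames[2] <= cfg$n_frames &&
        diff(cfg$engulf_window_frames) >= 0,
      "engulf_window_frames must lie within the movie duration")
  chk(all(cfg$channels %in% c("reporter", "prey")) && length(cfg$channels) >= 1,
      "channels must be a subset of c('reporter', 'prey')")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && is.finite(cfg$seed),
      "seed must be a single integer")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Turn off all noise sources in a simulation config
#'
#' @param config a [sim_config()] object.
#' @return The config with read and shot noise disabled.
#' @export
noise_free <- function(config) {
  config$snr <- Inf
  config$shot_factor <- 0
  validate_sim_config(config)
}

# moment-matched lognormal parameters for a positive latency distribution
lognormal_params <- function(mean, sd) {
  if (sd <= 0) return(list(meanlog = log(mean), sdlog = 0))
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}
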