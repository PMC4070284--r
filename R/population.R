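# Synthetic neuron populations: ground-truth tuning parameters per treatment
# group and stochastic (Poisson) responses to gratings, noise movies, and a
# forward model for intrinsic-signal imaging.

.group_labels <- c("non-deprived", "LTMD", "home-cage", "noise+run",
                   "grating+run")

#' Treatment-group effect profile
#'
#' Multipliers applied to the base parameter distributions of a simulated
#' population. They encode the qualitative group contrasts of the recovery
#' experiment: long-term monocular deprivation (LTMD) suppresses deprived-eye
#' (contra) gains and broadens tuning; recovery with a given stimulus during
#' locomotion restores mainly the gain for that stimulus; home-cage recovery
#' is slow. The numbers are documented package defaults, not measured effect
#' sizes.
#'
#' @param group One of `"non-deprived"`, `"LTMD"`, `"home-cage"`,
#'   `"noise+run"`, `"grating+run"`.
#' @return A list of class `group_effect_profile` with fields
#'   `grating_gain_contra`, `noise_gain_contra`, `spont_broad`,
#'   `spont_narrow`, `mismatch_sd_deg`, `osi_scale`, `group`.
#' @export
group_effect_profile <- function(group = "non-deprived") {
  if (inherits(group, "group_effect_profile")) return(group)
  if (!is.character(group) || length(group) != 1L ||
      !(group %in% .group_labels)) {
    stop("unknown group label; expected one of: ",
         paste(.group_labels, collapse = ", "))
  }
  p <- switch(group,
    "non-deprived" = list(grating_gain_contra = 1,    noise_gain_contra = 1,
                          spont_broad = 1,   spont_narrow = 1,
                          mismatch_sd_deg = 15, osi_scale = 1),
    "LTMD"         = list(grating_gain_contra = 0.25, noise_gain_contra = 0.25,
                          spont_broad = 1.5, spont_narrow = 0.4,
                          mismatch_sd_deg = 40, osi_scale = 0.6),
    "home-cage"    = list(grating_gain_contra = 0.35, noise_gain_contra = 0.35,
                          spont_broad = 1.3, spont_narrow = 0.45,
                          mismatch_sd_deg = 35, osi_scale = 0.65),
    "noise+run"    = list(grating_gain_contra = 0.5,  noise_gain_contra = 0.9,
                          spont_broad = 1.1, spont_narrow = 0.45,
                          mismatch_sd_deg = 35, osi_scale = 0.7),
    "grating+run"  = list(grating_gain_contra = 0.9,  noise_gain_contra = 0.5,
                          spont_broad = 1.1, spont_narrow = 0.5,
                          mismatch_sd_deg = 18, osi_scale = 0.9))
  p$group <- group
  structure(p, class = "group_effect_profile")
}

#' Sample a ground-truth neuron population
#'
#' Draws latent tuning and gain parameters for `n_units` simulated V1 units.
#' Roughly 80% of units are broad-spiking (putative excitatory), 20%
#' narrow-spiking (putative fast-spiking inhibitory). Contra is the deprived
#' eye in deprived groups; group multipliers act on contra-eye grating and
#' noise gains, on spontaneous rates by cell class, on the binocular
#' orientation mismatch spread, and (via tuning width) on orientation
#' selectivity.
#'
#' @param n_units Number of units (>= 1).
#' @param group Group label or [group_effect_profile()].
#' @param seed Integer seed.
#' @param broad_fraction Expected fraction of broad-spiking units.
#' @return A `data.frame`, one row per unit, with columns `unit_id`,
#'   `cell_class`, `eye_gain_contra`, `eye_gain_ipsi`, `theta_pref_contra`,
#'   `theta_pref_ipsi`, `tuning_sigma`, `dir_ratio`, `sf_pref_cpd`,
#'   `sf_sigma_oct`, `c50`, `hill_n`, `spont_rate`, `noise_gain_contra`,
#'   `noise_gain_ipsi`; attribute `group`.
#' @export
sample_population <- function(n_units, group = "non-deprived", seed = 1L,
                              broad_fraction = 0.8) {
  if (!is.numeric(n_units) || length(n_units) != 1L || n_units < 1) {
    stop("n_units must be >= 1")
  }
  n_units <- as.integer(n_units)
  prof <- group_effect_profile(group)
  set.seed(seed)

  cell_class <- ifelse(stats::runif(n_units) < broad_fraction,
                       "broad", "narrow")
  theta_c <- stats::runif(n_units, 0, 180)
  theta_i <- (theta_c + stats::rnorm(n_units, 0, prof$mismatch_sd_deg)) %% 180
  sigma <- pmin(stats::runif(n_units, 15, 35) / prof$osi_scale, 80)

  spont_base <- ifelse(cell_class == "broad",
                       stats::rlnorm(n_units, log(2), 0.7),
                       stats::rlnorm(n_units, log(5), 0.7))
  spont_mult <- ifelse(cell_class == "broad", prof$spont_broad,
                       prof$spont_narrow)

  units <- data.frame(
    unit_id = seq_len(n_units),
    cell_class = cell_class,
    eye_gain_contra = stats::rlnorm(n_units, log(10), 0.6) *
      prof$grating_gain_contra,
    eye_gain_ipsi = stats::rlnorm(n_units, log(8), 0.6),
    theta_pref_contra = theta_c,
    theta_pref_ipsi = theta_i,
    tuning_sigma = sigma,
    dir_ratio = stats::rbeta(n_units, 2, 2),
    sf_pref_cpd = pmin(pmax(stats::rlnorm(n_units, log(0.04), log(2)),
                            0.005), 0.5),
    sf_sigma_oct = stats::runif(n_units, 1, 2.5),
    c50 = pmin(pmax(stats::rbeta(n_units, 3, 6), 0.05), 0.95),
    hill_n = stats::runif(n_units, 1.5, 3),
    spont_rate = spont_base * spont_mult,
    noise_gain_contra = stats::rlnorm(n_units, log(10), 0.6) *
      prof$noise_gain_contra,
    noise_gain_ipsi = stats::rlnorm(n_units, log(8), 0.6),
    stringsAsFactors = FALSE)
  attr(units, "group") <- prof$group
  units
}

# Circularly wrapped Gaussian bump on the 360-degree direction axis:
# sum of images at delta + 360 k, k in {-1, 0, 1}; delta in degrees.
wrapped_gauss <- function(delta_deg, sigma_deg) {
  d <- ((delta_deg + 180) %% 360) - 180
  exp(-d^2 / (2 * sigma_deg^2)) +
    exp(-(d - 360)^2 / (2 * sigma_deg^2)) +
    exp(-(d + 360)^2 / (2 * sigma_deg^2))
}

# Direction profile with peaks (amplitudes 1 and dir_ratio) at theta_pref and
# theta_pref + 180, shared width.
direction_profile <- function(direction_deg, theta_pref_deg, sigma_deg,
                              dir_ratio) {
  wrapped_gauss(direction_deg - theta_pref_deg, sigma_deg) +
    dir_ratio * wrapped_gauss(direction_deg - theta_pref_deg - 180, sigma_deg)
}

# Log-Gaussian spatial-frequency profile with peak 1 at sf_pref; width in
# octaves. Zero response to blanks (sf = 0).
sf_profile <- function(sf_cpd, sf_pref_cpd, sf_sigma_oct) {
  n <- length(sf_cpd)
  pref <- rep_len(sf_pref_cpd, n)
  sig <- rep_len(sf_sigma_oct, n)
  out <- numeric(n)
  pos <- sf_cpd > 0
  out[pos] <- exp(-(log2(sf_cpd[pos] / pref[pos]))^2 / (2 * sig[pos]^2))
  out
}

#' Simulate grating trials for a population
#'
#' Forward model: per-trial firing rate
#' `spont + gain_eye * G(direction) * S(sf)` where `G` is the double wrapped
#' Gaussian direction profile (peaks at the eye's preferred orientation and
#' its opposite direction, amplitudes 1 and `dir_ratio`, shared width) and
#' `S` the log-Gaussian spatial-frequency profile; blank trials fire at the
#' spontaneous rate. Spike counts are Poisson with mean `rate * duration`.
#'
#' @param units Population `data.frame` from [sample_population()] (or any
#'   data frame with the same columns); may be a single row.
#' @param protocol Trial protocol from [build_grating_protocol()].
#' @param seed Integer seed.
#' @return A trial table `data.frame` with columns `unit_id`, `eye`,
#'   `direction_deg`, `sf_cpd`, `is_blank`, `trial_index`, `spike_count`,
#'   `duration_s`.
#' @export
simulate_grating_trials <- function(units, protocol, seed = 1L) {
  stopifnot(is.data.frame(units), is.data.frame(protocol),
            all(c("eye", "direction_deg", "sf_cpd", "is_blank",
                  "trial_index", "duration_s") %in% names(protocol)))
  set.seed(seed)
  nu <- nrow(units)
  ntr <- nrow(protocol)

  # long layout: protocol repeated per unit
  uidx <- rep(seq_len(nu), each = ntr)
  p <- protocol[rep(seq_len(ntr), times = nu), ]

  contra <- p$eye == "contra"
  gain <- ifelse(contra, units$eye_gain_contra[uidx],
                 units$eye_gain_ipsi[uidx])
  theta <- ifelse(contra, units$theta_pref_contra[uidx],
                  units$theta_pref_ipsi[uidx])
  G <- direction_profile(p$direction_deg, theta, units$tuning_sigma[uidx],
                         units$dir_ratio[uidx])
  S <- sf_profile(p$sf_cpd, units$sf_pref_cpd[uidx],
                  units$sf_sigma_oct[uidx])
  rate <- units$spont_rate[uidx] + ifelse(p$is_blank, 0, gain * G * S)
  rate <- pmax(rate, 0)

  data.frame(unit_id = units$unit_id[uidx],
             eye = p$eye,
             direction_deg = p$direction_deg,
             sf_cpd = p$sf_cpd,
             is_blank = p$is_blank,
             trial_index = p$trial_index,
             spike_count = stats::rpois(length(rate), rate * p$duration_s),
             duration_s = p$duration_s,
             stringsAsFactors = FALSE)
}

#' Simulate binned spike counts in response to the noise movie
#'
#' The firing rate follows the contrast envelope through a Naka-Rushton (Hill)
#' nonlinearity: `rate(t) = spont + gain * c(t)^n / (c(t)^n + c50^n)` with
#' `c(t)` the movie's contrast trace; counts are an inhomogeneous Poisson
#' process discretized at the frame rate. If `duration_s` exceeds the movie
#' duration, the movie (and hence the periodic contrast trace) repeats, as in
#' prolonged presentations of a short movie.
#'
#' @param units Population `data.frame` (one or more rows).
#' @param movie A `stimulus_movie` (only `contrast_trace` and `fps` are used
#'   by the rate model).
#' @param eye `"contra"` or `"ipsi"`: which eye's noise gain drives the unit.
#' @param duration_s Simulated duration; defaults to the movie duration.
#' @param seed Integer seed.
#' @return A matrix of spike counts, `n_units x n_bins`, with attributes
#'   `dt` (bin width, s), `period_s` (contrast period) and rownames set to
#'   `unit_id`.
#' @export
simulate_noise_response <- function(units, movie, eye = "contra",
                                    duration_s = NULL, seed = 1L) {
  stopifnot(is.data.frame(units), !is.null(movie$contrast_trace))
  eye <- match.arg(eye, c("contra", "ipsi"))
  set.seed(seed)
  fps <- movie$fps
  ctr <- movie$contrast_trace
  if (is.null(duration_s)) duration_s <- length(ctr) / fps
  nbin <- as.integer(round(duration_s * fps))
  cvec <- ctr[((seq_len(nbin) - 1) %% length(ctr)) + 1]

  gain <- if (eye == "contra") units$noise_gain_contra else
    units$noise_gain_ipsi
  # rate matrix n_units x n_bins
  hill <- function(cc, c50, n) cc^n / (cc^n + c50^n)
  rate <- units$spont_rate +
    gain * t(vapply(seq_len(nrow(units)),
                    function(i) hill(cvec, units$c50[i], units$hill_n[i]),
                    numeric(nbin)))
  rate <- pmax(rate, 0)
  counts <- matrix(stats::rpois(length(rate), rate / fps),
                   nrow = nrow(units))
  rownames(counts) <- units$unit_id
  attr(counts, "dt") <- 1 / fps
  attr(counts, "period_s") <- movie$contrast_period_s
  counts
}

# Default waveform-feature distributions per cell class (ms, a.u./ms).
.waveform_params <- list(
  broad = list(t2p_mean = 0.75, t2p_sd = 0.12, slope_mean = 0.06,
               slope_sd = 0.03),
  narrow = list(t2p_mean = 0.33, t2p_sd = 0.07, slope_mean = -0.05,
                slope_sd = 0.025))

#' Sample extracellular waveform features
#'
#' Draws (trough-to-peak time, waveform slope 0.5 ms after the trough) pairs
#' from class-specific bivariate normal distributions. The defaults separate
#' the classes so the two-criterion classifier in [classify_waveform()]
#' recovers the true class for >= 95% of draws.
#'
#' @param cell_class Character vector of `"broad"` / `"narrow"` labels.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `cell_class`, `trough_to_peak_ms`,
#'   `slope_05ms`.
#' @export
sample_waveform_features <- function(cell_class, seed = 1L) {
  if (!all(cell_class %in% c("broad", "narrow"))) {
    stop("cell_class entries must be 'broad' or 'narrow'")
  }
  set.seed(seed)
  n <- length(cell_class)
  p <- .waveform_params
  broad <- cell_class == "broad"
  t2p <- ifelse(broad,
                stats::rnorm(n, p$broad$t2p_mean, p$broad$t2p_sd),
                stats::rnorm(n, p$narrow$t2p_mean, p$narrow$t2p_sd))
  slope <- ifelse(broad,
                  stats::rnorm(n, p$broad$slope_mean, p$broad$slope_sd),
                  stats::rnorm(n, p$narrow$slope_mean, p$narrow$slope_sd))
  data.frame(cell_class = cell_class,
             trough_to_peak_ms = pmax(t2p, 0.05),
             slope_05ms = slope,
             stringsAsFactors = FALSE)
}

#' Simulate an intrinsic-signal imaging movie
#'
#' Forward model for the periodic-stimulus imaging analysis: each pixel
#' oscillates as `A(x, y) * sin(2 pi f t + phi(x, y))`, plus slow drift (a
#' per-pixel random linear trend and a one-cycle-per-recording cosine of
#' random phase, both scaled by `drift_scale`) and white Gaussian noise of
#' standard deviation `noise_scale`.
#'
#' @param amplitude_map Matrix of ground-truth response amplitudes `A(x, y)`.
#' @param stim_freq_hz Stimulus frequency, Hz; must be below `fps / 2`.
#' @param fps Frame rate, frames/s.
#' @param duration_s Recording duration, seconds.
#' @param phase_map Optional matrix of ground-truth phases, radians
#'   (default 0).
#' @param drift_scale Drift magnitude, same units as the amplitude map.
#' @param noise_scale White-noise standard deviation.
#' @param seed Integer seed.
#' @return An object of class `imaging_movie`: list with `frames`
#'   (`ny x nx x nt`), `fps`, `stim_freq_hz`, and `truth` (the amplitude and
#'   phase maps).
#' @export
simulate_imaging_movie <- function(amplitude_map, stim_freq_hz, fps,
                                   duration_s, phase_map = NULL,
                                   drift_scale = 0, noise_scale = 0,
                                   seed = 1L) {
  stopifnot(is.matrix(amplitude_map))
  if (stim_freq_hz >= fps / 2) {
    stop("stim_freq_hz must be below the Nyquist frequency fps/2")
  }
  set.seed(seed)
  ny <- nrow(amplitude_map)
  nx <- ncol(amplitude_map)
  nt <- as.integer(round(fps * duration_s))
  if (is.null(phase_map)) phase_map <- matrix(0, ny, nx)
  stopifnot(dim(phase_map) == dim(amplitude_map))

  tt <- (seq_len(nt) - 1) / fps
  npx <- ny * nx
  # npx x nt signal
  sig <- matrix(amplitude_map, npx, nt) *
    sin(2 * pi * stim_freq_hz * rep(tt, each = npx) +
          matrix(phase_map, npx, nt))
  if (drift_scale > 0) {
    slope <- stats::rnorm(npx)
    ph <- stats::runif(npx, 0, 2 * pi)
    ramp <- (tt - mean(tt)) / max(duration_s, 1)
    sig <- sig + drift_scale * (outer(slope, ramp) +
      cos(2 * pi * rep(tt, each = npx) / duration_s + ph))
  }
  if (noise_scale > 0) {
    sig <- sig + stats::rnorm(length(sig), 0, noise_scale)
  }
  frames <- array(sig, dim = c(ny, nx, nt))
  structure(list(frames = frames, fps = fps, stim_freq_hz = stim_freq_hz,
                 truth = list(amplitude = amplitude_map, phase = phase_map)),
            class = "imaging_movie")
}
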