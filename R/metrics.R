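# Per-unit response metrics: spontaneous/evoked rates, preferred orientation,
# orientation and spatial-frequency tuning fits, OSI, tuning width, binocular
# mismatch, ODI, F1 response to contrast-modulated noise, contrast
# sensitivity, and waveform classification.

#' Spontaneous firing rate from blank trials
#'
#' Mean of `spike_count / duration_s` over all blank-condition presentations.
#'
#' @param trials Trial table (columns `unit_id`, `is_blank`, `spike_count`,
#'   `duration_s`).
#' @param unit_id Optional unit to select; by default all rows are used.
#' @return Rate in spikes/s.
#' @export
spontaneous_rate <- function(trials, unit_id = NULL) {
  if (!is.null(unit_id)) trials <- trials[trials$unit_id == unit_id, ]
  bl <- trials[trials$is_blank, ]
  if (nrow(bl) == 0L) {
    stop("no blank trials: spontaneous rate (baseline) is undefined")
  }
  mean(bl$spike_count / bl$duration_s)
}

#' Baseline-subtracted evoked response for one condition
#'
#' Mean firing rate over trials of the given (eye, direction, spatial
#' frequency) condition minus the spontaneous rate. Negative values
#' (suppression) are preserved.
#'
#' @param trials Trial table.
#' @param unit_id Unit to select.
#' @param eye,direction_deg,sf_cpd Condition.
#' @param spont Optional precomputed spontaneous rate (spikes/s).
#' @return Evoked rate in spikes/s.
#' @export
evoked_response <- function(trials, unit_id, eye, direction_deg, sf_cpd,
                            spont = NULL) {
  tr <- trials[trials$unit_id == unit_id & trials$eye == eye &
                 !trials$is_blank & trials$direction_deg == direction_deg &
                 trials$sf_cpd == sf_cpd, ]
  if (nrow(tr) == 0L) stop("unknown condition: no matching trials")
  if (is.null(spont)) spont <- spontaneous_rate(trials, unit_id)
  mean(tr$spike_count / tr$duration_s) - spont
}

# Evoked-response table for one unit and eye: mean baseline-subtracted rate
# per (direction, sf) condition.
evoked_table <- function(trials, unit_id, eye, spont = NULL) {
  tr <- trials[trials$unit_id == unit_id, ]
  if (is.null(spont)) spont <- spontaneous_rate(tr)
  tr <- tr[tr$eye == eye & !tr$is_blank, ]
  if (nrow(tr) == 0L) {
    return(data.frame(direction_deg = numeric(0), sf_cpd = numeric(0),
                      evoked = numeric(0)))
  }
  agg <- stats::aggregate(cbind(rate = spike_count / duration_s) ~
                            direction_deg + sf_cpd, data = tr, FUN = mean)
  data.frame(direction_deg = agg$direction_deg, sf_cpd = agg$sf_cpd,
             evoked = agg$rate - spont)
}

#' Preferred orientation by complex vector averaging
#'
#' Half the complex phase of `sum(F(theta) * exp(2 i theta))` over the tested
#' directions, with `F` the (typically baseline-subtracted) response averaged
#' across spatial frequencies; the result is mapped into `[0, 180)` degrees.
#'
#' @param directions_deg Stimulus directions, degrees.
#' @param responses Responses `F(theta)`, spikes/s (may be negative when
#'   baseline-subtracted).
#' @param tol Relative tolerance below which the resultant is treated as zero
#'   (perfect symmetry) and the preference declared undefined.
#' @return Preferred orientation in degrees, `[0, 180)`.
#' @export
preferred_orientation <- function(directions_deg, responses, tol = 1e-8) {
  stopifnot(length(directions_deg) == length(responses))
  if (length(unique(directions_deg %% 180)) < 2L) {
    stop("need at least 2 distinct orientations")
  }
  z <- sum(responses * exp(2i * directions_deg * pi / 180))
  if (Mod(z) <= tol * (sum(abs(responses)) + .Machine$double.eps)) {
    stop("undefined orientation preference: resultant vector is zero")
  }
  (Arg(z) / 2 * 180 / pi) %% 180
}

# Double wrapped-Gaussian tuning model over the 360-degree direction domain.
tuning_model <- function(direction_deg, theta_pref, A1, A2, sigma, B) {
  B + A1 * wrapped_gauss(direction_deg - theta_pref, sigma) +
    A2 * wrapped_gauss(direction_deg - theta_pref - 180, sigma)
}

#' Fit the orientation tuning curve
#'
#' Bounded nonlinear least squares of
#' `B + A1 g(theta; theta_pref, sigma) + A2 g(theta; theta_pref + 180, sigma)`
#' with circularly wrapped Gaussians `g` of shared width, the preferred
#' orientation held fixed at the vector-average estimate. Multi-start over
#' `sigma_starts` guards against local minima; the lowest-residual fit wins.
#'
#' @param directions_deg Stimulus directions, degrees (full 360 cycle).
#' @param responses Mean evoked responses per direction, spikes/s.
#' @param theta_pref Fixed preferred orientation from
#'   [preferred_orientation()], degrees.
#' @param sigma_bounds Lower/upper bounds on the shared width, degrees.
#' @param sigma_starts Width start values for the multi-start, degrees.
#' @return An object of class `tuning_fit`: list with `theta_pref`, `A1`,
#'   `A2`, `sigma`, `B`, `R_pref`, `R_ortho` (fitted values at the preferred
#'   and orthogonal orientations), `converged`, `rss`.
#' @export
fit_orientation_tuning <- function(directions_deg, responses, theta_pref,
                                   sigma_bounds = c(5, 90),
                                   sigma_starts = c(10, 20, 40)) {
  stopifnot(length(directions_deg) == length(responses),
            length(responses) >= 5L)
  resid_fun <- function(par) {
    tuning_model(directions_deg, theta_pref, par[1], par[2], par[3],
                 par[4]) - responses
  }
  near <- function(th) {
    d <- abs(((directions_deg - th + 180) %% 360) - 180)
    responses[which.min(d)]
  }
  B0 <- min(responses)
  starts <- lapply(sigma_starts, function(s0) {
    c(A1 = max(near(theta_pref) - B0, 0.1),
      A2 = max(near(theta_pref + 180) - B0, 0.1),
      sigma = s0, B = B0)
  })

  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = st, fn = resid_fun,
      lower = c(0, 0, sigma_bounds[1], -Inf),
      upper = c(Inf, Inf, sigma_bounds[2], Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(theta_pref = theta_pref, A1 = NA_real_,
                          A2 = NA_real_, sigma = NA_real_, B = NA_real_,
                          R_pref = NA_real_, R_ortho = NA_real_,
                          converged = FALSE, rss = NA_real_),
                     class = "tuning_fit"))
  }
  p <- best$par
  R_pref <- tuning_model(theta_pref, theta_pref, p[1], p[2], p[3], p[4])
  R_ortho <- mean(tuning_model(theta_pref + c(90, -90), theta_pref,
                               p[1], p[2], p[3], p[4]))
  structure(list(theta_pref = theta_pref, A1 = unname(p[1]),
                 A2 = unname(p[2]), sigma = unname(p[3]), B = unname(p[4]),
                 R_pref = unname(R_pref), R_ortho = unname(R_ortho),
                 converged = best$info %in% 1:3, rss = best$deviance),
            class = "tuning_fit")
}

#' Orientation selectivity index
#'
#' `(R_pref - R_ortho) / (R_pref + R_ortho)`, computed from the fitted
#' responses at the preferred and orthogonal orientations. Negative fitted
#' responses are clipped to zero before forming the ratio.
#'
#' @param fit A `tuning_fit` (or a list with `R_pref`, `R_ortho`).
#' @return OSI, unitless.
#' @export
osi <- function(fit) {
  rp <- max(fit$R_pref, 0)
  ro <- max(fit$R_ortho, 0)
  if (!is.finite(rp + ro) || rp + ro <= 0) {
    stop("OSI undefined: R_pref + R_ortho is not positive")
  }
  (rp - ro) / (rp + ro)
}

#' Tuning width (half-width at half-maximum above baseline)
#'
#' Scans the fitted tuning curve outward from the preferred orientation for
#' the point where it drops to baseline plus half the above-baseline peak.
#' For an isolated Gaussian lobe this equals `sigma * sqrt(2 log 2)`.
#'
#' @param fit A converged `tuning_fit` with `A1 > 0`.
#' @return HWHM in degrees, or `NA` if the curve never falls below the
#'   half-maximum within 90 degrees (extremely flat tuning).
#' @export
tuning_width <- function(fit) {
  if (!isTRUE(fit$converged) || !is.finite(fit$A1) || fit$A1 <= 0) {
    stop("tuning width undefined: fit not converged or A1 <= 0")
  }
  curve_at <- function(x) {
    tuning_model(fit$theta_pref + x, fit$theta_pref, fit$A1, fit$A2,
                 fit$sigma, fit$B)
  }
  peak <- curve_at(0)
  half <- fit$B + (peak - fit$B) / 2
  f <- function(x) curve_at(x) - half
  if (f(90) > 0) return(NA_real_)
  stats::uniroot(f, c(1e-9, 90), tol = 1e-8)$root
}

#' Signed binocular difference in preferred orientation
#'
#' Contralateral minus ipsilateral preferred orientation, wrapped along the
#' 180-degree orientation cycle into `(-90, 90]`.
#'
#' @param theta_contra,theta_ipsi Preferred orientations, degrees.
#' @return Signed difference in degrees; take `abs()` for the binocular
#'   matching statistic `|dO|`.
#' @export
orientation_difference <- function(theta_contra, theta_ipsi) {
  w <- (theta_contra - theta_ipsi) %% 180
  ifelse(w > 90, w - 180, w)
}

#' Fit the spatial-frequency tuning curve
#'
#' Difference of two Gaussians (centred at zero) on the linear spatial
#' frequency axis:
#' `R(sf) = Ac exp(-sf^2 / (2 wc^2)) - As exp(-sf^2 / (2 ws^2))`, amplitudes
#' constrained non-negative. The preferred spatial frequency is the argmax of
#' the fitted curve on a fine grid over `[0, 2 * max(sf)]`. If the fit fails,
#' the raw-response argmax is used and the result flagged.
#'
#' @param sf_cpd Tested spatial frequencies, cycles/degree (>= 4 values).
#' @param responses Mean evoked responses at the preferred orientation,
#'   spikes/s.
#' @return An object of class `sf_fit`: list with `Ac`, `wc`, `As`, `ws`,
#'   `sf_pref_cpd`, `converged`, `rss`.
#' @export
fit_sf_tuning <- function(sf_cpd, responses) {
  stopifnot(length(sf_cpd) == length(responses))
  ok <- sf_cpd > 0
  sf_cpd <- sf_cpd[ok]
  responses <- responses[ok]
  if (length(sf_cpd) < 4L) stop("need >= 4 non-blank spatial frequencies")

  dog <- function(s, p) {
    p[1] * exp(-s^2 / (2 * p[2]^2)) - p[3] * exp(-s^2 / (2 * p[4]^2))
  }
  resid_fun <- function(p) dog(sf_cpd, p) - responses
  smax <- max(sf_cpd)
  rmax <- max(responses)
  starts <- list(
    c(Ac = max(rmax, 0.1), wc = smax / 2, As = max(rmax, 0.1) / 2,
      ws = smax / 8),
    c(Ac = max(rmax, 0.1), wc = smax, As = 0.01, ws = smax / 4),
    c(Ac = max(2 * rmax, 0.1), wc = smax / 4, As = max(rmax, 0.1),
      ws = smax / 16))
  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = st, fn = resid_fun,
      lower = c(0, 1e-4, 0, 1e-4), upper = c(Inf, 10 * smax, Inf, 10 * smax),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best) || !(best$info %in% 1:3)) {
    return(structure(list(Ac = NA_real_, wc = NA_real_, As = NA_real_,
                          ws = NA_real_,
                          sf_pref_cpd = sf_cpd[which.max(responses)],
                          converged = FALSE, rss = NA_real_),
                     class = "sf_fit"))
  }
  p <- best$par
  grid <- seq(0, 2 * smax, length.out = 2001)
  structure(list(Ac = unname(p[1]), wc = unname(p[2]), As = unname(p[3]),
                 ws = unname(p[4]),
                 sf_pref_cpd = grid[which.max(dog(grid, p))],
                 converged = TRUE, rss = best$deviance),
            class = "sf_fit")
}

#' Ocular dominance index of a unit
#'
#' `(contra - ipsi) / (contra + ipsi)` of the two eyes' response amplitudes
#' (contra = deprived eye in deprived groups). Negative inputs (suppressed
#' evoked responses) are clipped to zero before forming the ratio.
#'
#' @param resp_contra,resp_ipsi Response amplitudes, spikes/s.
#' @return ODI in `[-1, 1]`.
#' @export
odi_unit <- function(resp_contra, resp_ipsi) {
  cc <- max(resp_contra, 0)
  ii <- max(resp_ipsi, 0)
  if (cc + ii <= 0) {
    stop("ODI undefined: both responses are zero (after clipping negatives)")
  }
  (cc - ii) / (cc + ii)
}

#' Select units responsive to the optimal grating
#'
#' Keeps units whose peak evoked grating response reaches the threshold
#' (default 2.0 spikes/s) through either eye.
#'
#' @param metrics Unit-metrics `data.frame` with columns
#'   `peak_grating_resp_contra`, `peak_grating_resp_ipsi`.
#' @param threshold Response threshold, spikes/s.
#' @return Filtered `data.frame`.
#' @export
select_responsive_grating <- function(metrics, threshold = 2.0) {
  keep <- !is.na(metrics$peak_grating_resp_contra) &
    !is.na(metrics$peak_grating_resp_ipsi) &
    (metrics$peak_grating_resp_contra >= threshold |
       metrics$peak_grating_resp_ipsi >= threshold)
  metrics[keep, , drop = FALSE]
}

#' F1 response: first harmonic of the cycle-averaged rate
#'
#' Folds the binned spike counts into one contrast-modulation cycle, averages
#' the rate per phase bin, and returns the amplitude of the first harmonic:
#' `F1 = 2 |sum_k r(phi_k) exp(-2 pi i k / m)| / m` in spikes/s (0.1 Hz for
#' the standard 10-s period).
#'
#' @param counts Binned spike counts (vector), or a matrix from
#'   [simulate_noise_response()] (rows = units; a vector is returned).
#' @param dt Bin width, seconds (taken from `attr(counts, "dt")` if present).
#' @param period_s Modulation period, seconds (attribute `period_s` if
#'   present). `period_s / dt` must be an integer.
#' @return F1 amplitude(s), spikes/s.
#' @export
f1_response <- function(counts, dt = attr(counts, "dt"),
                        period_s = attr(counts, "period_s")) {
  if (is.null(dt) || is.null(period_s)) {
    stop("dt and period_s must be supplied (or attached as attributes)")
  }
  m <- period_s / dt
  if (abs(m - round(m)) > 1e-8) {
    stop("bins do not align with the period: period_s/dt must be an integer (resample first)")
  }
  m <- as.integer(round(m))
  one <- function(v) {
    ncyc <- floor(length(v) / m)
    if (ncyc < 2L) stop("recording must span at least 2 full periods")
    v <- v[seq_len(ncyc * m)]
    r <- rowMeans(matrix(v / dt, nrow = m))
    2 * Mod(sum(r * exp(-2i * pi * (seq_len(m) - 1) / m))) / m
  }
  if (is.matrix(counts)) apply(counts, 1, one) else one(as.numeric(counts))
}

#' Contrast-response curve and semi-saturation contrast
#'
#' Bins the instantaneous rate by the instantaneous stimulus contrast
#' (default 20 equal-width bins over `[0, 1]`) and averages over all cycles.
#' `C_1/2` is the lowest contrast at which the linearly interpolated curve
#' crosses halfway between the low-contrast baseline and the maximum.
#'
#' @param counts Binned spike counts (vector) with bin width `dt`.
#' @param contrast_trace Per-bin contrast values in `[0, 1]`; recycled
#'   periodically if shorter than `counts`.
#' @param dt Bin width, seconds.
#' @param n_bins Number of contrast bins.
#' @return List with `curve` (`data.frame`: `contrast`, `rate`, `n`) and
#'   `c_half` (`NA` if the curve never crosses half-maximum).
#' @export
contrast_response <- function(counts, contrast_trace,
                              dt = attr(counts, "dt"), n_bins = 20) {
  counts <- as.numeric(counts)
  if (is.null(dt)) stop("dt must be supplied")
  nb <- length(counts)
  cvec <- contrast_trace[((seq_len(nb) - 1) %% length(contrast_trace)) + 1]
  bin <- pmin(pmax(ceiling(cvec * n_bins), 1L), n_bins)
  rate <- counts / dt
  agg_rate <- tapply(rate, bin, mean)
  agg_n <- tapply(rate, bin, length)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  idx <- as.integer(names(agg_rate))
  curve <- data.frame(contrast = centers[idx],
                      rate = as.numeric(agg_rate),
                      n = as.integer(agg_n))
  curve <- curve[order(curve$contrast), ]
  rownames(curve) <- NULL

  baseline <- curve$rate[1]
  half <- (max(curve$rate) + baseline) / 2
  c_half <- NA_real_
  above <- curve$rate >= half
  if (max(curve$rate) > baseline && any(above[-1])) {
    j <- which(above)[1]
    if (j == 1L) {
      c_half <- curve$contrast[1]
    } else {
      x0 <- curve$contrast[j - 1]; x1 <- curve$contrast[j]
      y0 <- curve$rate[j - 1]; y1 <- curve$rate[j]
      c_half <- x0 + (half - y0) / (y1 - y0) * (x1 - x0)
    }
  }
  list(curve = curve, c_half = c_half)
}

#' Classify a unit as broad- or narrow-spiking
#'
#' Two-criterion rule on extracellular waveform features: a unit is narrow
#' iff its trough-to-peak time is below `t_thresh_ms` and the waveform slope
#' 0.5 ms after the trough is at most `slope_thresh`; otherwise broad.
#' Thresholds are configurable; the defaults are calibrated on the package's
#' synthetic waveform-feature distributions.
#'
#' @param trough_to_peak_ms Trough-to-peak times, ms (vectorised).
#' @param slope_05ms Waveform slope 0.5 ms after the trough.
#' @param t_thresh_ms Trough-to-peak threshold, ms.
#' @param slope_thresh Slope threshold.
#' @return Character vector of `"broad"` / `"narrow"`.
#' @export
classify_waveform <- function(trough_to_peak_ms, slope_05ms,
                              t_thresh_ms = 0.5, slope_thresh = 0) {
  if (any(!is.finite(trough_to_peak_ms)) || any(!is.finite(slope_05ms))) {
    stop("waveform features must be finite")
  }
  ifelse(trough_to_peak_ms < t_thresh_ms & slope_05ms <= slope_thresh,
         "narrow", "broad")
}

# Per-eye orientation/SF analysis for one unit; returns a list of scalars.
analyse_eye <- function(ev, fit_tuning) {
  out <- list(peak = NA_real_, theta_pref = NA_real_, osi = NA_real_,
              sigma = NA_real_, hwhm = NA_real_, sf_pref = NA_real_,
              fit_converged = NA)
  if (nrow(ev) == 0L) return(out)
  out$peak <- max(ev$evoked)
  by_dir <- tapply(ev$evoked, ev$direction_deg, mean)
  dirs <- as.numeric(names(by_dir))
  th <- try(preferred_orientation(dirs, as.numeric(by_dir)), silent = TRUE)
  if (inherits(th, "try-error")) return(out)
  out$theta_pref <- th
  if (fit_tuning) {
    ft <- fit_orientation_tuning(dirs, as.numeric(by_dir), th)
    out$fit_converged <- ft$converged
    if (isTRUE(ft$converged)) {
      out$sigma <- ft$sigma
      o <- try(osi(ft), silent = TRUE)
      if (!inherits(o, "try-error")) out$osi <- o
      w <- try(tuning_width(ft), silent = TRUE)
      if (!inherits(w, "try-error")) out$hwhm <- w
    }
    # responses at the preferred orientation: nearest direction on the
    # 180-degree cycle (both drift directions), per SF
    dd <- abs(((ev$direction_deg - th + 90) %% 180) - 90)
    at_pref <- ev[dd <= min(dd) + 1e-9, ]
    by_sf <- tapply(at_pref$evoked, at_pref$sf_cpd, mean)
    sfs <- as.numeric(names(by_sf))
    if (length(sfs) >= 4L) {
      sfit <- try(fit_sf_tuning(sfs, as.numeric(by_sf)), silent = TRUE)
      if (!inherits(sfit, "try-error")) out$sf_pref <- sfit$sf_pref_cpd
    }
  }
  out
}

#' Compute the full per-unit metrics table
#'
#' Driver over a trial table (and optionally noise-response count matrices
#' and waveform features) producing one row per unit: spontaneous rate, peak
#' evoked grating response and responsiveness per eye, grating ODI, preferred
#' orientation / OSI / tuning width / preferred SF per eye, binocular
#' orientation mismatch, noise F1 per eye, noise responsiveness and ODI, and
#' semi-saturation contrast.
#'
#' @param trials Trial table from [simulate_grating_trials()] or read from
#'   CSV.
#' @param noise_contra,noise_ipsi Optional count matrices from
#'   [simulate_noise_response()] (rownames = unit ids, attributes `dt`,
#'   `period_s`).
#' @param contrast_trace Optional contrast trace for `C_1/2` (required with
#'   noise counts to compute `c_half`).
#' @param waveforms Optional `data.frame` from [sample_waveform_features()]
#'   with one row per unit (in `trials` unit order) to classify cells.
#' @param fit_tuning Fit orientation/SF tuning curves (slower); when `FALSE`
#'   only rates, peaks, ODIs and F1s are computed.
#' @param resp_threshold Grating responsiveness threshold, spikes/s.
#' @param f1_threshold Noise responsiveness threshold on F1, spikes/s.
#' @return A `data.frame` of class `unit_metrics`, one row per unit.
#' @export
compute_unit_metrics <- function(trials, noise_contra = NULL,
                                 noise_ipsi = NULL, contrast_trace = NULL,
                                 waveforms = NULL, fit_tuning = TRUE,
                                 resp_threshold = 2.0, f1_threshold = 0.2) {
  ids <- unique(trials$unit_id)
  f1_c <- if (!is.null(noise_contra)) f1_response(noise_contra) else NULL
  f1_i <- if (!is.null(noise_ipsi)) f1_response(noise_ipsi) else NULL

  rows <- lapply(seq_along(ids), function(k) {
    id <- ids[k]
    tr <- trials[trials$unit_id == id, ]
    spont <- tryCatch(spontaneous_rate(tr), error = function(e) NA_real_)
    ev_c <- evoked_table(tr, id, "contra", spont = spont)
    ev_i <- evoked_table(tr, id, "ipsi", spont = spont)
    a_c <- analyse_eye(ev_c, fit_tuning)
    a_i <- analyse_eye(ev_i, fit_tuning)

    odi_g <- tryCatch(odi_unit(a_c$peak, a_i$peak),
                      error = function(e) NA_real_)
    dO <- if (is.finite(a_c$theta_pref) && is.finite(a_i$theta_pref)) {
      orientation_difference(a_c$theta_pref, a_i$theta_pref)
    } else NA_real_

    key <- as.character(id)
    f1c <- if (!is.null(f1_c) && key %in% names(f1_c)) f1_c[[key]] else
      NA_real_
    f1i <- if (!is.null(f1_i) && key %in% names(f1_i)) f1_i[[key]] else
      NA_real_
    odi_n <- if (is.finite(f1c) && is.finite(f1i)) {
      tryCatch(odi_unit(f1c, f1i), error = function(e) NA_real_)
    } else NA_real_
    ch <- NA_real_
    if (!is.null(noise_contra) && !is.null(contrast_trace) &&
        key %in% rownames(noise_contra)) {
      ch <- contrast_response(noise_contra[key, ], contrast_trace,
                              dt = attr(noise_contra, "dt"))$c_half
    }

    data.frame(
      unit_id = id,
      spont_rate = spont,
      peak_grating_resp_contra = a_c$peak,
      peak_grating_resp_ipsi = a_i$peak,
      responsive_grating = isTRUE(a_c$peak >= resp_threshold) ||
        isTRUE(a_i$peak >= resp_threshold),
      odi_grating = odi_g,
      theta_pref_contra = a_c$theta_pref,
      theta_pref_ipsi = a_i$theta_pref,
      osi_contra = a_c$osi,
      osi_ipsi = a_i$osi,
      hwhm_contra = a_c$hwhm,
      hwhm_ipsi = a_i$hwhm,
      dO_abs_deg = abs(dO),
      sf_pref_contra = a_c$sf_pref,
      sf_pref_ipsi = a_i$sf_pref,
      f1_contra = f1c,
      f1_ipsi = f1i,
      responsive_noise = isTRUE(f1c > f1_threshold) ||
        isTRUE(f1i > f1_threshold),
      odi_noise = odi_n,
      c_half_contra = ch,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(waveforms)) {
    out$cell_class <- classify_waveform(waveforms$trough_to_peak_ms,
                                        waveforms$slope_05ms)
  }
  class(out) <- c("unit_metrics", class(out))
  out
}
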