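# Fourier analysis of intrinsic-signal imaging movies: per-pixel amplitude
# and phase at the stimulus frequency, ROI quantification, imaging ODI.

#' Amplitude and phase maps at the stimulus frequency
#'
#' Per pixel: trim the recording to a whole number of stimulus cycles, remove
#' a linear trend, and take the complex Fourier component at the stimulus
#' frequency. Amplitude uses the single-sided convention `2 |X_f| / N`; phase
#' is expressed for the `A sin(2 pi f t + phi)` convention, in `(-pi, pi]`.
#'
#' @param movie An `imaging_movie` (list with `frames` = `ny x nx x nt`
#'   array, `fps`, `stim_freq_hz`).
#' @param detrend Remove a per-pixel linear trend before the Fourier step
#'   (default `TRUE`; intrinsic signals drift). Disable for drift-free
#'   synthetic data when exact amplitude recovery is wanted.
#' @return An object of class `response_map`: list with `amplitude` and
#'   `phase` matrices, `stim_freq_hz`, `n_frames_used`.
#' @export
fourier_response_map <- function(movie, detrend = TRUE) {
  fr <- movie$frames
  stopifnot(length(dim(fr)) == 3L)
  fps <- movie$fps
  f <- movie$stim_freq_hz
  nt <- dim(fr)[3]
  ncyc <- floor(nt * f / fps)
  if (ncyc < 2) {
    stop("stimulus frequency not resolvable: recording spans fewer than 2 cycles")
  }
  n_use <- round(ncyc * fps / f)
  if (n_use > nt) n_use <- nt

  ny <- dim(fr)[1]; nx <- dim(fr)[2]
  y <- matrix(fr[, , seq_len(n_use)], ny * nx, n_use)
  tt <- (seq_len(n_use) - 1) / fps
  y <- y - rowMeans(y)
  if (detrend) {
    # per-pixel linear detrend (closed form on the common time axis)
    tc <- tt - mean(tt)
    slope <- (y %*% tc) / sum(tc^2)
    y <- y - slope %*% t(tc)
  }

  e <- exp(-2i * pi * f * tt)
  Xf <- y %*% e
  amp <- matrix(2 * Mod(Xf) / n_use, ny, nx)
  ph <- Arg(Xf) + pi / 2
  ph <- ((ph + pi) %% (2 * pi)) - pi
  structure(list(amplitude = amp, phase = matrix(ph, ny, nx),
                 stim_freq_hz = f, n_frames_used = n_use),
            class = "response_map")
}

#' Mean response amplitude over a region of interest
#'
#' @param map A `response_map`.
#' @param roi_mask Logical matrix (same size as the amplitude map); `TRUE`
#'   pixels belong to the ROI.
#' @return Mean amplitude over the ROI.
#' @export
roi_amplitude <- function(map, roi_mask) {
  stopifnot(is.matrix(roi_mask), dim(roi_mask) == dim(map$amplitude))
  roi_mask <- roi_mask > 0
  if (!any(roi_mask)) stop("empty ROI mask")
  mean(map$amplitude[roi_mask])
}

#' Average repeated response measurements
#'
#' Arithmetic mean of repeated amplitude measurements; at least `min_n`
#' (default four) are required.
#'
#' @param values Numeric vector of measurements.
#' @param min_n Minimum number of measurements.
#' @return Mean value.
#' @export
average_measurements <- function(values, min_n = 4) {
  if (length(values) < min_n) {
    stop(sprintf("need at least %d measurements, got %d", min_n,
                 length(values)))
  }
  mean(values)
}

#' Ocular dominance index from imaging response amplitudes
#'
#' `(R - L) / (R + L)` with `R`, `L` the peak response amplitudes through the
#' right and left eyes.
#'
#' @param R_right,R_left Non-negative response amplitudes.
#' @return ODI in `[-1, 1]`.
#' @export
odi_imaging <- function(R_right, R_left) {
  if (R_right < 0 || R_left < 0) stop("response amplitudes must be >= 0")
  if (R_right + R_left <= 0) stop("ODI undefined: R + L = 0")
  (R_right - R_left) / (R_right + R_left)
}

#' Write amplitude/phase maps as 32-bit float TIFFs
#'
#' Amplitude is scaled by its maximum into `[0, 1]` and phase mapped from
#' `(-pi, pi]` to `[0, 1]`; the scale factors go in a JSON sidecar.
#'
#' @param map A `response_map`.
#' @param amp_path,phase_path Output TIFF paths.
#' @return `amp_path`, invisibly.
#' @export
write_response_map <- function(map, amp_path, phase_path) {
  amax <- max(map$amplitude, 1e-12)
  tiff::writeTIFF(map$amplitude / amax, amp_path, bits.per.sample = 32L)
  tiff::writeTIFF((map$phase + pi) / (2 * pi), phase_path,
                  bits.per.sample = 32L)
  jsonlite::write_json(list(amplitude_scale = amax,
                            phase_transform = "phi = v*2*pi - pi",
                            stim_freq_hz = map$stim_freq_hz),
                       paste0(amp_path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(amp_path)
}
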