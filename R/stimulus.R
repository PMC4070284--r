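# Stimulus synthesis: band-limited contrast-modulated noise movies and
# drifting-grating trial protocols.

#' Specification for a contrast-modulated noise movie
#'
#' Parameters of the stochastic noise stimulus: spatiotemporal Gaussian noise,
#' low-pass filtered in space and time, then multiplied by a slow periodic
#' contrast envelope.
#'
#' Axes convention: frames are `ny x nx` matrices with pixel `[1, 1]` at the
#' top-left corner; the x index increases rightward (azimuth) and the y index
#' increases downward (elevation).
#'
#' @param grid_px Pixels per side of the (square) movie frame.
#' @param span_deg Visual angle subtended by one side, degrees.
#' @param fps Frame rate, frames/s.
#' @param duration_s Movie duration, seconds.
#' @param sf_cutoff_cpd Spatial low-pass cutoff, cycles/degree. Must lie below
#'   the spatial Nyquist frequency `grid_px / (2 * span_deg)`.
#' @param tf_cutoff_hz Temporal low-pass cutoff, Hz. Must lie below `fps / 2`.
#' @param contrast_period_s Period of the contrast envelope, seconds.
#' @param seed Integer seed; the same seed reproduces the movie bit-exactly.
#' @return An object of class `noise_movie_spec`.
#' @export
noise_movie_spec <- function(grid_px = 60, span_deg = 30, fps = 30,
                             duration_s = 300, sf_cutoff_cpd = 0.05,
                             tf_cutoff_hz = 4, contrast_period_s = 10,
                             seed = 1L) {
  vals <- c(grid_px = grid_px, span_deg = span_deg, fps = fps,
            duration_s = duration_s, sf_cutoff_cpd = sf_cutoff_cpd,
            tf_cutoff_hz = tf_cutoff_hz, contrast_period_s = contrast_period_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all noise_movie_spec parameters must be positive and finite")
  }
  nyq_sp <- grid_px / (2 * span_deg)
  if (sf_cutoff_cpd >= nyq_sp) {
    stop(sprintf(
      "sf_cutoff_cpd (%.4g cpd) must be below the spatial Nyquist frequency %.4g cpd = grid_px/(2*span_deg)",
      sf_cutoff_cpd, nyq_sp))
  }
  if (tf_cutoff_hz >= fps / 2) {
    stop(sprintf(
      "tf_cutoff_hz (%.4g Hz) must be below the temporal Nyquist frequency %.4g Hz = fps/2",
      tf_cutoff_hz, fps / 2))
  }
  structure(list(grid_px = as.integer(grid_px), span_deg = span_deg, fps = fps,
                 duration_s = duration_s, sf_cutoff_cpd = sf_cutoff_cpd,
                 tf_cutoff_hz = tf_cutoff_hz,
                 contrast_period_s = contrast_period_s,
                 seed = as.integer(seed)),
            class = "noise_movie_spec")
}

#' Periodic contrast envelope
#'
#' Envelope taking the stimulus smoothly from gray (0) to full contrast (1)
#' and back to gray once per period. The default raised-cosine form is
#' `(1 - cos(2 pi t / period)) / 2`; the rectified-sine alternative
#' `|sin(pi t / period)|` is also available.
#'
#' @param t Time, seconds (vectorised; must be non-negative).
#' @param period Envelope period, seconds.
#' @param form `"raised_cosine"` (default) or `"abs_sine"`.
#' @return Envelope values in `[0, 1]`.
#' @export
contrast_envelope <- function(t, period = 10,
                              form = c("raised_cosine", "abs_sine")) {
  form <- match.arg(form)
  if (!is.numeric(period) || length(period) != 1L || period <= 0) {
    stop("period must be a single positive number")
  }
  if (any(t < 0)) stop("t must be non-negative")
  switch(form,
         raised_cosine = (1 - cos(2 * pi * t / period)) / 2,
         abs_sine = abs(sin(pi * t / period)))
}

# Signed FFT bin frequencies: cycles per unit for an n-point axis spanning
# `extent` units.
fft_freqs <- function(n, extent) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / extent
}

#' Synthesize a contrast-modulated noise movie
#'
#' Draws spatiotemporal white Gaussian noise, removes all Fourier power above
#' the spatial and temporal cutoffs (the masked spectrum of a real array is
#' Hermitian, so the inverse transform is real to machine precision), rescales
#' so that the 99.9th percentile of absolute value equals 1, clips to
#' `[-1, 1]`, and multiplies every frame by the contrast envelope.
#'
#' @param spec A [noise_movie_spec()].
#' @param keep_raw Keep the band-limited, rescaled but unclipped and
#'   un-enveloped frame stack as `frames_raw` (useful for spectral checks).
#' @return An object of class `stimulus_movie`: a list with `frames`
#'   (array `ny x nx x nt`, signed contrast in `[-1, 1]`), `contrast_trace`
#'   (per-frame envelope value), `fps`, `span_deg`, `contrast_period_s`,
#'   `spec`, and optionally `frames_raw`.
#' @export
synthesize_noise_movie <- function(spec = noise_movie_spec(),
                                   keep_raw = FALSE) {
  stopifnot(inherits(spec, "noise_movie_spec"))
  n <- spec$grid_px
  nt <- as.integer(round(spec$fps * spec$duration_s))
  if (nt < 2L) stop("movie must contain at least 2 frames")

  set.seed(spec$seed)
  x <- array(stats::rnorm(as.double(n) * n * nt), dim = c(n, n, nt))
  X <- stats::fft(x)

  fy <- fft_freqs(n, spec$span_deg)
  fx <- fft_freqs(n, spec$span_deg)
  ft <- fft_freqs(nt, nt / spec$fps)
  sf_rad <- sqrt(outer(fy^2, fx^2, "+"))
  keep_sp <- sf_rad <= spec$sf_cutoff_cpd + 1e-12
  keep_t <- abs(ft) <= spec$tf_cutoff_hz + 1e-12
  if (sum(keep_sp) <= 1L || sum(keep_t) <= 1L) {
    stop("cutoffs admit no non-DC frequency bins; increase duration/grid or cutoffs")
  }
  mask <- array(keep_sp, dim = c(n, n, nt)) &
    rep(keep_t, each = as.double(n) * n)
  X[!mask] <- 0 + 0i
  rm(x, mask)

  y <- Re(stats::fft(X, inverse = TRUE)) / (as.double(n) * n * nt)
  rm(X)

  q <- stats::quantile(abs(y), 0.999, names = FALSE)
  if (q <= 0) stop("degenerate movie: all values zero after filtering")
  y <- y / q
  frames_raw <- if (keep_raw) y else NULL

  y <- pmin(pmax(y, -1), 1)
  dim(y) <- c(n, n, nt)
  tt <- (seq_len(nt) - 1) / spec$fps
  env <- contrast_envelope(tt %% spec$contrast_period_s,
                           spec$contrast_period_s)
  y <- y * rep(env, each = as.double(n) * n)

  out <- list(frames = y, contrast_trace = env, fps = spec$fps,
              span_deg = spec$span_deg,
              contrast_period_s = spec$contrast_period_s, spec = spec)
  if (keep_raw) {
    dim(frames_raw) <- c(n, n, nt)
    out$frames_raw <- frames_raw
  }
  structure(out, class = "stimulus_movie")
}

#' Build a randomized drifting-grating trial protocol
#'
#' One repeat block holds every combination of 12 equally spaced drift
#' directions with the spatial frequencies tested (default 0.01, 0.02, 0.04,
#' 0.08, 0.16, 0.32 cpd) plus blank (full-field flicker, sf = 0) trials, one
#' per direction slot. Blocks are shuffled independently per eye and repeat,
#' so blanks are interspersed throughout.
#'
#' @param repeats Repeats of the full condition set per eye (default 6).
#' @param seed Integer seed for the trial-order shuffle.
#' @param directions_deg Drift directions, degrees (default 0, 30, ..., 330).
#' @param spatial_freqs_cpd Non-blank spatial frequencies, cycles/degree.
#' @param eyes Eye labels (stimulation is monocular, one eye per trial).
#' @param temporal_freq_hz Grating temporal frequency, Hz (recorded only).
#' @param trial_duration_s Presentation duration per trial, seconds.
#' @return A `data.frame` with columns `trial_index`, `eye`, `direction_deg`,
#'   `sf_cpd`, `is_blank`, `rep`, `duration_s` and attributes
#'   `temporal_freq_hz`.
#' @export
build_grating_protocol <- function(repeats = 6, seed = 1L,
                                   directions_deg = seq(0, 330, by = 30),
                                   spatial_freqs_cpd = c(0.01, 0.02, 0.04,
                                                         0.08, 0.16, 0.32),
                                   eyes = c("contra", "ipsi"),
                                   temporal_freq_hz = 2,
                                   trial_duration_s = 1.5) {
  if (repeats < 1) stop("repeats must be >= 1")
  if (any(spatial_freqs_cpd <= 0)) {
    stop("spatial_freqs_cpd must be positive; blanks (sf = 0) are added automatically")
  }
  set.seed(seed)
  block <- rbind(
    expand.grid(direction_deg = directions_deg, sf_cpd = spatial_freqs_cpd,
                KEEP.OUT.ATTRS = FALSE),
    data.frame(direction_deg = directions_deg, sf_cpd = 0))
  block$is_blank <- block$sf_cpd == 0

  pieces <- vector("list", repeats * length(eyes))
  k <- 0L
  for (r in seq_len(repeats)) {
    for (e in eyes) {
      k <- k + 1L
      b <- block[sample.int(nrow(block)), , drop = FALSE]
      b$eye <- e
      b$rep <- r
      pieces[[k]] <- b
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out$trial_index <- seq_len(nrow(out))
  out$duration_s <- trial_duration_s
  out <- out[, c("trial_index", "eye", "direction_deg", "sf_cpd", "is_blank",
                 "rep", "duration_s")]
  attr(out, "temporal_freq_hz") <- temporal_freq_hz
  out
}

#' Write a movie as multi-frame 32-bit TIFF plus JSON sidecar
#'
#' Signed contrast values in `[-1, 1]` are stored as `(v + 1) / 2`; the
#' transform and calibration (fps, span, envelope period, seed) go in the
#' sidecar `<path>.json`.
#'
#' @param movie A `stimulus_movie` or `imaging_movie`-like list with `frames`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stimulus_movie <- function(movie, path) {
  fr <- movie$frames
  frames01 <- lapply(seq_len(dim(fr)[3]), function(i) (fr[, , i] + 1) / 2)
  tiff::writeTIFF(frames01, path, bits.per.sample = 32L)
  sidecar <- list(fps = movie$fps, span_deg = movie$span_deg,
                  contrast_period_s = movie$contrast_period_s,
                  seed = movie$spec$seed, transform = "v01 = (v + 1)/2",
                  contrast_trace = movie$contrast_trace)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a movie written by [write_stimulus_movie()]
#'
#' @param path TIFF path (sidecar `<path>.json` must exist).
#' @return A `stimulus_movie`-like list.
#' @export
read_stimulus_movie <- function(path) {
  frames01 <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fr <- array(unlist(frames01), dim = c(dim(frames01[[1]]), length(frames01)))
  fr <- fr * 2 - 1
  structure(list(frames = fr, contrast_trace = meta$contrast_trace,
                 fps = meta$fps, span_deg = meta$span_deg,
                 contrast_period_s = meta$contrast_period_s,
                 spec = list(seed = meta$seed)),
            class = "stimulus_movie")
}
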