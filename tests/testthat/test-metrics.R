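# Per-unit metrics: rates, preferred orientation, tuning fits, ODI, F1,
# contrast sensitivity, classification.

test_that("spontaneous and evoked rates are blank-trial arithmetic", {
  tr <- make_trials(counts_blank = c(3, 3, 3), counts_cond = c(15, 15, 15))
  expect_equal(spontaneous_rate(tr, 1), 2)
  expect_equal(evoked_response(tr, 1, "contra", 0, 0.04), 8)
  # mean rate equal to spont -> 0
  tr2 <- make_trials(counts_blank = c(3, 3, 3), counts_cond = c(3, 3, 3))
  expect_equal(evoked_response(tr2, 1, "contra", 0, 0.04), 0)
  expect_equal(spontaneous_rate(make_trials(c(0, 0, 0))), 0)
  expect_error(spontaneous_rate(make_trials(c(1))[0, ]), "blank")
  expect_error(evoked_response(tr, 1, "contra", 90, 0.04), "condition")
})

test_that("preferred orientation is half the complex phase of the direction resultant", {
  dirs <- seq(0, 330, by = 30)
  # single nonzero response at 45 degrees
  expect_equal(preferred_orientation(c(45, 90), c(1, 0)), 45)
  # pure second harmonic centred at 30 degrees
  F <- 1 + cos(2 * (dirs - 30) * pi / 180)
  expect_equal(preferred_orientation(dirs, F), 30, tolerance = 1e-9)
  # perfect symmetry -> undefined
  expect_error(preferred_orientation(c(0, 90), c(1, 1)), "undefined")
  expect_error(preferred_orientation(c(10, 10), c(1, 2)), "distinct")
})

test_that("preferred orientation is rotation-equivariant (property)", {
  dirs <- seq(0, 330, by = 30)
  set.seed(31)
  for (i in 1:20) {
    th0 <- runif(1, 0, 180)
    F <- 0.5 + exp(cos(2 * (dirs - th0) * pi / 180))
    delta <- runif(1, -180, 180)
    a <- preferred_orientation(dirs, F)
    b <- preferred_orientation((dirs + delta) %% 360, F)
    expect_equal(min(abs(((b - a - delta) %% 180)),
                     abs(180 - ((b - a - delta) %% 180))), 0,
                 tolerance = 1e-8)
  }
})

test_that("orientation tuning fit recovers exact double-Gaussian parameters", {
  dirs <- seq(0, 330, by = 30)
  truth <- list(A1 = 10, A2 = 5, sigma = 20, B = 1, theta = 77)
  resp <- visrecov:::tuning_model(dirs, truth$theta, truth$A1, truth$A2,
                                  truth$sigma, truth$B)
  fit <- fit_orientation_tuning(dirs, resp, truth$theta)
  expect_true(fit$converged)
  expect_equal(fit$A1, truth$A1, tolerance = 0.01)
  expect_equal(fit$A2, truth$A2, tolerance = 0.01)
  expect_equal(fit$sigma, truth$sigma, tolerance = 0.01)
  expect_equal(fit$B, truth$B, tolerance = 0.01)

  # flat responses: no orientation modulation
  flat <- fit_orientation_tuning(dirs, rep(2, 12), 30)
  expect_lt(flat$A1 + flat$A2, 0.5)
  expect_lt(abs(osi(flat)), 0.1)
})

test_that("OSI is the depth of modulation between preferred and orthogonal", {
  expect_equal(osi(list(R_pref = 3, R_ortho = 0)), 1)
  expect_equal(osi(list(R_pref = 2, R_ortho = 2)), 0)
  expect_equal(osi(list(R_pref = 3, R_ortho = 1)), 0.5)
  expect_error(osi(list(R_pref = 0, R_ortho = 0)), "undefined")
  # negative orthogonal response clipped, not allowed to push OSI above 1
  expect_equal(osi(list(R_pref = 3, R_ortho = -1)), 1)
})

test_that("tuning width matches the closed-form HWHM of an isolated Gaussian", {
  fit <- structure(list(theta_pref = 90, A1 = 10, A2 = 0, sigma = 20, B = 1,
                        converged = TRUE), class = "tuning_fit")
  expect_equal(tuning_width(fit), 20 * sqrt(2 * log(2)), tolerance = 1e-3)
  fit$sigma <- 5
  expect_equal(tuning_width(fit), 5 * sqrt(2 * log(2)), tolerance = 1e-3)
  fit$A1 <- 0
  expect_error(tuning_width(fit), "undefined")

  # oracle agreement: brute-force half-max scan of the fitted curve
  fit$A1 <- 8; fit$A2 <- 3; fit$sigma <- 28
  w <- tuning_width(fit)
  grid <- seq(0, 90, by = 0.001)
  curve <- visrecov:::tuning_model(90 + grid, 90, 8, 3, 28, 1)
  half <- 1 + (curve[1] - 1) / 2
  w_scan <- grid[which(curve < half)[1]]
  expect_lt(abs(w - w_scan), 0.1)
})

test_that("binocular orientation difference wraps along the 180-degree cycle", {
  expect_equal(orientation_difference(30, 30), 0)
  expect_equal(orientation_difference(170, 10), -20)
  expect_equal(orientation_difference(100, 10), 90)
  expect_equal(orientation_difference(10, 170), 20)
  # enumeration over wrap cases: result always in (-90, 90] and consistent
  # with the minimal circular distance
  set.seed(4)
  tc <- runif(200, 0, 180); ti <- runif(200, 0, 180)
  d <- orientation_difference(tc, ti)
  expect_true(all(d > -90 & d <= 90))
  circ <- pmin(abs(tc - ti), 180 - abs(tc - ti))
  expect_equal(abs(d), circ, tolerance = 1e-9)
})

test_that("spatial-frequency DoG fit recovers exact parameters and handles degenerate shapes", {
  sfs <- c(0.01, 0.02, 0.04, 0.08, 0.16, 0.32)
  truth <- c(Ac = 12, wc = 0.08, As = 8, ws = 0.03)
  dog <- function(s, p) p[1] * exp(-s^2 / (2 * p[2]^2)) -
    p[3] * exp(-s^2 / (2 * p[4]^2))
  fit <- fit_sf_tuning(sfs, dog(sfs, truth))
  expect_true(fit$converged)
  expect_equal(dog(sfs, c(fit$Ac, fit$wc, fit$As, fit$ws)), dog(sfs, truth),
               tolerance = 0.01)
  # peak location of the fitted curve matches the generating curve
  grid <- seq(0, 0.64, length.out = 2001)
  expect_equal(fit$sf_pref_cpd, grid[which.max(dog(grid, truth))],
               tolerance = 0.005)

  # monotonically decreasing responses: low-pass, preference at/below lowest SF
  fit_lp <- fit_sf_tuning(sfs, 10 * exp(-sfs / 0.02))
  expect_lte(fit_lp$sf_pref_cpd, 0.01)
  expect_error(fit_sf_tuning(c(0.01, 0.02, 0.04), c(1, 2, 1)), ">= 4")
})

test_that("unit ODI is the normalized two-eye difference", {
  expect_equal(odi_unit(1, 1), 0)
  expect_equal(odi_unit(2, 0), 1)
  expect_equal(odi_unit(6, 2), 0.5)
  expect_equal(odi_unit(-1, 2), -1) # negative evoked clipped to 0
  expect_error(odi_unit(0, 0), "undefined")
})

test_that("responsiveness selection thresholds at 2 spikes/s through either eye", {
  met <- data.frame(peak_grating_resp_contra = c(1.9, 2.0, 0.5, 5),
                    peak_grating_resp_ipsi = c(1.9, 0, 2.4, 5))
  sel <- select_responsive_grating(met)
  expect_equal(nrow(sel), 3)
  expect_false(1.9 %in% sel$peak_grating_resp_contra &
                 1.9 %in% sel$peak_grating_resp_ipsi)
  expect_equal(nrow(select_responsive_grating(met[0, ])), 0)
})

test_that("F1 response equals the first-harmonic amplitude of the cycle-averaged rate", {
  m <- 100; dt <- 0.1
  phase <- (0:(m - 1)) / m
  rate <- 5 + 3 * cos(2 * pi * phase)
  counts <- rep(rate * dt, 4)
  expect_equal(f1_response(counts, dt = dt, period_s = 10), 3,
               tolerance = 1e-9)
  expect_lt(f1_response(rep(0.5, 400), dt = dt, period_s = 10), 1e-12)
  # invariance to the phase origin of the fold
  shifted <- counts[c(31:400, 1:30)]
  expect_equal(f1_response(shifted, dt = dt, period_s = 10), 3,
               tolerance = 1e-9)
  expect_error(f1_response(counts, dt = 0.3, period_s = 10), "integer")
  expect_error(f1_response(counts[1:100], dt = dt, period_s = 10),
               "2 full periods")
})

test_that("contrast-response curve locates the semi-saturation contrast", {
  # ideal Naka-Rushton rates sampled along the envelope, no spiking noise
  ctr <- contrast_envelope(seq(0, 9.9, by = 0.1), 10)
  rate <- 20 * ctr^2 / (ctr^2 + 0.3^2)
  cr <- contrast_response(rate * 0.1, ctr, dt = 0.1)
  # closed-form half-max of the generating function: baseline ~ rate at the
  # lowest contrast bin, so the crossing sits within a bin of c50
  expect_lt(abs(cr$c_half - 0.3), 0.05)
  # contrast-independent rate: undefined C1/2
  flat <- contrast_response(rep(1, 99), ctr, dt = 0.1)
  expect_true(is.na(flat$c_half))
  # doubling the gain leaves C1/2 unchanged (scale invariance)
  cr2 <- contrast_response(2 * rate * 0.1, ctr, dt = 0.1)
  expect_equal(cr2$c_half, cr$c_half, tolerance = 1e-9)
})

test_that("waveform classification applies the two-criterion rule", {
  expect_equal(classify_waveform(1.0, 0.05), "broad")
  expect_equal(classify_waveform(0.2, -0.05), "narrow")
  # each criterion alone is not sufficient for narrow
  expect_equal(classify_waveform(0.2, 0.05), "broad")
  expect_equal(classify_waveform(1.0, -0.05), "broad")
  expect_error(classify_waveform(NA, 0), "finite")
})

test_that("metrics driver assembles a coherent per-unit table", {
  units <- rbind(make_unit(1, theta_contra = 30, theta_ipsi = 50),
                 make_unit(2, eye_gain_contra = 20, eye_gain_ipsi = 2,
                           theta_contra = 120, theta_ipsi = 120))
  prot <- build_grating_protocol(repeats = 6, seed = 3)
  tr <- simulate_grating_trials(units, prot, seed = 7)
  mv <- synthesize_noise_movie(small_movie_spec(seed = 2))
  nc <- simulate_noise_response(units, mv, "contra", duration_s = 60, seed = 1)
  ni <- simulate_noise_response(units, mv, "ipsi", duration_s = 60, seed = 2)
  met <- compute_unit_metrics(tr, noise_contra = nc, noise_ipsi = ni,
                              contrast_trace = mv$contrast_trace)
  expect_equal(nrow(met), 2)
  expect_true(all(abs(met$odi_grating) <= 1, na.rm = TRUE))
  expect_true(all(abs(met$odi_noise) <= 1, na.rm = TRUE))
  expect_true(all(met$dO_abs_deg >= 0 & met$dO_abs_deg <= 90, na.rm = TRUE))
  # unit 2 is strongly contra-dominant
  expect_gt(met$odi_grating[2], met$odi_grating[1])
  # preferred orientations near truth for these high-gain units
  err1 <- min(abs(met$theta_pref_contra[1] - 30),
              180 - abs(met$theta_pref_contra[1] - 30))
  expect_lt(err1, 15)
})
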