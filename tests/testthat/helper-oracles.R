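# Independent oracles and fixture builders used across tests.

# All permutations of 1..n (n <= 8), one per row.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(p >= k, p + 1L, p))
  }))
}

# Brute-force minimum mean assignment cost over all permutations
# (uniform masses 1/n on both sides).
brute_force_emd <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, n <= 8)
  P <- all_permutations(n)
  lin <- as.vector((P - 1) * n) + rep(seq_len(n), each = nrow(P))
  min(rowSums(matrix(cost[lin], nrow = nrow(P)))) / n
}

# A small movie spec that synthesizes quickly but still has non-trivial
# spatial and temporal pass-bands.
small_movie_spec <- function(seed = 1, duration_s = 20) {
  noise_movie_spec(grid_px = 20, span_deg = 30, fps = 10,
                   duration_s = duration_s, sf_cutoff_cpd = 0.05,
                   tf_cutoff_hz = 2, contrast_period_s = 10, seed = seed)
}

# One-unit ground-truth row with explicit parameters.
make_unit <- function(unit_id = 1, eye_gain_contra = 10, eye_gain_ipsi = 8,
                      theta_contra = 40, theta_ipsi = 40, sigma = 25,
                      dir_ratio = 0.5, sf_pref = 0.04, sf_sigma_oct = 1.5,
                      c50 = 0.3, hill_n = 2, spont = 2,
                      noise_gain_contra = 10, noise_gain_ipsi = 8,
                      cell_class = "broad") {
  data.frame(unit_id = unit_id, cell_class = cell_class,
             eye_gain_contra = eye_gain_contra, eye_gain_ipsi = eye_gain_ipsi,
             theta_pref_contra = theta_contra, theta_pref_ipsi = theta_ipsi,
             tuning_sigma = sigma, dir_ratio = dir_ratio,
             sf_pref_cpd = sf_pref, sf_sigma_oct = sf_sigma_oct, c50 = c50,
             hill_n = hill_n, spont_rate = spont,
             noise_gain_contra = noise_gain_contra,
             noise_gain_ipsi = noise_gain_ipsi,
             stringsAsFactors = FALSE)
}

# Hand-built trial table: one unit, explicit counts.
make_trials <- function(counts_blank, counts_cond = NULL, eye = "contra",
                        direction = 0, sf = 0.04, duration = 1.5) {
  bl <- data.frame(unit_id = 1, eye = eye, direction_deg = 0, sf_cpd = 0,
                   is_blank = TRUE, trial_index = seq_along(counts_blank),
                   spike_count = counts_blank, duration_s = duration)
  if (is.null(counts_cond)) return(bl)
  cd <- data.frame(unit_id = 1, eye = eye, direction_deg = direction,
                   sf_cpd = sf, is_blank = FALSE,
                   trial_index = length(counts_blank) + seq_along(counts_cond),
                   spike_count = counts_cond, duration_s = duration)
  rbind(bl, cd)
}
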