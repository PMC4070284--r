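# Group-level statistics: bootstrap SE of the median, Kolmogorov-Smirnov
# comparisons, Bonferroni correction, and the pairwise comparison matrix.

#' Bootstrap standard error of the median
#'
#' Standard deviation of the medians of `n_boot` with-replacement resamples.
#'
#' @param values Numeric vector (length >= 2).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return Standard error of the median.
#' @export
bootstrap_median_se <- function(values, n_boot = 1000, seed = 1L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 finite values")
  set.seed(seed)
  meds <- vapply(seq_len(n_boot),
                 function(i) stats::median(sample(values, n, replace = TRUE)),
                 numeric(1))
  stats::sd(meds)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D = sup |ECDF_a - ECDF_b|` with the p-value from [stats::ks.test()]
#' (exact for small samples without ties, asymptotic otherwise).
#'
#' @param a,b Numeric vectors.
#' @param exact Passed to [stats::ks.test()]; `NULL` lets it decide.
#' @return List with `D` and `p`.
#' @export
ks_compare <- function(a, b, exact = NULL) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be nonempty")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` per p-value for a family of `m` comparisons.
#'
#' @param p_values Numeric vector of raw p-values.
#' @param m Family size; must be at least `length(p_values)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) {
    stop("family size m must be at least the number of tests")
  }
  pmin(1, p_values * m)
}

.sig_breaks <- c(1e-5, 1e-4, 1e-3, 1e-2, 0.05)
.sig_labels <- c("<0.00001", "<0.0001", "<0.001", "<0.01", "<0.05", "n.s.")

#' Significance bucket for an adjusted p-value
#'
#' Maps an adjusted p-value to the significance levels used in the pairwise
#' comparison table: `<0.00001`, `<0.0001`, `<0.001`, `<0.01`, `<0.05`,
#' `n.s.`.
#'
#' @param p_adj Adjusted p-value(s).
#' @return Character vector of bucket labels.
#' @export
significance_bucket <- function(p_adj) {
  .sig_labels[findInterval(p_adj, .sig_breaks, left.open = FALSE) + 1L]
}

#' Pairwise KS comparison matrix across treatment groups
#'
#' For every metric and every group pair, runs a two-sample KS test,
#' Bonferroni-adjusts over the number of pairs (the per-metric family), and
#' buckets the adjusted p-value into significance levels.
#'
#' @param groups Named list: one element per group, each a `data.frame` (or
#'   named list) holding the metric vectors.
#' @param metrics Character vector of metric names to compare.
#' @param pairs Optional list of length-2 character vectors of group labels;
#'   defaults to all unordered pairs in `groups` order.
#' @param m Bonferroni family size; defaults to the number of pairs.
#' @return A `data.frame` (rows = metrics, columns = `groupA vs groupB`)
#'   of bucket labels, with attribute `raw`: a `data.frame` of metric, pair,
#'   `n_a`, `n_b`, `D`, `p`, `p_adj`. Missing metrics yield `"absent"` cells.
#' @export
comparison_matrix <- function(groups, metrics, pairs = NULL, m = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  labs <- names(groups)
  if (is.null(pairs)) {
    cmb <- utils::combn(labs, 2, simplify = FALSE)
    pairs <- cmb
  }
  if (is.null(m)) m <- length(pairs)
  pair_names <- vapply(pairs, function(p) paste(p, collapse = " vs "),
                       character(1))

  raw <- list()
  cells <- matrix("absent", nrow = length(metrics), ncol = length(pairs),
                  dimnames = list(metrics, pair_names))
  for (met in metrics) {
    for (k in seq_along(pairs)) {
      ga <- groups[[pairs[[k]][1]]]
      gb <- groups[[pairs[[k]][2]]]
      if (!(met %in% names(ga)) || !(met %in% names(gb))) next
      a <- ga[[met]]; b <- gb[[met]]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) == 0L || length(b) == 0L) next
      ks <- ks_compare(a, b)
      p_adj <- bonferroni_adjust(ks$p, m)
      cells[met, k] <- significance_bucket(p_adj)
      raw[[length(raw) + 1L]] <- data.frame(
        metric = met, pair = pair_names[k], n_a = length(a),
        n_b = length(b), D = ks$D, p = ks$p, p_adj = p_adj,
        stringsAsFactors = FALSE)
    }
  }
  out <- as.data.frame(cells, stringsAsFactors = FALSE)
  attr(out, "raw") <- if (length(raw)) do.call(rbind, raw) else NULL
  out
}
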