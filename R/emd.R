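# Fictive-longitudinal analysis: earth-mover's-distance correspondence
# between cross-sectional populations in the 2-D (grating response, noise F1)
# response plane, flow heat maps, and the diagonal-flow chi-square contrast.

#' Per-axis scale factors for the 2-D response plane
#'
#' Pooled 95th percentiles of the grating-response and noise-F1 axes across
#' one or more population samples, so both axes span roughly `[0, 1]` before
#' computing transport distances. Compute these once from the pooled samples
#' and pass them to [select_top_responsive()] and
#' [earth_mover_correspondence()] so all conditions share one scaling.
#'
#' @param ... Population samples (`data.frame`s with `grating_resp`,
#'   `noise_f1`).
#' @return Named vector `c(grating=, noise=)`.
#' @export
axis_scales <- function(...) {
  pooled <- do.call(rbind, lapply(list(...), function(d) {
    d[, c("grating_resp", "noise_f1")]
  }))
  s <- c(grating = stats::quantile(pooled$grating_resp, 0.95, names = FALSE),
         noise = stats::quantile(pooled$noise_f1, 0.95, names = FALSE))
  s[s <= 0] <- 1
  s
}

#' Select the most responsive units of a population sample
#'
#' Ranks units by `max(grating_resp / s_g, noise_f1 / s_n)` with per-axis
#' scale factors `s` (pooled 95th percentiles, computed from the sample
#' itself unless supplied, e.g. pooled across the two populations being
#' matched) and keeps the top `n`. Ties break deterministically by `unit_id`.
#'
#' @param sample `data.frame` with columns `unit_id`, `grating_resp`,
#'   `noise_f1`.
#' @param n Number of units to keep (default 500).
#' @param scales Optional named vector `c(grating=, noise=)` of axis scales.
#' @return The selected rows (a warning is issued and all rows returned when
#'   the sample is smaller than `n`).
#' @export
select_top_responsive <- function(sample, n = 500, scales = NULL) {
  stopifnot(all(c("unit_id", "grating_resp", "noise_f1") %in% names(sample)))
  if (is.null(scales)) scales <- axis_scales(sample)
  if (nrow(sample) < n) {
    warning(sprintf("sample has only %d units (< n = %d); using all",
                    nrow(sample), n))
    n <- nrow(sample)
  }
  score <- pmax(sample$grating_resp / scales[["grating"]],
                sample$noise_f1 / scales[["noise"]])
  ord <- order(-score, sample$unit_id)
  out <- sample[ord[seq_len(n)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Earth-mover's-distance correspondence between two populations
#'
#' Solves the uniform-weight optimal-transport problem between the two point
#' clouds in the scaled 2-D response plane (Euclidean ground distance). Axis
#' scales default to the pooled 95th percentiles of the two samples. For
#' equal-sized clouds the optimal plan is a one-to-one assignment; unequal
#' sizes split mass. The total cost is the mass-weighted mean transport
#' distance in scaled units (masses sum to 1 on each side).
#'
#' @param A,B Population samples: `data.frame`s with `unit_id`,
#'   `grating_resp`, `noise_f1` (e.g. before and after recovery).
#' @param scales Optional named axis scales `c(grating=, noise=)`.
#' @return An object of class `correspondence_result`: list with `flows`
#'   (`data.frame`: source/target indices, source and target coordinates in
#'   original spikes/s (`x0`, `y0`, `x1`, `y1`; x = grating, y = noise) and
#'   `mass`), `total_cost`, `scaling`.
#' @export
earth_mover_correspondence <- function(A, B, scales = NULL) {
  stopifnot(nrow(A) >= 1L, nrow(B) >= 1L)
  if (is.null(scales)) scales <- axis_scales(A, B)
  ax <- A$grating_resp / scales[["grating"]]
  ay <- A$noise_f1 / scales[["noise"]]
  bx <- B$grating_resp / scales[["grating"]]
  by <- B$noise_f1 / scales[["noise"]]
  cost <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
  m <- nrow(A); n <- nrow(B)
  sol <- transport_ssp(cost, rep(1 / m, m), rep(1 / n, n))
  flows <- data.frame(
    source = sol$source, target = sol$target,
    x0 = A$grating_resp[sol$source], y0 = A$noise_f1[sol$source],
    x1 = B$grating_resp[sol$target], y1 = B$noise_f1[sol$target],
    mass = sol$mass)
  structure(list(flows = flows, total_cost = sol$total_cost,
                 scaling = scales, n_source = m),
            class = "correspondence_result")
}

#' Heat map of summed flow components along one response axis
#'
#' Bins every transport flow at its source point on a grid over the scaled
#' `[0, 1]^2` response plane and accumulates `mass * (target - source)` along
#' the chosen axis, in original spikes/s. Sources outside `[0, 1]` (beyond
#' the 95th-percentile scale) are clamped to the edge bins.
#'
#' @param corr A `correspondence_result`.
#' @param axis `"noise"` or `"grating"`: which displacement component to sum.
#' @param bins Bins per axis (default 25).
#' @return An object of class `flow_heatmap`: list with `grid` (matrix,
#'   rows = grating-axis bins, cols = noise-axis bins; signed spikes/s x
#'   mass), `axis`, `edges` (bin edges in scaled units), `scaling`,
#'   `n_clamped`.
#' @export
flow_heatmap <- function(corr, axis = c("noise", "grating"), bins = 25) {
  axis <- match.arg(axis)
  fl <- corr$flows
  s <- corr$scaling
  gx <- fl$x0 / s[["grating"]]
  gy <- fl$y0 / s[["noise"]]
  edges <- seq(0, 1, length.out = bins + 1)
  ix <- findInterval(gx, edges, rightmost.closed = TRUE)
  iy <- findInterval(gy, edges, rightmost.closed = TRUE)
  n_clamped <- sum(ix < 1 | ix > bins | iy < 1 | iy > bins)
  ix <- pmin(pmax(ix, 1L), bins)
  iy <- pmin(pmax(iy, 1L), bins)
  comp <- if (axis == "noise") fl$y1 - fl$y0 else fl$x1 - fl$x0
  grid <- matrix(0, bins, bins)
  vals <- fl$mass * comp
  for (k in seq_along(vals)) {
    grid[ix[k], iy[k]] <- grid[ix[k], iy[k]] + vals[k]
  }
  structure(list(grid = grid, axis = axis, edges = edges, scaling = s,
                 n_clamped = n_clamped, n_source = corr$n_source),
            class = "flow_heatmap")
}

#' Chi-square contrast of positive flow across the diagonal
#'
#' Builds a 2x2 contingency table of positive-flow magnitude, split by side
#' of the scaled-space diagonal (bins where the scaled noise coordinate
#' exceeds the scaled grating coordinate are "above") and by condition
#' (the two heat maps), and returns Pearson's chi-square statistic and
#' p-value (no continuity correction). Since transport masses sum to 1 per
#' population, each map's magnitudes are multiplied by its number of source
#' neurons, so table entries are total spikes/s of positive displacement
#' summed over the population (the scale at which the flow fields are drawn).
#'
#' @param hm_x,hm_y Two `flow_heatmap`s on identical grids.
#' @return List with `table` (2x2 matrix), `chi2`, `p`.
#' @export
diagonal_flow_contrast <- function(hm_x, hm_y) {
  stopifnot(inherits(hm_x, "flow_heatmap"), inherits(hm_y, "flow_heatmap"),
            identical(dim(hm_x$grid), dim(hm_y$grid)),
            identical(hm_x$edges, hm_y$edges))
  bins <- nrow(hm_x$grid)
  centers <- (hm_x$edges[-1] + hm_x$edges[-(bins + 1)]) / 2
  above <- outer(centers, centers, function(g, n) n > g) # rows grating, cols noise
  pos <- function(hm) {
    ns <- if (is.null(hm$n_source)) 1 else hm$n_source
    pmax(hm$grid, 0) * ns
  }
  tab <- rbind(above = c(x = sum(pos(hm_x)[above]), y = sum(pos(hm_y)[above])),
               below = c(x = sum(pos(hm_x)[!above]), y = sum(pos(hm_y)[!above])))
  if (sum(tab) <= 0) {
    stop("diagonal flow contrast undefined: no positive flow in either map")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, chi2 = unname(ct$statistic), p = ct$p.value)
}
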