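# Earth-mover's-distance correspondence, flow heat maps, diagonal contrast.

make_sample <- function(g, f1, ids = seq_along(g)) {
  data.frame(unit_id = ids, grating_resp = g, noise_f1 = f1)
}

test_that("top-responsive selection is order-invariant with deterministic ties", {
  set.seed(1)
  s <- make_sample(runif(50, 0, 15), runif(50, 0, 4))
  top <- select_top_responsive(s, 10)
  shuf <- s[sample.int(50), ]
  top2 <- select_top_responsive(shuf, 10)
  expect_setequal(top$unit_id, top2$unit_id)
  # a unit dominating both axes is always ranked first
  s2 <- rbind(s, make_sample(100, 100, ids = 999))
  expect_equal(select_top_responsive(s2, 5)$unit_id[1], 999)
  # n equal to the sample size is the identity (as a set)
  expect_setequal(select_top_responsive(s, 50)$unit_id, s$unit_id)
  expect_warning(select_top_responsive(s, 60), "using all")
})

test_that("EMD is zero on identical clouds, symmetric, and recovers translations", {
  set.seed(2)
  A <- make_sample(runif(20, 0, 10), runif(20, 0, 3))
  self <- earth_mover_correspondence(A, A)
  expect_equal(self$total_cost, 0, tolerance = 1e-12)

  B <- make_sample(runif(15, 0, 10), runif(15, 0, 3))
  ab <- earth_mover_correspondence(A, B)
  ba <- earth_mover_correspondence(B, A)
  expect_equal(ab$total_cost, ba$total_cost, tolerance = 1e-10)
  expect_gte(ab$total_cost, 0)
  expect_true(all(ab$flows$mass >= 0))
  expect_equal(sum(ab$flows$mass), 1, tolerance = 1e-10)

  # translation along one axis: cost equals the scaled shift
  sc <- visrecov:::axis_scales(A, A)
  d_orig <- 2
  Bt <- A; Bt$noise_f1 <- A$noise_f1 + d_orig
  sc2 <- c(grating = unname(sc["grating"]), noise = 1)
  tr <- earth_mover_correspondence(A, Bt, scales = c(grating = 1, noise = 1))
  expect_equal(tr$total_cost, d_orig, tolerance = 1e-10)
})

test_that("solver flows match the exhaustive-permutation minimum on small clouds", {
  set.seed(3)
  for (i in 1:40) {
    n <- sample(2:8, 1)
    A <- make_sample(runif(n, 0, 15), runif(n, 0, 4))
    B <- make_sample(runif(n, 0, 15), runif(n, 0, 4))
    corr <- earth_mover_correspondence(A, B)
    sc <- corr$scaling
    cost <- sqrt(outer(A$grating_resp / sc[["grating"]],
                       B$grating_resp / sc[["grating"]], "-")^2 +
                 outer(A$noise_f1 / sc[["noise"]],
                       B$noise_f1 / sc[["noise"]], "-")^2)
    expect_equal(corr$total_cost, brute_force_emd(cost), tolerance = 1e-9)
    # equal sizes with uniform mass: the plan is a one-to-one assignment
    expect_equal(sort(corr$flows$source), 1:n)
    expect_equal(sort(corr$flows$target), 1:n)
  }
})

test_that("EMD satisfies the triangle inequality on random triples", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(3:6, 1)
    A <- make_sample(runif(n, 0, 10), runif(n, 0, 3))
    B <- make_sample(runif(n, 0, 10), runif(n, 0, 3))
    C <- make_sample(runif(n, 0, 10), runif(n, 0, 3))
    sc <- c(grating = 10, noise = 3)
    ab <- earth_mover_correspondence(A, B, scales = sc)$total_cost
    bc <- earth_mover_correspondence(B, C, scales = sc)$total_cost
    ac <- earth_mover_correspondence(A, C, scales = sc)$total_cost
    expect_lte(ac, ab + bc + 1e-9)
  }
})

test_that("unequal-size transport splits mass and conserves marginals", {
  set.seed(5)
  A <- make_sample(runif(7, 0, 10), runif(7, 0, 3))
  B <- make_sample(runif(4, 0, 10), runif(4, 0, 3))
  corr <- earth_mover_correspondence(A, B)
  sm <- tapply(corr$flows$mass, corr$flows$source, sum)
  tm <- tapply(corr$flows$mass, corr$flows$target, sum)
  expect_equal(max(abs(sm - 1 / 7)), 0, tolerance = 1e-10)
  expect_equal(max(abs(tm - 1 / 4)), 0, tolerance = 1e-10)
  # 1 x n transport is uniquely determined: cost is the mean ground distance
  A1 <- make_sample(5, 1.5)
  corr1 <- earth_mover_correspondence(A1, B, scales = c(grating = 1, noise = 1))
  direct <- mean(sqrt((5 - B$grating_resp)^2 + (1.5 - B$noise_f1)^2))
  expect_equal(corr1$total_cost, direct, tolerance = 1e-10)
})

test_that("flow heat maps conserve the total displacement along each axis", {
  set.seed(6)
  A <- make_sample(runif(40, 0, 15), runif(40, 0, 4))
  B <- make_sample(runif(40, 0, 15), runif(40, 0, 4))
  corr <- earth_mover_correspondence(A, B)
  for (ax in c("noise", "grating")) {
    hm <- flow_heatmap(corr, axis = ax)
    comp <- if (ax == "noise") corr$flows$y1 - corr$flows$y0 else
      corr$flows$x1 - corr$flows$x0
    expect_equal(sum(hm$grid), sum(corr$flows$mass * comp), tolerance = 1e-10)
  }
  # zero-length flows -> all-zero heat map
  hm0 <- flow_heatmap(earth_mover_correspondence(A, A), axis = "noise")
  expect_true(all(hm0$grid == 0))
  # a single flow lands its full signed displacement in one source bin
  one_a <- make_sample(1, 0.5)
  one_b <- make_sample(1, 4.5)
  c1 <- earth_mover_correspondence(one_a, one_b,
                                   scales = c(grating = 10, noise = 5))
  hm1 <- flow_heatmap(c1, axis = "noise")
  expect_equal(sum(hm1$grid), 4)
  expect_equal(sum(hm1$grid != 0), 1)
})

test_that("diagonal-flow chi-square separates opposite flow patterns", {
  set.seed(7)
  A <- make_sample(runif(30, 0, 10), runif(30, 0, 10))
  B <- A; B$noise_f1 <- B$noise_f1 + 1
  sc <- c(grating = 10, noise = 10)
  corr <- earth_mover_correspondence(A, B, scales = sc)
  hm <- flow_heatmap(corr, axis = "noise")
  # identical heat maps -> chi2 = 0, p = 1
  same <- diagonal_flow_contrast(hm, hm)
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-9)

  # all positive flow above the diagonal in X, all below in Y: the table is
  # maximally unbalanced and the chi-square equals its closed form n_tot
  hx <- hm; hx$grid[] <- 0; hx$grid[1, 25] <- 5   # above diagonal
  hy <- hm; hy$grid[] <- 0; hy$grid[25, 1] <- 5   # below diagonal
  res <- diagonal_flow_contrast(hx, hy)
  tab <- res$table
  # closed-form Pearson chi-square for this 2x2
  n_tot <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n_tot
  expect_equal(res$chi2, sum((tab - e)^2 / e), tolerance = 1e-9)
  expect_lt(res$p, 0.01)
  hz <- hm; hz$grid[] <- -1
  expect_error(diagonal_flow_contrast(hz, hz), "no positive flow")
})
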