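test_that("the hinge model evaluates by direct substitution and is continuous", {
  m <- piecewise_model(alpha = 1, intercept = 0, betas = -2, psis = 5)
  expect_equal(predict(m, 5), 5)   # hinge term vanishes at the breakpoint
  expect_equal(predict(m, 0), 0)   # below the breakpoint: pure line
  expect_equal(predict(m, 7), 3)   # 7 + (-2)*2
  expect_equal(predict(m, c(0, 5, 7)), c(0, 5, 3))
  # continuity at every breakpoint of a two-kink model
  m2 <- piecewise_model(0.8, 1.2, betas = c(-0.5, -1.1), psis = c(2, 6))
  for (p in m2$psis) {
    d <- 10^-(4:9)
    expect_true(all(abs(predict(m2, p - d) - predict(m2, p + d)) < 1e-3))
    expect_equal(predict(m2, p - 1e-12), predict(m2, p + 1e-12),
                 tolerance = 1e-9)
  }
  # segment slopes accumulate the slope changes
  expect_equal(segment_slopes(m2), c(0.8, 0.3, -0.8))
})

test_that("model construction rejects inconsistent breakpoints", {
  expect_error(piecewise_model(1, 0, betas = -2, psis = c(1, 2)),
               "same length")
  expect_error(piecewise_model(1, 0, betas = c(-1, -1), psis = c(5, 2)),
               "strictly increasing")
})

test_that("weighted line fits match the closed-form normal equations", {
  # exact line
  f <- fit_wls_line(0:2, c(0, 1, 2))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$rss, 0, tolerance = 1e-20)
  # a zero-weight point is ignored by the fit
  f2 <- fit_wls_line(c(0, 1, 2), c(0, 1, 5), w = c(1, 1, 0))
  expect_equal(f2$slope, 1)
  expect_equal(f2$intercept, 0, tolerance = 1e-12)
  expect_gt(f2$rss_unweighted, f2$rss)  # unweighted RSS sees the residual
  # random designs against the normal-equations oracle
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(20); y <- 2 * x + 1 + rnorm(20)
    w <- runif(20, 0.1, 3)
    f3 <- fit_wls_line(x, y, w)
    oracle <- wls_normal_equations(x, y, w)
    expect_equal(f3$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(f3$intercept, oracle$intercept, tolerance = 1e-10)
  }
  expect_error(fit_wls_line(c(1, 1, 1), c(1, 2, 3)), "singular")
  expect_error(fit_wls_line(1:3, 1:3, w = c(1, 0, 0)), "positive weight")
})

test_that("a noiseless kink is recovered exactly", {
  kd <- kink_data()
  f <- fit_segmented(kd$x, kd$y, n_breakpoints = 1)
  expect_equal(f$model$alpha, 1, tolerance = 1e-8)
  expect_equal(f$model$intercept, 0, tolerance = 1e-8)
  expect_equal(f$model$betas, -2, tolerance = 1e-8)
  expect_equal(f$model$psis, 5, tolerance = 1e-6)
  expect_lt(f$rss, 1e-16)
  expect_true(f$converged)
})

test_that("zero breakpoints reduces exactly to the weighted line fit", {
  set.seed(9)
  x <- runif(15); y <- 3 - 2 * x + rnorm(15, 0, 0.2)
  w <- runif(15, 0.5, 2)
  f0 <- fit_segmented(x, y, w, n_breakpoints = 0)
  line <- fit_wls_line(x, y, w)
  expect_equal(f0$model$alpha, line$slope)
  expect_equal(f0$model$intercept, line$intercept)
  expect_equal(f0$rss, line$rss)
})

test_that("collinear data demoted to a straight line when a kink is requested", {
  x <- seq(0, 10, length.out = 12)
  y <- 0.7 * x + 2
  f <- fit_segmented(x, y, n_breakpoints = 1)
  line <- fit_wls_line(x, y)
  expect_lt(abs(f$model$betas), 1e-6)
  expect_equal(f$rss, line$rss, tolerance = 1e-12)
  # the breakpoint of a zero slope change carries no information
  expect_true(is.na(f$psi_se))
})

test_that("iterative fits match the exhaustive grid-search oracle", {
  for (seed in 1:8) {
    d <- generate_volcano(sim_config(n = 20, noise_sd = 0.1, seed = seed))
    f <- fit_segmented(d$x, d$y, n_breakpoints = 1)
    oracle <- oracle_grid_fit(d$x, d$y, n_breakpoints = 1)
    expect_lte(f$rss, oracle$rss * 1.01)
    expect_lt(abs(f$model$psis - oracle$psi), 0.05 * diff(range(d$x)))
  }
})

test_that("fitted quantities are invariant to row permutation", {
  d <- generate_volcano(sim_config(n = 24, seed = 5))
  f1 <- fit_segmented(d$x, d$y, n_breakpoints = 1)
  set.seed(77)
  perm <- sample(nrow(d))
  f2 <- fit_segmented(d$x[perm], d$y[perm], n_breakpoints = 1)
  expect_equal(f1$model$psis, f2$model$psis, tolerance = 1e-10)
  expect_equal(f1$model$alpha, f2$model$alpha, tolerance = 1e-10)
  expect_equal(f1$rss, f2$rss, tolerance = 1e-10)
  expect_equal(f1$psi_se, f2$psi_se, tolerance = 1e-8)
})

test_that("adding a breakpoint never worsens the residual sum of squares", {
  for (seed in c(2, 13, 31)) {
    d <- generate_volcano(sim_config(n = 30, seed = seed, noise_sd = 0.5))
    sel <- select_model(d$x, d$y, min_segment = 5)
    fits <- sel$candidates
    bs <- sort(as.integer(names(fits)))
    for (i in seq_along(bs)[-1]) {
      expect_lte(fits[[as.character(bs[i])]]$rss,
                 fits[[as.character(bs[i - 1])]]$rss * (1 + 1e-6))
    }
  }
})

test_that("fitted breakpoints stay strictly inside the data range, ordered", {
  for (seed in 1:6) {
    d <- generate_volcano(sim_config(
      alpha = 1.2, betas = c(-1.2, -1.4), psis = c(3, 7), n = 30,
      seed = seed, noise_sd = 0.4))
    f <- fit_segmented(d$x, d$y, n_breakpoints = 2)
    expect_true(all(f$model$psis > min(d$x)))
    expect_true(all(f$model$psis < max(d$x)))
    if (f$model$n_breakpoints == 2)
      expect_gt(diff(f$model$psis), 0)
  }
})

test_that("delta-method breakpoint SE vanishes in the noiseless limit", {
  kd <- kink_data()
  f <- fit_segmented(kd$x, kd$y, n_breakpoints = 1)
  expect_lt(f$psi_se, 1e-6)
  # SE shrinks with the noise level
  ses <- vapply(c(0.5, 0.05), function(s) {
    d <- generate_volcano(sim_config(n = 30, noise_sd = s, seed = 100,
                                     equispaced = TRUE))
    fit_segmented(d$x, d$y, n_breakpoints = 1)$psi_se
  }, numeric(1))
  expect_lt(ses[2], ses[1])
})

test_that("breakpoint SE requires a converged fit", {
  d <- generate_volcano(sim_config(n = 20, seed = 3))
  f <- fit_segmented(d$x, d$y, n_breakpoints = 1)
  f$converged <- FALSE
  expect_error(breakpoint_se(f), "converged")
})

test_that("a user-supplied psi_init must sit inside the data range", {
  kd <- kink_data()
  expect_error(fit_segmented(kd$x, kd$y, n_breakpoints = 1,
                             psi_init = 12), "strictly inside")
  f <- fit_segmented(kd$x, kd$y, n_breakpoints = 1, psi_init = 3)
  expect_equal(f$model$psis, 5, tolerance = 1e-6)
})

test_that("infeasible sample sizes for the requested breakpoints error out", {
  expect_error(fit_segmented(1:4, c(1, 2, 3, 1), n_breakpoints = 1),
               "at least")
})

test_that("iterative fits agree with the CRAN segmented implementation", {
  skip_if_not_installed("segmented")
  for (seed in c(4, 21)) {
    d <- generate_volcano(sim_config(n = 25, noise_sd = 0.3, seed = seed))
    f <- fit_segmented(d$x, d$y, n_breakpoints = 1)
    base_lm <- stats::lm(y ~ x, data = data.frame(x = d$x, y = d$y))
    ref <- segmented::segmented(base_lm, seg.Z = ~x,
                                psi = stats::median(d$x))
    ref_rss <- sum(stats::residuals(ref)^2)
    expect_equal(f$rss, ref_rss, tolerance = 0.01)
    expect_equal(f$model$psis, unname(ref$psi[, "Est."]), tolerance = 0.1)
  }
})
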