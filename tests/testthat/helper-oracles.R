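# Independent oracles used to cross-check the iterative fitter.  These are
# deliberately brute-force and share no code with the package internals.

# Closed-form weighted least squares for a straight line via the normal
# equations.
wls_normal_equations <- function(x, y, w) {
  X <- cbind(1, x)
  A <- crossprod(X, w * X)
  b <- crossprod(X, w * y)
  co <- solve(A, b)
  list(intercept = co[1L], slope = co[2L])
}

# Exhaustive breakpoint search: a dense grid of candidate positions with a
# fixed-hinge WLS solve at each candidate.  For two breakpoints, a coarser
# grid over ordered pairs.
oracle_grid_fit <- function(x, y, w = rep(1, length(x)), n_breakpoints = 1L,
                            n_grid = 500L) {
  n <- length(x)
  xs <- sort(x)
  hinge_rss <- function(psis) {
    X <- cbind(1, x)
    for (p in psis) X <- cbind(X, pmax(x - p, 0))
    f <- tryCatch(stats::lm.wfit(X, y, w), error = function(e) NULL)
    if (is.null(f) || anyNA(f$coefficients)) return(Inf)
    sum(w * f$residuals^2)
  }
  if (n_breakpoints == 0L)
    return(list(rss = hinge_rss(numeric(0)), psi = numeric(0)))
  grid <- seq(xs[2L], xs[n - 1L], length.out = n_grid)
  if (n_breakpoints == 1L) {
    rss <- vapply(grid, hinge_rss, numeric(1))
    i <- which.min(rss)
    return(list(rss = rss[i], psi = grid[i]))
  }
  g2 <- seq(xs[2L], xs[n - 1L], length.out = min(n_grid, 60L))
  best <- list(rss = Inf, psi = c(NA_real_, NA_real_))
  for (i in seq_along(g2)) {
    for (j in seq_along(g2)) {
      if (g2[j] <= g2[i]) next
      r <- hinge_rss(c(g2[i], g2[j]))
      if (r < best$rss) best <- list(rss = r, psi = c(g2[i], g2[j]))
    }
  }
  best
}

# Brute-force minimum-covariance-determinant estimate: enumerate every
# subset of size h, keep the one whose sample covariance has the smallest
# determinant.  Only usable for small n.
brute_mcd <- function(Z, h = floor((nrow(Z) + ncol(Z) + 1) / 2)) {
  n <- nrow(Z)
  combos <- utils::combn(n, h)
  best_det <- Inf
  best <- NULL
  for (k in seq_len(ncol(combos))) {
    idx <- combos[, k]
    S <- stats::cov(Z[idx, , drop = FALSE])
    d <- det(S)
    if (d < best_det) {
      best_det <- d
      best <- list(center = colMeans(Z[idx, , drop = FALSE]), cov = S,
                   subset = idx)
    }
  }
  best
}

# Shared fixture: a noiseless sharp volcano sampled on integers.
kink_data <- function() {
  x <- 0:10
  list(x = x, y = ifelse(x < 5, x, 10 - x))
}
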