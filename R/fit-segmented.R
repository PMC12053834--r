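#' Weighted least-squares straight line
#'
#' Minimizes \eqn{\sum_i w_i (y_i - a x_i - b)^2}.  This is the zero-
#' breakpoint base case of the segmented fitter; weights let noisy
#' low-activity points count less (see [compute_weights()]).
#'
#' @param x,y numeric vectors of equal length.
#' @param w nonnegative weights, recycled scalar allowed; default uniform.
#' @return list with \code{slope}, \code{intercept}, \code{fitted},
#'   \code{rss} (weighted, the WLS objective) and \code{rss_unweighted}.
#' @examples
#' fit_wls_line(0:2, c(0, 1, 2))$slope   # 1
#' @export
fit_wls_line <- function(x, y, w = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' lengths differ")
  if (is.null(w)) w <- rep(1, n)
  if (length(w) == 1L) w <- rep(w, n)
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(w)))
    stop("non-finite values in 'x', 'y' or 'w'")
  if (any(w < 0)) stop("weights must be nonnegative")
  pos <- w > 0
  if (sum(pos) < 2L)
    stop("need at least 2 points with strictly positive weight")
  if (diff(range(x[pos])) == 0)
    stop("singular design: 'x' constant among positive-weight points")
  fit <- stats::lm.wfit(cbind(`(Intercept)` = 1, x = x), y, w)
  fitted <- y - fit$residuals
  list(slope = unname(fit$coefficients["x"]),
       intercept = unname(fit$coefficients["(Intercept)"]),
       fitted = fitted,
       rss = sum(w * fit$residuals^2),
       rss_unweighted = sum(fit$residuals^2))
}

## Deterministic breakpoint initializations via a coarse profile scan:
## evaluate the fixed-hinge WLS residual at candidate positions (interval
## midpoints for small samples, quantiles otherwise) and seed the
## iteration from the lowest-RSS basins.  No RNG anywhere, so a fit is
## reproducible from (data, weights) alone.
scan_psi_inits <- function(x, y, w, n_breakpoints) {
  xs <- sort(unique(x))
  m <- length(xs)
  lo <- sort(x)[2L]; hi <- sort(x)[length(x) - 1L]
  cand <- if (m <= 26L) {
    (xs[-1L] + xs[-m]) / 2
  } else {
    unname(stats::quantile(x, seq(0.05, 0.95, length.out = 24L),
                           type = 7))
  }
  cand <- sort(unique(pmin(pmax(cand, lo), hi)))
  rss_at <- function(p) {
    f <- fit_at_psi(x, y, w, p)
    if (is.null(f)) Inf else f$rss
  }
  if (n_breakpoints == 1L) {
    rss <- vapply(cand, rss_at, numeric(1))
    starts <- cand[order(rss)][seq_len(min(6L, length(cand)))]
    return(lapply(starts, identity))
  }
  ## two breakpoints: scan ordered pairs on a thinned candidate set
  thin <- cand[unique(round(seq(1L, length(cand),
                                length.out = min(12L, length(cand)))))]
  pairs <- list(); prss <- numeric(0)
  for (i in seq_along(thin)) {
    for (j in seq_along(thin)) {
      if (thin[j] <= thin[i]) next
      pairs[[length(pairs) + 1L]] <- c(thin[i], thin[j])
      prss[length(pairs)] <- rss_at(c(thin[i], thin[j]))
    }
  }
  keep <- order(prss)[seq_len(min(5L, length(pairs)))]
  inits <- pairs[keep]
  ## tertile pair as a shape-agnostic fallback start
  c(inits, list(unname(stats::quantile(x, c(1, 2) / 3, type = 7))))
}

## One run of the iterative breakpoint-refinement (working-covariate)
## scheme from a given starting psi.  The raw update can 2-cycle between
## adjacent data points, so each proposed step is accepted only if the
## hinge-fit RSS does not get worse, with step halving otherwise (the
## standard safeguard for this algorithm).  Returns NULL on failure
## (singular working design or vanishing slope change).
muggeo_iterate <- function(x, y, w, psi, tol, max_iter) {
  n <- length(x)
  B <- length(psi)
  xs <- sort(x)
  lo <- xs[2L]; hi <- xs[n - 1L]
  xrange <- xs[n] - xs[1L]
  rss_at <- function(p) {
    f <- fit_at_psi(x, y, w, p)
    if (is.null(f)) Inf else f$rss
  }
  rss_cur <- rss_at(psi)
  converged <- FALSE
  n_iter <- 0L
  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    U <- vapply(psi, function(p) pmax(x - p, 0), numeric(n))
    V <- vapply(psi, function(p) -heaviside(x - p), numeric(n))
    X <- cbind(1, x, U, V)
    fit <- tryCatch(stats::lm.wfit(X, y, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) return(NULL)
    beta_hat <- fit$coefficients[2L + seq_len(B)]
    gamma_hat <- fit$coefficients[2L + B + seq_len(B)]
    if (any(abs(beta_hat) < 1e-10 * max(1, stats::sd(y)))) return(NULL)
    step <- gamma_hat / beta_hat
    h <- 1
    psi_new <- psi
    improved <- FALSE
    for (halving in 1:12) {
      cand <- sort(pmin(pmax(psi + h * step, lo), hi))
      rss_cand <- rss_at(cand)
      if (rss_cand <= rss_cur * (1 + 1e-12)) {
        psi_new <- cand
        rss_cur <- min(rss_cur, rss_cand)
        improved <- TRUE
        break
      }
      h <- h / 2
    }
    if (!improved) { converged <- TRUE; break }  # no downhill move left
    shift <- max(abs(psi_new - psi))
    psi <- psi_new
    if (shift < tol * xrange) { converged <- TRUE; break }
  }
  list(psi = psi, converged = converged, n_iter = n_iter)
}

## Fit the hinge model at FIXED breakpoints (gamma terms dropped): WLS of
## y on [1, x, U_1..U_B].  Returns NULL if the design is singular (e.g. a
## breakpoint outside the span of positive-weight x).
fit_at_psi <- function(x, y, w, psi) {
  n <- length(x)
  B <- length(psi)
  if (B > 0L) {
    U <- vapply(psi, function(p) pmax(x - p, 0), numeric(n))
    X <- cbind(1, x, U)
  } else X <- cbind(1, x)
  fit <- tryCatch(stats::lm.wfit(X, y, w), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) return(NULL)
  co <- unname(fit$coefficients)
  model <- piecewise_model(alpha = co[2L], intercept = co[1L],
                           betas = if (B > 0L) co[2L + seq_len(B)] else numeric(0),
                           psis = psi)
  res <- fit$residuals
  list(model = model, rss = sum(w * res^2), rss_unweighted = sum(res^2),
       fitted = y - res)
}

#' Fit a continuous piecewise-linear model with iterative breakpoint
#' refinement
#'
#' Implements the classic iterative scheme for segmented regression: at the
#' current breakpoint estimates \eqn{\psi_i}, augment the design with the
#' working covariates \eqn{U_i = (x-\psi_i)H(x-\psi_i)} and
#' \eqn{V_i = -H(x-\psi_i)}, solve a weighted least-squares problem for
#' \eqn{y} on \eqn{[1, x, U, V]}, and update each breakpoint by
#' \eqn{\psi_i \leftarrow \psi_i + \hat\gamma_i/\hat\beta_i} (with
#' \eqn{\hat\gamma_i} the \eqn{V_i} coefficient), clamping updates inside
#' the observed data range, until the largest shift falls below
#' \code{tol * range(x)}.  The reported model refits at the converged
#' breakpoints with the \eqn{\gamma} terms dropped.
#'
#' Because the iteration only finds a local optimum, the fitter first
#' scans a deterministic coarse grid of candidate breakpoints
#' (fixed-hinge WLS at interval midpoints, or quantiles for larger
#' samples), starts the refinement from the lowest-RSS basins, and keeps
#' the best converged solution.  Breakpoints that collapse closer than the smallest
#' inter-point gap are merged and the fit is demoted to fewer breakpoints
#' (flagged via \code{demoted}).
#'
#' @param x,y numeric vectors of equal length.
#' @param w optional nonnegative weights (default uniform).
#' @param n_breakpoints 0, 1 or 2.
#' @param psi_init optional numeric vector of starting breakpoints,
#'   strictly inside the range of \code{x}; when supplied it is tried
#'   first, ahead of the default restarts.
#' @param tol convergence tolerance as a fraction of \code{range(x)}
#'   (default \code{1e-4}).
#' @param max_iter maximum refinement iterations per restart (default 100).
#' @return an object of class \code{"segmented_fit"}: a list with
#'   \code{model} (a [piecewise_model()]), and diagnostics \code{rss}
#'   (weighted), \code{rss_unweighted}, \code{n}, \code{k}
#'   \code{= 2*(n_breakpoints+1)}, \code{bic}, \code{r2} (unweighted),
#'   \code{psi_se} (delta-method breakpoint standard errors, \code{NA}
#'   where undefined), \code{converged}, \code{n_iter}, \code{demoted},
#'   \code{fitted}, plus the data used.
#' @examples
#' x <- 0:10
#' y <- ifelse(x < 5, x, 10 - x)
#' f <- fit_segmented(x, y, n_breakpoints = 1)
#' f$model$psis   # 5
#' @export
fit_segmented <- function(x, y, w = NULL, n_breakpoints = 1L,
                          psi_init = NULL, tol = 1e-4, max_iter = 100L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' lengths differ")
  if (is.null(w)) w <- rep(1, n)
  if (length(w) == 1L) w <- rep(w, n)
  if (any(w < 0)) stop("weights must be nonnegative")
  n_breakpoints <- as.integer(n_breakpoints)
  if (!n_breakpoints %in% 0:2)
    stop("'n_breakpoints' must be 0, 1 or 2")
  k <- 2L * (n_breakpoints + 1L)
  if (n < k + 1L)
    stop(sprintf("need at least %d points to fit %d breakpoint(s), got %d",
                 k + 1L, n_breakpoints, n))
  xr <- range(x)
  if (diff(xr) == 0) stop("singular design: 'x' is constant")

  if (n_breakpoints == 0L) {
    line <- fit_wls_line(x, y, w)
    model <- piecewise_model(line$slope, line$intercept)
    return(new_segmented_fit(model, x, y, w, line$rss, line$rss_unweighted,
                             line$fitted, converged = TRUE, n_iter = 0L,
                             demoted = FALSE))
  }

  if (!is.null(psi_init)) {
    psi_init <- sort(as.numeric(psi_init))
    if (length(psi_init) != n_breakpoints)
      stop("'psi_init' length must equal 'n_breakpoints'")
    if (any(psi_init <= xr[1L]) || any(psi_init >= xr[2L]))
      stop("'psi_init' must lie strictly inside the range of 'x'")
  }
  inits <- scan_psi_inits(x, y, w, n_breakpoints)
  if (!is.null(psi_init)) inits <- c(list(psi_init), inits)

  best <- NULL
  best_nonconv <- NULL
  for (ini in inits) {
    it <- muggeo_iterate(x, y, w, ini, tol, max_iter)
    if (is.null(it)) next
    final <- fit_at_psi(x, y, w, it$psi)
    if (is.null(final)) next
    cand <- c(final, list(converged = it$converged, n_iter = it$n_iter))
    if (it$converged) {
      if (is.null(best) || cand$rss < best$rss) best <- cand
    } else {
      if (is.null(best_nonconv) || cand$rss < best_nonconv$rss)
        best_nonconv <- cand
    }
  }
  ## Non-convergence returns the best iterate flagged, never an error.
  if (is.null(best)) best <- best_nonconv
  if (is.null(best)) {
    ## Refinement failed in every restart because the slope change is
    ## numerically zero (collinear data): report the degenerate hinge fit
    ## at the default initialization, whose beta ~ 0 reproduces the
    ## straight line.
    fb <- fit_at_psi(x, y, w, inits[[1L]])
    if (is.null(fb))
      stop("segmented fit failed: singular design for the requested ",
           "breakpoint count")
    best <- c(fb, list(converged = TRUE, n_iter = 0L))
  }

  fit <- check_psi_merge(best, x, y, w)
  new_segmented_fit(fit$model, x, y, w, fit$rss, fit$rss_unweighted,
                    fit$fitted, converged = fit$converged,
                    n_iter = fit$n_iter, demoted = isTRUE(fit$demoted))
}

## Merge breakpoints closer than the smallest inter-point gap and demote
## to a fit with fewer breakpoints (flagged).
check_psi_merge <- function(fit, x, y, w) {
  psi <- fit$model$psis
  if (length(psi) < 2L) return(fit)
  gap <- min(diff(sort(unique(x))))
  if (all(diff(psi) >= gap)) return(fit)
  merged <- mean(psi)
  demo <- fit_at_psi(x, y, w, merged)
  if (is.null(demo)) return(fit)
  c(demo, list(converged = fit$converged, n_iter = fit$n_iter,
               demoted = TRUE))
}

new_segmented_fit <- function(model, x, y, w, rss, rss_unweighted, fitted,
                              converged, n_iter, demoted) {
  n <- length(x)
  k <- 2L * (model$n_breakpoints + 1L)
  r2 <- if (stats::sd(y) > 0) r_squared(y, fitted) else NA_real_
  ## numerically exact fits (RSS at rounding-noise level relative to the
  ## weighted total sum of squares) score the -Inf sentinel
  tss_w <- sum(w * (y - stats::weighted.mean(y, w))^2)
  rss_eff <- if (rss <= 1e-12 * max(tss_w, .Machine$double.xmin)) 0 else rss
  out <- structure(
    list(model = model, x = x, y = y, w = w,
         rss = rss, rss_unweighted = rss_unweighted, fitted = fitted,
         n = n, k = k,
         bic = if (n > k) bic_score(rss_eff, n, k) else NA_real_,
         r2 = r2,
         psi_se = rep(NA_real_, model$n_breakpoints),
         converged = converged, n_iter = n_iter, demoted = demoted,
         min_segment_ok = NA),
    class = "segmented_fit")
  if (model$n_breakpoints > 0L && converged) {
    se <- tryCatch(breakpoint_se(out), error = function(e) NULL)
    if (!is.null(se)) out$psi_se <- se
  }
  out
}

#' @export
print.segmented_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  n = %d, k = %d, RSS = %.6g, BIC = %.6g, R2 = %.4f\n",
              x$n, x$k, x$rss, x$bic, x$r2))
  if (x$model$n_breakpoints > 0L)
    cat("  breakpoint SE:", paste(signif(x$psi_se, 4), collapse = ", "),
        "\n")
  if (!x$converged) cat("  WARNING: breakpoint refinement did not converge\n")
  if (x$demoted) cat("  NOTE: coincident breakpoints merged (fit demoted)\n")
  invisible(x)
}

#' @export
predict.segmented_fit <- function(object, x = object$x, ...) {
  predict(object$model, x)
}

#' Delta-method standard errors for fitted breakpoints
#'
#' Refits the working regression of the breakpoint-refinement scheme at the
#' converged breakpoint estimates and applies the delta method:
#' \eqn{SE(\hat\psi_i) \approx SE(\hat\gamma_i) / |\hat\beta_i|}.  Returns
#' \code{NA} (undefined) for a breakpoint whose slope change is numerically
#' zero.
#'
#' @param fit a converged \code{"segmented_fit"} with at least one
#'   breakpoint.
#' @return numeric vector of standard errors, one per breakpoint.
#' @export
breakpoint_se <- function(fit) {
  stopifnot(inherits(fit, "segmented_fit"))
  B <- fit$model$n_breakpoints
  if (B == 0L) return(numeric(0))
  if (!fit$converged)
    stop("breakpoint standard errors require a converged fit")
  x <- fit$x; y <- fit$y; w <- fit$w
  psi <- fit$model$psis
  n <- length(x)
  U <- vapply(psi, function(p) pmax(x - p, 0), numeric(n))
  V <- vapply(psi, function(p) -heaviside(x - p), numeric(n))
  df <- as.data.frame(cbind(y = y, x = x, U, V))
  names(df) <- c("y", "x", paste0("U", seq_len(B)), paste0("V", seq_len(B)))
  lmfit <- stats::lm(y ~ ., data = df, weights = w)
  sm <- suppressWarnings(summary(lmfit))$coefficients
  se <- rep(NA_real_, B)
  for (i in seq_len(B)) {
    bn <- paste0("U", i); gn <- paste0("V", i)
    if (!(bn %in% rownames(sm)) || !(gn %in% rownames(sm))) next
    beta_hat <- sm[bn, "Estimate"]
    if (!is.finite(beta_hat) || abs(beta_hat) < 1e-10 * max(1, stats::sd(y)))
      next
    se[i] <- sm[gn, "Std. Error"] / abs(beta_hat)
  }
  se
}
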