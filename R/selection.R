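#' Bayesian information criterion for a least-squares fit
#'
#' Gaussian-likelihood form \eqn{BIC = n \ln(RSS/n) + k \ln(n)}: the
#' \eqn{k \ln n} penalty balances the fit improvement of each extra
#' segment (two more parameters) against overfitting.  An exact fit
#' (\code{rss = 0}) returns \code{-Inf} as a sentinel so that it always
#' wins model selection.
#'
#' @param rss residual sum of squares (nonnegative).
#' @param n number of data points.
#' @param k number of fitted parameters; must satisfy \code{n > k}.
#' @return the BIC value (\code{-Inf} for an exact fit).
#' @examples
#' bic_score(10, 10, 2)   # 2 * log(10)
#' @export
bic_score <- function(rss, n, k) {
  if (rss < 0) stop("'rss' must be nonnegative")
  if (n <= k) stop("underdetermined: need n > k")
  if (rss == 0) return(-Inf)
  n * log(rss / n) + k * log(n)
}

#' Parameter count of a piecewise-linear model
#'
#' Each segment contributes a slope and one further free quantity
#' (the intercept for the first segment, the breakpoint position for each
#' later one), so the count grows by two per additional segment:
#' \eqn{k = 2 (B + 1)} for \eqn{B} breakpoints.
#'
#' @param n_breakpoints integer in \code{0:2}.
#' @return integer parameter count.
#' @export
param_count <- function(n_breakpoints) {
  n_breakpoints <- as.integer(n_breakpoints)
  if (!all(n_breakpoints %in% 0:2))
    stop("'n_breakpoints' must be 0, 1 or 2")
  2L * (n_breakpoints + 1L)
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum (y_{act} - y_{pred})^2 / \sum (y_{act} - \bar y)^2},
#' always computed on unweighted residuals regardless of any weights used
#' during fitting.  A weighted fit can therefore score \emph{negative}
#' \eqn{R^2} on the raw data — worse than predicting the mean — which is
#' exactly the signal used to invalidate false-positive volcano claims.
#'
#' @param y_act observed response values.
#' @param y_pred predicted values, same length.
#' @return a real number \eqn{\le 1}.
#' @examples
#' r_squared(c(0, 1, 2), c(2, 1, 0))   # -3
#' @export
r_squared <- function(y_act, y_pred) {
  y_act <- as.numeric(y_act); y_pred <- as.numeric(y_pred)
  if (length(y_act) != length(y_pred)) stop("length mismatch")
  if (length(y_act) < 2L) stop("need at least 2 points")
  sstot <- sum((y_act - mean(y_act))^2)
  if (sstot == 0) stop("R^2 undefined: 'y_act' is constant")
  1 - sum((y_act - y_pred)^2) / sstot
}

#' Fit 0-, 1- and 2-breakpoint models and choose by BIC
#'
#' Fits every feasible breakpoint count \eqn{B \in \{0, ...,
#' \code{max_breakpoints}\}} and selects the candidate with the lowest
#' BIC.  Feasibility follows the points-per-segment rule: \eqn{B} is
#' attempted only when \eqn{n \ge \code{min\_segment} (B+1)}, and a fitted
#' candidate is discarded (with a recorded reason) when any of its fitted
#' segments holds fewer than \code{min_segment} points.  The default
#' \code{min_segment = 5} is the minimal requirement; 10 is the
#' conservative choice.
#'
#' A nesting guard reruns a \eqn{B}-breakpoint fit from extra starting
#' values seeded by the \eqn{(B-1)}-breakpoint solution if the larger
#' model ever lands on a worse RSS than the smaller one (the larger model
#' contains the smaller one, so its optimal RSS cannot be worse).
#'
#' @param x descriptor values.
#' @param y performance values.
#' @param w optional nonnegative weights.
#' @param max_breakpoints maximum breakpoints to consider (0, 1 or 2;
#'   default 2).
#' @param min_segment minimum points per fitted segment (default 5).
#' @param flat_tol,orientation passed to [classify_shape()].
#' @param z half-width of the peak uncertainty band in standard errors
#'   (default 1).
#' @return an object of class \code{"model_selection"}: list with
#'   \code{candidates} (one \code{"segmented_fit"} per feasible B),
#'   \code{infeasible} (named reasons), \code{chosen_b}, \code{fit} (the
#'   chosen fit), \code{shape}, and \code{peak} (a \code{"volcano_peak"}
#'   or \code{NULL}).
#' @examples
#' x <- 0:10; y <- ifelse(x < 5, x, 10 - x)
#' sel <- select_model(x, y, min_segment = 3)
#' sel$chosen_b   # 1
#' sel$shape      # "volcano_sharp"
#' @export
select_model <- function(x, y, w = NULL, max_breakpoints = 2L,
                         min_segment = 5L, flat_tol = 0.1,
                         orientation = c("maximize", "minimize"), z = 1) {
  orientation <- match.arg(orientation)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n < 3L) stop("need at least 3 points")
  max_breakpoints <- as.integer(max_breakpoints)
  stopifnot(max_breakpoints %in% 0:2, min_segment >= 2)

  candidates <- list()
  infeasible <- character(0)
  for (B in 0:max_breakpoints) {
    key <- as.character(B)
    if (n < min_segment * (B + 1L)) {
      infeasible[key] <- sprintf(
        "n = %d < %d points required for %d segment(s) of >= %d", n,
        min_segment * (B + 1L), B + 1L, min_segment)
      next
    }
    fit <- tryCatch(fit_segmented(x, y, w, n_breakpoints = B),
                    error = function(e) conditionMessage(e))
    if (is.character(fit)) { infeasible[key] <- fit; next }
    fit$min_segment_ok <- min_segment_ok(x, fit$model, min_segment)
    if (!fit$min_segment_ok) {
      infeasible[key] <- sprintf(
        "a fitted segment holds fewer than %d points", min_segment)
      next
    }
    candidates[[key]] <- fit
  }
  if (length(candidates) == 0L)
    stop("no feasible candidate model: ",
         paste(sprintf("[B=%s] %s", names(infeasible), infeasible),
               collapse = "; "))

  ## Nesting guard: a B-model with beta_B = 0 reproduces the (B-1)-model,
  ## so its optimal RSS cannot exceed the smaller model's.
  bs <- as.integer(names(candidates))
  for (B in sort(bs)) {
    if (!((B - 1L) %in% bs)) next
    small <- candidates[[as.character(B - 1L)]]
    big <- candidates[[as.character(B)]]
    if (big$rss <= small$rss * (1 + 1e-8)) next
    psi0 <- small$model$psis
    extra <- unname(stats::quantile(x, c(0.3, 0.7), type = 7))
    for (p in extra) {
      ini <- sort(c(psi0, p))[seq_len(B)]
      if (any(ini <= min(x)) || any(ini >= max(x))) next
      refit <- tryCatch(fit_segmented(x, y, w, n_breakpoints = B,
                                      psi_init = ini),
                        error = function(e) NULL)
      if (!is.null(refit) && refit$rss < big$rss &&
          min_segment_ok(x, refit$model, min_segment)) {
        refit$min_segment_ok <- TRUE
        candidates[[as.character(B)]] <- refit
        big <- refit
      }
    }
  }

  bics <- vapply(candidates, function(f) f$bic, numeric(1))
  ## ties (including several exact fits at -Inf) break toward parsimony
  ord <- order(bics, as.integer(names(candidates)))
  chosen_key <- names(candidates)[ord[1L]]
  fit <- candidates[[chosen_key]]

  out <- structure(
    list(candidates = candidates, infeasible = infeasible,
         chosen_b = as.integer(chosen_key), fit = fit,
         min_segment = as.integer(min_segment),
         flat_tol = flat_tol, orientation = orientation, z = z,
         shape = NA_character_, peak = NULL),
    class = "model_selection")
  out$shape <- classify_shape(out, flat_tol = flat_tol,
                              orientation = orientation)
  if (out$shape %in% c("volcano_sharp", "volcano_plateau"))
    out$peak <- locate_peak(fit, out$shape, z = z)
  out
}

## Count points per fitted segment (H(0) = 1: x == psi belongs to the
## segment to the right) and check the minimum-points rule.
min_segment_ok <- function(x, model, min_segment) {
  edges <- c(-Inf, model$psis, Inf)
  counts <- vapply(seq_len(length(edges) - 1L), function(j) {
    sum(x >= edges[j] & x < edges[j + 1L])
  }, numeric(1))
  all(counts >= min_segment)
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Piecewise-linear model selection (BIC)\n")
  for (key in names(x$candidates)) {
    f <- x$candidates[[key]]
    marker <- if (as.integer(key) == x$chosen_b) " <- chosen" else ""
    cat(sprintf("  B = %s: BIC = %.4g, RSS = %.4g, R2 = %.4f%s\n",
                key, f$bic, f$rss, f$r2, marker))
  }
  for (key in names(x$infeasible))
    cat(sprintf("  B = %s: infeasible (%s)\n", key, x$infeasible[key]))
  cat("  shape:", x$shape, "\n")
  if (!is.null(x$peak))
    cat(sprintf("  peak: x = %.6g (band %.6g .. %.6g), y = %.6g\n",
                x$peak$x_peak, x$peak$x_lo, x$peak$x_hi, x$peak$y_peak))
  invisible(x)
}

#' Classify the shape of the selected piecewise trend
#'
#' Uses the orientation-adjusted segment slopes \eqn{s_1, ..., s_{B+1}}
#' of the chosen fit:
#' \itemize{
#'   \item \eqn{B = 0}: \code{flat} when \eqn{|s_1| sd(x)/sd(y) \le}
#'     \code{flat_tol} (a scale-free slope magnitude), else
#'     \code{monotonic}.
#'   \item \eqn{B = 1}: \code{volcano_sharp} when \eqn{s_1 > 0} and
#'     \eqn{s_2 < 0}; \code{inverted} when \eqn{s_1 < 0 < s_2}; else
#'     \code{monotonic}.
#'   \item \eqn{B = 2}: \code{volcano_plateau} when \eqn{s_1 > 0},
#'     \eqn{|s_2| \le} \code{flat_tol}\eqn{\cdot\max(|s_1|, |s_3|)} and
#'     \eqn{s_3 < 0}; otherwise a rise followed by a fall is classed
#'     \code{volcano_sharp}, a fall followed by a rise \code{inverted},
#'     and a single sign \code{monotonic}.
#' }
#' Any chosen fit with unweighted \eqn{R^2 < 0} is classed
#' \code{invalid}: the claimed trend has no statistical support
#' (a false-positive volcano).
#'
#' @param result a \code{"model_selection"} object.
#' @param flat_tol relative slope tolerance for "flat" (default 0.1).
#' @param orientation \code{"maximize"} (activity-like metrics) or
#'   \code{"minimize"} (cost-like metrics, e.g. overpotential); the latter
#'   sign-flips slopes instead of mutating the data.
#' @return one of \code{"volcano_sharp"}, \code{"volcano_plateau"},
#'   \code{"monotonic"}, \code{"inverted"}, \code{"flat"},
#'   \code{"invalid"}.
#' @export
classify_shape <- function(result, flat_tol = 0.1,
                           orientation = c("maximize", "minimize")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(result, "model_selection"))
  fit <- result$fit
  if (is.finite(fit$r2) && fit$r2 < 0) return("invalid")
  s <- segment_slopes(fit$model)
  if (orientation == "minimize") s <- -s
  B <- fit$model$n_breakpoints
  if (B == 0L) {
    sdx <- stats::sd(fit$x); sdy <- stats::sd(fit$y)
    if (sdy > 0 && abs(s[1L]) * sdx / sdy <= flat_tol) return("flat")
    return("monotonic")
  }
  if (B == 1L) {
    if (s[1L] > 0 && s[2L] < 0) return("volcano_sharp")
    if (s[1L] < 0 && s[2L] > 0) return("inverted")
    return("monotonic")
  }
  ## B == 2
  if (s[1L] > 0 && abs(s[2L]) <= flat_tol * max(abs(s[1L]), abs(s[3L])) &&
      s[3L] < 0) return("volcano_plateau")
  if (any(s > 0) && any(s < 0)) {
    pos_first <- which(s > 0)[1L]
    neg_first <- which(s < 0)[1L]
    if (pos_first < neg_first) return("volcano_sharp")
    return("inverted")
  }
  "monotonic"
}

#' Locate the volcano peak with an uncertainty band
#'
#' For a sharp volcano the peak sits at the breakpoint where the slope
#' turns negative, with band \eqn{\psi \pm z\, SE(\psi)}; for a plateau
#' volcano the point estimate is the plateau midpoint
#' \eqn{(\psi_1+\psi_2)/2} with band
#' \eqn{[\psi_1 - z\, SE(\psi_1),\ \psi_2 + z\, SE(\psi_2)]}.  When a
#' breakpoint standard error is undefined the band is marked unavailable
#' but the point estimate is still returned.
#'
#' @param fit the chosen \code{"segmented_fit"}.
#' @param shape \code{"volcano_sharp"} or \code{"volcano_plateau"}.
#' @param z band half-width in standard errors (default 1).
#' @return a \code{"volcano_peak"}: list with \code{x_peak},
#'   \code{y_peak}, \code{x_lo}, \code{x_hi}, \code{kind},
#'   \code{band_available}.
#' @export
locate_peak <- function(fit, shape, z = 1) {
  stopifnot(inherits(fit, "segmented_fit"),
            shape %in% c("volcano_sharp", "volcano_plateau"))
  model <- fit$model
  se <- fit$psi_se
  if (shape == "volcano_sharp") {
    s <- segment_slopes(model)
    turn <- which(s[-1L] < 0 & s[-length(s)] > 0)
    i <- if (length(turn)) turn[length(turn)] else model$n_breakpoints
    x_peak <- model$psis[i]
    band_ok <- is.finite(se[i])
    x_lo <- if (band_ok) x_peak - z * se[i] else x_peak
    x_hi <- if (band_ok) x_peak + z * se[i] else x_peak
  } else {
    x_peak <- mean(model$psis[1:2])
    band_ok <- all(is.finite(se[1:2]))
    x_lo <- if (band_ok) model$psis[1L] - z * se[1L] else model$psis[1L]
    x_hi <- if (band_ok) model$psis[2L] + z * se[2L] else model$psis[2L]
  }
  structure(list(x_peak = x_peak, y_peak = predict(model, x_peak),
                 x_lo = x_lo, x_hi = x_hi,
                 kind = sub("volcano_", "", shape),
                 band_available = band_ok),
            class = "volcano_peak")
}
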