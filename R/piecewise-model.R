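#' Continuous piecewise-linear (hinge) model
#'
#' Constructs a continuous piecewise-linear model
#' \deqn{\hat y(x) = c + \alpha x + \sum_i \beta_i (x - \psi_i) H(x - \psi_i)}
#' where \eqn{H} is the Heaviside step function (with the convention
#' \eqn{H(0) = 1}), \eqn{\alpha} and \eqn{c} are the slope and intercept of
#' the first segment, \eqn{\beta_i} is the slope change at breakpoint
#' \eqn{\psi_i}, and the curve is continuous everywhere.  This is the
#' canonical hinge parameterization used for empirical volcano plots: a
#' one-breakpoint model with \eqn{\alpha > 0} and \eqn{\alpha + \beta < 0}
#' rises to a tip at \eqn{\psi} and falls beyond it (Sabatier behavior).
#'
#' @param alpha slope of the first segment (response units per descriptor
#'   unit).
#' @param intercept intercept of the first segment.
#' @param betas numeric vector (possibly empty) of slope changes, one per
#'   breakpoint.
#' @param psis numeric vector of breakpoint positions, strictly increasing,
#'   same length as \code{betas}.
#' @return an object of class \code{"piecewise_model"}.
#' @examples
#' m <- piecewise_model(alpha = 1, intercept = 0, betas = -2, psis = 5)
#' predict(m, c(0, 5, 7))   # 0, 5, 3
#' segment_slopes(m)        # 1, -1
#' @seealso [fit_segmented()], [segment_slopes()]
#' @export
piecewise_model <- function(alpha, intercept, betas = numeric(0),
                            psis = numeric(0)) {
  betas <- as.numeric(betas)
  psis <- as.numeric(psis)
  if (length(betas) != length(psis))
    stop("'betas' and 'psis' must have the same length")
  if (length(psis) > 1L && any(diff(psis) <= 0))
    stop("breakpoint positions 'psis' must be strictly increasing")
  stopifnot(is.finite(alpha), is.finite(intercept),
            all(is.finite(betas)), all(is.finite(psis)))
  structure(
    list(alpha = as.numeric(alpha), intercept = as.numeric(intercept),
         betas = betas, psis = psis, n_breakpoints = length(psis)),
    class = "piecewise_model")
}

#' Evaluate a piecewise-linear model
#'
#' Total function: finite output for any finite \code{x}, continuous in
#' \code{x} (the hinge term vanishes at each breakpoint).
#'
#' @param object a \code{"piecewise_model"}.
#' @param x numeric vector of descriptor values.
#' @param ... unused.
#' @return predicted response, same length as \code{x}.
#' @export
predict.piecewise_model <- function(object, x, ...) {
  x <- as.numeric(x)
  y <- object$intercept + object$alpha * x
  if (object$n_breakpoints > 0L) {
    for (i in seq_len(object$n_breakpoints)) {
      y <- y + object$betas[i] * pmax(x - object$psis[i], 0)
    }
  }
  y
}

#' @export
print.piecewise_model <- function(x, ...) {
  cat("Continuous piecewise-linear model with", x$n_breakpoints,
      "breakpoint(s)\n")
  cat(sprintf("  first segment: slope %.6g, intercept %.6g\n",
              x$alpha, x$intercept))
  if (x$n_breakpoints > 0L) {
    s <- segment_slopes(x)
    for (i in seq_len(x$n_breakpoints)) {
      cat(sprintf("  breakpoint %d: psi = %.6g, slope change %.6g (-> slope %.6g)\n",
                  i, x$psis[i], x$betas[i], s[i + 1L]))
    }
  }
  invisible(x)
}

#' Segment slopes of a piecewise model
#'
#' The slope of segment \eqn{j} is \eqn{\alpha + \sum_{i \le j-1} \beta_i}.
#'
#' @param model a \code{"piecewise_model"}.
#' @return numeric vector of length \code{n_breakpoints + 1}.
#' @export
segment_slopes <- function(model) {
  cumsum(c(model$alpha, model$betas))
}

## Heaviside with H(0) = 1; used for the V working covariate of the
## breakpoint-refinement regression (the hinge itself never needs it since
## the hinge term is 0 at psi either way).
heaviside <- function(x) as.numeric(x >= 0)
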