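#' Flag outliers in the descriptor-performance plane
#'
#' Standardizes \code{(x, y)} to zero mean and unit variance, fits a
#' minimum-covariance-determinant (MCD) estimate of location and scatter
#' (via \code{MASS::cov.rob}), and computes robust Mahalanobis distances.
#' Points whose squared robust distance exceeds the
#' \eqn{\chi^2_2} quantile at \code{1 - contamination} are flag
#' candidates; at most \code{ceiling(contamination * n)} of them (the
#' largest distances) are flagged.  Below \eqn{n = 7} the MCD is
#' unreliable, so the method falls back to a per-axis robust z-score
#' (median/MAD, threshold 3.5).
#'
#' Flagged points are \emph{never} removed automatically: in the low-data
#' regime an outlier is hard to distinguish from an extreme yet genuine
#' point, so removal is the analyst's call.
#'
#' @param x descriptor values.
#' @param y performance values.
#' @param contamination expected outlier fraction, in \code{(0, 0.5)}
#'   (default 0.1).
#' @return an \code{"outlier_report"}: list with logical \code{flags},
#'   \code{robust_distance} (squared robust Mahalanobis distance, or
#'   max per-axis |z| in fallback mode), \code{contamination},
#'   \code{cutoff}, \code{method} (\code{"mcd"} or \code{"robust_z"}).
#' @export
flag_outliers <- function(x, y, contamination = 0.1) {
  if (contamination <= 0 || contamination >= 0.5)
    stop("'contamination' must be in (0, 0.5)")
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  max_flags <- ceiling(contamination * n)

  if (n >= 7L) {
    zx <- scale_unit(x); zy <- scale_unit(y)
    Z <- cbind(zx, zy)
    ## MCD subset search is randomized for large n; pin the RNG locally
    ## so reports are reproducible, without touching the caller's stream.
    mcd <- with_local_seed(20240801L,
                           MASS::cov.rob(Z, method = "mcd", nsamp = "best"))
    d2 <- stats::mahalanobis(Z, center = mcd$center, cov = mcd$cov)
    cutoff <- stats::qchisq(1 - contamination, df = 2)
    candidate <- d2 > cutoff
    flags <- rep(FALSE, n)
    if (any(candidate)) {
      ord <- order(d2, decreasing = TRUE)
      keep <- ord[seq_len(min(max_flags, sum(candidate)))]
      flags[intersect(keep, which(candidate))] <- TRUE
    }
    method <- "mcd"
    dist <- d2
  } else {
    zscore <- function(v) {
      m <- stats::median(v); s <- stats::mad(v)
      if (s == 0) return(rep(0, length(v)))
      abs(v - m) / s
    }
    dist <- pmax(zscore(x), zscore(y))
    cutoff <- 3.5
    flags <- rep(FALSE, n)
    candidate <- dist > cutoff
    if (any(candidate)) {
      ord <- order(dist, decreasing = TRUE)
      keep <- ord[seq_len(min(max_flags, sum(candidate)))]
      flags[intersect(keep, which(candidate))] <- TRUE
    }
    method <- "robust_z"
  }
  structure(list(flags = flags, robust_distance = dist,
                 contamination = contamination, cutoff = cutoff,
                 method = method),
            class = "outlier_report")
}

scale_unit <- function(v) {
  s <- stats::sd(v)
  if (s == 0) return(v - mean(v))
  (v - mean(v)) / s
}

## Evaluate an expression with a pinned RNG state, restoring the caller's
## state (or lack of one) afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Outlier report (%s, contamination %.2f): %d of %d flagged\n",
              x$method, x$contamination, sum(x$flags), length(x$flags)))
  invisible(x)
}

#' Augment a descriptor pool with mathematical operators
#'
#' Generates candidate composite descriptors from the originals with the
#' operator set \{multiplication, division, square, square root, natural
#' logarithm\}: \code{a*b} for unordered pairs, \code{a/b} for ordered
#' pairs whose denominator is bounded away from zero, \code{a^2} for all,
#' and \code{sqrt(a)}, \code{log(a)} only when \code{a} is strictly
#' positive for every record.  Candidates with any non-finite value are
#' excluded, with the reason recorded in the \code{"excluded"} attribute.
#' Expressions are canonical (commutative products ordered
#' lexicographically) and deduplicated.  With all operators and \eqn{d}
#' all-positive descriptors the candidate count is
#' \eqn{d + d(d-1)/2 + d(d-1) + 3d}.
#'
#' @param dataset a [kinetic_dataset()] (or a data frame of numeric
#'   descriptor columns).
#' @param ops character subset of
#'   \code{c("multiply", "divide", "square", "sqrt", "log")}; empty set
#'   returns the originals only.
#' @param depth 1 (default) for one round of composition, or 2 to also
#'   apply the unary operators to the binary results (covers forms such
#'   as the square root of a ratio).
#' @return a list of \code{"feature_candidate"} objects, each with
#'   \code{expression} and \code{values}; attribute \code{"excluded"} is
#'   a data frame of rejected expressions and reasons.
#' @export
augment_features <- function(dataset,
                             ops = c("multiply", "divide", "square",
                                     "sqrt", "log"),
                             depth = 1L) {
  if (length(ops) > 0L) {
    ops <- match.arg(ops, c("multiply", "divide", "square", "sqrt", "log"),
                     several.ok = TRUE)
  }
  cols <- if (inherits(dataset, "kinetic_dataset")) {
    nm <- attr(dataset, "descriptor_names")
    stats::setNames(lapply(nm, function(d) dataset[[d]]), nm)
  } else {
    stopifnot(is.data.frame(dataset))
    as.list(dataset)
  }
  if (length(cols) == 0L) stop("need at least one descriptor")

  excluded <- list()
  out <- list()
  seen <- character(0)
  add <- function(expr, values, reason_if_bad = NULL) {
    if (expr %in% seen) return(invisible(NULL))
    if (any(!is.finite(values))) {
      excluded[[length(excluded) + 1L]] <<-
        data.frame(expression = expr,
                   reason = reason_if_bad %||% "non-finite values")
      return(invisible(NULL))
    }
    seen <<- c(seen, expr)
    out[[length(out) + 1L]] <<- structure(
      list(expression = expr, values = values), class = "feature_candidate")
    invisible(NULL)
  }
  exclude <- function(expr, reason) {
    excluded[[length(excluded) + 1L]] <<-
      data.frame(expression = expr, reason = reason)
  }

  nm <- names(cols)
  for (a in nm) add(a, cols[[a]])

  apply_ops <- function(pool, unary_only = FALSE) {
    pn <- names(pool)
    if ("multiply" %in% ops && !unary_only && length(pn) > 1L) {
      for (i in seq_along(pn)) for (j in seq_along(pn)) {
        if (i >= j) next
        pair <- sort(c(pn[i], pn[j]))
        add(paste(pair[1L], "*", pair[2L]),
            pool[[pair[1L]]] * pool[[pair[2L]]])
      }
    }
    if ("divide" %in% ops && !unary_only && length(pn) > 1L) {
      for (a in pn) for (b in pn) {
        if (a == b) next
        expr <- paste(a, "/", b)
        den <- pool[[b]]
        if (any(abs(den) < 1e-12 * max(abs(den), 1))) {
          exclude(expr, "denominator too close to zero")
          next
        }
        add(expr, pool[[a]] / den)
      }
    }
    if ("square" %in% ops)
      for (a in pn) add(paste0("(", a, ")^2"), pool[[a]]^2)
    if ("sqrt" %in% ops) {
      for (a in pn) {
        if (all(pool[[a]] > 0)) add(paste0("sqrt(", a, ")"), sqrt(pool[[a]]))
        else exclude(paste0("sqrt(", a, ")"), "non-positive values")
      }
    }
    if ("log" %in% ops) {
      for (a in pn) {
        if (all(pool[[a]] > 0)) add(paste0("log(", a, ")"), log(pool[[a]]))
        else exclude(paste0("log(", a, ")"), "non-positive values")
      }
    }
  }

  apply_ops(cols)
  if (depth >= 2L) {
    binary <- out[vapply(out, function(f)
      grepl(" [*/] ", f$expression), logical(1))]
    if (length(binary)) {
      pool2 <- stats::setNames(
        lapply(binary, function(f) f$values),
        vapply(binary, function(f) paste0("(", f$expression, ")"),
               character(1)))
      apply_ops(pool2, unary_only = TRUE)
    }
  }
  attr(out, "excluded") <- if (length(excluded)) {
    do.call(rbind, excluded)
  } else data.frame(expression = character(0), reason = character(0))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen candidate descriptors for the best volcano fit
#'
#' Runs the full model-selection pipeline ([select_model()]) on every
#' candidate, classifies the resulting shape, and ranks candidates by
#' unweighted \eqn{R^2} (descending) among those whose shape is a sharp
#' or plateau volcano; non-volcano candidates are listed after the
#' volcano block, flagged.  Ties break deterministically by the canonical
#' expression string, so repeated runs yield identical rankings.
#'
#' @param dataset a [kinetic_dataset()] supplying the performance vector.
#' @param candidates list of feature candidates from
#'   [augment_features()]; default augments the dataset's descriptors
#'   with all operators.
#' @param w optional weights (default: the dataset's \code{weight}
#'   column).
#' @param ... further arguments passed to [select_model()]
#'   (\code{min_segment}, \code{max_breakpoints}, \code{flat_tol},
#'   \code{orientation}, \code{z}).
#' @return a \code{"screen_result"}: list with \code{ranking} (a data
#'   frame: rank, expression, shape, r2, bic, chosen_b, x_peak,
#'   is_volcano) and \code{selections} (named list of
#'   \code{"model_selection"} objects for candidates that could be fit).
#' @export
screen_descriptors <- function(dataset, candidates = NULL, w = NULL, ...) {
  if (is.null(candidates)) candidates <- augment_features(dataset)
  if (length(candidates) == 0L) stop("no candidates to screen")
  y <- performance_values(dataset)
  if (is.null(w)) w <- dataset$weight %||% rep(1, length(y))

  rows <- list()
  selections <- list()
  failures <- character(0)
  for (cand in candidates) {
    sel <- tryCatch(
      suppressWarnings(select_model(cand$values, y, w, ...)),
      error = function(e) conditionMessage(e))
    if (is.character(sel)) { failures[cand$expression] <- sel; next }
    selections[[cand$expression]] <- sel
    is_volcano <- sel$shape %in% c("volcano_sharp", "volcano_plateau")
    rows[[length(rows) + 1L]] <- data.frame(
      expression = cand$expression,
      shape = sel$shape,
      r2 = sel$fit$r2,
      bic = sel$fit$bic,
      chosen_b = sel$chosen_b,
      x_peak = if (!is.null(sel$peak)) sel$peak$x_peak else NA_real_,
      is_volcano = is_volcano,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("screening failed for every candidate: ",
         paste(sprintf("[%s] %s", names(failures), failures),
               collapse = "; "))
  tab <- do.call(rbind, rows)
  ord <- order(!tab$is_volcano, -tab$r2, tab$expression)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab <- tab[, c("rank", "expression", "shape", "r2", "bic", "chosen_b",
                 "x_peak", "is_volcano")]
  structure(list(ranking = tab, selections = selections,
                 failures = failures),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Descriptor screening:", nrow(x$ranking), "candidates ranked\n")
  print(utils::head(x$ranking, 10), digits = 4)
  if (nrow(x$ranking) > 10) cat("  ...\n")
  invisible(x)
}
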