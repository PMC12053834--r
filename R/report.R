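#' One-shot volcano analysis of a dataset
#'
#' Runs the full pipeline on a single descriptor: read (if given a path),
#' weight, fit 0/1/2-breakpoint models, select by BIC, classify the
#' shape, locate the peak, and flag outliers.  The returned report embeds
#' every setting needed to re-execute it, and serializes losslessly to
#' JSON via [write_report_json()].
#'
#' @param data a [kinetic_dataset()] or a file path accepted by
#'   [read_kinetic_table()].
#' @param x_col descriptor column (default: the dataset's first
#'   descriptor).
#' @param y_col performance column (required when \code{data} is a path).
#' @param sd_col,label_col,weight_col passed to [read_kinetic_table()].
#' @param lambda weighting parameter (default 0 = uniform); ignored when
#'   the input carries an explicit weight column.
#' @param weight_floor floor of the weighting scheme (default 0.05).
#' @param min_segment,max_breakpoints,flat_tol,orientation,z passed to
#'   [select_model()].
#' @param contamination passed to [flag_outliers()].
#' @return a \code{"volcano_report"} list: \code{dataset} summary,
#'   \code{settings}, \code{selection} (candidate diagnostics),
#'   \code{model} (chosen coefficients), \code{shape}, \code{peak},
#'   \code{outliers}, per-point \code{table}, and \code{version}.
#' @examples
#' d <- generate_volcano(sim_config(n = 20, seed = 7))
#' rep <- run_fit(d)
#' rep$shape
#' @export
run_fit <- function(data, x_col = NULL, y_col = NULL, sd_col = NULL,
                    label_col = NULL, weight_col = NULL,
                    lambda = 0, weight_floor = 0.05,
                    min_segment = 5L, max_breakpoints = 2L,
                    flat_tol = 0.1, orientation = "maximize", z = 1,
                    contamination = 0.1) {
  dataset <- if (inherits(data, "kinetic_dataset")) data else {
    if (is.null(y_col)) stop("'y_col' is required when reading from a file")
    read_kinetic_table(data, y_col = y_col, x_col = x_col,
                       sd_col = sd_col, label_col = label_col,
                       weight_col = weight_col)
  }
  if (is.null(x_col)) x_col <- attr(dataset, "descriptor_names")[1L]
  if (!x_col %in% attr(dataset, "descriptor_names"))
    stop(sprintf("descriptor column '%s' not in dataset", x_col))
  x <- dataset[[x_col]]
  y <- performance_values(dataset)

  explicit_w <- !is.null(weight_col) ||
    (!is.null(dataset$weight) && any(dataset$weight != 1))
  w <- if (explicit_w) {
    dataset$weight
  } else if (lambda > 0) {
    compute_weights(dataset, weight_scheme(lambda, weight_floor))
  } else rep(1, length(y))

  sel <- suppressWarnings(
    select_model(x, y, w, max_breakpoints = max_breakpoints,
                 min_segment = min_segment, flat_tol = flat_tol,
                 orientation = orientation, z = z))
  out_rep <- flag_outliers(x, y, contamination = contamination)
  fit <- sel$fit

  report <- list(
    dataset = list(
      n = nrow(dataset),
      x_col = x_col,
      y_col = attr(dataset, "performance_name"),
      descriptor_names = attr(dataset, "descriptor_names"),
      dropped_rows = attr(dataset, "dropped") %||% 0L,
      provenance = attr(dataset, "provenance") %||% ""),
    settings = list(
      lambda = lambda, weight_floor = weight_floor,
      explicit_weights = explicit_w,
      min_segment = as.integer(min_segment),
      max_breakpoints = as.integer(max_breakpoints),
      flat_tol = flat_tol, orientation = orientation, z = z,
      contamination = contamination,
      bic_form = "n*log(rss/n) + k*log(n) on the weighted RSS"),
    selection = list(
      chosen_b = sel$chosen_b,
      candidates = lapply(sel$candidates, function(f) list(
        n_breakpoints = f$model$n_breakpoints, rss = f$rss,
        rss_unweighted = f$rss_unweighted, bic = f$bic, r2 = f$r2,
        converged = f$converged, n_iter = f$n_iter)),
      infeasible = as.list(sel$infeasible)),
    model = list(
      alpha = fit$model$alpha, intercept = fit$model$intercept,
      betas = fit$model$betas, psis = fit$model$psis,
      segment_slopes = segment_slopes(fit$model),
      psi_se = fit$psi_se, r2 = fit$r2, bic = fit$bic, rss = fit$rss,
      converged = fit$converged, demoted = fit$demoted),
    shape = sel$shape,
    peak = if (!is.null(sel$peak)) {
      list(x_peak = sel$peak$x_peak, y_peak = sel$peak$y_peak,
           x_lo = sel$peak$x_lo, x_hi = sel$peak$x_hi,
           kind = sel$peak$kind,
           band_available = sel$peak$band_available)
    },
    outliers = list(
      method = out_rep$method, contamination = out_rep$contamination,
      cutoff = out_rep$cutoff, flags = out_rep$flags,
      robust_distance = out_rep$robust_distance),
    table = data.frame(
      label = dataset$label, x = x, y = y, weight = w,
      predicted = predict(fit$model, x),
      residual = y - predict(fit$model, x),
      outlier = out_rep$flags),
    version = as.character(utils::packageVersion("volcanofit")))
  class(report) <- "volcano_report"
  report
}

#' @export
print.volcano_report <- function(x, ...) {
  cat(sprintf("Volcano report: n = %d, shape = %s, B = %d, R2 = %.4f\n",
              x$dataset$n, x$shape, x$selection$chosen_b, x$model$r2))
  if (!is.null(x$peak))
    cat(sprintf("  peak at x = %.6g (band %.6g .. %.6g), y = %.6g\n",
                x$peak$x_peak, x$peak$x_lo, x$peak$x_hi, x$peak$y_peak))
  nf <- sum(x$outliers$flags)
  if (nf > 0)
    cat("  flagged outlier(s):",
        paste(x$table$label[x$outliers$flags], collapse = ", "), "\n")
  invisible(x)
}

#' Write a volcano report as deterministic JSON
#'
#' No timestamps, fixed key order, full numeric precision: the same
#' analysis always yields a byte-identical file, and every numeric field
#' round-trips losslessly.
#'
#' @param report a \code{"volcano_report"} (or any list).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = I(17), dataframe = "columns",
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON volcano report
#' @param path a file written by [write_report_json()].
#' @return the report as a list (class \code{"volcano_report"}).
#' @export
read_report_json <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(rep) <- "volcano_report"
  rep
}

#' Screen every (augmented) descriptor of a dataset
#'
#' Pipeline behind the \code{screen} CLI subcommand: read, augment the
#' descriptor pool with operators, screen all candidates, and build the
#' full [run_fit()] report for the top-ranked volcano.
#'
#' @param data a [kinetic_dataset()] or file path.
#' @param y_col,sd_col,label_col passed to [read_kinetic_table()] when
#'   \code{data} is a path.
#' @param ops,depth passed to [augment_features()].
#' @param lambda,weight_floor weighting as in [run_fit()].
#' @param ... further [select_model()] options.
#' @return a \code{"screen_report"}: list with \code{ranking} (data
#'   frame), \code{excluded} (dropped candidates and reasons),
#'   \code{settings}, and \code{top_report} (full
#'   \code{"volcano_report"} of the best volcano candidate, or
#'   \code{NULL} when none is volcano-shaped).
#' @export
run_screen <- function(data, y_col = NULL, sd_col = NULL, label_col = NULL,
                       ops = c("multiply", "divide", "square", "sqrt",
                               "log"),
                       depth = 1L, lambda = 0, weight_floor = 0.05, ...) {
  dataset <- if (inherits(data, "kinetic_dataset")) data else {
    if (is.null(y_col)) stop("'y_col' is required when reading from a file")
    read_kinetic_table(data, y_col = y_col, sd_col = sd_col,
                       label_col = label_col)
  }
  candidates <- augment_features(dataset, ops = ops, depth = depth)
  if (length(candidates) == 0L)
    stop("no usable descriptor candidates: ",
         paste(attr(candidates, "excluded")$reason, collapse = "; "))
  w <- if (lambda > 0) {
    compute_weights(dataset, weight_scheme(lambda, weight_floor))
  } else NULL
  res <- screen_descriptors(dataset, candidates, w = w, ...)

  top <- NULL
  volcano_rows <- res$ranking[res$ranking$is_volcano, , drop = FALSE]
  if (nrow(volcano_rows) > 0L) {
    top_expr <- volcano_rows$expression[1L]
    cand <- candidates[[which(vapply(candidates, function(f)
      f$expression, character(1)) == top_expr)]]
    tmp <- as.data.frame(dataset)
    tmp$..candidate <- cand$values
    ds2 <- suppressWarnings(kinetic_dataset(
      tmp, descriptor_names = "..candidate",
      performance_name = attr(dataset, "performance_name"),
      provenance = attr(dataset, "provenance") %||% ""))
    top <- run_fit(ds2, x_col = "..candidate", lambda = lambda,
                   weight_floor = weight_floor, ...)
    top$dataset$x_col <- top_expr
  }
  structure(list(ranking = res$ranking,
                 excluded = attr(candidates, "excluded"),
                 failures = res$failures,
                 settings = list(ops = ops, depth = depth, lambda = lambda,
                                 weight_floor = weight_floor),
                 top_report = top),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Descriptor screen:", nrow(x$ranking), "candidates;",
      sum(x$ranking$is_volcano), "volcano-shaped\n")
  print(utils::head(x$ranking, 10), digits = 4)
  invisible(x)
}

#' Plot a fitted volcano
#'
#' Points (outliers highlighted), the fitted piecewise segments, a
#' vertical line at the volcano tip, and a shaded peak-uncertainty band.
#' Every annotated number equals the corresponding report field.
#'
#' @param x a \code{"volcano_report"} from [run_fit()].
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, \code{x}.
#' @export
plot.volcano_report <- function(x, main = NULL, ...) {
  tab <- x$table
  if (is.null(main))
    main <- sprintf("%s  (R2 = %.3f)", x$shape, x$model$r2)
  graphics::plot(tab$x, tab$y, pch = 19,
                 col = ifelse(tab$outlier, "red", "black"),
                 xlab = x$dataset$x_col, ylab = x$dataset$y_col,
                 main = main, ...)
  if (!is.null(x$peak) && isTRUE(x$peak$band_available)) {
    usr <- graphics::par("usr")
    graphics::rect(x$peak$x_lo, usr[3L], x$peak$x_hi, usr[4L],
                   col = grDevices::adjustcolor("steelblue", 0.2),
                   border = NA)
  }
  xs <- seq(min(tab$x), max(tab$x), length.out = 200)
  model <- piecewise_model(x$model$alpha, x$model$intercept,
                           x$model$betas, x$model$psis)
  graphics::lines(xs, predict(model, xs), lwd = 2, col = "steelblue")
  if (!is.null(x$peak))
    graphics::abline(v = x$peak$x_peak, col = "blue", lwd = 1.5)
  if (any(tab$outlier))
    graphics::legend("bottomright", legend = "flagged outlier",
                     pch = 19, col = "red", bty = "n")
  invisible(x)
}

#' Save a volcano plot to SVG or PNG
#' @param report a \code{"volcano_report"}.
#' @param path output path ending in \code{.svg} or \code{.png}.
#' @param width,height device size in inches.
#' @return \code{path}, invisibly.
#' @export
save_volcano_plot <- function(report, path, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         svg = grDevices::svg(path, width = width, height = height),
         png = grDevices::png(path, width = width * 100,
                              height = height * 100),
         stop("unsupported plot format: .", ext))
  on.exit(grDevices::dev.off())
  plot(report)
  invisible(path)
}

#' Analyze benchmark tables deposited on disk
#'
#' Runs [run_fit()] on each table of a directory of curated case-study
#' CSV/XLSX files (with a manifest naming column roles and per-case
#' weighting parameters) and collects peak positions, shapes and
#' \eqn{R^2} values.  The curated tables themselves are an external
#' deposit and are not shipped with the package.
#'
#' @param dir directory containing the tables plus a \code{manifest.csv}
#'   with columns \code{file}, \code{x_col}, \code{y_col}, and optional
#'   \code{sd_col}, \code{lambda}, \code{contamination}.
#' @return data frame with one row per table (file, shape, r2, x_peak,
#'   n_outliers).
#' @export
run_benchmarks <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path))
    stop("no benchmark manifest at '", manifest_path, "'")
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    rep <- run_fit(file.path(dir, m$file),
                   x_col = if (nzchar(m$x_col %||% "")) m$x_col,
                   y_col = m$y_col,
                   sd_col = if (nzchar(m$sd_col %||% "")) m$sd_col,
                   lambda = if (!is.null(m$lambda) && is.finite(m$lambda))
                     m$lambda else 0,
                   contamination = if (!is.null(m$contamination) &&
                                       is.finite(m$contamination))
                     m$contamination else 0.1)
    data.frame(file = m$file, shape = rep$shape, r2 = rep$model$r2,
               x_peak = if (!is.null(rep$peak)) rep$peak$x_peak
                        else NA_real_,
               n_outliers = sum(rep$outliers$flags))
  })
  do.call(rbind, rows)
}
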