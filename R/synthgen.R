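#' Configuration for a synthetic volcano dataset
#'
#' Bundles the ground-truth piecewise model with sampling parameters.
#' Defaults emulate small curated kinetic tables: a couple of dozen
#' catalysts, a single-breakpoint volcano, homoscedastic Gaussian noise.
#'
#' @param alpha,intercept,betas,psis ground-truth piecewise model, see
#'   [piecewise_model()].
#' @param n number of records (>= 3; default 25).
#' @param x_range numeric length-2 descriptor range; breakpoints must lie
#'   inside it.
#' @param noise_sd Gaussian noise standard deviation (absolute response
#'   units; default 0.1 of the noiseless response range).
#' @param seed integer seed; the generator never touches the global RNG
#'   stream outside its own scope.
#' @param equispaced logical; \code{TRUE} for an equispaced descriptor
#'   grid, \code{FALSE} (default) for uniform draws.
#' @param n_outliers number of injected outliers (default 0).
#' @param outlier_shift outlier displacement in units of \code{noise_sd}
#'   (default -8: a gross downward error, the common failure mode of
#'   kinetic measurements).
#' @param n_decoys number of uninformative decoy descriptors (default 0;
#'   used by [generate_descriptor_table()]).
#' @param replicates replicate measurements per record (default 1).  With
#'   more than one, the performance column is the replicate mean and a
#'   \code{performance_sd} column carries the replicate SD.
#' @param heteroscedastic logical; \code{TRUE} scales the noise SD
#'   proportionally to the noiseless response level (default
#'   \code{FALSE}).
#' @return a \code{"sim_config"} list.
#' @export
sim_config <- function(alpha = 1, intercept = 0, betas = -2, psis = 5,
                       n = 25L, x_range = c(0, 10), noise_sd = NULL,
                       seed = 1L, equispaced = FALSE, n_outliers = 0L,
                       outlier_shift = -8, n_decoys = 0L, replicates = 1L,
                       heteroscedastic = FALSE) {
  truth <- piecewise_model(alpha, intercept, betas, psis)
  stopifnot(length(x_range) == 2L, x_range[1L] < x_range[2L], n >= 3L,
            n_outliers >= 0L, n_decoys >= 0L, replicates >= 1L)
  if (truth$n_breakpoints > 0L &&
      (any(truth$psis <= x_range[1L]) || any(truth$psis >= x_range[2L])))
    stop("breakpoints must lie strictly inside 'x_range'")
  if (is.null(noise_sd)) {
    yr <- range(predict(truth, seq(x_range[1L], x_range[2L],
                                   length.out = 101L)))
    noise_sd <- 0.1 * diff(yr)
  }
  stopifnot(noise_sd >= 0)
  structure(list(truth = truth, n = as.integer(n), x_range = x_range,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 equispaced = equispaced,
                 n_outliers = as.integer(n_outliers),
                 outlier_shift = outlier_shift,
                 n_decoys = as.integer(n_decoys),
                 replicates = as.integer(replicates),
                 heteroscedastic = heteroscedastic),
            class = "sim_config")
}

#' Generate a synthetic volcano dataset with known ground truth
#'
#' Draws descriptor values over the configured range, evaluates the
#' ground-truth piecewise model, adds Gaussian noise (replicate means and
#' SDs when \code{replicates > 1}), and optionally displaces a few points
#' to emulate gross measurement errors.  The same configuration and seed
#' always produce the identical dataset.
#'
#' @param config a [sim_config()].
#' @return a [kinetic_dataset()] with descriptor column \code{"x"} and
#'   performance column \code{"y"}; attributes \code{"truth"} (the
#'   generating [piecewise_model()]) and \code{"outlier_idx"} (indices of
#'   displaced records).
#' @export
generate_volcano <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    n <- config$n
    x <- if (config$equispaced) {
      seq(config$x_range[1L], config$x_range[2L], length.out = n)
    } else {
      sort(stats::runif(n, config$x_range[1L], config$x_range[2L]))
    }
    mu <- predict(config$truth, x)
    sds <- if (config$heteroscedastic) {
      base <- abs(mu - min(mu))
      config$noise_sd * (0.5 + base / max(base, 1e-12))
    } else rep(config$noise_sd, n)
    if (config$replicates > 1L) {
      reps <- vapply(seq_len(config$replicates),
                     function(r) mu + stats::rnorm(n, 0, sds),
                     numeric(n))
      y <- rowMeans(reps)
      ysd <- apply(reps, 1L, stats::sd)
    } else {
      y <- mu + stats::rnorm(n, 0, sds)
      ysd <- NULL
    }
    outlier_idx <- integer(0)
    if (config$n_outliers > 0L) {
      outlier_idx <- sort(sample.int(n, config$n_outliers))
      y[outlier_idx] <- y[outlier_idx] +
        config$outlier_shift * max(config$noise_sd, 1e-12)
    }
    df <- data.frame(label = sprintf("cat%02d", seq_len(n)), x = x, y = y)
    sd_name <- NULL
    if (!is.null(ysd)) { df$y_sd <- ysd; sd_name <- "y_sd" }
    out <- suppressWarnings(
      kinetic_dataset(df, descriptor_names = "x", performance_name = "y",
                      sd_name = sd_name, provenance = "synthetic"))
    attr(out, "truth") <- config$truth
    attr(out, "outlier_idx") <- outlier_idx
    out
  })
}

#' Generate a screening table with one planted and several decoy
#' descriptors
#'
#' The planted descriptor drives the performance through the ground-truth
#' volcano model; decoys are independent uniform draws carrying no signal.
#' Column order is shuffled by the seed so screening cannot cheat on
#' position.
#'
#' @param config a [sim_config()] with \code{n_decoys} set.
#' @param planted_name name for the informative descriptor column
#'   (default \code{"x_true"}).
#' @return a [kinetic_dataset()] with \code{1 + n_decoys} descriptor
#'   columns; attributes \code{"truth"}, \code{"planted"} (the planted
#'   column name) and \code{"outlier_idx"}.
#' @export
generate_descriptor_table <- function(config, planted_name = "x_true") {
  stopifnot(inherits(config, "sim_config"))
  base <- generate_volcano(config)
  with_local_seed(config$seed + 104729L, {
    n <- config$n
    df <- data.frame(label = base$label)
    df[[planted_name]] <- base$x
    if (config$n_decoys > 0L) {
      for (j in seq_len(config$n_decoys)) {
        df[[sprintf("decoy%02d", j)]] <-
          stats::runif(n, config$x_range[1L], config$x_range[2L])
      }
    }
    desc <- c(planted_name,
              if (config$n_decoys > 0L)
                sprintf("decoy%02d", seq_len(config$n_decoys)))
    desc <- sample(desc)  # randomized column order
    df <- df[, c("label", desc)]
    df$y <- base$y
    if (!is.null(attr(base, "sd_name"))) df$y_sd <- base$y_sd
    out <- suppressWarnings(
      kinetic_dataset(df, descriptor_names = desc, performance_name = "y",
                      provenance = "synthetic"))
    attr(out, "truth") <- config$truth
    attr(out, "planted") <- planted_name
    attr(out, "outlier_idx") <- attr(base, "outlier_idx")
    out
  })
}

#' Write a synthetic dataset and its ground truth to disk
#'
#' Emits the dataset as CSV plus a JSON sidecar holding the generating
#' model, for use as a programmatic test fixture.
#'
#' @param dataset a synthetic [kinetic_dataset()] carrying a
#'   \code{"truth"} attribute.
#' @param csv_path,json_path output paths.
#' @return \code{csv_path}, invisibly.
#' @export
write_fixture <- function(dataset, csv_path,
                          json_path = sub("\\.csv$", ".json", csv_path)) {
  write_kinetic_csv(dataset, csv_path)
  truth <- attr(dataset, "truth")
  jsonlite::write_json(
    list(alpha = truth$alpha, intercept = truth$intercept,
         betas = truth$betas, psis = truth$psis,
         outlier_idx = attr(dataset, "outlier_idx")),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
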