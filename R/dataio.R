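#' Kinetic dataset container
#'
#' A \code{kinetic_dataset} is a plain data frame (one row per catalyst,
#' enzyme or material) with attributes recording column roles:
#' \code{label} (identifier), one or more numeric descriptor columns, a
#' numeric performance column, and optional \code{performance_sd} and
#' \code{weight} columns.  All fitting and screening functions accept it.
#'
#' @param data a data frame.
#' @param descriptor_names character vector of descriptor column names.
#' @param performance_name name of the performance column.
#' @param sd_name optional name of the standard-deviation column.
#' @param units optional named character vector of unit strings.
#' @param provenance free-text origin note.
#' @param warn_min_n warn when fewer than this many rows (default 10, the
#'   classic rule of thumb for a predictive linear fit).
#' @return the data frame with class \code{"kinetic_dataset"} prepended.
#' @export
kinetic_dataset <- function(data, descriptor_names, performance_name,
                            sd_name = NULL, units = NULL, provenance = "",
                            warn_min_n = 10L) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  missing_cols <- setdiff(c(descriptor_names, performance_name, sd_name),
                          names(data))
  if (length(missing_cols))
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  for (cn in c(descriptor_names, performance_name, sd_name)) {
    if (!is.numeric(data[[cn]]))
      stop(sprintf("column '%s' must be numeric", cn))
    if (any(!is.finite(data[[cn]])))
      stop(sprintf("column '%s' contains non-finite values", cn))
  }
  if (!is.null(sd_name) && any(data[[sd_name]] < 0))
    stop("standard deviations must be nonnegative")
  if (!"label" %in% names(data))
    data$label <- paste0("row", seq_len(nrow(data)))
  if (!"weight" %in% names(data)) data$weight <- 1
  if (any(data$weight < 0)) stop("weights must be nonnegative")
  if (nrow(data) < 3L) stop("need at least 3 usable rows")
  if (nrow(data) < warn_min_n)
    warning(sprintf("only %d data points; fits below %d points are fragile",
                    nrow(data), as.integer(warn_min_n)))
  structure(data,
            class = c("kinetic_dataset", "data.frame"),
            descriptor_names = descriptor_names,
            performance_name = performance_name,
            sd_name = sd_name,
            units = units,
            provenance = provenance)
}

#' @export
print.kinetic_dataset <- function(x, ...) {
  cat(sprintf("Kinetic dataset: %d records, performance '%s', descriptors: %s\n",
              nrow(x), attr(x, "performance_name"),
              paste(attr(x, "descriptor_names"), collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Accessors for kinetic datasets
#' @param dataset a \code{"kinetic_dataset"}.
#' @param name a descriptor column name (default: the first).
#' @return numeric vector of descriptor or performance values.
#' @export
descriptor_values <- function(dataset, name = NULL) {
  if (is.null(name)) name <- attr(dataset, "descriptor_names")[1L]
  dataset[[name]]
}

#' @rdname descriptor_values
#' @export
performance_values <- function(dataset) {
  dataset[[attr(dataset, "performance_name")]]
}

## Strict numeric coercion: periods only as decimal separators.  A column
## that looks numeric but uses comma decimals is a locale problem, not a
## descriptor, and is rejected loudly.
coerce_numeric_strict <- function(v, col) {
  if (is.numeric(v)) return(v)
  v_chr <- trimws(as.character(v))
  v_chr[v_chr == ""] <- NA_character_
  if (any(grepl("^-?[0-9]+,[0-9]+$", v_chr[!is.na(v_chr)])))
    stop(sprintf(
      "column '%s' uses comma decimal separators; only '.' is accepted",
      col))
  out <- suppressWarnings(as.numeric(v_chr))
  if (any(is.na(out) & !is.na(v_chr))) return(NULL)  # genuinely non-numeric
  out
}

#' Read a tabular kinetic dataset from CSV or XLSX
#'
#' Reads a header-rowed table (CSV per RFC 4180, or the first sheet of an
#' XLSX workbook via \pkg{readxl}), assigns column roles, drops rows with
#' a missing performance value (counted in the \code{"dropped"}
#' attribute, never imputed), and validates the result.  When
#' \code{x_col} is omitted, every numeric column other than the
#' performance, SD, label and weight columns becomes a candidate
#' descriptor (screening mode).
#'
#' @param path file path (\code{.csv} or \code{.xlsx}).
#' @param y_col name of the numeric performance column (required).
#' @param x_col optional descriptor column name; omit to treat all other
#'   numeric columns as descriptors.
#' @param sd_col optional standard-deviation column name.
#' @param label_col optional identifier column name.
#' @param weight_col optional explicit per-point weight column; when
#'   present it overrides [compute_weights()].
#' @param sheet XLSX sheet name or index (default first).
#' @return a [kinetic_dataset()]; the integer attribute \code{"dropped"}
#'   counts removed rows and \code{"dropped_labels"} names them.
#' @export
read_kinetic_table <- function(path, y_col, x_col = NULL, sd_col = NULL,
                               label_col = NULL, weight_col = NULL,
                               sheet = 1) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx requires the 'readxl' package")
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (nrow(raw) == 0L) stop("no data rows in '", path, "'")
  if (!y_col %in% names(raw))
    stop(sprintf("performance column '%s' not found in '%s'", y_col, path))

  reserved <- c(y_col, sd_col, label_col, weight_col)
  ## strict numeric coercion for every non-label column
  numeric_cols <- character(0)
  for (cn in setdiff(names(raw), label_col)) {
    v <- coerce_numeric_strict(raw[[cn]], cn)
    if (!is.null(v)) { raw[[cn]] <- v; numeric_cols <- c(numeric_cols, cn) }
  }
  if (!y_col %in% numeric_cols)
    stop(sprintf("performance column '%s' is not numeric", y_col))

  descriptors <- if (is.null(x_col)) {
    setdiff(numeric_cols, reserved)
  } else {
    if (!all(x_col %in% numeric_cols))
      stop("descriptor column(s) not found or not numeric: ",
           paste(setdiff(x_col, numeric_cols), collapse = ", "))
    x_col
  }
  if (length(descriptors) == 0L)
    stop("no numeric descriptor columns found")

  labels <- if (!is.null(label_col)) {
    as.character(raw[[label_col]])
  } else if (!is.null(raw[["label"]])) {
    as.character(raw[["label"]])
  } else paste0("row", seq_len(nrow(raw)))

  keep_cols <- c(descriptors, y_col, sd_col)
  df <- raw[, keep_cols, drop = FALSE]
  df$label <- labels
  df$weight <- if (!is.null(weight_col)) raw[[weight_col]] else 1

  usable <- stats::complete.cases(df[, keep_cols, drop = FALSE])
  dropped <- sum(!usable)
  dropped_labels <- labels[!usable]
  if (dropped > 0L)
    warning(sprintf("dropped %d row(s) with missing values: %s", dropped,
                    paste(dropped_labels, collapse = ", ")))
  df <- df[usable, , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) < 3L)
    stop(sprintf("only %d usable rows in '%s'; need at least 3",
                 nrow(df), path))

  out <- kinetic_dataset(df, descriptor_names = descriptors,
                         performance_name = y_col, sd_name = sd_col,
                         provenance = path)
  attr(out, "dropped") <- dropped
  attr(out, "dropped_labels") <- dropped_labels
  out
}

#' Write the cleaned dataset back to CSV (provenance dump)
#'
#' Numeric columns are written with 17 significant digits so a round trip
#' through CSV reproduces every value to full double precision.
#'
#' @param dataset a \code{"kinetic_dataset"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_kinetic_csv <- function(dataset, path) {
  df <- as.data.frame(dataset)
  for (cn in names(df)) {
    if (is.numeric(df[[cn]]))
      df[[cn]] <- formatC(df[[cn]], digits = 17, format = "g")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Weighting scheme for noisy low-activity points
#'
#' Kinetic measurements at the bottom of a volcano plot are often the
#' least trustworthy (stability or solubility issues, detection limits),
#' so fits can down-weight them.  A single scalar \code{lambda} controls
#' the strength: each point receives
#' \deqn{w_i = \max(\tilde y_i, floor)^{\lambda}, \qquad
#'       \tilde y_i = (y_i - y_{min})/(y_{max} - y_{min}),}
#' i.e. min–max-normalized performance raised to \code{lambda} with a
#' small floor so the lowest point never gets exactly zero weight.
#' \code{lambda = 0} gives uniform weights; larger values concentrate the
#' fit on high-performing points.  Weights are monotone nondecreasing in
#' performance for any \code{lambda > 0}, and invariant to affine
#' rescaling of the performance axis.
#'
#' @param lambda nonnegative weighting parameter (default 0 = uniform).
#' @param floor lower bound for the normalized performance in \code{(0,1]}
#'   (default 0.05).
#' @return a \code{"weight_scheme"} list.
#' @export
weight_scheme <- function(lambda = 0, floor = 0.05) {
  stopifnot(lambda >= 0, floor > 0, floor <= 1)
  structure(list(lambda = lambda, floor = floor), class = "weight_scheme")
}

#' Compute per-point weights from a weighting scheme
#'
#' @param dataset a \code{"kinetic_dataset"} (or a numeric performance
#'   vector).
#' @param scheme a [weight_scheme()].
#' @return numeric weight vector, one per record, in record order.
#' @examples
#' compute_weights(c(0, 5, 10), weight_scheme(lambda = 1))  # 0.05 0.5 1
#' @export
compute_weights <- function(dataset, scheme = weight_scheme()) {
  stopifnot(inherits(scheme, "weight_scheme"))
  y <- if (inherits(dataset, "kinetic_dataset")) {
    performance_values(dataset)
  } else as.numeric(dataset)
  if (scheme$lambda == 0) return(rep(1, length(y)))
  rng <- range(y)
  if (diff(rng) == 0)
    stop("degenerate weighting: performance is constant but lambda > 0")
  ytilde <- (y - rng[1L]) / diff(rng)
  pmax(ytilde, scheme$floor)^scheme$lambda
}
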