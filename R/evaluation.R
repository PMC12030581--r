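# Goodness-of-fit metrics and per-sample / aggregate comparison tables.

#' Mean squared error and coefficient of determination
#'
#' `metric_mse()` returns `mean((y - yhat)^2)`; on the 0-100 percent release
#' scale its units are squared percent, so e.g. a value of 20 means the
#' prediction at an average time point is off by about 4.5 percentage
#' points. `metric_r2()` returns `1 - SS_res/SS_tot`; it is at most 1, is 0
#' for the mean predictor, and goes negative for fits worse than the mean.
#'
#' @param y observed values (release percent).
#' @param yhat predicted values, same length.
#' @return A numeric scalar.
#' @export
#' @examples
#' metric_mse(c(0, 2), c(1, 1))  # 1
#' metric_r2(c(0, 10), c(0, 10)) # 1
metric_mse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 1L) stop("empty input", call. = FALSE)
  mean((y - yhat)^2)
}

#' @rdname metric_mse
#' @export
metric_r2 <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 2L) stop("need at least 2 observations", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    stop("R2 undefined for a constant observation vector", call. = FALSE)
  }
  1 - sum((y - yhat)^2) / sst
}

#' Population standard deviation
#'
#' Dispersion with the `N` divisor (not `N - 1`). This is the form used for
#' the across-sample spread rows of the comparison tables.
#'
#' @param x numeric vector.
#' @return `sqrt(mean((x - mean(x))^2))`.
#' @export
population_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

#' Score a predictor on one sample
#'
#' Computes MSE and R-squared of a fitted predictor over the observed
#' points of a sample's release curve, on the percent scale. Kinetic fits
#' (`release_fit`) are evaluated through their model function; trained
#' networks (`release_mlp`) through [predict_curve()]. By default all of a
#' sample's observed points are scored; `mode = "test_only"` restricts to a
#' supplied subset of times (e.g. the held-out rows of a pooled split).
#'
#' @param predictor a `release_fit` or `release_mlp`.
#' @param dataset a `release_dataset`.
#' @param sample_id the sample to score.
#' @param mode `"all_points"` (default) or `"test_only"`.
#' @param test_times numeric times defining the test subset when
#'   `mode = "test_only"`.
#' @return list with elements `mse` and `r2`.
#' @export
score_sample <- function(predictor, dataset, sample_id,
                         mode = c("all_points", "test_only"),
                         test_times = NULL) {
  mode <- match.arg(mode)
  curve <- release_curve(dataset, sample_id)
  if (mode == "test_only") {
    if (is.null(test_times)) {
      stop("test_only scoring needs test_times", call. = FALSE)
    }
    curve <- curve[curve$time_h %in% test_times, , drop = FALSE]
    if (nrow(curve) < 2L) {
      stop("fewer than 2 test points for sample ", sample_id, call. = FALSE)
    }
  }
  yhat <- predict_release(predictor, dataset, sample_id, curve$time_h)
  list(mse = metric_mse(curve$release_pct, yhat),
       r2 = metric_r2(curve$release_pct, yhat))
}

predict_release <- function(predictor, dataset, sample_id, times) {
  if (inherits(predictor, "release_fit")) {
    p <- predictor$params
    if (predictor$model == "kp") {
      100 * kp_release(times, p[["k"]], p[["n"]])
    } else {
      100 * weibull_release(times, p[["tau"]], p[["beta"]])
    }
  } else if (inherits(predictor, "release_mlp")) {
    predict_curve(predictor, dataset, sample_id, times)$release_pct
  } else {
    stop("unsupported predictor of class ", class(predictor)[1],
         call. = FALSE)
  }
}

#' Aggregate a per-sample metric table
#'
#' Appends an `avg` row (arithmetic mean) and a `std` row (population
#' standard deviation, `N` divisor) to a per-sample metric table with one
#' column per method. Display rounding, if any, happens after aggregation,
#' never before.
#'
#' @param table data.frame whose first column is `sample_id` and remaining
#'   columns are per-method metric values.
#' @return The table with two extra rows, `sample_id` = `"avg"` and
#'   `"std"`.
#' @export
#' @examples
#' aggregate_metrics(data.frame(sample_id = 1:2, kp = c(1, 3)))
aggregate_metrics <- function(table) {
  stopifnot(is.data.frame(table), names(table)[1] == "sample_id",
            ncol(table) >= 2L)
  if (nrow(table) < 2L) stop("need at least 2 samples", call. = FALSE)
  vals <- table[, -1, drop = FALSE]
  if (anyNA(vals)) {
    bad <- table$sample_id[rowSums(is.na(vals)) > 0]
    stop("missing metric cells for sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  avg <- vapply(vals, mean, numeric(1))
  std <- vapply(vals, population_sd, numeric(1))
  extra <- data.frame(sample_id = c("avg", "std"),
                      rbind(avg, std), row.names = NULL,
                      stringsAsFactors = FALSE)
  names(extra) <- names(table)
  table$sample_id <- as.character(table$sample_id)
  out <- rbind(table, extra)
  rownames(out) <- NULL
  out
}

#' Reference per-sample metrics for the 39-sample literature dataset
#'
#' Per-sample MSE and R-squared of the Korsmeyer-Peppas, Weibull and
#' neural-network fits on a published 39-sample compilation of in vitro
#' PLGA release experiments, shipped with the package as plain CSV. These
#' serve as a fixed reference for the aggregation layer and for comparing
#' new runs against reported results.
#'
#' @return list with data.frames `mse` and `r2`, each with columns
#'   `sample_id`, `kp`, `weibull`, `mlp`.
#' @export
reference_metrics <- function() {
  read1 <- function(f) {
    read.csv(system.file("extdata", f, package = "plgarelease",
                         mustWork = TRUE), stringsAsFactors = FALSE)
  }
  list(mse = read1("reference_metrics_mse.csv"),
       r2 = read1("reference_metrics_r2.csv"))
}

#' Build and write the three-way comparison report
#'
#' Produces the standard report tables: per-sample MSE per method
#' (with `avg` row), per-sample R-squared per method (with `avg` row), and
#' a dispersion table of population standard deviations, written as
#' `table2_mse.csv`, `table3_r2.csv` and `table4_std.csv`.
#'
#' @param mse_table,r2_table per-sample data.frames (first column
#'   `sample_id`, one column per method).
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of written file paths.
#' @export
write_report <- function(mse_table, r2_table, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- aggregate_metrics(mse_table)
  r <- aggregate_metrics(r2_table)
  std <- data.frame(
    metric = c("mse", "r2"),
    rbind(m[m$sample_id == "std", -1], r[r$sample_id == "std", -1]),
    row.names = NULL)
  f1 <- file.path(dir, "table2_mse.csv")
  f2 <- file.path(dir, "table3_r2.csv")
  f3 <- file.path(dir, "table4_std.csv")
  write.csv(m[m$sample_id != "std", ], f1, row.names = FALSE)
  write.csv(r[r$sample_id != "std", ], f2, row.names = FALSE)
  write.csv(std, f3, row.names = FALSE)
  invisible(c(f1, f2, f3))
}
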