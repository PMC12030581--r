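#' @importFrom stats sd rnorm runif setNames predict coef
#' @importFrom utils read.csv write.csv head
NULL

#' Canonical feature names
#'
#' The model input is a fixed 21-vector: the six PLGA carrier features, the
#' fourteen drug molecular descriptors, and the release time point (hours),
#' always in this order. The order is part of the package contract: feature
#' rows, scalers and trained models all use it.
#'
#' @return Character vector of length 6 (`carrier_features()`),
#'   14 (`descriptor_features()`) or 21 (`feature_names()`).
#' @export
#' @examples
#' feature_names()
feature_names <- function() {
  c(carrier_features(), descriptor_features(), "time_h")
}

#' @rdname feature_names
#' @export
carrier_features <- function() {
  c("polymer_mw", "pdi", "particle_size", "zeta_potential",
    "monomer_ratio", "encapsulation_efficiency")
}

#' @rdname feature_names
#' @export
descriptor_features <- function() {
  c("molecular_weight", "logp", "hbd_count", "hba_count",
    "heavy_atom_count", "rotatable_bond_count", "tpsa", "ring_count",
    "aromatic_ring_count", "molar_refractivity",
    "lipinski_mw_ok", "lipinski_logp_ok", "lipinski_hbd_ok",
    "lipinski_hba_ok")
}

sample_columns <- function() {
  c("sample_id", "drug_name", "smiles", carrier_features(),
    descriptor_features(), "source")
}

#' Construct a release dataset
#'
#' A release dataset couples a samples table (one row per formulation: id,
#' drug name, optional SMILES, the six carrier features, optionally the
#' fourteen drug descriptors, a source tag) with an observations table of
#' cumulative release measurements (`sample_id`, `time_h`, `release_pct`).
#'
#' Validity rules: sample ids unique; every observation belongs to a sample;
#' times non-negative and strictly increasing within a sample (duplicate
#' times are rejected); release values finite and within 0--110 percent
#' (small over-100 excursions from assay noise are tolerated); carrier
#' fields, when present, within their physical ranges (PDI >= 0, particle
#' size > 0, monomer ratio in [0, 1], encapsulation efficiency in
#' [0, 100]). Missing values are `NA` (never sentinel numbers).
#'
#' @param samples data.frame with at least `sample_id`, `drug_name` and the
#'   six carrier feature columns. Missing optional columns are added as `NA`.
#' @param observations data.frame with `sample_id`, `time_h`, `release_pct`.
#'   Rows are sorted by sample and time.
#' @param provenance free-text provenance tag carried along with the data.
#' @return An object of class `release_dataset`.
#' @export
release_dataset <- function(samples, observations, provenance = "") {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  observations <- as.data.frame(observations, stringsAsFactors = FALSE)
  for (col in sample_columns()) {
    if (!col %in% names(samples)) {
      samples[[col]] <- if (col %in% c("drug_name", "smiles", "source")) {
        NA_character_
      } else if (col == "sample_id") {
        stop("samples table lacks required column 'sample_id'", call. = FALSE)
      } else {
        NA_real_
      }
    }
  }
  need <- c("sample_id", "time_h", "release_pct")
  miss <- setdiff(need, names(observations))
  if (length(miss)) {
    stop("observations table lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  samples <- samples[, sample_columns()]
  observations <- observations[, need]
  # canonical column types (all-NA columns read from CSV arrive as logical)
  samples$sample_id <- as.integer(samples$sample_id)
  observations$sample_id <- as.integer(observations$sample_id)
  for (col in c("drug_name", "smiles", "source")) {
    samples[[col]] <- as.character(samples[[col]])
  }
  for (col in c(carrier_features(), descriptor_features())) {
    samples[[col]] <- as.numeric(samples[[col]])
  }
  observations$time_h <- as.numeric(observations$time_h)
  observations$release_pct <- as.numeric(observations$release_pct)
  ord <- order(observations$sample_id, observations$time_h)
  observations <- observations[ord, , drop = FALSE]
  rownames(samples) <- rownames(observations) <- NULL
  x <- structure(
    list(samples = samples, observations = observations,
         provenance = provenance),
    class = "release_dataset"
  )
  validate_release_dataset(x)
  x
}

#' @rdname release_dataset
#' @param x object to validate.
#' @export
validate_release_dataset <- function(x) {
  stopifnot(inherits(x, "release_dataset"))
  s <- x$samples
  o <- x$observations
  if (nrow(s) == 0L) stop("dataset has no samples", call. = FALSE)
  if (anyDuplicated(s$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(s$sample_id[duplicated(s$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  orphan <- setdiff(o$sample_id, s$sample_id)
  if (length(orphan)) {
    stop("observations reference unknown sample_id: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(o$time_h)) || any(o$time_h < 0)) {
    stop("observation times must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(o$release_pct))) {
    stop("release values must be finite", call. = FALSE)
  }
  if (any(o$release_pct < 0 | o$release_pct > 110)) {
    bad <- unique(o$sample_id[o$release_pct < 0 | o$release_pct > 110])
    stop("release percent outside [0, 110] in sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (id in unique(o$sample_id)) {
    tt <- o$time_h[o$sample_id == id]
    if (anyDuplicated(tt)) {
      stop("duplicated time point in sample ", id, call. = FALSE)
    }
    if (is.unsorted(tt, strictly = TRUE)) {
      stop("times not strictly increasing in sample ", id, call. = FALSE)
    }
  }
  chk <- function(cond, msg) {
    if (any(cond, na.rm = TRUE)) stop(msg, call. = FALSE)
  }
  chk(s$pdi < 0, "pdi must be >= 0")
  chk(s$particle_size <= 0, "particle_size must be > 0")
  chk(s$monomer_ratio < 0 | s$monomer_ratio > 1,
      "monomer_ratio must lie in [0, 1]")
  chk(s$encapsulation_efficiency < 0 | s$encapsulation_efficiency > 100,
      "encapsulation_efficiency must lie in [0, 100]")
  invisible(x)
}

#' @export
print.release_dataset <- function(x, ...) {
  npts <- table(factor(x$observations$sample_id, levels = x$samples$sample_id))
  cat(sprintf("release_dataset: %d samples, %d observations\n",
              nrow(x$samples), nrow(x$observations)))
  cat(sprintf("  points per sample: %d-%d (median %g)\n",
              min(npts), max(npts), stats::median(as.numeric(npts))))
  cat(sprintf("  time span: %.3g-%.4g h; release %.3g-%.4g%%\n",
              min(x$observations$time_h), max(x$observations$time_h),
              min(x$observations$release_pct),
              max(x$observations$release_pct)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Extract one sample's release curve
#'
#' @param dataset a `release_dataset`.
#' @param sample_id id of the sample.
#' @return data.frame with columns `time_h`, `release_pct`, sorted by time.
#' @export
release_curve <- function(dataset, sample_id) {
  stopifnot(inherits(dataset, "release_dataset"))
  if (!sample_id %in% dataset$samples$sample_id) {
    stop("unknown sample_id: ", sample_id, call. = FALSE)
  }
  o <- dataset$observations
  o <- o[o$sample_id == sample_id, c("time_h", "release_pct")]
  rownames(o) <- NULL
  o
}

# ---- file I/O --------------------------------------------------------------

#' Read and write release datasets
#'
#' The canonical on-disk layout is either a pair of CSV files sharing a path
#' stem (`<stem>_samples.csv` and `<stem>_observations.csv`) or a single
#' JSON document bundling both tables. Missing values are empty CSV cells /
#' JSON nulls. `write_release_dataset()` followed by `read_release_dataset()`
#' reproduces the dataset exactly.
#'
#' @param path for CSV, the path stem (without the `_samples.csv` /
#'   `_observations.csv` suffix); for JSON, the file path.
#' @param format `"csv"` or `"json"`.
#' @param dataset a `release_dataset`.
#' @return `read_release_dataset()` returns a validated `release_dataset`;
#'   `write_release_dataset()` returns the written path(s) invisibly.
#' @export
read_release_dataset <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    fs <- paste0(path, "_samples.csv")
    fo <- paste0(path, "_observations.csv")
    for (f in c(fs, fo)) {
      if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
    }
    samples <- read.csv(fs, stringsAsFactors = FALSE)
    observations <- read.csv(fo, stringsAsFactors = FALSE)
    prov <- ""
  } else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    doc <- jsonlite::fromJSON(path)
    samples <- as.data.frame(doc$samples, stringsAsFactors = FALSE)
    observations <- as.data.frame(doc$observations, stringsAsFactors = FALSE)
    prov <- if (is.null(doc$provenance)) "" else doc$provenance
  }
  release_dataset(samples, observations, provenance = prov)
}

#' @rdname read_release_dataset
#' @export
write_release_dataset <- function(dataset, path, format = c("csv", "json")) {
  stopifnot(inherits(dataset, "release_dataset"))
  format <- match.arg(format)
  if (format == "csv") {
    fs <- paste0(path, "_samples.csv")
    fo <- paste0(path, "_observations.csv")
    write.csv(dataset$samples, fs, row.names = FALSE, na = "")
    write.csv(dataset$observations, fo, row.names = FALSE, na = "")
    invisible(c(fs, fo))
  } else {
    doc <- list(provenance = dataset$provenance,
                samples = dataset$samples,
                observations = dataset$observations)
    jsonlite::write_json(doc, path, dataframe = "columns", na = "null",
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

# ---- imputation ------------------------------------------------------------

#' Mean-impute missing carrier and descriptor features
#'
#' Replaces each missing carrier or descriptor value by the arithmetic mean
#' of that feature over a reference dataset (by default the dataset itself).
#' Non-missing values are never touched, so the operation is idempotent.
#' Protein/biologic drugs without a molecular structure typically enter with
#' all fourteen descriptors missing and leave with the dataset means.
#'
#' @param dataset a `release_dataset`.
#' @param reference optional `release_dataset` providing the imputation
#'   means (e.g. the training portion of a split). Defaults to `dataset`.
#' @return A `release_dataset` with no missing feature values.
#' @export
impute_missing <- function(dataset, reference = NULL) {
  stopifnot(inherits(dataset, "release_dataset"))
  if (is.null(reference)) reference <- dataset
  stopifnot(inherits(reference, "release_dataset"))
  feats <- c(carrier_features(), descriptor_features())
  s <- dataset$samples
  for (f in feats) {
    idx <- is.na(s[[f]])
    if (!any(idx)) next
    m <- mean(reference$samples[[f]], na.rm = TRUE)
    if (!is.finite(m)) {
      stop("feature entirely missing in reference: ", f, call. = FALSE)
    }
    s[[f]][idx] <- m
  }
  dataset$samples <- s
  dataset
}

# ---- feature rows ----------------------------------------------------------

#' Pool a dataset into per-time-point feature rows
#'
#' Each (sample, observation) pair becomes one training record: the sample's
#' 6 carrier features and 14 drug descriptors plus the observation time as
#' the 21st feature, with the observed release percent as the target. This
#' is the pooled, time-point-level representation the regression network is
#' trained on.
#'
#' @param dataset a `release_dataset` whose descriptors are present for
#'   every sample (compute or impute them first).
#' @return data.frame with columns `sample_id`, the 21 [feature_names()],
#'   and `release_pct` (the target). Row count equals the total number of
#'   observations.
#' @export
to_feature_rows <- function(dataset) {
  stopifnot(inherits(dataset, "release_dataset"))
  s <- dataset$samples
  feats <- c(carrier_features(), descriptor_features())
  bad <- s$sample_id[rowSums(is.na(s[, feats])) > 0]
  if (length(bad)) {
    stop("missing features (impute or compute descriptors first) in sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  o <- dataset$observations
  i <- match(o$sample_id, s$sample_id)
  rows <- cbind(
    data.frame(sample_id = o$sample_id),
    s[i, feats, drop = FALSE],
    data.frame(time_h = o$time_h, release_pct = o$release_pct)
  )
  rownames(rows) <- NULL
  rows
}

# ---- scaling ---------------------------------------------------------------

#' Fit a z-score feature scaler
#'
#' Computes per-feature mean and standard deviation from the supplied rows
#' (typically the training split only, so no information leaks from held-out
#' rows). Constant features get scale 1 so they transform to exactly 0.
#' The target (`release_pct`) is left on its natural 0--100 percent scale;
#' squared-percent loss magnitudes are then directly interpretable.
#'
#' @param rows feature rows from [to_feature_rows()].
#' @return An object of class `release_scaler` holding per-feature centers
#'   and scales.
#' @export
fit_scaler <- function(rows) {
  feats <- feature_names()
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L,
            all(feats %in% names(rows)))
  m <- as.matrix(rows[, feats, drop = FALSE])
  center <- colMeans(m)
  scale <- apply(m, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  structure(list(center = center, scale = scale, features = feats,
                 target_scaled = FALSE),
            class = "release_scaler")
}

#' Apply or invert a fitted scaler
#'
#' @param scaler a `release_scaler` from [fit_scaler()].
#' @param rows data.frame containing the scaler's feature columns (extra
#'   columns such as `sample_id` or `release_pct` pass through untouched).
#' @return Rows with feature columns standardized (`scale_rows`) or restored
#'   (`unscale_rows`); `unscale_rows(scaler, scale_rows(scaler, x))` is the
#'   identity to machine precision.
#' @export
scale_rows <- function(scaler, rows) {
  stopifnot(inherits(scaler, "release_scaler"))
  for (f in scaler$features) {
    rows[[f]] <- (rows[[f]] - scaler$center[[f]]) / scaler$scale[[f]]
  }
  rows
}

#' @rdname scale_rows
#' @export
unscale_rows <- function(scaler, rows) {
  stopifnot(inherits(scaler, "release_scaler"))
  for (f in scaler$features) {
    rows[[f]] <- rows[[f]] * scaler$scale[[f]] + scaler$center[[f]]
  }
  rows
}

#' @export
print.release_scaler <- function(x, ...) {
  cat(sprintf("release_scaler: z-score over %d features (target unscaled)\n",
              length(x$features)))
  invisible(x)
}

# ---- splitting -------------------------------------------------------------

#' Random train/test split over pooled time-point rows
#'
#' Partitions pooled feature rows at the time-point level, not the sample
#' level: every release curve typically contributes points to both splits,
#' so the model sees part of each curve during training. Train size is
#' `round(n * train_fraction)`; the partition is disjoint, exhaustive and
#' reproducible for a fixed seed.
#'
#' @param rows feature rows from [to_feature_rows()].
#' @param train_fraction proportion of rows assigned to training,
#'   strictly between 0 and 1 (default 0.8).
#' @param seed integer seed controlling the permutation.
#' @return list with elements `train` and `test` (both data.frames).
#' @export
split_rows <- function(rows, train_fraction = 0.8, seed = 1L) {
  stopifnot(is.data.frame(rows))
  n <- nrow(rows)
  if (n < 2L) stop("need at least 2 rows to split", call. = FALSE)
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n_train <- round(n * train_fraction)
  n_train <- max(1L, min(n - 1L, n_train))
  perm <- with_seed(seed, sample.int(n))
  idx <- sort(perm[seq_len(n_train)])
  list(train = rows[idx, , drop = FALSE],
       test = rows[-idx, , drop = FALSE])
}

# Run code under a temporary RNG state; restores the caller's state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive an independent 31-bit sub-seed from a base seed and a stage label,
# so one global seed can feed several stages without draw-count coupling.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}
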