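#' @name station_data
#' @title Station-table handling: normalization, windows, batches
#' @description Predictor columns are `P`, `TA`, `VPD`, `SW_IN`, `LAI`;
#'   target columns are `GPP` and `RECO`. Targets are never normalized.
NULL

#' Predictor feature names
#' @export
flux_features <- function() c("P", "TA", "VPD", "SW_IN", "LAI")

#' Fit z-normalization statistics on training rows
#'
#' Computes the per-feature mean and sample (n-1) standard deviation over
#' the supplied training rows only, skipping missing values. Target columns
#' are excluded by construction.
#'
#' @param rows data.frame containing at least the feature columns.
#' @param features character vector of feature columns (default
#'   [flux_features()]).
#' @return a `norm_stats` object: list with named numeric vectors `mean` and
#'   `sd`.
#' @export
fit_norm_stats <- function(rows, features = flux_features()) {
  missing_cols <- setdiff(features, names(rows))
  if (length(missing_cols))
    stopf("schema error: feature(s) absent from rows: %s",
          paste(missing_cols, collapse = ", "))
  mu <- vapply(features, function(f) mean(rows[[f]], na.rm = TRUE), numeric(1))
  sdv <- vapply(features, function(f) stats::sd(rows[[f]], na.rm = TRUE), numeric(1))
  n_ok <- vapply(features, function(f) sum(!is.na(rows[[f]])), numeric(1))
  if (any(n_ok < 2)) stopf("need >= 2 non-missing values per feature (%s)",
                           paste(features[n_ok < 2], collapse = ", "))
  degenerate <- features[!is.na(sdv) & sdv == 0]
  if (length(degenerate))
    stopf("degenerate feature with zero variance: %s",
          paste(degenerate, collapse = ", "))
  structure(list(mean = mu, sd = sdv, features = features), class = "norm_stats")
}

#' Apply (or invert) z-normalization
#'
#' Maps every feature `x` to `(x - mean) / sd` with statistics fitted on
#' training data; target columns and any non-feature column pass through
#' untouched.
#'
#' @param rows data.frame with the feature columns.
#' @param stats a `norm_stats` from [fit_norm_stats()].
#' @return the transformed data.frame.
#' @export
z_normalize <- function(rows, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  absent <- setdiff(stats$features, names(rows))
  if (length(absent))
    stopf("schema error: feature(s) absent from rows: %s",
          paste(absent, collapse = ", "))
  for (f in stats$features)
    rows[[f]] <- (rows[[f]] - stats$mean[[f]]) / stats$sd[[f]]
  rows
}

#' @rdname z_normalize
#' @export
z_denormalize <- function(rows, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  for (f in intersect(stats$features, names(rows)))
    rows[[f]] <- rows[[f]] * stats$sd[[f]] + stats$mean[[f]]
  rows
}

# TRUE where a row is usable: all features and the target present
.row_complete <- function(data, target, features = flux_features()) {
  ok <- !is.na(data[[target]])
  for (f in features) ok <- ok & !is.na(data[[f]])
  ok
}

# maximal runs of TRUE in a logical vector -> list of index ranges
.runs <- function(ok) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(i) starts[i]:ends[i])
}

#' Cut a station record into contiguous gap-free windows
#'
#' Emits every window of `window` consecutive timesteps that contains no
#' missing feature or target value and no calendar gap (for daily records,
#' consecutive rows must be consecutive days). The prediction target of a
#' window is the target value at its final timestep.
#'
#' @param record a `station_record` or a plain data.frame with the station
#'   schema.
#' @param target `"GPP"` or `"RECO"`.
#' @param window window length in timesteps (default 30).
#' @param stride step between window starts (default 1).
#' @param features feature columns.
#' @return list with `x` (array `n_windows x window x n_features`), `y`
#'   (numeric vector), and `end_index` (row index of each window's final
#'   timestep); `n_windows` may be 0 for short series.
#' @export
make_windows <- function(record, target = "GPP", window = 30L, stride = 1L,
                         features = flux_features()) {
  if (window < 1) stopf("`window` must be >= 1")
  data <- if (inherits(record, "station_record")) record$data else record
  ok <- .row_complete(data, target, features)
  # break runs at calendar gaps as well as missing values
  if (inherits(data$date, "Date") && nrow(data) > 1) {
    dd <- diff(as.numeric(data$date))
    step <- stats::median(dd)
    gap_after <- c(dd > step + 0.5, FALSE)  # TRUE at last row of a segment
    seg_id <- cumsum(c(0, utils::head(gap_after, -1)))
  } else seg_id <- rep(0L, nrow(data))
  starts <- integer(0)
  for (run in .runs(ok)) {
    for (sub in split(run, seg_id[run])) {
      if (length(sub) >= window) {
        s <- sub[seq(1L, length(sub) - window + 1L, by = stride)]
        starts <- c(starts, s)
      }
    }
  }
  nw <- length(starts)
  x <- array(NA_real_, dim = c(nw, window, length(features)),
             dimnames = list(NULL, NULL, features))
  y <- numeric(nw)
  end_index <- integer(nw)
  for (k in seq_len(nw)) {
    rows <- starts[k]:(starts[k] + window - 1L)
    x[k, , ] <- as.matrix(data[rows, features])
    y[k] <- data[[target]][rows[window]]
    end_index[k] <- rows[window]
  }
  list(x = x, y = y, end_index = end_index)
}

#' Assemble instantaneous (row-wise) inputs for the MLP
#'
#' @inheritParams make_windows
#' @return list with `x` (matrix `n x n_features`), `y`, and `index` (row
#'   indices of retained complete rows).
#' @export
make_instant <- function(record, target = "GPP", features = flux_features()) {
  data <- if (inherits(record, "station_record")) record$data else record
  ok <- .row_complete(data, target, features)
  list(x = as.matrix(data[ok, features, drop = FALSE]),
       y = data[[target]][ok], index = which(ok))
}

#' Seeded shuffle-and-chunk batching
#'
#' Shuffles item indices with the given seed and chunks them into batches of
#' `batch_size`; the final batch may be smaller. The batches partition the
#' input exactly.
#'
#' @param n_items number of items (rows or windows) to batch.
#' @param batch_size maximum batch size (default 256).
#' @param seed integer seed for the shuffle; `NULL` keeps input order.
#' @return list of integer index vectors.
#' @export
make_batches <- function(n_items, batch_size = 256L, seed = NULL) {
  if (n_items < 1) stopf("non-empty input required")
  idx <- if (is.null(seed)) seq_len(n_items) else
    with_seed(seed, sample.int(n_items))
  split(idx, ceiling(seq_along(idx) / batch_size))
}
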