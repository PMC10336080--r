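#' Construct the four meta-learning datasets
#'
#' Target tasks are the data-sparse stations: half (rounded down) of the
#' tropical stations, half of the semi-arid stations (both sampled with
#' `seed`), plus one randomly chosen representative for every
#' plant-functional-type level not already covered by that selection
#' (coverage, not duplication). Base tasks are the complement. Each
#' station's usable rows are then split 80:20 chronologically (earliest 80%
#' train), which avoids temporal leakage into windowed models.
#'
#' @param network a `station_network` (or list of `station_record`).
#' @param seed integer seed driving the random selections.
#' @param train_frac fraction of each station's rows used for training
#'   (default 0.8).
#' @return a `meta_split`: list with `base`, `target` (character station
#'   ids), `rows` (per-station list with `train` and `test` integer row
#'   indices), and `seed`.
#' @export
split_tasks <- function(network, seed = 1L, train_frac = 0.8) {
  stations <- if (inherits(network, "station_network")) network$stations else network
  if (length(stations) == 0) stopf("configuration error: no stations")
  ids <- unname(vapply(stations, function(s) s$station_id, character(1)))
  zones <- unname(vapply(stations, function(s) s$zone, character(1)))
  pfts <- unname(vapply(stations, function(s) s$pft, character(1)))
  known <- c("tropics", "semi-arid", "temperate", "continental")
  if (!all(zones %in% known))
    stopf("schema error: unknown zone label(s): %s",
          paste(unique(setdiff(zones, known)), collapse = ", "))
  target <- with_seed(seed, {
    sel <- character(0)
    for (z in c("tropics", "semi-arid")) {
      pool <- ids[zones == z]
      n_half <- floor(length(pool) / 2)
      if (n_half > 0) sel <- c(sel, sample(pool, n_half))
    }
    for (p in sort(unique(pfts))) {
      if (p %in% pfts[ids %in% sel]) next      # PFT already represented
      pool <- setdiff(ids[pfts == p], sel)
      if (length(pool) > 0) sel <- c(sel, sample(pool, 1L))
    }
    unname(sel)
  })
  base <- setdiff(ids, target)
  if (length(base) == 0)
    stopf("configuration error: base set empty after target selection")
  rows <- lapply(stations, function(s) {
    n <- nrow(s$data)
    n_train <- floor(train_frac * n)
    list(train = seq_len(n_train),
         test = if (n_train < n) (n_train + 1L):n else integer(0))
  })
  names(rows) <- ids
  structure(list(base = sort(base), target = sort(target), rows = rows,
                 seed = as.integer(seed)),
            class = "meta_split")
}

#' Build a meta-split from explicit target membership
#'
#' Lower-level companion to [split_tasks()] for benchmarks and experiments
#' where target membership is fixed by design (e.g. "the whole sparse
#' zone") rather than sampled; rows are still split chronologically.
#'
#' @param network a `station_network` (or list of `station_record`).
#' @param target_ids station ids forming the target tasks.
#' @param train_frac fraction of each station's rows used for training.
#' @return a `meta_split`.
#' @export
make_meta_split <- function(network, target_ids, train_frac = 0.8) {
  stations <- if (inherits(network, "station_network")) network$stations else network
  ids <- unname(vapply(stations, function(s) s$station_id, character(1)))
  target_ids <- unname(target_ids)
  if (!all(target_ids %in% ids)) stopf("unknown target station id(s)")
  base <- setdiff(ids, target_ids)
  if (length(base) == 0)
    stopf("configuration error: base set empty after target selection")
  rows <- lapply(stations, function(s) {
    n <- nrow(s$data)
    n_train <- floor(train_frac * n)
    list(train = seq_len(n_train),
         test = if (n_train < n) (n_train + 1L):n else integer(0))
  })
  names(rows) <- ids
  structure(list(base = sort(base), target = sort(target_ids), rows = rows,
                 seed = NA_integer_),
            class = "meta_split")
}

#' Pool a meta-split into baseline train/test sets
#'
#' The non-meta baseline trains on the union of base-train and target-train
#' rows and is tested on the union of the two test sets.
#'
#' @param split a `meta_split` from [split_tasks()].
#' @return list with `train` and `test`, each a named list mapping
#'   station id to integer row indices.
#' @export
baseline_datasets <- function(split) {
  stopifnot(inherits(split, "meta_split"))
  all_ids <- c(split$base, split$target)
  list(train = stats::setNames(lapply(all_ids, function(id) split$rows[[id]]$train), all_ids),
       test = stats::setNames(lapply(all_ids, function(id) split$rows[[id]]$test), all_ids))
}

#' Serialize / restore a meta-split as JSON
#'
#' @param split a `meta_split`.
#' @param path file path.
#' @return `read_meta_split` returns the restored `meta_split`.
#' @export
write_meta_split <- function(split, path) {
  stopifnot(inherits(split, "meta_split"))
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_meta_split
#' @export
read_meta_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$rows <- lapply(x$rows, function(r)
    list(train = as.integer(r$train), test = as.integer(r$test)))
  structure(list(base = as.character(x$base), target = as.character(x$target),
                 rows = x$rows, seed = as.integer(x$seed)),
            class = "meta_split")
}
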