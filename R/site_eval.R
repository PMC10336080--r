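#' Root-mean-square error
#'
#' @param pred,obs equal-length numeric vectors.
#' @return `sqrt(mean((pred - obs)^2))`.
#' @export
rmse <- function(pred, obs) {
  if (length(pred) != length(obs))
    stopf("schema error: %d predictions vs %d observations",
          length(pred), length(obs))
  if (length(pred) < 1) stopf("need at least one pair")
  sqrt(mean((pred - obs)^2))
}

#' Extreme-observation robustness sweep
#'
#' For every threshold `t`, selects the observations whose z-normalized
#' value (using training-target statistics, pooled across stations) exceeds
#' `t`, and reports the RMSE over that subset, the subset size, and the mean
#' observed flux. Selections at increasing `t` are nested, so counts are
#' non-increasing. Extremes are the high tail only (`z > t`), matching the
#' magnitudes of interest for peak carbon uptake and release.
#'
#' @param pred,obs prediction and observation vectors.
#' @param stats list with `mean` and `sd` of the target flux, fitted on
#'   training observations.
#' @param thresholds z-thresholds, ascending (default 1.0 to 2.0).
#' @return data.frame with columns `t`, `n_selected`, `rmse` (NA when the
#'   subset is empty), `mean_obs`.
#' @export
extreme_eval <- function(pred, obs, stats,
                         thresholds = c(1.0, 1.25, 1.5, 1.75, 2.0)) {
  if (length(pred) != length(obs))
    stopf("schema error: prediction/observation length mismatch")
  if (is.unsorted(thresholds)) stopf("`thresholds` must be ascending")
  z <- (obs - stats$mean) / stats$sd
  out <- lapply(thresholds, function(t) {
    sel <- which(z > t)
    data.frame(t = t, n_selected = length(sel),
               rmse = if (length(sel)) rmse(pred[sel], obs[sel]) else NA_real_,
               mean_obs = if (length(sel)) mean(obs[sel]) else NA_real_)
  })
  do.call(rbind, out)
}

#' Per-climate-zone RMSE report
#'
#' RMSE per zone with the across-member spread (standard deviation of the
#' member-wise zone RMSEs) when per-member predictions are supplied;
#' optionally restricted to the extreme subset `z > extreme_t`.
#'
#' @param pred ensemble-mean predictions.
#' @param obs observations.
#' @param zones character vector of zone labels, one per record.
#' @param member_preds optional matrix `(n, members)` of per-member
#'   predictions.
#' @param extreme_t optional z-threshold restricting the report to extreme
#'   observations (requires `stats`).
#' @param stats target mean/sd, needed when `extreme_t` is given.
#' @return data.frame with columns `zone`, `n`, `rmse`, `spread`.
#' @export
zone_report <- function(pred, obs, zones, member_preds = NULL,
                        extreme_t = NULL, stats = NULL) {
  if (anyNA(zones) || any(!nzchar(zones)))
    stopf("schema error: unlabeled record (missing zone)")
  if (length(zones) != length(obs)) stopf("schema error: zone labels do not match records")
  keep <- seq_along(obs)
  if (!is.null(extreme_t)) {
    if (is.null(stats)) stopf("`stats` required for extreme restriction")
    keep <- which((obs - stats$mean) / stats$sd > extreme_t)
  }
  out <- lapply(sort(unique(zones[keep])), function(z) {
    sel <- keep[zones[keep] == z]
    spread <- if (!is.null(member_preds))
      stats::sd(apply(member_preds[sel, , drop = FALSE], 2,
                      function(p) rmse(p, obs[sel]))) else NA_real_
    data.frame(zone = z, n = length(sel), rmse = rmse(pred[sel], obs[sel]),
               spread = spread)
  })
  do.call(rbind, out)
}

#' Full site-level evaluation report
#'
#' Combines overall RMSE, the per-zone report and the extreme-threshold
#' sweep into one object; serializable as JSON.
#'
#' @param model an `ensemble_model`.
#' @param xy an xy set (e.g. `data$target_test` from [meta_datasets()]).
#' @param zones zone label per record in `xy`.
#' @param stats target mean/sd fitted on training observations.
#' @param thresholds extreme z-thresholds.
#' @return an `eval_report`: list with `rmse_overall`, `rmse_by_zone`,
#'   `extreme_curve`.
#' @export
evaluate_sites <- function(model, xy, zones, stats,
                           thresholds = c(1.0, 1.25, 1.5, 1.75, 2.0)) {
  pe <- predict_ensemble(model, xy$x)
  member_preds <- vapply(model$members, function(m) predict_learner(m, xy$x),
                         numeric(length(xy$y)))
  member_preds <- matrix(member_preds, ncol = length(model$members))
  structure(list(
    rmse_overall = rmse(pe$mean, xy$y),
    rmse_by_zone = zone_report(pe$mean, xy$y, zones, member_preds),
    extreme_curve = extreme_eval(pe$mean, xy$y, stats, thresholds)
  ), class = "eval_report")
}

#' @rdname evaluate_sites
#' @param report an `eval_report`.
#' @param path output JSON path.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
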