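#' Latitude-band climate-zone map
#'
#' Assigns each grid cell a zone label from its latitude band: tropics
#' (|lat| <= 15), semi-arid (15-35), temperate (35-55), continental
#' (55-66.5), `"masked"` poleward of that — mirroring the zone anchors of
#' the synthetic world.
#'
#' @param lat,lon cell-center coordinate vectors.
#' @return character matrix `(lat, lon)` of zone labels.
#' @export
zone_map_from_latlon <- function(lat, lon) {
  zone_of <- function(a) {
    a <- abs(a)
    if (a <= 15) "tropics" else if (a <= 35) "semi-arid"
    else if (a <= 55) "temperate" else if (a <= 66.5) "continental"
    else "masked"
  }
  matrix(vapply(lat, zone_of, character(1)),
         nrow = length(lat), ncol = length(lon))
}

.check_zonemap <- function(field_arr, zonemap) {
  if (!identical(dim(field_arr)[2:3], dim(zonemap)))
    stopf("geometry error: zone map does not match the product grid")
}

#' Per-zone monthly climatology
#'
#' For each zone, averages the member cells per calendar month across all
#' years. Zones with no cells are omitted with a warning.
#'
#' @param field array `(time, lat, lon)`.
#' @param dates Date vector along the time axis (>= 12 monthly steps, or
#'   daily steps spanning >= 12 months).
#' @param zonemap character matrix from [zone_map_from_latlon()].
#' @return data.frame with columns `zone`, `month` (1-12), `value`.
#' @export
zone_seasonality <- function(field, dates, zonemap) {
  .check_zonemap(field, zonemap)
  months <- as.integer(format(dates, "%m"))
  if (length(unique(months)) < 12)
    stopf("need at least 12 monthly steps (a full seasonal cycle)")
  zones <- setdiff(sort(unique(as.vector(zonemap))), "masked")
  out <- list()
  for (z in zones) {
    cells <- which(zonemap == z)
    if (length(cells) == 0) { warning(sprintf("zone %s has no cells", z)); next }
    fm <- matrix(field, dim(field)[1], prod(dim(field)[2:3]))[, cells, drop = FALSE]
    series <- rowMeans(fm, na.rm = TRUE)
    clim <- tapply(series, months, mean, na.rm = TRUE)
    out[[z]] <- data.frame(zone = z, month = as.integer(names(clim)),
                           value = as.numeric(clim))
  }
  do.call(rbind, out)
}

#' Interannual coefficient of variation per cell
#'
#' Per cell, annual means are formed over whole calendar years and the CV
#' is their sample (n-1) standard deviation over their mean. Cells with a
#' zero or missing mean become missing.
#'
#' @param field array `(time, lat, lon)`.
#' @param dates Date vector along the time axis covering >= 2 whole years.
#' @return matrix `(lat, lon)` of CV values.
#' @export
interannual_cv <- function(field, dates) {
  years <- format(dates, "%Y")
  if (length(unique(years)) < 2) stopf("need at least 2 whole years")
  fm <- matrix(field, dim(field)[1], prod(dim(field)[2:3]))
  annual <- apply(fm, 2, function(x) tapply(x, years, mean, na.rm = TRUE))
  annual <- matrix(annual, nrow = length(unique(years)))
  mu <- colMeans(annual)
  sdv <- apply(annual, 2, stats::sd)
  cv <- sdv / mu
  cv[!is.finite(cv) | mu == 0] <- NA_real_
  matrix(cv, dim(field)[2], dim(field)[3])
}

#' Ordinary-least-squares trend of an annual series
#'
#' @param values annual values (e.g. global totals in PgC yr-1).
#' @param years numeric years (defaults to `seq_along(values)`).
#' @return a `trend_result`: list with `slope`, `stderr`, `p_value`,
#'   `intercept`.
#' @export
trend_fit <- function(values, years = seq_along(values)) {
  if (length(values) < 3) stopf("sample-size error: need >= 3 annual values")
  fit <- stats::lm(values ~ years)
  # summary.lm warns on perfect fits; the zero-residual case is handled below
  sm <- suppressWarnings(summary(fit))$coefficients
  stderr <- if (nrow(sm) >= 2) sm["years", "Std. Error"] else NA_real_
  p <- if (nrow(sm) >= 2) sm["years", "Pr(>|t|)"] else NA_real_
  # an exact line has zero residual variance up to floating rounding;
  # report stderr 0 rather than the rounding artifact
  if (!is.finite(stderr) ||
      sum(stats::residuals(fit)^2) <= 1e-20 * max(1, sum(values^2))) {
    stderr <- 0
    p <- 0
  }
  structure(list(slope = unname(stats::coef(fit)["years"]),
                 stderr = unname(stderr), p_value = unname(p),
                 intercept = unname(stats::coef(fit)["(Intercept)"])),
            class = "trend_result")
}

#' Net ecosystem exchange approximation
#'
#' NEE = Reco - GPP cellwise (negative values are net carbon uptake);
#' missing values propagate.
#'
#' @param gpp,reco arrays of identical geometry.
#' @return array of NEE.
#' @export
nee_approx <- function(gpp, reco) {
  if (!identical(dim(gpp), dim(reco)))
    stopf("geometry error: GPP and Reco shapes differ")
  reco - gpp
}

#' Spherical cell areas
#'
#' @param lat cell-center latitudes (degrees).
#' @param resolution cell size in degrees.
#' @return vector of cell areas in m^2, one per latitude row.
#' @export
cell_area_m2 <- function(lat, resolution) {
  r_earth <- 6371000
  dlam <- resolution * pi / 180
  phi1 <- (lat - resolution / 2) * pi / 180
  phi2 <- (lat + resolution / 2) * pi / 180
  r_earth^2 * dlam * abs(sin(phi2) - sin(phi1))
}

#' Area-integrated annual global totals
#'
#' Integrates a flux-density field (gC m-2 d-1) over the grid with
#' spherical cell-area weights and over the days of each calendar year,
#' returning totals in PgC yr-1 — the series [trend_fit()] consumes.
#'
#' @param field array `(time, lat, lon)` of flux densities.
#' @param lat cell-center latitudes.
#' @param dates Date vector along the time axis.
#' @param resolution cell size in degrees.
#' @param timescale `"daily"` or `"monthly"` (monthly steps count their
#'   calendar days).
#' @return data.frame with columns `year`, `total_pgc`.
#' @export
global_annual_series <- function(field, lat, dates, resolution,
                                 timescale = c("daily", "monthly")) {
  timescale <- match.arg(timescale)
  area <- cell_area_m2(lat, resolution)
  d <- dim(field)
  w <- matrix(rep(area, d[3]), d[2], d[3])          # area per (lat, lon) cell
  step_days <- if (timescale == "daily") rep(1, length(dates)) else
    as.numeric(diff(c(dates, seq(dates[length(dates)], by = "month",
                                 length.out = 2)[2])))
  daily_total <- vapply(seq_len(d[1]), function(t) {
    slab <- field[t, , ]
    sum(slab * w, na.rm = TRUE)
  }, numeric(1))
  years <- format(dates, "%Y")
  totals <- tapply(daily_total * step_days, years, sum) / 1e15   # gC -> PgC
  data.frame(year = as.integer(names(totals)), total_pgc = as.numeric(totals))
}

.pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

#' Per-zone Pearson correlation against a reference field
#'
#' Builds zone-mean time series of both fields (e.g. GPP and a SIF-like
#' reference) and correlates them per zone. Correlation is computed on the
#' raw zone means; any display scaling is irrelevant to r.
#'
#' @param field,reference arrays `(time, lat, lon)` on a common time axis.
#' @param zonemap character matrix from [zone_map_from_latlon()].
#' @return data.frame with columns `zone`, `r`, `n`.
#' @export
zone_correlation <- function(field, reference, zonemap) {
  if (!identical(dim(field), dim(reference)))
    stopf("schema error: field and reference time axes/geometry differ")
  .check_zonemap(field, zonemap)
  nt <- dim(field)[1]
  if (nt < 3) stopf("need >= 3 time steps")
  zones <- setdiff(sort(unique(as.vector(zonemap))), "masked")
  out <- lapply(zones, function(z) {
    cells <- which(zonemap == z)
    if (length(cells) == 0) return(NULL)
    fm <- matrix(field, nt, prod(dim(field)[2:3]))[, cells, drop = FALSE]
    rm_ <- matrix(reference, nt, prod(dim(field)[2:3]))[, cells, drop = FALSE]
    data.frame(zone = z, r = .pearson(rowMeans(fm, na.rm = TRUE),
                                      rowMeans(rm_, na.rm = TRUE)),
               n = nt)
  })
  do.call(rbind, out)
}

#' @rdname zone_correlation
#' @return `pixel_correlation`: matrix `(lat, lon)` of per-pixel Pearson r
#'   (missing where either series has zero variance).
#' @export
pixel_correlation <- function(field, reference) {
  if (!identical(dim(field), dim(reference)))
    stopf("schema error: field and reference time axes/geometry differ")
  d <- dim(field)
  if (d[1] < 3) stopf("need >= 3 time steps")
  fm <- matrix(field, d[1], d[2] * d[3])
  rm_ <- matrix(reference, d[1], d[2] * d[3])
  r <- vapply(seq_len(ncol(fm)), function(j) .pearson(fm[, j], rm_[, j]),
              numeric(1))
  matrix(r, d[2], d[3])
}
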