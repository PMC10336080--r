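#' Vapor pressure deficit from air and dewpoint temperature
#'
#' VPD = SVP(Ta) - AVP, with the actual vapor pressure taken as the
#' saturation vapor pressure at the dewpoint, both from the Magnus formula
#' `0.61094 * exp(17.625 * T / (T + 243.04))` kPa. Supersaturated inputs
#' (Td > Ta) would give negative deficits and are clamped to 0; the clamp
#' count is attached as attribute `n_clamped`.
#'
#' @param ta air temperature, degC (vector/matrix/array).
#' @param td dewpoint temperature, degC, same shape.
#' @return VPD in kPa, same shape as `ta`, with attribute `n_clamped`.
#' @export
compute_vpd <- function(ta, td) {
  scalar_ok <- length(ta) == 1 || length(td) == 1
  if (!scalar_ok && (!identical(dim(ta), dim(td)) || length(ta) != length(td)))
    stopf("geometry error: Ta and Td shapes differ")
  vpd <- .magnus(ta) - .magnus(td)
  n_clamped <- sum(vpd < 0, na.rm = TRUE)
  vpd[!is.na(vpd) & vpd < 0] <- 0
  attr(vpd, "n_clamped") <- n_clamped
  vpd
}

#' Block-average a fine grid to a coarser resolution
#'
#' Every coarse cell is the arithmetic mean of its `factor x factor` block
#' over the non-missing fine cells; an all-missing block stays missing.
#'
#' @param field matrix `(lat, lon)` or array `(time, lat, lon)`.
#' @param factor integer aggregation factor; must divide both spatial
#'   dimensions.
#' @return the coarsened matrix or array.
#' @export
regrid_mean <- function(field, factor) {
  d <- dim(field)
  if (is.null(d)) stopf("geometry error: `field` must be a matrix or array")
  sp <- if (length(d) == 2) d else d[2:3]
  if (any(sp %% factor != 0))
    stopf("geometry error: factor %d does not divide grid %s", factor,
          paste(sp, collapse = "x"))
  block_mean <- function(M) {
    nr <- nrow(M) %/% factor; nc <- ncol(M) %/% factor
    out <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      b <- M[((i - 1) * factor + 1):(i * factor),
             ((j - 1) * factor + 1):(j * factor)]
      if (any(!is.na(b))) out[i, j] <- mean(b, na.rm = TRUE)
    }
    out
  }
  if (length(d) == 2) return(block_mean(field))
  out <- array(NA_real_, dim = c(d[1], d[2] %/% factor, d[3] %/% factor))
  for (t in seq_len(d[1])) out[t, , ] <- block_mean(field[t, , ])
  out
}

#' Cold-region mask
#'
#' Flags cells poleward of the Arctic circle (default 66.5 N) or of the
#' Antarctic threshold (default 60 S).
#'
#' @param lat,lon cell-center coordinate vectors.
#' @param arctic_lat,antarctic_lat mask boundaries in degrees.
#' @return logical matrix `(lat, lon)`; `TRUE` marks excluded cells.
#' @export
build_mask <- function(lat, lon, arctic_lat = 66.5, antarctic_lat = -60) {
  matrix(lat > arctic_lat | lat < antarctic_lat,
         nrow = length(lat), ncol = length(lon))
}

#' Upscale a trained ensemble onto a predictor grid
#'
#' Derives VPD from the grid's air and dewpoint temperatures, normalizes
#' the five predictors with the training statistics, runs each flux
#' ensemble over every unmasked cell and timestep, and assembles the
#' four-variable gridded product (ensemble mean and across-member standard
#' deviation for both fluxes). Windowed architectures consume the trailing
#' `window` timesteps for each prediction; leading-edge timesteps are
#' missing by default (`spin_up = "missing"`) or predicted from a window
#' padded by repeating the first timestep (`"shortened"`).
#'
#' @param models named list with `GPP` and `RECO` `ensemble_model`s (one of
#'   the two may be omitted; its fields stay missing).
#' @param grid a `predictor_grid` from [gen_grid()] (or any list with the
#'   same structure).
#' @param stats the training `norm_stats`.
#' @param mask optional logical `(lat, lon)` matrix from [build_mask()].
#' @param spin_up `"missing"` or `"shortened"`.
#' @return a `gridded_field`: list with `lat`, `lon`, `dates`, and arrays
#'   `GPP`, `RECO`, `GPP_std`, `RECO_std` shaped `(time, lat, lon)`.
#' @export
upscale_grid <- function(models, grid, stats, mask = NULL,
                         spin_up = c("missing", "shortened")) {
  spin_up <- match.arg(spin_up)
  needed <- c("P", "TA", "TD", "SW_IN", "LAI")
  absent <- setdiff(needed, names(grid$vars))
  if (length(absent))
    stopf("schema error: predictor variable(s) missing: %s",
          paste(absent, collapse = ", "))
  nt <- length(grid$dates); nlat <- length(grid$lat); nlon <- length(grid$lon)
  ncell <- nlat * nlon
  vpd <- compute_vpd(grid$vars$TA, grid$vars$TD)
  feats <- list(P = grid$vars$P, TA = grid$vars$TA, VPD = vpd,
                SW_IN = grid$vars$SW_IN, LAI = grid$vars$LAI)
  for (f in names(feats))
    feats[[f]] <- (feats[[f]] - stats$mean[[f]]) / stats$sd[[f]]
  out <- list()
  for (target in c("GPP", "RECO")) {
    mu <- array(NA_real_, c(nt, nlat, nlon))
    sd_ <- array(NA_real_, c(nt, nlat, nlon))
    model <- models[[target]]
    if (!is.null(model)) {
      arch <- model$members[[1]]$config$arch
      if (arch == "mlp") {
        x <- cbind(as.vector(feats$P), as.vector(feats$TA),
                   as.vector(feats$VPD), as.vector(feats$SW_IN),
                   as.vector(feats$LAI))
        pe <- predict_ensemble(model, x)
        mu[] <- pe$mean
        sd_[] <- pe$std
      } else {
        w <- model$members[[1]]$config$window
        fm <- lapply(feats, function(a) matrix(a, nt, ncell))
        for (t_out in seq_len(nt)) {
          if (t_out < w && spin_up == "missing") next
          steps <- (t_out - w + 1L):t_out
          steps[steps < 1L] <- 1L               # shortened: repeat first step
          x <- array(NA_real_, c(ncell, w, 5L))
          for (k in seq_len(5L))
            x[, , k] <- t(fm[[k]][steps, , drop = FALSE])
          pe <- predict_ensemble(model, x)
          mu[t_out, , ] <- pe$mean
          sd_[t_out, , ] <- pe$std
        }
      }
      if (!is.null(mask)) {
        mask_t <- aperm(array(mask, c(nlat, nlon, nt)), c(3, 1, 2))
        mu[mask_t] <- NA_real_
        sd_[mask_t] <- NA_real_
      }
    }
    out[[target]] <- mu
    out[[paste0(target, "_std")]] <- sd_
  }
  structure(list(lat = grid$lat, lon = grid$lon, dates = grid$dates,
                 GPP = out$GPP, RECO = out$RECO, GPP_std = out$GPP_std,
                 RECO_std = out$RECO_std),
            class = "gridded_field")
}

.product_units <- "gC m-2 d-1"
.product_vars <- c("GPP", "RECO", "GPP_std", "RECO_std")
.product_longnames <- c(
  GPP = "gross primary production, ensemble mean",
  RECO = "ecosystem respiration, ensemble mean",
  GPP_std = "gross primary production, ensemble standard deviation",
  RECO_std = "ecosystem respiration, ensemble standard deviation")

.write_one_product <- function(field, sel, path) {
  time_days <- as.numeric(field$dates[sel] - as.Date("1970-01-01"))
  vars <- lapply(.product_vars, function(v)
    list(data = field[[v]][sel, , , drop = FALSE],
         dims = c("time", "lat", "lon"), type = "float",
         attrs = list(units = .product_units,
                      long_name = unname(.product_longnames[[v]]),
                      `_FillValue` = NaN)))
  names(vars) <- .product_vars
  nc_write(path,
           dims = list(time = time_days, lat = field$lat, lon = field$lon),
           vars = vars,
           global_attrs = list(title = "gridded GPP/Reco flux product"),
           dim_attrs = list(time = list(units = "days since 1970-01-01"),
                            lat = list(units = "degrees_north"),
                            lon = list(units = "degrees_east")))
}

#' Write a gridded flux product as NetCDF files
#'
#' Daily fields are written one file per calendar month, named
#' `METAFLUX_GPP_RECO_daily_<year><month>.nc` (month zero-padded 01-12);
#' monthly fields one file per year, `METAFLUX_GPP_RECO_monthly_<year>.nc`.
#' Each file holds exactly the four product variables in float32 with
#' CF-style attributes. Partial periods are an error.
#'
#' @param field a `gridded_field`.
#' @param dir output directory (created if needed).
#' @param timescale `"daily"` or `"monthly"`.
#' @return invisibly, the written file paths.
#' @export
write_product <- function(field, dir, timescale = c("daily", "monthly")) {
  timescale <- match.arg(timescale)
  stopifnot(inherits(field, "gridded_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dates <- field$dates
  paths <- character(0)
  if (timescale == "daily") {
    ym <- format(dates, "%Y%m")
    for (g in unique(ym)) {
      sel <- which(ym == g)
      month_start <- as.Date(paste0(g, "01"), "%Y%m%d")
      n_days <- as.integer(seq(month_start, by = "month", length.out = 2)[2] -
                             month_start)
      if (length(sel) != n_days ||
          !all(sort(dates[sel]) == seq(month_start, by = "day", length.out = n_days)))
        stopf("period error: month %s is incomplete", g)
      p <- file.path(dir, sprintf("METAFLUX_GPP_RECO_daily_%s.nc", g))
      .write_one_product(field, sel, p)
      paths <- c(paths, p)
    }
  } else {
    yr <- format(dates, "%Y")
    for (g in unique(yr)) {
      sel <- which(yr == g)
      if (length(sel) != 12 ||
          !all(sort(unique(format(dates[sel], "%m"))) == sprintf("%02d", 1:12)))
        stopf("period error: year %s is incomplete", g)
      p <- file.path(dir, sprintf("METAFLUX_GPP_RECO_monthly_%s.nc", g))
      .write_one_product(field, sel, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Read a gridded product back from NetCDF files
#'
#' @param paths NetCDF file paths (or a directory containing them).
#' @return a `gridded_field` with the files concatenated along time.
#' @export
read_product <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "^METAFLUX_GPP_RECO_.*\\.nc$",
                        full.names = TRUE)
  if (length(paths) == 0) stopf("no product files found")
  parts <- lapply(sort(paths), nc_read)
  dates <- as.Date(unlist(lapply(parts, function(p) p$dims$time)),
                   origin = "1970-01-01")
  arr <- function(v) {
    slabs <- lapply(parts, function(p) p$vars[[v]]$data)
    out <- array(NA_real_, c(length(dates), dim(slabs[[1]])[2], dim(slabs[[1]])[3]))
    pos <- 0L
    for (s in slabs) {
      out[(pos + 1L):(pos + dim(s)[1]), , ] <- s
      pos <- pos + dim(s)[1]
    }
    out
  }
  structure(list(lat = parts[[1]]$dims$lat, lon = parts[[1]]$dims$lon,
                 dates = dates, GPP = arr("GPP"), RECO = arr("RECO"),
                 GPP_std = arr("GPP_std"), RECO_std = arr("RECO_std")),
            class = "gridded_field")
}
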