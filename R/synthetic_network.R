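#' Generator parameters for synthetic station networks
#'
#' Bundles every knob of the synthetic world: how many stations per climate
#' zone, how long the record is, the per-zone multiplicative shift applied to
#' flux-response parameters (this is what creates the base/target
#' distribution gap), the water-stress memory half-life, observation noise,
#' the probability weight of heavy-tailed flux extremes, and the fraction of
#' missing records.
#'
#' @param n_stations_per_zone named integer vector; names are climate zones
#'   from `c("tropics", "semi-arid", "temperate", "continental")`.
#' @param years number of simulated years.
#' @param timestep `"daily"` or `"monthly"`.
#' @param zone_shift named numeric vector of multiplicative offsets applied
#'   to the light-saturated assimilation rate and basal respiration of
#'   stations in that zone; zones not named get 1 (no shift).
#' @param memory_halflife half-life, in days, of the exponentially decaying
#'   soil-water bucket that carries water stress across time.
#' @param noise_sd Gaussian observation noise on both fluxes, gC m-2 d-1.
#' @param extreme_tail probability that a record receives an additional
#'   heavy-tailed positive flux spike (see Details).
#' @param gap_fraction fraction of records whose fluxes are set missing.
#' @param response_jitter_sd lognormal sd of per-station jitter on response
#'   parameters (0 = all stations in a zone share one response).
#' @param climate_lat,climate_wetness reference latitude (deg) and wetness
#'   index of the shared station climatology. Every station's weather draws
#'   from this one distribution, so with all `zone_shift` at 1 the zones are
#'   statistically exchangeable and mean fluxes differ only through sampling
#'   noise; any base/target gap comes solely from the response shift.
#' @param seed integer master seed; every draw in the generator derives from
#'   it, so outputs are pure functions of the parameter set.
#'
#' @details Spikes representing extreme fluxes are drawn for every record at
#' fixed seed and applied only where a uniform draw falls below
#' `extreme_tail`; selections at increasing `extreme_tail` are therefore
#' nested, which makes extreme counts monotone in the tail weight.
#'
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(n_stations_per_zone = c(temperate = 8, tropics = 4),
                             years = 2,
                             timestep = c("daily", "monthly"),
                             zone_shift = NULL,
                             memory_halflife = 15,
                             noise_sd = 0.8,
                             extreme_tail = 0,
                             gap_fraction = 0,
                             response_jitter_sd = 0.1,
                             climate_lat = 40,
                             climate_wetness = 0.6,
                             seed = 1L) {
  timestep <- match.arg(timestep)
  zones <- c("tropics", "semi-arid", "temperate", "continental")
  if (length(n_stations_per_zone) == 0 || is.null(names(n_stations_per_zone)))
    stopf("`n_stations_per_zone` must be a named vector of station counts")
  if (!all(names(n_stations_per_zone) %in% zones))
    stopf("unknown zone label(s): %s",
          paste(setdiff(names(n_stations_per_zone), zones), collapse = ", "))
  if (!all(vapply(n_stations_per_zone, is_count, logical(1))))
    stopf("station counts must be non-negative integers")
  if (!is.numeric(years) || years <= 0) stopf("`years` must be positive")
  if (!is.numeric(gap_fraction) || gap_fraction < 0 || gap_fraction >= 1)
    stopf("`gap_fraction` must be in [0, 1)")
  if (!is.numeric(noise_sd) || noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (!is.numeric(memory_halflife) || memory_halflife <= 0)
    stopf("`memory_halflife` must be > 0")
  if (!is.numeric(extreme_tail) || extreme_tail < 0 || extreme_tail > 1)
    stopf("`extreme_tail` must be in [0, 1]")
  shift <- stats::setNames(rep(1, length(zones)), zones)
  if (!is.null(zone_shift)) {
    if (is.null(names(zone_shift)) || !all(names(zone_shift) %in% zones))
      stopf("`zone_shift` must be named with known zones")
    shift[names(zone_shift)] <- zone_shift
  }
  structure(list(
    n_stations_per_zone = n_stations_per_zone, years = years,
    timestep = timestep, zone_shift = shift,
    memory_halflife = memory_halflife, noise_sd = noise_sd,
    extreme_tail = extreme_tail, gap_fraction = gap_fraction,
    response_jitter_sd = response_jitter_sd,
    climate_lat = climate_lat, climate_wetness = climate_wetness,
    seed = as.integer(seed)
  ), class = "generator_params")
}

#' Ground-truth flux response of a synthetic station
#'
#' Minimal generative model used by the synthetic world: a saturating light
#' response times a Gaussian temperature response times a soil-water stress
#' factor and a canopy (LAI) interception term for GPP, and a Q10
#' respiration curve times the same stress factor for Reco.
#'
#' @param pmax light-saturated assimilation rate, gC m-2 d-1.
#' @param k_light initial slope of the light response per W m-2.
#' @param t_opt,t_width optimum and width (degC) of the temperature response.
#' @param r0 basal respiration at 10 degC, gC m-2 d-1.
#' @param q10 respiration temperature sensitivity (> 1).
#' @param w_sens exponent of the water-stress factor; 0 switches water
#'   stress off entirely (the factor becomes exactly 1).
#' @return an object of class `flux_response`.
#' @export
flux_response <- function(pmax = 12, k_light = 0.04, t_opt = 20, t_width = 12,
                          r0 = 2.5, q10 = 2, w_sens = 1) {
  if (pmax <= 0 || r0 <= 0) stopf("`pmax` and `r0` must be > 0")
  if (q10 <= 1) stopf("`q10` must be > 1")
  if (t_width <= 0) stopf("`t_width` must be > 0")
  if (w_sens < 0) stopf("`w_sens` must be >= 0")
  structure(list(pmax = pmax, k_light = k_light, t_opt = t_opt,
                 t_width = t_width, r0 = r0, q10 = q10, w_sens = w_sens),
            class = "flux_response")
}

# zone climatology anchors: latitude band and a 0-1 wetness index
.zone_lat_range <- list(
  tropics = c(-15, 15), `semi-arid` = c(15, 35),
  temperate = c(35, 55), continental = c(55, 65))
.zone_wetness <- c(tropics = 0.9, `semi-arid` = 0.25,
                   temperate = 0.6, continental = 0.5)

.magnus <- function(t_c) 0.61094 * exp(17.625 * t_c / (t_c + 243.04))

.gen_dates <- function(years, timestep, origin = as.Date("2001-01-01")) {
  if (timestep == "daily") {
    seq(origin, by = "day", length.out = round(365.25 * years))
  } else {
    seq(origin, by = "month", length.out = round(12 * years))
  }
}

# AR(1) noise, vectorised recursion via filter()
.ar1 <- function(n, sd, rho) {
  as.numeric(stats::filter(stats::rnorm(n, 0, sd * sqrt(1 - rho^2)),
                           rho, method = "recursive"))
}

# Seasonal weather drivers for one location. Consumes RNG; call under a seed.
.gen_climate <- function(lat, wetness, dates) {
  n <- length(dates)
  doy <- as.numeric(format(dates, "%j"))
  peak <- if (lat >= 0) 196 else 14                   # mid-July vs mid-January
  seas <- cos(2 * pi * (doy - peak) / 365.25)
  ta <- (27 - 0.42 * abs(lat)) + (3 + 0.28 * abs(lat)) * seas + .ar1(n, 1.5, 0.7)
  sw <- pmax(10, (260 - 1.6 * abs(lat)) + (40 + 2.2 * abs(lat)) * seas +
               .ar1(n, 25, 0.5))
  p_wet <- pmin(0.95, pmax(0.02, wetness * (0.75 + 0.45 * seas)))
  p <- stats::rbinom(n, 1L, p_wet) *
    stats::rgamma(n, shape = 1.5, scale = 3 + 6 * wetness)
  dep <- pmax(0, 2 + 12 * (1 - wetness) - 0.15 * p + stats::rnorm(n, 0, 1))
  td <- ta - dep
  vpd <- pmax(0, .magnus(ta) - .magnus(td))
  lai <- pmax(0.1, (1 + 4.5 * wetness) * (0.65 + 0.35 * seas) + .ar1(n, 0.15, 0.8))
  data.frame(date = dates, P = p, TA = ta, TD = td, VPD = vpd,
             SW_IN = sw, LAI = lai)
}

# Exponentially decaying soil-water bucket and the derived 0-1 stress factor.
.water_stress <- function(p, halflife_days, step_days, w_sens, w_half = 20) {
  decay <- exp(-log(2) * step_days / halflife_days)
  w <- as.numeric(stats::filter(p, decay, method = "recursive", init = w_half))
  stress <- if (w_sens == 0) rep(1, length(p)) else (w / (w + w_half))^w_sens
  list(bucket = w, stress = stress)
}

.clean_fluxes <- function(clim, response, stress) {
  light <- response$pmax * (1 - exp(-response$k_light * clim$SW_IN / response$pmax))
  tempf <- exp(-(clim$TA - response$t_opt)^2 / (2 * response$t_width^2))
  canopy <- 1 - exp(-0.5 * clim$LAI)
  gpp <- light * tempf * stress * canopy
  reco <- response$r0 * response$q10^((clim$TA - 10) / 10) * stress
  list(gpp = gpp, reco = reco)
}

#' Simulate one station's flux record
#'
#' Draws the station's weather, propagates the water-stress bucket, applies
#' the flux response, then adds Gaussian noise, optional heavy-tailed
#' positive spikes, and missing-data gaps. Deterministic in
#' `(params, response, station_seed)`.
#'
#' @param params a [generator_params()] object.
#' @param response a [flux_response()] object (the station's ground truth).
#' @param station_seed integer seed for this station's draws.
#' @param station_id,zone,pft,lat,lon station metadata; `lat`/`lon` are
#'   bookkeeping only (station weather draws from the shared reference
#'   climatology in `params`); `lat` defaults to the middle of the zone's
#'   latitude band.
#' @param climate optional pre-built driver table (columns `date`, `P`, `TA`,
#'   `TD`, `VPD`, `SW_IN`, `LAI`); when supplied, only fluxes and noise are
#'   simulated. Used to inject controlled drivers in tests.
#' @return a `station_record`: list with `station_id`, `data` (the
#'   observation table), `zone`, `pft`, `lat`, `lon`, `response`, and a
#'   `latent` table holding the hidden water bucket and stress factor.
#' @export
gen_station_series <- function(params, response, station_seed,
                               station_id = "ST_1", zone = "temperate",
                               pft = "ENF", lat = NULL, lon = 0,
                               climate = NULL) {
  if (!inherits(params, "generator_params")) stopf("`params` must be generator_params")
  if (!inherits(response, "flux_response")) stopf("`response` must be flux_response")
  if (is.null(lat)) lat <- mean(.zone_lat_range[[zone]])
  step_days <- if (params$timestep == "daily") 1 else 30.44
  with_seed(station_seed, {
    if (is.null(climate)) {
      dates <- .gen_dates(params$years, params$timestep)
      climate <- .gen_climate(params$climate_lat, params$climate_wetness, dates)
    }
    n <- nrow(climate)
    ws <- .water_stress(climate$P, params$memory_halflife, step_days,
                        response$w_sens)
    fl <- .clean_fluxes(climate, response, ws$stress)
    noise_one <- function() {
      eps <- stats::rnorm(n, 0, params$noise_sd)
      u <- stats::runif(n)
      spike <- params$noise_sd * (3 + stats::rexp(n, rate = 0.5))
      eps + ifelse(u < params$extreme_tail, spike, 0)
    }
    gpp <- pmax(0, fl$gpp + noise_one())
    reco <- pmax(0, fl$reco + noise_one())
    if (params$gap_fraction > 0) {
      n_gap <- round(params$gap_fraction * n)
      gap <- sample.int(n, n_gap)
      gpp[gap] <- NA_real_
      reco[gap] <- NA_real_
    }
    structure(list(
      station_id = station_id,
      data = data.frame(date = climate$date, P = climate$P, TA = climate$TA,
                        VPD = climate$VPD, SW_IN = climate$SW_IN,
                        LAI = climate$LAI, GPP = gpp, RECO = reco),
      zone = zone, pft = pft, lat = lat, lon = lon, response = response,
      latent = data.frame(bucket = ws$bucket, stress = ws$stress)
    ), class = "station_record")
  })
}

.pft_levels <- c("ENF", "DBF", "EBF", "GRA", "CRO", "SHR")

#' Simulate a multi-zone station network
#'
#' Stations in each zone draw their flux response from a common distribution
#' (per-station lognormal jitter around one base response) whose assimilation
#' and respiration scales are multiplied by that zone's `zone_shift`. With
#' all shifts at 1, every zone samples the identical response distribution;
#' shifted zones create the base/target distribution gap that meta-learning
#' is meant to bridge.
#'
#' @param params a [generator_params()] object.
#' @param base_response the zone-agnostic base [flux_response()].
#' @return a `station_network`: list with `stations` (list of
#'   `station_record`), `params`, and attribute-level per-zone response
#'   distribution parameters in `$zone_response`.
#' @export
gen_network <- function(params, base_response = flux_response()) {
  if (!inherits(params, "generator_params")) stopf("`params` must be generator_params")
  counts <- params$n_stations_per_zone[params$n_stations_per_zone > 0]
  if (length(counts) == 0 || sum(counts) == 0)
    stopf("configuration error: empty network (no stations in any zone)")
  zone_response <- lapply(names(counts), function(z) {
    r <- base_response
    r$pmax <- r$pmax * params$zone_shift[[z]]
    r$r0 <- r$r0 * params$zone_shift[[z]]
    r
  })
  names(zone_response) <- names(counts)
  stations <- list()
  k <- 0L
  for (z in names(counts)) {
    for (i in seq_len(counts[[z]])) {
      k <- k + 1L
      meta_seed <- child_seed(params$seed, 2L * k)
      st_meta <- with_seed(meta_seed, {
        band <- .zone_lat_range[[z]]
        lat <- stats::runif(1, band[1], band[2])
        if (z == "semi-arid" && stats::runif(1) < 0.5) lat <- -lat
        list(lat = lat, lon = stats::runif(1, -180, 180),
             pft = sample(.pft_levels, 1L),
             jit = exp(stats::rnorm(2, 0, params$response_jitter_sd)))
      })
      resp <- zone_response[[z]]
      resp$pmax <- resp$pmax * st_meta$jit[1]
      resp$r0 <- resp$r0 * st_meta$jit[2]
      id <- sprintf("ST_%s_%02d", gsub("-", "", z), i)
      stations[[id]] <- gen_station_series(
        params, resp, station_seed = child_seed(params$seed, 2L * k + 1L),
        station_id = id, zone = z, pft = st_meta$pft,
        lat = st_meta$lat, lon = st_meta$lon)
    }
  }
  structure(list(stations = stations, params = params,
                 zone_response = zone_response),
            class = "station_network")
}

#' Simulate a gridded predictor cube
#'
#' Builds a lat/lon/time cube of the five predictors (plus dewpoint, so the
#' VPD-derivation path can be exercised) with smooth latitudinal gradients
#' and a smooth longitudinal perturbation, together with the noise-free
#' ground-truth GPP and Reco fields implied by `response` — the closed-loop
#' reference for upscaling tests.
#'
#' @param extent numeric `c(lat_min, lat_max, lon_min, lon_max)` in degrees.
#' @param resolution cell size in degrees; must divide both extents.
#' @param params a [generator_params()] object (years, timestep, memory,
#'   seed).
#' @param response the [flux_response()] generating the truth fields.
#' @param dates optional Date vector overriding the `params` time axis.
#' @return a `predictor_grid`: list with `lat`, `lon` (cell centers, lat
#'   descending), `dates`, `vars` (arrays `time x lat x lon` named `P`,
#'   `TA`, `TD`, `SW_IN`, `LAI`), and `truth` (`GPP`, `RECO`).
#' @export
gen_grid <- function(extent, resolution, params, response = flux_response(),
                     dates = NULL) {
  if (length(extent) != 4) stopf("`extent` must be c(lat_min, lat_max, lon_min, lon_max)")
  dlat <- extent[2] - extent[1]; dlon <- extent[4] - extent[3]
  if (dlat <= 0 || dlon <= 0) stopf("geometry error: empty extent")
  nlat <- dlat / resolution; nlon <- dlon / resolution
  if (abs(nlat - round(nlat)) > 1e-8 || abs(nlon - round(nlon)) > 1e-8)
    stopf("geometry error: resolution %g does not divide extent", resolution)
  nlat <- as.integer(round(nlat)); nlon <- as.integer(round(nlon))
  lat <- rev(extent[1] + (seq_len(nlat) - 0.5) * resolution)  # north to south
  lon <- extent[3] + (seq_len(nlon) - 0.5) * resolution
  if (is.null(dates)) dates <- .gen_dates(params$years, params$timestep)
  nt <- length(dates)
  step_days <- if (params$timestep == "daily") 1 else 30.44
  vars <- lapply(c("P", "TA", "TD", "SW_IN", "LAI"), function(v)
    array(NA_real_, dim = c(nt, nlat, nlon)))
  names(vars) <- c("P", "TA", "TD", "SW_IN", "LAI")
  # smooth longitudinal perturbations, seeded once for the whole grid
  pert <- with_seed(child_seed(params$seed, 7919L), {
    ph <- stats::runif(3, 0, 2 * pi)
    list(ta = 0.8 * sin(2 * pi * seq_len(nlon) / nlon + ph[1]),
         sw = 10 * sin(2 * pi * seq_len(nlon) / nlon + ph[2]),
         p = 0.15 * sin(2 * pi * seq_len(nlon) / nlon + ph[3]))
  })
  for (i in seq_len(nlat)) {
    wet <- .lat_wetness(lat[i])
    row_clim <- with_seed(child_seed(params$seed, 100000L + i),
                          .gen_climate(lat[i], wet, dates))
    for (j in seq_len(nlon)) {
      ta <- row_clim$TA + pert$ta[j]
      sw <- pmax(10, row_clim$SW_IN + pert$sw[j])
      p <- row_clim$P * (1 + pert$p[j])
      td <- row_clim$TD + pert$ta[j]          # keep depression unchanged
      vars$P[, i, j] <- p
      vars$TA[, i, j] <- ta
      vars$TD[, i, j] <- td
      vars$SW_IN[, i, j] <- sw
      vars$LAI[, i, j] <- row_clim$LAI
    }
  }
  # truth fluxes: propagate the bucket cellwise (vectorised over cells)
  ncell <- nlat * nlon
  pm <- matrix(vars$P, nrow = nt, ncol = ncell)
  decay <- exp(-log(2) * step_days / params$memory_halflife)
  w <- matrix(0, nt, ncell)
  prev <- rep(20, ncell)
  for (t in seq_len(nt)) {
    prev <- decay * prev + pm[t, ]
    w[t, ] <- prev
  }
  stress <- if (response$w_sens == 0) matrix(1, nt, ncell) else (w / (w + 20))^response$w_sens
  ta_m <- matrix(vars$TA, nt, ncell); sw_m <- matrix(vars$SW_IN, nt, ncell)
  lai_m <- matrix(vars$LAI, nt, ncell)
  light <- response$pmax * (1 - exp(-response$k_light * sw_m / response$pmax))
  tempf <- exp(-(ta_m - response$t_opt)^2 / (2 * response$t_width^2))
  canopy <- 1 - exp(-0.5 * lai_m)
  gpp <- array(light * tempf * stress * canopy, dim = c(nt, nlat, nlon))
  reco <- array(response$r0 * response$q10^((ta_m - 10) / 10) * stress,
                dim = c(nt, nlat, nlon))
  structure(list(lat = lat, lon = lon, dates = dates, vars = vars,
                 truth = list(GPP = gpp, RECO = reco), resolution = resolution,
                 response = response),
            class = "predictor_grid")
}

# piecewise wetness by |lat|, mirroring the zone anchors
.lat_wetness <- function(lat) {
  a <- abs(lat)
  if (a <= 15) 0.9 else if (a <= 35) 0.25 else if (a <= 55) 0.6 else 0.5
}

#' Write a station network to CSV (one file per station plus a metadata
#' sidecar)
#'
#' @param network a `station_network` or list of `station_record`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_station_csv <- function(network, dir) {
  stations <- if (inherits(network, "station_network")) network$stations else network
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  meta <- do.call(rbind, lapply(stations, function(s)
    data.frame(station_id = s$station_id, lat = s$lat, lon = s$lon,
               zone = s$zone, pft = s$pft)))
  for (s in stations) {
    p <- file.path(dir, paste0(s$station_id, ".csv"))
    out <- cbind(station_id = s$station_id, s$data)
    out$date <- format(out$date, "%Y-%m-%d")
    utils::write.csv(out, p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "stations_meta.csv")
  utils::write.csv(meta, mp, row.names = FALSE)
  invisible(c(paths, mp))
}

#' Read a station network written by [write_station_csv()]
#'
#' @param dir directory holding `<station_id>.csv` files and
#'   `stations_meta.csv`.
#' @param na_token string(s) treated as the missing sentinel (default: empty
#'   cell or `"NA"`).
#' @return a `station_network` (responses and latent states are not part of
#'   the on-disk schema and are absent).
#' @export
read_station_csv <- function(dir, na_token = c("", "NA")) {
  mp <- file.path(dir, "stations_meta.csv")
  if (!file.exists(mp)) stopf("no stations_meta.csv in %s", dir)
  meta <- utils::read.csv(mp, stringsAsFactors = FALSE)
  stations <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    d <- utils::read.csv(file.path(dir, paste0(m$station_id, ".csv")),
                         stringsAsFactors = FALSE, na.strings = na_token)
    d$date <- as.Date(d$date)
    if (is.unsorted(d$date, strictly = TRUE)) stopf("dates not strictly increasing in %s", m$station_id)
    structure(list(station_id = m$station_id,
                   data = d[, c("date", "P", "TA", "VPD", "SW_IN", "LAI", "GPP", "RECO")],
                   zone = m$zone, pft = m$pft, lat = m$lat, lon = m$lon,
                   response = NULL, latent = NULL),
              class = "station_record")
  })
  names(stations) <- meta$station_id
  structure(list(stations = stations, params = NULL, zone_response = NULL),
            class = "station_network")
}
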