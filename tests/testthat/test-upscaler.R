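test_that("VPD derivation: saturation, Magnus arithmetic, clamping, monotonicity", {
  expect_equal(as.numeric(compute_vpd(20, 20)), 0)
  magnus <- function(t) 0.61094 * exp(17.625 * t / (t + 243.04))  # oracle
  expect_equal(as.numeric(compute_vpd(25, 20)), magnus(25) - magnus(20))
  expect_equal(as.numeric(compute_vpd(25, 20)), 0.830, tolerance = 0.005)
  v <- compute_vpd(25, 26)                  # supersaturated: clamp to 0
  expect_equal(as.numeric(v), 0)
  expect_equal(attr(v, "n_clamped"), 1)
  ta <- seq(0, 40, length.out = 50)
  expect_true(all(diff(as.numeric(compute_vpd(ta, 0))) > 0))
  expect_true(all((as.numeric(compute_vpd(ta, 15)) == 0) == (ta <= 15)))
})

test_that("block regridding equals a brute-force per-block mean", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)          # block [1,2,3,4] column-major
  expect_equal(regrid_mean(m, 2)[1, 1], 2.5)
  m2 <- matrix(c(1, 3, NA, NA), 2, 2)
  expect_equal(regrid_mean(m2, 2)[1, 1], 2.0)
  expect_equal(regrid_mean(matrix(NA_real_, 2, 2), 2)[1, 1], NA_real_)
  expect_equal(regrid_mean(matrix(7, 6, 4), 2), matrix(7, 3, 2))
  set.seed(71)
  f <- matrix(rnorm(12 * 8), 12, 8)
  f[sample(96, 10)] <- NA
  got <- regrid_mean(f, 4)
  for (i in 1:3) for (j in 1:2) {
    blk <- f[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j)]
    want <- if (all(is.na(blk))) NA_real_ else mean(blk, na.rm = TRUE)
    expect_equal(got[i, j], want)
  }
  expect_error(regrid_mean(matrix(0, 5, 4), 2), "geometry error")
})

test_that("cold-region mask flags poleward cells only", {
  lat <- c(80, 70, 40, 0, -40, -70)
  m <- build_mask(lat, c(0, 10))
  expect_true(all(m[1:2, ]))                # inside the Arctic circle
  expect_false(any(m[3:5, ]))
  expect_true(all(m[6, ]))
  frac <- mean(build_mask(seq(-89.875, 89.875, by = 0.25), 0))
  expect_true(frac > 0 && frac < 1)
})

test_that("upscaling writes ensemble stats per cell and honors the mask", {
  params <- generator_params(c(temperate = 1), years = 1, seed = 72)
  dates <- seq(as.Date("2001-01-01"), by = "day", length.out = 5)
  grid <- gen_grid(c(60, 70, 0, 5), 0.5, params, dates = dates)
  stats <- structure(list(mean = stats::setNames(rep(0, 5), flux_features()),
                          sd = stats::setNames(rep(1, 5), flux_features()),
                          features = flux_features()), class = "norm_stats")
  one <- structure(list(members = list(constant_learner(3, input_dim = 5))),
                   class = "ensemble_model")
  mask <- build_mask(grid$lat, grid$lon)
  expect_true(any(mask) && !all(mask))      # grid straddles 66.5 N
  field <- upscale_grid(list(GPP = one, RECO = one), grid, stats, mask)
  open_rows <- which(!mask[, 1])
  expect_true(all(field$GPP_std[, open_rows, ] == 0))   # single member
  for (v in c("GPP", "RECO", "GPP_std", "RECO_std"))
    for (t in c(1, 5))
      expect_true(all(is.na(field[[v]][t, , ][mask])))
  expect_true(all(field$GPP[, 20, 1] == 3))
  bad <- grid; bad$vars$TA <- NULL
  expect_error(upscale_grid(list(GPP = one), bad, stats), "schema error")
})

test_that("windowed upscaling handles the leading edge as configured", {
  params <- generator_params(c(temperate = 1), years = 1, seed = 73)
  dates <- seq(as.Date("2001-01-01"), by = "day", length.out = 8)
  grid <- gen_grid(c(40, 42, 0, 2), 1, params, dates = dates)
  stats <- structure(list(mean = stats::setNames(rep(0, 5), flux_features()),
                          sd = stats::setNames(rep(1, 5), flux_features()),
                          features = flux_features()), class = "norm_stats")
  lst <- structure(list(members = list(constant_learner(1, arch = "lstm",
                                                        input_dim = 5))),
                   class = "ensemble_model")
  miss <- upscale_grid(list(GPP = lst), grid, stats, spin_up = "missing")
  expect_true(all(is.na(miss$GPP[1:3, , ])))        # window = 4
  expect_true(all(!is.na(miss$GPP[4:8, , ])))
  full <- upscale_grid(list(GPP = lst), grid, stats, spin_up = "shortened")
  expect_true(all(!is.na(full$GPP)))
})

test_that("product files follow the naming convention and round trip", {
  nlat <- 3; nlon <- 2
  dates <- seq(as.Date("2021-03-01"), as.Date("2021-04-30"), by = "day")
  nt <- length(dates)
  set.seed(74)
  mk <- function() array(runif(nt * nlat * nlon, 0, 10), c(nt, nlat, nlon))
  field <- structure(list(lat = c(45, 44.75, 44.5), lon = c(0.125, 0.375),
                          dates = dates, GPP = mk(), RECO = mk(),
                          GPP_std = mk(), RECO_std = mk()),
                     class = "gridded_field")
  dir <- withr::local_tempdir()
  paths <- write_product(field, dir, "daily")
  expect_setequal(basename(paths), c("METAFLUX_GPP_RECO_daily_202103.nc",
                                     "METAFLUX_GPP_RECO_daily_202104.nc"))
  back <- read_product(dir)
  expect_equal(back$dates, dates)
  expect_equal(back$GPP, field$GPP, tolerance = 1e-6)   # float32 storage
  nc <- nc_read(paths[1])
  expect_setequal(names(nc$vars), c("GPP", "RECO", "GPP_std", "RECO_std"))
  expect_true(all(vapply(nc$vars, function(v) v$attrs$units, character(1)) ==
                    "gC m-2 d-1"))
  # partial periods are refused
  part <- field
  part$dates <- dates[-3]
  part$GPP <- part$GPP[-3, , , drop = FALSE]; part$RECO <- part$RECO[-3, , , drop = FALSE]
  part$GPP_std <- part$GPP_std[-3, , , drop = FALSE]; part$RECO_std <- part$RECO_std[-3, , , drop = FALSE]
  expect_error(write_product(part, dir, "daily"), "period error")
})

test_that("monthly product files are one per complete year", {
  dates <- seq(as.Date("2021-01-01"), by = "month", length.out = 12)
  arr <- array(1, c(12, 2, 2))
  field <- structure(list(lat = c(10, 9.75), lon = c(0, 0.25), dates = dates,
                          GPP = arr, RECO = arr, GPP_std = arr * 0,
                          RECO_std = arr * 0), class = "gridded_field")
  dir <- withr::local_tempdir()
  paths <- write_product(field, dir, "monthly")
  expect_equal(basename(paths), "METAFLUX_GPP_RECO_monthly_2021.nc")
  expect_error(write_product(
    structure(c(field[setdiff(names(field), "dates")],
                list(dates = dates[1:6])), class = "gridded_field"),
    dir, "monthly"), "period error")
})
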