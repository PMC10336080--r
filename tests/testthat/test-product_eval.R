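mk_field <- function(values, nlat = 2, nlon = 2) {
  # values: vector along time, recycled per cell
  nt <- length(values)
  array(rep(values, nlat * nlon), c(nt, nlat, nlon))
}

test_that("zone climatology reproduces constants and periodic signals", {
  dates <- seq(as.Date("2001-01-01"), by = "month", length.out = 24)
  zm <- matrix(c("tropics", "tropics", "temperate", "temperate"), 2, 2)
  clim <- zone_seasonality(mk_field(rep(7, 24)), dates, zm)
  expect_true(all(clim$value == 7))
  # a pure 12-month sinusoid is recovered exactly over whole years
  s <- sin(2 * pi * (0:23) / 12)
  clim2 <- zone_seasonality(mk_field(s), dates, zm)
  expect_equal(clim2$value[clim2$zone == "tropics"], s[1:12], tolerance = 1e-12)
  # disjoint constants stay disjoint
  f <- mk_field(rep(1, 24))
  f[, , 2] <- 5
  zm2 <- matrix(c("tropics", "tropics", "temperate", "temperate"),
                2, 2)                    # lon column 1 tropics, column 2 temperate
  clim3 <- zone_seasonality(f, dates, zm2)
  expect_true(all(clim3$value[clim3$zone == "tropics"] == 1))
  expect_true(all(clim3$value[clim3$zone == "temperate"] == 5))
  expect_error(zone_seasonality(mk_field(rep(1, 6)), dates[1:6], zm),
               "12 monthly steps")
})

test_that("interannual CV: arithmetic, invariance and brute-force agreement", {
  dates <- seq(as.Date("2001-01-01"), by = "month", length.out = 24)
  # annual means 2 and 4 -> sd sqrt(2), mean 3
  f <- mk_field(c(rep(2, 12), rep(4, 12)))
  cv <- interannual_cv(f, dates)
  expect_equal(cv[1, 1], sqrt(2) / 3)
  expect_equal(cv[1, 1], 0.4714, tolerance = 1e-4)
  expect_equal(interannual_cv(mk_field(rep(3, 24)), dates)[1, 1], 0)
  expect_equal(interannual_cv(f * 13.7, dates), cv)     # scale invariance
  set.seed(81)
  rnd <- array(rnorm(24 * 5 * 4, mean = 10), c(24, 5, 4))
  got <- interannual_cv(rnd, dates)
  years <- format(dates, "%Y")
  for (i in 1:5) for (j in 1:4) {
    ann <- tapply(rnd[, i, j], years, mean)
    expect_equal(got[i, j], sd(ann) / mean(ann))
  }
  expect_error(interannual_cv(mk_field(rep(1, 12)), dates[1:12]), "2 whole years")
})

test_that("trend fitting: exact lines, constants, and significance fields", {
  years <- 2001:2010
  tr <- trend_fit(2 * years + 5, years)
  expect_equal(tr$slope, 2)
  expect_equal(tr$stderr, 0)
  expect_equal(trend_fit(rep(4, 10), years)$slope, 0)
  set.seed(82)
  noisy <- trend_fit(0.01 * years + rnorm(10, 0, 0.005), years)
  expect_true(noisy$p_value >= 0 && noisy$p_value <= 1)
  expect_gte(noisy$stderr, 0)
  expect_error(trend_fit(c(1, 2)), "sample-size error")
})

test_that("OLS slope recovery over many seeded replicates", {
  years <- 0:20
  slopes <- vapply(1:500, function(s) {
    set.seed(s)
    trend_fit(0.01 * years + rnorm(21, 0, 0.005), years)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.01), 0.002)
})

test_that("NEE approximation: sign convention and missing propagation", {
  gpp <- mk_field(c(10, 10)); reco <- mk_field(c(7, 7))
  nee <- nee_approx(gpp, reco)
  expect_true(all(nee == -3))              # net uptake is negative
  expect_true(all(nee_approx(gpp, gpp) == 0))
  gpp[1, 1, 1] <- NA
  expect_true(is.na(nee_approx(gpp, reco)[1, 1, 1]))
  expect_error(nee_approx(gpp, mk_field(c(1, 2, 3))), "geometry error")
})

test_that("correlations: exact cases, hand arithmetic, degenerate pixels", {
  dates <- seq(as.Date("2001-01-01"), by = "month", length.out = 12)
  set.seed(83)
  f <- array(rnorm(12 * 2 * 2, 5), c(12, 2, 2))
  zm <- zone_map_from_latlon(c(10, -10), c(0, 1))
  expect_true(all(zm == "tropics"))
  zc <- zone_correlation(f, f, zm)
  expect_equal(zc$r, 1)
  expect_equal(zone_correlation(f, -f, zm)$r, -1)
  # direct Pearson arithmetic oracle
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  r_hand <- sum((x - 2) * (y - mean(y))) /
    sqrt(sum((x - 2)^2) * sum((y - mean(y))^2))
  fx <- mk_field(x, 1, 1); fy <- mk_field(y, 1, 1)
  expect_equal(pixel_correlation(fx, fy)[1, 1], r_hand)
  expect_equal(r_hand, 0.9820, tolerance = 1e-4)
  # affine invariance (positive scale)
  expect_equal(pixel_correlation(fx, fy * 3.2 + 1)[1, 1], r_hand)
  # zero-variance pixels are missing
  expect_true(is.na(pixel_correlation(mk_field(rep(1, 12), 1, 1), fy_long <-
                                        mk_field(rnorm(12), 1, 1))[1, 1]))
  expect_error(zone_correlation(f, f[1:6, , , drop = FALSE], zm), "schema error")
})

test_that("area weighting integrates a uniform field to the sphere band area", {
  lat <- seq(-89.875, 89.875, by = 0.25)
  total <- sum(cell_area_m2(lat, 0.25)) * (360 / 0.25)
  expect_equal(total, 4 * pi * 6371000^2, tolerance = 1e-6)
  dates <- seq(as.Date("2001-01-01"), by = "month", length.out = 24)
  f <- mk_field(rep(1, 24), 2, 2)          # 1 gC m-2 d-1 everywhere
  ann <- global_annual_series(f, c(45, 44.75), dates, 0.25, "monthly")
  area <- sum(cell_area_m2(c(45, 44.75), 0.25)) * 2
  expect_equal(ann$total_pgc, rep(area * 365 / 1e15, 2))
})
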