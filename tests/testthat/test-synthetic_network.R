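test_that("generator parameter validation catches bad inputs", {
  expect_error(generator_params(c(temperate = -1)), "non-negative")
  expect_error(generator_params(c(mars = 1)), "unknown zone")
  expect_error(generator_params(gap_fraction = 1), "gap_fraction")
  expect_error(generator_params(memory_halflife = 0), "memory_halflife")
  expect_error(flux_response(q10 = 1), "q10")
})

test_that("station series obeys the generative contract on controlled drivers", {
  params <- generator_params(noise_sd = 0, gap_fraction = 0, seed = 1)
  resp <- flux_response(w_sens = 0)
  # zero light -> zero GPP on every timestep
  dark <- gen_station_series(params, resp, 1, climate = flat_climate(SW = 0))
  expect_true(all(dark$data$GPP == 0))
  # Ta pinned at 10 C, water stress off -> Reco = r0 exactly
  at10 <- gen_station_series(params, resp, 1, climate = flat_climate(TA = 10))
  expect_equal(at10$data$RECO, rep(resp$r0, nrow(at10$data)))
})

test_that("station series is byte-identical under a fixed seed", {
  params <- generator_params(c(temperate = 1), years = 1, gap_fraction = 0.1,
                             extreme_tail = 0.05, seed = 5)
  a <- gen_station_series(params, flux_response(), 99)
  b <- gen_station_series(params, flux_response(), 99)
  expect_identical(a, b)
})

test_that("network conserves station counts, labels and seeded assignment", {
  net <- tiny_network(n_temperate = 20, n_tropics = 4, seed = 2)
  zones <- vapply(net$stations, function(s) s$zone, character(1))
  expect_length(net$stations, 24)
  expect_equal(sum(zones == "temperate"), 20)
  expect_equal(sum(zones == "tropics"), 4)
  net2 <- tiny_network(n_temperate = 20, n_tropics = 4, seed = 2)
  expect_identical(vapply(net$stations, function(s) s$pft, character(1)),
                   vapply(net2$stations, function(s) s$pft, character(1)))
  expect_error(gen_network(generator_params(c(temperate = 0))), "empty network")
})

test_that("no zone shift means identical response distributions across zones", {
  net <- tiny_network(n_temperate = 3, n_tropics = 3, seed = 4)
  expect_identical(net$zone_response$temperate, net$zone_response$tropics)
  shifted <- tiny_network(n_temperate = 3, n_tropics = 3,
                          zone_shift = c(tropics = 1.3), seed = 4)
  expect_equal(shifted$zone_response$tropics$pmax,
               1.3 * shifted$zone_response$temperate$pmax)
})

test_that("zones are statistically exchangeable without a shift", {
  net <- tiny_network(n_temperate = 25, n_tropics = 25, years = 2, seed = 5)
  mg <- vapply(net$stations, function(s) mean(s$data$GPP), numeric(1))
  zones <- vapply(net$stations, function(s) s$zone, character(1))
  # same climatology and response distribution: a two-sample t-test should
  # not reject at any strict level
  p <- t.test(mg[zones == "temperate"], mg[zones == "tropics"])$p.value
  expect_gt(p, 1e-3)
})

test_that("heavy-tail weight monotonically inflates extreme counts (fixed seed)", {
  counts <- vapply(c(0.01, 0.05, 0.1), function(p) {
    net <- gen_network(generator_params(c(temperate = 2), years = 2,
                                        extreme_tail = p, seed = 9))
    g <- unlist(lapply(net$stations, function(s) s$data$GPP))
    z <- (g - mean(g)) / sd(g)
    sum(z > 2)
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("water-bucket memory length grows with the half-life", {
  for (seed in c(3, 17)) {
    ac <- vapply(c(5, 15, 45), function(hl) {
      net <- gen_network(generator_params(c(temperate = 1), years = 4,
                                          memory_halflife = hl, seed = seed))
      stats::acf(net$stations[[1]]$latent$bucket, plot = FALSE,
                 lag.max = 10)$acf[11]
    }, numeric(1))
    expect_true(all(diff(ac) > 0))
  }
})

test_that("gap_fraction marks the stated share of rows missing", {
  net <- gen_network(generator_params(c(temperate = 1), years = 2,
                                      gap_fraction = 0.2, seed = 6))
  d <- net$stations[[1]]$data
  expect_equal(sum(is.na(d$GPP)), round(0.2 * nrow(d)))
  expect_identical(which(is.na(d$GPP)), which(is.na(d$RECO)))
})

test_that("gridded generator geometry, saturation and determinism", {
  params <- generator_params(c(temperate = 1), years = 1, seed = 8)
  dates <- seq(as.Date("2001-01-01"), by = "day", length.out = 10)
  g <- gen_grid(c(35, 45, 0, 10), 0.25, params, dates = dates)
  expect_equal(dim(g$vars$TA), c(10, 40, 40))
  expect_equal(length(g$lat), 40)
  expect_true(all(diff(g$lat) < 0))          # north to south
  # saturated air: Td == Ta gives identically zero VPD downstream
  vpd <- compute_vpd(g$vars$TA, g$vars$TA)
  expect_true(all(vpd == 0))
  g2 <- gen_grid(c(35, 45, 0, 10), 0.25, params, dates = dates)
  expect_identical(g$vars, g2$vars)
  expect_error(gen_grid(c(0, 1, 0, 1), 0.3, params), "geometry error")
})

test_that("station CSV round trip preserves data and metadata", {
  net <- tiny_network(n_temperate = 2, n_tropics = 1, seed = 12,
                      gap_fraction = 0.1)
  dir <- withr::local_tempdir()
  write_station_csv(net, dir)
  back <- read_station_csv(dir)
  expect_setequal(names(back$stations), names(net$stations))
  s0 <- net$stations[[1]]; s1 <- back$stations[[s0$station_id]]
  expect_equal(s1$data$GPP, s0$data$GPP)
  expect_equal(s1$zone, s0$zone)
  expect_equal(s1$lat, s0$lat)
})
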