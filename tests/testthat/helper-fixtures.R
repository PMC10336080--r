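# Shared fixtures, all generated in code at test time.

tiny_network <- function(n_temperate = 4, n_tropics = 2, years = 1,
                         zone_shift = NULL, seed = 11, ...) {
  params <- generator_params(
    n_stations_per_zone = c(temperate = n_temperate, tropics = n_tropics),
    years = years, zone_shift = zone_shift, seed = seed, ...)
  gen_network(params)
}

zone_split <- function(net, target_zone = "tropics") {
  zones <- vapply(net$stations, function(s) s$zone, character(1))
  make_meta_split(net, names(net$stations)[zones == target_zone])
}

# controlled driver table for gen_station_series(climate = ...)
flat_climate <- function(n = 40, P = 2, TA = 15, SW = 200, LAI = 3) {
  dates <- seq(as.Date("2001-01-01"), by = "day", length.out = n)
  data.frame(date = dates, P = P, TA = TA, TD = TA - 5,
             VPD = 0.5, SW_IN = SW, LAI = LAI)
}

# a tiny learner whose prediction is a known constant: all weights zero,
# output bias set
constant_learner <- function(value, arch = "mlp", input_dim = 2) {
  cfg <- learner_config(arch, input_dim = input_dim, hidden_size = 3,
                        window = 4, seed = 1)
  l <- build_learner(cfg)
  theta <- rep(0, n_params(l))
  theta[length(theta)] <- value         # b3 is last in the flat layout
  set_params(l, theta)
}

# central finite-difference gradient oracle
fd_grad <- function(learner, x, y, eps = 1e-6) {
  th <- get_params(learner)
  vapply(seq_along(th), function(i) {
    tp <- th; tp[i] <- tp[i] + eps
    tm <- th; tm[i] <- tm[i] - eps
    (loss_and_grad(set_params(learner, tp), x, y)$loss -
       loss_and_grad(set_params(learner, tm), x, y)$loss) / (2 * eps)
  }, numeric(1))
}
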