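# random but chemically plausible water samples for property tests
random_water_samples <- function(n, seed = 101) {
  withr::with_seed(seed, tibble::tibble(
    ph = runif(n, 6, 9.5),
    temperature_c = runif(n, 5, 35),
    tds = runif(n, 100, 40000),
    calcium = runif(n, 50, 1200),
    alkalinity = runif(n, 20, 500)
  ))
}

# random simulator parameter sets spanning gated and ungated regimes
random_sim_params <- function(seed) {
  withr::with_seed(seed, {
    k <- runif(1, 0.8, 2)
    simulation_params(
      mu = runif(1, 0.2, 0.8),
      k_capacity = k,
      x0 = runif(1, 0.02, 0.3) * k,
      ash_fraction = runif(1, 0, 0.2),
      nahco3_molarity = sample(c(0, 0.02, 0.1), 1),
      ph_air = runif(1, 8.2, 9),
      ph_relax_rate = runif(1, 0.5, 4),
      precip_rate_constant = runif(1, 0.1, 2),
      lsi_threshold = runif(1, 0.3, 1.5),
      calcium = runif(1, 300, 1200),
      alkalinity = runif(1, 80, 300),
      noise_cv = 0,
      seed = seed
    )
  })
}

# minimal three-point series used across I/O and summary tests
toy_series <- function() {
  culture_series(
    tibble::tibble(
      day = c(0, 12, 14),
      od750 = c(0.4, 5.0, 5.1),
      cell_density = c(1.9e7, 2.6e8, 2.7e8),
      dry_weight = c(0.11, 1.54, 1.60),
      afdw = c(0.10, 1.47, 1.52),
      ph = c(7.3, 7.3, 8.6),
      precipitate = c(0, 0, 0.59)
    ),
    label = "toy", nahco3_molarity = 0.02, volume = 1,
    footprint_area = 0.01, area_ratio = 1.2,
    events = tibble::tibble(day = 12, kind = "co2_shutoff")
  )
}

write_toy_csv <- function(path) {
  readr::write_csv(tibble::tibble(
    day = c(0, 12, 14),
    od750 = c(0.04, 0.5, 0.051),
    dilution_factor = c(10, 10, 100),
    cell_density = c(1.9e7, 2.6e8, 2.7e8),
    dry_weight_g_L = c(0.11, 1.54, 1.60),
    afdw_g_L = c(0.10, 1.47, 1.52),
    ph = c(7.3, 7.3, 8.6),
    precipitate_g_L = c(0, 0, 0.59)
  ), path)
  path
}
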