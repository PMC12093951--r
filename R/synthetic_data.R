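# scalar LSI via the same kernel compute_lsi() uses
lsi_value <- function(ph, temperature_c, tds, calcium, alkalinity) {
  lsi_terms(ph, temperature_c, tds, calcium, alkalinity)$lsi
}

#' Parameters for the batch-culture simulator
#'
#' Defines the "reference" default scenario: a 1 L column culture of a
#' marine microalga sparged with CO2-enriched gas, supplemented with
#' 0.02 M NaHCO3, with the sparge switched to ambient air on day 12 and
#' carbonate precipitation setting in as the pH (and hence the LSI) rises.
#' All defaults can be overridden.
#'
#' @param mu Intrinsic logistic growth rate, day^-1.
#' @param k_capacity Carrying capacity, g AFDW/L.
#' @param x0 Initial biomass, g AFDW/L; must be below `k_capacity`.
#' @param ash_fraction Fraction of dry weight that is cellular ash;
#'   `dry_weight = afdw / (1 - ash_fraction)`.
#' @param nahco3_molarity NaHCO3 present from inoculation, mol/L. Drives
#'   the growth dose response and the initial alkalinity
#'   (+ molarity x 50,000 mg/L as CaCO3, i.e. one equivalent per mole).
#' @param dose_optimum,dose_peak,dose_inhibition,dose_hill Dose-response
#'   shape: molarity of peak enhancement, peak fold-enhancement (> 1),
#'   molarity scale of osmotic inhibition, and inhibition steepness.
#' @param ph_sparged Culture pH while CO2 sparging is active.
#' @param ph_air Asymptotic pH under ambient air.
#' @param ph_relax_rate Exponential relaxation rate of pH toward `ph_air`
#'   after CO2 shutoff, day^-1.
#' @param precip_rate_constant g CaCO3 L^-1 day^-1 per unit of LSI excess
#'   over the threshold.
#' @param lsi_threshold Precipitation begins when LSI exceeds this
#'   (default 1, the scale-forming boundary).
#' @param calcium,magnesium,alkalinity,conductivity,temperature_c Initial
#'   chemistry: Ca and total alkalinity in mg/L as CaCO3, Mg in mg/L
#'   (passive tracer), conductivity in µS/cm, temperature in degrees C.
#' @param afdw_per_od g AFDW per OD750 unit (observation scaling).
#' @param cells_per_g cells per g AFDW (observation scaling).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal measurement noise applied at observation sampling.
#' @param seed Integer seed for the observation-noise generator.
#'
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(mu = 0.45,
                              k_capacity = 1.5,
                              x0 = 0.1,
                              ash_fraction = 0.05,
                              nahco3_molarity = 0.02,
                              dose_optimum = 0.02,
                              dose_peak = 1.6,
                              dose_inhibition = 0.5,
                              dose_hill = 4,
                              ph_sparged = 7.3,
                              ph_air = 8.6,
                              ph_relax_rate = 2.0,
                              precip_rate_constant = 0.5,
                              lsi_threshold = 1.0,
                              calcium = 600,
                              magnesium = 1290,
                              alkalinity = 150,
                              conductivity = 53000,
                              temperature_c = 25,
                              afdw_per_od = 0.3,
                              cells_per_g = 1.9e11,
                              noise_cv = 0,
                              seed = 1L) {
  p <- list(
    mu = mu, k_capacity = k_capacity, x0 = x0, ash_fraction = ash_fraction,
    nahco3_molarity = nahco3_molarity, dose_optimum = dose_optimum,
    dose_peak = dose_peak, dose_inhibition = dose_inhibition,
    dose_hill = dose_hill, ph_sparged = ph_sparged, ph_air = ph_air,
    ph_relax_rate = ph_relax_rate,
    precip_rate_constant = precip_rate_constant,
    lsi_threshold = lsi_threshold, calcium = calcium, magnesium = magnesium,
    alkalinity = alkalinity, conductivity = conductivity,
    temperature_c = temperature_c, afdw_per_od = afdw_per_od,
    cells_per_g = cells_per_g, noise_cv = noise_cv, seed = as.integer(seed)
  )
  check_number(p$mu, "mu", min = 0, strict_min = TRUE)
  check_number(p$k_capacity, "k_capacity", min = 0, strict_min = TRUE)
  check_number(p$x0, "x0", min = 0, strict_min = TRUE)
  if (p$x0 >= p$k_capacity) abort("`x0` must be below `k_capacity`.")
  check_number(p$ash_fraction, "ash_fraction", min = 0, max = 1 - 1e-12)
  check_number(p$noise_cv, "noise_cv", min = 0)
  check_number(p$dose_peak, "dose_peak", min = 1, strict_min = TRUE)
  for (nm in c("calcium", "alkalinity", "conductivity", "ph_relax_rate",
               "precip_rate_constant", "afdw_per_od", "cells_per_g")) {
    check_number(p[[nm]], nm, min = 0, strict_min = TRUE)
  }
  class(p) <- "simulation_params"
  # the dose response must enhance at the optimum and inhibit at the
  # inhibition molarity, or the scenario is internally inconsistent
  if (dose_modifier(p$dose_optimum, p) <= 1) {
    abort("dose response does not enhance growth at `dose_optimum`.")
  }
  if (dose_modifier(p$dose_inhibition, p) >= 1) {
    abort("dose response does not inhibit growth at `dose_inhibition`.")
  }
  p
}

#' NaHCO3 dose-response growth modifier
#'
#' A unimodal smooth multiplier on the intrinsic growth rate: exactly 1 at
#' 0 M (control normalisation), rising to a peak fold-enhancement at the
#' optimum molarity, and falling below 1 around the inhibition molarity
#' (osmotic stress). The shape is a gamma-type stimulation term damped by
#' a Hill-type inhibition term:
#' \deqn{f(m) = \frac{1 + (p - 1)\,(m/m_{opt})\,e^{1 - m/m_{opt}}}{1 + (m/m_{inh})^h}}
#'
#' @param molarity NaHCO3 concentration, mol/L; non-negative, vectorised.
#' @param params A [simulation_params()] object (only the `dose_*` fields
#'   are used).
#' @return Dimensionless growth multiplier.
#' @examples
#' p <- simulation_params()
#' dose_modifier(c(0, 0.02, 0.5), p)
#' @export
dose_modifier <- function(molarity, params = simulation_params()) {
  check_number(molarity, "molarity", min = 0)
  stim <- 1 + (params$dose_peak - 1) * (molarity / params$dose_optimum) *
    exp(1 - molarity / params$dose_optimum)
  stim / (1 + (molarity / params$dose_inhibition)^params$dose_hill)
}

default_events <- function(shutoff_day = 12) {
  tibble::tibble(day = shutoff_day, kind = "co2_shutoff",
                 molarity = NA_real_)
}

#' Simulate a carbonate-precipitating batch culture
#'
#' Discrete-time simulation of the batch-culture phenomenology the
#' analysis pipeline assumes. Per step of length `dt`:
#' \enumerate{
#'   \item biomass grows logistically at rate
#'     `mu * dose_modifier(molarity)`;
#'   \item pH is pinned at `ph_sparged` while the CO2 sparge is active and
#'     relaxes exponentially toward `ph_air` after a `co2_shutoff` event;
#'     a `nahco3_addition` event raises alkalinity stepwise by
#'     `molarity x 50,000 mg/L` as CaCO3;
#'   \item the LSI is recomputed from the current chemistry;
#'   \item while LSI exceeds `lsi_threshold`, CaCO3 precipitates at
#'     `precip_rate_constant x (LSI - threshold)`, capped so calcium and
#'     alkalinity never go non-positive; each gram of CaCO3 draws down
#'     calcium and alkalinity by the same amount in as-CaCO3 units, so
#'     mass balance closes exactly.
#' }
#' Noise-free state is recorded at every step; observations are sampled at
#' integer days with multiplicative lognormal noise (`noise_cv`), one
#' seeded generator per simulation. The same noise factor is applied to
#' dry weight and AFDW (they come from the same pellet), so the
#' `afdw <= dry_weight` invariant survives measurement noise; the
#' precipitate, OD and cell-count draws are independent. Magnesium is a
#' passive tracer (minority co-precipitation is ignored).
#'
#' @param params A [simulation_params()] object.
#' @param events Event table (`day`, `kind`, optional `molarity` for
#'   `nahco3_addition` rows); defaults to a CO2 shutoff on day 12. Use
#'   `events = NULL` for an uninterrupted sparge.
#' @param horizon_days Simulation length, days.
#' @param dt Step size, days; must divide the horizon into whole steps.
#'
#' @return A list of class `culture_sim` with elements `truth` (noise-free
#'   per-step state: day, afdw, dry_weight, ph, calcium, alkalinity,
#'   magnesium, tds, lsi, precipitate), `observations` (a
#'   [culture_series()] at integer days, noisy), `params`, `events`.
#' @examples
#' sim <- simulate_culture(simulation_params(noise_cv = 0.05, seed = 42))
#' tail(sim$truth)
#' @export
simulate_culture <- function(params = simulation_params(),
                             events = default_events(),
                             horizon_days = 14, dt = 0.1) {
  stopifnot(inherits(params, "simulation_params"))
  check_number(dt, "dt", min = 0, strict_min = TRUE)
  check_number(horizon_days, "horizon_days", min = dt)
  if (is.null(events)) {
    events <- tibble::tibble(day = numeric(), kind = character(),
                             molarity = numeric())
  }
  events <- tibble::as_tibble(events)
  if (nrow(events) > 0) {
    if (!"molarity" %in% names(events)) events$molarity <- NA_real_
    events <- validate_events_sim(events, horizon_days)
  }

  n_steps <- round(horizon_days / dt)
  if (abs(n_steps * dt - horizon_days) > 1e-9) {
    abort("`dt` must divide `horizon_days` into whole steps.")
  }
  days <- (0:n_steps) * dt

  shutoff_day <- events$day[events$kind == "co2_shutoff"]
  sparging_from_start <- TRUE

  ph_at <- function(t) {
    if (length(shutoff_day) == 0 || t <= shutoff_day) {
      params$ph_sparged
    } else {
      params$ph_air - (params$ph_air - params$ph_sparged) *
        exp(-params$ph_relax_rate * (t - shutoff_day))
    }
  }

  tds <- tds_from_conductivity(params$conductivity)
  floor_mg <- 1  # mg/L as CaCO3; keeps logarithms defined at the cap

  afdw <- params$x0
  molarity <- params$nahco3_molarity
  ca <- params$calcium
  alk <- params$alkalinity + molarity * 50000
  precip_mg <- 0

  m <- matrix(NA_real_, nrow = n_steps + 1, ncol = 7,
              dimnames = list(NULL, c("afdw", "ph", "calcium", "alkalinity",
                                      "lsi", "precipitate", "molarity")))
  record <- function(i) {
    ph <- ph_at(days[i])
    m[i, ] <<- c(afdw, ph,
                 ca, alk,
                 lsi_value(ph, params$temperature_c, tds, ca, alk),
                 precip_mg / 1000, molarity)
  }
  record(1)

  for (i in seq_len(n_steps)) {
    t_prev <- days[i]
    t_now <- days[i + 1]
    # apply stepwise alkalinity additions crossing into this step
    add <- events[events$kind == "nahco3_addition" &
                    events$day >= t_prev & events$day < t_now, , drop = FALSE]
    if (nrow(add) > 0) {
      added <- sum(ifelse(is.na(add$molarity), 0.02, add$molarity))
      molarity <- molarity + added
      alk <- alk + added * 50000
    }

    rate <- params$mu * dose_modifier(molarity, params)
    afdw <- afdw + rate * afdw * (1 - afdw / params$k_capacity) * dt

    ph <- ph_at(t_now)
    lsi_now <- lsi_value(ph, params$temperature_c, tds, ca, alk)
    if (lsi_now > params$lsi_threshold) {
      delta_mg <- params$precip_rate_constant *
        (lsi_now - params$lsi_threshold) * dt * 1000
      delta_mg <- min(delta_mg, ca - floor_mg, alk - floor_mg)
      delta_mg <- max(delta_mg, 0)
      ca <- ca - delta_mg
      alk <- alk - delta_mg
      precip_mg <- precip_mg + delta_mg
    }
    record(i + 1)
  }

  truth <- tibble::tibble(
    day = days,
    afdw = m[, "afdw"],
    dry_weight = m[, "afdw"] / (1 - params$ash_fraction),
    ph = m[, "ph"],
    calcium = m[, "calcium"],
    alkalinity = m[, "alkalinity"],
    magnesium = params$magnesium,
    conductivity = params$conductivity,
    tds = tds,
    temperature_c = params$temperature_c,
    lsi = m[, "lsi"],
    precipitate = m[, "precipitate"],
    nahco3_molarity = m[, "molarity"]
  )

  obs_idx <- which(abs(days - round(days)) < 1e-9)
  obs_truth <- truth[obs_idx, ]
  n_obs <- nrow(obs_truth)

  noisy <- withr::with_seed(params$seed, {
    cv <- params$noise_cv
    draw <- function(n) {
      if (cv == 0) return(rep(1, n))
      sdlog <- sqrt(log(1 + cv^2))
      rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    pellet <- draw(n_obs)   # shared by dry weight and AFDW
    tibble::tibble(
      day = round(obs_truth$day),
      od750 = obs_truth$afdw / params$afdw_per_od * draw(n_obs),
      cell_density = obs_truth$afdw * params$cells_per_g / 1000 * draw(n_obs),
      dry_weight = obs_truth$dry_weight * pellet,
      afdw = obs_truth$afdw * pellet,
      ph = obs_truth$ph,
      precipitate = obs_truth$precipitate * draw(n_obs)
    )
  })

  observations <- culture_series(
    noisy,
    label = sprintf("synthetic %.3g M NaHCO3", params$nahco3_molarity),
    nahco3_molarity = params$nahco3_molarity,
    co2_percent = 10,
    volume = 1, footprint_area = 0.01, area_ratio = 1.2,
    events = events[c("day", "kind")]
  )

  structure(
    list(truth = truth, observations = observations, params = params,
         events = events),
    class = "culture_sim"
  )
}

validate_events_sim <- function(events, horizon_days) {
  events <- tibble::as_tibble(events)
  out <- validate_events(events[c("day", "kind")])
  out$molarity <- events$molarity[order(events$day)]
  if (any(out$day < 0 | out$day > horizon_days)) {
    abort("events must lie within [0, horizon_days].")
  }
  out
}

#' @export
print.culture_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic batch culture: %d steps over %g days, %d observation days\n",
    nrow(x$truth) - 1, max(x$truth$day), nrow(x$observations)
  ))
  cat(sprintf("  final AFDW %.3f g/L, cumulative precipitate %.3f g/L\n",
              x$truth$afdw[nrow(x$truth)],
              x$truth$precipitate[nrow(x$truth)]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.culture_sim <- function(x, ...) x$truth

#' @exportS3Method generics::glance
glance.culture_sim <- function(x, ...) {
  last <- nrow(x$truth)
  tibble::tibble(
    horizon_days = x$truth$day[last],
    final_afdw = x$truth$afdw[last],
    final_precipitate = x$truth$precipitate[last],
    ca_drawdown = (x$truth$calcium[1] - x$truth$calcium[last]) / 1000,
    max_lsi = max(x$truth$lsi),
    noise_cv = x$params$noise_cv,
    seed = x$params$seed
  )
}

#' Plot a simulated culture
#'
#' Noise-free state trajectories (lines) with the noisy integer-day
#' observations overlaid (points) for biomass, pH, LSI and precipitate.
#'
#' @param object A `culture_sim` from [simulate_culture()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.culture_sim <- function(object, ...) {
  keep <- c("afdw", "ph", "lsi", "precipitate")
  truth_long <- tidyr::pivot_longer(object$truth[c("day", keep)], -"day",
                                    names_to = "variable",
                                    values_to = "value")
  obs <- tidy(object$observations)
  obs$lsi <- NA_real_
  obs_long <- tidyr::pivot_longer(
    obs[c("day", intersect(keep, names(obs)))], -"day",
    names_to = "variable", values_to = "value"
  )
  ggplot2::ggplot(truth_long, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = obs_long, colour = "steelblue", size = 1) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "day", y = NULL) +
    ggplot2::theme_minimal()
}

#' Check pipeline recovery of simulator ground truth
#'
#' Runs the analysis pipeline on a simulation's (noisy) observations and
#' compares its estimates against the generator's noise-free truth at the
#' same days: final AFDW, overall AFDW productivity, cumulative
#' precipitate yield (% of AFDW) and extra-CO2 percentage at the final
#' sampling day.
#'
#' @param sim A `culture_sim` from [simulate_culture()].
#' @param constants A [stoich_constants()] object.
#' @return A tibble with columns `quantity`, `truth`, `estimate`,
#'   `abs_error`, `rel_error` (signed, relative to truth).
#' @export
parameter_recovery_check <- function(sim, constants = stoich_constants()) {
  stopifnot(inherits(sim, "culture_sim"))
  obs <- sim$observations
  obs_days <- tidy(obs)$day
  truth <- sim$truth[abs(sim$truth$day - round(sim$truth$day)) < 1e-9 &
                       round(sim$truth$day) %in% obs_days, ]

  d0 <- min(obs_days); dend <- max(obs_days)
  est_final_afdw <- tidy(obs)$afdw[which.max(obs_days)]
  tru_final_afdw <- truth$afdw[which.max(truth$day)]
  est_prod <- average_productivity(obs, d0, dend, "afdw")
  tru_prod <- (tru_final_afdw - truth$afdw[which.min(truth$day)]) / (dend - d0)

  est_precip <- tidy(obs)$precipitate[which.max(obs_days)]
  tru_precip <- truth$precipitate[which.max(truth$day)]
  est_yield <- precipitate_yield_percent(est_precip, est_final_afdw)
  tru_yield <- precipitate_yield_percent(tru_precip, tru_final_afdw)
  est_extra <- extra_co2_percent(est_precip, est_final_afdw, constants)
  tru_extra <- extra_co2_percent(tru_precip, tru_final_afdw, constants)

  out <- tibble::tibble(
    quantity = c("final_afdw", "afdw_productivity",
                 "precipitate_yield_percent", "extra_co2_percent"),
    truth = c(tru_final_afdw, tru_prod, tru_yield, tru_extra),
    estimate = c(est_final_afdw, est_prod, est_yield, est_extra)
  )
  out$abs_error <- out$estimate - out$truth
  out$rel_error <- ifelse(out$truth != 0, out$abs_error / out$truth, NA_real_)
  out
}
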