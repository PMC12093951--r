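#' Stoichiometric constants for CO2 equivalence
#'
#' The accounting uses two fixed factors: 183 g of CO2 fixes 100 g of algal
#' biomass (ash-free dry weight), and 100 g CaCO3 (1 mol) stores 44 g CO2
#' (1 mol). Integer molar masses (44, 100) are the defaults so that the
#' reference-figure arithmetic reproduces exactly; exact masses (44.01,
#' 100.09) can be supplied if preferred.
#'
#' @param co2_per_biomass g CO2 fixed per g biomass; default 183/100.
#' @param molar_mass_co2 g/mol; default 44.
#' @param molar_mass_caco3 g/mol; default 100.
#' @param co2_per_caco3 g CO2 per g CaCO3; defaults to
#'   `molar_mass_co2 / molar_mass_caco3`.
#'
#' @return A list of class `stoich_constants`.
#' @examples
#' stoich_constants()
#' @export
stoich_constants <- function(co2_per_biomass = 183 / 100,
                             molar_mass_co2 = 44,
                             molar_mass_caco3 = 100,
                             co2_per_caco3 = molar_mass_co2 / molar_mass_caco3) {
  for (nm in c("co2_per_biomass", "molar_mass_co2", "molar_mass_caco3",
               "co2_per_caco3")) {
    check_number(get(nm), nm, min = 0, strict_min = TRUE)
  }
  structure(
    list(
      co2_per_biomass = co2_per_biomass,
      co2_per_caco3 = co2_per_caco3,
      molar_mass_co2 = molar_mass_co2,
      molar_mass_caco3 = molar_mass_caco3
    ),
    class = "stoich_constants"
  )
}

#' @export
print.stoich_constants <- function(x, ...) {
  cat("CO2-equivalence constants\n")
  cat(sprintf("  g CO2 per g biomass (AFDW): %.4g\n", x$co2_per_biomass))
  cat(sprintf("  g CO2 per g CaCO3:          %.4g\n", x$co2_per_caco3))
  invisible(x)
}

#' CO2 equivalent of algal biomass
#'
#' @param afdw_mass Biomass as ash-free dry weight, g (or g/L for
#'   volumetric accounting). Non-negative; vectorised.
#' @param constants A [stoich_constants()] object.
#' @return Equivalent CO2 mass, same units basis as `afdw_mass`.
#' @examples
#' co2_of_biomass(100) # 183
#' @export
co2_of_biomass <- function(afdw_mass, constants = stoich_constants()) {
  check_number(afdw_mass, "afdw_mass", min = 0)
  afdw_mass * constants$co2_per_biomass
}

#' CO2 equivalent of CaCO3 precipitate
#'
#' @param caco3_mass CaCO3 mass, g (or g/L). Non-negative; vectorised.
#' @inheritParams co2_of_biomass
#' @return Equivalent CO2 mass.
#' @examples
#' co2_of_caco3(100) # 44
#' @export
co2_of_caco3 <- function(caco3_mass, constants = stoich_constants()) {
  check_number(caco3_mass, "caco3_mass", min = 0)
  caco3_mass * constants$co2_per_caco3
}

#' CaCO3 formed per mass of CO2 stored
#'
#' Inverse of [co2_of_caco3()]: the CaCO3 that would sequester a given
#' CO2 mass at the 1:1 molar ratio.
#'
#' @param co2_mass CO2 mass, g. Non-negative; vectorised.
#' @inheritParams co2_of_biomass
#' @return CaCO3 mass, g.
#' @examples
#' caco3_from_co2(183) # ~416
#' @export
caco3_from_co2 <- function(co2_mass, constants = stoich_constants()) {
  check_number(co2_mass, "co2_mass", min = 0)
  co2_mass / constants$co2_per_caco3
}

#' Extra CO2 consumption from carbonate precipitation
#'
#' The CO2 equivalent stored in precipitated CaCO3, expressed as a
#' percentage of the CO2 equivalent fixed in algal biomass over the same
#' window. Invariant to common rescaling of the two masses, so
#' concentrations (g/L) work as well as absolute masses.
#'
#' @param precipitate Precipitate recovered, g/L (or g). Non-negative.
#' @param afdw Biomass AFDW, g/L (or g). Strictly positive.
#' @inheritParams co2_of_biomass
#' @return Percentage (numeric, unrounded).
#' @examples
#' extra_co2_percent(0.59, 1.52) # ~9.3
#' @export
extra_co2_percent <- function(precipitate, afdw,
                              constants = stoich_constants()) {
  check_number(precipitate, "precipitate", min = 0)
  check_number(afdw, "afdw", min = 0, strict_min = TRUE)
  100 * co2_of_caco3(precipitate, constants) /
    co2_of_biomass(afdw, constants)
}

#' Precipitate yield as a percentage of biomass
#'
#' @inheritParams extra_co2_percent
#' @return Percentage of AFDW (numeric, unrounded).
#' @examples
#' precipitate_yield_percent(0.59, 1.52)
#' @export
precipitate_yield_percent <- function(precipitate, afdw) {
  check_number(precipitate, "precipitate", min = 0)
  check_number(afdw, "afdw", min = 0, strict_min = TRUE)
  100 * precipitate / afdw
}

#' Convert a volumetric rate to an areal rate
#'
#' Converts g L^-1 day^-1 to g m^-2 day^-1 given the culture volume and the
#' facility footprint. The `area_ratio` (default 1.2) inflates the
#' bioreactor footprint to the facility footprint (a 1:1.2
#' bioreactor-to-facility ratio), so the divisor is
#' `footprint_area * area_ratio`.
#'
#' @param volumetric_rate Rate in g L^-1 day^-1; may be negative
#'   (biomass loss).
#' @param volume Culture volume, L; > 0.
#' @param footprint_area Bioreactor footprint, m^2; > 0.
#' @param area_ratio Facility-to-bioreactor footprint ratio; > 0.
#' @return Rate in g m^-2 day^-1.
#' @examples
#' areal_rate(0.12, volume = 500, footprint_area = 1) # 50
#' @export
areal_rate <- function(volumetric_rate, volume, footprint_area,
                       area_ratio = 1.2) {
  check_number(volumetric_rate, "volumetric_rate")
  check_number(volume, "volume", min = 0, strict_min = TRUE)
  check_number(footprint_area, "footprint_area", min = 0, strict_min = TRUE)
  check_number(area_ratio, "area_ratio", min = 0, strict_min = TRUE)
  volumetric_rate * volume / (footprint_area * area_ratio)
}

#' Build a carbon ledger from productivities
#'
#' Converts biomass and precipitate volumetric productivities into areal
#' CO2 capture rates and assembles the full per-window ledger: the CO2
#' equivalent of each component, their sum, and the extra-CO2 percentage.
#'
#' @param biomass_productivity AFDW productivity, g L^-1 day^-1 (>= 0).
#' @param precipitate_productivity CaCO3 productivity, g L^-1 day^-1
#'   (>= 0). Vectorised with `biomass_productivity` (windows as rows).
#' @param volume,footprint_area,area_ratio Geometry; see [areal_rate()].
#' @param constants A [stoich_constants()] object.
#' @param window_start,window_end Optional window bounds (days), carried
#'   into the ledger for reporting.
#'
#' @return A tibble of class `carbon_ledger` with one row per window:
#'   `window_start`, `window_end`, `biomass_co2`, `precipitate_co2`,
#'   `total_co2` (all g CO2 L^-1 day^-1), `extra_co2_percent`,
#'   `biomass_co2_areal`, `precipitate_co2_areal`,
#'   `areal_capture_rate` (g CO2 m^-2 day^-1).
#' @examples
#' capture_rate(0.10, 0.05, volume = 1, footprint_area = 1, area_ratio = 1)
#' @export
capture_rate <- function(biomass_productivity, precipitate_productivity,
                         volume, footprint_area, area_ratio = 1.2,
                         constants = stoich_constants(),
                         window_start = NA_real_, window_end = NA_real_) {
  check_number(biomass_productivity, "biomass_productivity", min = 0)
  check_number(precipitate_productivity, "precipitate_productivity", min = 0)

  biomass_co2 <- co2_of_biomass(biomass_productivity, constants)
  precipitate_co2 <- co2_of_caco3(precipitate_productivity, constants)
  out <- tibble::tibble(
    window_start = window_start,
    window_end = window_end,
    biomass_co2 = biomass_co2,
    precipitate_co2 = precipitate_co2,
    total_co2 = biomass_co2 + precipitate_co2,
    extra_co2_percent = ifelse(biomass_co2 > 0,
                               100 * precipitate_co2 / biomass_co2,
                               NA_real_),
    biomass_co2_areal = areal_rate(biomass_co2, volume, footprint_area,
                                   area_ratio),
    precipitate_co2_areal = areal_rate(precipitate_co2, volume,
                                       footprint_area, area_ratio)
  )
  out$areal_capture_rate <- out$biomass_co2_areal + out$precipitate_co2_areal
  class(out) <- c("carbon_ledger", class(out))
  out
}

#' @exportS3Method generics::glance
glance.carbon_ledger <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x),
    max_capture_rate = max(x$areal_capture_rate, na.rm = TRUE),
    max_extra_co2_percent = if (all(is.na(x$extra_co2_percent))) NA_real_
      else max(x$extra_co2_percent, na.rm = TRUE),
    total_co2 = sum(x$total_co2, na.rm = TRUE)
  )
}

#' Plot a carbon ledger
#'
#' Stacked bars of the areal CO2 capture rate per window, split into the
#' biomass and precipitate components.
#'
#' @param object A `carbon_ledger` tibble from [capture_rate()] or
#'   [account_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.carbon_ledger <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$window <- factor(
    ifelse(is.na(df$window_end), as.character(seq_len(nrow(df))),
           sprintf("d%g-%g", df$window_start, df$window_end)),
    levels = unique(ifelse(is.na(df$window_end),
                           as.character(seq_len(nrow(df))),
                           sprintf("d%g-%g", df$window_start, df$window_end)))
  )
  long <- tidyr::pivot_longer(
    df, c("biomass_co2_areal", "precipitate_co2_areal"),
    names_to = "component", values_to = "rate"
  )
  long$component <- ifelse(long$component == "biomass_co2_areal",
                           "biomass", "precipitate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window, y = .data$rate,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "window", y = expression(g ~ CO[2] ~ m^-2 ~ day^-1),
                  fill = NULL) +
    ggplot2::theme_minimal()
}
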