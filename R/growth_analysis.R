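#' Construct a culture time series
#'
#' Bundles ordered batch-culture observations with treatment metadata and
#' culture events (CO2 shutoff, NaHCO3 or nutrient additions) into a
#' `culture_series`: a tibble of observations carrying the metadata as
#' attributes, so it pipes through dplyr verbs like any tibble.
#'
#' @param observations A data frame with columns `day` and any of `od750`,
#'   `cell_density` (cells/mL), `dry_weight` (g/L), `afdw` (g/L), `ph`,
#'   `precipitate` (g/L, cumulative recovered at each sampling point).
#'   Days must be strictly increasing; masses non-negative; `afdw <=
#'   dry_weight` wherever both are present.
#' @param label Treatment name.
#' @param nahco3_molarity NaHCO3 supplementation, mol/L.
#' @param co2_percent CO2 fraction of the sparge gas, percent v/v.
#' @param volume Culture volume, L.
#' @param footprint_area Bioreactor footprint, m^2.
#' @param area_ratio Facility-to-bioreactor footprint ratio.
#' @param events A data frame with columns `day` and `kind` (one of
#'   `"co2_shutoff"`, `"nahco3_addition"`, `"nutrient_addition"`), or NULL.
#'   At most one `co2_shutoff` event is allowed.
#'
#' @return A `culture_series` tibble.
#' @export
culture_series <- function(observations, label = "culture",
                           nahco3_molarity = 0, co2_percent = 10,
                           volume = 1, footprint_area = 0.01,
                           area_ratio = 1.2, events = NULL) {
  obs <- tibble::as_tibble(observations)
  if (!"day" %in% names(obs)) abort("`observations` must have a `day` column.")
  if (nrow(obs) == 0) abort("`observations` must contain at least one row.")
  check_number(obs$day, "day", min = 0)
  if (is.unsorted(obs$day, strictly = TRUE)) {
    abort("observation days must be strictly increasing (no duplicates).")
  }
  for (col in c("od750", "cell_density", "dry_weight", "afdw", "precipitate")) {
    if (col %in% names(obs)) {
      check_number(obs[[col]], col, min = 0, allow_na = TRUE)
    }
  }
  if (all(c("afdw", "dry_weight") %in% names(obs))) {
    both <- !is.na(obs$afdw) & !is.na(obs$dry_weight)
    bad <- both & obs$afdw > obs$dry_weight
    if (any(bad)) {
      abort(sprintf("row %d: afdw (%g) exceeds dry_weight (%g).",
                    which(bad)[1], obs$afdw[which(bad)[1]],
                    obs$dry_weight[which(bad)[1]]))
    }
  }
  events <- validate_events(events)
  check_number(volume, "volume", min = 0, strict_min = TRUE)
  check_number(footprint_area, "footprint_area", min = 0, strict_min = TRUE)
  check_number(area_ratio, "area_ratio", min = 0, strict_min = TRUE)

  structure(
    obs,
    class = c("culture_series", class(obs)),
    meta = list(
      label = label, nahco3_molarity = nahco3_molarity,
      co2_percent = co2_percent, volume = volume,
      footprint_area = footprint_area, area_ratio = area_ratio
    ),
    events = events
  )
}

validate_events <- function(events) {
  if (is.null(events) || (is.data.frame(events) && nrow(events) == 0)) {
    return(tibble::tibble(day = numeric(), kind = character()))
  }
  events <- tibble::as_tibble(events)
  if (!all(c("day", "kind") %in% names(events))) {
    abort("`events` needs columns `day` and `kind`.")
  }
  allowed <- c("co2_shutoff", "nahco3_addition", "nutrient_addition")
  if (!all(events$kind %in% allowed)) {
    abort(paste0("event kind must be one of: ",
                 paste(allowed, collapse = ", "), "."))
  }
  if (sum(events$kind == "co2_shutoff") > 1) {
    abort("at most one co2_shutoff event is allowed.")
  }
  dplyr::arrange(events[c("day", "kind")], .data$day)
}

#' @rdname culture_series
#' @param x,series A `culture_series` object.
#' @export
series_meta <- function(series) attr(series, "meta")

#' @rdname culture_series
#' @export
series_events <- function(series) attr(series, "events")

#' @exportS3Method generics::tidy
tidy.culture_series <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "meta") <- NULL
  attr(out, "events") <- NULL
  out
}

#' @exportS3Method generics::glance
glance.culture_series <- function(x, ...) {
  meta <- series_meta(x)
  last <- function(v) if (is.null(v) || all(is.na(v))) NA_real_ else
    v[max(which(!is.na(v)))]
  tibble::tibble(
    label = meta$label,
    nahco3_molarity = meta$nahco3_molarity,
    co2_percent = meta$co2_percent,
    n_obs = nrow(x),
    first_day = min(x$day),
    last_day = max(x$day),
    final_afdw = last(x[["afdw"]]),
    final_precipitate = last(x[["precipitate"]])
  )
}

#' Plot a culture series
#'
#' Facetted trajectories of biomass (dry weight and AFDW), pH and
#' cumulative precipitate over time, with dashed vertical lines at culture
#' events.
#'
#' @param object A `culture_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.culture_series <- function(object, ...) {
  df <- tidy(object)
  keep <- intersect(c("dry_weight", "afdw", "ph", "precipitate"), names(df))
  long <- tidyr::pivot_longer(df[c("day", keep)], -"day",
                              names_to = "variable", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "day", y = NULL,
                  title = series_meta(object)$label) +
    ggplot2::theme_minimal()
  ev <- series_events(object)
  if (nrow(ev) > 0) {
    p <- p + ggplot2::geom_vline(data = ev,
                                 ggplot2::aes(xintercept = .data$day),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

# metric value at an arbitrary day: exact at observed days, linear
# interpolation between neighbours, never extrapolation
metric_at_day <- function(series, day, metric) {
  obs <- tibble::as_tibble(series)
  if (!metric %in% names(obs)) {
    abort(sprintf("series has no `%s` column.", metric))
  }
  keep <- !is.na(obs[[metric]])
  x <- obs$day[keep]
  y <- obs[[metric]][keep]
  if (length(x) == 0) abort(sprintf("`%s` has no non-missing values.", metric))
  if (day < min(x) || day > max(x)) {
    abort(sprintf(
      "day %g is outside the observed range [%g, %g] for `%s`; extrapolation is not performed.",
      day, min(x), max(x), metric
    ))
  }
  if (length(x) == 1) return(y)
  approx(x, y, xout = day, method = "linear", ties = "ordered")$y
}

#' Average productivity over a window
#'
#' The net rate of change of a biomass metric between two days:
#' `(metric(end) - metric(start)) / (end - start)`, in g L^-1 day^-1.
#' Endpoints falling between sampling days are linearly interpolated;
#' windows outside the observed range are an error. Negative values
#' (biomass loss) are reported, not clipped.
#'
#' @param series A `culture_series` (or data frame with `day` and the
#'   metric column).
#' @param start_day,end_day Window bounds in days; `end_day > start_day`.
#' @param metric `"afdw"` (default) or `"dry_weight"`; any numeric column
#'   works (e.g. `"precipitate"` for a precipitation rate).
#' @return Productivity in g L^-1 day^-1 (scalar).
#' @examples
#' obs <- tibble::tibble(day = c(0, 12), afdw = c(0.73, 1.47))
#' average_productivity(culture_series(obs), 0, 12)
#' @export
average_productivity <- function(series, start_day, end_day,
                                 metric = c("afdw", "dry_weight")) {
  metric <- if (is.character(metric) && length(metric) > 1)
    metric[1] else as.character(metric)
  check_number(start_day, "start_day")
  check_number(end_day, "end_day")
  if (end_day <= start_day) abort("`end_day` must exceed `start_day`.")
  (metric_at_day(series, end_day, metric) -
     metric_at_day(series, start_day, metric)) / (end_day - start_day)
}

#' Ash content of biomass
#'
#' Ash is the mineral residue after combustion: dry weight minus ash-free
#' dry weight. Reported both as a concentration and as a percentage of dry
#' weight. Rising ash content in a precipitating culture tracks entrained
#' CaCO3.
#'
#' @param dry_weight Dry weight, g/L; vectorised.
#' @param afdw Ash-free dry weight, g/L; must not exceed `dry_weight`.
#' @return A tibble with columns `ash_g_L` and `ash_percent` (% of DW).
#' @examples
#' ash_content(1.54, 1.47)
#' @export
ash_content <- function(dry_weight, afdw) {
  check_number(dry_weight, "dry_weight", min = 0, allow_na = TRUE)
  check_number(afdw, "afdw", min = 0, allow_na = TRUE)
  both <- !is.na(dry_weight) & !is.na(afdw)
  if (any(both & afdw > dry_weight)) {
    abort("`afdw` exceeds `dry_weight`; ash content would be negative.")
  }
  ash <- dry_weight - afdw
  tibble::tibble(
    ash_g_L = ash,
    ash_percent = ifelse(!is.na(dry_weight) & dry_weight > 0,
                         100 * ash / dry_weight, NA_real_)
  )
}

#' Fold change between a treatment and a control
#'
#' @param treatment_value Value under treatment.
#' @param control_value Value under control; strictly positive.
#' @return `treatment_value / control_value`.
#' @examples
#' fold_change(1.23, 0.78) # ~1.6
#' @export
fold_change <- function(treatment_value, control_value) {
  check_number(treatment_value, "treatment_value")
  check_number(control_value, "control_value", min = 0, strict_min = TRUE)
  treatment_value / control_value
}

#' Per-sampling-point summary of a culture series
#'
#' One row per observation, combining: ash content, cumulative precipitate
#' yield (% of AFDW), extra-CO2 percentage, windowed biomass/precipitate
#' productivities, the LSI when a water-chemistry panel is supplied, and
#' event annotations (events on the day, post-CO2-shutoff flag).
#'
#' @param series A `culture_series`.
#' @param chemistry Optional water-chemistry tibble (as from
#'   [read_water_csv()]) with a `day` column; the LSI is computed with
#'   [compute_lsi()] and joined on day.
#' @param constants A [stoich_constants()] object.
#' @param window_mode `"interval"` (productivity since the previous
#'   sampling point, the default) or `"cumulative"` (since the first).
#' @return A tibble with one row per observation. Productivity columns are
#'   NA on the first row (no preceding window).
#' @export
summarize_series <- function(series, chemistry = NULL,
                             constants = stoich_constants(),
                             window_mode = c("interval", "cumulative")) {
  window_mode <- match.arg(window_mode)
  obs <- tibble::as_tibble(series)
  if (nrow(obs) == 0) abort("`series` has no observations.")
  events <- if (inherits(series, "culture_series")) series_events(series)
    else tibble::tibble(day = numeric(), kind = character())

  get_col <- function(nm) if (nm %in% names(obs)) obs[[nm]] else
    rep(NA_real_, nrow(obs))
  dw <- get_col("dry_weight"); af <- get_col("afdw")
  pr <- get_col("precipitate")

  ash <- ash_content(dw, af)
  # same ratio as precipitate_yield_percent(), tolerant of NA rows
  yield <- ifelse(!is.na(pr) & !is.na(af) & af > 0, 100 * pr / af, NA_real_)
  extra <- ifelse(!is.na(yield),
                  yield * constants$co2_per_caco3 / constants$co2_per_biomass,
                  NA_real_)

  window_rate <- function(v) {
    if (all(is.na(v))) return(rep(NA_real_, nrow(obs)))
    ref_day <- if (window_mode == "interval") dplyr::lag(obs$day)
      else rep(obs$day[1], nrow(obs))
    ref_val <- if (window_mode == "interval") dplyr::lag(v)
      else rep(v[1], nrow(obs))
    out <- (v - ref_val) / (obs$day - ref_day)
    out[obs$day == ref_day | is.na(ref_day)] <- NA_real_
    out
  }

  shutoff_day <- events$day[events$kind == "co2_shutoff"]
  events_on_day <- purrr::map_chr(obs$day, function(d) {
    k <- events$kind[events$day == d]
    if (length(k) == 0) NA_character_ else paste(k, collapse = ";")
  })

  out <- dplyr::mutate(
    obs,
    ash_g_L = ash$ash_g_L,
    ash_percent = ash$ash_percent,
    precipitate_yield_percent = yield,
    extra_co2_percent = extra,
    afdw_productivity = window_rate(af),
    dry_weight_productivity = window_rate(dw),
    precipitate_productivity = window_rate(pr),
    events = events_on_day,
    post_shutoff = if (length(shutoff_day) == 1) obs$day > shutoff_day
      else FALSE
  )

  if (!is.null(chemistry)) {
    lsi_tab <- compute_lsi(chemistry)
    out <- dplyr::left_join(
      out, lsi_tab[c("day", "lsi", "phs", "classification")], by = "day"
    )
  }
  tibble::as_tibble(out)
}

#' Per-window carbon ledger for a culture series
#'
#' Differences cumulative AFDW and precipitate between sampling points (or
#' against the first point, in cumulative mode), converts each window's
#' productivities to CO2-equivalent areal capture rates with the series
#' geometry, and returns one ledger row per window. Windows with net
#' biomass or precipitate loss contribute zero for that component (capture
#' cannot be negative); the raw signed productivities are retained in the
#' `afdw_productivity` / `precipitate_productivity` columns.
#'
#' @inheritParams summarize_series
#' @return A `carbon_ledger` tibble (see [capture_rate()]) with the raw
#'   signed productivities appended.
#' @export
account_series <- function(series, constants = stoich_constants(),
                           window_mode = c("interval", "cumulative")) {
  window_mode <- match.arg(window_mode)
  meta <- if (inherits(series, "culture_series")) series_meta(series)
    else list(volume = 1, footprint_area = 0.01, area_ratio = 1.2)
  rep_tab <- summarize_series(series, constants = constants,
                              window_mode = window_mode)
  rows <- which(!is.na(rep_tab$afdw_productivity))
  if (length(rows) == 0) {
    abort("series has fewer than two sampling points with AFDW; no window to account.")
  }
  start_day <- if (window_mode == "interval") rep_tab$day[rows - 1]
    else rep(rep_tab$day[1], length(rows))
  af_rate <- rep_tab$afdw_productivity[rows]
  pr_rate <- rep_tab$precipitate_productivity[rows]
  pr_rate[is.na(pr_rate)] <- 0
  ledger <- capture_rate(
    biomass_productivity = pmax(af_rate, 0),
    precipitate_productivity = pmax(pr_rate, 0),
    volume = meta$volume, footprint_area = meta$footprint_area,
    area_ratio = meta$area_ratio, constants = constants,
    window_start = start_day, window_end = rep_tab$day[rows]
  )
  ledger$afdw_productivity <- af_rate
  ledger$precipitate_productivity <- pr_rate
  ledger
}
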