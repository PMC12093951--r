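#' Estimate total dissolved solids from conductivity
#'
#' Applies the seawater conversion factor 0.67 to convert specific
#' conductivity to total dissolved solids (TDS).
#'
#' @param conductivity Specific conductivity in µS/cm. Vectorised;
#'   values must be non-negative.
#'
#' @return TDS in mg/L, same length as `conductivity`.
#' @examples
#' tds_from_conductivity(53000) # typical full-strength seawater
#' @export
tds_from_conductivity <- function(conductivity) {
  check_number(conductivity, "conductivity", min = 0)
  conductivity * 0.67
}

#' Convert elemental calcium to calcium-as-CaCO3
#'
#' The Langelier index convention expresses calcium hardness in mg/L as
#' CaCO3 equivalents. Laboratories often report elemental Ca instead; this
#' helper rescales by the molar-mass ratio 100.09/40.08.
#'
#' @param calcium_mg_L Elemental calcium, mg/L.
#' @return Calcium hardness, mg/L as CaCO3.
#' @export
ca_elemental_to_caco3 <- function(calcium_mg_L) {
  check_number(calcium_mg_L, "calcium_mg_L", min = 0)
  calcium_mg_L * 100.09 / 40.08
}

#' Classify a Langelier Saturation Index value
#'
#' Water with LSI below zero is undersaturated with respect to CaCO3 and
#' corrosive; water with LSI above one is strongly supersaturated and
#' scale-forming. Values in \[0, 1\] are labelled `indeterminate`: the index
#' convention used here attaches no interpretation to that band, and
#' inventing one (e.g. "stable") would overstate it.
#'
#' @param lsi Numeric vector of LSI values; must be finite.
#' @return Character vector with values `"corrosive"`, `"indeterminate"`,
#'   or `"scale_forming"`.
#' @examples
#' classify_lsi(c(-0.5, 0.3, 1.5))
#' @export
classify_lsi <- function(lsi) {
  check_number(lsi, "lsi")
  dplyr::case_when(
    lsi < 0 ~ "corrosive",
    lsi > 1 ~ "scale_forming",
    .default = "indeterminate"
  )
}

#' Compute the Langelier Saturation Index and its terms
#'
#' For each water sample, computes the four LSI terms
#' \deqn{A = (\log_{10} TDS - 1)/10}
#' \deqn{B = -13.12 \log_{10}(T + 273) + 34.55}
#' \deqn{C = \log_{10}[Ca^{2+}] - 0.4}
#' \deqn{D = \log_{10}[alkalinity]}
#' the saturation pH \eqn{pH_s = (9.3 + A + B) - (C + D)}, the index
#' \eqn{LSI = pH - pH_s}, and the scaling classification.
#'
#' Calcium and alkalinity are both in mg/L as CaCO3 equivalents (the
#' standard Langelier convention; see [ca_elemental_to_caco3()] if your
#' laboratory reports elemental Ca). The temperature term uses 273 exactly.
#' If `tds` is missing it is derived from `conductivity` via
#' [tds_from_conductivity()]. No rounding is applied; round at the
#' reporting layer.
#'
#' @param data A data frame with columns `ph`, `temperature_c`, `calcium`,
#'   `alkalinity`, and at least one of `tds` and `conductivity`. Extra
#'   columns (e.g. `magnesium`, `day`) are carried through untouched.
#'
#' @return `data` as a tibble with appended columns `tds` (resolved),
#'   `a_term`, `b_term`, `c_term`, `d_term`, `phs`, `lsi`,
#'   `classification`.
#' @examples
#' library(tibble)
#' panel <- tibble(
#'   ph = c(7.29, 8.0), temperature_c = 25,
#'   conductivity = 1000, calcium = 400, alkalinity = 120
#' )
#' compute_lsi(panel)
#' @export
compute_lsi <- function(data) {
  data <- tibble::as_tibble(data)
  needed <- c("ph", "temperature_c", "calcium", "alkalinity")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` lacks required column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (!any(c("tds", "conductivity") %in% names(data))) {
    abort("`data` must contain at least one of `tds` and `conductivity`.")
  }

  tds <- if ("tds" %in% names(data)) data$tds else rep(NA_real_, nrow(data))
  if ("conductivity" %in% names(data)) {
    use_cond <- is.na(tds)
    tds[use_cond] <- tds_from_conductivity(data$conductivity[use_cond])
  }
  if (anyNA(tds)) {
    abort(sprintf(
      "row %d: neither `tds` nor `conductivity` is available.",
      which(is.na(tds))[1]
    ))
  }

  check_number(data$ph, "ph", min = 0, max = 14, strict_min = TRUE)
  check_number(data$temperature_c, "temperature_c", min = -273, strict_min = TRUE)
  check_number(tds, "tds", min = 0, strict_min = TRUE)
  check_number(data$calcium, "calcium", min = 0, strict_min = TRUE)
  check_number(data$alkalinity, "alkalinity", min = 0, strict_min = TRUE)

  terms <- lsi_terms(data$ph, data$temperature_c, tds,
                     data$calcium, data$alkalinity)
  dplyr::mutate(
    data,
    tds = !!tds,
    a_term = terms$a, b_term = terms$b, c_term = terms$c, d_term = terms$d,
    phs = terms$phs, lsi = terms$lsi,
    classification = classify_lsi(terms$lsi)
  )
}

# LSI arithmetic kernel, shared with the simulator; no validation here
lsi_terms <- function(ph, temperature_c, tds, calcium, alkalinity) {
  a <- (log10(tds) - 1) / 10
  b <- -13.12 * log10(temperature_c + 273) + 34.55
  cc <- log10(calcium) - 0.4
  d <- log10(alkalinity)
  phs <- (9.3 + a + b) - (cc + d)
  list(a = a, b = b, c = cc, d = d, phs = phs, lsi = ph - phs)
}

#' Read a water-chemistry panel CSV
#'
#' Reads panels with columns `sample_id`, `day`, `ph`, `temperature_c`,
#' `conductivity_uS_cm`, `tds_mg_L`, `calcium_mg_L_CaCO3`,
#' `magnesium_mg_L`, `alkalinity_mg_L_CaCO3`. One of the conductivity/TDS
#' columns may be absent or NA per row, not both. Lines starting with `#`
#' are comments.
#'
#' @param path Path to the CSV file.
#' @return A tibble with normalised column names (`ph`, `temperature_c`,
#'   `conductivity`, `tds`, `calcium`, `magnesium`, `alkalinity`) ready for
#'   [compute_lsi()].
#' @export
read_water_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  required <- c("ph", "temperature_c", "calcium_mg_L_CaCO3",
                "alkalinity_mg_L_CaCO3")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (!any(c("conductivity_uS_cm", "tds_mg_L") %in% names(raw))) {
    abort(paste0(path, ": need `conductivity_uS_cm` or `tds_mg_L`."))
  }
  out <- tibble::tibble(
    sample_id = if ("sample_id" %in% names(raw)) raw$sample_id else
      as.character(seq_len(nrow(raw))),
    day = if ("day" %in% names(raw)) as.numeric(raw$day) else NA_real_,
    ph = as.numeric(raw$ph),
    temperature_c = as.numeric(raw$temperature_c),
    conductivity = if ("conductivity_uS_cm" %in% names(raw))
      as.numeric(raw$conductivity_uS_cm) else NA_real_,
    tds = if ("tds_mg_L" %in% names(raw)) as.numeric(raw$tds_mg_L) else
      NA_real_,
    calcium = as.numeric(raw$calcium_mg_L_CaCO3),
    magnesium = if ("magnesium_mg_L" %in% names(raw))
      as.numeric(raw$magnesium_mg_L) else NA_real_,
    alkalinity = as.numeric(raw$alkalinity_mg_L_CaCO3)
  )
  both_absent <- is.na(out$conductivity) & is.na(out$tds)
  if (any(both_absent)) {
    abort(sprintf(
      "%s: row %d has neither conductivity nor TDS.",
      path, which(both_absent)[1]
    ))
  }
  out
}
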