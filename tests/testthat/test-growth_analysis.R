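test_that("culture_series validates observations and events", {
  s <- toy_series()
  expect_s3_class(s, "culture_series")
  expect_equal(nrow(s), 3)
  expect_equal(series_meta(s)$nahco3_molarity, 0.02)
  expect_equal(series_events(s)$kind, "co2_shutoff")

  expect_error(culture_series(tibble::tibble(day = c(2, 1), afdw = 1:2)),
               "strictly increasing")
  expect_error(
    culture_series(tibble::tibble(day = 1, dry_weight = 1, afdw = 1.2)),
    "afdw"
  )
  expect_error(
    culture_series(tibble::tibble(day = 1), events = tibble::tibble(
      day = c(1, 2), kind = c("co2_shutoff", "co2_shutoff")
    )),
    "co2_shutoff"
  )
  g <- glance(s)
  expect_equal(g$final_afdw, 1.52)
  expect_equal(g$final_precipitate, 0.59)
})

test_that("average productivity is exact on linear data and interpolates", {
  lin <- culture_series(tibble::tibble(day = c(0, 3, 7, 12),
                                       afdw = 0.2 + 0.11 * c(0, 3, 7, 12)))
  expect_equal(average_productivity(lin, 0, 12), 0.11)
  expect_equal(average_productivity(lin, 2, 9), 0.11)   # interpolated ends

  obs <- culture_series(tibble::tibble(day = c(0, 12), afdw = c(0.73, 1.47)))
  expect_equal(average_productivity(obs, 0, 12), (1.47 - 0.73) / 12)
  expect_equal(average_productivity(obs, 0, 12), 0.0617, tolerance = 1e-3)

  flat <- culture_series(tibble::tibble(day = c(0, 5, 10), afdw = 1))
  expect_equal(average_productivity(flat, 0, 10), 0)

  # decline is reported as negative, not clipped
  down <- culture_series(tibble::tibble(day = c(0, 4), afdw = c(1.5, 1.1)))
  expect_equal(average_productivity(down, 0, 4), -0.1)

  expect_error(average_productivity(obs, 0, 14), "outside")
  expect_error(average_productivity(obs, 5, 5), "exceed")
})

test_that("productivity is additive over adjacent windows", {
  withr::with_seed(21, {
    days <- c(0, sort(runif(5, 1, 11)), 12)
    vals <- cumsum(c(0.1, runif(6, -0.05, 0.3)))
  })
  s <- culture_series(tibble::tibble(day = days, afdw = vals))
  mid <- days[4]
  full <- average_productivity(s, 0, 12)
  left <- average_productivity(s, 0, mid)
  right <- average_productivity(s, mid, 12)
  expect_equal(full, (left * mid + right * (12 - mid)) / 12)
})

test_that("ash content splits dry weight into organic and mineral parts", {
  a <- ash_content(1.54, 1.47)
  expect_equal(a$ash_g_L, 0.07)
  expect_equal(a$ash_percent, 100 * 0.07 / 1.54)
  expect_equal(a$ash_percent, 4.55, tolerance = 1e-2)
  b <- ash_content(1.23, 1.14)
  expect_equal(b$ash_g_L, 0.09)
  expect_equal(b$ash_percent, 7.32, tolerance = 1e-2)
  expect_equal(ash_content(2, 2), tibble::tibble(ash_g_L = 0, ash_percent = 0))
  expect_error(ash_content(1, 1.2), "exceeds")
})

test_that("fold change reproduces the reference treatment contrast", {
  expect_equal(round(fold_change(1.23, 0.78), 1), 1.6)
  expect_equal(fold_change(2, 2), 1)
  expect_equal(fold_change(2.6, 2), 1.3)
  expect_equal(fold_change(1.23, 0.78) * fold_change(0.78, 1.23), 1)
  expect_error(fold_change(1, 0), "control_value")
})

test_that("summarize_series reports one row per observation with events", {
  s <- toy_series()
  rep_tab <- summarize_series(s)
  expect_equal(nrow(rep_tab), 3)
  expect_true(all(c("ash_g_L", "ash_percent", "precipitate_yield_percent",
                    "extra_co2_percent", "afdw_productivity",
                    "dry_weight_productivity", "precipitate_productivity",
                    "events", "post_shutoff") %in% names(rep_tab)))
  expect_equal(rep_tab$post_shutoff, c(FALSE, FALSE, TRUE))
  expect_equal(rep_tab$events[2], "co2_shutoff")
  expect_true(is.na(rep_tab$afdw_productivity[1]))
  expect_equal(rep_tab$afdw_productivity[2], (1.47 - 0.10) / 12)
  expect_equal(round(rep_tab$extra_co2_percent[3], 1), 9.3)

  one <- culture_series(tibble::tibble(day = 3, afdw = 1, dry_weight = 1.1))
  rep_one <- summarize_series(one)
  expect_equal(nrow(rep_one), 1)
  expect_true(is.na(rep_one$afdw_productivity))
})

test_that("cumulative and interval window modes differ as intended", {
  s <- toy_series()
  int <- summarize_series(s, window_mode = "interval")
  cum <- summarize_series(s, window_mode = "cumulative")
  expect_equal(int$afdw_productivity[3], (1.52 - 1.47) / 2)
  expect_equal(cum$afdw_productivity[3], (1.52 - 0.10) / 14)
  expect_equal(int$afdw_productivity[2], cum$afdw_productivity[2])
})

test_that("summarize_series joins LSI when chemistry is supplied", {
  chem <- tibble::tibble(day = c(12, 14), ph = c(7.3, 8.6),
                         temperature_c = 25, tds = 35510,
                         calcium = 600, alkalinity = 1150)
  rep_tab <- summarize_series(toy_series(), chemistry = chem)
  expect_true(all(c("lsi", "phs", "classification") %in% names(rep_tab)))
  expect_true(is.na(rep_tab$lsi[1]))
  expect_gt(rep_tab$lsi[3], rep_tab$lsi[2])
})

test_that("account_series converts windows into a capture-rate ledger", {
  s <- toy_series()
  ledger <- account_series(s)
  expect_equal(nrow(ledger), 2)
  expect_equal(ledger$window_start, c(0, 12))
  expect_equal(ledger$window_end, c(12, 14))
  meta <- series_meta(s)
  expect_equal(
    ledger$areal_capture_rate[2],
    areal_rate((1.52 - 1.47) / 2 * 1.83 + (0.59 / 2) * 0.44,
               meta$volume, meta$footprint_area, meta$area_ratio)
  )
  expect_s3_class(autoplot(s), "ggplot")
})
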