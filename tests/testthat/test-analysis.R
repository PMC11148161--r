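fake_sim <- function(time_h, conc, regimen) {
  structure(list(
    profile = tibble::tibble(time_h = time_h, plasma_nmol_L = conc),
    regimen = regimen),
    class = "pbpkeo_sim")
}

test_that("interval summaries match analytic oracles", {
  reg <- dose_regimen(10, n_days = 1)
  tt <- seq(0, 24, by = 0.1)
  # constant 10 nmol/L over 24 h
  s <- summarize_pk(fake_sim(tt, rep(10, length(tt)), reg))
  expect_equal(s$auc_nmol_h_L, 240)
  expect_equal(s$cmax_nmol_L, 10)
  expect_equal(s$ctrough_nmol_L, 10)
  # mono-exponential decay: AUC = C0 (1 - e^{-k tau}) / k
  k <- 0.1; c0 <- 100
  s2 <- summarize_pk(fake_sim(tt, c0 * exp(-k * tt), reg))
  expect_equal(s2$auc_nmol_h_L, c0 * (1 - exp(-k * 24)) / k,
               tolerance = 1e-4)
  expect_equal(s2$cmax_nmol_L, c0)
  expect_equal(s2$ctrough_nmol_L, c0 * exp(-k * 24), tolerance = 1e-6)
})

test_that("prediction-observation comparison computes ratios and summary
           bounds", {
  obs <- table3_observed()
  pred <- dplyr::transmute(obs, study, dose_mg, metric,
                           predicted = observed)
  v <- validate_predictions(pred, obs)
  expect_true(all(abs(v$records$ratio - 1) < 1e-12))
  expect_equal(v$summary$frac_in_0.7_1.3, 1)
  # rows without an observed value are skipped with a message
  expect_message(validate_predictions(pred, obs), "skipped")
})

test_that("fixture tables have not drifted (checksums)", {
  t3 <- table3_observed()
  expect_equal(sum(t3$observed, na.rm = TRUE), 123077.1, tolerance = 1e-8)
  expect_equal(sum(t3$reference_predicted, na.rm = TRUE), 140167.9,
               tolerance = 1e-8)
  t4 <- table4_ddi()
  expect_equal(sum(t4$auc_ratio_ref), 7.56, tolerance = 1e-8)
  expect_equal(sum(t4$cmax_ratio_ref), 6.46, tolerance = 1e-8)
  pt <- parameter_table(frozen_cfg)
  expect_equal(sum(pt$value, na.rm = TRUE), 74335.5279, tolerance = 1e-4)
})

test_that("sensitivity coefficients: near-proportional parameters are
           ranked top and disconnected parameters are exactly zero", {
  sc <- sensitivity_scan(frozen_cfg)
  expect_setequal(unique(sc$direction), c("+20%", "-20%"))
  pl <- dplyr::filter(sc, output == "plasma_ctrough", direction == "+20%")
  get <- function(p) pl$sc[pl$parameter == p]
  # binding parameters drive plasma trough near-proportionally
  expect_gt(abs(get("fu_plasma")), 0.9)
  expect_gt(abs(get("albumin")), 0.9)
  # no pathway from the occupancy parameters back to the pharmacokinetics
  expect_equal(get("kon"), 0)
  expect_equal(get("egfr_t0"), 0)
  expect_equal(get("kdeg"), 0)
  # occupancy is insensitive to the initial receptor level (linear system)
  eo_t0 <- dplyr::filter(sc, output == "eo_trough",
                         parameter == "egfr_t0")
  expect_lt(max(abs(eo_t0$sc)), 1e-4)
})

test_that("sweep crossings are bracketed by opposite-sign grid values and
           refined consistently", {
  sw <- factor_sweep(frozen_cfg, "albumin",
                     grid = c(0.4, 0.6, 0.8, 1.0))
  cr <- sw$crossings$level_at_crossing[
    sw$crossings$quantity == "plasma_ctrough_nmol_L"]
  expect_false(is.na(cr))
  above <- sw$curve$plasma_ctrough_nmol_L[sw$curve$level < cr]
  below <- sw$curve$plasma_ctrough_nmol_L[sw$curve$level > cr]
  expect_true(all(above > 711))
  expect_true(all(below < 711))
  # plasma trough increases as albumin decreases (published direction)
  expect_true(all(diff(sw$curve$plasma_ctrough_nmol_L) < 0))
})

test_that("feasibility flags are consistent with the stored values", {
  ds <- dose_regimen_search(frozen_cfg, doses = c(20, 240),
                            intervals = 24, n_days = 10)
  expect_equal(ds$feasible,
               ds$eo_trough_t790m_pct >= 80 & ds$eo_trough_l858r_pct >= 80 &
                 ds$ctrough_nmol_L < 711)
  expect_equal(ds$feasible, ds$pass_eo & ds$pass_safety)
})

test_that("run manifests capture the locked mode and calibration", {
  tmp <- tempfile(fileext = ".json")
  m <- write_run_manifest(tmp, frozen_cfg, seed = 42, scenario = "unit")
  back <- jsonlite::read_json(tmp)
  expect_equal(back$seed, 42)
  expect_equal(back$eo_mode$drive, "brt_total")
  expect_true(isTRUE(back$calibration$frozen))
  expect_equal(back$config_hash, m$config_hash)
})
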