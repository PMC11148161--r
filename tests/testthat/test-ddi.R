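perps <- load_perpetrators()

test_that("competitive inhibition and induction algebra", {
  cl <- c(CYP3A4 = 100, CYP1A2 = 20)
  # no perpetrator exposure: multipliers exactly 1
  r0 <- apply_interaction(cl, 0, perps$itraconazole)
  expect_equal(r0$combined_mult, c(1, 1))
  # I = Ki halves the inhibited enzyme only
  ki <- perps$itraconazole$inhibition$CYP3A4
  r1 <- apply_interaction(cl, ki, perps$itraconazole)
  expect_equal(r1$inhibition_mult[r1$enzyme == "CYP3A4"], 0.5)
  expect_equal(r1$combined_mult[r1$enzyme == "CYP1A2"], 1)
  # induction fold 1 + Emax/2 at I = EC50: with Emax 10.8 this is 6.4
  mock <- list(inhibition = list(),
               induction = list(CYP3A4 = list(emax = 10.8, ec50_u = 0.12)))
  r2 <- apply_interaction(c(CYP3A4 = 1), 0.12, mock)
  expect_equal(r2$induction_fold, 6.4)
})

test_that("perpetrator exposure model matches the closed-form average and
           superposes linearly", {
  p <- perps$rifampicin
  prof <- perpetrator_unbound_profile(p, horizon_h = 14 * 24)
  ss <- dplyr::filter(prof, time_h >= 13 * 24)
  css_avg <- mean(ss$conc_uM)
  # Css,avg = fu x Dose / (CL/F x tau), hand-checked closed form
  expected <- p$pk$fu * mg_to_umol(p$regimen$dose_mg, p$molecular_weight) /
    (p$pk$cl_f * p$regimen$interval)
  expect_equal(css_avg, expected, tolerance = 0.02)
  # doubling the dose doubles the concentration
  p2 <- p; p2$regimen$dose_mg <- 2 * p$regimen$dose_mg
  prof2 <- perpetrator_unbound_profile(p2, horizon_h = 14 * 24)
  expect_equal(prof2$conc_uM[-1] / prof$conc_uM[-1],
               rep(2, nrow(prof) - 1), tolerance = 1e-9)
  # zero dose: identically zero
  p0 <- p; p0$regimen$dose_mg <- 0
  expect_equal(max(perpetrator_unbound_profile(p0, 48)$conc_uM), 0)
})

test_that("a null perpetrator leaves every ratio at one", {
  mdl <- build_body_model(frozen_cfg)
  d <- ddi_scenario(mdl, NULL, dose_regimen(80, n_days = 6))
  expect_equal(d$ratios$auc_ratio, 1, tolerance = 1e-9)
  expect_equal(d$ratios$cmax_ratio, 1, tolerance = 1e-9)
  expect_equal(d$ratios$ctrough_ratio, 1, tolerance = 1e-9)
})

test_that("inhibitors raise and inducers lower victim exposure, and the
           intracranial occupancy moves with exposure", {
  mdl <- build_body_model(frozen_cfg)
  reg <- dose_regimen(80)
  ratios <- purrr::imap_dfr(perps, function(p, nm) {
    d <- ddi_scenario(mdl, p, reg, variants = "t790m_l858r")
    eo <- tidyr::pivot_wider(d$eo[, c("arm", "eo_trough_pct")],
                             names_from = "arm",
                             values_from = "eo_trough_pct")
    tibble::tibble(perpetrator = nm, auc_ratio = d$ratios$auc_ratio,
                   eo_shift = eo$co_administered - eo$victim_alone)
  })
  inhibitors <- c("itraconazole", "fluconazole", "fluvoxamine")
  inducers <- c("rifampicin", "efavirenz")
  expect_true(all(ratios$auc_ratio[ratios$perpetrator %in% inhibitors] > 1))
  expect_true(all(ratios$auc_ratio[ratios$perpetrator %in% inducers] < 1))
  expect_true(all(ratios$eo_shift[ratios$perpetrator %in% inhibitors] > 0))
  expect_true(all(ratios$eo_shift[ratios$perpetrator %in% inducers] < 0))
})

test_that("interaction strength is monotone in perpetrator exposure", {
  mdl <- build_body_model(frozen_cfg)
  reg <- dose_regimen(80, n_days = 10)
  doses <- c(0.5, 1, 2)
  aucr <- vapply(doses, function(f) {
    p <- perps$fluconazole
    p$regimen$dose_mg <- p$regimen$dose_mg * f
    ddi_scenario(mdl, p, reg, perp_days = 1:10)$ratios$auc_ratio
  }, numeric(1))
  expect_true(all(diff(aucr) > 0))
})

test_that("the DDI ratio table fixture is structurally sound", {
  t4 <- table4_ddi()
  expect_equal(nrow(t4), 7)
  expect_true(all(t4$auc_ratio_ref > 0))
  expect_setequal(unique(t4$perpetrator),
                  c("itraconazole", "fluconazole", "fluvoxamine",
                    "rifampicin", "efavirenz"))
})
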