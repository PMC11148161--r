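test_that("mass is conserved to solver tolerance and states stay
           non-negative", {
  sim <- base_sim()
  mb <- mass_balance(sim)
  expect_lt(max(abs(mb$rel_error)), 1e-6)
  states <- as.matrix(sim$profile[, 2:22])
  expect_gte(min(states), -1e-8)
})

test_that("a zero dose yields identically zero concentrations", {
  sim <- quick_sim(dose = 0, n_days = 2)
  expect_equal(max(sim$profile$plasma_nmol_L), 0)
  expect_equal(max(abs(as.matrix(sim$profile[, 2:22]))), 0)
})

test_that("exposure is dose-proportional when auto-interaction is off", {
  s80 <- summarize_pk(base_sim())
  s160 <- summarize_pk(quick_sim(dose = 160))
  expect_equal(s160$auc_nmol_h_L / s80$auc_nmol_h_L, 2, tolerance = 1e-6)
  expect_equal(s160$cmax_nmol_L / s80$cmax_nmol_L, 2, tolerance = 1e-6)
})

test_that("daily dosing reaches periodic steady state by day 14", {
  p <- base_sim()$profile
  ct <- function(d) p$plasma_nmol_L[which.min(abs(p$time_h - d * 24))]
  expect_lt(abs(ct(14) - ct(13)) / ct(13), 0.01)
  expect_true(summarize_pk(base_sim())$at_steady_state)
})

test_that("unbound brain attenuation lies in (0, 1] and respects the
           passive/efflux limits", {
  expect_gt(brain_kpuu(base_sim()), 0)
  expect_lte(brain_kpuu(base_sim()), 1 + 1e-6)
  # no efflux: interstitial reaches the passive partition equilibrium
  cfg0 <- frozen_cfg
  cfg0$brain_transport$abcb1_clint <- 0
  cfg0$brain_transport$bcrp_clint <- 0
  expect_equal(brain_kpuu(quick_sim(cfg0)), 1, tolerance = 0.05)
  # overwhelming efflux drives interstitial free toward zero
  sim_hi <- quick_sim(subject = {
    s <- mean_subject(frozen_cfg); s$m_abcb1 <- 500; s
  })
  expect_lt(summarize_pk(sim_hi,
                         column = "brain_interstitial_free_nmol_L")$ctrough_nmol_L,
            0.1 * summarize_pk(base_sim(),
                               column = "brain_interstitial_free_nmol_L")$ctrough_nmol_L)
})

test_that("trough is sampled immediately before the next scheduled dose", {
  sim <- base_sim()
  s <- summarize_pk(sim)
  i <- which.min(abs(sim$profile$time_h - 14 * 24))
  expect_equal(s$ctrough_nmol_L, sim$profile$plasma_nmol_L[i])
  expect_gte(s$cmax_nmol_L, s$ctrough_nmol_L)
  expect_gte(s$auc_nmol_h_L, 24 * s$ctrough_nmol_L * 0.999)
})

test_that("twice-daily dosing at half the dose preserves the daily AUC and
           raises the trough", {
  od <- summarize_pk(quick_sim(dose = 80))
  bid <- summarize_pk(quick_sim(dose = 40, interval = 12))
  expect_equal(2 * bid$auc_nmol_h_L / od$auc_nmol_h_L, 1, tolerance = 0.02)
  expect_gte(bid$ctrough_nmol_L, od$ctrough_nmol_L)
})

test_that("simulation exports tidy records and broom-style summaries", {
  sim <- base_sim()
  td <- tidy(sim)
  expect_named(td, c("time_h", "compartment", "concentration_nmol_per_L"))
  expect_setequal(unique(td$compartment),
                  c("plasma", "brain_interstitial_free", "brain_total"))
  g <- glance(sim)
  expect_equal(g$dose_mg, 80)
  tmp <- tempfile(fileext = ".csv")
  export_profile_csv(sim, tmp)
  back <- utils::read.csv(tmp)
  expect_equal(nrow(back), nrow(td))
  p <- autoplot(sim)
  expect_s3_class(p, "ggplot")
})
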