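test_that("unionized fraction follows the single-site base equation", {
  expect_equal(unionized_fraction(7.4, 7.4), 0.5)
  # closed form 10^-2.1 / (1 + 10^-2.1)
  expect_equal(unionized_fraction(9.5, 7.4),
               10^(-2.1) / (1 + 10^(-2.1)), tolerance = 1e-12)
  expect_equal(unionized_fraction(9.5, 7.4), 0.00788, tolerance = 1e-3)
  # fully unionized limit for a vanishing pKa
  expect_equal(unionized_fraction(-50, 7.4), 1.0)
  # strictly increasing in pH for a base
  ph <- seq(1, 13, by = 0.5)
  expect_true(all(diff(unionized_fraction(9.5, ph)) > 0))
})

test_that("transwell efflux clearance reproduces both tabulated values", {
  cfg <- frozen_cfg
  a <- cfg$brain_transport$assay
  cl_abcb1 <- transporter_clint_from_assay(a$papp_ab_abcb1, a$nfr_abcb1,
                                           a$filter_surface_area,
                                           a$cell_count, a$assay_ph)
  cl_bcrp <- transporter_clint_from_assay(a$papp_ab_bcrp, a$nfr_bcrp,
                                          a$filter_surface_area,
                                          a$cell_count, a$assay_ph)
  # one back-calculated assay scale (SA 1.12 cm2, 3.92e6 cells) must
  # reproduce both transporter clearances
  expect_equal(cl_abcb1, cfg$brain_transport$abcb1_clint, tolerance = 5e-3)
  expect_equal(cl_bcrp, cfg$brain_transport$bcrp_clint, tolerance = 5e-3)
})

test_that("efflux clearance algebra: zero at unity efflux ratio, linear in
           surface area, inverse in cell count", {
  expect_equal(transporter_clint_from_assay(1.36, 1, 1.12, 3.92), 0)
  base <- transporter_clint_from_assay(1.36, 13.4, 1.12, 3.92)
  expect_equal(transporter_clint_from_assay(1.36, 13.4, 2.24, 3.92),
               2 * base)
  expect_equal(transporter_clint_from_assay(1.36, 13.4, 1.12, 7.84),
               base / 2)
  expect_error(transporter_clint_from_assay(1.36, 0.8, 1.12, 3.92),
               "negative efflux")
})

test_that("plasma-protein scale factor matches the independent
           albumin-dilution relation", {
  expect_equal(ppsf(0.5, 4.5, 4.5), 1)
  expect_equal(ppsf(1, 2.0, 4.5), 1)   # nothing bound, nothing to scale
  # independent oracle: fu2 = 1 / (1 + (alb2/alb1) (1 - fu1)/fu1)
  fu1 <- 0.011
  fu2_oracle <- 1 / (1 + (0.31 / 0.45) * (1 - fu1) / fu1)
  expect_equal(fu1 * ppsf(fu1, 0.31, 0.45), fu2_oracle, tolerance = 1e-12)
  expect_equal(ppsf(fu1, 0.31, 0.45), 1.444, tolerance = 1e-3)
  expect_equal(scaled_fu(fu1, 0.31, 0.45), 0.0159, tolerance = 1e-3)
  # strictly decreasing in patient albumin (physiological orientation)
  alb <- seq(1, 6, by = 0.5)
  expect_true(all(diff(vapply(alb, function(a) ppsf(fu1, a, 4.5),
                              numeric(1))) < 0))
  # the as-printed orientation inverts the direction
  expect_true(ppsf(fu1, 0.31, 0.45, orientation = "as_printed") < 1)
})

test_that("degradation rate constant from half-life", {
  expect_equal(kdeg_from_halflife(27.5), 0.025, tolerance = 1e-2)
  expect_equal(kdeg_from_halflife(log(2)), 1.0)
  expect_equal(kdeg_from_halflife(1), log(2))
  expect_error(kdeg_from_halflife(0))
})

test_that("configuration loads, validates and round-trips losslessly", {
  cfg <- frozen_cfg
  expect_s3_class(cfg, "pbpkeo_config")
  expect_equal(cfg$compound$molecular_weight, 499.6)
  expect_equal(cfg$eo$kdeg, kdeg_from_halflife(cfg$eo$egfr_halflife),
               tolerance = 1e-6)
  tmp <- tempfile(fileext = ".yaml")
  save_model_config(cfg, tmp)
  cfg2 <- load_model_config(tmp)
  pt1 <- parameter_table(cfg)
  pt2 <- parameter_table(cfg2)
  expect_equal(pt1$value, pt2$value)
  expect_equal(pt1$parameter, pt2$parameter)
})
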