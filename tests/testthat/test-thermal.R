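test_that("melting line starts at the dry melting point and falls with dilution", {
  expect_identical(melting_temperature(0), 515)
  # hand evaluation of the depression relation at phi = 0.5
  expect_equal(melting_temperature(0.5), 383.07, tolerance = 1e-4)
  phi <- seq(0, 0.9, by = 0.02)
  for (chi_p in c(0, 0.25, 0.5)) {
    tm <- melting_temperature(phi, chi_p = chi_p)
    expect_true(all(diff(tm) < 0))
  }
  expect_error(melting_temperature(1), "pure-diluent")
})

test_that("dough descriptors order predicted gelatinization temperatures", {
  params <- formulation_params(default_recipes())
  tm <- melting_temperature(params$phi_w_eff)
  # higher effective water fraction melts starch earlier
  expect_identical(order(tm), order(params$phi_w_eff, decreasing = TRUE))
})

test_that("state diagram evaluates each configured line on the grid", {
  d <- state_diagram(c(0, 0.25, 0.5))
  expect_identical(nrow(d), 6L)
  expect_setequal(unique(d$line), c("starch", "gluten"))
  expect_equal(d$T_K[d$phi == 0 & d$line == "starch"], 515)
  expect_identical(nrow(state_diagram(numeric(0))), 0L)
  expect_error(state_diagram(1), "pure-diluent")
  expect_s3_class(plot_state_diagram(d), "ggplot")
})

test_that("DSC features recover constructed endotherms", {
  # piecewise-linear leading edge: tangent intersection is the exact onset
  pw <- gen_dsc_curve(t_onset = 58, t_peak = 65, shape = "piecewise")
  f <- dsc_features(pw)
  expect_true(f$found)
  expect_equal(f$t_onset_C, 58, tolerance = 0.3 / 58)
  expect_equal(f$t_peak_C, 65, tolerance = 0.2 / 65)
  # gaussian peak on a flat baseline
  g <- dsc_features(gen_dsc_curve(t_peak = 65, shape = "gaussian"))
  expect_equal(g$t_peak_C, 65, tolerance = 0.2 / 65)
  # flat curve: sentinel, not an error
  flat <- tibble::tibble(temperature_C = seq(30, 110, length.out = 100),
                         value = 0.5)
  expect_false(dsc_features(flat)$found)
})

test_that("DSC features are scale- and shift-invariant in the documented sense", {
  pw <- gen_dsc_curve(t_onset = 58, t_peak = 65, shape = "piecewise")
  f <- dsc_features(pw)
  scaled <- dplyr::mutate(pw, value = value * 7.3)
  expect_equal(dsc_features(scaled)$t_onset_C, f$t_onset_C)
  shifted <- dplyr::mutate(pw, temperature_C = temperature_C + 11)
  expect_equal(dsc_features(shifted)$t_onset_C, f$t_onset_C + 11, tolerance = 1e-6)
})

test_that("DMTA features recover a constructed structuring transition", {
  dm <- gen_dmta_curve(baseline = 1e3, amplitude = 99e3, t_infl = 70, width = 2)
  f <- dmta_features(dm$gprime, dm$tand)
  expect_true(f$found)
  # analytic tangent onset of the logistic is t_infl - 2 width = 66
  expect_gte(f$t_on_C, 64)
  expect_lte(f$t_on_C, 70)
  expect_equal(f$gmax_over_gmin, 100, tolerance = 0.05)
  expect_equal(f$g28_Pa, 1e3, tolerance = 1e-3)
  expect_equal(f$t_gmax_C, 95, tolerance = 0.01)
  expect_lt(f$t_on_C, f$t_gmax_C)
  # dip-then-peak ratio is a plain quotient
  tc <- seq(25, 95, length.out = 200)
  dip <- 1000 - 500 * exp(-(tc - 40)^2 / 20) + 49500 * (1 + tanh((tc - 80) / 3))
  gd <- tibble::tibble(temperature_C = tc, value = dip)
  td <- tibble::tibble(temperature_C = tc, value = 0.4)
  fd <- dmta_features(gd, td)
  expect_equal(fd$gmax_over_gmin, max(dip) / min(dip))
})

test_that("DMTA handles flat curves and mismatched grids", {
  tc <- seq(25, 95, length.out = 100)
  cg <- tibble::tibble(temperature_C = tc, value = 1000)
  ct <- tibble::tibble(temperature_C = tc, value = 0.4)
  f <- dmta_features(cg, ct)
  expect_false(f$found)
  expect_identical(f$gmax_over_gmin, 1)
  dm <- gen_dmta_curve()
  coarse <- dm$tand[seq(1, nrow(dm$tand), by = 2), ]
  expect_warning(dmta_features(dm$gprime, coarse), "resampling")
})

test_that("extension features find the rupture point", {
  # triangle peaking at (20 mm, 0.5 N) with an abrupt collapse
  tri <- tibble::tibble(
    displacement_mm = c(seq(0, 20, length.out = 40), 20.5, 21, 21.5),
    force_N = c(seq(0, 0.5, length.out = 40), 0.05, 0.02, 0)
  )
  f <- extension_features(tri)
  expect_equal(f$resistance_N, 0.5)
  expect_equal(f$extensibility_mm, 20)
  # monotone rise never ruptures
  mono <- tibble::tibble(displacement_mm = seq(0, 30, length.out = 50),
                         force_N = seq(0, 1, length.out = 50))
  expect_error(extension_features(mono), "50%")
  # seeded noisy curve with rupture at 35 mm
  noisy <- gen_extension_curve(rupture_mm = 35, peak_force_N = 0.5,
                               sigma = 0.005, seed = 4)
  expect_equal(extension_features(noisy)$extensibility_mm, 35, tolerance = 1 / 35)
})
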