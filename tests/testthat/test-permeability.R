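test_that("cleared volume accumulates interval receiver amounts from the origin", {
  # constant flux: 10 uL cleared per 20-min interval
  # signal for 10 uL: 10 uL * 50 uM dose = 500 pmol -> /1500 uL * 100 AU/uM
  sig <- rep(10 * 50 / 1500 * 100, 3)
  s <- cleared_volume_series(c(20, 40, 60), sig, signal_per_conc = 100)
  expect_equal(s$time_min, c(0, 20, 40, 60))
  expect_equal(s$cleared_uL, c(0, 10, 20, 30))

  # all-zero signals stay at zero
  s0 <- cleared_volume_series(c(20, 40, 60), c(0, 0, 0), 100)
  expect_equal(s0$cleared_uL, rep(0, 4))

  # noiseless forward simulation at PS_true = 0.6 uL/min
  s6 <- cleared_volume_series(c(20, 40, 60), sink_receiver_signals(0.6), 100)
  expect_equal(s6$cleared_uL, c(0, 12, 24, 36))
})

test_that("invalid clearance inputs are rejected with typed errors", {
  expect_error(cleared_volume_series(c(20, 20, 60), c(1, 1, 1), 100),
               class = "barriertools_invalid_series")
  expect_error(cleared_volume_series(c(0, 20, 40), c(1, 1, 1), 100),
               class = "barriertools_invalid_series")
  expect_error(cleared_volume_series(c(20, 40, 60), c(1, -1, 1), 100),
               class = "barriertools_invalid_reading")
  expect_error(cleared_volume_series(c(20, 40, 60), c(1, 1, 1), 0))
})

test_that("fit_ps is ordinary least squares with a free intercept", {
  fit <- fit_ps(tibble::tibble(time_min = c(0, 20, 40, 60),
                               cleared_uL = c(0, 10, 20, 30)))
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_points, 4L)

  v <- c(0, 9.6, 20.7, 29.9)
  fit2 <- fit_ps(tibble::tibble(time_min = c(0, 20, 40, 60), cleared_uL = v))
  oracle <- ols_oracle(c(0, 20, 40, 60), v)
  expect_equal(fit2$slope, unname(oracle["slope"]))
  expect_equal(fit2$slope, 0.504, tolerance = 1e-12)
  expect_equal(fit2$intercept, unname(oracle["intercept"]))

  flat <- fit_ps(tibble::tibble(time_min = c(0, 20, 40, 60),
                                cleared_uL = rep(0, 4)))
  expect_equal(flat$slope, 0)

  expect_error(fit_ps(tibble::tibble(time_min = rep(5, 3),
                                     cleared_uL = 1:3)),
               class = "barriertools_degenerate_fit")

  td <- tidy(fit2)
  expect_equal(td$estimate[td$term == "slope_uL_per_min"], fit2$slope)
  expect_equal(glance(fit2)$r_squared, fit2$r_squared)
})

test_that("series-resistance correction recovers the monolayer PS", {
  # non-limiting filter: PSe -> PSt
  expect_equal(correct_series_resistance(0.5, 1e9), 0.5, tolerance = 1e-8)
  # control-condition algebra: PSt 0.4644, PSf 2 -> PSe 0.6048, Pe 0.54e-3
  pse <- correct_series_resistance(0.4644, 2.0)
  expect_equal(pse, 0.6048, tolerance = 1e-3)
  expect_equal(pe_from_ps(pse, 1.12), 0.54e-3, tolerance = 1e-3)
  # cells apparently more permeable than the blank filter is impossible
  expect_error(correct_series_resistance(2.0, 2.0),
               class = "barriertools_cells_more_permeable")
  expect_error(correct_series_resistance(3.0, 2.0),
               class = "barriertools_cells_more_permeable")
  # additive variant reproduces the printed sign convention
  expect_equal(correct_series_resistance(2, 2, form = "as_printed"), 1)
})

test_that("Pe is PSe/S after uL -> cm^3 conversion", {
  expect_equal(pe_from_ps(1.12, 1.12), 1e-3)
  expect_equal(pe_from_ps(0, 1.12), 0)
  expect_error(pe_from_ps(1, 0), class = "barriertools_invalid_geometry")
})

test_that("round-trip and monotonicity of the corrected form hold", {
  psf <- 2.0
  for (pst in c(0.05, 0.3, 0.4644, 1.2, 1.9)) {
    pse <- correct_series_resistance(pst, psf)
    pe <- pe_from_ps(pse, 1.12)
    pst_back <- 1 / (1 / (pe * 1.12 * 1e3) + 1 / psf)
    expect_equal(pst_back, pst, tolerance = 1e-12)
  }
  pst_grid <- seq(0.1, 1.9, by = 0.2)
  pe_grid <- pe_from_ps(correct_series_resistance(pst_grid, 2.0), 1.12)
  expect_true(all(diff(pe_grid) > 0))
  # at a fixed measured total PS, a leakier filter implies a tighter
  # monolayer: corrected Pe decreases in PSf (the additive printed form
  # increases instead)
  psf_grid <- seq(1.0, 5.0, by = 0.5)
  pe_psf <- pe_from_ps(correct_series_resistance(0.9, psf_grid), 1.12)
  expect_true(all(diff(pe_psf) < 0))
  pe_psf_printed <- pe_from_ps(
    correct_series_resistance(0.9, psf_grid, form = "as_printed"), 1.12)
  expect_true(all(diff(pe_psf_printed) > 0))
})

test_that("mass balance is recovered dose over initial dose, bounds inclusive", {
  # initial 25 nmol, receiver 5 nmol, donor final 19 nmol -> 96 %, pass
  mb <- mass_balance(receiver_signal = 5, donor_final_signal = 19 / 25,
                     signal_per_conc = 1, donor_conc = 1,
                     donor_volume_uL = 25, receiver_volume_uL = 1)
  expect_equal(mb$mass_balance_pct, 96)
  expect_true(mb$qc_pass)
  # recovered 17.5 / 25 -> 70 %, fail
  mb2 <- mass_balance(17.5, 0, 1, donor_conc = 1, donor_volume_uL = 25,
                      receiver_volume_uL = 1)
  expect_equal(mb2$mass_balance_pct, 70)
  expect_false(mb2$qc_pass)
  # exactly 80 % passes (inclusive bound)
  mb3 <- mass_balance(20, 0, 1, donor_conc = 1, donor_volume_uL = 25,
                      receiver_volume_uL = 1)
  expect_equal(mb3$mass_balance_pct, 80)
  expect_true(mb3$qc_pass)
})

test_that("pathway decomposition subtracts exactly and never clamps", {
  d <- decompose_pathways(0.54e-3, 0.18e-3)
  expect_identical(d$pe_transcellular, 0.54e-3 - 0.18e-3)
  expect_false(d$negative_transcellular)

  same <- decompose_pathways(0.4e-3, 0.4e-3)
  expect_equal(same$pe_transcellular, 0)

  expect_warning(neg <- decompose_pathways(0.1e-3, 0.2e-3),
                 class = "barriertools_negative_transcellular")
  expect_equal(neg$pe_transcellular, -0.1e-3)
  expect_true(neg$negative_transcellular)

  # additivity by construction
  for (tot in c(0.5e-3, 1e-3)) {
    for (para in c(0.1e-3, 0.4e-3)) {
      dd <- decompose_pathways(tot, para)
      expect_identical(dd$pe_paracellular + dd$pe_transcellular, dd$pe_total)
    }
  }

  ctl <- decompose_pathways(0.54e-3, 0.18e-3)
  rel <- decompose_pathways(1.0e-3, 0.36e-3, control = ctl)
  expect_equal(rel$pct_paracellular, 200)
})

test_that("plate-level pipeline recovers configured truth without noise", {
  cfg <- noiseless_config(seed = 42)
  sim <- simulate_clearance_assay(cfg)
  pe <- analyze_permeability(sim$readings)
  joined <- merge(pe[pe$condition_id != "FILTER", ], sim$truth,
                  by = "condition_id")
  at37 <- joined[joined$temperature_C == 37, ]
  at4 <- joined[joined$temperature_C == 4, ]
  expect_equal(at37$pe_mean, at37$pe_total, tolerance = 1e-9)
  expect_equal(at4$pe_mean, at4$pe_paracellular, tolerance = 1e-9)
  expect_true(all(abs(joined$mass_balance_mean - 100) < 1e-9))

  dec <- decompose_conditions(pe, control_condition = "CTRL")
  tr <- merge(dec, sim$truth, by = "condition_id")
  expect_equal(tr$pe_transcellular.x, tr$pe_transcellular.y, tolerance = 1e-9)
})

test_that("percent-of-control decomposition reproduces the configured effects", {
  cfg <- noiseless_config()
  sim <- simulate_clearance_assay(cfg)
  dec <- decompose_conditions(analyze_permeability(sim$readings),
                              control_condition = "CTRL")
  tnf <- dec[dec$condition_id == "TNFa", ]
  expect_equal(tnf$pct_transcellular, 140.1, tolerance = 1e-6)
  expect_equal(tnf$pct_paracellular, 275.2, tolerance = 1e-6)
  il <- dec[dec$condition_id == "IL1b", ]
  expect_equal(il$pct_transcellular, 194.2, tolerance = 1e-6)
  expect_equal(il$pct_paracellular, 141.3, tolerance = 1e-6)
})
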