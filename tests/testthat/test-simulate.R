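test_that("identical config and seed reproduce every table exactly", {
  cfg <- sim_config(noise_cv = 0.05, seed = 123, n_images = 1,
                    image_px = 96, nuclei_n = 12)
  a <- simulate_all_assays(cfg)
  b <- simulate_all_assays(cfg)
  expect_identical(a$clearance$readings, b$clearance$readings)
  expect_identical(a$transport$readings, b$transport$readings)
  expect_identical(a$qpcr$readings, b$qpcr$readings)
  expect_identical(a$mtt$readings, b$mtt$readings)
  expect_identical(a$images$images$stain, b$images$images$stain)

  # a different seed changes the noisy readings
  c2 <- simulate_clearance_assay(sim_config(noise_cv = 0.05, seed = 124))
  expect_false(identical(a$clearance$readings, c2$readings))
})

test_that("generators do not disturb the caller's random stream", {
  set.seed(77)
  before <- .Random.seed
  invisible(simulate_clearance_assay(sim_config(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("noiseless mass balance is exactly 100 percent on every well", {
  cfg <- noiseless_config(seed = 2)
  sim <- simulate_clearance_assay(cfg)
  cal <- mean(sim$readings$signal_AU[sim$readings$filter_type == "calibration"])
  wells <- split(
    sim$readings[sim$readings$filter_type != "calibration", ],
    sim$readings$well_id[sim$readings$filter_type != "calibration"]
  )
  for (w in wells) {
    recv <- w[w$compartment == "basolateral", ]
    donor <- w[w$compartment == "apical", ]
    mb <- mass_balance(recv$signal_AU, donor$signal_AU, cal,
                       donor_conc = w$donor_conc[1],
                       donor_volume_uL = w$donor_volume_uL[1],
                       receiver_volume_uL = w$receiver_volume_uL[1])
    expect_equal(mb$mass_balance_pct, 100, tolerance = 1e-12)
  }
})

test_that("noisy mass balances stay within QC bounds almost always", {
  # CV 5 %: pool wells across seeds; at least 99 % inside [80, 120]
  sims <- lapply(1:10, function(s) {
    sim <- simulate_clearance_assay(sim_config(noise_cv = 0.05, seed = s))
    cal <- mean(sim$readings$signal_AU[sim$readings$filter_type == "calibration"])
    dat <- sim$readings[sim$readings$filter_type != "calibration", ]
    vapply(split(dat, dat$well_id), function(w) {
      recv <- w[w$compartment == "basolateral", ]
      donor <- w[w$compartment == "apical", ]
      mass_balance(recv$signal_AU, donor$signal_AU, cal,
                   donor_conc = w$donor_conc[1],
                   donor_volume_uL = w$donor_volume_uL[1],
                   receiver_volume_uL = w$receiver_volume_uL[1])$mass_balance_pct
    }, numeric(1))
  })
  all_pcts <- unlist(sims)
  expect_gte(mean(all_pcts >= 80 & all_pcts <= 120), 0.99)
})

test_that("donor depletion mode biases the sink-assumption Pe by under 3 percent", {
  cfg <- noiseless_config(seed = 4)
  sim <- simulate_clearance_assay(cfg, deplete_donor = TRUE)
  pe <- analyze_permeability(sim$readings)
  ctl <- pe[pe$condition_id == "CTRL" & pe$temperature_C == 37, ]
  rel_err <- abs(ctl$pe_mean - cfg$pe_true_total) / cfg$pe_true_total
  expect_gt(rel_err, 0)      # the bias exists...
  expect_lt(rel_err, 0.03)   # ...and is bounded
  # mass balance stays exact: depletion is bookkept into the donor reading
  expect_equal(ctl$mass_balance_mean, 100, tolerance = 1e-9)
})

test_that("unphysical configurations are rejected at load", {
  expect_error(sim_config(pe_true_paracellular = 0.6e-3),
               class = "barriertools_invalid_config")
  expect_error(sim_config(noise_cv = -0.1),
               class = "barriertools_invalid_config")
  expect_error(sim_config(psf_true = 0.5),
               class = "barriertools_invalid_config")
  expect_error(sim_config(stain_fraction_true = 0.5),
               class = "barriertools_invalid_config")
})

test_that("YAML run configuration round-trips into a sim_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "noise_cv: 0",
    "seed: 99",
    "n_filters: 4",
    "conditions:",
    "  - {condition_id: CTRL, trans_mult: 1, para_mult: 1,",
    "     abeta_influx_mult: 1, abeta_efflux_mult: 1, stain_mult: 1}"
  ), path)
  cfg <- read_run_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$seed, 99L)
  expect_equal(cfg$n_filters, 4)
  expect_equal(nrow(cfg$conditions), 1)
  expect_equal(cfg$pe_true_total, 0.54e-3)  # defaults retained

  writeLines("bogus_key: 1", path)
  expect_error(read_run_config(path), class = "barriertools_invalid_config")
})
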