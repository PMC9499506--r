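make_ct_records <- function(sample_cts, gene = "g", condition = "CTRL",
                            sample_id = "s1", controls = NULL) {
  recs <- tibble::tibble(
    sample_id = sample_id, condition_id = condition, gene = gene,
    replicate = seq_along(sample_cts), ct = sample_cts, well_type = "sample"
  )
  if (!is.null(controls)) recs <- dplyr::bind_rows(recs, controls)
  recs
}

test_that("Ct summarisation averages determined replicates and gates on NTC/NRT", {
  recs <- make_ct_records(c(20.0, 20.2, 19.8))
  out <- summarize_ct(recs)
  expect_equal(out$ct_mean, 20.0)
  expect_equal(out$n_replicates, 3L)
  expect_true(out$qc_pass)

  # NTC amplifying within 5 cycles of the sample mean fails the gene
  ntc <- tibble::tibble(sample_id = "NTC", condition_id = "CONTROL",
                        gene = "g", replicate = 1L, ct = 24,
                        well_type = "NTC")
  out2 <- summarize_ct(make_ct_records(c(22, 22, 22), controls = ntc))
  expect_false(out2$qc_pass)

  # undetermined NRT passes
  nrt <- tibble::tibble(sample_id = "NRT", condition_id = "CONTROL",
                        gene = "g", replicate = 1L, ct = NA_real_,
                        well_type = "NRT")
  out3 <- summarize_ct(make_ct_records(c(22, 22, 22), controls = nrt))
  expect_true(out3$qc_pass)

  expect_error(summarize_ct(make_ct_records(c(NA_real_, NA_real_))),
               class = "barriertools_missing_gene")
})

test_that("delta-delta-Ct fold is 2^(-ddCt)", {
  same <- ddct_fold(25, 20, 25, 20)
  expect_equal(same$fold, 1)
  expect_equal(same$pct_of_control, 100)

  up <- ddct_fold(25, 20, 24, 20)  # dCt 5 -> 4
  expect_equal(up$fold, 2)
  expect_equal(up$pct_of_control, 200)

  # dCt 5.000 -> 3.741: fold 2^1.259, +139.4 % vs control
  cl5 <- ddct_fold(25.000, 20, 23.741, 20)
  expect_equal(cl5$fold, 2^1.259, tolerance = 1e-12)
  expect_equal(cl5$pct_of_control, 239.4, tolerance = 1e-3)

  expect_error(ddct_fold(25, NA, 24, 20),
               class = "barriertools_missing_gene")
})

test_that("fold is invariant to global Ct shifts and stable references", {
  base <- ddct_fold(25, 20, 23.5, 20.2)
  for (shift in c(-3, 1.7, 10)) {
    shifted <- ddct_fold(25 + shift, 20 + shift, 23.5 + shift, 20.2 + shift)
    expect_equal(shifted$fold, base$fold, tolerance = 1e-12)
  }
  # target and reference shifting identically between conditions -> fold 1
  sh <- ddct_fold(25, 20, 25 + 2, 20 + 2)
  expect_equal(sh$fold, 1)
})

test_that("primer-efficiency QC accepts the validated primer range", {
  expect_true(efficiency_qc(106.3))   # reference gene
  expect_true(efficiency_qc(86.1))    # lowest validated pair
  expect_true(efficiency_qc(112.3))   # highest validated pair
  expect_false(efficiency_qc(120))
  expect_false(efficiency_qc(80))
})

test_that("densitometry percent-of-control divides actin-normalized ratios", {
  expect_equal(densitometry_pct_of_control(1, 2, 1, 2), 100)
  expect_equal(densitometry_pct_of_control(0.5, 1, 1, 1), 50)
  expect_equal(densitometry_pct_of_control(1.222, 1, 1, 1), 122.2)
  expect_error(densitometry_pct_of_control(1, 0, 1, 1))
  expect_error(densitometry_pct_of_control(1, 1, 0, 1))

  dens <- tibble::tibble(
    condition_id = c("CTRL", "CTRL", "TNFa", "TNFa"),
    protein = "icam1",
    band_density = c(1.0, 1.0, 1.22, 1.22),
    actin_density = 1
  )
  out <- analyze_densitometry(dens, "CTRL")
  expect_equal(out$pct_of_control_mean[out$condition_id == "TNFa"], 122)
})

test_that("noiseless qPCR plate analysis returns the configured folds exactly", {
  cfg <- noiseless_config(seed = 11)
  sim <- simulate_qpcr_plate(cfg)
  res <- analyze_qpcr(sim$readings, reference_gene = "cyclophilin_A",
                      control_condition = "CTRL")
  joined <- merge(res, sim$truth, by = c("gene", "condition_id"))
  expect_equal(joined$fold_mean, joined$fold, tolerance = 1e-9)
  cl5 <- res[res$gene == "claudin5" & res$condition_id == "TNFa", ]
  expect_equal(cl5$pct_of_control_mean, 239.4, tolerance = 1e-6)
  expect_true(all(res$qc_pass))
})

test_that("missing reference gene is an error", {
  cfg <- noiseless_config()
  sim <- simulate_qpcr_plate(cfg)
  expect_error(analyze_qpcr(sim$readings, "nonexistent_gene", "CTRL"),
               class = "barriertools_missing_gene")
})
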