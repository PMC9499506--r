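# Seed substreams: each assay generator draws from its own deterministic
# stream derived from config$seed so the assays can be simulated in any
# order (or alone) with identical results.
SEED_OFFSETS <- c(clearance = 101L, transport = 211L, qpcr = 307L,
                  mtt = 401L, images = 503L)

with_assay_seed <- function(config, assay, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((config$seed + SEED_OFFSETS[[assay]]) %% .Machine$integer.max)
  force(code)
}

# multiplicative Gaussian measurement noise, clipped at zero
noisy <- function(x, cv) {
  if (cv == 0) return(x)
  pmax(0, x * rnorm(length(x), mean = 1, sd = cv))
}

# endothelial-only PS (uL/min) implied by a Pe (cm/min)
ps_from_pe <- function(pe, surface_cm2) pe * surface_cm2 * UL_PER_CM3

# whole-insert PS: endothelium and filter in series
compose_series <- function(ps_endo, ps_filter) {
  1 / (1 / ps_endo + 1 / ps_filter)
}

# per-condition true Pe at both temperatures from the effect multipliers
condition_pe_truth <- function(config) {
  trans0 <- config$pe_true_total - config$pe_true_paracellular
  config$conditions |>
    dplyr::mutate(
      pe_transcellular = trans0 * .data$trans_mult,
      pe_paracellular = config$pe_true_paracellular * .data$para_mult,
      pe_total = .data$pe_transcellular + .data$pe_paracellular
    ) |>
    dplyr::select("condition_id", "pe_total", "pe_paracellular",
                  "pe_transcellular")
}

#' Simulate a lucifer-yellow clearance (integrity) assay
#'
#' Forward-simulates the 20/40/60-min insert-transfer clearance protocol
#' for every configured condition at 37 and 4 degC, plus matched
#' filter-only (coating) control inserts at both temperatures and a
#' calibration row. Per interval the amount reaching the fresh receiver
#' well is `PS_true * C_donor * dt` under the sink assumption (constant
#' donor concentration); the whole-insert PS is the configured endothelial
#' PS composed in series with the filter PS. 4 degC runs transport only
#' the paracellular component. The donor's final reading is the initial
#' amount minus everything transferred, so the noiseless mass balance is
#' exactly 100 %. Multiplicative Gaussian noise (`noise_cv`) perturbs
#' every reading.
#'
#' With `deplete_donor = TRUE` the donor concentration is instead updated
#' after each transfer; this is more faithful to the physical experiment
#' but biases the sink-assumption analysis slightly low (< 3 % at default
#' settings).
#'
#' @param config A [sim_config()].
#' @param deplete_donor Simulate stepwise donor depletion (default FALSE:
#'   constant-donor sink flux).
#' @return A list with `readings` (long-format plate tibble readable by
#'   [analyze_permeability()]) and `truth` (per condition x temperature
#'   true Pe and PS values).
#' @export
simulate_clearance_assay <- function(config, deplete_donor = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  with_assay_seed(config, "clearance", {
    times <- c(20, 40, 60)
    dt <- diff(c(0, times))
    donor_conc <- 50       # uM lucifer yellow
    dv <- 500; rv <- 1500  # uL
    cal <- 100             # AU per uM
    pe_truth <- condition_pe_truth(config)

    specs <- dplyr::bind_rows(
      tidyr::expand_grid(condition_id = pe_truth$condition_id,
                         filter_type = "cells",
                         temperature_C = c(37, 4),
                         filter = seq_len(config$n_filters)),
      tidyr::expand_grid(condition_id = "FILTER",
                         filter_type = "filter_only",
                         temperature_C = c(37, 4),
                         filter = seq_len(config$n_filters))
    )

    simulate_one <- function(condition_id, filter_type, temperature_C, filter) {
      if (filter_type == "filter_only") {
        ps_insert <- config$psf_true
        pe <- NA_real_
      } else {
        row <- pe_truth[pe_truth$condition_id == condition_id, ]
        pe <- if (temperature_C == 4) row$pe_paracellular else row$pe_total
        ps_insert <- compose_series(ps_from_pe(pe, config$surface_cm2),
                                    config$psf_true)
      }
      initial <- donor_conc * dv  # pmol-equivalent dose
      if (deplete_donor) {
        amt_donor <- initial
        transferred <- numeric(length(dt))
        for (k in seq_along(dt)) {
          transferred[k] <- ps_insert * (amt_donor / dv) * dt[k]
          amt_donor <- amt_donor - transferred[k]
        }
      } else {
        transferred <- ps_insert * donor_conc * dt
      }
      donor_final <- initial - sum(transferred)
      wid <- sprintf("%s_%s_%dC_f%d", condition_id, filter_type,
                     temperature_C, filter)
      dplyr::bind_rows(
        tibble(well_id = wid, condition_id = condition_id,
               filter_type = filter_type, temperature_C = temperature_C,
               compartment = "basolateral", time_min = times,
               signal_AU = noisy(transferred / rv * cal, config$noise_cv)),
        tibble(well_id = wid, condition_id = condition_id,
               filter_type = filter_type, temperature_C = temperature_C,
               compartment = "apical", time_min = max(times),
               signal_AU = noisy(donor_final / dv * cal, config$noise_cv))
      )
    }

    readings <- purrr::pmap_dfr(specs, simulate_one) |>
      dplyr::mutate(plate_id = "SIM1", donor_volume_uL = dv,
                    receiver_volume_uL = rv, donor_conc = donor_conc,
                    .before = 1L)
    calibration <- tibble(
      plate_id = "SIM1", donor_volume_uL = dv, receiver_volume_uL = rv,
      donor_conc = donor_conc, well_id = "CAL1", condition_id = "CAL",
      filter_type = "calibration", temperature_C = NA_real_,
      compartment = NA_character_, time_min = NA_real_, signal_AU = cal
    )
    truth <- pe_truth |>
      dplyr::mutate(ps_filter_true = config$psf_true,
                    surface_cm2 = config$surface_cm2)
    list(readings = dplyr::bind_rows(readings, calibration), truth = truth)
  })
}

#' Simulate a bidirectional amyloid-beta / inulin transport assay
#'
#' Single 30-min interval, both directions, with amyloid-beta(1-40),
#' FITC-inulin and the sucrose integrity tracer co-dosed per insert. The
#' receiver amount is `Papp_true * A * C0 * t`; cytokine conditions scale
#' the amyloid-beta Papp by the configured direction-specific multipliers
#' while the inulin reference is untouched. Donor-final readings account
#' for the transferred amount so the noiseless mass balance is 100 %.
#'
#' @param config A [sim_config()].
#' @return A list with `readings` (long tibble readable by
#'   [analyze_transport()]) and `truth` (per condition x direction x
#'   tracer true Papp).
#' @export
simulate_transport_assay <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_assay_seed(config, "transport", {
    duration <- 30
    conc <- c(abeta_cy5 = 10, fitc_inulin = 1000, sucrose_14C = 100)  # nM
    cal <- c(abeta_cy5 = 100, fitc_inulin = 10, sucrose_14C = 50)     # AU/nM

    truth <- tidyr::expand_grid(
      condition_id = config$conditions$condition_id,
      config$papp_true
    ) |>
      dplyr::left_join(config$conditions, by = "condition_id") |>
      dplyr::mutate(
        mult = dplyr::case_when(
          .data$tracer != "abeta_cy5" ~ 1,
          .data$direction == "influx" ~ .data$abeta_influx_mult,
          TRUE ~ .data$abeta_efflux_mult
        ),
        papp_true = .data$papp * .data$mult
      ) |>
      dplyr::select("condition_id", "direction", "tracer", "papp_true")

    grid <- tidyr::expand_grid(truth, filter = seq_len(config$n_filters))
    vols <- direction_volumes(grid$direction)

    grid <- grid |>
      dplyr::mutate(
        donor_volume_uL = vols$donor_uL,
        receiver_volume_uL = vols$receiver_uL,
        donor_conc = unname(conc[.data$tracer]),
        signal_per_conc = unname(cal[.data$tracer]),
        q = .data$papp_true * config$surface_cm2 *
          (.data$donor_conc * UL_PER_CM3) * duration,
        well_id = sprintf("%s_%s_f%d", .data$condition_id, .data$direction,
                          .data$filter)
      )

    readings <- grid |>
      dplyr::mutate(
        receiver = noisy(.data$q / .data$receiver_volume_uL *
                           .data$signal_per_conc, config$noise_cv),
        donor = noisy((.data$donor_conc * .data$donor_volume_uL - .data$q) /
                        .data$donor_volume_uL * .data$signal_per_conc,
                      config$noise_cv)
      ) |>
      dplyr::select("well_id", "condition_id", "direction", "tracer",
                    "donor_volume_uL", "receiver_volume_uL", "donor_conc",
                    "signal_per_conc", "receiver", "donor") |>
      tidyr::pivot_longer(c("receiver", "donor"), names_to = "compartment",
                          values_to = "signal_AU") |>
      dplyr::mutate(duration_min = duration)

    list(readings = readings, truth = truth)
  })
}

#' Simulate a qPCR Ct plate
#'
#' One Ct table for the configured genes and conditions: per biological
#' sample, triplicate technical wells with
#' `Ct = base_ct(gene) - log2(fold * noise)` where the multiplicative
#' Gaussian noise acts on the linear expression scale. The reference gene
#' has fold 1 in every condition. NRT and NTC control wells are emitted
#' undetermined (NA Ct).
#'
#' @param config A [sim_config()].
#' @return A list with `readings` (Ct tibble readable by [analyze_qpcr()])
#'   and `truth` (gene x condition true fold).
#' @export
simulate_qpcr_plate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_assay_seed(config, "qpcr", {
    genes <- unique(config$qpcr_fold_true$gene)
    conditions <- unique(c("CTRL", config$qpcr_fold_true$condition_id))
    base_ct <- setNames(c(18, 22 + seq_along(genes) * 0.5),
                        c(config$reference_gene, genes))

    truth <- tidyr::expand_grid(
      gene = c(config$reference_gene, genes),
      condition_id = conditions
    ) |>
      dplyr::left_join(config$qpcr_fold_true, by = c("gene", "condition_id")) |>
      dplyr::mutate(fold = dplyr::if_else(
        is.na(.data$fold) | .data$gene == config$reference_gene,
        1, .data$fold))

    wells <- tidyr::expand_grid(
      truth,
      sample = seq_len(config$n_filters),
      replicate = 1:3
    ) |>
      dplyr::mutate(
        sample_id = sprintf("%s_s%d", .data$condition_id, .data$sample),
        ct = base_ct[.data$gene] -
          log2(.data$fold * noisy(rep(1, dplyr::n()), config$noise_cv)),
        well_type = "sample"
      ) |>
      dplyr::select("sample_id", "condition_id", "gene", "replicate",
                    "ct", "well_type")

    controls <- tidyr::expand_grid(
      gene = c(config$reference_gene, genes),
      well_type = c("NRT", "NTC")
    ) |>
      dplyr::mutate(sample_id = .data$well_type, condition_id = "CONTROL",
                    replicate = 1L, ct = NA_real_)

    list(readings = dplyr::bind_rows(wells, controls), truth = truth)
  })
}

#' Simulate an MTT viability plate
#'
#' Per condition and well, the formazan net OD is proportional to the
#' configured viability fraction; a shared background absorbance appears
#' at both 570 and 630 nm, and each reading gets multiplicative noise.
#'
#' @param config A [sim_config()].
#' @return A list with `readings` (tibble readable by [analyze_mtt()]) and
#'   `truth` (condition x viability fraction).
#' @export
simulate_mtt_plate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_assay_seed(config, "mtt", {
    od_scale <- 0.8   # net OD of fully viable control wells
    background <- 0.05
    readings <- tidyr::expand_grid(config$viability_true,
                                   well = seq_len(config$n_filters)) |>
      dplyr::mutate(
        od570 = noisy(.data$viability * od_scale + background,
                      config$noise_cv),
        od630 = noisy(rep(background, dplyr::n()), config$noise_cv)
      ) |>
      dplyr::select("condition_id", "well", "od570", "od630")
    list(readings = readings, truth = config$viability_true)
  })
}

# paint a disk of radius r centred at (cy, cx) into matrix m
paint_disk <- function(m, cy, cx, r, value) {
  ys <- pmax(1, cy - r):pmin(nrow(m), cy + r)
  xs <- pmax(1, cx - r):pmin(ncol(m), cx + r)
  for (y in ys) {
    for (x in xs) {
      if ((y - cy)^2 + (x - cx)^2 <= r^2) m[y, x] <- value
    }
  }
  m
}

#' Render synthetic junctional-stain / nuclei image pairs
#'
#' Builds, per condition and image, a nuclei channel of `nuclei_n`
#' non-overlapping bright disks on a jittered grid and a stain channel
#' whose above-threshold area is painted to an exact pixel count:
#' cell-border lattice lines first (the honeycomb-like junctional
#' phenotype), then widened borders, then scattered cytoplasmic dots to
#' mimic junction-protein delocalization at high stained fractions. The
#' painted fraction equals `stain_fraction_true * stain_mult` for the
#' condition exactly (by construction) before noise.
#'
#' Generator intensities: background 50, stain 800, nuclei 1000. Quantify
#' with `stain_threshold = 400`, `nuclei_threshold = 500`.
#'
#' @param config A [sim_config()].
#' @return A list with `images` (tibble: `condition_id`, `image`,
#'   list-columns `stain` and `nuclei`) and `truth` (per condition true
#'   painted fraction and nuclei count).
#' @export
render_monolayer_images <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_assay_seed(config, "images", {
    np <- config$image_px
    bg <- 50; stain_hi <- 800; nuc_hi <- 1000; nuc_r <- 4
    k <- ceiling(sqrt(config$nuclei_n))
    spacing <- np %/% k
    if (spacing < 2 * nuc_r + 3) {
      abort("image too small for the requested nuclei count.",
            class = "barriertools_invalid_config")
    }

    truth <- config$conditions |>
      dplyr::transmute(
        condition_id = .data$condition_id,
        stain_fraction_true = config$stain_fraction_true * .data$stain_mult,
        nuclei_n = config$nuclei_n
      )
    if (any(truth$stain_fraction_true > 1)) {
      abort("stained fraction above 1 is infeasible.",
            class = "barriertools_invalid_config")
    }

    render_one <- function(frac) {
      # nuclei: one disk per occupied grid cell, jittered, non-overlapping
      nuclei <- matrix(bg, np, np)
      cells <- utils::head(sample(k * k), config$nuclei_n)
      jitter_max <- spacing %/% 2 - nuc_r - 1
      for (cell in cells) {
        gy <- (cell - 1) %/% k
        gx <- (cell - 1) %% k
        cy <- round(gy * spacing + spacing / 2 +
                      sample(-jitter_max:jitter_max, 1))
        cx <- round(gx * spacing + spacing / 2 +
                      sample(-jitter_max:jitter_max, 1))
        cy <- min(max(cy, nuc_r + 1), np - nuc_r)
        cx <- min(max(cx, nuc_r + 1), np - nuc_r)
        nuclei <- paint_disk(nuclei, cy, cx, nuc_r, nuc_hi)
      }

      # stain: candidate pixels in priority order, cut at the exact count
      target <- round(frac * np * np)
      rows <- matrix(seq_len(np), np, np)
      cols <- matrix(seq_len(np), np, np, byrow = TRUE)
      on_line <- (rows %% spacing == 0) | (cols %% spacing == 0)
      widened <- ((rows + 1) %% spacing == 0) | ((cols + 1) %% spacing == 0)
      border_px <- c(which(on_line), which(widened & !on_line))
      rest <- setdiff(seq_len(np * np), border_px)
      candidates <- c(border_px, sample(rest))
      stain <- matrix(bg, np, np)
      if (target > 0) stain[candidates[seq_len(target)]] <- stain_hi
      if (config$noise_cv > 0) {
        stain <- matrix(noisy(as.numeric(stain), config$noise_cv), np, np)
        nuclei <- matrix(noisy(as.numeric(nuclei), config$noise_cv), np, np)
      }
      list(stain = stain, nuclei = nuclei)
    }

    images <- tidyr::expand_grid(truth, image = seq_len(config$n_images)) |>
      dplyr::mutate(pair = purrr::map(.data$stain_fraction_true, render_one),
                    stain = purrr::map(.data$pair, "stain"),
                    nuclei = purrr::map(.data$pair, "nuclei")) |>
      dplyr::select("condition_id", "image", "stain", "nuclei")
    list(images = images, truth = truth)
  })
}

#' Simulate every supported assay at once
#'
#' @param config A [sim_config()].
#' @return Named list of the five generators' outputs: `clearance`,
#'   `transport`, `qpcr`, `mtt`, `images`.
#' @export
simulate_all_assays <- function(config) {
  list(
    clearance = simulate_clearance_assay(config),
    transport = simulate_transport_assay(config),
    qpcr = simulate_qpcr_plate(config),
    mtt = simulate_mtt_plate(config),
    images = render_monolayer_images(config)
  )
}
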