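#' Configuration for the synthetic Transwell assay generator
#'
#' Bundles the ground-truth parameters, effect sizes, noise model and seed
#' that drive every `simulate_*()` generator. The defaults are the control
#' values and effect sizes of the brain-like endothelial cell (BLEC)
#' coculture model the package targets: control lucifer-yellow Pe
#' 0.54e-3 cm/min total with a 0.18e-3 paracellular (4 degC) component;
#' control amyloid-beta(1-40)/inulin Papp pairs 5.14/1.67 (influx) and
#' 4.47/1.41 (efflux) x 1e-6 cm/min; cytokine effect multipliers matching
#' the reported percent changes (TNF-alpha: transcellular +40.1 %,
#' paracellular +175.2 %, efflux quotient -26.9 %; IL-1beta: +94.2 %,
#' +41.3 %, -25.9 %); qPCR fold changes per junctional gene; 10 % DMSO
#' viability 73.5 %.
#'
#' @param pe_true_total Control total Pe at 37 degC, cm/min.
#' @param pe_true_paracellular Control paracellular (4 degC) Pe, cm/min;
#'   must satisfy `0 < pe_true_paracellular <= pe_true_total`.
#' @param psf_true Coated-filter-only PS, uL/min; must exceed the
#'   endothelial PS implied by `pe_true_total` (physical ordering).
#' @param surface_cm2 Filter area, cm^2.
#' @param papp_true Tibble `direction`, `tracer`, `papp` (cm/min) of
#'   control apparent permeabilities.
#' @param conditions Tibble of per-condition effect multipliers:
#'   `condition_id`, `trans_mult`, `para_mult`, `abeta_influx_mult`,
#'   `abeta_efflux_mult`, `stain_mult`.
#' @param qpcr_fold_true Tibble `gene`, `condition_id`, `fold` of true
#'   expression fold changes vs control (reference gene is always fold 1).
#' @param reference_gene Reference gene name used in the Ct table.
#' @param viability_true Tibble `condition_id`, `viability` (fraction of
#'   control, in `[0, 1]` or slightly above for stimulated growth).
#' @param stain_fraction_true Control stained area fraction per image.
#' @param nuclei_n Nuclei per synthetic image (the model's fields hold
#'   about 50 cells per image).
#' @param image_px Side length of the square synthetic images, pixels.
#' @param n_images Images per condition.
#' @param n_filters Replicate filters (or samples / wells) per condition.
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   noise applied to every simulated reading (0.03 = a typical 3 % plate
#'   reader CV; set 0 for noiseless runs).
#' @param seed Integer seed; identical config + seed reproduces every
#'   simulated table exactly.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(pe_true_total = 0.54e-3,
                       pe_true_paracellular = 0.18e-3,
                       psf_true = 2.0,
                       surface_cm2 = 1.12,
                       papp_true = default_papp_true(),
                       conditions = default_conditions(),
                       qpcr_fold_true = default_qpcr_folds(),
                       reference_gene = "cyclophilin_A",
                       viability_true = default_viability(),
                       stain_fraction_true = 0.10,
                       nuclei_n = 50,
                       image_px = 192,
                       n_images = 3,
                       n_filters = 3,
                       noise_cv = 0.03,
                       seed = 1) {
  cfg <- list(
    pe_true_total = pe_true_total,
    pe_true_paracellular = pe_true_paracellular,
    psf_true = psf_true,
    surface_cm2 = surface_cm2,
    papp_true = papp_true,
    conditions = conditions,
    qpcr_fold_true = qpcr_fold_true,
    reference_gene = reference_gene,
    viability_true = viability_true,
    stain_fraction_true = stain_fraction_true,
    nuclei_n = nuclei_n,
    image_px = image_px,
    n_images = n_images,
    n_filters = n_filters,
    noise_cv = noise_cv,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!(cfg$pe_true_paracellular > 0 &&
        cfg$pe_true_paracellular <= cfg$pe_true_total)) {
    abort("need 0 < pe_true_paracellular <= pe_true_total.",
          class = "barriertools_invalid_config")
  }
  if (cfg$noise_cv < 0) {
    abort("noise_cv must be >= 0.", class = "barriertools_invalid_config")
  }
  ps_endo <- cfg$pe_true_total * cfg$surface_cm2 * UL_PER_CM3
  if (!(ps_endo < cfg$psf_true)) {
    abort("endothelial PS implied by pe_true_total must be below psf_true.",
          class = "barriertools_invalid_config")
  }
  # worst-case endothelial PS after effect multipliers must stay below PSf
  trans <- cfg$pe_true_total - cfg$pe_true_paracellular
  pe_max <- max(trans * cfg$conditions$trans_mult +
                  cfg$pe_true_paracellular * cfg$conditions$para_mult)
  if (!(pe_max * cfg$surface_cm2 * UL_PER_CM3 < cfg$psf_true)) {
    abort("a condition's effect multipliers push endothelial PS above psf_true.",
          class = "barriertools_invalid_config")
  }
  if (cfg$stain_fraction_true * max(cfg$conditions$stain_mult) > 1) {
    abort("stained fraction above 1 is infeasible.",
          class = "barriertools_invalid_config")
  }
  structure(cfg, class = "sim_config")
}

#' Default effect-size and ground-truth tables for the generator
#'
#' The tables behind [sim_config()]'s defaults, exported so runs can start
#' from them and override single entries: per-condition pathway and
#' transport multipliers (`default_conditions()`), control Papp per
#' direction and tracer (`default_papp_true()`), true qPCR fold changes
#' per junctional gene (`default_qpcr_folds()`), and viability fractions
#' including the 10 % DMSO toxicity control (`default_viability()`).
#'
#' @return A tibble (see [sim_config()] for the column contracts).
#' @name sim_defaults
NULL

#' @rdname sim_defaults
#' @export
default_conditions <- function() {
  tibble(
    condition_id      = c("CTRL", "TNFa", "IL1b"),
    trans_mult        = c(1, 1.401, 1.942),
    para_mult         = c(1, 2.752, 1.413),
    abeta_influx_mult = c(1, 1, 1),
    abeta_efflux_mult = c(1, 0.731, 0.741),
    stain_mult        = c(1, 2.618, 1)
  )
}

#' @rdname sim_defaults
#' @export
default_papp_true <- function() {
  tibble(
    direction = rep(c("influx", "efflux"), each = 3),
    tracer    = rep(c("abeta_cy5", "fitc_inulin", "sucrose_14C"), 2),
    papp      = c(5.14e-6, 1.67e-6, 1.5e-6,
                  4.47e-6, 1.41e-6, 1.5e-6)
  )
}

#' @rdname sim_defaults
#' @export
default_qpcr_folds <- function() {
  tibble(
    gene = rep(c("zo1", "tricellulin", "occludin", "claudin3", "claudin5",
                 "vecadherin"), 2),
    condition_id = rep(c("TNFa", "IL1b"), each = 6),
    fold = c(0.778, 0.319, 0.337, 0.382, 2.394, 1.00,
             0.519, 0.372, 0.360, 0.187, 1.481, 0.85)
  )
}

#' @rdname sim_defaults
#' @export
default_viability <- function() {
  tibble(condition_id = c("CTRL", "TNFa", "IL1b", "DMSO10"),
         viability = c(1, 1, 1, 0.735))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic Transwell assay configuration\n")
  cat(sprintf("  Pe true (total / paracellular): %.3g / %.3g cm/min\n",
              x$pe_true_total, x$pe_true_paracellular))
  cat(sprintf("  PSf %.3g uL/min, area %.3g cm^2\n", x$psf_true, x$surface_cm2))
  cat(sprintf("  %d conditions, %d filters each, noise CV %.3g, seed %d\n",
              nrow(x$conditions), x$n_filters, x$noise_cv, x$seed))
  invisible(x)
}

#' Read a generator configuration from a YAML run file
#'
#' The file may set any argument of [sim_config()]; tabular arguments
#' (`conditions`, `papp_true`, `qpcr_fold_true`, `viability_true`) are
#' given as YAML lists of records. Unset keys keep their defaults.
#'
#' @param path Path to the YAML file.
#' @return A validated `sim_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  tab_fields <- c("conditions", "papp_true", "qpcr_fold_true", "viability_true")
  for (f in intersect(names(raw), tab_fields)) {
    raw[[f]] <- dplyr::bind_rows(raw[[f]])
  }
  unknown <- setdiff(names(raw), names(formals(sim_config)))
  if (length(unknown) > 0L) {
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")),
          class = "barriertools_invalid_config")
  }
  do.call(sim_config, raw)
}
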