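#' Apparent permeability coefficient for a single-interval transport assay
#'
#' For a 30-min bidirectional Transwell transport experiment the apparent
#' permeability is `Papp = Q / (t * A * C0)` where Q is the amount that
#' reached the receiver compartment, t the duration, A the filter area and
#' C0 the initial donor concentration. With Q derived from the receiver
#' signal, volumes in uL and C0 in the calibration's concentration unit,
#' the result is returned in cm/min (quote as x 1e-6 cm/min).
#'
#' @param receiver_signal Receiver fluorescence at the end (AU), >= 0.
#'   Vectorized.
#' @param signal_per_conc AU per concentration unit (e.g. AU/nM), > 0.
#' @param receiver_volume_uL Receiver compartment volume (1500 uL for
#'   influx, 500 uL for efflux).
#' @param donor_conc Initial donor concentration in the calibration's unit,
#'   > 0 (10 nM amyloid-beta, 1000 nM FITC-inulin).
#' @param duration_min Assay duration, minutes (default 30).
#' @param area_cm2 Filter area (default 1.12).
#' @return Papp in cm/min.
#' @examples
#' # 1.727 fmol in the receiver after 30 min at C0 = 10 nM:
#' compute_papp(1.727 / 1500, 1, 1500, 10) * 1e6  # ~5.14
#' @export
compute_papp <- function(receiver_signal, signal_per_conc,
                         receiver_volume_uL, donor_conc,
                         duration_min = 30, area_cm2 = 1.12) {
  if (!isTRUE(area_cm2 > 0)) abort("`area_cm2` must be > 0.")
  if (!isTRUE(duration_min > 0)) abort("`duration_min` must be > 0.")
  if (any(donor_conc <= 0)) {
    abort("zero or negative donor concentration.",
          class = "barriertools_invalid_assay")
  }
  if (any(receiver_signal < 0)) {
    abort("negative receiver signal.", class = "barriertools_invalid_reading")
  }
  # amount / C0 has units of volume (uL); convert to cm^3
  q_over_c0 <- receiver_signal / signal_per_conc * receiver_volume_uL / donor_conc
  (q_over_c0 / UL_PER_CM3) / (duration_min * area_cm2)
}

#' Transcytosis quotient of a tracer against its paracellular reference
#'
#' Ratio of the tracer's Papp to the Papp of co-dosed FITC-inulin measured
#' on the same filter and in the same direction. Inulin is not actively
#' transported, so the quotient isolates the tracer-specific (receptor /
#' vesicular) component from nonspecific paracellular leak. Compute the
#' ratio per filter and average the ratios across filters (not the ratio
#' of averages).
#'
#' @param papp_tracer,papp_reference Papp values (same units), vectorized
#'   over filters; `papp_reference` must be > 0.
#' @return The per-filter quotient(s), dimensionless.
#' @examples
#' transcytosis_quotient(5.14, 1.67)
#' @export
transcytosis_quotient <- function(papp_tracer, papp_reference) {
  if (any(papp_reference <= 0)) {
    abort("reference Papp must be > 0.",
          class = "barriertools_undefined_quotient")
  }
  papp_tracer / papp_reference
}

#' Percent change of a transcytosis quotient relative to control
#'
#' @param q_treated,q_control Quotients; `q_control` must be > 0.
#' @return `100 * (q_treated - q_control) / q_control`.
#' @examples
#' relative_quotient(2.354, 3.22)  # about -26.9
#' @export
relative_quotient <- function(q_treated, q_control) {
  if (any(q_control <= 0)) abort("`q_control` must be > 0.")
  100 * (q_treated - q_control) / q_control
}

#' Barrier-integrity flag from a co-run integrity tracer
#'
#' Inserts whose integrity-marker (e.g. sucrose) permeability exceeds the
#' control mean by more than 3 control standard deviations are flagged as
#' leaky; their transport measurements should be discarded.
#'
#' @param pe_condition Integrity-marker Pe of the insert(s) under test.
#' @param pe_control Vector of integrity-marker Pe values of control
#'   inserts (>= 3 replicates required).
#' @return Character vector: `"pass"`, `"leaky"` per insert, or
#'   `"not_evaluable"` for all when the control is missing/too small.
#' @export
integrity_flag <- function(pe_condition, pe_control) {
  if (is.null(pe_control) || sum(is.finite(pe_control)) < 3L) {
    return(rep("not_evaluable", length(pe_condition)))
  }
  lim <- mean(pe_control) + 3 * sd(pe_control)
  ifelse(pe_condition > lim, "leaky", "pass")
}

# volumes implied by direction: the apical compartment holds 500 uL and the
# basolateral 1500 uL; direction decides which is donor.
direction_volumes <- function(direction) {
  stopifnot(all(direction %in% c("influx", "efflux")))
  list(
    donor_uL    = ifelse(direction == "influx", 500, 1500),
    receiver_uL = ifelse(direction == "influx", 1500, 500)
  )
}

#' Bidirectional transport analysis with inulin-referenced quotients
#'
#' Computes per-filter Papp for every tracer from a long-format transport
#' table, forms the tracer/reference transcytosis quotient per filter, and
#' summarises Papp and quotient per condition and direction as mean +/-
#' SEM, optionally with the quotient's percent change vs a control
#' condition.
#'
#' @param plate Long-format table, one row per well x tracer x compartment:
#'   columns `well_id`, `condition_id`, `direction` (`influx` / `efflux`),
#'   `tracer`, `compartment` (`receiver` / `donor`), `signal_AU`,
#'   `signal_per_conc`, `donor_conc`, `donor_volume_uL`,
#'   `receiver_volume_uL`, `duration_min`.
#' @param tracer Tracer of interest (default `"abeta_cy5"`).
#' @param reference_tracer Paracellular reference (default `"fitc_inulin"`).
#' @param area_cm2 Filter area.
#' @param control_condition Optional condition used as quotient reference.
#' @return A `transport_summary` tibble per condition x direction with
#'   `n_filters`, `papp_tracer_mean`/`_sem`, `papp_reference_mean`/`_sem`
#'   (cm/min; `*_scaled` in 1e-6 cm/min), `quotient_mean`, `quotient_sem`,
#'   `mass_balance_mean` and, with a control, `quotient_pct_change`.
#' @export
analyze_transport <- function(plate, tracer = "abeta_cy5",
                              reference_tracer = "fitc_inulin",
                              area_cm2 = 1.12, control_condition = NULL) {
  tracers_kept <- c(tracer, reference_tracer)
  per_filter <- plate |>
    dplyr::filter(.data$tracer %in% tracers_kept) |>
    tidyr::pivot_wider(names_from = "compartment", values_from = "signal_AU") |>
    dplyr::mutate(
      papp = compute_papp(.data$receiver, .data$signal_per_conc,
                          .data$receiver_volume_uL, .data$donor_conc,
                          duration_min = .data$duration_min[1L],
                          area_cm2 = area_cm2),
      mass_balance_pct = 100 *
        (.data$receiver / .data$signal_per_conc * .data$receiver_volume_uL +
           .data$donor / .data$signal_per_conc * .data$donor_volume_uL) /
        (.data$donor_conc * .data$donor_volume_uL)
    )

  wide <- per_filter |>
    dplyr::select("well_id", "condition_id", "direction", "tracer",
                  "papp", "mass_balance_pct") |>
    tidyr::pivot_wider(names_from = "tracer",
                       values_from = c("papp", "mass_balance_pct")) |>
    dplyr::mutate(
      quotient = transcytosis_quotient(.data[[paste0("papp_", tracer)]],
                                       .data[[paste0("papp_", reference_tracer)]])
    )

  out <- wide |>
    dplyr::group_by(.data$condition_id, .data$direction) |>
    dplyr::summarise(
      n_filters = dplyr::n(),
      papp_tracer_mean = mean(.data[[paste0("papp_", tracer)]]),
      papp_tracer_sem = sem(.data[[paste0("papp_", tracer)]]),
      papp_reference_mean = mean(.data[[paste0("papp_", reference_tracer)]]),
      papp_reference_sem = sem(.data[[paste0("papp_", reference_tracer)]]),
      quotient_mean = mean(.data$quotient),
      quotient_sem = sem(.data$quotient),
      mass_balance_mean = mean(.data[[paste0("mass_balance_pct_", tracer)]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      papp_tracer_scaled = .data$papp_tracer_mean * 1e6,
      papp_reference_scaled = .data$papp_reference_mean * 1e6
    )

  if (!is.null(control_condition)) {
    ctl <- out |>
      dplyr::filter(.data$condition_id == control_condition) |>
      dplyr::select("direction", q_control = "quotient_mean")
    out <- out |>
      dplyr::left_join(ctl, by = "direction") |>
      dplyr::mutate(quotient_pct_change =
                      relative_quotient(.data$quotient_mean, .data$q_control)) |>
      dplyr::select(-"q_control")
  }
  class(out) <- c("transport_summary", class(out))
  out
}
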