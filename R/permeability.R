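#' Cumulative cleared-volume series for one Transwell insert
#'
#' Converts the fluorescence read in the receiver (basolateral) well at each
#' transfer of the insert into the cumulative volume of donor solution
#' cleared across the monolayer. Because the insert is moved to a fresh
#' receiver well at every interval, each reading measures only that
#' interval's flux; the clearance curve is their running sum, with the
#' origin (0, 0) prepended.
#'
#' The cleared volume of interval j is
#' `(signal_j / signal_per_conc) * receiver_volume / donor_conc`:
#' receiver amount divided by the (nominal, sink-assumption) donor
#' concentration.
#'
#' @param time_min End time of each transfer interval, minutes, strictly
#'   increasing, first value > 0.
#' @param receiver_signal Blank-subtracted receiver fluorescence (AU) for
#'   each interval, same length as `time_min`, all non-negative.
#' @param signal_per_conc Calibration factor, AU per concentration unit
#'   (must use the same concentration unit as `donor_conc`), > 0.
#' @param receiver_volume_uL Receiver well volume (default 1500 uL).
#' @param donor_conc Nominal donor concentration (default 50, the uM
#'   lucifer-yellow dose), > 0.
#' @return A tibble with columns `time_min` and `cleared_uL`, the first row
#'   being (0, 0).
#' @examples
#' cleared_volume_series(c(20, 40, 60), c(500, 500, 500),
#'                       signal_per_conc = 100)
#' @export
cleared_volume_series <- function(time_min, receiver_signal,
                                  signal_per_conc,
                                  receiver_volume_uL = 1500,
                                  donor_conc = 50) {
  if (length(time_min) != length(receiver_signal)) {
    abort("`time_min` and `receiver_signal` must have equal length.")
  }
  if (length(time_min) < 1L || any(!is.finite(time_min))) {
    abort("at least one finite interval time is required.")
  }
  if (any(diff(c(0, time_min)) <= 0)) {
    abort("interval times must be strictly increasing and start after 0.",
          class = "barriertools_invalid_series")
  }
  if (any(receiver_signal < 0)) {
    abort("negative receiver signal.", class = "barriertools_invalid_reading")
  }
  if (!isTRUE(signal_per_conc > 0)) abort("`signal_per_conc` must be > 0.")
  if (!isTRUE(donor_conc > 0)) abort("`donor_conc` must be > 0.")
  if (!isTRUE(receiver_volume_uL > 0)) abort("`receiver_volume_uL` must be > 0.")

  interval_cleared <- receiver_signal / signal_per_conc *
    receiver_volume_uL / donor_conc
  tibble(
    time_min   = c(0, time_min),
    cleared_uL = c(0, cumsum(interval_cleared))
  )
}

#' Fit the clearance slope (PS, permeability-surface-area product)
#'
#' Ordinary least-squares fit of cleared volume against time with a free
#' intercept; the origin is an ordinary data point. The slope is the PS
#' product in uL/min.
#'
#' @param series A data frame with columns `time_min` and `cleared_uL`, as
#'   returned by [cleared_volume_series()].
#' @return A `ps_fit` object with elements `slope` (uL/min), `intercept`
#'   (uL), `r_squared` and `n_points`. Use [tidy()] / [glance()] to get it
#'   as a tibble.
#' @examples
#' fit_ps(tibble::tibble(time_min = c(0, 20, 40, 60),
#'                       cleared_uL = c(0, 10, 20, 30)))
#' @export
fit_ps <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("time_min", "cleared_uL") %in% names(series)))
  t <- series$time_min
  v <- series$cleared_uL
  if (length(t) < 2L) abort("at least 2 points are required to fit PS.")
  if (diff(range(t)) == 0) {
    abort("all times identical: degenerate fit.",
          class = "barriertools_degenerate_fit")
  }
  fit <- lm(v ~ t)
  ss_tot <- sum((v - mean(v))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(fit$residuals^2) / ss_tot
  structure(
    list(slope = unname(coef(fit)[2L]),
         intercept = unname(coef(fit)[1L]),
         r_squared = r2,
         n_points = length(t)),
    class = "ps_fit"
  )
}

#' @export
print.ps_fit <- function(x, ...) {
  cat(sprintf("PS fit: slope %.4g uL/min, intercept %.3g uL, r^2 %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Correct a whole-insert PS for the resistance of the empty filter
#'
#' The coated filter and the endothelial monolayer are two permeation
#' barriers in series, so their resistances (1/PS) add:
#' `1/PSt = 1/PSe + 1/PSf`, hence the monolayer-only product is
#' `PSe = 1/(1/PSt - 1/PSf)`. This subtractive form is the default
#' (`form = "corrected"`) and guarantees `PSe >= PSt`. The additive variant
#' `1/PSe = 1/PSt + 1/PSf` is available as `form = "as_printed"` for
#' comparison with reports that quote it; it makes the monolayer appear
#' more permeable than filter plus monolayer.
#'
#' @param ps_total PSt, slope for filter + cells, uL/min, > 0. Vectorized.
#' @param ps_filter PSf, slope for the coated filter alone, uL/min, > 0.
#' @param form `"corrected"` (series-resistance subtraction, default) or
#'   `"as_printed"`.
#' @return PSe in uL/min.
#' @examples
#' correct_series_resistance(0.4644, 2.0)  # 0.6048 uL/min
#' @export
correct_series_resistance <- function(ps_total, ps_filter,
                                      form = c("corrected", "as_printed")) {
  form <- match.arg(form)
  if (any(ps_total <= 0) || any(ps_filter <= 0)) {
    abort("`ps_total` and `ps_filter` must be > 0.")
  }
  if (form == "corrected") {
    if (any(ps_total >= ps_filter)) {
      abort(paste("PSt >= PSf: the insert with cells cannot be more permeable",
                  "than the blank filter; check for swapped inputs."),
            class = "barriertools_cells_more_permeable")
    }
    1 / (1 / ps_total - 1 / ps_filter)
  } else {
    1 / (1 / ps_total + 1 / ps_filter)
  }
}

#' Endothelial permeability coefficient from a PS product
#'
#' `Pe = PSe / S` with PSe converted from uL/min to cm^3/min, giving Pe in
#' cm/min.
#'
#' @param ps_e PSe in uL/min (vectorized).
#' @param surface_cm2 Filter growth area in cm^2 (default 1.12, the 12-well
#'   Transwell insert).
#' @return Pe in cm/min (multiply by 1e3 to quote in the conventional
#'   1e-3 cm/min units).
#' @examples
#' pe_from_ps(0.6048)  # 0.54e-3 cm/min
#' @export
pe_from_ps <- function(ps_e, surface_cm2 = 1.12) {
  if (!isTRUE(surface_cm2 > 0)) {
    abort("`surface_cm2` must be > 0.", class = "barriertools_invalid_geometry")
  }
  (ps_e / UL_PER_CM3) / surface_cm2
}

#' Tracer mass balance for one insert
#'
#' Recovered amount (sum of all receiver interval amounts plus the donor
#' compartment at the end) as a percentage of the dose initially added to
#' the donor compartment. Runs outside 80--120 % (bounds inclusive) fail
#' QC and should not contribute to Pe.
#'
#' @param receiver_signal Vector of interval receiver signals (AU).
#' @param donor_final_signal Donor signal at the end of the experiment (AU).
#' @param signal_per_conc Calibration factor, AU per concentration unit.
#' @param donor_conc Nominal initial donor concentration, > 0.
#' @param donor_volume_uL,receiver_volume_uL Compartment volumes (uL).
#' @param bounds Inclusive QC bounds in percent, default `c(80, 120)`.
#' @return A one-row tibble with `mass_balance_pct` and `qc_pass`.
#' @export
mass_balance <- function(receiver_signal, donor_final_signal,
                         signal_per_conc, donor_conc = 50,
                         donor_volume_uL = 500, receiver_volume_uL = 1500,
                         bounds = c(80, 120)) {
  if (!isTRUE(donor_conc > 0) || !isTRUE(donor_volume_uL > 0)) {
    abort("initial donor amount must be > 0.")
  }
  initial <- donor_conc * donor_volume_uL
  recovered <- sum(receiver_signal / signal_per_conc * receiver_volume_uL) +
    donor_final_signal / signal_per_conc * donor_volume_uL
  pct <- 100 * recovered / initial
  tibble(mass_balance_pct = pct,
         qc_pass = pct >= bounds[1] & pct <= bounds[2])
}

#' Split total permeability into paracellular and transcellular pathways
#'
#' At 4 degrees C all active (vesicular / receptor-mediated) transport is
#' blocked, so the 4 degC permeability isolates the paracellular route and
#' the transcellular component is the difference
#' `pe_transcellular = pe_total - pe_paracellular`. A negative difference
#' is physically suspect (it would mean cooling increased permeability);
#' it is reported as-is with `negative_transcellular = TRUE`, never clamped.
#'
#' @param pe_total Pe at 37 degC, cm/min.
#' @param pe_paracellular Pe at 4 degC, cm/min.
#' @param control Optional control decomposition (a one-row data frame as
#'   returned by this function, or a named vector with `pe_total`,
#'   `pe_paracellular`, `pe_transcellular`); when supplied each component is
#'   also expressed as percent of control.
#' @return A one-row tibble with `pe_total`, `pe_paracellular`,
#'   `pe_transcellular`, `negative_transcellular`, and when `control` is
#'   given `pct_total`, `pct_paracellular`, `pct_transcellular`.
#' @examples
#' decompose_pathways(0.54e-3, 0.18e-3)
#' @export
decompose_pathways <- function(pe_total, pe_paracellular, control = NULL) {
  trans <- pe_total - pe_paracellular
  if (trans < 0) {
    warn("transcellular Pe is negative; reported unclamped.",
         class = "barriertools_negative_transcellular")
  }
  out <- tibble(
    pe_total = pe_total,
    pe_paracellular = pe_paracellular,
    pe_transcellular = trans,
    negative_transcellular = trans < 0
  )
  if (!is.null(control)) {
    ctl <- if (is.data.frame(control)) as.list(control[1L, ]) else as.list(control)
    out$pct_total <- 100 * pe_total / ctl$pe_total
    out$pct_paracellular <- 100 * pe_paracellular / ctl$pe_paracellular
    out$pct_transcellular <- 100 * trans / ctl$pe_transcellular
  }
  out
}

# Per-well clearance analysis: slope, mass balance. `well` is the long-form
# reading table filtered to one well (basolateral interval rows + the final
# apical row).
analyze_clearance_well <- function(well, signal_per_conc) {
  recv <- dplyr::filter(well, .data$compartment == "basolateral")
  recv <- dplyr::arrange(recv, .data$time_min)
  donor <- dplyr::filter(well, .data$compartment == "apical")
  if (nrow(donor) != 1L) {
    abort("expected exactly one final apical (donor) reading per well.")
  }
  dv <- well$donor_volume_uL[1L]
  rv <- well$receiver_volume_uL[1L]
  dc <- well$donor_conc[1L]
  series <- cleared_volume_series(recv$time_min, recv$signal_AU,
                                  signal_per_conc,
                                  receiver_volume_uL = rv, donor_conc = dc)
  fit <- fit_ps(series)
  mb <- mass_balance(recv$signal_AU, donor$signal_AU, signal_per_conc,
                     donor_conc = dc, donor_volume_uL = dv,
                     receiver_volume_uL = rv)
  tibble(ps = fit$slope, intercept = fit$intercept,
         r_squared = fit$r_squared, n_points = fit$n_points,
         mass_balance_pct = mb$mass_balance_pct, qc_pass = mb$qc_pass)
}

plate_calibration <- function(plate) {
  cal <- dplyr::filter(plate, .data$filter_type == "calibration")
  if (nrow(cal) == 0L) {
    abort("no calibration rows (filter_type == 'calibration') found.")
  }
  mean(cal$signal_AU)
}

#' Per-condition endothelial permeability from a long-format plate table
#'
#' Full clearance-assay pipeline: per well, the cleared-volume series is
#' accumulated and its slope fitted; the filter-only wells at the same
#' temperature give PSf; each cells well's PSt is corrected for the filter
#' in series to PSe and converted to Pe; wells failing the 80--120 % mass
#' balance are excluded from the condition mean. Pe is summarised per
#' condition and temperature as mean +/- SEM over replicate filters.
#'
#' @param plate Long-format readings, one row per reading, with columns
#'   `well_id`, `condition_id`, `filter_type` (`cells`, `filter_only` or
#'   `calibration`), `temperature_C`, `compartment` (`apical` /
#'   `basolateral`), `time_min`, `signal_AU`, `donor_volume_uL`,
#'   `receiver_volume_uL`, `donor_conc`. Calibration rows carry the AU per
#'   concentration-unit factor in `signal_AU`.
#' @param surface_cm2 Filter area, cm^2.
#' @param series_form Passed to [correct_series_resistance()].
#' @return A `pe_summary` tibble, one row per condition x temperature:
#'   `condition_id`, `temperature_C`, `n_filters` (QC-passing), `ps_filter`,
#'   `ps_total_mean`, `ps_e_mean`, `pe_mean`, `pe_sem` (cm/min),
#'   `pe_mean_scaled` (1e-3 cm/min units), `mass_balance_mean`,
#'   `n_qc_fail`.
#' @export
analyze_permeability <- function(plate, surface_cm2 = 1.12,
                                 series_form = c("corrected", "as_printed")) {
  series_form <- match.arg(series_form)
  cal <- plate_calibration(plate)

  wells <- plate |>
    dplyr::filter(.data$filter_type %in% c("cells", "filter_only")) |>
    dplyr::group_by(.data$well_id, .data$condition_id, .data$filter_type,
                    .data$temperature_C) |>
    dplyr::group_modify(~ analyze_clearance_well(.x, cal)) |>
    dplyr::ungroup()

  psf <- wells |>
    dplyr::filter(.data$filter_type == "filter_only") |>
    dplyr::group_by(.data$temperature_C) |>
    dplyr::summarise(ps_filter = mean(.data$ps), .groups = "drop")
  if (nrow(psf) == 0L) abort("no filter-only control wells found.")

  cells <- wells |>
    dplyr::filter(.data$filter_type == "cells") |>
    dplyr::left_join(psf, by = "temperature_C") |>
    dplyr::mutate(
      ps_e = correct_series_resistance(.data$ps, .data$ps_filter,
                                       form = series_form),
      pe = pe_from_ps(.data$ps_e, surface_cm2)
    )

  out <- cells |>
    dplyr::group_by(.data$condition_id, .data$temperature_C) |>
    dplyr::summarise(
      n_filters = sum(.data$qc_pass),
      n_qc_fail = sum(!.data$qc_pass),
      ps_filter = .data$ps_filter[1L],
      ps_total_mean = mean(.data$ps[.data$qc_pass]),
      ps_e_mean = mean(.data$ps_e[.data$qc_pass]),
      pe_mean = mean(.data$pe[.data$qc_pass]),
      pe_sem = sem(.data$pe[.data$qc_pass]),
      mass_balance_mean = mean(.data$mass_balance_pct),
      .groups = "drop"
    ) |>
    dplyr::mutate(pe_mean_scaled = .data$pe_mean * 1e3)
  class(out) <- c("pe_summary", class(out))
  out
}

#' Pathway decomposition for every condition of a permeability summary
#'
#' Pairs the 37 degC and 4 degC rows of [analyze_permeability()] output by
#' `condition_id` and decomposes each condition's Pe into paracellular
#' (4 degC) and transcellular (difference) components, expressed as percent
#' of the control condition when one is named.
#'
#' @param pe_summary Output of [analyze_permeability()].
#' @param control_condition Optional `condition_id` used as the 100 %
#'   reference.
#' @return A `decomposition_summary` tibble, one row per condition, with
#'   the Pe triplet (cm/min), its `*_scaled` (1e-3 cm/min) versions and
#'   percent-of-control columns.
#' @export
decompose_conditions <- function(pe_summary, control_condition = NULL) {
  wide <- pe_summary |>
    dplyr::select("condition_id", "temperature_C", "pe_mean") |>
    tidyr::pivot_wider(names_from = "temperature_C", values_from = "pe_mean",
                       names_prefix = "pe_")
  if (!all(c("pe_37", "pe_4") %in% names(wide))) {
    abort("both 37 and 4 degC runs are required for decomposition.")
  }
  ctl <- NULL
  if (!is.null(control_condition)) {
    ctl_row <- dplyr::filter(wide, .data$condition_id == control_condition)
    if (nrow(ctl_row) != 1L) abort("control condition not found.")
    ctl <- decompose_pathways(ctl_row$pe_37, ctl_row$pe_4)
  }
  out <- wide |>
    dplyr::group_by(.data$condition_id) |>
    dplyr::group_modify(~ decompose_pathways(.x$pe_37, .x$pe_4, control = ctl)) |>
    dplyr::ungroup() |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("pe_"), ~ .x * 1e3,
                                .names = "{.col}_scaled"))
  class(out) <- c("decomposition_summary", class(out))
  out
}
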