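#' Mean Ct per sample and gene with no-template / no-RT QC
#'
#' Averages the determined technical replicates (triplicate wells) of each
#' sample-gene pair. A gene fails QC for the whole plate when any of its
#' NRT (no reverse transcriptase) or NTC (no template) control wells
#' amplifies within `ntc_gate_cycles` of the sample mean — close enough
#' that genomic DNA carry-over or primer dimers could contaminate the
#' quantification. Undetermined control wells (NA Ct) pass.
#'
#' @param records Tibble with columns `sample_id`, `condition_id`, `gene`,
#'   `replicate`, `ct` (NA = undetermined) and `well_type`
#'   (`sample` / `NRT` / `NTC`).
#' @param ntc_gate_cycles Proximity gate in cycles (default 5).
#' @return Tibble per sample x gene: `condition_id`, `ct_mean`,
#'   `n_replicates`, `qc_pass`.
#' @export
summarize_ct <- function(records, ntc_gate_cycles = 5) {
  samples <- records |>
    dplyr::filter(.data$well_type == "sample") |>
    dplyr::group_by(.data$sample_id, .data$condition_id, .data$gene) |>
    dplyr::summarise(
      ct_mean = mean(.data$ct[!is.na(.data$ct)]),
      n_replicates = sum(!is.na(.data$ct)),
      .groups = "drop"
    )
  if (any(samples$n_replicates == 0L)) {
    bad <- samples[samples$n_replicates == 0L, ]
    abort(sprintf("all replicates undetermined for %s / %s.",
                  bad$sample_id[1L], bad$gene[1L]),
          class = "barriertools_missing_gene")
  }
  controls <- records |>
    dplyr::filter(.data$well_type %in% c("NRT", "NTC"), !is.na(.data$ct)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(control_ct_min = suppressWarnings(min(.data$ct)),
                     .groups = "drop")
  samples |>
    dplyr::left_join(controls, by = "gene") |>
    dplyr::mutate(
      qc_pass = is.na(.data$control_ct_min) |
        (.data$control_ct_min - .data$ct_mean) > ntc_gate_cycles
    ) |>
    dplyr::select(-"control_ct_min")
}

#' Relative expression by the delta-delta-Ct method
#'
#' `dCt = Ct_target - Ct_reference` within each condition;
#' `ddCt = dCt_treated - dCt_control`; fold change `2^(-ddCt)`, also given
#' as percent of control (`100 * fold`). No primer-efficiency correction is
#' applied; efficiencies are QC metadata (see [efficiency_qc()]).
#'
#' @param ct_target_control,ct_reference_control Mean Cts in the control
#'   condition for the target and reference gene.
#' @param ct_target_treated,ct_reference_treated Same for the treated
#'   condition.
#' @return One-row tibble: `delta_ct_control`, `delta_ct_treated`, `ddct`,
#'   `fold`, `pct_of_control`.
#' @examples
#' ddct_fold(25, 20, 23.741, 20)  # fold 2.394, +139.4 % vs control
#' @export
ddct_fold <- function(ct_target_control, ct_reference_control,
                      ct_target_treated, ct_reference_treated) {
  if (any(is.na(c(ct_target_control, ct_reference_control,
                  ct_target_treated, ct_reference_treated)))) {
    abort("all four mean Cts must be available.",
          class = "barriertools_missing_gene")
  }
  dct_c <- ct_target_control - ct_reference_control
  dct_t <- ct_target_treated - ct_reference_treated
  ddct <- dct_t - dct_c
  fold <- 2^(-ddct)
  tibble(delta_ct_control = dct_c, delta_ct_treated = dct_t,
         ddct = ddct, fold = fold, pct_of_control = 100 * fold)
}

#' Primer-efficiency QC gate
#'
#' Amplification efficiencies far from 100 % bias plain delta-delta-Ct
#' quantification; pairs outside the accepted band are flagged so their
#' fold changes are read with caution.
#'
#' @param efficiency_pct Efficiency in percent (vectorized).
#' @param bounds Accepted band, default `c(85, 115)` percent.
#' @return Logical: `TRUE` = pass, `FALSE` = warn.
#' @export
efficiency_qc <- function(efficiency_pct, bounds = c(85, 115)) {
  efficiency_pct >= bounds[1] & efficiency_pct <= bounds[2]
}

#' Full qPCR plate analysis
#'
#' Summarises triplicate Cts per sample, forms per-sample dCt against the
#' reference gene, anchors ddCt on the mean control dCt, and reports the
#' per-sample fold changes per gene x condition as mean +/- SEM percent of
#' control.
#'
#' @param records Ct table as for [summarize_ct()].
#' @param reference_gene Stable reference gene (e.g. cyclophilin A).
#' @param control_condition Condition used as the 100 % anchor.
#' @param ntc_gate_cycles Passed to [summarize_ct()].
#' @return A `qpcr_summary` tibble per gene x condition: `n_samples`,
#'   `fold_mean`, `fold_sem`, `pct_of_control_mean`, `pct_of_control_sem`,
#'   `qc_pass`.
#' @export
analyze_qpcr <- function(records, reference_gene, control_condition,
                         ntc_gate_cycles = 5) {
  ct <- summarize_ct(records, ntc_gate_cycles = ntc_gate_cycles)
  if (!reference_gene %in% ct$gene) {
    abort("reference gene not found in the Ct table.",
          class = "barriertools_missing_gene")
  }
  ref <- ct |>
    dplyr::filter(.data$gene == reference_gene) |>
    dplyr::select("sample_id", ct_ref = "ct_mean")
  dct <- ct |>
    dplyr::filter(.data$gene != reference_gene) |>
    dplyr::left_join(ref, by = "sample_id") |>
    dplyr::mutate(dct = .data$ct_mean - .data$ct_ref)
  anchor <- dct |>
    dplyr::filter(.data$condition_id == control_condition) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(dct_control = mean(.data$dct), .groups = "drop")
  if (nrow(anchor) == 0L) abort("control condition not found in Ct table.")
  out <- dct |>
    dplyr::left_join(anchor, by = "gene") |>
    dplyr::mutate(fold = 2^(-(.data$dct - .data$dct_control))) |>
    dplyr::group_by(.data$gene, .data$condition_id) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      fold_mean = mean(.data$fold),
      fold_sem = sem(.data$fold),
      pct_of_control_mean = 100 * mean(.data$fold),
      pct_of_control_sem = 100 * sem(.data$fold),
      qc_pass = all(.data$qc_pass),
      .groups = "drop"
    )
  class(out) <- c("qpcr_summary", class(out))
  out
}

#' Densitometry percent-of-control after loading-control normalization
#'
#' Each band density is divided by the beta-actin density of the same lane,
#' and the condition's normalized ratio is expressed relative to the
#' control lane's ratio.
#'
#' @param band_density,actin_density Densities of the target band and the
#'   actin band in the condition lane (AU); `actin_density` > 0.
#' @param control_band_density,control_actin_density Same for the control
#'   lane.
#' @return Percent of control (vectorized).
#' @examples
#' densitometry_pct_of_control(0.5, 1, 1, 1)  # 50
#' @export
densitometry_pct_of_control <- function(band_density, actin_density,
                                        control_band_density,
                                        control_actin_density) {
  if (any(actin_density <= 0) || any(control_actin_density <= 0)) {
    abort("actin densities must be > 0.")
  }
  ctl_ratio <- control_band_density / control_actin_density
  if (any(ctl_ratio <= 0)) {
    abort("control band/actin ratio must be > 0.")
  }
  100 * (band_density / actin_density) / ctl_ratio
}

#' Per-protein densitometry summary against a control condition
#'
#' @param records Tibble with columns `condition_id`, `protein`,
#'   `band_density`, `actin_density` (one row per lane / replicate).
#' @param control_condition Condition used as the 100 % reference; its
#'   mean normalized ratio anchors the percentages.
#' @return A tibble per protein x condition with `n`, `pct_of_control_mean`
#'   and `pct_of_control_sem`.
#' @export
analyze_densitometry <- function(records, control_condition) {
  ratios <- records |>
    dplyr::mutate(ratio = .data$band_density / .data$actin_density)
  anchor <- ratios |>
    dplyr::filter(.data$condition_id == control_condition) |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(control_ratio = mean(.data$ratio), .groups = "drop")
  if (nrow(anchor) == 0L) abort("control condition not found.")
  ratios |>
    dplyr::left_join(anchor, by = "protein") |>
    dplyr::mutate(pct = 100 * .data$ratio / .data$control_ratio) |>
    dplyr::group_by(.data$protein, .data$condition_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      pct_of_control_mean = mean(.data$pct),
      pct_of_control_sem = sem(.data$pct),
      .groups = "drop"
    )
}
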