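#' Relative cell viability from a dual-wavelength MTT reading
#'
#' `100 * (OD570 - OD630)_condition / (OD570 - OD630)_control`: the
#' formazan absorbance at 570 nm, background-corrected at 630 nm, relative
#' to untreated cells.
#'
#' @param od570,od630 Condition readings (AU). Vectorized.
#' @param control_od570,control_od630 Control readings (may be means of
#'   replicate control wells); the control net OD must be > 0.
#' @return Percent viability.
#' @examples
#' mtt_viability(0.638, 0.05, 0.85, 0.05)  # 73.5
#' @export
mtt_viability <- function(od570, od630, control_od570, control_od630) {
  ctl_net <- control_od570 - control_od630
  if (any(ctl_net <= 0)) abort("control net OD must be > 0.")
  100 * (od570 - od630) / ctl_net
}

#' Per-condition MTT viability summary
#'
#' Each well's net OD is referenced to the mean control net OD; conditions
#' are summarised as mean +/- SEM viability.
#'
#' @param records Tibble with `condition_id`, `od570`, `od630`, one row per
#'   well.
#' @param control_condition The 100 % reference condition.
#' @return An `mtt_summary` tibble per condition: `n`, `viability_mean`,
#'   `viability_sem`.
#' @export
analyze_mtt <- function(records, control_condition) {
  ctl <- dplyr::filter(records, .data$condition_id == control_condition)
  if (nrow(ctl) == 0L) abort("control condition not found.")
  ctl_net <- mean(ctl$od570 - ctl$od630)
  if (ctl_net <= 0) abort("control net OD must be > 0.")
  out <- records |>
    dplyr::mutate(viability = 100 * (.data$od570 - .data$od630) / ctl_net) |>
    dplyr::group_by(.data$condition_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      viability_mean = mean(.data$viability),
      viability_sem = sem(.data$viability),
      .groups = "drop"
    )
  class(out) <- c("mtt_summary", class(out))
  out
}

# 8-connected component labelling of a logical matrix by iterative
# flood fill. Returns an integer matrix of labels (0 = background).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  next_label <- 0L
  idx <- which(mask)
  offsets <- expand.grid(dr = -1:1, dc = -1:1)
  offsets <- offsets[!(offsets$dr == 0 & offsets$dc == 0), ]
  for (start in idx) {
    if (labels[start] != 0L) next
    next_label <- next_label + 1L
    stack <- start
    labels[start] <- next_label
    while (length(stack) > 0L) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((p - 1L) %% nr) + 1L
      c <- ((p - 1L) %/% nr) + 1L
      nbr_r <- r + offsets$dr
      nbr_c <- c + offsets$dc
      ok <- nbr_r >= 1L & nbr_r <= nr & nbr_c >= 1L & nbr_c <= nc
      nbr <- (nbr_c[ok] - 1L) * nr + nbr_r[ok]
      nbr <- nbr[mask[nbr] & labels[nbr] == 0L]
      labels[nbr] <- next_label
      stack <- c(stack, nbr)
    }
  }
  labels
}

#' Count nuclei in a DAPI-like channel
#'
#' Thresholds the nuclei channel and counts 8-connected components with at
#' least `min_area_px` pixels; smaller specks are rejected as debris.
#'
#' @param nuclei_channel Numeric matrix of intensities.
#' @param threshold Intensity above which a pixel belongs to a nucleus.
#' @param min_area_px Minimum component area in pixels (default 20).
#' @return Integer count. An empty (all-background) image returns 0 with a
#'   warning.
#' @export
count_nuclei <- function(nuclei_channel, threshold, min_area_px = 20) {
  if (length(nuclei_channel) == 0L) {
    warn("empty nuclei channel.")
    return(0L)
  }
  mask <- nuclei_channel >= threshold
  if (!any(mask)) {
    warn("no above-threshold pixels in nuclei channel.")
    return(0L)
  }
  labels <- label_components(mask)
  sizes <- tabulate(labels[labels > 0L])
  sum(sizes >= min_area_px)
}

#' Stained area fraction of an image, normalized by nuclei count
#'
#' Fraction of pixels at or above the stain threshold over all pixels,
#' divided by the number of nuclei in the paired DAPI channel. Because the
#' acquisition threshold is fixed per stain within an experiment, the
#' normalized fractions of different conditions are comparable and are
#' reported as percent of control downstream.
#'
#' @param stain_channel Numeric matrix of stain intensities.
#' @param threshold Fixed per-stain intensity threshold, > 0.
#' @param nuclei_count Number of nuclei in the image (>= 1), e.g. from
#'   [count_nuclei()].
#' @return One-row tibble: `area_fraction` (in `[0, 1]`), `nuclei_count`,
#'   `normalized_fraction`.
#' @export
area_fraction <- function(stain_channel, threshold, nuclei_count) {
  if (!isTRUE(threshold > 0)) abort("`threshold` must be > 0.")
  if (!isTRUE(nuclei_count >= 1)) {
    abort("at least one nucleus is required to normalize.",
          class = "barriertools_not_evaluable")
  }
  frac <- mean(stain_channel >= threshold)
  tibble(area_fraction = frac,
         nuclei_count = as.integer(nuclei_count),
         normalized_fraction = frac / nuclei_count)
}

#' Quantify one stain / nuclei image pair
#'
#' Convenience wrapper: counts nuclei in the DAPI channel, then computes
#' the nuclei-normalized stained area fraction.
#'
#' @param stain_channel,nuclei_channel Same-dimension intensity matrices.
#' @param stain_threshold Fixed per-stain threshold.
#' @param nuclei_threshold Threshold for the nuclei channel.
#' @param min_area_px Minimum nucleus area (pixels).
#' @return One-row tibble as [area_fraction()].
#' @export
quantify_stain_image <- function(stain_channel, nuclei_channel,
                                 stain_threshold, nuclei_threshold,
                                 min_area_px = 20) {
  if (!all(dim(stain_channel) == dim(nuclei_channel))) {
    abort("stain and nuclei channels must have the same dimensions.")
  }
  n <- count_nuclei(nuclei_channel, nuclei_threshold, min_area_px)
  area_fraction(stain_channel, stain_threshold, n)
}

#' Summarise per-image area fractions as percent of control
#'
#' @param records Tibble with `condition_id` and `normalized_fraction`,
#'   one row per image (e.g. rows of [quantify_stain_image()]).
#' @param control_condition The 100 % reference condition.
#' @return Tibble per condition: `n_images`, `pct_of_control_mean`,
#'   `pct_of_control_sem`.
#' @export
summarize_area_fractions <- function(records, control_condition) {
  ctl <- dplyr::filter(records, .data$condition_id == control_condition)
  if (nrow(ctl) == 0L) abort("control condition not found.")
  anchor <- mean(ctl$normalized_fraction)
  if (anchor <= 0) abort("control mean normalized fraction must be > 0.")
  records |>
    dplyr::group_by(.data$condition_id) |>
    dplyr::summarise(
      n_images = dplyr::n(),
      pct_of_control_mean = 100 * mean(.data$normalized_fraction) / anchor,
      pct_of_control_sem = 100 * sem(.data$normalized_fraction) / anchor,
      .groups = "drop"
    )
}
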