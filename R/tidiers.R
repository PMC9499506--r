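#' Tidy a clearance-slope fit
#'
#' @param x A `ps_fit` from [fit_ps()].
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`.
#' @export
tidy.ps_fit <- function(x, ...) {
  tibble(term = c("intercept_uL", "slope_uL_per_min"),
         estimate = c(x$intercept, x$slope))
}

#' One-row fit summary of a clearance-slope fit
#'
#' @param x A `ps_fit` from [fit_ps()].
#' @param ... Unused.
#' @return One-row tibble: `ps`, `intercept`, `r_squared`, `n_points`.
#' @export
glance.ps_fit <- function(x, ...) {
  tibble(ps = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n_points = x$n_points)
}

#' Tidy a two-group comparison
#'
#' @param x A `group_comparison` from [mann_whitney()] or [t_unpaired()].
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `p_two_sided`, `method`, `stars`,
#'   `n_a`, `n_b`, `degenerate`.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(statistic = x$statistic, p_two_sided = x$p_two_sided,
         method = x$method, stars = x$stars,
         n_a = x$n[1L], n_b = x$n[2L], degenerate = x$degenerate)
}
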