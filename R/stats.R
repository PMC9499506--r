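#' Standard error of the mean
#'
#' @param x Numeric vector.
#' @return `sd(x)/sqrt(length(x))`; `NA` for length-1 input.
#' @export
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  sd(x) / sqrt(length(x))
}

#' Significance stars
#'
#' Strict-inequality banding of a p-value into the conventional labels:
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns`
#' otherwise (so p = 0.05 is `ns`).
#'
#' @param p P-value(s) in `[0, 1]`.
#' @return Character vector of labels.
#' @export
stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  dplyr::case_when(
    is.na(p)  ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01  ~ "**",
    p < 0.05  ~ "*",
    TRUE      ~ "ns"
  )
}

# Exact null distribution of the Mann-Whitney U statistic for group sizes
# n, m without ties: counts N(u; n, m) of arrangements with U = u, via the
# standard recurrence N(u; n, m) = N(u - m; n - 1, m) + N(u; n, m - 1).
# Returns the vector of counts for u = 0..n*m (sums to choose(n + m, n)).
u_null_counts <- function(n, m) {
  # dp[[i]] holds counts for group sizes (i-1, j) as j advances
  dp <- vector("list", n + 1L)
  for (i in 0:n) dp[[i + 1L]] <- c(1, numeric(i * 0L))  # N(0; i, 0) = 1
  for (j in seq_len(m)) {
    new <- vector("list", n + 1L)
    new[[1L]] <- 1  # N(u; 0, j): only u = 0
    for (i in seq_len(n)) {
      prev_i <- c(rep(0, j), new[[i]])            # N(u - j; i - 1, j)
      length(prev_i) <- i * j + 1L
      prev_j <- dp[[i + 1L]]                      # N(u; i, j - 1)
      length(prev_j) <- i * j + 1L
      prev_i[is.na(prev_i)] <- 0
      prev_j[is.na(prev_j)] <- 0
      new[[i + 1L]] <- prev_i + prev_j
    }
    dp <- new
  }
  dp[[n + 1L]]
}

#' Mann-Whitney U test for two independent groups
#'
#' With small samples (`n + m <= exact_max`) and no ties, the exact null
#' distribution of U is enumerated and the two-sided p-value is
#' `min(1, 2 * P(U <= min(U_ab, U_ba)))`. Otherwise mid-ranks are used
#' with the normal approximation, tie-corrected variance and continuity
#' correction. The method actually used is recorded in the result.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param exact_max Largest `n + m` for which the exact enumeration is
#'   used (default 16).
#' @return A `group_comparison` object: `statistic` (U = min of the two
#'   one-sided counts), `p_two_sided`, `method`
#'   (`mann_whitney_exact` / `mann_whitney_normal`), `stars`, `n`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney <- function(a, b, exact_max = 16) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) abort("both groups must be non-empty.")
  pooled <- c(a, b)
  r <- rank(pooled)  # mid-ranks under ties
  u_a <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  u_b <- n * m - u_a
  u_min <- min(u_a, u_b)
  has_ties <- anyDuplicated(pooled) > 0L

  if (!has_ties && (n + m) <= exact_max) {
    counts <- u_null_counts(n, m)
    p <- min(1, 2 * sum(counts[seq_len(u_min + 1L)]) / sum(counts))
    method <- "mann_whitney_exact"
  } else {
    mu <- n * m / 2
    tie_sizes <- table(pooled)
    sig2 <- n * m / 12 *
      ((n + m + 1) - sum(tie_sizes^3 - tie_sizes) / ((n + m) * (n + m - 1)))
    if (sig2 <= 0) {
      p <- 1  # all observations identical
    } else {
      z <- max(0, abs(u_a - mu) - 0.5) / sqrt(sig2)
      p <- min(1, 2 * pnorm(-z))
    }
    method <- "mann_whitney_normal"
  }
  new_group_comparison(statistic = u_min, p = p, method = method,
                       n = c(n, m))
}

#' Unpaired two-sample t test
#'
#' Pooled-variance (equal-variance) form by default, matching the usual
#' reporting for qPCR fold changes; `var_equal = FALSE` gives the Welch
#' form. Degenerate inputs (zero variance in both groups) are handled
#' explicitly: p = 1 when the means are equal, p = 0 with a degenerate
#' flag when they differ.
#'
#' @param a,b Numeric vectors with at least 2 values each.
#' @param var_equal Use the pooled-variance form (default `TRUE`).
#' @return A `group_comparison` object with `statistic` (t), `p_two_sided`,
#'   `method` (`t_unpaired` / `t_welch`), `stars`, `n`, `degenerate`.
#' @export
t_unpaired <- function(a, b, var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    abort("at least 2 values per group are required.")
  }
  method <- if (var_equal) "t_unpaired" else "t_welch"
  if (sd(a) == 0 && sd(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(new_group_comparison(
      statistic = if (equal) 0 else Inf,
      p = if (equal) 1 else 0,
      method = method, n = c(length(a), length(b)),
      degenerate = TRUE
    ))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  new_group_comparison(statistic = unname(ht$statistic),
                       p = ht$p.value, method = method,
                       n = c(length(a), length(b)))
}

new_group_comparison <- function(statistic, p, method, n,
                                 degenerate = FALSE) {
  structure(
    list(statistic = statistic, p_two_sided = p, method = method,
         stars = stars(p), n = n, degenerate = degenerate),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, two-sided p %.4g %s (n = %s)%s\n",
              x$method, x$statistic, x$p_two_sided, x$stars,
              paste(x$n, collapse = "/"),
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Mean +/- SEM summary per condition
#'
#' @param data A data frame.
#' @param value Column (tidy-select) holding the measurement.
#' @param condition Grouping column (default `condition_id`).
#' @return Tibble per condition: `n`, `mean`, `sem`.
#' @export
summarize_conditions <- function(data, value, condition = "condition_id") {
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(condition))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean({{ value }}),
      sem = sem({{ value }}),
      .groups = "drop"
    )
}

#' Compare every condition against a control
#'
#' Runs the chosen two-group test of each non-control condition's values
#' against the control values and returns a tidy table with significance
#' stars.
#'
#' @param data A data frame with one measurement per row.
#' @param value Column (tidy-select) holding the measurement.
#' @param control_condition The reference condition.
#' @param condition Name of the grouping column (default `"condition_id"`).
#' @param test `"mann_whitney"` (default) or `"t"`.
#' @return Tibble per non-control condition: `statistic`, `p_two_sided`,
#'   `method`, `stars`.
#' @export
compare_conditions <- function(data, value, control_condition,
                               condition = "condition_id",
                               test = c("mann_whitney", "t")) {
  test <- match.arg(test)
  vals <- dplyr::pull(data, {{ value }})
  grp <- data[[condition]]
  ctl <- vals[grp == control_condition]
  if (length(ctl) == 0L) abort("control condition not found.")
  others <- setdiff(unique(grp), control_condition)
  purrr::map_dfr(others, function(g) {
    cmp <- if (test == "mann_whitney") {
      mann_whitney(vals[grp == g], ctl)
    } else {
      t_unpaired(vals[grp == g], ctl)
    }
    dplyr::bind_cols(tibble(!!condition := g), tidy(cmp))
  })
}
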