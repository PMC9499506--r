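#' Read a long-format plate table
#'
#' Thin wrapper over [readr::read_csv()] with quiet column typing; the
#' expected columns are documented in [analyze_permeability()] and
#' [analyze_transport()].
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_plate_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a results or plate table to CSV
#'
#' @param x A data frame.
#' @param path Destination path.
#' @return `x`, invisibly (pipe-friendly).
#' @export
write_plate_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}
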