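#' Candidate ice-ring resolution windows
#'
#' Hexagonal ice (ice Ih) diffracts at characteristic d-spacings; powder rings
#' from cryocooling artefacts therefore appear in narrow, known resolution
#' windows. The default table holds eight lettered windows (A-H) centred on
#' the strongest ice-Ih reflections, computed from the ice-Ih unit cell
#' (a = 4.4975, c = 7.3224 Angstrom): 3.895 (100), 3.661 (002), 3.439 (101),
#' 2.668 (102), 2.249 (110), 2.068 (103), 1.948/1.916 (200/112, one shared
#' window) and 1.882 (201) Angstrom. Windows are non-overlapping and sorted
#' from low to high resolution. A custom table can be supplied as a CSV with
#' columns `label,d_high,d_low`.
#'
#' @param path Optional CSV path overriding the packaged table.
#' @return A data frame with columns `label`, `d_high`, `d_low` (Angstrom,
#'   `d_high > d_low`) and, for the packaged table, `rings`.
#' @export
ice_ring_windows <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ice_ring_windows.csv", package = "icering")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_windows(tab)
  tab
}

validate_windows <- function(tab) {
  need <- c("label", "d_high", "d_low")
  if (!all(need %in% names(tab))) {
    stop("window table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$d_low <= 0) || any(tab$d_high <= tab$d_low)) {
    stop("each window needs 0 < d_low < d_high")
  }
  o <- order(-tab$d_high)
  so <- tab[o, ]
  if (any(diff(order(-so$d_low)) != 1) ||
      any(utils::head(so$d_low, -1) < utils::tail(so$d_high, -1))) {
    stop("windows must be non-overlapping")
  }
  invisible(tab)
}

#' Select the ice-ring windows covered by a data set
#'
#' A window is a candidate only when its full `[d_low, d_high]` interval lies
#' inside the observed resolution span of the reflection set; windows beyond
#' the data's resolution limit (or below its low-resolution edge) are
#' excluded, mirroring the exclusion of data sets whose maximum resolution
#' truncates a window.
#'
#' @param set A [reflection_set()].
#' @param table Window table, default [ice_ring_windows()].
#' @return The subset of `table` fully contained in the data's span.
#' @export
select_ranges <- function(set, table = ice_ring_windows()) {
  if (!inherits(set, "reflection_set")) stop("set must be a reflection_set")
  validate_windows(table)
  if (nrow(set$hkl) == 0) stop("empty reflection set")
  span <- resolution_span(set)  # c(d_max, d_min)
  keep <- table$d_high <= span[1] & table$d_low >= span[2]
  table[keep, , drop = FALSE]
}
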