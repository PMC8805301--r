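#' Construct a reflection set
#'
#' Container for merged reflection observations: Miller indices, an observed
#' value per reflection (intensity or structure-factor amplitude, arbitrary
#' scale), an optional uncertainty, and the unit cell. The resolution d of
#' every reflection is derived at construction. Reflections with non-finite
#' values or negative sigmas are dropped with a message; negative intensities
#' are retained, since they are legitimate post-merging observations.
#'
#' @param h,k,l Integer Miller indices.
#' @param value Observed value per reflection (I_obs or F_obs).
#' @param sigma Optional uncertainty, same units as `value`.
#' @param cell A [unit_cell()].
#' @param kind `"intensity"` or `"amplitude"`; which observable `value` holds.
#' @param source_label Free-text provenance tag.
#' @return An object of class `reflection_set`: a list with elements `cell`,
#'   `kind`, `hkl` (integer matrix), `value`, `sigma`, `d`, `source_label`.
#' @export
reflection_set <- function(h, k, l, value, sigma = NULL, cell, kind = c("intensity", "amplitude"),
                           source_label = "") {
  kind <- match.arg(kind)
  n <- length(value)
  if (length(h) != n || length(k) != n || length(l) != n) {
    stop("h, k, l and value must have equal length")
  }
  if (is.null(sigma)) sigma <- rep(NA_real_, n)
  if (length(sigma) != n) stop("sigma must match value length")
  hkl <- cbind(h = as.integer(h), k = as.integer(k), l = as.integer(l))
  if (any(rowSums(hkl != 0) == 0)) stop("reflection (0,0,0) is not allowed")
  keep <- is.finite(value) & (is.na(sigma) | sigma >= 0)
  if (any(!keep)) {
    message(sum(!keep), " reflection(s) dropped (non-finite value or negative sigma)")
    hkl <- hkl[keep, , drop = FALSE]
    value <- value[keep]
    sigma <- sigma[keep]
  }
  if (nrow(hkl) == 0) stop("reflection set is empty after filtering")
  d <- d_spacing(hkl[, 1], hkl[, 2], hkl[, 3], cell)
  structure(list(cell = cell, kind = kind, hkl = hkl, value = value,
                 sigma = sigma, d = d, source_label = source_label),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("reflection_set: %d reflections (%s), d range %.2f-%.2f A\n",
              nrow(x$hkl), x$kind, max(x$d), min(x$d)))
  print(x$cell)
  if (nzchar(x$source_label)) cat("source:", x$source_label, "\n")
  invisible(x)
}

#' Resolution span of a reflection set
#' @param set A [reflection_set()].
#' @return Numeric length-2 vector `c(d_max, d_min)` (low to high resolution).
#' @export
resolution_span <- function(set) {
  c(max(set$d), min(set$d))
}

#' Read reflection data from MTZ or the plain-text dialect
#'
#' Dispatches on the file signature: files beginning with the 4-byte magic
#' `"MTZ "` are parsed as binary MTZ, anything else as the plain-text
#' reflection dialect (see [write_reflections()]). Column selection follows
#' the intensity-first rule: merged observed-intensity columns (MTZ type `J`)
#' are preferred; if none exist, amplitude columns (type `F`) are used; with
#' multiple datasets (e.g. MAD wavelengths) the first listed column wins.
#'
#' @param path Path to an MTZ file or plain-text reflection file.
#' @param column_preference Character vector of MTZ column types in preference
#'   order; default intensity before amplitude.
#' @return A [reflection_set()].
#' @export
read_reflections <- function(path, column_preference = c("J", "F")) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  magic <- readBin(con, "raw", 4)
  close(con)
  if (identical(rawToChar(magic), "MTZ ")) {
    read_mtz(path, column_preference)
  } else {
    read_reflections_txt(path)
  }
}

#' Write a reflection set in the plain-text dialect
#'
#' The dialect is whitespace-separated: a comment line, a `cell` line with the
#' six cell parameters, a `kind` line, a column-header line, then one
#' `h k l value sigma` row per reflection (sigma written as `NA` when absent).
#'
#' @param set A [reflection_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reflections <- function(set, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    "# icering reflection data v1",
    sprintf("cell %.6g %.6g %.6g %.6g %.6g %.6g",
            set$cell$a, set$cell$b, set$cell$c,
            set$cell$alpha, set$cell$beta, set$cell$gamma),
    paste("kind", set$kind),
    "h k l value sigma"
  ), con)
  write.table(
    data.frame(set$hkl, value = format(set$value, digits = 17),
               sigma = ifelse(is.na(set$sigma), "NA", format(set$sigma, digits = 17))),
    con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_reflections_txt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  cell_line <- grep("^cell\\b", lines, value = TRUE)
  kind_line <- grep("^kind\\b", lines, value = TRUE)
  if (length(cell_line) != 1 || length(kind_line) != 1) {
    stop("not a valid reflection text file (need one 'cell' and one 'kind' line): ", path)
  }
  cp <- as.numeric(strsplit(trimws(cell_line), "\\s+")[[1]][-1])
  if (length(cp) != 6 || any(is.na(cp))) stop("malformed cell line in ", path)
  kind <- strsplit(trimws(kind_line), "\\s+")[[1]][2]
  if (!kind %in% c("intensity", "amplitude")) stop("kind must be intensity or amplitude")
  body <- lines[!grepl("^(cell|kind|h\\s+k\\s+l)\\b", lines)]
  if (length(body) == 0) stop("no reflections in ", path)
  df <- utils::read.table(text = body, col.names = c("h", "k", "l", "value", "sigma"),
                          na.strings = "NA")
  reflection_set(df$h, df$k, df$l, df$value, df$sigma,
                 cell = unit_cell(cp[1], cp[2], cp[3], cp[4], cp[5], cp[6]),
                 kind = kind, source_label = basename(path))
}
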