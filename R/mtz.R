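# Minimal reader/writer for the CCP4 MTZ binary reflection format.
#
# Layout: bytes 0-3 magic "MTZ ", bytes 4-7 int32 header location (1-based, in
# 4-byte words), bytes 8-11 machine stamp (number-format nibbles). Reflection
# records (nrefl x ncol float32, h/k/l stored as floats) start at word 21
# (byte 80). The header is a run of 80-character ASCII records (NCOL, CELL,
# COLUMN, ... , END). Only merged files (0 batches) are supported here.

#' Read a binary MTZ reflection file
#'
#' Parses the MTZ header, selects the observable column by MTZ column type
#' (`column_preference`, default intensity `J` before amplitude `F`; within a
#' type the first column listed in the file wins, which for multi-wavelength
#' depositions is the first dataset), attaches the sigma from an adjacent
#' type-`Q` column when present, and drops reflections flagged missing.
#'
#' @param path Path to an MTZ file.
#' @param column_preference Character vector of MTZ column types in order.
#' @return A [reflection_set()].
#' @export
read_mtz <- function(path, column_preference = c("J", "F")) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!identical(magic, "MTZ ")) stop("not an MTZ file (bad magic): ", path)
  hdr_raw <- readBin(con, "raw", 4)
  endian <- "little"
  hdr_loc <- readBin(hdr_raw, "integer", 1, size = 4, endian = endian)
  if (is.na(hdr_loc) || hdr_loc < 21 || hdr_loc > sz / 4 + 1) {
    endian <- "big"
    hdr_loc <- readBin(hdr_raw, "integer", 1, size = 4, endian = endian)
    if (is.na(hdr_loc) || hdr_loc < 21 || hdr_loc > sz / 4 + 1) {
      stop("corrupt MTZ header location in ", path)
    }
  }
  # header records: 80-char ASCII from word hdr_loc to end of file
  seek(con, (hdr_loc - 1) * 4)
  hdr_bytes <- readBin(con, "raw", sz - (hdr_loc - 1) * 4)
  nrec <- length(hdr_bytes) %/% 80
  recs <- vapply(seq_len(nrec), function(i) {
    rawToChar(hdr_bytes[((i - 1) * 80 + 1):(i * 80)])
  }, character(1))
  recs <- trimws(recs)
  take <- function(key) grep(paste0("^", key, "\\b"), recs, value = TRUE)
  fields <- function(r) strsplit(trimws(r), "\\s+")[[1]]

  ncol_rec <- take("NCOL")
  if (length(ncol_rec) == 0) stop("MTZ header lacks NCOL record")
  nc <- as.numeric(fields(ncol_rec[1])[-1])
  ncols <- nc[1]; nrefl <- nc[2]
  if (length(nc) >= 3 && nc[3] > 0) stop("unmerged MTZ (batches present) is not supported")

  cell_rec <- take("CELL")
  if (length(cell_rec) == 0) cell_rec <- take("DCELL")
  if (length(cell_rec) == 0) stop("MTZ header lacks a CELL record")
  cp <- as.numeric(fields(cell_rec[1])[-1])
  cp <- cp[!is.na(cp)]
  cp <- utils::tail(cp, 6)
  cell <- unit_cell(cp[1], cp[2], cp[3], cp[4], cp[5], cp[6])

  col_recs <- take("COLUMN")
  labels <- vapply(col_recs, function(r) fields(r)[2], character(1), USE.NAMES = FALSE)
  types <- vapply(col_recs, function(r) fields(r)[3], character(1), USE.NAMES = FALSE)
  if (length(labels) != ncols) stop("MTZ COLUMN records disagree with NCOL")

  valm_rec <- take("VALM")
  mnf <- if (length(valm_rec)) fields(valm_rec[1])[2] else "NAN"

  seek(con, 80)
  dat <- readBin(con, "numeric", n = ncols * nrefl, size = 4, endian = endian)
  dat <- matrix(dat, nrow = nrefl, ncol = ncols, byrow = TRUE)

  ih <- match("H", labels); ik <- match("K", labels); il <- match("L", labels)
  if (any(is.na(c(ih, ik, il)))) stop("MTZ file lacks H, K, L index columns")

  pick <- NA_integer_
  for (tp in column_preference) {
    cand <- which(types == tp)
    if (length(cand)) { pick <- cand[1]; break }
  }
  if (is.na(pick)) {
    stop("no observable column found (searched MTZ types: ",
         paste(column_preference, collapse = ", "), ")")
  }
  kind <- if (types[pick] == "J") "intensity" else "amplitude"
  # sigma: adjacent type-Q column, by convention immediately after the observable
  isig <- if (pick < ncols && types[pick + 1] == "Q") pick + 1L else NA_integer_

  value <- dat[, pick]
  sigma <- if (is.na(isig)) rep(NA_real_, nrefl) else dat[, isig]
  if (identical(toupper(mnf), "NAN")) {
    miss <- !is.finite(value)
  } else {
    miss <- !is.finite(value) | value == as.numeric(mnf)
  }
  if (all(miss)) stop("observable column ", labels[pick], " has no usable values")
  reflection_set(dat[!miss, ih], dat[!miss, ik], dat[!miss, il],
                 value[!miss], sigma[!miss], cell = cell, kind = kind,
                 source_label = paste0(basename(path), ":", labels[pick]))
}

#' Write a reflection set as a minimal merged MTZ file
#'
#' Produces a standards-conforming single-dataset MTZ (IEEE little-endian,
#' space group P1) with columns H, K, L, the observable (`IOBS` type `J` or
#' `FOBS` type `F`) and its sigma (type `Q`). Mainly intended for fixtures
#' and interoperability tests; metadata beyond the cell is minimal.
#'
#' @param set A [reflection_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mtz <- function(set, path) {
  obs_label <- if (set$kind == "intensity") "IOBS" else "FOBS"
  obs_type <- if (set$kind == "intensity") "J" else "F"
  sig <- ifelse(is.na(set$sigma), 0, set$sigma)
  dat <- cbind(set$hkl[, 1], set$hkl[, 2], set$hkl[, 3], set$value, sig)
  labels <- c("H", "K", "L", obs_label, paste0("SIG", substr(obs_label, 1, 1)))
  types <- c("H", "H", "H", obs_type, "Q")
  mtz_write_table(path, set$cell, dat, labels, types, srange = range(1 / set$d^2))
}

# Low-level MTZ emitter: arbitrary column labels/types over a data matrix
# (columns in file order, H K L first). Used by write_mtz and by tests that
# need multi-observable files.
mtz_write_table <- function(path, cell, dat, labels, types, srange = c(0.001, 0.4)) {
  n <- nrow(dat)
  rec <- function(...) {
    s <- paste(...)
    if (nchar(s) > 80) s <- substr(s, 1, 80)
    formatC(s, width = 80, flag = "-")
  }
  col_rec <- function(i) {
    rec(sprintf("COLUMN %-30s %s %17.4f %17.4f    1", labels[i], types[i],
                min(dat[, i]), max(dat[, i])))
  }
  hdr <- c(
    rec("VERS MTZ:V1.1"),
    rec("TITLE icering reflection export"),
    rec(sprintf("NCOL %8d %12d %8d", ncol(dat), n, 0)),
    rec(sprintf("CELL  %9.4f %9.4f %9.4f %9.4f %9.4f %9.4f",
                cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma)),
    rec("SORT    0   0   0   0   0"),
    rec("SYMINF   1  1 P     1                 'P 1'     PG1"),
    rec("SYMM X,  Y,  Z"),
    rec(sprintf("RESO %-20.10f %-20.10f", srange[1], srange[2])),
    rec("VALM NAN"),
    vapply(seq_len(ncol(dat)), col_rec, character(1)),
    rec("NDIF        1"),
    rec("PROJECT       1 icering"),
    rec("CRYSTAL       1 icering"),
    rec("DATASET       1 export"),
    rec(sprintf("DCELL         1  %9.4f %9.4f %9.4f %9.4f %9.4f %9.4f",
                cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma)),
    rec("DWAVEL        1    1.00000"),
    rec("END"),
    rec("MTZENDOFHEADERS")
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("MTZ ", con, 4, eos = NULL)
  hdr_loc <- 21L + as.integer(ncol(dat)) * as.integer(n)  # 1-based word index
  writeBin(hdr_loc, con, size = 4, endian = "little")
  # machine stamp: IEEE floats/ints, little-endian
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)
  writeBin(raw(80 - 12), con)
  writeBin(as.numeric(t(dat)), con, size = 4, endian = "little")
  writeChar(paste(hdr, collapse = ""), con, 80L * length(hdr), eos = NULL)
  invisible(path)
}
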