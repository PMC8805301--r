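#' Plot-generation configuration
#'
#' Controls the conversion of reflections into the two-dimensional histograms
#' fed to the classifier. Defaults: 80 x 80 bins; the value (y) axis is
#' clipped to the 0.5th-95th percentile of the in-plot values, excluding
#' extreme outliers; the resolution (x) axis spans the ice-ring window plus
#' `pad` window-widths of context on each side (so the ring itself falls in
#' the central columns), binned uniformly in 1/d^2 where reflections are
#' approximately uniformly dense.
#'
#' @param n_bins_x,n_bins_y Histogram size (default 80 x 80).
#' @param lo_percentile,hi_percentile Percentile clip limits for the value
#'   axis, in \[0, 100\] (defaults 0.5 and 95); linear-interpolation
#'   convention.
#' @param min_reflections Minimum in-plot reflection count for a plot to be
#'   considered predictable (default 30); sparser plots are flagged.
#' @param pad Window-widths of context added on each side of the ice-ring
#'   window along x (default 1, so the window is the central third).
#' @param x_transform Coordinate in which x bins are uniform: `"inv_d2"`
#'   (default) or `"d"`.
#' @param blank_bins,blank_eps Parameters forwarded to [is_blank()].
#' @return A list of class `plot_config`.
#' @export
plot_config <- function(n_bins_x = 80, n_bins_y = 80, lo_percentile = 0.5,
                        hi_percentile = 95, min_reflections = 30, pad = 1,
                        x_transform = c("inv_d2", "d"),
                        blank_bins = 4, blank_eps = 0.01) {
  x_transform <- match.arg(x_transform)
  if (n_bins_x < 1 || n_bins_y < 1) stop("bin counts must be positive")
  if (lo_percentile < 0 || hi_percentile > 100 || lo_percentile >= hi_percentile) {
    stop("need 0 <= lo_percentile < hi_percentile <= 100")
  }
  structure(list(n_bins_x = as.integer(n_bins_x), n_bins_y = as.integer(n_bins_y),
                 lo_percentile = lo_percentile, hi_percentile = hi_percentile,
                 min_reflections = as.integer(min_reflections), pad = pad,
                 x_transform = x_transform, blank_bins = as.integer(blank_bins),
                 blank_eps = blank_eps),
            class = "plot_config")
}

#' Percentile clip limits for the value axis
#'
#' Returns the (`lo_percentile`, `hi_percentile`) percentiles of `values`
#' under the linear-interpolation convention (the quantile at fraction q sits
#' at sorted index q*(n-1), interpolating between neighbours).
#'
#' @param values Numeric vector, non-empty.
#' @param cfg A [plot_config()].
#' @return Named numeric vector `c(clip_lo, clip_hi)`.
#' @export
clip_limits <- function(values, cfg = plot_config()) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values for clip limits")
  q <- stats::quantile(values, c(cfg$lo_percentile, cfg$hi_percentile) / 100,
                       type = 7, names = FALSE)
  c(clip_lo = q[1], clip_hi = q[2])
}

# x-axis geometry of a plot: coordinates increase with resolution.
# Returns list(lo, hi) of the padded extent and a function mapping d to x.
plot_x_geometry <- function(range, cfg) {
  if (cfg$x_transform == "inv_d2") {
    to_x <- function(d) 1 / d^2
  } else {
    to_x <- function(d) -d
  }
  w_lo <- to_x(range$d_high)
  w_hi <- to_x(range$d_low)
  w <- w_hi - w_lo
  list(lo = w_lo - cfg$pad * w, hi = w_hi + cfg$pad * w, to_x = to_x,
       win_lo = w_lo, win_hi = w_hi)
}

#' Build the 2D histogram for one ice-ring window
#'
#' Bins the reflections falling in the padded window extent into an
#' `n_bins_y` x `n_bins_x` count grid: columns partition the x extent
#' uniformly in the chosen resolution coordinate (low-resolution edge in
#' column 1), rows partition `[clip_lo, clip_hi]` uniformly (lowest values in
#' row 1, the "bottom"). Values outside the clip interval are excluded, not
#' clamped. The returned grid is the raw-count grid normalized to \[0, 1\] by
#' its maximum (an all-zero grid stays zero), which is the network input.
#'
#' @param set A [reflection_set()].
#' @param range One ice-ring window: a single-row subset of
#'   [ice_ring_windows()] or a list with `label`, `d_high`, `d_low`.
#' @param cfg A [plot_config()].
#' @return An object of class `ice_plot` with elements `grid` (normalized),
#'   `raw` (integer counts), `range_label`, `clip_lo`, `clip_hi`,
#'   `n_in_range`, `blank`, `predictable`, `kind`.
#' @export
make_plot <- function(set, range, cfg = plot_config()) {
  if (is.data.frame(range)) range <- as.list(range[1, ])
  geom <- plot_x_geometry(range, cfg)
  x <- geom$to_x(set$d)
  inx <- x >= geom$lo & x <= geom$hi
  v <- set$value[inx]
  xs <- x[inx]
  n_in <- length(v)
  nx <- cfg$n_bins_x; ny <- cfg$n_bins_y
  raw <- matrix(0L, ny, nx)
  clip <- c(NA_real_, NA_real_)
  blank <- is_blank(set, range, n_bins = cfg$blank_bins, eps = cfg$blank_eps)
  if (n_in > 0) {
    clip <- clip_limits(v, cfg)
    keep <- v >= clip[1] & v <= clip[2]
    vs <- v[keep]; xk <- xs[keep]
    if (length(vs) > 0) {
      ix <- pmin(floor((xk - geom$lo) / (geom$hi - geom$lo) * nx) + 1L, nx)
      if (clip[2] > clip[1]) {
        iy <- pmin(floor((vs - clip[1]) / (clip[2] - clip[1]) * ny) + 1L, ny)
      } else {
        iy <- rep(1L, length(vs))
      }
      raw <- matrix(tabulate((ix - 1L) * ny + iy, nbins = ny * nx), ny, nx)
    }
  }
  mx <- max(raw)
  structure(list(grid = if (mx > 0) raw / mx else raw * 0,
                 raw = raw,
                 range_label = range$label,
                 clip_lo = unname(clip[1]), clip_hi = unname(clip[2]),
                 n_in_range = n_in,
                 blank = blank,
                 predictable = !blank && n_in >= cfg$min_reflections,
                 kind = set$kind),
            class = "ice_plot")
}

#' @export
print.ice_plot <- function(x, ...) {
  cat(sprintf("ice_plot [%s] %dx%d: %d reflections, clips [%.4g, %.4g], blank=%s, predictable=%s\n",
              x$range_label, nrow(x$grid), ncol(x$grid), x$n_in_range,
              x$clip_lo, x$clip_hi, x$blank, x$predictable))
  invisible(x)
}

#' Display an ice plot
#'
#' Renders the count grid with resolution increasing left to right and value
#' increasing bottom to top, matching the orientation used by the classifier
#' and the sensitivity maps.
#'
#' @param x An `ice_plot`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.ice_plot <- function(x, ...) {
  graphics::image(seq_len(ncol(x$grid)), seq_len(nrow(x$grid)), t(x$grid),
                  xlab = "resolution bin", ylab = "value bin",
                  main = paste("window", x$range_label), ...)
}

#' Export an ice plot as PNG
#' @param plot An `ice_plot`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
export_plot_png <- function(plot, path) {
  grDevices::png(path, width = 400, height = 400)
  on.exit(grDevices::dev.off())
  plot.ice_plot(plot, col = grDevices::gray.colors(64, 0, 1))
  invisible(path)
}

#' Blank-window discriminator
#'
#' Detects resolution windows that are completely or partially blank, for
#' example because a shell was omitted during integration. The window is cut
#' into `n_bins` equal sub-bins (in the x binning coordinate); the window is
#' blank when any sub-bin is empty or has a mean observed value below `eps`
#' times the set-wide mean. Blank windows are nonpredictable: the classifier
#' is bypassed and a warning reaches the user.
#'
#' @param set A [reflection_set()].
#' @param range One ice-ring window (see [make_plot()]).
#' @param n_bins Number of sub-bins (default 4).
#' @param eps Relative mean threshold (default 0.01).
#' @return Logical.
#' @export
is_blank <- function(set, range, n_bins = 4, eps = 0.01) {
  if (is.data.frame(range)) range <- as.list(range[1, ])
  s <- 1 / set$d^2
  lo <- 1 / range$d_high^2; hi <- 1 / range$d_low^2
  edges <- seq(lo, hi, length.out = n_bins + 1)
  ref <- mean(set$value)
  if (!is.finite(ref) || ref <= 0) ref <- mean(abs(set$value))
  for (i in seq_len(n_bins)) {
    inb <- s >= edges[i] & (if (i == n_bins) s <= edges[i + 1] else s < edges[i + 1])
    if (!any(inb)) return(TRUE)
    if (mean(set$value[inb]) < eps * ref) return(TRUE)
  }
  FALSE
}

#' Average normalized plot grids
#'
#' Element-wise mean of the normalized grids of a list of plots, used to
#' visualize what distinguishes contaminated from clean windows (clean
#' averages show a smooth vertical gradient; contaminated averages an upward
#' spike in the central columns).
#'
#' @param plots Non-empty list of `ice_plot` objects of one kind and shape.
#' @return Numeric matrix of the same shape as each grid.
#' @export
average_plots <- function(plots) {
  if (length(plots) == 0) stop("empty plot list")
  kinds <- unique(vapply(plots, function(p) p$kind, character(1)))
  if (length(kinds) != 1) stop("plots mix intensity and amplitude kinds")
  dims <- vapply(plots, function(p) dim(p$grid), integer(2))
  if (any(dims != dims[, 1])) stop("plots have differing grid shapes")
  Reduce(`+`, lapply(plots, function(p) p$grid)) / length(plots)
}

#' Generate the plots for every covered window of a data set
#'
#' @param set A [reflection_set()].
#' @param table Window table, default [ice_ring_windows()].
#' @param cfg A [plot_config()].
#' @return Named list of `ice_plot` objects (one per selected window).
#' @export
make_dataset_plots <- function(set, table = ice_ring_windows(), cfg = plot_config()) {
  sel <- select_ranges(set, table)
  plots <- lapply(seq_len(nrow(sel)), function(i) make_plot(set, sel[i, ], cfg))
  names(plots) <- sel$label
  plots
}

# Stack normalized grids into the (ny, nx, N) array consumed by the network.
plots_to_array <- function(plots) {
  if (length(plots) == 0) stop("no plots")
  d <- dim(plots[[1]]$grid)
  arr <- array(0, c(d[1], d[2], length(plots)))
  for (i in seq_along(plots)) arr[, , i] <- plots[[i]]$grid
  arr
}
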