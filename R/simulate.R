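#' Simulation parameters for synthetic reflection data
#'
#' The simulator draws merged reflection intensities from acentric Wilson
#' statistics: every Friedel-unique lattice point with d >= `d_min` gets an
#' exponential intensity draw with resolution-dependent mean
#' `scale * exp(-wilson_B / (2 d^2))` plus Gaussian measurement noise, so the
#' (d, I) marginal matches what the classifier sees in real merged data. Ice
#' contamination is injected multiplicatively: within a contaminated window a
#' fraction of reflections has its intensity multiplied by the spike factor.
#' Blank windows have their reflections omitted, emulating excluded
#' resolution shells.
#'
#' @param cell A [unit_cell()].
#' @param d_min Resolution limit in Angstrom.
#' @param scale Wilson scale (arbitrary units).
#' @param wilson_B Wilson temperature factor in Angstrom^2.
#' @param sigma_fraction Noise scale as a fraction of the local Wilson mean.
#' @param contaminated_ranges Data frame with columns `label`,
#'   `spike_factor` (>= 1), `affected_fraction` in (0, 1\], and optionally
#'   `accumulating` (logical: contaminated and clean observations coexist at
#'   the same resolution, as when ice builds up during measurement).
#' @param blank_ranges Character vector of window labels to blank out.
#' @param n_target Optional cap on the reflection count (random subsample).
#' @param kind `"intensity"` or `"amplitude"` (amplitudes use F = sqrt(max(I, 0))).
#' @param seed Integer seed; identical parameters give identical sets.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(cell, d_min, scale = 100, wilson_B = 25,
                              sigma_fraction = 0.1, contaminated_ranges = NULL,
                              blank_ranges = character(0), n_target = NULL,
                              kind = c("intensity", "amplitude"), seed = 1) {
  kind <- match.arg(kind)
  if (d_min <= 0) stop("d_min must be positive")
  if (!is.null(contaminated_ranges)) {
    cr <- contaminated_ranges
    if (!all(c("label", "spike_factor", "affected_fraction") %in% names(cr))) {
      stop("contaminated_ranges needs columns label, spike_factor, affected_fraction")
    }
    if (any(cr$spike_factor < 1)) stop("spike factors must be >= 1")
    if (any(cr$affected_fraction <= 0 | cr$affected_fraction > 1)) {
      stop("affected_fraction must be in (0, 1]")
    }
    if (is.null(cr$accumulating)) cr$accumulating <- FALSE
    contaminated_ranges <- cr
  }
  structure(list(cell = cell, d_min = d_min, scale = scale, wilson_B = wilson_B,
                 sigma_fraction = sigma_fraction,
                 contaminated_ranges = contaminated_ranges,
                 blank_ranges = blank_ranges, n_target = n_target,
                 kind = kind, seed = as.integer(seed)),
            class = "simulation_params")
}

# Friedel-unique Miller indices with d >= d_min: h > 0, or h = 0 & k > 0,
# or h = k = 0 & l > 0.
enumerate_indices <- function(cell, d_min) {
  lim <- ceiling(max(cell$a, cell$b, cell$c) / d_min) + 1
  g <- expand.grid(h = 0:lim, k = -lim:lim, l = -lim:lim)
  g <- g[g$h > 0 | (g$h == 0 & g$k > 0) | (g$h == 0 & g$k == 0 & g$l > 0), ]
  d <- d_spacing(g$h, g$k, g$l, cell)
  g <- g[d >= d_min, ]
  g$d <- d[d >= d_min]
  g
}

#' Simulate a reflection set with known ground truth
#'
#' Generates Wilson-distributed reflections (see [simulation_params()]),
#' injects the configured ice spikes and blank shells, and labels each
#' covered ice-ring window by the plot-overlay visibility rule: a window
#' counts as contaminated when a spike factor above 1 was injected AND at
#' least 1% of histogram cells change occupancy between the contaminated and
#' the uncontaminated rendering of the plot. Blank windows get an `NA`
#' (nonpredictable) label.
#'
#' @param p A [simulation_params()].
#' @param table Window table, default [ice_ring_windows()].
#' @param cfg A [plot_config()] (used for the visibility labelling).
#' @return A list: `set` (a [reflection_set()]), `labels` (named logical per
#'   covered window), `windows` (the covered subset of `table`).
#' @export
simulate_reflections <- function(p, table = ice_ring_windows(), cfg = plot_config()) {
  g <- enumerate_indices(p$cell, p$d_min)
  if (nrow(g) == 0) stop("no lattice points with d >= d_min: empty set")
  with_seed(p$seed, {
    if (!is.null(p$n_target) && nrow(g) > p$n_target) {
      g <- g[sort(sample.int(nrow(g), p$n_target)), ]
    }
    n <- nrow(g)
    meanI <- p$scale * exp(-p$wilson_B / (2 * g$d^2))
    I_clean <- meanI * stats::rexp(n) + stats::rnorm(n, 0, p$sigma_fraction * meanI)
    I <- I_clean
    spiked_labels <- character(0)
    if (!is.null(p$contaminated_ranges)) {
      for (i in seq_len(nrow(p$contaminated_ranges))) {
        cr <- p$contaminated_ranges[i, ]
        win <- table[table$label == cr$label, ]
        if (nrow(win) != 1) stop("unknown window label: ", cr$label)
        idx <- which(g$d >= win$d_low & g$d <= win$d_high)
        if (length(idx) == 0) next
        m <- max(1L, round(cr$affected_fraction * length(idx)))
        hit <- if (isTRUE(cr$accumulating)) {
          # contiguous block of the enumeration order: contaminated and clean
          # observations coexist across the window's whole resolution range
          start <- sample.int(length(idx) - m + 1L, 1)
          idx[start:(start + m - 1L)]
        } else if (m < length(idx)) {
          sample(idx, m)
        } else {
          idx
        }
        I[hit] <- I[hit] * cr$spike_factor
        if (cr$spike_factor > 1) spiked_labels <- c(spiked_labels, win$label)
      }
    }
    keep <- rep(TRUE, n)
    for (lab in p$blank_ranges) {
      win <- table[table$label == lab, ]
      if (nrow(win) != 1) stop("unknown blank window label: ", lab)
      keep[g$d >= win$d_low & g$d <= win$d_high] <- FALSE
    }
    sig <- p$sigma_fraction * meanI
    if (p$kind == "amplitude") {
      val <- sqrt(pmax(I, 0))
      val_clean <- sqrt(pmax(I_clean, 0))
      sig <- sig / (2 * pmax(val, 1e-6))
    } else {
      val <- I
      val_clean <- I_clean
    }
    set <- reflection_set(g$h[keep], g$k[keep], g$l[keep], val[keep], sig[keep],
                          cell = p$cell, kind = p$kind, source_label = "simulated")
    clean_set <- set
    clean_set$value <- val_clean[keep]
    windows <- select_ranges(set, table)
    labels <- stats::setNames(rep(FALSE, nrow(windows)), windows$label)
    for (i in seq_len(nrow(windows))) {
      lab <- windows$label[i]
      if (lab %in% p$blank_ranges) {
        labels[lab] <- NA
      } else if (lab %in% spiked_labels) {
        labels[lab] <- spike_visible(set, clean_set, windows[i, ], cfg)
      }
    }
    list(set = set, labels = labels, windows = windows)
  })
}

# Visibility rule: overlay the contaminated and uncontaminated histograms of
# the same window (shared clip limits from the contaminated rendering) and
# measure the fraction of cells whose occupancy changed (gained or emptied).
spike_visible <- function(set, clean_set, win, cfg, min_area = 0.01) {
  pa <- make_plot(set, win, cfg)
  clip <- c(pa$clip_lo, pa$clip_hi)
  pb <- make_plot_clipped(clean_set, win, cfg, clip)
  changed <- xor(pa$raw > 0, pb > 0)
  mean(changed) >= min_area
}

# raw histogram of a window under externally fixed clip limits
make_plot_clipped <- function(set, range, cfg, clip) {
  if (is.data.frame(range)) range <- as.list(range[1, ])
  geom <- plot_x_geometry(range, cfg)
  x <- geom$to_x(set$d)
  inx <- x >= geom$lo & x <= geom$hi
  v <- set$value[inx]; xs <- x[inx]
  nx <- cfg$n_bins_x; ny <- cfg$n_bins_y
  if (anyNA(clip) || length(v) == 0) return(matrix(0L, ny, nx))
  keep <- v >= clip[1] & v <= clip[2]
  vs <- v[keep]; xk <- xs[keep]
  if (length(vs) == 0) return(matrix(0L, ny, nx))
  ix <- pmin(floor((xk - geom$lo) / (geom$hi - geom$lo) * nx) + 1L, nx)
  iy <- if (clip[2] > clip[1]) {
    pmin(floor((vs - clip[1]) / (clip[2] - clip[1]) * ny) + 1L, ny)
  } else {
    rep(1L, length(vs))
  }
  matrix(tabulate((ix - 1L) * ny + iy, nbins = ny * nx), ny, nx)
}

#' Generate a labelled synthetic plot corpus
#'
#' Simulates `n_sets` reflection sets with randomized cells, Wilson
#' B-factors, scales and noise, injects contamination so that the expected
#' fraction of contaminated plots matches `fraction_contaminated` (default
#' 0.075, the strong class imbalance typical of annotated archives), renders
#' every covered window, and returns plots, labels and a manifest of the
#' generating parameters. The difficulty mix assigns each set a regime:
#' `strong` spikes, `weak` spikes, `accumulating` contamination (partial
#' fractions), or `low_count` data; a small fraction of sets additionally
#' receives a blank window.
#'
#' @param n_sets Number of simulated data sets (>= 2).
#' @param fraction_contaminated Injection probability per window.
#' @param difficulty Named numeric mix over
#'   `c("strong", "weak", "accumulating", "low_count")`; normalized to 1.
#' @param blank_fraction Fraction of sets given one blank window.
#' @param spike_range Optional length-2 override: all spike factors drawn
#'   uniformly from this interval regardless of regime.
#' @param kind Observable to emit.
#' @param table Window table.
#' @param cfg A [plot_config()].
#' @param seed Integer seed.
#' @return A list of class `plot_corpus`: `plots` (list of `ice_plot`),
#'   `labels` (logical, `NA` = nonpredictable), `kind`, `manifest` (data
#'   frame, one row per plot).
#' @export
make_corpus <- function(n_sets, fraction_contaminated = 0.075,
                        difficulty = c(strong = 0.5, weak = 0.2,
                                       accumulating = 0.2, low_count = 0.1),
                        blank_fraction = 0.02, spike_range = NULL,
                        kind = c("intensity", "amplitude"),
                        table = ice_ring_windows(), cfg = plot_config(), seed = 1) {
  kind <- match.arg(kind)
  if (n_sets < 2) stop("n_sets must be >= 2")
  regimes <- c("strong", "weak", "accumulating", "low_count")
  if (!all(names(difficulty) %in% regimes) || any(difficulty < 0) || sum(difficulty) <= 0) {
    stop("degenerate difficulty mix")
  }
  mix <- difficulty / sum(difficulty)
  draw_spike <- function(regime) {
    if (!is.null(spike_range)) return(stats::runif(1, spike_range[1], spike_range[2]))
    switch(regime,
           strong = stats::runif(1, 4, 8),
           weak = stats::runif(1, 2.2, 3.5),
           accumulating = stats::runif(1, 3, 6),
           low_count = stats::runif(1, 3, 8))
  }
  with_seed(seed, {
    regime <- sample(names(mix), n_sets, replace = TRUE, prob = mix)
    set_seeds <- sample.int(.Machine$integer.max - 1, n_sets)
    plots <- list(); labels <- logical(0); rows <- list()
    for (si in seq_len(n_sets)) {
      cellp <- stats::runif(3, 32, 48)
      cell <- unit_cell(cellp[1], cellp[2], cellp[3])
      d_min <- stats::runif(1, 1.62, 1.80)
      n_target <- if (regime[si] == "low_count") round(stats::runif(1, 600, 1500)) else 4000
      contam_lab <- table$label[stats::runif(nrow(table)) < fraction_contaminated]
      cr <- NULL
      if (length(contam_lab) > 0) {
        cr <- data.frame(
          label = contam_lab,
          spike_factor = vapply(contam_lab, function(...) draw_spike(regime[si]), numeric(1)),
          affected_fraction = if (regime[si] == "accumulating") {
            stats::runif(length(contam_lab), 0.3, 0.7)
          } else {
            rep(1, length(contam_lab))
          },
          accumulating = regime[si] == "accumulating")
      }
      blank_lab <- if (stats::runif(1) < blank_fraction) sample(table$label, 1) else character(0)
      p <- simulation_params(cell = cell, d_min = d_min,
                             scale = 10^stats::runif(1, 1.5, 3),
                             wilson_B = stats::runif(1, 15, 40),
                             sigma_fraction = stats::runif(1, 0.05, 0.25),
                             contaminated_ranges = cr, blank_ranges = blank_lab,
                             n_target = n_target, kind = kind, seed = set_seeds[si])
      sim <- simulate_reflections(p, table, cfg)
      for (wi in seq_len(nrow(sim$windows))) {
        win <- sim$windows[wi, ]
        pl <- make_plot(sim$set, win, cfg)
        lab <- sim$labels[[win$label]]
        if (!pl$predictable) lab <- NA
        plots[[length(plots) + 1]] <- pl
        labels <- c(labels, lab)
        rows[[length(rows) + 1]] <- data.frame(
          set = si, window = win$label, regime = regime[si],
          spike_factor = if (!is.null(cr) && win$label %in% cr$label) {
            cr$spike_factor[match(win$label, cr$label)]
          } else 1,
          affected_fraction = if (!is.null(cr) && win$label %in% cr$label) {
            cr$affected_fraction[match(win$label, cr$label)]
          } else 0,
          blank = win$label %in% blank_lab,
          n_in_range = pl$n_in_range, label = lab)
      }
    }
    structure(list(plots = plots, labels = labels, kind = kind,
                   manifest = do.call(rbind, rows)),
              class = "plot_corpus")
  })
}

#' @export
print.plot_corpus <- function(x, ...) {
  cat(sprintf("plot_corpus: %d %s plots, %d contaminated, %d nonpredictable\n",
              length(x$plots), x$kind, sum(x$labels, na.rm = TRUE), sum(is.na(x$labels))))
  invisible(x)
}

#' Training material from a corpus
#'
#' Drops nonpredictable plots and stacks the rest into the network input
#' array with its label vector.
#'
#' @param corpus A `plot_corpus`.
#' @return A list with `x` (array), `y` (logical), `kind`, `index`
#'   (positions kept).
#' @export
corpus_training_data <- function(corpus) {
  keep <- which(!is.na(corpus$labels))
  list(x = plots_to_array(corpus$plots[keep]), y = corpus$labels[keep],
       kind = corpus$kind, index = keep)
}

#' Write a corpus manifest as CSV
#' @param corpus A `plot_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(corpus, path) {
  utils::write.csv(corpus$manifest, path, row.names = FALSE)
  invisible(path)
}
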