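# Shared fixtures and independent oracles for the test suite.

# A reflection_set-shaped object with fully controlled d values, for plotgen
# tests that never touch the Miller indices.
fake_set <- function(d, value, kind = "intensity", sigma = NULL) {
  n <- length(d)
  structure(list(cell = unit_cell(50, 50, 50), kind = kind,
                 hkl = cbind(h = seq_len(n), k = rep(0L, n), l = rep(0L, n)),
                 value = value,
                 sigma = if (is.null(sigma)) rep(NA_real_, n) else sigma,
                 d = d, source_label = "fixture"),
            class = "reflection_set")
}

# Independent d-spacing oracle: closed-form triclinic 1/d^2 expression in
# terms of the cell volume (no metric-tensor inversion).
d_oracle <- function(h, k, l, a, b, c, al, be, ga) {
  ca <- cos(al * pi / 180); cb <- cos(be * pi / 180); cg <- cos(ga * pi / 180)
  sa <- sin(al * pi / 180); sb <- sin(be * pi / 180); sg <- sin(ga * pi / 180)
  V <- a * b * c * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  s <- (h^2 * b^2 * c^2 * sa^2 + k^2 * a^2 * c^2 * sb^2 + l^2 * a^2 * b^2 * sg^2 +
        2 * h * k * a * b * c^2 * (ca * cb - cg) +
        2 * k * l * a^2 * b * c * (cb * cg - ca) +
        2 * h * l * a * b^2 * c * (ca * cg - cb)) / V^2
  1 / sqrt(s)
}

# Brute-force histogram oracle: loops over reflections and bins, restating
# the documented conventions (x padded by cfg$pad window-widths in 1/d^2,
# left-closed bins with a closed final edge, clip interval inclusive).
oracle_grid <- function(d, value, range, cfg) {
  s <- 1 / d^2
  w_lo <- 1 / range$d_high^2
  w_hi <- 1 / range$d_low^2
  w <- w_hi - w_lo
  lo <- w_lo - cfg$pad * w
  hi <- w_hi + cfg$pad * w
  inx <- which(s >= lo & s <= hi)
  grid <- matrix(0L, cfg$n_bins_y, cfg$n_bins_x)
  if (length(inx) == 0) return(grid)
  q <- stats::quantile(value[inx], c(cfg$lo_percentile, cfg$hi_percentile) / 100,
                       type = 7, names = FALSE)
  xe <- seq(lo, hi, length.out = cfg$n_bins_x + 1)
  ye <- seq(q[1], q[2], length.out = cfg$n_bins_y + 1)
  for (i in inx) {
    v <- value[i]
    if (v < q[1] || v > q[2]) next
    ix <- iy <- NA
    for (bx in seq_len(cfg$n_bins_x)) {
      if (s[i] >= xe[bx] && (s[i] < xe[bx + 1] || bx == cfg$n_bins_x)) { ix <- bx; break }
    }
    if (q[2] > q[1]) {
      for (by in seq_len(cfg$n_bins_y)) {
        if (v >= ye[by] && (v < ye[by + 1] || by == cfg$n_bins_y)) { iy <- by; break }
      }
    } else {
      iy <- 1
    }
    grid[iy, ix] <- grid[iy, ix] + 1L
  }
  grid
}

# tiny architecture/training settings for fast unit tests
tiny_arch <- function() {
  architecture_config(filters = c(2, 3, 4, 5), dense_units = c(8, 4))
}

# a small, easily separable labelled corpus (planted bright block)
toy_plots <- function(n, seed = 1, dim = 80) {
  set.seed(seed)
  y <- rep(c(FALSE, TRUE), length.out = n)
  x <- array(stats::runif(dim * dim * n, 0, 0.3), c(dim, dim, n))
  for (i in which(y)) x[30:55, 35:45, i] <- x[30:55, 35:45, i] + 0.7
  list(x = x, y = y)
}

# tolerance for matching a value printed with `digits` decimals (half-ulp)
printed_tol <- function(digits) 0.5 * 10^(-digits) + 1e-9
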