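#' Construct a crystallographic unit cell
#'
#' A unit cell is described by three edge lengths (Angstrom) and three angles
#' (degrees). The general (triclinic) metric tensor derived from the six
#' parameters must be positive definite, which the constructor checks.
#'
#' @param a,b,c Cell edge lengths in Angstrom, all > 0.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`.
#' @examples
#' unit_cell(78.1, 78.1, 37.2)
#' unit_cell(10, 12, 14, 95, 100, 110)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  p <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(p))) stop("unit cell parameters must be finite")
  if (any(p[1:3] <= 0)) stop("unit cell lengths must be positive")
  if (any(p[4:6] <= 0) || any(p[4:6] >= 180)) {
    stop("unit cell angles must lie in (0, 180) degrees")
  }
  cell <- structure(as.list(p), class = "unit_cell")
  G <- metric_tensor(cell)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("unit cell angles are geometrically impossible (metric tensor not positive definite)")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

# Direct-space metric tensor G (Angstrom^2); its inverse is the reciprocal
# metric tensor used for d-spacings.
metric_tensor <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  with(cell, matrix(c(
    a * a,      a * b * cg, a * c * cb,
    a * b * cg, b * b,      b * c * ca,
    a * c * cb, b * c * ca, c * c
  ), 3, 3))
}

#' Resolution (d-spacing) of reflections
#'
#' Computes the lattice-plane spacing d (Angstrom) of reflections with Miller
#' indices (h, k, l) from the general triclinic reciprocal metric tensor:
#' 1/d^2 = t(hkl) G* hkl with G* the inverse of the direct metric tensor.
#' Symmetric under negation of all indices.
#'
#' @param h,k,l Integer Miller indices (vectorized; recycled to a common
#'   length). The zero vector (0,0,0) is rejected.
#' @param cell A [unit_cell()].
#' @return Numeric vector of d-spacings in Angstrom.
#' @examples
#' cc <- unit_cell(10, 10, 10)
#' d_spacing(1, 0, 0, cc)   # 10
#' d_spacing(1, 1, 1, cc)   # 10 / sqrt(3)
#' @export
d_spacing <- function(h, k, l, cell) {
  if (!inherits(cell, "unit_cell")) stop("cell must be a unit_cell object")
  H <- cbind(h, k, l)
  if (any(!is.finite(H))) stop("Miller indices must be finite")
  if (any(rowSums(H != 0) == 0)) {
    stop("degenerate Miller index (0,0,0): zero scattering vector has no d-spacing")
  }
  Gstar <- solve(metric_tensor(cell))
  inv_d2 <- rowSums((H %*% Gstar) * H)
  1 / sqrt(inv_d2)
}
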