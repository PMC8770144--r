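#' Construct a unit cell
#'
#' A unit cell is described by the six lattice parameters: axis lengths
#' `a`, `b`, `c` in Angstrom and inter-axial angles `alpha`, `beta`, `gamma`
#' in degrees. The constructor validates that the parameters define a
#' non-degenerate lattice, i.e. that the metric tensor built from them is
#' symmetric positive definite.
#'
#' @param a,b,c Axis lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Inter-axial angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`: a named list with components
#'   `a`, `b`, `c`, `alpha`, `beta`, `gamma`.
#' @examples
#' uc <- unit_cell(5.938, 7.325, 29.202, 90, 95.44, 90)
#' cell_volume(uc)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  p <- c(a = unname(a), b = unname(b), c = unname(c),
         alpha = unname(alpha), beta = unname(beta), gamma = unname(gamma))
  if (any(!is.finite(p))) stop("unit cell parameters must be finite")
  if (any(p[1:3] <= 0)) stop("cell lengths must be positive")
  if (any(p[4:6] <= 0) || any(p[4:6] >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  cell <- structure(as.list(p), class = "unit_cell")
  G <- metric_tensor(cell)
  # positive definiteness via leading principal minors
  m1 <- G[1, 1]
  m2 <- det(G[1:2, 1:2])
  m3 <- det(G)
  if (m1 <= 0 || m2 <= 0 || m3 <= 0)
    stop("degenerate cell: metric tensor is not positive definite")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.4f b=%.4f c=%.4f A  alpha=%.3f beta=%.3f gamma=%.3f deg\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  cat(sprintf("  volume %.2f A^3\n", cell_volume(x)))
  invisible(x)
}

#' @export
as.numeric.unit_cell <- function(x, ...) {
  c(x$a, x$b, x$c, x$alpha, x$beta, x$gamma)
}

is_unit_cell <- function(x) inherits(x, "unit_cell")

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Direct-space metric tensor
#'
#' @param cell A [unit_cell()].
#' @return The symmetric 3x3 metric tensor G (units Angstrom^2), with
#'   `G[i,j]` the dot product of basis vectors i and j.
#' @export
metric_tensor <- function(cell) {
  stopifnot(is_unit_cell(cell))
  ca <- cos(deg2rad(cell$alpha)); cb <- cos(deg2rad(cell$beta)); cg <- cos(deg2rad(cell$gamma))
  with(cell, matrix(c(a * a,      a * b * cg, a * c * cb,
                      a * b * cg, b * b,      b * c * ca,
                      a * c * cb, b * c * ca, c * c), 3, 3))
}

#' Reciprocal-space metric tensor
#'
#' @param cell A [unit_cell()].
#' @return The 3x3 reciprocal metric G* = G^-1 (units Angstrom^-2), so that
#'   1/d(hkl)^2 = h' G* h.
#' @export
reciprocal_metric <- function(cell) solve(metric_tensor(cell))

#' Unit-cell volume
#'
#' Volume of the parallelepiped spanned by the cell basis,
#' V = sqrt(det G). For a monoclinic cell this reduces to a b c sin(beta).
#'
#' @param cell A [unit_cell()].
#' @return Volume in Angstrom^3.
#' @export
cell_volume <- function(cell) {
  d <- det(metric_tensor(cell))
  if (d <= 0) stop("degenerate cell: non-positive metric determinant")
  sqrt(d)
}

#' Calculated crystal density
#'
#' rho = Z * MW / (N_A * V), with V in Angstrom^3 converted to cm^3.
#'
#' @param cell A [unit_cell()].
#' @param z Formula units per cell (integer, >= 1).
#' @param molecular_weight Formula weight in g/mol.
#' @return Density in g/cm^3.
#' @export
cell_density <- function(cell, z, molecular_weight) {
  if (z < 1 || z != round(z)) stop("z must be a positive integer")
  if (molecular_weight <= 0) stop("molecular_weight must be positive")
  avogadro <- 6.02214076e23
  z * molecular_weight / (avogadro * cell_volume(cell) * 1e-24)
}

#' Interplanar d spacing
#'
#' d(hkl) = 1 / sqrt(h' G* h) with G* the reciprocal metric. Vectorised
#' over rows of `hkl`.
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer vector of length 3, or an n x 3 matrix of Miller
#'   indices. The zero index (0,0,0) is rejected.
#' @return d spacing(s) in Angstrom.
#' @export
d_spacing <- function(cell, hkl) {
  H <- as_hkl_matrix(hkl)
  if (any(rowSums(H != 0) == 0)) stop("d spacing undefined for hkl = (0,0,0)")
  Gs <- reciprocal_metric(cell)
  q2 <- rowSums((H %*% Gs) * H)
  1 / sqrt(q2)
}

as_hkl_matrix <- function(hkl) {
  if (is.matrix(hkl)) {
    if (ncol(hkl) != 3) stop("hkl matrix must have 3 columns")
    hkl
  } else {
    if (length(hkl) != 3) stop("hkl must have length 3")
    matrix(hkl, 1, 3)
  }
}

#' Crystallographic B matrix
#'
#' Busing-Levy orthogonalisation of the reciprocal basis: `B %*% h` is the
#' reciprocal-lattice vector of `h` in a Cartesian crystal frame
#' (Angstrom^-1), with `crossprod(B)` equal to the reciprocal metric.
#'
#' @param cell A [unit_cell()].
#' @return 3x3 matrix B.
#' @export
b_matrix <- function(cell) {
  G <- metric_tensor(cell)
  Gs <- solve(G)
  as_ <- sqrt(Gs[1, 1]); bs <- sqrt(Gs[2, 2]); cs <- sqrt(Gs[3, 3])
  cgs <- Gs[1, 2] / (as_ * bs)  # cos gamma*
  cbs <- Gs[1, 3] / (as_ * cs)  # cos beta*
  cas <- Gs[2, 3] / (bs * cs)   # cos alpha*
  sgs <- sqrt(max(0, 1 - cgs^2))
  matrix(c(as_, bs * cgs, cs * cbs,
           0,   bs * sgs, -cs * (cas - cbs * cgs) / sgs,
           0,   0,        1 / cell$c),
         3, 3, byrow = TRUE)
}

#' Rebuild a unit cell from a metric tensor
#'
#' @param G Symmetric positive-definite 3x3 matrix.
#' @return A [unit_cell()].
#' @export
cell_from_metric <- function(G) {
  a <- sqrt(G[1, 1]); b <- sqrt(G[2, 2]); c <- sqrt(G[3, 3])
  unit_cell(a, b, c,
            alpha = rad2deg(acos(G[2, 3] / (b * c))),
            beta  = rad2deg(acos(G[1, 3] / (a * c))),
            gamma = rad2deg(acos(G[1, 2] / (a * b))))
}

#' Apply a change of basis to a unit cell
#'
#' Rows of `basis_map` give the new basis vectors as integer (or rational)
#' combinations of the old ones: a_i' = sum_j P_ij a_j. The transformed
#' metric is P G P' and the volume scales by |det P|.
#'
#' @param cell A [unit_cell()].
#' @param basis_map 3x3 matrix with nonzero determinant.
#' @return The transformed [unit_cell()].
#' @examples
#' mith <- unit_cell(5.94, 7.32, 29.20, 90, 95.4, 90)
#' # pseudo-orthorhombic F setting: (a, b, a + 2c)
#' apply_change_of_basis(mith, rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 2)))
#' @export
apply_change_of_basis <- function(cell, basis_map) {
  P <- as.matrix(basis_map)
  if (!all(dim(P) == c(3, 3))) stop("basis_map must be 3x3")
  if (abs(det(P)) < 1e-12) stop("basis_map is singular")
  cell_from_metric(P %*% metric_tensor(cell) %*% t(P))
}
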