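#' Toy scatterer model
#'
#' A minimal structure model used by the simulator to give reflections
#' physically plausible, reproducible intensities: point scatterers at
#' fractional coordinates with a weight (electron count stand-in) and an
#' isotropic Debye-Waller B factor. Not a real form-factor model.
#'
#' @param positions n x 3 matrix of fractional coordinates.
#' @param weights Length-n positive scatterer weights.
#' @param b_factors Length-n isotropic B factors in Angstrom^2 (>= 0).
#' @return Object of class `toy_structure`.
#' @export
toy_structure <- function(positions, weights, b_factors = rep(0, length(weights))) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be n x 3")
  n <- nrow(positions)
  if (n == 0) stop("scatterer list must be non-empty")
  if (length(weights) != n || length(b_factors) != n)
    stop("weights and b_factors must match the number of positions")
  if (any(weights <= 0)) stop("weights must be positive")
  if (any(b_factors < 0)) stop("b_factors must be non-negative")
  structure(list(positions = positions, weights = weights, b_factors = b_factors),
            class = "toy_structure")
}

#' Default toy structure used by the simulator
#'
#' Three independent scatterers weighted like Ag/Se/C with small B factors,
#' expanded through a twofold axis along b and the C-centring translation
#' (12 sites in all). The expansion makes |F|^2 genuinely invariant under
#' the 2/m Laue group used for merging and makes the C-centring absences
#' exact, while the low-symmetry general positions keep intensities spread
#' over several orders of magnitude, as heavy-atom small-molecule data are.
#'
#' @return A [toy_structure()].
#' @export
default_toy_structure <- function() {
  base <- rbind(c(0.00, 0.25, 0.125),
                c(0.20, 0.55, 0.110),
                c(0.37, 0.11, 0.310))
  w <- c(47, 34, 6)
  b <- c(4.0, 4.5, 6.0)
  twofold <- base %*% diag(c(-1, 1, -1))
  pos <- rbind(base, twofold)
  pos <- rbind(pos, sweep(pos, 2, c(0.5, 0.5, 0), "+")) %% 1
  toy_structure(pos, rep(w, 4), rep(b, 4))
}

#' Squared structure factor of the toy model
#'
#' |F(hkl)|^2 = |sum_j w_j exp(-B_j (sin theta / lambda)^2) exp(2 pi i h.x_j)|^2
#' with (sin theta / lambda) = 1/(2 d). Real and non-negative by construction.
#'
#' @param structure A [toy_structure()].
#' @param hkl Length-3 vector or n x 3 matrix of Miller indices.
#' @param cell A [unit_cell()], needed for the B-factor damping; if NULL the
#'   damping term is skipped (equivalent to all B = 0).
#' @return Numeric vector of |F|^2 values.
#' @export
toy_structure_factor <- function(structure, hkl, cell = NULL) {
  stopifnot(inherits(structure, "toy_structure"))
  H <- as_hkl_matrix(hkl)
  if (is.null(cell) || all(structure$b_factors == 0)) {
    damp <- matrix(1, nrow(H), length(structure$weights))
  } else {
    stol2 <- (1 / (2 * d_spacing(cell, H)))^2   # (sin theta / lambda)^2
    damp <- exp(-outer(stol2, structure$b_factors))
  }
  phase <- 2 * pi * (H %*% t(structure$positions))   # n_hkl x n_atoms
  w <- matrix(structure$weights, nrow(H), length(structure$weights), byrow = TRUE)
  re <- rowSums(w * damp * cos(phase))
  im <- rowSums(w * damp * sin(phase))
  re^2 + im^2
}
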