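# Single-element operations, exposed for testing and diagnostics. The
# assembly uses the compiled equivalents.

elem_grads <- function(coords) {
  D <- cbind(1, coords)
  V <- det(D) / 6
  if (V <= 0) stop("element has non-positive reference volume")
  Dinv <- solve(D)
  list(G = t(Dinv[2:4, , drop = FALSE]), V = V)   # 4 x 3
}

#' Deformation gradient of a linear tetrahedron
#'
#' `F = I + du/dX` from the constant shape-function gradients; linear
#' elements carry one quadrature point, so `F` is element-constant and
#' affine displacement fields are reproduced exactly.
#'
#' @param coords 4 x 3 reference node coordinates (mm).
#' @param disp 4 x 3 nodal displacements (mm).
#' @return 3 x 3 deformation gradient.
#' @export
element_kinematics <- function(coords, disp) {
  g <- elem_grads(coords)
  diag(3) + t(disp) %*% g$G
}

#' Strain-displacement matrix of a linear tetrahedron
#'
#' The large-deformation operator `B` (6 x 12, Voigt order
#' 11, 22, 33, 12, 23, 13 with engineering shears) mapping virtual nodal
#' displacements to the variation of the Green-Lagrange strain,
#' `delta E = B delta u`, at the current deformation.
#'
#' @inheritParams element_kinematics
#' @return 6 x 12 matrix; columns ordered node-major (`u1x, u1y, u1z, u2x,
#'   ...`).
#' @export
strain_displacement_matrix <- function(coords, disp) {
  g <- elem_grads(coords)
  F <- diag(3) + t(disp) %*% g$G
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    Ga <- g$G[a, ]
    for (k in 1:3) {
      col <- 3 * (a - 1) + k
      B[1, col] <- F[k, 1] * Ga[1]
      B[2, col] <- F[k, 2] * Ga[2]
      B[3, col] <- F[k, 3] * Ga[3]
      B[4, col] <- F[k, 1] * Ga[2] + F[k, 2] * Ga[1]
      B[5, col] <- F[k, 2] * Ga[3] + F[k, 3] * Ga[2]
      B[6, col] <- F[k, 1] * Ga[3] + F[k, 3] * Ga[1]
    }
  }
  B
}
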