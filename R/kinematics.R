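# Growth kinematics: how the scalar tissue volume change v_hat maps into a
# second-order growth tensor Fg, the multiplicative split F = Fe.Fg, the
# isochoric measures of the elastic deformation, and collagen fiber stretch
# with recruitment.

#' Growth-kinematics kinds
#'
#' `IVG` isotropic, `PVG` in-plane (tangential), `TVG` in-thickness
#' (along the wall normal), `NVG` no volume growth (isochoric; requires an
#' all-CCV deposition assignment so that v_hat is identically one).
#' @export
kinematics_kinds <- c("IVG", "PVG", "TVG", "NVG")

#' Wall normal from the two fiber directions
#'
#' The tangential plane is spanned by the two collagen families; the wall
#' normal is their (normalized) cross product.
#'
#' @param a01,a02 referential unit fiber directions (length-3 vectors).
#' @return unit normal vector.
#' @export
wall_normal <- function(a01, a02) {
  n <- c(a01[2] * a02[3] - a01[3] * a02[2],
         a01[3] * a02[1] - a01[1] * a02[3],
         a01[1] * a02[2] - a01[2] * a02[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("fiber directions are parallel; wall normal undefined")
  n / nn
}

#' Growth tensor for a given kinematics kind
#'
#' Transversely anisotropic growth about the wall normal `n`:
#' \eqn{F_g = \alpha I + \beta\, n \otimes n} with \eqn{(\alpha,\beta)}
#' chosen per kind so that \eqn{\det F_g = \hat v}:
#' IVG \eqn{\hat v^{1/3} I}; PVG \eqn{\hat v^{1/2} I + (1-\hat v^{1/2}) n \otimes n};
#' TVG \eqn{I + (\hat v - 1) n \otimes n}; NVG \eqn{I}.
#'
#' @param v_hat normalized tissue volume change, `> 0`.
#' @param n unit wall normal.
#' @param kind one of [kinematics_kinds].
#' @return 3x3 growth tensor.
#' @export
growth_tensor <- function(v_hat, n, kind) {
  kind <- match.arg(kind, kinematics_kinds)
  if (!is.numeric(v_hat) || v_hat <= 0) stop("v_hat must be > 0")
  if (abs(sqrt(sum(n^2)) - 1) > 1e-8) stop("n must be a unit vector")
  I3 <- diag(3)
  N <- tcrossprod(n)
  g <- growth_stretches(v_hat, kind)
  g["tan"] * I3 + (g["nrm"] - g["tan"]) * N
}

# diagonal growth stretches (normal, tangential) in a frame aligned with n;
# used by the closed-form patch and vessel engines.
growth_stretches <- function(v_hat, kind) {
  switch(kind,
    IVG = c(nrm = v_hat^(1 / 3), tan = v_hat^(1 / 3)),
    PVG = c(nrm = 1, tan = sqrt(v_hat)),
    TVG = c(nrm = v_hat, tan = 1),
    NVG = c(nrm = 1, tan = 1),
    stop("unknown kinematics kind"))
}

#' Elastic part of the deformation gradient
#'
#' Inverts the multiplicative split \eqn{F = F_e F_g}.
#'
#' @param F total deformation gradient (3x3).
#' @param Fg growth tensor (3x3), invertible.
#' @return \eqn{F_e = F F_g^{-1}}.
#' @export
elastic_part <- function(F, Fg) {
  d <- det(Fg)
  if (!is.finite(d) || abs(d) < 1e-14) stop("singular growth tensor")
  F %*% solve(Fg)
}

#' Isochoric invariants of an elastic deformation
#'
#' With \eqn{J_e = \det F_e} and \eqn{\bar C = J_e^{-2/3} F_e^T F_e}:
#' \eqn{\bar I_1 = tr\,\bar C} and, for a fiber direction `a0`,
#' \eqn{\bar I_4 = \bar C : a_0 \otimes a_0}.
#'
#' @param Fe elastic deformation gradient, `det Fe > 0`.
#' @param a0 referential unit fiber direction.
#' @return list with `I1bar`, `I4bar`, `Je`, `Cbar`.
#' @export
isochoric_invariants <- function(Fe, a0 = c(1, 0, 0)) {
  Je <- det(Fe)
  if (!is.finite(Je) || Je <= 0) stop("det Fe must be > 0")
  Cbar <- Je^(-2 / 3) * crossprod(Fe)
  list(I1bar = sum(diag(Cbar)),
       I4bar = drop(a0 %*% Cbar %*% a0),
       Je = Je,
       Cbar = Cbar)
}

#' Squared collagen fiber stretch with recruitment
#'
#' Collagen fibers are undulated in the unloaded tissue and begin to bear
#' load only beyond the recruitment stretch; they carry no compressive or
#' bending load, hence the clamp at one:
#' \deqn{\bar I_4^c = \max(\bar I_4 / \bar\lambda_r^2,\; 1).}
#'
#' @param I4bar isochoric tissue invariant along the fiber, `> 0`.
#' @param lambda_r recruitment stretch, `> 0`.
#' @return \eqn{\bar I_4^c \ge 1}.
#' @export
fiber_stretch_sq <- function(I4bar, lambda_r) {
  if (any(I4bar <= 0) || any(lambda_r <= 0))
    stop("I4bar and lambda_r must be > 0")
  pmax(I4bar / lambda_r^2, 1)
}
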