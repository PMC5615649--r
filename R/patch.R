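# Closed-form equi-biaxial tissue patch: a neo-Hookean, elastically
# incompressible wall patch of referential dimensions L x L x H, stretched
# equally in plane while growing by v_hat under a chosen kinematics kind.
# Serves as the analytic laboratory for the kinematics/constitutive
# pipeline: first Piola-Kirchhoff stress admits a closed form per kind.

#' Equi-biaxial patch state
#'
#' @param lam in-plane stretch `> 0`.
#' @param v_hat normalized tissue volume change `> 0`.
#' @param rho_hat normalized density change.
#' @param mu neo-Hookean shear modulus (kPa).
#' @param kind one of [kinematics_kinds].
#' @return object of class `patch_state`.
#' @export
patch_state <- function(lam, v_hat = 1, rho_hat = 1, mu = 1,
                        kind = "IVG") {
  kind <- match.arg(kind, kinematics_kinds)
  stopifnot(lam > 0, v_hat > 0, rho_hat >= 0, mu >= 0)
  if (kind == "NVG" && abs(v_hat - 1) > 1e-12)
    stop("NVG requires v_hat = 1")
  structure(list(lam = lam, v_hat = v_hat, rho_hat = rho_hat,
                 mu = mu, kind = kind), class = "patch_state")
}

#' Elastic deformation of the equi-biaxial patch
#'
#' The out-of-plane total stretch is fixed by elastic incompressibility
#' (`det Fe = 1`, so the total volume equals `v_hat`):
#' \eqn{\lambda_3 = \hat v / \lambda^2}.  The wall normal is the
#' out-of-plane direction `e3`.
#'
#' @param s a [patch_state].
#' @return diagonal 3x3 elastic deformation gradient with unit determinant.
#' @export
patch_elastic_deformation <- function(s) {
  lam <- s$lam; v <- s$v_hat
  lam3 <- v / lam^2                      # total out-of-plane stretch
  Fe <- switch(s$kind,
    IVG = v^(-1 / 3) * diag(c(lam, lam, lam3)),
    PVG = diag(c(v^(-1 / 2) * lam, v^(-1 / 2) * lam, lam3)),
    TVG = diag(c(lam, lam, lam3 / v)),
    NVG = diag(c(lam, lam, lam3)))
  Fe
}

#' Closed-form equi-biaxial first Piola-Kirchhoff stress
#'
#' \deqn{P_{IVG} = \hat\rho\, \hat v^{1/3} \mu (\lambda - \hat v^2 \lambda^{-5})}
#' \deqn{P_{PVG} = \hat\rho\, \mu (\lambda - \hat v^3 \lambda^{-5})}
#' \deqn{P_{TVG} = \hat\rho\, \hat v\, \mu (\lambda - \lambda^{-5})
#'              = \hat m\, \mu (\lambda - \lambda^{-5})}
#' NVG is the \eqn{\hat v = 1} degenerate form.
#'
#' @param s a [patch_state].
#' @return first Piola-Kirchhoff stress (kPa, force per referential area).
#' @export
patch_biaxial_stress <- function(s) {
  lam <- s$lam; v <- s$v_hat; rho <- s$rho_hat; mu <- s$mu
  switch(s$kind,
    IVG = rho * v^(1 / 3) * mu * (lam - v^2 * lam^-5),
    PVG = rho * mu * (lam - v^3 * lam^-5),
    TVG = rho * v * mu * (lam - lam^-5),
    NVG = rho * mu * (lam - lam^-5))
}

#' Stress-stretch curves of the growing patch
#'
#' Long-format table of normalized stress `P/mu` over a stretch grid, per
#' kinematics kind and volume change.
#'
#' @param kinds character vector of [kinematics_kinds].
#' @param v_hat_list volume changes to sweep.
#' @param lam_grid stretch grid.
#' @param rho_hat normalized density (held fixed across the sweep).
#' @return data.frame with columns `kind`, `v_hat`, `lam`, `P_over_mu`,
#'   ordered by kind, then `v_hat`, then `lam`.
#' @export
patch_curves <- function(kinds = c("IVG", "PVG", "TVG"),
                         v_hat_list = c(0.5, 1.0, 1.5),
                         lam_grid = seq(0.8, 3, by = 0.02),
                         rho_hat = 1) {
  stopifnot(length(kinds) > 0, length(v_hat_list) > 0, length(lam_grid) > 0)
  kinds <- vapply(kinds, match.arg, character(1), choices = kinematics_kinds)
  out <- expand.grid(lam = lam_grid, v_hat = v_hat_list, kind = kinds,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("kind", "v_hat", "lam")]
  out <- out[order(match(out$kind, kinds), out$v_hat, out$lam), ]
  rownames(out) <- NULL
  out$P_over_mu <- mapply(function(k, v, l) {
    v_eff <- if (k == "NVG") 1 else v
    patch_biaxial_stress(patch_state(l, v_eff, rho_hat, 1, k))
  }, out$kind, out$v_hat, out$lam)
  out
}

# Assemble the patch stress through the generic pipeline (growth tensor ->
# elastic split -> Cauchy stress with exact incompressibility -> traction
# balance) rather than the closed form; used as the cross-check route.
patch_stress_pipeline <- function(s) {
  n <- c(0, 0, 1)
  v_eff <- if (s$kind == "NVG") 1 else s$v_hat
  lam3 <- s$v_hat / s$lam^2
  F <- diag(c(s$lam, s$lam, lam3))
  Fg <- growth_tensor(v_eff, n, s$kind)
  Fe <- elastic_part(F, Fg)
  # neo-Hookean-only composition: fold mu into the ground-matrix slot
  comp <- local_composition(rho_hat_e = 0, rho_hat_g = s$rho_hat,
                            rho_hat_c = numeric(0), lambda_r = numeric(0),
                            a0 = list())
  p <- material_params(mu_e = 0, mu_g = s$mu, k1 = 0)
  # plane stress: ph from sigma_33 = 0
  sig0 <- cauchy_stress(Fe, comp, p, mode = "incompressible", ph = 0)
  ph <- -sig0[3, 3]
  sig <- sig0 + ph * diag(3)
  # P = J sigma F^{-T} ; equi-biaxial diagonal: P11 = J sig11 / lam
  det(F) * sig[1, 1] / s$lam
}
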