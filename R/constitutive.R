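# Layered hyperelastic response of the vessel wall mixture: neo-Hookean
# elastin and ground matrix, exponential collagen fibers engaging beyond the
# recruitment stretch, and a volumetric penalty enforcing
# quasi-incompressibility.  All moduli in kPa.

#' Material parameters of the wall mixture
#'
#' @param mu_e elastin shear modulus (kPa).
#' @param mu_g ground-matrix shear modulus (kPa).
#' @param k1 collagen stiffness-like parameter (kPa).
#' @param k2 collagen exponential parameter (dimensionless).
#' @param kappa fictitious (penalty) bulk modulus (kPa).
#' @return object of class `material_params`.
#' @export
material_params <- function(mu_e = 133.81, mu_g = 33.45, k1 = 3.52,
                            k2 = 40, kappa = 100) {
  stopifnot(mu_e >= 0, mu_g >= 0, k1 >= 0, k2 > 0, kappa > 0)
  structure(list(mu_e = mu_e, mu_g = mu_g, k1 = k1, k2 = k2, kappa = kappa),
            class = "material_params")
}

#' Local composition entering the stress
#'
#' Normalized partial densities weight the constituent strain energies; the
#' adventitia carries `rho_hat_e = 0` (negligible elastin).  Collagen is
#' described per family by its partial density, recruitment stretch and
#' referential direction.
#'
#' @param rho_hat_e,rho_hat_g normalized partial densities of elastin and
#'   ground matrix.
#' @param rho_hat_c numeric vector, one entry per collagen family.
#' @param lambda_r recruitment stretch per family.
#' @param a0 list of referential unit fiber directions, one per family.
#' @return object of class `local_composition`.
#' @export
local_composition <- function(rho_hat_e = 1, rho_hat_g = 1,
                              rho_hat_c = c(1, 1),
                              lambda_r = c(1, 1),
                              a0 = list(c(0, 1, 0), c(0, 1, 0))) {
  stopifnot(rho_hat_e >= 0, rho_hat_g >= 0, all(rho_hat_c >= 0),
            all(lambda_r > 0), length(a0) == length(rho_hat_c),
            length(lambda_r) == length(rho_hat_c))
  structure(list(rho_hat_e = rho_hat_e, rho_hat_g = rho_hat_g,
                 rho_hat_c = rho_hat_c, lambda_r = lambda_r, a0 = a0),
            class = "local_composition")
}

#' Strain energy density of the wall (kPa)
#'
#' \deqn{\Psi = \frac{\kappa}{2}(J_e-1)^2
#'   + \hat\rho_e \frac{\mu_e}{2}(\bar I_1 - 3)
#'   + \hat\rho_g \frac{\mu_g}{2}(\bar I_1 - 3)
#'   + \sum_i \hat\rho_{ci} \frac{k_1}{2k_2}
#'     \left[e^{k_2 (\bar I_4^{ci} - 1)^2} - 1\right]}
#'
#' Slack fibers (\eqn{\bar I_4 < \bar I_4^r}) store no energy.
#'
#' @param Fe elastic deformation gradient.
#' @param comp a [local_composition].
#' @param params a [material_params].
#' @param volumetric include the penalty term (set `FALSE` for the purely
#'   isochoric energy used with exact incompressibility).
#' @return scalar energy density (kPa).
#' @export
strain_energy <- function(Fe, comp, params, volumetric = TRUE) {
  inv <- isochoric_invariants(Fe)
  psi <- if (volumetric) params$kappa / 2 * (inv$Je - 1)^2 else 0
  psi <- psi + (comp$rho_hat_e * params$mu_e / 2 +
                comp$rho_hat_g * params$mu_g / 2) * (inv$I1bar - 3)
  for (i in seq_along(comp$rho_hat_c)) {
    I4 <- drop(comp$a0[[i]] %*% inv$Cbar %*% comp$a0[[i]])
    I4c <- fiber_stretch_sq(I4, comp$lambda_r[i])
    psi <- psi + comp$rho_hat_c[i] * params$k1 / (2 * params$k2) *
      (exp(params$k2 * (I4c - 1)^2) - 1)
  }
  psi
}

#' Stress factors (derivatives of the constituent energies)
#'
#' \eqn{\bar\Psi_{\zeta,1} = \mu_\zeta/2} for elastin and ground matrix and
#' \deqn{\bar\Psi_{c,4} = k_1 (\bar I_4^r)^{-1} (\bar I_4^c - 1)
#'       e^{k_2 (\bar I_4^c - 1)^2},}
#' the derivative of the collagen energy with respect to \eqn{\bar I_4}
#' (the \eqn{(\bar I_4^r)^{-1}} factor is the chain rule through
#' \eqn{\bar I_4^c = \bar I_4 / \bar I_4^r}); zero in the slack regime.
#'
#' @param I1bar first isochoric invariant (unused; kept for a uniform call
#'   signature).
#' @param I4c squared (clamped) fiber stretch, `>= 1`.
#' @param I4r squared recruitment stretch.
#' @param params a [material_params].
#' @return list with `psi_e1`, `psi_g1`, `psi_c4` (kPa).
#' @export
stress_factors <- function(I1bar, I4c, I4r, params) {
  stopifnot(all(I4c >= 1))
  list(psi_e1 = params$mu_e / 2,
       psi_g1 = params$mu_g / 2,
       psi_c4 = params$k1 / I4r * (I4c - 1) * exp(params$k2 * (I4c - 1)^2))
}

#' Second Piola-Kirchhoff stress at the intermediate configuration
#'
#' \deqn{S_e = J_e p_h C_e^{-1} + 2 J_e^{-2/3}\left[
#'   (\hat\rho_e \bar\Psi_{e,1} + \hat\rho_g \bar\Psi_{g,1})\,Dev\,I
#'   + \sum_i \hat\rho_{ci} \bar\Psi_{ci,4}\,Dev\,A_{0i}\right]}
#' with \eqn{Dev(\cdot) = (\cdot) - \frac13 ((\cdot):C_e)\, C_e^{-1}}.
#'
#' @param Fe elastic deformation gradient.
#' @param comp a [local_composition].
#' @param params a [material_params].
#' @param ph hydrostatic pressure; `NULL` selects the penalty closure
#'   \eqn{p_h = \kappa (J_e - 1)}.
#' @return symmetric 3x3 stress tensor (kPa).
#' @export
second_pk_stress <- function(Fe, comp, params, ph = NULL) {
  inv <- isochoric_invariants(Fe)
  Je <- inv$Je
  Ce <- crossprod(Fe)
  Cinv <- solve(Ce)
  if (is.null(ph)) ph <- params$kappa * (Je - 1)
  Dev <- function(X) X - sum(X * Ce) / 3 * Cinv
  S <- Je * ph * Cinv
  iso <- (comp$rho_hat_e * params$mu_e / 2 +
          comp$rho_hat_g * params$mu_g / 2) * Dev(diag(3))
  for (i in seq_along(comp$rho_hat_c)) {
    A0 <- tcrossprod(comp$a0[[i]])
    I4 <- sum(inv$Cbar * A0)
    I4r <- comp$lambda_r[i]^2
    I4c <- fiber_stretch_sq(I4, comp$lambda_r[i])
    sf <- stress_factors(inv$I1bar, I4c, I4r, params)
    psi4 <- if (I4 > I4r) sf$psi_c4 else 0
    iso <- iso + comp$rho_hat_c[i] * psi4 * Dev(A0)
  }
  S <- S + 2 * Je^(-2 / 3) * iso
  (S + t(S)) / 2
}

#' Cauchy stress of the wall
#'
#' Push-forward of the second Piola-Kirchhoff stress:
#' \deqn{\sigma = p_h I + 2 J_e^{-1}\left[
#'   (\hat\rho_e \bar\Psi_{e,1} + \hat\rho_g \bar\Psi_{g,1})\,dev\,\bar b
#'   + \sum_i \hat\rho_{ci} \bar\Psi_{ci,4}\,dev\,\bar A_i\right]}
#' with the spatial deviator \eqn{dev(\cdot) = (\cdot) - \frac13 tr(\cdot) I}
#' and \eqn{\bar A_i = \bar F a_{0i} \otimes \bar F a_{0i}}.
#'
#' @param Fe elastic deformation gradient.
#' @param comp a [local_composition].
#' @param params a [material_params].
#' @param mode `"penalty"` computes \eqn{p_h = \kappa (J_e-1)};
#'   `"incompressible"` uses the supplied `ph` (and expects `det Fe = 1`).
#' @param ph hydrostatic pressure for `"incompressible"` mode (kPa).
#' @return symmetric 3x3 Cauchy stress (kPa).
#' @export
cauchy_stress <- function(Fe, comp, params,
                          mode = c("penalty", "incompressible"), ph = NULL) {
  mode <- match.arg(mode)
  inv <- isochoric_invariants(Fe)
  Je <- inv$Je
  if (mode == "penalty") {
    if (!is.null(ph)) stop("ph is determined by the penalty; do not supply it")
    ph <- params$kappa * (Je - 1)
  } else {
    if (is.null(ph)) stop("incompressible mode requires ph")
  }
  Fbar <- Je^(-1 / 3) * Fe
  bbar <- tcrossprod(Fbar)
  dev <- function(X) X - sum(diag(X)) / 3 * diag(3)
  sig <- ph * diag(3) +
    2 / Je * (comp$rho_hat_e * params$mu_e / 2 +
              comp$rho_hat_g * params$mu_g / 2) * dev(bbar)
  for (i in seq_along(comp$rho_hat_c)) {
    abar <- drop(Fbar %*% comp$a0[[i]])
    Abar <- tcrossprod(abar)
    I4 <- sum(abar^2)
    I4r <- comp$lambda_r[i]^2
    I4c <- fiber_stretch_sq(I4, comp$lambda_r[i])
    psi4 <- if (I4 > I4r)
      stress_factors(inv$I1bar, I4c, I4r, params)$psi_c4 else 0
    sig <- sig + 2 / Je * comp$rho_hat_c[i] * psi4 * dev(Abar)
  }
  (sig + t(sig)) / 2
}
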