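# Shared fixtures: random states are always drawn under a fixed seed inside
# each test; the calibrated fiber angle is computed once per session.

cached_gamma <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- calibrate_fiber_angle()$gamma
    val
  }
})

# random proper rotation (QR of a Gaussian matrix, det +1)
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# random deformation gradient with positive determinant, moderately strained
rand_F <- function(spread = 0.2) {
  repeat {
    F <- diag(3) + matrix(rnorm(9, sd = spread), 3)
    if (det(F) > 0.3) return(F)
  }
}

# random unit vector
rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# independent term-by-term strain energy as a function of C = Fe^T Fe,
# used as the finite-difference oracle for the stress
psi_of_C <- function(C, comp, params) {
  J <- sqrt(det(C))
  Cb <- det(C)^(-1 / 3) * C
  psi <- params$kappa / 2 * (J - 1)^2 +
    (comp$rho_hat_e * params$mu_e / 2 +
     comp$rho_hat_g * params$mu_g / 2) * (sum(diag(Cb)) - 3)
  for (i in seq_along(comp$rho_hat_c)) {
    I4 <- drop(comp$a0[[i]] %*% Cb %*% comp$a0[[i]])
    I4c <- max(I4 / comp$lambda_r[i]^2, 1)
    psi <- psi + comp$rho_hat_c[i] * params$k1 / (2 * params$k2) *
      (exp(params$k2 * (I4c - 1)^2) - 1)
  }
  psi
}

# symmetric finite-difference gradient 2 dPsi/dC
fd_second_pk <- function(Fe, comp, params, h = 1e-6) {
  C <- crossprod(Fe)
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    E <- matrix(0, 3, 3)
    E[i, j] <- E[i, j] + h / 2
    E[j, i] <- E[j, i] + h / 2
    d <- (psi_of_C(C + E, comp, params) -
          psi_of_C(C - E, comp, params)) / (2 * h)
    S[i, j] <- S[j, i] <- 2 * d
  }
  S
}
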