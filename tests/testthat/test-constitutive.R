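baseline_comp <- function(lambda_r = c(1.05, 1.05),
                          a0 = list(c(0, 1, 0), c(0, 0, 1))) {
  local_composition(rho_hat_e = 1, rho_hat_g = 1, rho_hat_c = c(1, 1),
                    lambda_r = lambda_r, a0 = a0)
}

test_that("strain energy vanishes in the reference state and for slack fibers", {
  p <- material_params()
  comp <- baseline_comp(lambda_r = c(1.2, 1.2))
  expect_equal(strain_energy(diag(3), comp, p), 0)
  # stretched along e1 only: both fibers (e2, e3) shorten -> slack, and the
  # collagen contribution must be exactly zero
  Fe <- diag(c(1.1, 1 / sqrt(1.1), 1 / sqrt(1.1)))
  no_col <- local_composition(1, 1, numeric(0), numeric(0), list())
  expect_equal(strain_energy(Fe, comp, p, volumetric = FALSE),
               strain_energy(Fe, no_col, p, volumetric = FALSE))
})

test_that("strain energy matches an independent term-by-term evaluation", {
  set.seed(31)
  p <- material_params()
  for (rep in 1:25) {
    Fe <- rand_F()
    comp <- baseline_comp(lambda_r = runif(2, 1, 1.15),
                          a0 = list(rand_unit(), rand_unit()))
    expect_equal(strain_energy(Fe, comp, p),
                 psi_of_C(crossprod(Fe), comp, p), tolerance = 1e-10)
  }
})

test_that("stress factors take the closed forms of the energy derivatives", {
  p <- material_params()
  sf <- stress_factors(3, 1, 1.2769, p)
  expect_equal(sf$psi_e1, 133.81 / 2)
  expect_equal(sf$psi_g1, 33.45 / 2)
  expect_equal(sf$psi_c4, 0)   # recruitment threshold
  sf2 <- stress_factors(3, 1.0572, 1.2769, p)
  # hand evaluation: k1/I4r * (I4c-1) * exp(k2 (I4c-1)^2)
  expect_equal(sf2$psi_c4,
               3.52 / 1.2769 * 0.0572 * exp(40 * 0.0572^2),
               tolerance = 1e-12)
  expect_equal(sf2$psi_c4, 0.180, tolerance = 2e-3)
})

test_that("second Piola-Kirchhoff stress equals 2 dPsi/dCe by finite differences", {
  set.seed(32)
  p <- material_params()
  nchecked <- 0
  for (rep in 1:120) {
    Fe <- rand_F(0.15)
    comp <- baseline_comp(lambda_r = runif(2, 1.0, 1.08),
                          a0 = list(rand_unit(), rand_unit()))
    # stay away from the recruitment kink where the energy is not smooth
    iv <- isochoric_invariants(Fe)
    I4 <- vapply(comp$a0, function(a) drop(a %*% iv$Cbar %*% a), numeric(1))
    if (any(abs(I4 / comp$lambda_r^2 - 1) < 5e-3)) next
    S <- second_pk_stress(Fe, comp, p)
    S_fd <- fd_second_pk(Fe, comp, p)
    expect_equal(S, S_fd, tolerance = 1e-5)
    nchecked <- nchecked + 1
  }
  expect_gte(nchecked, 100)
})

test_that("Cauchy stress is the push-forward of the second Piola-Kirchhoff stress", {
  set.seed(33)
  p <- material_params()
  for (rep in 1:20) {
    Fe <- rand_F()
    comp <- baseline_comp(a0 = list(rand_unit(), rand_unit()))
    Je <- det(Fe)
    sig_pf <- Fe %*% second_pk_stress(Fe, comp, p) %*% t(Fe) / Je
    expect_equal(cauchy_stress(Fe, comp, p), sig_pf, tolerance = 1e-9)
  }
})

test_that("Cauchy stress is objective and its deviatoric part is traceless", {
  set.seed(34)
  p <- material_params()
  for (rep in 1:20) {
    Fe <- rand_F()
    comp <- baseline_comp(a0 = list(rand_unit(), rand_unit()))
    Q <- rand_rotation()
    s1 <- cauchy_stress(Q %*% Fe, comp, p)
    s2 <- Q %*% cauchy_stress(Fe, comp, p) %*% t(Q)
    expect_equal(s1, s2, tolerance = 1e-9)
    Je <- det(Fe)
    dev_part <- cauchy_stress(Fe, comp, p) - p$kappa * (Je - 1) * diag(3)
    expect_lt(abs(sum(diag(dev_part))), 1e-10 * max(1, max(abs(dev_part))))
  }
})

test_that("reference state carries only the hydrostatic mode", {
  p <- material_params()
  comp <- baseline_comp(lambda_r = c(1.1, 1.1))
  expect_equal(cauchy_stress(diag(3), comp, p), matrix(0, 3, 3))
  expect_equal(cauchy_stress(diag(3), comp, p, mode = "incompressible",
                             ph = 5), 5 * diag(3))
  expect_error(cauchy_stress(diag(3), comp, p, mode = "incompressible"), "ph")
  expect_error(cauchy_stress(diag(3), comp, p, mode = "penalty", ph = 1),
               "penalty")
})

test_that("uniaxial incompressible response recovers the neo-Hookean closed form", {
  p <- material_params()
  comp <- baseline_comp(lambda_r = c(3, 3))    # collagen far slack
  for (lam in c(1.1, 1.3, 1.6)) {
    Fe <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
    s0 <- cauchy_stress(Fe, comp, p, mode = "incompressible", ph = 0)
    ph <- -s0[2, 2]
    sig <- s0 + ph * diag(3)
    expect_equal(sig[1, 1], (p$mu_e + p$mu_g) * (lam^2 - 1 / lam),
                 tolerance = 1e-10)
    expect_equal(sig[2, 2], 0, tolerance = 1e-12)
    expect_equal(sig[3, 3], 0, tolerance = 1e-12)
  }
})

test_that("a single active fiber family aligns the stress with the fiber", {
  p <- material_params()
  a0 <- c(0, 1, 0)
  comp <- local_composition(rho_hat_e = 0, rho_hat_g = 0, rho_hat_c = 1,
                            lambda_r = 1, a0 = list(a0))
  Fe <- diag(c(1 / sqrt(1.3), 1.3, 1 / sqrt(1.3)))
  sig <- cauchy_stress(Fe, comp, p, mode = "incompressible", ph = 0)
  ev <- eigen(sig)
  expect_equal(abs(ev$vectors[, 1]), a0, tolerance = 1e-10)
  expect_gt(ev$values[1], 0)
})

test_that("volumetric penalty drives Je to one as kappa grows", {
  target <- 20  # hydrostatic tension (kPa)
  comp <- local_composition(1, 1, numeric(0), numeric(0), list())
  err <- vapply(c(1e2, 1e3, 1e4), function(kap) {
    p <- material_params(kappa = kap)
    f <- function(J) cauchy_stress(J^(1 / 3) * diag(3), comp, p)[1, 1] - target
    J <- stats::uniroot(f, c(0.5, 3))$root
    abs(J - 1)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-2)
})
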