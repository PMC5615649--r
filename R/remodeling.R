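# Collagen turnover and prescribed elastin degradation on the slow
# remodeling time scale tau (years).  Collagen responds to the normalized
# gap between its current stretch and the attachment stretch at which new
# fibers are integrated; elastin loss is prescribed as an axially localized
# exponential decay.

#' Remodeling parameters
#'
#' @param alpha recruitment-stretch remodeling rate (1/year).
#' @param beta collagen net mass-growth rate (1/year).
#' @param lambda_a collagen attachment stretch (> 1).
#' @param lambda_rec0 initial collagen recruitment stretch.
#' @param c_min residual elastin fraction at the vessel center after time `T`.
#' @param T elastin degradation time (years).
#' @param m1 axial shape parameter of the degradation profile.
#' @param L vessel reference length (mm).
#' @param stimulus_form `"offset"` for
#'   \eqn{\xi = (\bar I_4^c - \bar I_4^a)/(\bar I_4^a - 1)} (default) or
#'   `"ratio"` for \eqn{\xi = \bar I_4^c/\bar I_4^a - 1} (sensitivity switch).
#' @return object of class `remodeling_params`.
#' @export
remodeling_params <- function(alpha = 0.6, beta = 1.0, lambda_a = 1.093,
                              lambda_rec0 = 1.13, c_min = 0.6, T = 10,
                              m1 = 20, L = 147.4,
                              stimulus_form = c("offset", "ratio")) {
  stimulus_form <- match.arg(stimulus_form)
  stopifnot(alpha > 0, beta > 0, T > 0, lambda_a > 1,
            c_min > 0, c_min <= 1, m1 >= 0, L > 0, lambda_rec0 > 0)
  structure(list(alpha = alpha, beta = beta, lambda_a = lambda_a,
                 lambda_rec0 = lambda_rec0, c_min = c_min, T = T,
                 m1 = m1, L = L, stimulus_form = stimulus_form),
            class = "remodeling_params")
}

#' Collagen state (recruitment stretch and normalized mass)
#'
#' @param lambda_r recruitment stretch, `> 0`.
#' @param m_hat_c normalized collagen mass, `> 0`.
#' @return object of class `collagen_state`.
#' @export
collagen_state <- function(lambda_r = 1.13, m_hat_c = 1) {
  stopifnot(lambda_r > 0, m_hat_c > 0)
  structure(list(lambda_r = lambda_r, m_hat_c = m_hat_c),
            class = "collagen_state")
}

#' Stretch-based turnover stimulus
#'
#' \deqn{\xi = \frac{\bar I_4^c - \bar I_4^a}{\bar I_4^a - 1}, \qquad
#'       \bar I_4^a = \bar\lambda_a^2.}
#' Vanishes at homeostasis (\eqn{\bar I_4^c = \bar I_4^a}); a fully slack
#' fiber (\eqn{\bar I_4^c = 1}) gives \eqn{\xi = -1}.
#'
#' @param I4c squared (clamped) collagen fiber stretch, `>= 1`.
#' @param params a [remodeling_params].
#' @return the stimulus \eqn{\xi}.
#' @export
stimulus <- function(I4c, params) {
  if (params$lambda_a <= 1) stop("lambda_a must be > 1")
  if (any(I4c < 1)) stop("I4c must be >= 1")
  I4a <- params$lambda_a^2
  if (params$stimulus_form == "offset") {
    (I4c - I4a) / (I4a - 1)
  } else {
    I4c / I4a - 1
  }
}

#' One forward-Euler step of the recruitment-stretch rate equation
#'
#' \eqn{\partial\bar\lambda_r/\partial\tau = \alpha\,\xi}.
#'
#' @param s a [collagen_state].
#' @param xi stimulus.
#' @param params a [remodeling_params].
#' @param dtau time step (years), `> 0`.
#' @return updated [collagen_state].
#' @export
step_recruitment <- function(s, xi, params, dtau) {
  stopifnot(dtau > 0)
  lr <- s$lambda_r + params$alpha * xi * dtau
  if (lr <= 0) stop("recruitment stretch became non-positive; reduce dtau")
  s$lambda_r <- lr
  s
}

#' One forward-Euler step of the collagen mass rate equation
#'
#' \eqn{\partial\hat m_c/\partial\tau = \beta\,\hat m_c\,\xi}.
#'
#' @inheritParams step_recruitment
#' @return updated [collagen_state].
#' @export
step_collagen_mass <- function(s, xi, params, dtau) {
  stopifnot(dtau > 0)
  m <- s$m_hat_c * (1 + params$beta * xi * dtau)
  if (m <= 0) stop("collagen mass became non-positive; reduce dtau")
  s$m_hat_c <- m
  s
}

#' Prescribed normalized elastin mass
#'
#' \deqn{\hat m_e(z, \tau) = 1 - \left(1 - c_{min}^{\tau/T}\right)
#'       \exp\left[-m_1 (2 z / L - 1)^2\right]}
#' Degradation is deepest at the vessel center \eqn{z = L/2}, where
#' \eqn{\hat m_e = c_{min}} at \eqn{\tau = T}; decay continues for
#' \eqn{\tau > T}.
#'
#' @param z axial coordinate (mm), in `[0, L]`.
#' @param tau remodeling time (years), `>= 0`.
#' @param params a [remodeling_params].
#' @return \eqn{\hat m_e \in (0, 1]} (vectorized over `z` and `tau`).
#' @export
elastin_mass <- function(z, tau, params) {
  if (any(z < 0) || any(z > params$L)) stop("z out of range [0, L]")
  if (any(tau < 0)) stop("tau must be >= 0")
  1 - (1 - params$c_min^(tau / params$T)) *
    exp(-params$m1 * (2 * z / params$L - 1)^2)
}
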