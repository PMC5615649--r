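# Normalized mass/volume/density bookkeeping for a constrained mixture.
#
# Every quantity is normalized by its value at the onset of remodeling
# (tau = 0): m_hat is constituent mass change, v_hat volume change, rho_hat
# partial-density change.  Deposition follows one of two extremal rules:
#   CCD -- constant constituent density: volume grows with mass, v_hat = m_hat
#   CCV -- constant constituent volume:  density grows with mass, v_hat = 1

#' Deposition rules
#'
#' Constituent mass may be added/removed at constant constituent density
#' (`"CCD"`, volume follows mass) or at constant constituent volume
#' (`"CCV"`, density follows mass).
#' @export
deposition_rules <- c("CCD", "CCV")

#' Create a constituent state
#'
#' @param name identifier, e.g. `"elastin"`, `"ground"`, `"collagen1"`.
#' @param rule deposition rule, one of [deposition_rules].
#' @param phi0 initial volume fraction within its layer, in `[0, 1]`.
#' @param m_hat normalized mass \eqn{\hat m = m(\tau)/m(0) \ge 0}.
#' @return an object of class `constituent_state`.
#' @export
constituent_state <- function(name, rule, phi0, m_hat = 1) {
  rule <- match.arg(rule, deposition_rules)
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(phi0) || phi0 < 0 || phi0 > 1)
    stop("phi0 must lie in [0, 1]")
  if (!is.numeric(m_hat) || m_hat < 0)
    stop("m_hat must be >= 0")
  structure(list(name = name, rule = rule, phi0 = phi0, m_hat = m_hat),
            class = "constituent_state")
}

#' Normalized volume change of a single constituent
#'
#' A CCD constituent changes volume in proportion to its mass; a CCV
#' constituent never changes volume.
#'
#' @param c a [constituent_state].
#' @return `m_hat` under CCD, `1` under CCV.
#' @export
constituent_volume_change <- function(c) {
  stopifnot(inherits(c, "constituent_state"))
  if (c$m_hat < 0) stop("invalid state: negative m_hat")
  if (c$rule == "CCD") c$m_hat else 1.0
}

#' Assemble a mixture composition
#'
#' Volume fractions are per layer and must sum to one.
#'
#' @param ... [constituent_state] objects.
#' @param tol tolerance on the fraction sum.
#' @return an object of class `mixture_composition`.
#' @export
mixture_composition <- function(..., tol = 1e-12) {
  cs <- list(...)
  if (length(cs) == 1L && is.list(cs[[1]]) && !inherits(cs[[1]], "constituent_state"))
    cs <- cs[[1]]
  if (length(cs) == 0L) stop("empty mixture")
  ok <- vapply(cs, inherits, logical(1), "constituent_state")
  if (!all(ok)) stop("all arguments must be constituent_state objects")
  s <- sum(vapply(cs, function(x) x$phi0, numeric(1)))
  if (abs(s - 1) > tol)
    stop(sprintf("volume fractions sum to %.15g, not 1", s))
  names(cs) <- vapply(cs, function(x) x$name, character(1))
  structure(list(constituents = cs), class = "mixture_composition")
}

#' Normalized tissue volume change of a mixture
#'
#' \deqn{\hat v = \sum_{\zeta \in CCD} \hat m_\zeta \phi_\zeta(0) +
#'               \sum_{\zeta \in CCV} \phi_\zeta(0)}
#'
#' @param mix a [mixture_composition].
#' @return the scalar \eqn{\hat v > 0}.
#' @export
tissue_volume_change <- function(mix) {
  stopifnot(inherits(mix, "mixture_composition"))
  cs <- mix$constituents
  if (length(cs) == 0L) stop("empty mixture")
  sum(vapply(cs, function(x) constituent_volume_change(x) * x$phi0, numeric(1)))
}

# vectorized kernel used by the vessel engine: m_hat, phi0, ccd are aligned
# vectors/matrices (one entry per constituent); returns sum over constituents.
.v_hat_num <- function(m_hat, phi0, ccd) {
  sum(ifelse(ccd, m_hat, 1) * phi0)
}

#' Normalized partial-density change of a constituent
#'
#' The partial density refers constituent mass to tissue volume, so its
#' normalized change is forced to \eqn{\hat\rho_\zeta = \hat m_\zeta / \hat v}
#' by constancy of the true density.
#'
#' @param m_hat normalized constituent mass.
#' @param v_hat normalized tissue volume change, `> 0`.
#' @return \eqn{\hat\rho_\zeta}.
#' @export
partial_density_change <- function(m_hat, v_hat) {
  if (any(v_hat <= 0)) stop("v_hat must be > 0")
  if (any(m_hat < 0)) stop("m_hat must be >= 0")
  m_hat / v_hat
}
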