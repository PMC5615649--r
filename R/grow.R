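# Phase-2 aneurysm evolution: explicit forward-Euler stepping of collagen
# recruitment and mass under the stretch-based stimulus, prescribed elastin
# degradation along the vessel axis, and re-equilibration of every section
# at each step of the slow time scale tau.

#' Grow an aneurysm from the homeostatic state
#'
#' Per time step and section: evaluate the prescribed elastin mass, compute
#' the turnover stimulus from the previously equilibrated state, advance the
#' collagen recruitment stretch and mass by forward Euler, recompute the
#' tissue volume change and growth tensor, and re-equilibrate.  If an
#' equilibrium solve fails the step is retried with up to four halvings of
#' the time step before the run is truncated with an explicit status
#' (mirroring termination on uncontrolled expansion).
#'
#' @param ves a homeostatic `vessel` (see [homeostasis_solve()]).
#' @param dtau time step (years).
#' @param tau_end end of the simulation (years).
#' @param stop_dhat optional early-stop threshold on the normalized mid-
#'   vessel diameter `di/d0`.
#' @param milestones normalized diameters at which transmural snapshots are
#'   recorded (default `c(1.5, 2)`).
#' @return object of class `simulation_record`: per-step series at the
#'   mid-vessel inner-wall point (diameter, thickness, collagen stretch and
#'   mass, local and total volume change), thickness-vs-z profiles,
#'   transmural snapshots at the milestones, and a termination status.
#' @export
grow <- function(ves, dtau = 0.01, tau_end = 10, stop_dhat = NULL,
                 milestones = c(1.5, 2)) {
  stopifnot(inherits(ves, "vessel"), dtau > 0, tau_end > 0)
  if (!isTRUE(ves$homeostatic))
    stop("grow() requires a homeostatic vessel; run homeostasis_solve() first")
  if (is.null(ves$solved)) stop("vessel has no solved state")
  geom <- ves$geom; rem <- ves$remod
  nz <- length(ves$z); nr <- length(ves$Rpts)
  d0 <- ves$d0; h0 <- ves$h0
  wR <- ves$w * ves$Rpts               # reference volume weights (per section)
  Vref <- sum(wR) * nz
  nmax <- ceiling(tau_end / dtau) + 1L
  ser <- data.frame(tau = numeric(nmax), di = NA_real_, d_hat = NA_real_,
                    h_mid = NA_real_, lambda_c_A = NA_real_,
                    m_hat_c_A = NA_real_, v_hat_A = NA_real_,
                    V_hat_tot = NA_real_)
  thick_z <- matrix(NA_real_, nmax, nz)
  snaps <- list()
  status <- "completed"
  record_row <- function(i, tau, v) {
    ser$tau[i] <<- tau
    ser$di[i] <<- 2 * v$solved$ri[1]
    ser$d_hat[i] <<- ser$di[i] / d0
    ser$h_mid[i] <<- v$solved$h[1]
    ser$lambda_c_A[i] <<- sqrt(v$solved$I4c[1, 1])
    ser$m_hat_c_A[i] <<- v$m_hat_c[1, 1]
    ser$v_hat_A[i] <<- v$v_hat[1, 1]
    ser$V_hat_tot[i] <<- sum(wR * v$v_hat) / Vref
    thick_z[i, ] <<- v$solved$h
  }
  take_snapshot <- function(tau, v, ms) {
    list(tau = tau, d_hat = 2 * v$solved$ri[1] / d0, milestone = ms,
         Rpts = ves$Rpts,
         lambda_c = sqrt(v$solved$I4c[, 1]),
         v_hat = v$v_hat[, 1],
         sigma_tt = v$solved$sigma_tt[, 1],
         thickness_z = v$solved$h)
  }
  # one Euler substep of size dt from time tau; returns vessel or NULL
  advance <- function(v, tau, dt) {
    xi <- stimulus(v$solved$I4c, rem)
    v$m_hat_e <- elastin_mass(v$z, tau + dt, rem)
    v$lambda_r <- pmax(v$lambda_r + rem$alpha * xi * dt, 1)
    v$m_hat_c <- v$m_hat_c * (1 + rem$beta * xi * dt)
    if (any(v$m_hat_c <= 0)) return(NULL)
    tryCatch(equilibrium_solve(v), error = function(e) NULL)
  }
  step_adaptive <- function(v, tau, dt, depth = 0) {
    v2 <- advance(v, tau, dt)
    if (!is.null(v2)) return(v2)
    if (depth >= 4) return(NULL)
    v2 <- step_adaptive(v, tau, dt / 2, depth + 1)
    if (is.null(v2)) return(NULL)
    step_adaptive(v2, tau + dt / 2, dt / 2, depth + 1)
  }
  i <- 1L
  record_row(i, 0, ves)
  pending <- sort(milestones)
  tau <- 0
  while (tau < tau_end - 1e-12) {
    dt <- min(dtau, tau_end - tau)
    v2 <- step_adaptive(ves, tau, dt)
    if (is.null(v2)) { status <- "truncated"; break }
    ves <- v2
    tau <- tau + dt
    i <- i + 1L
    record_row(i, tau, ves)
    while (length(pending) && ser$d_hat[i] >= pending[1]) {
      snaps[[sprintf("%g", pending[1])]] <- take_snapshot(tau, ves, pending[1])
      pending <- pending[-1]
    }
    if (!is.null(stop_dhat) && ser$d_hat[i] >= stop_dhat) {
      status <- "stopped_at_dhat"
      break
    }
  }
  ser <- ser[seq_len(i), ]
  thick_z <- thick_z[seq_len(i), , drop = FALSE]
  structure(list(series = ser, thickness_z = thick_z, z = ves$z,
                 d0 = d0, h0 = h0, kind = ves$kind,
                 beta = rem$beta, dtau = dtau,
                 milestones = snaps, status = status,
                 final = ves),
            class = "simulation_record")
}

# first upward crossing of a threshold, linearly interpolated; NA if never
.crossing_time <- function(tau, y, threshold) {
  above <- y >= threshold
  if (isTRUE(above[1])) return(tau[1])
  k <- which(!above[-length(above)] & above[-1])
  if (!length(k)) return(NA_real_)
  k <- k[1]
  tau[k] + (threshold - y[k]) * (tau[k + 1] - tau[k]) / (y[k + 1] - y[k])
}

#' Derived measurements of a growth simulation
#'
#' Growth rate as a centered finite difference of the maximum diameter over
#' a sliding window, clinically motivated crossing times (diameter and
#' growth-rate repair indications), and volume-change summaries.
#'
#' @param record a `simulation_record` from [grow()].
#' @param window growth-rate window (years).
#' @param d_repair,rate_repair repair-indication thresholds (mm, mm/year).
#' @return list with the growth-rate series and scalar summaries.
#' @export
measure <- function(record, window = 1, d_repair = 55, rate_repair = 10) {
  stopifnot(inherits(record, "simulation_record"))
  s <- record$series
  if (nrow(s) < 2) stop("record too short to measure")
  span <- s$tau[nrow(s)] - s$tau[1]
  if (window > span)
    stop("growth-rate window (", window, " y) exceeds the series span (",
         signif(span, 4), " y)")
  dfun <- stats::approxfun(s$tau, s$di, rule = 2)
  rate <- (dfun(pmin(s$tau + window / 2, max(s$tau))) -
           dfun(pmax(s$tau - window / 2, min(s$tau)))) /
    (pmin(s$tau + window / 2, max(s$tau)) -
     pmax(s$tau - window / 2, min(s$tau)))
  t_d <- .crossing_time(s$tau, s$di, d_repair)
  t_r <- .crossing_time(s$tau, rate, rate_repair)
  list(growth_rate = data.frame(tau = s$tau, rate = rate),
       peak_rate = max(rate),
       time_to_dhat_1.5 = .crossing_time(s$tau, s$d_hat, 1.5),
       time_to_dhat_2 = .crossing_time(s$tau, s$d_hat, 2),
       time_to_diameter = t_d,
       time_to_rate = t_r,
       time_to_repair = {
         tr <- suppressWarnings(min(t_d, t_r, na.rm = TRUE))
         if (is.finite(tr)) tr else NA_real_
       },
       final_h_mid = s$h_mid[nrow(s)],
       max_V_hat_tot = max(s$V_hat_tot),
       max_v_hat_A = max(s$v_hat_A),
       status = record$status)
}
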