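# Configuration schema (YAML), study drivers, and tabular/manifest writers.
#
# A run configuration is a plain named list mirroring the YAML layout; every
# default is the baseline parameter set shipped with the package (see
# inst/extdata/baseline.yaml).  All computation is deterministic -- no
# random numbers are drawn anywhere in a run.

#' Baseline run configuration
#'
#' Reference geometry, loads, material constants, composition, remodeling
#' rates and solver settings of the abdominal-aorta model.  The collagen
#' fiber angle is calibrated (to the target homeostatic diameter) when
#' `fiber$angle_deg` is `NULL`.
#'
#' @return nested named list (`run_config`).
#' @export
default_config <- function() {
  structure(list(
    geometry = list(Ri = 8.4, HM = 1.18, HA = 0.59, L = 147.4,
                    lambda_z = 1.2, p_i = 16),
    material = list(mu_e = 133.81, mu_g = 33.45, k1 = 3.52, k2 = 40,
                    kappa = 100),
    composition = list(
      media = list(phi_e = 0.12, phi_c = 0.075),
      adventitia = list(phi_c = 0.075),
      rules = list(elastin = "CCV", ground = "CCV", collagen = "CCD")),
    remodeling = list(alpha = 0.6, beta = 1.0, lambda_a = 1.093,
                      lambda_rec0 = 1.13, c_min = 0.6, T = 10, m1 = 20,
                      stimulus_form = "offset"),
    fiber = list(angle_deg = NULL, target_d0 = 23),
    kinematics = "TVG",
    schedule = list(dtau = 0.01, tau_end = 10),
    solver = list(n_radial = 4, n_axial = 30, mode = "exact")),
    class = "run_config")
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.null(override[[nm]])) next   # never delete a defaulted key
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, fills every missing key from [default_config()] and
#' validates the result.  An empty file yields the full baseline.
#'
#' @param path YAML file path.
#' @return validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .merge_config(default_config(), user)
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg a `run_config` list.
#' @return the config (invisibly classed), or an error listing offending keys.
#' @export
validate_config <- function(cfg) {
  bad <- character(0)
  known <- names(default_config())
  extra <- setdiff(names(cfg), known)
  if (length(extra)) bad <- c(bad, paste0("unknown key(s): ",
                                          paste(extra, collapse = ", ")))
  g <- cfg$geometry
  if (any(unlist(g[c("Ri", "HM", "HA", "L", "lambda_z")]) <= 0))
    bad <- c(bad, "geometry: Ri, HM, HA, L, lambda_z must be > 0")
  if (g$p_i < 0) bad <- c(bad, "geometry$p_i must be >= 0")
  if (!cfg$kinematics %in% kinematics_kinds)
    bad <- c(bad, "kinematics must be one of IVG, PVG, TVG, NVG")
  rl <- cfg$composition$rules
  if (!all(unlist(rl) %in% deposition_rules))
    bad <- c(bad, "composition$rules entries must be CCD or CCV")
  if (identical(cfg$kinematics, "NVG") && any(unlist(rl) == "CCD"))
    bad <- c(bad, "NVG kinematics requires an all-CCV deposition assignment")
  cm <- cfg$composition$media
  if (cm$phi_e + 2 * cm$phi_c > 1)
    bad <- c(bad, "medial fractions exceed 1 (ground matrix absorbs the complement)")
  if (2 * cfg$composition$adventitia$phi_c > 1)
    bad <- c(bad, "adventitial collagen fractions exceed 1")
  if (cfg$schedule$dtau <= 0 || cfg$schedule$tau_end <= 0)
    bad <- c(bad, "schedule: dtau and tau_end must be > 0")
  if (!cfg$solver$mode %in% c("exact", "penalty"))
    bad <- c(bad, "solver$mode must be 'exact' or 'penalty'")
  if (length(bad))
    stop("invalid configuration:\n  - ", paste(bad, collapse = "\n  - "))
  class(cfg) <- "run_config"
  cfg
}

#' Write a configuration to YAML
#'
#' @param cfg a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# model pieces from a config
.cfg_geom <- function(cfg) do.call(vessel_geometry, cfg$geometry)
.cfg_mat <- function(cfg) do.call(material_params, cfg$material)
.cfg_remod <- function(cfg) {
  r <- cfg$remodeling
  remodeling_params(alpha = r$alpha, beta = r$beta, lambda_a = r$lambda_a,
                    lambda_rec0 = r$lambda_rec0, c_min = r$c_min, T = r$T,
                    m1 = r$m1, L = cfg$geometry$L,
                    stimulus_form = r$stimulus_form)
}
.cfg_composition <- function(cfg) {
  cm <- cfg$composition
  baseline_composition(phi_e_media = cm$media$phi_e,
                       phi_c_media = cm$media$phi_c,
                       phi_c_adv = cm$adventitia$phi_c,
                       elastin_rule = cm$rules$elastin,
                       collagen_rule = cm$rules$collagen,
                       ground_rule = cm$rules$ground)
}

#' Resolve the collagen fiber angle of a configuration
#'
#' Returns the configured angle, or calibrates it to the target homeostatic
#' diameter when `fiber$angle_deg` is `NULL`.
#'
#' @param cfg a `run_config`.
#' @return angle in radians.
#' @export
resolve_fiber_angle <- function(cfg) {
  if (!is.null(cfg$fiber$angle_deg)) return(cfg$fiber$angle_deg * pi / 180)
  cal <- calibrate_fiber_angle(.cfg_geom(cfg), .cfg_mat(cfg),
                               .cfg_composition(cfg), .cfg_remod(cfg),
                               target_d = cfg$fiber$target_d0,
                               n_radial_per_layer = cfg$solver$n_radial)
  cal$gamma
}

#' Build a vessel model from a configuration
#'
#' @param cfg a `run_config`.
#' @param gamma fiber angle (rad); resolved from the config when missing.
#' @param n_axial number of axial stations (defaults to the config value).
#' @return a `vessel` (not yet homeostatic).
#' @export
vessel_from_config <- function(cfg, gamma = NULL, n_axial = NULL) {
  cfg <- validate_config(cfg)
  if (is.null(gamma)) gamma <- resolve_fiber_angle(cfg)
  build_vessel(.cfg_geom(cfg), .cfg_mat(cfg), .cfg_composition(cfg),
               .cfg_remod(cfg), cfg$solver$n_radial,
               if (is.null(n_axial)) cfg$solver$n_axial else n_axial,
               gamma, cfg$kinematics)
}

#' Define a parameter study
#'
#' `study1` sweeps the collagen net-growth rate beta over all four growth
#' kinematics (collagen CCD / elastin CCV; NVG all-CCV).  `study2` sweeps
#' initial volume fractions: elastin 0.12/0.18 (elastin CCD, others CCV)
#' and per-family medial collagen 0.075/0.15 (collagen CCD, others CCV).
#' Note the collagen sweep is stated elsewhere as total fractions
#' \{0.75, 0.15\}; 0.75 per family is geometrically impossible (fractions
#' would exceed one) and is interpreted as per-family \{0.075, 0.15\}.
#'
#' @param id `"study1"` or `"study2"`.
#' @param kinds kinematics kinds to run.
#' @param beta beta sweep for study 1 (1/year).
#' @param phi_e,phi_c fraction sweeps for study 2.
#' @return object of class `study_spec`.
#' @export
study_spec <- function(id = c("study1", "study2"),
                       kinds = kinematics_kinds,
                       beta = c(0.75, 1.00, 1.25),
                       phi_e = c(0.12, 0.18),
                       phi_c = c(0.075, 0.15)) {
  id <- match.arg(id)
  structure(list(id = id, kinds = kinds, beta = beta,
                 phi_e = phi_e, phi_c = phi_c), class = "study_spec")
}

# deposition assignment for a run: NVG forces all-CCV
.assign_rules <- function(cfg, kind, questioned = "collagen") {
  rules <- list(elastin = "CCV", ground = "CCV", collagen = "CCV")
  if (kind != "NVG") rules[[questioned]] <- "CCD"
  cfg$composition$rules <- rules
  cfg$kinematics <- kind
  cfg
}

#' Run a parameter study
#'
#' One growth simulation per (kinematics kind x sweep value), sharing the
#' calibrated fiber angle of the base configuration.  Individual run
#' failures are recorded and the study continues.
#'
#' Runs terminate at fourfold diameter expansion (`stop_dhat = 4`),
#' mirroring the termination of the full-field model once the aneurysm
#' reaches about four times its initial diameter.
#'
#' @param spec a [study_spec].
#' @param base base `run_config` (defaults from [default_config()]).
#' @param gamma fiber angle (rad); calibrated from `base` when `NULL`.
#' @param n_axial,tau_end,dtau optional overrides of the base schedule.
#' @param stop_dhat early-stop threshold on the normalized diameter.
#' @return list with `runs` (named list of `simulation_record`s) and
#'   `summary` (one row per run, deterministic order).
#' @export
run_study <- function(spec, base = default_config(), gamma = NULL,
                      n_axial = NULL, tau_end = NULL, dtau = NULL,
                      stop_dhat = 4) {
  stopifnot(inherits(spec, "study_spec"))
  base <- validate_config(base)
  if (is.null(gamma)) gamma <- resolve_fiber_angle(base)
  if (!is.null(tau_end)) base$schedule$tau_end <- tau_end
  if (!is.null(dtau)) base$schedule$dtau <- dtau
  variants <- list()
  if (spec$id == "study1") {
    for (k in spec$kinds) for (b in spec$beta) {
      cfg <- .assign_rules(base, k, "collagen")
      cfg$remodeling$beta <- b
      variants[[sprintf("%s_beta%.2f", k, b)]] <- cfg
    }
  } else {
    for (k in spec$kinds) {
      for (pe in spec$phi_e) {
        cfg <- .assign_rules(base, k, "elastin")
        cfg$composition$media$phi_e <- pe
        variants[[sprintf("%s_phie%.2f", k, pe)]] <- cfg
      }
      for (pc in spec$phi_c) {
        cfg <- .assign_rules(base, k, "collagen")
        cfg$composition$media$phi_c <- pc
        variants[[sprintf("%s_phic%.3f", k, pc)]] <- cfg
      }
    }
  }
  runs <- list()
  rows <- list()
  for (nm in names(variants)) {
    cfg <- variants[[nm]]
    rec <- tryCatch({
      v <- vessel_from_config(cfg, gamma = gamma, n_axial = n_axial)
      v <- homeostasis_solve(v, mode = cfg$solver$mode)
      grow(v, dtau = cfg$schedule$dtau, tau_end = cfg$schedule$tau_end,
           stop_dhat = stop_dhat)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      rows[[nm]] <- data.frame(run = nm, kind = cfg$kinematics,
                               beta = cfg$remodeling$beta,
                               phi_e = cfg$composition$media$phi_e,
                               phi_c = cfg$composition$media$phi_c,
                               status = paste("failed:", conditionMessage(rec)),
                               time_to_dhat_1.5 = NA, time_to_dhat_2 = NA,
                               time_to_diameter = NA, time_to_repair = NA,
                               peak_rate = NA, final_h_mid = NA,
                               max_V_hat_tot = NA, max_v_hat_A = NA)
      next
    }
    runs[[nm]] <- rec
    span <- max(rec$series$tau) - min(rec$series$tau)
    m <- measure(rec, window = min(1, span))
    rows[[nm]] <- data.frame(run = nm, kind = cfg$kinematics,
                             beta = cfg$remodeling$beta,
                             phi_e = cfg$composition$media$phi_e,
                             phi_c = cfg$composition$media$phi_c,
                             status = rec$status,
                             time_to_dhat_1.5 = m$time_to_dhat_1.5,
                             time_to_dhat_2 = m$time_to_dhat_2,
                             time_to_diameter = m$time_to_diameter,
                             time_to_repair = m$time_to_repair,
                             peak_rate = m$peak_rate,
                             final_h_mid = m$final_h_mid,
                             max_V_hat_tot = m$max_V_hat_tot,
                             max_v_hat_A = m$max_v_hat_A)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(runs = runs, summary = summary, gamma = gamma, spec = spec)
}

#' Write a simulation record to disk
#'
#' Writes the per-step series and the thickness-vs-z profile as CSV plus a
#' JSON manifest (configuration echo, package version, termination status).
#'
#' @param record a `simulation_record`.
#' @param dir output directory (created if missing).
#' @param name file-name stem.
#' @param config optional `run_config` echoed into the manifest.
#' @return named character vector of written paths, invisibly.
#' @export
write_record <- function(record, dir, name = "run", config = NULL) {
  stopifnot(inherits(record, "simulation_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_series <- file.path(dir, paste0(name, "_series.csv"))
  utils::write.csv(record$series, p_series, row.names = FALSE)
  tz <- data.frame(z = record$z,
                   thickness = record$thickness_z[nrow(record$thickness_z), ])
  p_thick <- file.path(dir, paste0(name, "_thickness_z.csv"))
  utils::write.csv(tz, p_thick, row.names = FALSE)
  manifest <- list(
    package = "vesselgrow",
    version = as.character(utils::packageVersion("vesselgrow")),
    kind = record$kind, beta = record$beta, dtau = record$dtau,
    d0 = record$d0, h0 = record$h0, status = record$status,
    config = if (is.null(config)) NULL else unclass(config))
  p_man <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, p_man, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(series = p_series, thickness = p_thick, manifest = p_man))
}
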