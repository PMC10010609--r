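#' Read and write experiment series CSV files
#'
#' Flat CSV with header `kind,x,Jv_ul_per_s,operating_pressure_MPa`; the
#' bath composition travels in the run configuration, not in the CSV.
#'
#' @param series an [experiment_series].
#' @param path CSV path.
#' @param bath a [bath_solution] attached to the series on reading.
#' @return `write_experiment` returns `path` invisibly; `read_experiment`
#'   returns an [experiment_series].
#' @export
write_experiment <- function(series, path) {
  op <- attr(series, "operating_pressure")
  out <- data.frame(kind = attr(series, "kind"), x = series$x,
                    Jv_ul_per_s = series$Jv,
                    operating_pressure_MPa = if (is.null(op)) NA_real_ else op)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(path, bath = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("kind", "x", "Jv_ul_per_s")
  if (!all(req %in% names(tab))) {
    stop("experiment CSV lacks columns: ",
         paste(setdiff(req, names(tab)), collapse = ", "), call. = FALSE)
  }
  kind <- unique(tab$kind)
  if (length(kind) != 1) stop("mixed experiment kinds in one file", call. = FALSE)
  op <- if ("operating_pressure_MPa" %in% names(tab)) {
    tab$operating_pressure_MPa[1]
  } else {
    NA_real_
  }
  experiment_series(kind, x = tab$x, Jv = tab$Jv_ul_per_s, bath = bath,
                    operating_pressure = op)
}

#' Export a steady state as a per-REV table
#'
#' One row per REV with geometry and solved fields, suitable for heat-map
#' rendering of pressures, concentrations and radial fluxes over the
#' architecture.
#'
#' @param state a `solve_state`.
#' @param g the `rev_graph` it was solved on.
#' @param path optional CSV path; when NULL the data.frame is returned only.
#' @return the per-REV data.frame, invisibly if written.
#' @export
solve_state_table <- function(state, g, path = NULL) {
  n <- g$nodes
  out <- data.frame(rev_id = n$rev_id, axis_id = n$axis_id, order = n$order,
                    dist_tip_m = n$dist_tip, length_m = n$length,
                    diameter_m = n$diameter,
                    P_MPa = state$P, C_mol_m3 = state$C,
                    C_peg_kg_l = state$C_peg,
                    j_m3_s = state$j, J_m3_s = state$J,
                    j_s_mol_s = state$j_s)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}

#' Write a fit result to JSON
#'
#' @param fr a `fit_result`.
#' @param path JSON path.
#' @param residual_csv optional path for the per-point residual table.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fr, path, residual_csv = NULL) {
  payload <- list(
    k_m_per_MPa_s = fr$params$k,
    sigma = fr$params$sigma,
    Js_star_mol_m2_s = fr$params$Js_star,
    Ps_m_s = fr$params$Ps,
    K_knots = list(dist_m = fr$params$K_knots$dist,
                   K_m4_MPa_s = fr$params$K_knots$K),
    F_ul2_s2 = fr$F,
    R2 = fr$R2,
    P0_MPa = if (!is.null(fr$P0)) fr$P0 else NULL,
    stage_trace = fr$stage_trace)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(residual_csv)) {
    utils::write.csv(fr$residuals, residual_csv, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

# polynomial rolling hash of the canonical JSON of a list; enough to
# fingerprint a configuration in run manifests
.config_hash <- function(x) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(txt))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run configuration
#'
#' Reads (or builds) the YAML configuration shared by all command-line
#' entries. Every physical quantity carries an explicit unit suffix in its
#' key name to avoid mixed-unit mistakes.
#'
#' @param path YAML file, or NULL for defaults.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(path = NULL) {
  defaults <- list(
    schema_version = 1L,
    bath = list(Pe_MPa = 0, Ce_mol_m3 = 13.72, w_peg_kg_l = 0, T_K = 298),
    discretization = list(l_target_m = 1e-3),
    solver = list(tol = 1e-8, max_iter = 500L, damping = 0.5,
                  viscosity_coupling = TRUE,
                  basal_inflow = "zero_gradient"),
    params = list(k_m_per_MPa_s = 1e-7, sigma = 0.85,
                  Js_star_mol_m2_s = 1e-7, Ps_m_s = 1e-9,
                  K_knots_dist_m = c(0.05, 0.15),
                  K_knots_m4_MPa_s = c(1e-12, 1e-10)),
    generator = list(primary_length_m = 0.35, lateral_density_per_m = 60,
                     lateral_length_mean_m = 0.04,
                     lateral_length_sd_m = 0.015, apical_zone_m = 0.02,
                     condition = "CTR"),
    protocol = list(pressure_steps_MPa = default_pressure_steps(),
                    operating_pressure_MPa = NA,
                    noise_sd_rel = 0),
    fit = list(stage1_maxit = 40L, stage2_maxit = 30L,
               stage3_maxit = 40L, monotone_K = TRUE),
    seed = 1L)
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(defaults, user)
  }
  stopifnot(cfg$solver$tol > 0, cfg$discretization$l_target_m > 0)
  class(cfg) <- c("run_config", "list")
  cfg
}

.cfg_bath <- function(cfg, Pe = cfg$bath$Pe_MPa) {
  bath_solution(Pe = Pe, Ce = cfg$bath$Ce_mol_m3,
                w_peg = cfg$bath$w_peg_kg_l, T = cfg$bath$T_K)
}

.cfg_params <- function(cfg) {
  transport_params(
    k = cfg$params$k_m_per_MPa_s,
    K_knots = data.frame(dist = cfg$params$K_knots_dist_m,
                         K = cfg$params$K_knots_m4_MPa_s),
    sigma = cfg$params$sigma,
    Js_star = cfg$params$Js_star_mol_m2_s,
    Ps = cfg$params$Ps_m_s,
    T = cfg$bath$T_K)
}

.cfg_control <- function(cfg) {
  solve_control(tol = cfg$solver$tol, max_iter = cfg$solver$max_iter,
                damping = cfg$solver$damping,
                viscosity_coupling = cfg$solver$viscosity_coupling,
                basal_inflow = cfg$solver$basal_inflow)
}

.write_manifest <- function(cfg, out_dir, outputs) {
  manifest <- list(package = "rootflow",
                   version = as.character(utils::packageVersion("rootflow")),
                   config_hash = .config_hash(unclass(cfg)),
                   seed = cfg$seed,
                   outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
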