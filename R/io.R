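#' Readers and writers for the pipeline's file formats
#'
#' Tabular data travel as CSV, parameters and metrics as JSON, and
#' configuration as YAML.  Schemas:
#' biaxial CSV \code{time_s, pressure_mmHg, outer_diameter_um,
#' axial_length_um, axial_force_mN, protocol_id};
#' geometry JSON \code{\{"L_um", "OD_um", "H_um", "lambda_z_iv"\}};
#' parameters JSON \code{\{"c_kPa", "families": [\{"alpha0_deg",
#' "c1_kPa", "c2"\}, ...]\}}.
#'
#' @name pamech-io
NULL

#' @rdname pamech-io
#' @param path file path.
#' @return \code{read_biaxial_csv}: a data.frame of biaxial records.
#' @export
read_biaxial_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pressure_mmHg", "outer_diameter_um", "axial_length_um",
            "axial_force_mN")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("biaxial CSV lacks columns: ", paste(miss, collapse = ", "))
  df
}

#' @rdname pamech-io
#' @param data biaxial record data.frame.
#' @export
write_biaxial_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pamech-io
#' @export
read_geometry_json <- function(path) {
  g <- jsonlite::fromJSON(path)
  unloaded_geometry(g$L_um, g$OD_um, g$H_um,
                    lambda_z_iv = g$lambda_z_iv)
}

#' @rdname pamech-io
#' @param geom an \code{\link{unloaded_geometry}}.
#' @export
write_geometry_json <- function(geom, path) {
  jsonlite::write_json(
    list(L_um = geom$L_um, OD_um = geom$OD_um, H_um = geom$H_um,
         lambda_z_iv = geom$lambda_z_iv),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname pamech-io
#' @export
read_params_json <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  fam <- p$families
  diag <- fam[fam$alpha0_deg > 0 & fam$alpha0_deg < 90, , drop = FALSE]
  four_fiber_params(
    c_kPa = p$c_kPa,
    c1_axial_kPa = fam$c1_kPa[fam$alpha0_deg == 0],
    c2_axial = fam$c2[fam$alpha0_deg == 0],
    c1_circ_kPa = fam$c1_kPa[fam$alpha0_deg == 90],
    c2_circ = fam$c2[fam$alpha0_deg == 90],
    c1_diag_kPa = diag$c1_kPa[1], c2_diag = diag$c2[1],
    alpha0_deg = diag$alpha0_deg[1])
}

#' @rdname pamech-io
#' @param params a \code{\link{four_fiber_params}}.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(
    list(c_kPa = params$c_kPa,
         families = data.frame(alpha0_deg = params$alpha0_deg,
                               c1_kPa = params$c1_kPa, c2 = params$c2)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

pipeline_config_keys <- c("seed", "out_dir", "simulate", "fit", "pwv",
                          "vaso", "histology", "stats")

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order on a simulated
#' two-group cohort: biaxial simulation, constitutive fitting, stored
#' energy/stiffness/PWV, vasoactive summaries, histology fractions, and
#' the group statistics, writing every artifact under \code{out_dir}.
#' All randomness derives from the configured seed, so a rerun with the
#' same configuration reproduces the bundle exactly.
#'
#' @param config a YAML file path or an equivalent named list.  Top-level
#'   keys: \code{seed}, \code{out_dir}, and per-stage sections
#'   \code{simulate} (\code{n_normoxic}, \code{n_hypoxic},
#'   \code{stiffness_factor}), \code{fit} (\code{n_starts}), \code{pwv}
#'   (\code{P_dias_mmHg}, \code{P_sys_mmHg}, \code{rho_kg_m3}),
#'   \code{vaso} (\code{amplitude_normoxic}, \code{amplitude_hypoxic},
#'   \code{tau_min}, \code{noise_sd}), \code{histology}
#'   (\code{fractions_normoxic}, \code{fractions_hypoxic}).  Unknown keys
#'   raise a validation error before any computation.
#' @param out_dir overrides \code{config$out_dir}.
#' @return (invisibly) a list with the per-vessel metrics table, the fit
#'   results and the statistics report; artifacts are written under
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), pipeline_config_keys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  seed <- config$seed %||% 1
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("out_dir must be configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$simulate %||% list()
  n_nor <- sim$n_normoxic %||% 3
  n_hyp <- sim$n_hypoxic %||% 3
  stiff <- sim$stiffness_factor %||% 2
  fit_cfg <- config$fit %||% list()
  pwv_cfg <- config$pwv %||% list()
  vcfg <- config$vaso %||% list()
  base <- synthetic_vessel_spec()
  stiff_params <- do.call(four_fiber_params, unname(as.list(
    params_to_vector(base$params) *
      c(stiff, stiff, 1, stiff, 1, stiff, 1, 1))))
  metrics <- list(); fits <- list()
  vessel_seed <- function(i) seed * 1000 + i
  for (grp in c("normoxia", "hypoxia")) {
    nn <- if (grp == "normoxia") n_nor else n_hyp
    spec <- if (grp == "normoxia") base
            else synthetic_vessel_spec(params = stiff_params)
    for (i in seq_len(nn)) {
      vid <- sprintf("%s_%02d", grp, i)
      vs <- vessel_seed(length(metrics) + 1)
      dat <- simulate_biaxial_protocols(spec, seed = vs)
      write_biaxial_csv(dat, file.path(out_dir,
                                       paste0("biaxial_", vid, ".csv")))
      fit <- fit_four_fiber(dat, spec$geom,
                            n_starts = fit_cfg$n_starts %||% 6, seed = vs)
      fits[[vid]] <- fit
      write_params_json(fit$params,
                        file.path(out_dir, paste0("params_", vid, ".json")))
      en <- stored_energy_at_pressures(fit$params, spec$geom)
      hw <- model_pwv(fit$params, spec$geom,
                      P_dias_mmHg = pwv_cfg$P_dias_mmHg %||% 5,
                      P_sys_mmHg = pwv_cfg$P_sys_mmHg %||% 25,
                      rho_kg_m3 = pwv_cfg$rho_kg_m3 %||% 1050)
      tr <- simulate_vaso_trace(
        d0_um = hw$d_dias_um,
        amplitude = if (grp == "normoxia") vcfg$amplitude_normoxic %||% 0.35
                    else vcfg$amplitude_hypoxic %||% 0.28,
        tau_min = vcfg$tau_min %||% 2,
        noise_sd = vcfg$noise_sd %||% 0.005,
        seed = vs, vessel_id = vid, group = grp)
      metrics[[vid]] <- data.frame(
        vessel_id = vid, group = grp,
        metric = c("PWV_m_per_s", "D_Pa_inv", "W15_kPa", "Ctttt15_kPa",
                   "Czzzz15_kPa", "vaso_pct15"),
        value = c(hw$PWV_m_per_s, hw$D_Pa_inv, en$W_kPa[2],
                  en$C_tttt_kPa[2], en$C_zzzz_kPa[2],
                  percent_change_at(tr, 15)))
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  stats_out <- lapply(split(metrics, metrics$metric), function(m) {
    tt <- unpaired_t_test(m$value[m$group == "normoxia"],
                          m$value[m$group == "hypoxia"])
    list(metric = m$metric[1], t = tt$t, p = tt$p, df = tt$df)
  })
  jsonlite::write_json(list(seed = seed,
                            package_version = as.character(
                              utils::packageVersion("pamech")),
                            tests = stats_out),
                       file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(metrics = metrics, fits = fits, stats = stats_out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
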