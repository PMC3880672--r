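#' Run the full residual-stress pipeline from a configuration
#'
#' Executes estimate-residual-stress -> inflate-at-each-pressure ->
#' summaries from a single declarative configuration, writing plain-text
#' tables and a JSON run manifest. Two runs with the same configuration
#' produce byte-identical outputs.
#'
#' The configuration is a nested list (or a YAML file path) with sections:
#' \describe{
#'   \item{material}{either `file` (a key-value parameter file) or the
#'     eight parameters by name; default: packaged parameters.}
#'   \item{geometry}{`r_i`, `r_o` of the unloaded tube (cm); for
#'     `residual$source = "opening_angle"` the closed tube of the solved
#'     sector is used instead and `geometry` may give `R_i`, `R_o`,
#'     `alpha_deg`, `lambda_z` of the sector (defaults 2.5, 4.2, 85, 1).}
#'   \item{fibre}{`phi_endo`, `phi_epi`, `beta_endo`, `beta_epi` degrees.}
#'   \item{residual}{`source`: `"none"`, `"costa"` or `"opening_angle"`;
#'     for `"costa"` either `strain_table` (CSV path) or `fixture` (a list
#'     of [generate_strain_fixture()] arguments) plus optional `method`
#'     (`"isotropic"`/`"orthotropic"`).}
#'   \item{model}{`"baseline"`, `"simple"` or `"extended"`.}
#'   \item{pressures_mmHg}{vector of loading pressures.}
#'   \item{solver}{`n_radial`, `tol_root`, `tol_quad`.}
#'   \item{seed}{integer seed for the fixture generator.}
#' }
#'
#' @param config nested list or path to a YAML configuration file (a run
#'   manifest written by a previous run is also accepted).
#' @param out_dir output directory (created if missing); NULL writes no
#'   files.
#' @return (Invisibly) a list with `params`, `tau`, `solutions`,
#'   `pv`, `surfaces`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.null(config$config)) config <- config$config # manifest round-trip
  cfg <- resolve_config(config)

  params <- if (!is.null(cfg$material$file)) {
    read_material_params(cfg$material$file)
  } else {
    do.call(ho_params, cfg$material)
  }
  fibre <- fibre_rule(cfg$fibre$phi_endo, cfg$fibre$phi_epi,
                      cfg$fibre$beta_endo, cfg$fibre$beta_epi)

  tau <- NULL
  tube <- NULL
  if (cfg$residual$source == "opening_angle") {
    geom <- cylinder_geometry(cfg$geometry$R_i, cfg$geometry$R_o,
                              alpha_deg = cfg$geometry$alpha_deg,
                              lambda_z = cfg$geometry$lambda_z)
    tau <- opening_angle_field(geom, params,
                               energy_mode = cfg$residual$method_oa,
                               fibre = fibre,
                               n_radial = cfg$solver$n_radial)
    tube <- closed_tube(tau)
  } else {
    tube <- lv_tube(cfg$geometry$r_i, cfg$geometry$r_o)
    if (cfg$residual$source == "costa") {
      prof <- if (!is.null(cfg$residual$strain_table)) {
        read_strain_profile(cfg$residual$strain_table)
      } else if (!is.null(cfg$residual$fixture)) {
        do.call(generate_strain_fixture,
                c(cfg$residual$fixture, list(seed = cfg$seed)))
      } else {
        stop("residual source 'costa' needs a strain_table path or a fixture block",
             call. = FALSE)
      }
      tau <- estimate_tau(prof, params, method = cfg$residual$method)
    }
  }
  if (cfg$model == "baseline" && !is.null(tau)) {
    stop("model 'baseline' is incompatible with a residual-stress source",
         call. = FALSE)
  }

  solutions <- purrr::map(cfg$pressures_mmHg, function(P) {
    inflate(tube, P, params = params, model = cfg$model, tau = tau,
            fibre = fibre, n_radial = cfg$solver$n_radial,
            tol_root = cfg$solver$tol_root, tol_quad = cfg$solver$tol_quad)
  })
  pv <- if (length(cfg$pressures_mmHg) > 2 && cfg$pressures_mmHg[1] == 0) {
    pv_curve(tube, params, model = cfg$model, tau = tau,
             pressures_mmHg = cfg$pressures_mmHg, fibre = fibre,
             n_radial = cfg$solver$n_radial)
  } else NULL
  surfaces <- purrr::map_dfr(solutions, function(s) {
    dplyr::mutate(surface_summary(s), pressure_mmHg = s$pressure_mmHg,
                  .before = 1)
  })

  manifest <- list(
    package = "resmyo",
    version = as.character(utils::packageVersion("resmyo")),
    config = cfg,
    resolved = list(
      params = unclass(params),
      tube = unclass(tube),
      tolerances = cfg$solver
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      utils::write.csv(as.data.frame(df), file.path(out_dir, name),
                       row.names = FALSE, quote = FALSE)
    }
    for (i in seq_along(solutions)) {
      wr(round_df(solutions[[i]]$profile),
         sprintf("profile_P%gmmHg.csv", cfg$pressures_mmHg[i]))
    }
    if (!is.null(tau)) wr(round_df(tibble::as_tibble(tau)), "residual_stress.csv")
    if (!is.null(pv)) wr(round_df(tibble::as_tibble(pv)), "pv_curve.csv")
    wr(round_df(surfaces), "surface_summary.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(list(params = params, tau = tau, tube = tube,
                 solutions = solutions, pv = pv, surfaces = surfaces,
                 manifest = manifest))
}

round_df <- function(df) {
  dplyr::mutate(tibble::as_tibble(df),
                dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 10)))
}

pipeline_defaults <- function() {
  list(
    material = list(),
    geometry = list(r_i = 2.2, r_o = 3.8, R_i = 2.5, R_o = 4.2,
                    alpha_deg = 85, lambda_z = 1),
    fibre = list(phi_endo = 60, phi_epi = -60, beta_endo = -45, beta_epi = 45),
    residual = list(source = "none", method = "isotropic",
                    method_oa = "isotropic", strain_table = NULL,
                    fixture = NULL),
    model = "baseline",
    pressures_mmHg = c(0, 3, 8),
    solver = list(n_radial = 200, tol_root = 1e-8, tol_quad = 1e-8),
    seed = 0
  )
}

resolve_config <- function(config) {
  def <- pipeline_defaults()
  if (is.null(config)) config <- list()
  bad <- setdiff(names(config), names(def))
  if (length(bad)) {
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(config)) {
    if (is.list(def[[sec]]) && !is.null(names(def[[sec]]))) {
      if (!is.list(config[[sec]])) {
        stop("configuration section '", sec, "' must be a mapping", call. = FALSE)
      }
      extra <- setdiff(names(config[[sec]]),
                       c(names(def[[sec]]),
                         if (sec == "material") param_names else character()))
      if (length(extra)) {
        stop("unknown key(s) in section '", sec, "': ",
             paste(extra, collapse = ", "), call. = FALSE)
      }
      def[[sec]][names(config[[sec]])] <- config[[sec]]
    } else {
      def[[sec]] <- config[[sec]]
    }
  }
  if (!def$residual$source %in% c("none", "costa", "opening_angle")) {
    stop("residual$source must be 'none', 'costa' or 'opening_angle'",
         call. = FALSE)
  }
  if (def$residual$source != "none" && def$model == "baseline") {
    def$model <- "simple"
  }
  def$pressures_mmHg <- as.numeric(def$pressures_mmHg)
  def
}
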