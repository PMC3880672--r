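#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a transmural residual stress field
#'
#' @param object a `residual_field`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.residual_field <- function(object, ...) {
  df <- tibble::as_tibble(object)
  xvar <- if ("xi" %in% names(df)) "xi" else "r"
  comps <- intersect(c("tau_rr", "tau_thth", "tau_zz",
                       "tau_ff", "tau_ss", "tau_nn"), names(df))
  long <- tidyr::pivot_longer(df[c(xvar, comps)], -dplyr::all_of(xvar),
                              names_to = "component", values_to = "tau_kPa")
  ggplot2::ggplot(long, ggplot2::aes(.data[[xvar]], .data$tau_kPa,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(
      x = if (xvar == "xi") "wall depth fraction (endo → epi)" else "radius (cm)",
      y = "residual stress (kPa)", colour = NULL,
      title = "Transmural residual stress"
    )
}

#' Plot transmural stresses of an inflation solution
#'
#' @param object an `lv_inflation`.
#' @param components stress columns to show (default the fibre-frame
#'   normal stresses).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.lv_inflation <- function(object,
                                  components = c("sigma_ff", "sigma_ss",
                                                 "sigma_nn"), ...) {
  long <- tidyr::pivot_longer(object$profile[c("xi", components)], -"xi",
                              names_to = "component", values_to = "sigma_kPa")
  ggplot2::ggplot(long, ggplot2::aes(.data$xi, .data$sigma_kPa,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "wall depth fraction (endo → epi)", y = "Cauchy stress (kPa)",
      colour = NULL,
      title = sprintf("Transmural stress at %g mmHg (%s%s)",
                      object$pressure_mmHg, object$model,
                      if (object$has_tau) ", with residual stress" else "")
    )
}

#' Plot a pressure-volume curve
#'
#' @param object a `pv_curve`.
#' @param normalized plot the normalised volume (default TRUE) or the
#'   cavity area.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pv_curve <- function(object, normalized = TRUE, ...) {
  y <- if (normalized) "volume_norm" else "cavity_area_cm2"
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data[[y]], .data$pressure_mmHg)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(
      x = if (normalized) "normalised cavity volume" else
        "cavity area (cm² per unit length)",
      y = "pressure (mmHg)", title = "Diastolic pressure-volume relation"
    )
}

#' Plot the convergence of an unloaded-configuration recovery
#'
#' @param object an `unload_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.unload_result <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(.data$iteration, .data$mismatch_area_pct)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "cavity-area mismatch (%)",
                  title = "Backward-displacement convergence")
}

#' @importFrom rlang .data
NULL
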