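#' Geometry of an opened cylindrical sector
#'
#' Describes the stress-free configuration of the opening-angle method: a
#' radially cut ring that has sprung open into a sector with inner and
#' outer radii `R_i`, `R_o` and opening angle `alpha`. Closing the sector
#' back into a full tube (circumferential stretch `kappa = 2 pi / (2 pi -
#' alpha)` at fixed axial stretch `lambda_z`) generates the residual
#' stress of the intact unloaded ring.
#'
#' @param R_i,R_o inner and outer sector radii (cm), `0 < R_i < R_o`.
#' @param alpha_deg opening angle in degrees (stored in radians),
#'   `0 <= alpha < 360`.
#' @param lambda_z axial stretch of the closing map (default 1).
#' @param L sector length (cm); carried for completeness.
#' @param alpha opening angle in radians; alternative to `alpha_deg`.
#' @return An object of class `cylinder_geometry` with fields `R_i`,
#'   `R_o`, `alpha` (radians), `lambda_z`, `L`, `kappa`.
#' @examples
#' cylinder_geometry(R_i = 2.5, R_o = 4.2, alpha_deg = 85)
#' @export
cylinder_geometry <- function(R_i, R_o, alpha_deg = NULL, lambda_z = 1,
                              L = 1, alpha = NULL) {
  if (is.null(alpha)) {
    if (is.null(alpha_deg)) stop("supply alpha_deg or alpha", call. = FALSE)
    alpha <- alpha_deg * pi / 180
  }
  if (!is.finite(R_i) || !is.finite(R_o) || R_i <= 0 || R_o <= R_i) {
    stop("require 0 < R_i < R_o", call. = FALSE)
  }
  if (alpha < 0 || alpha >= 2 * pi) stop("require 0 <= alpha < 2 pi", call. = FALSE)
  if (!is.finite(lambda_z) || lambda_z <= 0) stop("lambda_z must be > 0", call. = FALSE)
  structure(list(R_i = R_i, R_o = R_o, alpha = alpha, lambda_z = lambda_z,
                 L = L, kappa = 2 * pi / (2 * pi - alpha)),
            class = "cylinder_geometry")
}

#' @export
print.cylinder_geometry <- function(x, ...) {
  cat(sprintf(
    "Opened sector: R_i = %g cm, R_o = %g cm, alpha = %g deg (kappa = %.6g), lambda_z = %g\n",
    x$R_i, x$R_o, x$alpha * 180 / pi, x$kappa, x$lambda_z))
  invisible(x)
}

#' Sector-to-tube closing map
#'
#' Maps reference radii `R` of the opened sector to radii `r` of the
#' closed tube, `r = sqrt((R^2 - R_i^2) / (kappa lambda_z) + r_i^2)`,
#' given the closed inner radius `r_i`, and returns the principal
#' stretches `lambda_r = R / (r kappa lambda_z)`, `lambda_theta = kappa r
#' / R`. The map is isochoric: `lambda_r lambda_theta lambda_z = 1` at
#' every radius.
#'
#' @param geom a [cylinder_geometry()].
#' @param r_i closed inner radius (cm), `> 0`; normally found by
#'   [opening_angle_field()].
#' @param R reference radii to map (default: 200-point grid spanning the
#'   wall).
#' @return Tibble with columns `R`, `r`, `lambda_r`, `lambda_th`,
#'   `lambda_z`.
#' @export
close_sector <- function(geom, r_i, R = seq(geom$R_i, geom$R_o, length.out = 200)) {
  stopifnot(inherits(geom, "cylinder_geometry"))
  if (!is.finite(r_i) || r_i <= 0) stop("r_i must be positive", call. = FALSE)
  if (any(R < geom$R_i - 1e-12) || any(R > geom$R_o + 1e-12)) {
    stop("R must lie within [R_i, R_o]", call. = FALSE)
  }
  r <- sqrt((R^2 - geom$R_i^2) / (geom$kappa * geom$lambda_z) + r_i^2)
  tibble::tibble(
    R = R, r = r,
    lambda_r = R / (r * geom$kappa * geom$lambda_z),
    lambda_th = geom$kappa * r / R,
    lambda_z = geom$lambda_z
  )
}

oa_stretches <- function(geom, r_i, R) {
  r <- sqrt((R^2 - geom$R_i^2) / (geom$kappa * geom$lambda_z) + r_i^2)
  list(r = r,
       lr = R / (r * geom$kappa * geom$lambda_z),
       lt = geom$kappa * r / R,
       lz = geom$lambda_z)
}

# (sigma_hat_tt - sigma_hat_rr)/r * dr/dR at reference radii R, for a
# candidate closed inner radius r_i
oa_integrand <- function(R, geom, r_i, params, energy_mode, fibre) {
  st <- oa_stretches(geom, r_i, R)
  fib <- if (energy_mode == "orthotropic") {
    # frames are assigned by depth fraction in the closed (unloaded) tube
    r_o <- sqrt((geom$R_o^2 - geom$R_i^2) / (geom$kappa * geom$lambda_z) + r_i^2)
    xi <- (st$r - r_i) / (r_o - r_i)
    rule_vectors(fibre, pmin(pmax(xi, 0), 1))
  } else NULL
  sh <- hat_stress_profile(st$lr, st$lt, st$lz, params, fibre = fib)
  (sh$tt - sh$rr) / st$r * R / (geom$kappa * geom$lambda_z * st$r)
}

#' Residual stress of a closed tube by the opening-angle method
#'
#' Solves the radial equilibrium boundary-value problem for the residual
#' stress generated by closing an opened sector into an intact tube:
#' `d tau_rr / dr + (tau_rr - tau_thth) / r = 0` with traction-free inner
#' and outer surfaces. The closed inner radius `r_i` is the unknown; it is
#' found by bracketed root finding so that the radial stress integrated
#' from the inner surface also vanishes at the outer surface. The default
#' constitutive response of the closing deformation is the isotropic
#' matrix part of the law (consistent with the strain-measurement
#' estimator); `energy_mode = "orthotropic"` uses the full law with the
#' transmural fibre rule.
#'
#' @param geom a [cylinder_geometry()].
#' @param params an [ho_params()] object.
#' @param energy_mode `"isotropic"` (default) or `"orthotropic"`.
#' @param fibre a [fibre_rule()]; used only in orthotropic mode and for
#'   later frame rotation.
#' @param n_radial number of radial grid points for the returned profile.
#' @param bracket search bracket for `r_i` as multiples of `R_i`
#'   (default `c(0.2, 2)`).
#' @param tol_r root tolerance on `r_i` in cm (default 1e-10).
#' @param tol_quad absolute quadrature tolerance in kPa (default 1e-8).
#' @return A tibble of class `residual_field` (frame `"cylindrical"`)
#'   with columns `R`, `r` (cm), `xi`, `lambda_r`, `lambda_th`,
#'   `lambda_z`, `tau_rr`, `tau_thth`, `tau_zz` and (orthotropic mode)
#'   shear columns `tau_rt`, `tau_rz`, `tau_tz` (kPa). Attribute
#'   `geometry` carries `geom`, the solved `r_i`, `r_o` and the achieved
#'   boundary residual.
#' @examples
#' geom <- cylinder_geometry(2.5, 4.2, alpha_deg = 85)
#' fld <- opening_angle_field(geom, ho_params(), n_radial = 60)
#' @export
opening_angle_field <- function(geom, params = ho_params(),
                                energy_mode = c("isotropic", "orthotropic"),
                                fibre = fibre_rule(), n_radial = 200,
                                bracket = c(0.2, 2), tol_r = 1e-10,
                                tol_quad = 1e-8) {
  energy_mode <- match.arg(energy_mode)
  stopifnot(inherits(geom, "cylinder_geometry"), inherits(params, "ho_params"))

  R_grid <- seq(geom$R_i, geom$R_o, length.out = n_radial)

  if (geom$alpha == 0 && geom$lambda_z == 1) {
    # identity map: stress-free tube
    r_i <- geom$R_i
    st <- oa_stretches(geom, r_i, R_grid)
    out <- tibble::tibble(
      R = R_grid, r = st$r, xi = (st$r - st$r[1]) / diff(range(st$r)),
      lambda_r = st$lr, lambda_th = st$lt, lambda_z = st$lz,
      tau_rr = 0, tau_thth = 0, tau_zz = 0,
      tau_rt = 0, tau_rz = 0, tau_tz = 0
    )
    return(new_residual_field(out, frame = "cylindrical",
                              method = energy_mode,
                              geometry = list(geom = geom, r_i = r_i,
                                              r_o = st$r[n_radial],
                                              boundary_residual = 0)))
  }

  traction_gap <- function(r_i) {
    safe_integrate(function(R) oa_integrand(R, geom, r_i, params,
                                            energy_mode, fibre),
                   geom$R_i, geom$R_o, abs_tol = tol_quad)
  }
  lo <- bracket[1] * geom$R_i
  hi <- bracket[2] * geom$R_i
  flo <- traction_gap(lo); fhi <- traction_gap(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    stop(sprintf(
      "no admissible closed inner radius in bracket [%.4g, %.4g] cm (residuals %.4g, %.4g kPa)",
      lo, hi, flo, fhi), call. = FALSE)
  }
  r_i <- stats::uniroot(traction_gap, c(lo, hi), tol = tol_r)$root

  # cumulative radial stress profile on the reference grid
  sol <- deSolve::ode(
    y = c(tau_rr = 0), times = R_grid,
    func = function(R, y, parms) {
      list(oa_integrand(R, geom, r_i, params, energy_mode, fibre))
    },
    rtol = 1e-10, atol = 1e-12
  )
  tau_rr <- sol[, "tau_rr"]

  st <- oa_stretches(geom, r_i, R_grid)
  xi <- (st$r - st$r[1]) / (st$r[n_radial] - st$r[1])
  fib <- if (energy_mode == "orthotropic") rule_vectors(fibre, xi) else NULL
  sh <- hat_stress_profile(st$lr, st$lt, st$lz, params, fibre = fib)

  out <- tibble::tibble(
    R = R_grid, r = st$r, xi = xi,
    lambda_r = st$lr, lambda_th = st$lt, lambda_z = st$lz,
    tau_rr = tau_rr,
    tau_thth = tau_rr + (sh$tt - sh$rr),
    tau_zz = tau_rr + (sh$zz - sh$rr),
    tau_rt = sh$rt, tau_rz = sh$rz, tau_tz = sh$tz
  )
  new_residual_field(out, frame = "cylindrical", method = energy_mode,
                     geometry = list(geom = geom, r_i = r_i,
                                     r_o = st$r[n_radial],
                                     boundary_residual = tau_rr[n_radial]))
}

#' Rotate a cylindrical residual stress field into the fibre frame
#'
#' Applies the orthogonal change of basis `tau = Q^T tau_bar Q` from the
#' cylindrical basis `(e_r, e_theta, e_z)` to the local fibre frame
#' `(f0, s0, n0)` given by the transmural fibre rule. Eigenvalues and
#' trace are preserved. Fibre-frame shear components are small relative
#' to the normal components for physiological rules; by default they are
#' zeroed (the shear-neglect assumption made explicit), `keep_shear =
#' TRUE` preserves them.
#'
#' @param field a cylindrical-frame `residual_field` (from
#'   [opening_angle_field()]).
#' @param fibre a [fibre_rule()].
#' @param keep_shear keep the fibre-frame shear components (default
#'   FALSE).
#' @return The field with added columns `tau_ff`, `tau_ss`, `tau_nn`,
#'   `tau_fs`, `tau_fn`, `tau_sn` (kPa).
#' @export
rotate_to_fibre_frame <- function(field, fibre = fibre_rule(),
                                  keep_shear = FALSE) {
  if (!identical(attr(field, "frame"), "cylindrical")) {
    stop("field must be in the cylindrical frame", call. = FALSE)
  }
  stopifnot(inherits(fibre, "fibre_rule"))
  v <- rule_vectors(fibre, field$xi)
  cyl <- list(rr = field$tau_rr, tt = field$tau_thth, zz = field$tau_zz,
              rt = field$tau_rt %||% 0 * field$tau_rr,
              rz = field$tau_rz %||% 0 * field$tau_rr,
              tz = field$tau_tz %||% 0 * field$tau_rr)
  quad <- function(u, w) {
    cyl$rr * u[, 1] * w[, 1] + cyl$tt * u[, 2] * w[, 2] +
      cyl$zz * u[, 3] * w[, 3] +
      cyl$rt * (u[, 1] * w[, 2] + u[, 2] * w[, 1]) +
      cyl$rz * (u[, 1] * w[, 3] + u[, 3] * w[, 1]) +
      cyl$tz * (u[, 2] * w[, 3] + u[, 3] * w[, 2])
  }
  out <- dplyr::mutate(
    tibble::as_tibble(field),
    tau_ff = quad(v$f0, v$f0),
    tau_ss = quad(v$s0, v$s0),
    tau_nn = quad(v$n0, v$n0),
    tau_fs = if (keep_shear) quad(v$f0, v$s0) else 0,
    tau_fn = if (keep_shear) quad(v$f0, v$n0) else 0,
    tau_sn = if (keep_shear) quad(v$s0, v$n0) else 0
  )
  new_residual_field(out, frame = "cylindrical+fibre",
                     method = attr(field, "method"),
                     geometry = attr(field, "geometry"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Unloaded tube implied by an opening-angle solution
#'
#' @param field a `residual_field` from [opening_angle_field()].
#' @return An [lv_tube()] with the closed inner/outer radii and the axial
#'   stretch of the sector geometry.
#' @export
closed_tube <- function(field) {
  g <- attr(field, "geometry")
  if (is.null(g)) stop("field carries no geometry attribute", call. = FALSE)
  lv_tube(r_i = g$r_i, r_o = g$r_o, lambda_z = g$geom$lambda_z)
}
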