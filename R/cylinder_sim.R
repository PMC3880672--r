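#' Unloaded thick-walled tube (LV surrogate)
#'
#' The desk-scale stand-in for the left-ventricular wall: an incompressible
#' thick-walled cylinder given by its unloaded (residually stressed) inner
#' and outer radii. When the residual stress comes from the opening-angle
#' method, the natural choice is the closed tube of that solution
#' ([closed_tube()]).
#'
#' @param r_i,r_o unloaded inner and outer radii (cm), `0 < r_i < r_o`.
#' @param lambda_z axial stretch held during inflation (default 1, plane
#'   deformation).
#' @return Object of class `lv_tube`.
#' @export
lv_tube <- function(r_i, r_o, lambda_z = 1) {
  if (!is.finite(r_i) || !is.finite(r_o) || r_i <= 0 || r_o <= r_i) {
    stop("require 0 < r_i < r_o", call. = FALSE)
  }
  if (!is.finite(lambda_z) || lambda_z <= 0) stop("lambda_z must be > 0", call. = FALSE)
  structure(list(r_i = r_i, r_o = r_o, lambda_z = lambda_z), class = "lv_tube")
}

#' @export
print.lv_tube <- function(x, ...) {
  cat(sprintf("Unloaded tube: r_i = %g cm, r_o = %g cm, lambda_z = %g\n",
              x$r_i, x$r_o, x$lambda_z))
  invisible(x)
}

#' @rdname lv_tube
#' @details `mmHg_to_kPa()` converts pressures; 1 mmHg = 0.133322 kPa.
#' @param p_mmHg pressure in mmHg.
#' @export
mmHg_to_kPa <- function(p_mmHg) p_mmHg * 0.133322

# Interpolators (monotone cubic in xi) for the six cylindrical tau
# components of a residual_field; returns function(xi) -> component list.
tau_interpolator <- function(field, fibre) {
  if (is.null(field)) return(function(xi) NULL)
  frame <- attr(field, "frame")
  mono <- function(y) {
    if (length(unique(field$xi)) < 2) stop("tau field needs >= 2 xi samples",
                                           call. = FALSE)
    stats::splinefun(field$xi, y, method = "monoH.FC")
  }
  if (!is.null(frame) && startsWith(frame, "cylindrical")) {
    fns <- lapply(list(rr = field$tau_rr, tt = field$tau_thth,
                       zz = field$tau_zz,
                       rt = field$tau_rt %||% 0 * field$tau_rr,
                       rz = field$tau_rz %||% 0 * field$tau_rr,
                       tz = field$tau_tz %||% 0 * field$tau_rr), mono)
    function(xi) lapply(fns, function(f) f(xi))
  } else {
    # fibre-frame field: interpolate fibre components, then rotate into the
    # cylindrical basis with the frame of the transmural rule at each xi
    fns <- lapply(list(ff = field$tau_ff, ss = field$tau_ss,
                       nn = field$tau_nn,
                       fs = field$tau_fs %||% 0 * field$tau_ff,
                       fn = field$tau_fn %||% 0 * field$tau_ff,
                       sn = field$tau_sn %||% 0 * field$tau_ff), mono)
    function(xi) {
      tf <- lapply(fns, function(f) f(xi))
      v <- rule_vectors(fibre, xi)
      comp <- function(a, b) {
        tf$ff * v$f0[, a] * v$f0[, b] + tf$ss * v$s0[, a] * v$s0[, b] +
          tf$nn * v$n0[, a] * v$n0[, b] +
          tf$fs * (v$f0[, a] * v$s0[, b] + v$s0[, a] * v$f0[, b]) +
          tf$fn * (v$f0[, a] * v$n0[, b] + v$n0[, a] * v$f0[, b]) +
          tf$sn * (v$s0[, a] * v$n0[, b] + v$n0[, a] * v$s0[, b])
      }
      list(rr = comp(1, 1), tt = comp(2, 2), zz = comp(3, 3),
           rt = comp(1, 2), rz = comp(1, 3), tz = comp(2, 3))
    }
  }
}

inflate_stretches <- function(tube, r_i_def, rho) {
  r <- sqrt(r_i_def^2 + (rho^2 - tube$r_i^2) / 1) # lambda_z of inflation = 1
  lt <- r / rho
  list(r = r, lr = 1 / lt, lt = lt, lz = rep_len(1, length(rho)))
}

inflate_integrand <- function(rho, tube, r_i_def, params, model, fibre,
                              tau_at) {
  st <- inflate_stretches(tube, r_i_def, rho)
  xi <- (rho - tube$r_i) / (tube$r_o - tube$r_i)
  fib <- rule_vectors(fibre, xi)
  sh <- hat_stress_profile(st$lr, st$lt, st$lz, params, fibre = fib,
                           tau = tau_at(xi), model = model)
  (sh$tt - sh$rr) / st$r * rho / st$r
}

#' Inflate the residually stressed tube to a diastolic pressure
#'
#' Solves the axisymmetric plane inflation of the incompressible,
#' fibre-reinforced, residually stressed tube under an endocardial pressure
#' `P`: the deformed inner radius is found by shooting on the radial
#' equilibrium equation `d sigma_rr / dr + (sigma_rr - sigma_thth)/r = 0`
#' with `sigma_rr = -P` at the inner and `0` at the outer surface. The
#' total Cauchy stress includes the residual contribution of the chosen
#' formulation; the incompressibility pressure field is closed by the
#' radial traction condition.
#'
#' @param tube an [lv_tube()] unloaded geometry.
#' @param pressure_mmHg endocardial pressure in mmHg (`>= 0`).
#' @param params an [ho_params()] object.
#' @param model `"baseline"`, `"simple"` or `"extended"`.
#' @param tau `NULL` (no residual stress) or a `residual_field` — either a
#'   cylindrical-frame field from [opening_angle_field()] or a fibre-frame
#'   field from [estimate_tau()]; components are interpolated in the
#'   wall-depth fraction with monotone cubic splines. `model = "baseline"`
#'   requires `tau = NULL`.
#' @param fibre a [fibre_rule()].
#' @param n_radial grid points across the wall (default 200).
#' @param tol_root root tolerance on the deformed inner radius (cm).
#' @param tol_quad absolute quadrature tolerance (kPa).
#' @return Object of class `lv_inflation`: list with `profile` (tibble:
#'   `rho`, `r`, `xi`, stretches, cylindrical stress components, `p`,
#'   `sigma_ff`, `sigma_ss`, `sigma_nn`, all kPa), `pressure_mmHg`,
#'   `P_kPa`, `r_i_def`, `r_o_def`, `cavity_area` (cm^2 per unit length),
#'   `model`, `has_tau`, `tube`, `fibre`.
#' @examples
#' tube <- lv_tube(2.2, 3.8)
#' sol <- inflate(tube, pressure_mmHg = 3, n_radial = 60)
#' @export
inflate <- function(tube, pressure_mmHg, params = ho_params(),
                    model = c("baseline", "simple", "extended"),
                    tau = NULL, fibre = fibre_rule(), n_radial = 200,
                    tol_root = 1e-8, tol_quad = 1e-8) {
  model <- match.arg(model)
  stopifnot(inherits(tube, "lv_tube"), inherits(params, "ho_params"),
            inherits(fibre, "fibre_rule"))
  if (!is.finite(pressure_mmHg) || pressure_mmHg < 0) {
    stop("pressure must be non-negative", call. = FALSE)
  }
  if (model == "baseline" && !is.null(tau)) {
    stop("model 'baseline' takes no residual stress; use 'simple' or 'extended'",
         call. = FALSE)
  }
  # the inflation map is plane (axial stretch 1 relative to the unloaded
  # tube); tube$lambda_z records how the unloaded state relates to any
  # stress-free sector and plays no role here
  P <- mmHg_to_kPa(pressure_mmHg)
  tau_at <- tau_interpolator(tau, fibre)

  gap <- function(r_i_def) {
    -P + safe_integrate(function(rho) {
      inflate_integrand(rho, tube, r_i_def, params, model, fibre, tau_at)
    }, tube$r_i, tube$r_o, abs_tol = tol_quad)
  }
  br <- c(0.6, 2.5) * tube$r_i
  flo <- gap(br[1]); fhi <- gap(br[2])
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    stop(sprintf(
      "shooting failed to bracket the deformed inner radius in [%.4g, %.4g] cm (gaps %.4g, %.4g kPa)",
      br[1], br[2], flo, fhi), call. = FALSE)
  }
  r_i_def <- stats::uniroot(gap, br, tol = tol_root)$root

  rho <- seq(tube$r_i, tube$r_o, length.out = n_radial)
  sol <- deSolve::ode(
    y = c(sigma_rr = -P), times = rho,
    func = function(rho, y, parms) {
      list(inflate_integrand(rho, tube, r_i_def, params, model, fibre, tau_at))
    },
    rtol = 1e-10, atol = 1e-12
  )
  sigma_rr <- sol[, "sigma_rr"]

  st <- inflate_stretches(tube, r_i_def, rho)
  xi <- (rho - tube$r_i) / (tube$r_o - tube$r_i)
  fib <- rule_vectors(fibre, xi)
  sh <- hat_stress_profile(st$lr, st$lt, st$lz, params, fibre = fib,
                           tau = tau_at(xi), model = model)
  p_field <- sh$rr - sigma_rr
  sig <- list(rr = sigma_rr, tt = sh$tt - p_field, zz = sh$zz - p_field,
              rt = sh$rt, rz = sh$rz, tz = sh$tz)

  # normal stresses along the deformed (unit) fibre, sheet and normal axes
  dirs <- lapply(fib, function(v0) {
    v <- cbind(st$lr * v0[, 1], st$lt * v0[, 2], st$lz * v0[, 3])
    v / sqrt(rowSums(v^2))
  })
  normal_stress <- function(u) {
    sig$rr * u[, 1]^2 + sig$tt * u[, 2]^2 + sig$zz * u[, 3]^2 +
      2 * (sig$rt * u[, 1] * u[, 2] + sig$rz * u[, 1] * u[, 3] +
             sig$tz * u[, 2] * u[, 3])
  }

  profile <- tibble::tibble(
    rho = rho, r = st$r, xi = xi,
    lambda_r = st$lr, lambda_th = st$lt, lambda_z = st$lz,
    sigma_rr = sig$rr, sigma_thth = sig$tt, sigma_zz = sig$zz,
    sigma_rt = sig$rt, sigma_rz = sig$rz, sigma_tz = sig$tz,
    p = p_field,
    sigma_ff = normal_stress(dirs$f0),
    sigma_ss = normal_stress(dirs$s0),
    sigma_nn = normal_stress(dirs$n0)
  )
  structure(list(
    profile = profile,
    pressure_mmHg = pressure_mmHg, P_kPa = P,
    r_i_def = r_i_def, r_o_def = st$r[n_radial],
    cavity_area = pi * r_i_def^2,
    model = model, has_tau = !is.null(tau),
    tube = tube, fibre = fibre
  ), class = "lv_inflation")
}

#' @export
print.lv_inflation <- function(x, ...) {
  cat(sprintf(
    "Inflated tube at %g mmHg (%.4g kPa), model = %s%s\n  deformed radii: %.5g -> %.5g cm; cavity area %.5g cm^2\n",
    x$pressure_mmHg, x$P_kPa, x$model,
    if (x$has_tau) " (with residual stress)" else "",
    x$r_i_def, x$r_o_def, x$cavity_area))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.lv_inflation <- function(x, ...) x$profile

#' @importFrom generics glance
#' @export
glance.lv_inflation <- function(x, ...) {
  tibble::tibble(
    pressure_mmHg = x$pressure_mmHg, P_kPa = x$P_kPa, model = x$model,
    has_tau = x$has_tau, r_i_def_cm = x$r_i_def, r_o_def_cm = x$r_o_def,
    cavity_area_cm2 = x$cavity_area,
    sigma_rr_inner_kPa = x$profile$sigma_rr[1],
    sigma_rr_outer_kPa = x$profile$sigma_rr[nrow(x$profile)]
  )
}

#' Pressure-volume curve of the tube surrogate
#'
#' Inflates the tube through an increasing pressure grid and reports the
#' cavity area per unit length (the cylinder-scale cavity volume) plus a
#' normalised volume for shape comparison across configurations: the
#' volume is mapped to `[0, 1]` over the grid.
#'
#' @inheritParams inflate
#' @param pressures_mmHg increasing pressure grid starting at 0 (default
#'   0 to 8 mmHg in 9 steps).
#' @return Tibble of class `pv_curve` with columns `pressure_mmHg`,
#'   `P_kPa`, `r_i_def_cm`, `cavity_area_cm2`, `volume_norm`.
#' @export
pv_curve <- function(tube, params = ho_params(),
                     model = c("baseline", "simple", "extended"),
                     tau = NULL, pressures_mmHg = seq(0, 8, length.out = 9),
                     fibre = fibre_rule(), n_radial = 200, ...) {
  model <- match.arg(model)
  if (is.unsorted(pressures_mmHg, strictly = TRUE) || pressures_mmHg[1] != 0) {
    stop("pressures must increase strictly from 0", call. = FALSE)
  }
  sols <- purrr::map(pressures_mmHg, function(P) {
    inflate(tube, P, params = params, model = model, tau = tau,
            fibre = fibre, n_radial = n_radial, ...)
  })
  A <- vapply(sols, `[[`, numeric(1), "cavity_area")
  out <- tibble::tibble(
    pressure_mmHg = pressures_mmHg,
    P_kPa = mmHg_to_kPa(pressures_mmHg),
    r_i_def_cm = vapply(sols, `[[`, numeric(1), "r_i_def"),
    cavity_area_cm2 = A,
    volume_norm = (A - A[1]) / (A[length(A)] - A[1])
  )
  structure(out, model = model, has_tau = !is.null(tau),
            class = c("pv_curve", class(tibble::tibble())))
}

#' Compare the simple and extended residual formulations
#'
#' Per-component maximum difference between two inflation solutions
#' computed with identical inputs except the residual model, scaled by the
#' transmural maximum magnitude of that component (a robust relative
#' measure that is well defined where the stress crosses zero).
#'
#' @param sol_a,sol_b two [inflate()] solutions on the same tube, pressure
#'   and grid.
#' @param threshold flag level for the "almost identical" verdict
#'   (default 0.05, i.e. 5 percent).
#' @return Tibble with columns `component`, `max_abs_diff_kPa`,
#'   `scale_kPa`, `max_rel_diff`, `within`.
#' @export
compare_models <- function(sol_a, sol_b, threshold = 0.05) {
  stopifnot(inherits(sol_a, "lv_inflation"), inherits(sol_b, "lv_inflation"))
  if (sol_a$pressure_mmHg != sol_b$pressure_mmHg ||
      nrow(sol_a$profile) != nrow(sol_b$profile) ||
      max(abs(sol_a$profile$rho - sol_b$profile$rho)) > 1e-12) {
    stop("solutions must share pressure and radial grid", call. = FALSE)
  }
  comps <- c("sigma_ff", "sigma_ss", "sigma_nn", "sigma_rr", "sigma_thth")
  purrr::map_dfr(comps, function(cc) {
    d <- abs(sol_a$profile[[cc]] - sol_b$profile[[cc]])
    sc <- max(abs(sol_a$profile[[cc]]), abs(sol_b$profile[[cc]]), 1e-12)
    tibble::tibble(component = sub("sigma_", "", cc),
                   max_abs_diff_kPa = max(d), scale_kPa = sc,
                   max_rel_diff = max(d) / sc,
                   within = max(d) / sc < threshold)
  })
}

#' Surface stress summary
#'
#' Mean and standard deviation of the fibre-frame normal stresses over a
#' thin band adjacent to the endocardial and epicardial surfaces
#' (`band` as a fraction of the wall thickness). A band rather than the
#' single surface point gives a summary with spread, mirroring how
#' surface averages are reported for 3-D models.
#'
#' @param sol an [inflate()] solution.
#' @param band band width as wall-depth fraction (default 0.05).
#' @return Tibble with columns `surface` (`"endo"`/`"epi"`), `component`
#'   (`"ff"`, `"ss"`, `"nn"`), `mean_kPa`, `sd_kPa`.
#' @export
surface_summary <- function(sol, band = 0.05) {
  stopifnot(inherits(sol, "lv_inflation"))
  pr <- sol$profile
  pick <- list(endo = pr$xi <= band, epi = pr$xi >= 1 - band)
  purrr::map_dfr(names(pick), function(sf) {
    sub <- pr[pick[[sf]], ]
    purrr::map_dfr(c("ff", "ss", "nn"), function(cc) {
      v <- sub[[paste0("sigma_", cc)]]
      tibble::tibble(surface = sf, component = cc,
                     mean_kPa = mean(v), sd_kPa = stats::sd(v))
    })
  })
}
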