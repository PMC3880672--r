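#' Left Cauchy-Green tensor from an Euler-Almansi residual strain
#'
#' Measured residual strains in the unloaded wall are reported as the
#' Euler-Almansi tensor `e0` of the unloaded configuration relative to the
#' (fictitious) stress-free configuration. The corresponding left
#' Cauchy-Green tensor of that pre-deformation is
#' `B_r = solve(I - 2 e0)`, which must be symmetric positive definite.
#'
#' @param e0 symmetric 3x3 Euler-Almansi strain (dimensionless).
#' @param label optional label (e.g. the wall depth) used in error messages.
#' @return Symmetric positive-definite 3x3 matrix `B_r`.
#' @examples
#' strain_to_B(diag(c(0.1, -0.05, 0)))
#' @export
strain_to_B <- function(e0, label = NULL) {
  e0 <- check_symmetric3(e0, "e0")
  A <- diag(3) - 2 * e0
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) {
    stop("I - 2 e0 is not positive definite",
         if (!is.null(label)) paste0(" at ", label) else "", call. = FALSE)
  }
  Br <- solve(A)
  (Br + t(Br)) / 2
}

e0_matrix <- function(row) {
  m <- matrix(c(row$e_ff, row$e_fs, row$e_fn,
                row$e_fs, row$e_ss, row$e_sn,
                row$e_fn, row$e_sn, row$e_nn), 3, 3)
  m
}

strain_cols <- c("e_ff", "e_ss", "e_nn", "e_fs", "e_fn", "e_sn")

check_strain_profile <- function(profile) {
  need <- c("xi", strain_cols)
  if (!all(need %in% names(profile))) {
    stop("strain profile needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.unsorted(profile$xi, strictly = TRUE) ||
      any(profile$xi < 0) || any(profile$xi > 1)) {
    stop("xi must be strictly increasing within [0, 1]", call. = FALSE)
  }
  invisible(profile)
}

#' Estimate residual stress from a transmural residual-strain profile
#'
#' Converts measured Euler-Almansi residual strains (components in the
#' fibre frame) to the residual Cauchy stress `tau` of the unloaded
#' configuration. Two constitutive assumptions are available for the
#' pre-deformation from the stress-free to the unloaded state:
#' \describe{
#'   \item{`"isotropic"` (default)}{the fibres are taken as relaxed in the
#'     unloaded state, so only the isotropic matrix responds:
#'     `tau = a exp(b (I1r - 3)) B_r - a I` with `I1r = tr(B_r)` and the
#'     unloaded pressure `p_r = a`.}
#'   \item{`"orthotropic"`}{the full orthotropic law (with its tension-only
#'     switch on the fibre and sheet terms) evaluates the stress of the
#'     pre-deformation; it reduces exactly to the isotropic estimate when
#'     the anisotropic terms are inactive.}
#' }
#' Off-diagonal (shear) strain components must be below `shear_tol`; they
#' are zeroed before the estimate when `zero_shear = TRUE` (the
#' principal-direction assumption made explicit), otherwise retained.
#'
#' @param profile tibble with columns `xi` (wall-depth fraction, strictly
#'   increasing in `[0, 1]`) and the six fibre-frame strain components
#'   `e_ff`, `e_ss`, `e_nn`, `e_fs`, `e_fn`, `e_sn`.
#' @param params an [ho_params()] object.
#' @param method `"isotropic"` or `"orthotropic"`.
#' @param shear_tol admissible magnitude of shear strain components when
#'   `zero_shear = TRUE` (default 0.02); larger shears are an error rather
#'   than a silent approximation.
#' @param zero_shear zero the shear strains before estimating (default
#'   TRUE). With FALSE the full symmetric `e0` is used.
#' @return A tibble of class `residual_field` (frame attribute `"fibre"`)
#'   with columns `xi`, `tau_ff`, `tau_ss`, `tau_nn`, `tau_fs`, `tau_fn`,
#'   `tau_sn` (kPa).
#' @examples
#' prof <- generate_strain_fixture()
#' estimate_tau(prof, ho_params())
#' @export
estimate_tau <- function(profile, params = ho_params(),
                         method = c("isotropic", "orthotropic"),
                         shear_tol = 0.02, zero_shear = TRUE) {
  method <- match.arg(method)
  check_strain_profile(profile)
  stopifnot(inherits(params, "ho_params"))
  frame <- fibre_frame(c(1, 0, 0), c(0, 1, 0)) # fibre frame is the basis here
  rows <- purrr::pmap(profile[c("xi", strain_cols)], function(xi, ...) {
    row <- list(...)
    sh <- c(row$e_fs, row$e_fn, row$e_sn)
    if (zero_shear) {
      if (max(abs(sh)) > shear_tol) {
        stop("shear strain exceeds shear_tol (", shear_tol, ") at xi = ", xi,
             "; set zero_shear = FALSE to keep shears", call. = FALSE)
      }
      row$e_fs <- row$e_fn <- row$e_sn <- 0
    }
    e0 <- e0_matrix(row)
    tau <- estimate_tau_point(e0, params, method, frame,
                              label = paste0("xi = ", xi))
    tibble::tibble(xi = xi,
                   tau_ff = tau[1, 1], tau_ss = tau[2, 2], tau_nn = tau[3, 3],
                   tau_fs = tau[1, 2], tau_fn = tau[1, 3], tau_sn = tau[2, 3])
  })
  out <- dplyr::bind_rows(rows)
  new_residual_field(out, frame = "fibre", method = method)
}

#' Residual stress estimate at a single material point
#'
#' Pointwise core of [estimate_tau()]: maps one Euler-Almansi strain tensor
#' to the residual Cauchy stress under the chosen constitutive assumption.
#'
#' @inheritParams strain_to_B
#' @inheritParams estimate_tau
#' @param frame the [fibre_frame()] in whose basis `e0` is expressed
#'   (defaults to the coordinate axes).
#' @param label optional label for error messages.
#' @return Symmetric 3x3 matrix `tau` (kPa) in the same basis as `e0`.
#' @export
estimate_tau_point <- function(e0, params = ho_params(),
                               method = c("isotropic", "orthotropic"),
                               frame = fibre_frame(c(1, 0, 0), c(0, 1, 0)),
                               label = NULL) {
  method <- match.arg(method)
  Br <- strain_to_B(e0, label = label)
  if (method == "isotropic") {
    I1r <- sum(diag(Br))
    tau <- params$a * exp(params$b * (I1r - 3)) * Br - params$a * diag(3)
    return((tau + t(tau)) / 2)
  }
  # orthotropic: tau = F0 dW/dF0 - p_r I with the full law; take the
  # symmetric square root of B_r as F0 (the rotation part is immaterial
  # because W depends on F0 only through C0 = B_r for symmetric F0)
  F0 <- sqrtm_spd(Br)
  st <- deformation_state(F0, tol = Inf)
  cauchy_stress("baseline", params, st, frame, p_lagrange = params$a)$sigma
}

sqrtm_spd <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(e$values) < 0) stop("matrix is not positive semi-definite", call. = FALSE)
  e$vectors %*% (sqrt(e$values) * t(e$vectors))
}

new_residual_field <- function(df, frame, method = NULL, geometry = NULL) {
  structure(
    tibble::as_tibble(df),
    frame = frame, method = method, geometry = geometry,
    class = c("residual_field", class(tibble::tibble()))
  )
}

#' Radial-equilibrium diagnostic for a residual stress field
#'
#' A genuine residual stress field is self-equilibrated, `Div(tau) = 0`.
#' For an axisymmetric field on a cylinder annulus the only non-trivial
#' component is the radial one, `d tau_rr / dr + (tau_rr - tau_thth)/r`.
#' This returns the discrete residual of that equation on the sampling
#' grid. Stress fields estimated from measured strains generally violate
#' it; the diagnostic reports, it never rejects.
#'
#' @param field tibble with columns `r` (cm), `tau_rr`, `tau_thth` (kPa),
#'   e.g. an [opening_angle_field()] result or a strain-based estimate
#'   mapped onto a tube by [costa_field_on_tube()].
#' @return The input with an added column `equilibrium_residual`
#'   (kPa/cm), computed by central differences (one-sided at the ends).
#' @export
divergence_diagnostic <- function(field) {
  if (!all(c("r", "tau_rr", "tau_thth") %in% names(field))) {
    stop("field needs columns r, tau_rr, tau_thth", call. = FALSE)
  }
  if (nrow(field) < 3L) {
    stop("at least 3 radial samples are required", call. = FALSE)
  }
  r <- field$r
  dtau <- grad_central(field$tau_rr, r)
  dplyr::mutate(tibble::as_tibble(field),
                equilibrium_residual = abs(dtau + (field$tau_rr - field$tau_thth) / r))
}

grad_central <- function(y, x) {
  n <- length(x)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  }
  g
}

#' Synthetic transmural residual-strain profile
#'
#' Generates a plausible transmural profile of fibre-frame Euler-Almansi
#' residual strains for testing and demonstration: smooth low-order
#' polynomials in the wall-depth fraction, a compressive fibre strain at
#' the endocardium rising to tension at the epicardium, smaller cross-fibre
#' and radial components, and negligible shears. A seeded low-amplitude
#' smooth perturbation emulates measurement-to-measurement variability;
#' the output is deterministic given the seed.
#'
#' This generator emulates the qualitative structure of published canine
#' measurements; it is synthetic data, not a digitisation of any figure.
#'
#' @param n number of depth samples (default 21, uniform in `[0, 1]`).
#' @param e_ff_endo,e_ff_epi fibre strain at the two surfaces (defaults
#'   -0.04 and +0.06).
#' @param e_ss_endo,e_ss_epi sheet strain endpoints (defaults +0.02, -0.015).
#' @param e_nn_endo,e_nn_epi sheet-normal strain endpoints (defaults
#'   +0.015, -0.03).
#' @param shear_amp amplitude of the smooth shear components (default
#'   0.005, well below the 0.02 admissibility bound).
#' @param noise_sd standard deviation of the seeded smooth perturbation
#'   coefficients (default 0.002).
#' @param seed integer seed (default 0).
#' @return Tibble with columns `xi`, `e_ff`, `e_ss`, `e_nn`, `e_fs`,
#'   `e_fn`, `e_sn`, suitable for [estimate_tau()].
#' @export
generate_strain_fixture <- function(n = 21,
                                    e_ff_endo = -0.04, e_ff_epi = 0.06,
                                    e_ss_endo = 0.02, e_ss_epi = -0.015,
                                    e_nn_endo = 0.015, e_nn_epi = -0.03,
                                    shear_amp = 0.005,
                                    noise_sd = 0.002,
                                    seed = 0) {
  amps <- c(e_ff_endo, e_ff_epi, e_ss_endo, e_ss_epi, e_nn_endo, e_nn_epi)
  if (any(abs(amps) >= 0.25) || shear_amp < 0 || shear_amp > 0.02 ||
      noise_sd < 0) {
    stop("inadmissible fixture amplitudes", call. = FALSE)
  }
  if (n < 3) stop("need at least 3 depth samples", call. = FALSE)
  xi <- seq(0, 1, length.out = n)
  smooth <- function(lo, hi, curv_frac = 0) {
    # mild bowing proportional to the transmural span, so zero amplitudes
    # give an identically zero profile
    lo + (hi - lo) * xi + curv_frac * (hi - lo) * xi * (1 - xi)
  }
  pert <- function(rng_coef) {
    # smooth seeded perturbation: quadratic Legendre-style modes, zero at
    # the endpoints so the surface signs are set by the amplitudes alone
    rng_coef[1] * xi * (1 - xi) + rng_coef[2] * xi * (1 - xi) * (2 * xi - 1)
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  coefs <- matrix(stats::rnorm(12, sd = noise_sd), nrow = 6)
  out <- tibble::tibble(
    xi = xi,
    e_ff = smooth(e_ff_endo, e_ff_epi, curv_frac = -0.1) + pert(coefs[1, ]),
    e_ss = smooth(e_ss_endo, e_ss_epi) + pert(coefs[2, ]),
    e_nn = smooth(e_nn_endo, e_nn_epi) + pert(coefs[3, ]),
    e_fs = shear_amp * sin(pi * xi) + pert(coefs[4, ]) / 4,
    e_fn = shear_amp * xi * (1 - xi) + pert(coefs[5, ]) / 4,
    e_sn = -shear_amp * xi * (1 - xi) + pert(coefs[6, ]) / 4
  )
  if (max(abs(as.matrix(out[strain_cols]))) > 0.1) {
    stop("generated strain magnitudes exceed 0.1; reduce amplitudes",
         call. = FALSE)
  }
  out
}

#' Read / write a transmural strain-profile table
#'
#' Plain-text comma-separated table with a header and columns `xi`,
#' `e_ff`, `e_ss`, `e_nn`, `e_fs`, `e_fn`, `e_sn`; `xi` strictly
#' increasing in `[0, 1]`.
#'
#' @param path file path.
#' @return `read_strain_profile()` returns the validated tibble.
#' @export
read_strain_profile <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  check_strain_profile(df)
  tibble::as_tibble(df)
}

#' @rdname read_strain_profile
#' @param profile a strain-profile tibble.
#' @export
write_strain_profile <- function(profile, path) {
  check_strain_profile(profile)
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Map a fibre-frame residual field onto a cylinder annulus
#'
#' Expresses a strain-based (fibre-frame) residual stress estimate in the
#' cylindrical basis of a tube, using the transmural fibre rule to supply
#' the frame at each wall depth. Useful for the radial-equilibrium
#' diagnostic and for plotting against opening-angle fields.
#'
#' @param field a fibre-frame `residual_field` from [estimate_tau()].
#' @param tube an [lv_tube()].
#' @param fibre a [fibre_rule()].
#' @param n_radial radial samples (default: one per xi sample, at least 50).
#' @return A cylindrical-frame `residual_field` with columns `r`, `xi`,
#'   `tau_rr`, `tau_thth`, `tau_zz`, `tau_rt`, `tau_rz`, `tau_tz` (kPa).
#' @export
costa_field_on_tube <- function(field, tube, fibre = fibre_rule(),
                                n_radial = max(50L, nrow(field))) {
  if (!identical(attr(field, "frame"), "fibre")) {
    stop("field must be a fibre-frame residual field", call. = FALSE)
  }
  stopifnot(inherits(tube, "lv_tube"))
  r <- seq(tube$r_i, tube$r_o, length.out = n_radial)
  xi <- (r - tube$r_i) / (tube$r_o - tube$r_i)
  comp <- tau_interpolator(field, fibre)(xi)
  out <- tibble::tibble(
    r = r, xi = xi,
    tau_rr = comp$rr, tau_thth = comp$tt, tau_zz = comp$zz,
    tau_rt = comp$rt, tau_rz = comp$rz, tau_tz = comp$tz
  )
  new_residual_field(out, frame = "cylindrical",
                     method = attr(field, "method"),
                     geometry = list(tube = tube))
}
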