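#' Strain-energy density of the (residually stressed) myocardium
#'
#' The baseline orthotropic law is
#' \deqn{W = \frac{a}{2b} e^{b(I_1-3)}
#'   + \sum_{i=f,s} \frac{a_i}{2b_i}\{e^{b_i(I_{4i}-1)^2}-1\}
#'   + \frac{a_{fs}}{2b_{fs}}\{e^{b_{fs} I_{4fs}^2}-1\},}
#' with the fibre and sheet terms included only when the corresponding
#' `I4` invariant exceeds 1 (fibres support extension, not compression).
#' Residual stress enters through extra invariant terms with constant
#' coefficients fixed by consistency of the unloaded state:
#' `model = "simple"` adds `I6 / 2`; `model = "extended"` adds
#' `I6 / 4 + I7 / 8`; `model = "full"` adds
#' `W6 I6 + W7 I7 + W8 I8 + W9 I9` with user-supplied weights (a research
#' mode, see `full_weights`).
#'
#' @param model one of `"baseline"`, `"simple"`, `"extended"`, `"full"`.
#' @param params an [ho_params()] object.
#' @param inv a one-row tibble (or named list) of invariants as returned by
#'   [invariants()]; residual models require `I6` (and `I7`; `"full"` also
#'   `I8`, `I9`).
#' @param full_weights for `model = "full"` only: named list with `W6`,
#'   `W7`, `W8`, `W9` (units 1, 1, 1/kPa, 1/kPa). They must satisfy the
#'   unloaded-state consistency conditions `2 (W6 + 2 W7) = 1` and
#'   `W8 + 2 W9 = 0`.
#' @return Scalar energy density in kPa.
#' @examples
#' p <- ho_params()
#' st <- deformation_state(diag(3))
#' fr <- fibre_frame(c(0, 1, 0), c(1, 0, 0))
#' strain_energy("baseline", p, invariants(st, fr)) # = a / (2 b)
#' @export
strain_energy <- function(model, params, inv, full_weights = NULL) {
  model <- match_model(model)
  stopifnot(inherits(params, "ho_params"))
  inv <- as.list(inv)
  W <- baseline_energy(params, inv)
  if (model == "baseline") return(W)
  need <- switch(model, simple = "I6", extended = c("I6", "I7"),
                 full = c("I6", "I7", "I8", "I9"))
  if (!all(need %in% names(inv)) || any(vapply(inv[need], is.null, TRUE))) {
    stop("model '", model, "' requires residual-stress invariants: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  w <- residual_weights(model, full_weights)
  W + w$W6 * inv$I6 + w$W7 * inv$I7 +
    (if (model == "full") w$W8 * inv$I8 + w$W9 * inv$I9 else 0)
}

match_model <- function(model) {
  if (!is.character(model) || length(model) != 1L ||
      !model %in% c("baseline", "simple", "extended", "full")) {
    stop("unknown model: must be one of 'baseline', 'simple', 'extended', 'full'",
         call. = FALSE)
  }
  model
}

baseline_energy <- function(params, inv) {
  p <- params
  W <- p$a / (2 * p$b) * exp(p$b * (inv$I1 - 3))
  if (inv$I4f > 1) {
    W <- W + p$a_f / (2 * p$b_f) * (exp(p$b_f * (inv$I4f - 1)^2) - 1)
  }
  if (inv$I4s > 1) {
    W <- W + p$a_s / (2 * p$b_s) * (exp(p$b_s * (inv$I4s - 1)^2) - 1)
  }
  W + p$a_fs / (2 * p$b_fs) * (exp(p$b_fs * inv$I4fs^2) - 1)
}

residual_weights <- function(model, full_weights = NULL) {
  switch(model,
    baseline = list(W6 = 0, W7 = 0, W8 = 0, W9 = 0),
    simple   = list(W6 = 1 / 2, W7 = 0, W8 = 0, W9 = 0),
    extended = list(W6 = 1 / 4, W7 = 1 / 8, W8 = 0, W9 = 0),
    full = {
      w <- full_weights
      if (is.null(w) || !all(c("W6", "W7", "W8", "W9") %in% names(w))) {
        stop("model 'full' requires full_weights = list(W6, W7, W8, W9)",
             call. = FALSE)
      }
      if (abs(2 * (w$W6 + 2 * w$W7) - 1) > 1e-12 ||
          abs(w$W8 + 2 * w$W9) > 1e-12) {
        stop("full_weights must satisfy 2(W6 + 2 W7) = 1 and W8 + 2 W9 = 0",
             call. = FALSE)
      }
      w
    })
}

#' Cauchy stress of the (residually stressed) myocardium
#'
#' Evaluates the Cauchy stress `sigma = -p I + F dW/dF` for the chosen
#' formulation. The residual contribution is `Sigma = F tau t(F)` for the
#' simple model and `Sigma/2 + (Sigma B + B Sigma)/4` for the extended
#' model. The incompressibility pressure `p` is not a material quantity:
#' it must be supplied by the caller (or left at 0, in which case the
#' returned stress is `sigma + p I`); [pressure_for_traction()] closes it
#' from a prescribed normal traction.
#'
#' At the identity deformation with `p = a`, both residual models return
#' `sigma = tau` exactly: the unloaded configuration is in equilibrium
#' with its own residual stress.
#'
#' @inheritParams strain_energy
#' @param state a [deformation_state()] (must be isochoric for physical use).
#' @param frame a [fibre_frame()].
#' @param tau symmetric 3x3 residual Cauchy stress in the global basis
#'   (kPa); required by the residual models, ignored by `"baseline"`.
#' @param p Lagrange pressure in kPa (default 0, i.e. the returned tensor
#'   is the stress up to `-p I`).
#' @return An object of class `stress_result`: list with `sigma` (3x3,
#'   kPa), `p`, `model`, and `terms`, a named list of the additive 3x3
#'   contributions (`matrix`, `fibre`, `sheet`, `fibre_sheet`, `residual`).
#' @examples
#' p <- ho_params()
#' st <- deformation_state(diag(3))
#' fr <- fibre_frame(c(0, 1, 0), c(1, 0, 0))
#' tau <- diag(c(-0.1, 0.05, 0.02))
#' cauchy_stress("simple", p, st, fr, tau = tau, p_lagrange = p$a)$sigma # = tau
#' @export
cauchy_stress <- function(model, params, state, frame, tau = NULL,
                          p_lagrange = 0, full_weights = NULL) {
  model <- match_model(model)
  stopifnot(inherits(params, "ho_params"),
            inherits(state, "deformation_state"),
            inherits(frame, "fibre_frame"))
  if (model != "baseline" && is.null(tau)) {
    stop("model '", model, "' requires a residual stress tensor tau",
         call. = FALSE)
  }
  if (!is.null(tau)) tau <- check_symmetric3(tau, "tau")
  pm <- params
  F <- state$F; B <- state$B
  inv <- strain_invariants(state, frame)
  f <- as.numeric(F %*% frame$f0)
  s <- as.numeric(F %*% frame$s0)

  terms <- list(
    matrix = pm$a * exp(pm$b * (inv$I1 - 3)) * B,
    fibre = if (inv$I4f > 1) {
      2 * pm$a_f * (inv$I4f - 1) * exp(pm$b_f * (inv$I4f - 1)^2) * tcrossprod(f)
    } else matrix(0, 3, 3),
    sheet = if (inv$I4s > 1) {
      2 * pm$a_s * (inv$I4s - 1) * exp(pm$b_s * (inv$I4s - 1)^2) * tcrossprod(s)
    } else matrix(0, 3, 3),
    fibre_sheet = pm$a_fs * inv$I4fs * exp(pm$b_fs * inv$I4fs^2) *
      (tcrossprod(f, s) + tcrossprod(s, f))
  )

  terms$residual <- if (model == "baseline" || is.null(tau)) {
    matrix(0, 3, 3)
  } else {
    Sigma <- F %*% tau %*% t(F)
    w <- residual_weights(model, full_weights)
    res <- 2 * w$W6 * Sigma + 2 * w$W7 * (Sigma %*% B + B %*% Sigma)
    if (model == "full" && (w$W8 != 0 || w$W9 != 0)) {
      Binv <- solve(B)
      SBS <- Sigma %*% Binv %*% Sigma
      res <- res + 2 * w$W8 * SBS +
        2 * w$W9 * (SBS %*% B + B %*% SBS)
    }
    res
  }

  sigma <- Reduce(`+`, terms) - p_lagrange * diag(3)
  structure(list(sigma = (sigma + t(sigma)) / 2, p = p_lagrange,
                 model = model, terms = terms, invariants = inv),
            class = "stress_result")
}

#' @export
print.stress_result <- function(x, ...) {
  cat("Cauchy stress (kPa), model =", x$model, ", p =", format(x$p), "kPa\n")
  print(x$sigma)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.stress_result <- function(x, ...) {
  idx <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  tibble::tibble(
    component = c("11", "22", "33", "12", "13", "23"),
    sigma_kPa = x$sigma[idx],
    !!!stats::setNames(
      lapply(x$terms, function(M) M[idx]),
      paste0(names(x$terms), "_kPa")
    )
  )
}

#' Close the Lagrange pressure from a prescribed normal traction
#'
#' For an incompressible material the pressure `p` is statically
#' indeterminate pointwise; it is fixed by a traction boundary condition.
#' Given a stress evaluated with `p = 0`, this returns the `p` such that
#' the normal stress `n . sigma n` equals `value`.
#'
#' @param stress a `stress_result` evaluated with `p_lagrange = 0`.
#' @param normal unit normal direction (3-vector).
#' @param value prescribed normal Cauchy stress in kPa (e.g. `-P` under a
#'   pressure load `P`, 0 on a free surface).
#' @return Scalar `p` in kPa.
#' @export
pressure_for_traction <- function(stress, normal, value = 0) {
  stopifnot(inherits(stress, "stress_result"))
  n <- as.numeric(normal)
  n <- n / sqrt(sum(n^2))
  if (stress$p != 0) {
    stop("supply a stress evaluated with p_lagrange = 0", call. = FALSE)
  }
  as.numeric(n %*% stress$sigma %*% n) - value
}

#' Residual-model consistency constants at the unloaded configuration
#'
#' Returns the constant energy derivatives `W1`, `W6`, `W7`, `W8`, `W9`
#' that each residual formulation hard-codes, evaluated at the unloaded
#' configuration, together with the three consistency conditions that the
#' unloaded state imposes: `2 W1 = p_r = a`, `2 (W6 + 2 W7) = 1`, and
#' `W8 + 2 W9 = 0`.
#'
#' @param model `"simple"` or `"extended"` (or `"full"` with
#'   `full_weights`).
#' @param params an [ho_params()] object (only `a` is used, for `W1`).
#' @inheritParams strain_energy
#' @return One-row tibble with `model`, `W1`, `W6`, `W7`, `W8`, `W9`,
#'   `p_r`, and logical columns `cond_pressure`, `cond_tau`, `cond_tau2`
#'   reporting the three conditions.
#' @export
consistency_constants <- function(model, params = ho_params(),
                                  full_weights = NULL) {
  model <- match_model(model)
  if (model == "baseline") {
    stop("consistency constants are defined for the residual models",
         call. = FALSE)
  }
  w <- residual_weights(model, full_weights)
  W1 <- params$a / 2 # dW/dI1 at I1 = 3
  tibble::tibble(
    model = model, W1 = W1, W6 = w$W6, W7 = w$W7, W8 = w$W8, W9 = w$W9,
    p_r = 2 * W1,
    cond_pressure = abs(2 * W1 - params$a) < 1e-14,
    cond_tau = abs(2 * (w$W6 + 2 * w$W7) - 1) < 1e-14,
    cond_tau2 = abs(w$W8 + 2 * w$W9) < 1e-14
  )
}

#' Principal-direction reduction of the I6 invariant
#'
#' When the residual stress is diagonal in the fibre frame,
#' `I6 = tr(tau C)` reduces to structural invariants already present in
#' the orthotropic law:
#' `I6 = tau_nn I1 + (tau_ff - tau_nn) I4f + (tau_ss - tau_nn) I4s`.
#'
#' @param tau_ff,tau_ss,tau_nn principal residual stresses in the fibre
#'   frame (kPa). Alternatively `tau_ff` may be a 3x3 matrix, which must
#'   then be diagonal (its fibre-frame representation).
#' @param inv invariants as returned by [invariants()] (needs `I1`, `I4f`,
#'   `I4s`).
#' @param tol tolerance for the diagonality check when a matrix is given.
#' @return Scalar `I6` in kPa, equal to `tr(tau C)`.
#' @export
reduced_I6 <- function(tau_ff, tau_ss = NULL, tau_nn = NULL, inv, tol = 1e-10) {
  if (is.matrix(tau_ff)) {
    tau <- check_symmetric3(tau_ff, "tau")
    off <- max(abs(tau[upper.tri(tau)]))
    if (off > tol * max(1, max(abs(diag(tau))))) {
      stop("tau must be diagonal in the fibre frame for the reduced I6 form",
           call. = FALSE)
    }
    tau_ff <- tau[1, 1]; tau_ss <- tau[2, 2]; tau_nn <- tau[3, 3]
  }
  inv <- as.list(inv)
  tau_nn * inv$I1 + (tau_ff - tau_nn) * inv$I4f + (tau_ss - tau_nn) * inv$I4s
}
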