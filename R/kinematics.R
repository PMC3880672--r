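#' Deformation state of a material point
#'
#' Wraps a deformation gradient `F` together with the derived right and left
#' Cauchy-Green tensors `C = t(F) %*% F`, `B = F %*% t(F)` and the volume
#' ratio `J = det(F)`. The model is incompressible, so `J` should equal 1;
#' a departure is flagged (`isochoric = FALSE`) but is not an error, since
#' intermediate states (e.g. finite-difference probes) may be slightly
#' compressible.
#'
#' @param F a 3x3 numeric matrix with positive determinant.
#' @param tol relative tolerance used to flag `J != 1`.
#' @return An object of class `deformation_state`: a list with elements
#'   `F`, `C`, `B`, `J`, `isochoric`.
#' @examples
#' deformation_state(diag(3))
#' deformation_state(diag(c(1.2, 1 / 1.2, 1)))
#' @export
deformation_state <- function(F, tol = 1e-8) {
  check_matrix3(F, "F")
  J <- det(F)
  if (!is.finite(J) || J <= 0) {
    stop("F must have a positive finite determinant", call. = FALSE)
  }
  structure(
    list(F = F, C = crossprod(F), B = tcrossprod(F), J = J,
         isochoric = abs(J - 1) <= tol * max(1, abs(J))),
    class = "deformation_state"
  )
}

#' @export
print.deformation_state <- function(x, ...) {
  cat("Deformation state: J =", format(x$J, digits = 12),
      if (x$isochoric) "(isochoric)" else "(NOT isochoric)", "\n")
  cat("F =\n"); print(x$F)
  invisible(x)
}

check_matrix3 <- function(M, name) {
  if (!is.matrix(M) || !all(dim(M) == c(3L, 3L)) || !is.numeric(M) ||
      any(!is.finite(M))) {
    stop(name, " must be a finite numeric 3x3 matrix", call. = FALSE)
  }
  invisible(M)
}

check_symmetric3 <- function(M, name, tol = 1e-8) {
  check_matrix3(M, name)
  scale <- max(1, max(abs(M)))
  if (max(abs(M - t(M))) > tol * scale) {
    stop(name, " must be symmetric", call. = FALSE)
  }
  invisible((M + t(M)) / 2)
}

#' Orthonormal fibre-sheet-normal frame
#'
#' The local material triad of ventricular myocardium: the fibre (myocyte)
#' axis `f0`, the sheet axis `s0`, and the sheet-normal axis
#' `n0 = f0 x s0`. Inputs are normalised; `f0` and `s0` must be orthogonal
#' (within `tol`) and `n0` is always recomputed as the exact cross product.
#'
#' @param f0,s0 numeric 3-vectors.
#' @param tol orthogonality tolerance.
#' @return An object of class `fibre_frame`: list with unit vectors
#'   `f0`, `s0`, `n0`.
#' @examples
#' fibre_frame(c(1, 0, 0), c(0, 1, 0))
#' @export
fibre_frame <- function(f0, s0, tol = 1e-8) {
  f0 <- as.numeric(f0); s0 <- as.numeric(s0)
  if (length(f0) != 3L || length(s0) != 3L || any(!is.finite(c(f0, s0)))) {
    stop("f0 and s0 must be finite numeric 3-vectors", call. = FALSE)
  }
  nf <- sqrt(sum(f0^2)); ns <- sqrt(sum(s0^2))
  if (nf == 0 || ns == 0) stop("frame vectors must be non-zero", call. = FALSE)
  f0 <- f0 / nf; s0 <- s0 / ns
  if (abs(sum(f0 * s0)) > tol) {
    stop("f0 and s0 must be orthogonal", call. = FALSE)
  }
  # re-orthogonalise s0 against f0 so the triad is orthonormal to machine
  # precision even when the inputs are only tol-orthogonal
  s0 <- s0 - sum(f0 * s0) * f0
  s0 <- s0 / sqrt(sum(s0^2))
  n0 <- cross3(f0, s0)
  structure(list(f0 = f0, s0 = s0, n0 = n0), class = "fibre_frame")
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' @export
print.fibre_frame <- function(x, ...) {
  cat("Fibre frame (rows f0, s0, n0):\n")
  print(rbind(f0 = x$f0, s0 = x$s0, n0 = x$n0))
  invisible(x)
}

#' Structural (quasi-)invariants of a deformation
#'
#' Computes the isotropic invariants `I1 = tr(C)`,
#' `I2 = (I1^2 - tr(C^2))/2`, `I3 = det(C)` and the fibre-frame
#' quasi-invariants `I4f = f0.(C f0)`, `I4s = s0.(C s0)`,
#' `I4n = n0.(C n0)`, `I4fs = f0.(C s0)` and the second-order
#' `I5i = i0.(C^2 i0)` for i in f, s, n. For an orthonormal triad the
#' identity `I1 = I4f + I4s + I4n` holds exactly.
#'
#' `I2` is computed for completeness only: no strain-energy term in this
#' package uses it.
#'
#' @param state a [deformation_state()].
#' @param frame a [fibre_frame()].
#' @return A one-row tibble with columns `I1`, `I2`, `I3`, `I4f`, `I4s`,
#'   `I4n`, `I4fs`, `I5f`, `I5s`, `I5n`.
#' @examples
#' st <- deformation_state(diag(3))
#' fr <- fibre_frame(c(1, 0, 0), c(0, 1, 0))
#' strain_invariants(st, fr)
#' @export
strain_invariants <- function(state, frame) {
  stopifnot(inherits(state, "deformation_state"), inherits(frame, "fibre_frame"))
  C <- state$C
  C2 <- C %*% C
  qf <- function(v, M) as.numeric(v %*% M %*% v)
  tibble::tibble(
    I1 = sum(diag(C)),
    I2 = (sum(diag(C))^2 - sum(diag(C2))) / 2,
    I3 = det(C),
    I4f = qf(frame$f0, C),
    I4s = qf(frame$s0, C),
    I4n = qf(frame$n0, C),
    I4fs = as.numeric(frame$f0 %*% C %*% frame$s0),
    I5f = qf(frame$f0, C2),
    I5s = qf(frame$s0, C2),
    I5n = qf(frame$n0, C2)
  )
}

#' Residual-stress invariants
#'
#' The four invariants coupling the right Cauchy-Green tensor `C` with the
#' residual Cauchy stress `tau` of the unloaded configuration:
#' `I6 = tr(tau C)`, `I7 = tr(tau C^2)`, `I8 = tr(tau^2 C)`,
#' `I9 = tr(tau^2 C^2)`. At the identity deformation `I6 = I7 = tr(tau)`
#' and `I8 = I9 = tr(tau^2)`.
#'
#' @param state a [deformation_state()].
#' @param tau symmetric 3x3 residual Cauchy stress (kPa).
#' @return A one-row tibble with columns `I6`, `I7` (kPa) and `I8`, `I9`
#'   (kPa^2).
#' @examples
#' st <- deformation_state(diag(c(2, 1, 1)))
#' residual_invariants(st, diag(c(1, 2, 3)))
#' @export
residual_invariants <- function(state, tau) {
  stopifnot(inherits(state, "deformation_state"))
  tau <- check_symmetric3(tau, "tau")
  C <- state$C
  C2 <- C %*% C
  tau2 <- tau %*% tau
  tibble::tibble(
    I6 = sum(tau * C),        # tr(tau C) for symmetric tau
    I7 = sum(tau * t(C2)),
    I8 = sum(tau2 * t(C)),
    I9 = sum(tau2 * t(C2))
  )
}

#' All invariants used by the residually stressed constitutive law
#'
#' Convenience wrapper binding [strain_invariants()] and, when `tau` is
#' given, [residual_invariants()] into one row.
#'
#' @inheritParams strain_invariants
#' @inheritParams residual_invariants
#' @return One-row tibble.
#' @export
invariants <- function(state, frame, tau = NULL) {
  out <- strain_invariants(state, frame)
  if (!is.null(tau)) {
    out <- dplyr::bind_cols(out, residual_invariants(state, tau))
  }
  out
}
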