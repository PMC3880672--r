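# Vectorised evaluation of the constitutive stress along a radial grid of
# an axisymmetric tube. The deformation gradient is diagonal in the local
# cylindrical basis (e_r, e_theta, e_z), F = diag(lr, lt, lz), which makes
# every term of the law expressible componentwise without per-point matrix
# algebra. This is the hot path of the opening-angle and inflation solvers;
# the pointwise tensor API (cauchy_stress) is the reference it is tested
# against.
#
# Arguments:
#   lr, lt, lz : principal stretches (vectors; lz may be scalar)
#   params     : ho_params
#   fibre      : NULL for the isotropic matrix only, else list(f0, s0) of
#                3-column matrices of frame components in (e_r, e_theta, e_z)
#   tau        : NULL or list of components rr, tt, zz, rt, rz, tz (kPa) in
#                the cylindrical basis
#   model      : "baseline", "simple" or "extended" (residual term choice)
#
# Returns a list of the six components of sigma + p I (i.e. the stress up
# to the Lagrange pressure): rr, tt, zz, rt, rz, tz.
hat_stress_profile <- function(lr, lt, lz, params, fibre = NULL, tau = NULL,
                               model = "baseline") {
  n <- length(lr)
  lz <- rep_len(lz, n)
  p <- params
  I1 <- lr^2 + lt^2 + lz^2
  k <- p$a * exp(p$b * (I1 - 3))
  out <- list(rr = k * lr^2, tt = k * lt^2, zz = k * lz^2,
              rt = numeric(n), rz = numeric(n), tz = numeric(n))

  if (!is.null(fibre)) {
    f <- cbind(lr * fibre$f0[, 1], lt * fibre$f0[, 2], lz * fibre$f0[, 3])
    s <- cbind(lr * fibre$s0[, 1], lt * fibre$s0[, 2], lz * fibre$s0[, 3])
    I4f <- rowSums(f^2)
    I4s <- rowSums(s^2)
    I4fs <- rowSums(f * s)

    cf <- ifelse(I4f > 1,
                 2 * p$a_f * (I4f - 1) * exp(p$b_f * (I4f - 1)^2), 0)
    cs <- ifelse(I4s > 1,
                 2 * p$a_s * (I4s - 1) * exp(p$b_s * (I4s - 1)^2), 0)
    cfs <- p$a_fs * I4fs * exp(p$b_fs * I4fs^2)

    out$rr <- out$rr + cf * f[, 1]^2 + cs * s[, 1]^2 + 2 * cfs * f[, 1] * s[, 1]
    out$tt <- out$tt + cf * f[, 2]^2 + cs * s[, 2]^2 + 2 * cfs * f[, 2] * s[, 2]
    out$zz <- out$zz + cf * f[, 3]^2 + cs * s[, 3]^2 + 2 * cfs * f[, 3] * s[, 3]
    out$rt <- out$rt + cf * f[, 1] * f[, 2] + cs * s[, 1] * s[, 2] +
      cfs * (f[, 1] * s[, 2] + s[, 1] * f[, 2])
    out$rz <- out$rz + cf * f[, 1] * f[, 3] + cs * s[, 1] * s[, 3] +
      cfs * (f[, 1] * s[, 3] + s[, 1] * f[, 3])
    out$tz <- out$tz + cf * f[, 2] * f[, 3] + cs * s[, 2] * s[, 3] +
      cfs * (f[, 2] * s[, 3] + s[, 2] * f[, 3])
  }

  if (!is.null(tau) && model != "baseline") {
    lam <- list(lr, lt, lz)
    comp <- list(rr = c(1, 1), tt = c(2, 2), zz = c(3, 3),
                 rt = c(1, 2), rz = c(1, 3), tz = c(2, 3))
    for (nm in names(comp)) {
      a <- comp[[nm]][1]; b <- comp[[nm]][2]
      Sig <- lam[[a]] * lam[[b]] * tau[[nm]]
      out[[nm]] <- out[[nm]] + switch(model,
        simple = Sig,
        extended = Sig / 2 + Sig * (lam[[a]]^2 + lam[[b]]^2) / 4,
        stop("unsupported residual model in profile evaluation", call. = FALSE)
      )
    }
  }
  out
}

zero_tau_profile <- function(n) {
  z <- numeric(n)
  list(rr = z, tt = z, zz = z, rt = z, rz = z, tz = z)
}

# Adaptive quadrature with a fixed-grid composite-Simpson fallback: the
# tension-only switches make the integrand piecewise smooth, and the
# adaptive rule can refuse near a kink under tight tolerances.
safe_integrate <- function(f, lower, upper, abs_tol) {
  val <- tryCatch(
    stats::integrate(f, lower, upper, abs.tol = abs_tol, rel.tol = 1e-9,
                     subdivisions = 400L)$value,
    error = function(e) NA_real_)
  if (is.finite(val)) return(val)
  n <- 4001L # odd, uniform; O(h^4) on the smooth pieces
  x <- seq(lower, upper, length.out = n)
  y <- f(x)
  h <- (upper - lower) / (n - 1L)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- w[n] <- 1
  sum(w * y) * h / 3
}
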