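#' Transmural fibre-angle rule for the cylindrical LV surrogate
#'
#' Analytic stand-in for rule-based fibre generation: the helix (fibre)
#' angle `phi` and the sheet angle `beta` vary linearly with the wall-depth
#' fraction `xi` (0 = endocardium, 1 = epicardium). The local triad at a
#' point, expressed in the cylindrical basis `(e_r, e_theta, e_z)`, is
#' \itemize{
#'   \item `f0 = cos(phi) e_theta + sin(phi) e_z` (fibres lie in the
#'     circumferential-axial plane),
#'   \item `s0` = `e_r` rotated about `f0` by the sheet angle `beta`,
#'   \item `n0 = f0 x s0`.
#' }
#' Defaults follow the usual rule of a +/-60 degree helix and +/-45 degree
#' sheet angle; the endo/epi orientation can be swapped via the arguments.
#'
#' @param phi_endo,phi_epi fibre angle in degrees at the endocardial and
#'   epicardial surfaces (default +60 to -60).
#' @param beta_endo,beta_epi sheet angle in degrees (default -45 to +45).
#' @return An object of class `fibre_rule`.
#' @examples
#' rule <- fibre_rule()
#' fibre_frame_at(rule, xi = 0.5)
#' @export
fibre_rule <- function(phi_endo = 60, phi_epi = -60,
                       beta_endo = -45, beta_epi = 45) {
  vals <- c(phi_endo, phi_epi, beta_endo, beta_epi)
  if (any(!is.finite(vals))) stop("fibre rule angles must be finite", call. = FALSE)
  structure(list(phi_endo = phi_endo, phi_epi = phi_epi,
                 beta_endo = beta_endo, beta_epi = beta_epi),
            class = "fibre_rule")
}

#' @export
print.fibre_rule <- function(x, ...) {
  cat(sprintf("Fibre rule: phi %g to %g deg, beta %g to %g deg (endo to epi)\n",
              x$phi_endo, x$phi_epi, x$beta_endo, x$beta_epi))
  invisible(x)
}

rule_angles <- function(rule, xi) {
  list(
    phi = (rule$phi_endo + (rule$phi_epi - rule$phi_endo) * xi) * pi / 180,
    beta = (rule$beta_endo + (rule$beta_epi - rule$beta_endo) * xi) * pi / 180
  )
}

# Frame vectors at depth fractions xi, vectorised: returns a list of three
# 3-column matrices (rows follow xi) with components in (e_r, e_theta, e_z).
rule_vectors <- function(rule, xi) {
  an <- rule_angles(rule, xi)
  cph <- cos(an$phi); sph <- sin(an$phi)
  cbe <- cos(an$beta); sbe <- sin(an$beta)
  f0 <- cbind(r = 0 * xi, th = cph, z = sph)
  s0 <- cbind(r = cbe, th = sbe * sph, z = -sbe * cph)
  n0 <- cbind(r = -sbe, th = cbe * sph, z = -cbe * cph)
  list(f0 = f0, s0 = s0, n0 = n0)
}

#' Fibre frame at a given wall depth
#'
#' @param rule a [fibre_rule()].
#' @param xi wall-depth fraction in `[0, 1]` (scalar).
#' @return A [fibre_frame()] with components in the local cylindrical basis
#'   `(e_r, e_theta, e_z)`.
#' @export
fibre_frame_at <- function(rule, xi) {
  stopifnot(inherits(rule, "fibre_rule"), length(xi) == 1L, xi >= 0, xi <= 1)
  v <- rule_vectors(rule, xi)
  fibre_frame(v$f0[1, ], v$s0[1, ])
}
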