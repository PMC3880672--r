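# Shared fixtures. Everything is generated in code; geometry and material
# parameters follow the package defaults (sector 2.5/4.2 cm, opening angle
# 85 degrees, unit axial stretch).

params_default <- ho_params()
params_iso <- ho_params(a_f = 0, a_s = 0, a_fs = 0)

ref_geometry <- function() cylinder_geometry(2.5, 4.2, alpha_deg = 85)

# cached reference opening-angle field + closed tube (solved once per run)
.fixture_env <- new.env()
ref_oa_field <- function(n_radial = 120) {
  key <- paste0("oa", n_radial)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- opening_angle_field(ref_geometry(), params_default,
                                               n_radial = n_radial)
  }
  .fixture_env[[key]]
}
ref_tube <- function(n_radial = 120) closed_tube(ref_oa_field(n_radial))

# random isochoric deformation / frame / symmetric tau (package-internal
# generator reused so tests and selftest probe the same distribution)
random_point <- resmyo:::random_point
stress_fd_error <- resmyo:::stress_fd_error
energy_of_F <- resmyo:::energy_of_F

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
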