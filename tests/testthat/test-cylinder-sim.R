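test_that("vectorised radial stress kernel agrees with the tensor API", {
  # the profile solvers use a componentwise kernel for diagonal F in the
  # cylindrical basis; check it against cauchy_stress at scattered points
  p <- params_default
  rule <- fibre_rule()
  set.seed(31)
  xi <- runif(6)
  lt <- runif(6, 0.9, 1.25)
  lz <- 1
  lr <- 1 / (lt * lz)
  v <- resmyo:::rule_vectors(rule, xi)
  tau_comp <- list(rr = rnorm(6, sd = 0.1), tt = rnorm(6, sd = 0.1),
                   zz = rnorm(6, sd = 0.1), rt = rnorm(6, sd = 0.02),
                   rz = rnorm(6, sd = 0.02), tz = rnorm(6, sd = 0.02))
  for (model in c("baseline", "simple", "extended")) {
    sh <- resmyo:::hat_stress_profile(lr, lt, lz, p, fibre = v,
                                      tau = if (model == "baseline") NULL else tau_comp,
                                      model = model)
    for (k in seq_along(xi)) {
      F <- diag(c(lr[k], lt[k], lz))
      fr <- fibre_frame(v$f0[k, ], v$s0[k, ])
      tau <- matrix(c(tau_comp$rr[k], tau_comp$rt[k], tau_comp$rz[k],
                      tau_comp$rt[k], tau_comp$tt[k], tau_comp$tz[k],
                      tau_comp$rz[k], tau_comp$tz[k], tau_comp$zz[k]), 3, 3)
      sg <- cauchy_stress(model, p, deformation_state(F), fr,
                          tau = if (model == "baseline") NULL else tau)$sigma
      expect_equal(c(sh$rr[k], sh$tt[k], sh$zz[k], sh$rt[k], sh$rz[k], sh$tz[k]),
                   c(sg[1, 1], sg[2, 2], sg[3, 3], sg[1, 2], sg[1, 3], sg[2, 3]),
                   tolerance = 1e-12)
    }
  }
})

test_that("unloaded stress-free tube stays put at zero pressure", {
  tube <- lv_tube(2.2, 3.8)
  sol <- inflate(tube, 0, params_default, n_radial = 60)
  expect_equal(sol$r_i_def, tube$r_i, tolerance = 1e-7)
  expect_lt(max(abs(sol$profile$sigma_rr)), 1e-8)
  expect_lt(max(abs(sol$profile$sigma_thth)), 1e-6)
  expect_lt(max(abs(sol$profile$sigma_ff)), 1e-6)
  expect_equal(sol$profile$lambda_th, rep(1, 60), tolerance = 1e-7)
})

test_that("at zero pressure the residually stressed tube carries sigma = tau", {
  fld <- ref_oa_field()
  tube <- ref_tube()
  sol <- inflate(tube, 0, params_default, model = "simple", tau = fld,
                 n_radial = 120)
  expect_equal(sol$r_i_def, tube$r_i, tolerance = 1e-4)
  expect_lt(max(abs(sol$profile$sigma_rr - fld$tau_rr)), 1e-3)
  expect_lt(max(abs(sol$profile$sigma_thth - fld$tau_thth)), 2e-2)
})

test_that("inflation satisfies boundary tractions and radial equilibrium", {
  tube <- ref_tube()
  fld <- ref_oa_field()
  for (tau in list(NULL, fld)) {
    model <- if (is.null(tau)) "baseline" else "simple"
    sol <- inflate(tube, 3, params_default, model = model, tau = tau,
                   n_radial = 120)
    pr <- sol$profile
    expect_equal(pr$sigma_rr[1], -sol$P_kPa, tolerance = 1e-10)
    expect_lt(abs(pr$sigma_rr[120]), 1e-6)
    # independent equilibrium check: d sigma_rr/dr ~ (sigma_thth - sigma_rr)/r
    dsig <- resmyo:::grad_central(pr$sigma_rr, pr$r)
    resid <- abs(dsig - (pr$sigma_thth - pr$sigma_rr) / pr$r)
    expect_lt(max(resid[3:118]), 5e-3) # FD discretisation error bound
    # exact incompressibility of the map: wall cross-section conserved
    expect_lt(abs((sol$r_o_def^2 - sol$r_i_def^2) - (tube$r_o^2 - tube$r_i^2)),
              1e-10)
  }
  expect_error(inflate(tube, -1, params_default), "non-negative")
  expect_error(inflate(tube, 3, params_default, model = "baseline", tau = fld),
               "no residual stress")
})

test_that("residual stress shifts fibre stress down at endo, up at epi", {
  tube <- ref_tube()
  fld <- ref_oa_field()
  s_no <- inflate(tube, 3, params_default, n_radial = 120)
  s_oa <- inflate(tube, 3, params_default, model = "simple", tau = fld,
                  n_radial = 120)
  sm_no <- surface_summary(s_no)
  sm_oa <- surface_summary(s_oa)
  d_endo <- sm_oa$mean_kPa[sm_oa$surface == "endo" & sm_oa$component == "ff"] -
    sm_no$mean_kPa[sm_no$surface == "endo" & sm_no$component == "ff"]
  d_epi <- sm_oa$mean_kPa[sm_oa$surface == "epi" & sm_oa$component == "ff"] -
    sm_no$mean_kPa[sm_no$surface == "epi" & sm_no$component == "ff"]
  expect_lt(d_endo, 0)
  expect_gt(d_epi, 0)
  # tau = 0 field: identically zero differences
  z <- ref_oa_field()
  z$tau_rr <- z$tau_thth <- z$tau_zz <- 0 * z$tau_rr
  s_z <- inflate(tube, 3, params_default, model = "simple", tau = z,
                 n_radial = 120)
  expect_equal(surface_summary(s_z)$mean_kPa, sm_no$mean_kPa, tolerance = 1e-9)
})

test_that("simple and extended formulations nearly coincide; scaled tau does not", {
  tube <- ref_tube()
  fld <- ref_oa_field()
  s1 <- inflate(tube, 3, params_default, model = "simple", tau = fld,
                n_radial = 120)
  s2 <- inflate(tube, 3, params_default, model = "extended", tau = fld,
                n_radial = 120)
  cmp <- compare_models(s1, s2)
  expect_true(all(cmp$within))
  expect_lt(max(cmp$max_rel_diff), 0.05)

  # the agreement rests on the residual stress being small relative to the
  # deformation scale: a 100x tau at late-diastolic pressure (where B - I
  # is appreciable) drives the two formulations visibly apart
  big <- ref_oa_field()
  for (cc in c("tau_rr", "tau_thth", "tau_zz")) big[[cc]] <- 100 * big[[cc]]
  b1 <- inflate(tube, 8, params_default, model = "simple", tau = big,
                n_radial = 120)
  b2 <- inflate(tube, 8, params_default, model = "extended", tau = big,
                n_radial = 120)
  cmp_big <- compare_models(b1, b2)
  expect_false(all(cmp_big$within))
  expect_gt(max(cmp_big$max_rel_diff), 10 * max(cmp$max_rel_diff))

  s_other <- inflate(tube, 8, params_default, model = "simple", tau = fld,
                     n_radial = 120)
  expect_error(compare_models(s1, s_other), "share pressure")
})

test_that("pressure-volume curve is monotone and normalised to [0, 1]", {
  tube <- ref_tube()
  pv <- pv_curve(tube, params_default, pressures_mmHg = c(0, 2, 4, 6, 8),
                 n_radial = 60)
  expect_true(all(diff(pv$cavity_area_cm2) > 0))
  expect_equal(pv$volume_norm[1], 0)
  expect_equal(pv$volume_norm[nrow(pv)], 1)
  expect_error(pv_curve(tube, params_default, pressures_mmHg = c(1, 2)),
               "increase strictly from 0")
})

test_that("baseline and simple-with-zero-tau pressure-volume curves coincide", {
  tube <- ref_tube()
  z <- ref_oa_field()
  z$tau_rr <- z$tau_thth <- z$tau_zz <- 0 * z$tau_rr
  ps <- c(0, 4, 8)
  pv0 <- pv_curve(tube, params_default, model = "baseline",
                  pressures_mmHg = ps, n_radial = 60)
  pvz <- pv_curve(tube, params_default, model = "simple", tau = z,
                  pressures_mmHg = ps, n_radial = 60)
  expect_equal(pvz$cavity_area_cm2, pv0$cavity_area_cm2, tolerance = 1e-10)
})

test_that("tidiers and plots expose the solution tables", {
  tube <- ref_tube()
  sol <- inflate(tube, 3, params_default, n_radial = 40)
  expect_s3_class(tidy(sol), "tbl_df")
  expect_equal(nrow(glance(sol)), 1L)
  expect_s3_class(autoplot(sol), "ggplot")
  expect_s3_class(autoplot(ref_oa_field()), "ggplot")
  pv <- pv_curve(tube, params_default, pressures_mmHg = c(0, 4, 8),
                 n_radial = 40)
  expect_s3_class(autoplot(pv), "ggplot")
})
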