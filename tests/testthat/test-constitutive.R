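fr_xy <- fibre_frame(c(1, 0, 0), c(0, 1, 0))
st_id <- deformation_state(diag(3))

test_that("energy at the identity has the closed-form residual offsets", {
  p <- params_default
  tau <- diag(c(1, 2, 3))
  inv0 <- invariants(st_id, fr_xy, tau = tau)
  W0 <- p$a / (2 * p$b)
  expect_equal(strain_energy("baseline", p, inv0), W0)
  # oracle: at identity I6 = I7 = tr(tau) = 6, so the residual parts are
  # 1/2 * 6 = 3 and (1/4 + 1/8) * 6 = 2.25
  expect_equal(strain_energy("simple", p, inv0), W0 + 3)
  expect_equal(strain_energy("extended", p, inv0), W0 + 2.25)
  expect_error(strain_energy("fancy", p, inv0), "unknown model")
  expect_error(strain_energy("simple", p, invariants(st_id, fr_xy)),
               "residual-stress invariants")
})

test_that("consistency constants satisfy the unloaded-state conditions", {
  cs <- consistency_constants("simple", params_default)
  expect_equal(cs$W6, 1 / 2)
  expect_equal(cs$W7, 0)
  ce <- consistency_constants("extended", params_default)
  expect_equal(ce$W6, 1 / 4)
  expect_equal(ce$W7, 1 / 8)
  for (cc in list(cs, ce)) {
    expect_equal(2 * cc$W1, params_default$a)
    expect_equal(cc$p_r, params_default$a)
    expect_equal(2 * (cc$W6 + 2 * cc$W7), 1)
    expect_equal(cc$W8 + 2 * cc$W9, 0)
    expect_true(all(cc$cond_pressure, cc$cond_tau, cc$cond_tau2))
  }
})

test_that("at the identity with p = a the stress is exactly tau", {
  set.seed(3)
  for (i in 1:25) {
    A <- matrix(rnorm(9), 3, 3)
    tau <- (A + t(A)) / 2
    for (m in c("simple", "extended")) {
      sg <- cauchy_stress(m, params_default, st_id, fr_xy, tau = tau,
                          p_lagrange = params_default$a)$sigma
      expect_lt(max(abs(sg - tau)), 1e-14)
    }
  }
})

test_that("zero tau collapses all models to the baseline stress", {
  set.seed(4)
  rp <- random_point()
  z <- matrix(0, 3, 3)
  sb <- cauchy_stress("baseline", params_default, rp$state, rp$frame)$sigma
  for (m in c("simple", "extended")) {
    sm <- cauchy_stress(m, params_default, rp$state, rp$frame, tau = z)$sigma
    expect_equal(sm, sb, tolerance = 1e-14)
  }
  expect_error(cauchy_stress("simple", params_default, rp$state, rp$frame),
               "requires a residual stress")
})

test_that("analytic stress matches the finite-difference energy gradient", {
  set.seed(5)
  for (i in 1:30) {
    rp <- random_point(0.15)
    for (m in c("baseline", "simple", "extended")) {
      err <- stress_fd_error(m, params_default, rp$state, rp$frame,
                             if (m == "baseline") NULL else rp$tau)
      expect_lt(err, 1e-6)
    }
  }
})

test_that("full-invariant research mode honours supplied weights", {
  w <- list(W6 = 1 / 4, W7 = 1 / 8, W8 = 0.05, W9 = -0.025)
  tau <- diag(c(0.3, -0.1, 0.2))
  set.seed(6)
  rp <- random_point()
  # identity consistency still holds because W8 + 2 W9 = 0
  sg <- cauchy_stress("full", params_default, st_id, fr_xy, tau = tau,
                      p_lagrange = params_default$a, full_weights = w)$sigma
  expect_equal(sg, tau, tolerance = 1e-12)
  err <- stress_fd_error("full", params_default, rp$state, rp$frame, rp$tau,
                         full_weights = w)
  expect_lt(err, 1e-6)
  badw <- list(W6 = 1 / 2, W7 = 0, W8 = 0.1, W9 = 0.1)
  expect_error(cauchy_stress("full", params_default, st_id, fr_xy, tau = tau,
                             full_weights = badw), "W8")
})

test_that("energy and stress are continuous across the tension switch", {
  p <- params_default
  eps <- 1e-8
  for (lam2 in c(1 - eps, 1 + eps)) {
    F <- diag(c(sqrt(lam2), 1 / sqrt(lam2), 1))
    st <- deformation_state(F)
    inv <- invariants(st, fr_xy)
    Wm <- strain_energy("baseline", p, inv)
    assign(if (lam2 < 1) "W_lo" else "W_hi", Wm)
    sg <- cauchy_stress("baseline", p, st, fr_xy)$sigma
    assign(if (lam2 < 1) "S_lo" else "S_hi", sg)
  }
  expect_lt(abs(W_hi - W_lo), 1e-10)
  expect_lt(max(abs(S_hi - S_lo)), 1e-6)
})

test_that("simple and extended stresses coincide as tau shrinks, at first order", {
  set.seed(8)
  rp <- random_point(0.1)
  diffs <- vapply(10^-(0:3), function(t) {
    tau <- t * rp$tau
    s1 <- cauchy_stress("simple", params_default, rp$state, rp$frame, tau = tau)$sigma
    s2 <- cauchy_stress("extended", params_default, rp$state, rp$frame, tau = tau)$sigma
    max(abs(s1 - s2))
  }, numeric(1))
  expect_true(all(diff(diffs) < 0))
  # linear decay in ||tau||: each decade of tau shrinks the gap ~10x
  ratios <- diffs[-length(diffs)] / diffs[-1]
  expect_true(all(abs(ratios - 10) < 0.5))
})

test_that("reduced I6 form equals the direct trace for principal tau", {
  set.seed(9)
  for (i in 1:20) {
    rp <- random_point()
    tau_d <- diag(c(-0.1, 0.02, 0.05))
    # express tau in the frame basis: tau = sum tau_ii e_i x e_i
    M <- rbind(rp$frame$f0, rp$frame$s0, rp$frame$n0)
    tau_global <- t(M) %*% tau_d %*% M
    inv <- invariants(rp$state, rp$frame, tau = tau_global)
    expect_lt(abs(reduced_I6(-0.1, 0.02, 0.05, inv = inv) - inv$I6), 1e-10)
  }
  inv0 <- invariants(st_id, fr_xy)
  expect_equal(reduced_I6(1, 2, 3, inv = inv0), 6)
  expect_equal(reduced_I6(0.5, 0.5, 0.5, inv = inv0), 0.5 * inv0$I1)
  expect_error(reduced_I6(matrix(c(1, 0.2, 0, 0.2, 1, 0, 0, 0, 1), 3, 3),
                          inv = inv0), "diagonal")
})

test_that("pressure closure reproduces a prescribed normal traction", {
  set.seed(10)
  rp <- random_point()
  s0 <- cauchy_stress("simple", params_default, rp$state, rp$frame, tau = rp$tau)
  n <- c(1, 0, 0)
  p_hat <- pressure_for_traction(s0, n, value = -0.4)
  s1 <- cauchy_stress("simple", params_default, rp$state, rp$frame,
                      tau = rp$tau, p_lagrange = p_hat)
  expect_equal(as.numeric(n %*% s1$sigma %*% n), -0.4, tolerance = 1e-12)
})
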