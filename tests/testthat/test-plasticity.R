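test_that("dopamine signal is piecewise linear with a neutral band", {
  expect_equal(dopamine_signal(5), 0)
  expect_equal(dopamine_signal(7), 0)     # upper band edge, continuous
  expect_equal(dopamine_signal(3), 0)     # lower band edge
  expect_equal(dopamine_signal(10), 3)
  expect_equal(dopamine_signal(2), -1)
  expect_equal(dopamine_signal(0), -3)
  expect_error(dopamine_signal(-1), "non-negative")
})

test_that("dopamine signal is odd-symmetric about the neutral band", {
  for (x in seq(0, 2.9, by = 0.3)) {
    expect_equal(dopamine_signal(5 + 2 + x), -dopamine_signal(5 - 2 - x))
  }
})

test_that("Hebbian coincidence: VTA product, PFC suppression, floor", {
  r_pre <- c(0, 0.2, 0.5)
  r_post <- c(0.1, 0.3)
  H <- hebbian_coincidence(r_pre, r_post, "VTA")
  expect_equal(H, outer(r_post, r_pre))
  expect_equal(H[, 1], c(0, 0))                     # silent presynapse
  # PFC at D = 0 identical to VTA
  expect_equal(hebbian_coincidence(r_pre, r_post, "PFC", D = 0), H)
  # alpha * D = 1 halves the PFC term
  expect_equal(hebbian_coincidence(r_pre, r_post, "PFC", D = 1, alpha = 1),
               H / 2)
  # strongly negative D: divisor clamped at the floor, H stays >= 0
  Hn <- hebbian_coincidence(r_pre, r_post, "PFC", D = -50, alpha = 1,
                            floor = 0.1)
  expect_equal(Hn, H / 0.1)
  expect_true(all(Hn >= 0))
})

test_that("eligibility traces decay, saturate and match the analytic fixed point", {
  cfg <- flex_config()
  el <- eligibility_state(1, 1, "recurrent", cfg)
  # pure decay from x: T_p(t) = x exp(-t/tau_p)
  el$T_p[] <- 2e-3
  el0 <- el
  for (t in 1:900) el <- update_eligibility(el, matrix(0, 1, 1), dt = 1)
  expect_equal(el$T_p[1, 1], 2e-3 * exp(-900 / el$tau_p), tolerance = 1e-3)
  # constant H held long: steady state eta*H*T_max/(1 + eta*H) per trace
  H <- matrix(0.002, 1, 1)
  el <- el0
  for (t in 1:40000) el <- update_eligibility(el, H, dt = 1)
  expect_equal(el$T_p[1, 1],
               eligibility_steady_state(0.002, el$eta_p, el$T_max_p),
               tolerance = 1e-3)
  expect_equal(el$T_d[1, 1],
               eligibility_steady_state(0.002, el$eta_d, el$T_max_d),
               tolerance = 1e-3)
})

test_that("traces never exceed saturation for adversarially large H", {
  cfg <- flex_config()
  for (variant in c("recurrent", "feedforward")) {
    el <- eligibility_state(2, 2, variant, cfg)
    set.seed(5)
    for (t in 1:200) {
      H <- matrix(10^runif(4, -3, 6), 2, 2)
      el <- update_eligibility(el, H, dt = 1)
      expect_true(all(el$T_p >= 0 & el$T_p <= el$T_max_p))
      expect_true(all(el$T_d >= 0 & el$T_d <= el$T_max_d))
    }
  }
})

test_that("saturated LTD trace exceeds LTP during drive, crosses after it ends", {
  # strong sustained Hebbian drive pushes both traces to their ceilings
  # (T_max_d > T_max_p); after the drive stops the LTP trace outlives the
  # LTD trace, so they cross.  Crossing time checked against a numerical
  # ODE oracle on a fine grid.
  cfg <- flex_config()
  el <- eligibility_state(1, 1, "recurrent", cfg)
  H_on <- matrix(1, 1, 1)
  for (t in 1:600) el <- update_eligibility(el, H_on, dt = 1)
  expect_true(el$T_d[1, 1] > el$T_p[1, 1])
  Tp0 <- el$T_p[1, 1]; Td0 <- el$T_d[1, 1]
  # simulated crossing
  cross_sim <- NA
  for (t in 1:600) {
    el <- update_eligibility(el, matrix(0, 1, 1), dt = 1)
    if (is.na(cross_sim) && el$T_p[1, 1] > el$T_d[1, 1]) cross_sim <- t
  }
  # oracle: pure exponential decay from the levels at drive offset
  f <- function(t) Td0 * exp(-t / 800) - Tp0 * exp(-t / 1800)
  cross_oracle <- uniroot(f, c(1, 600))$root
  expect_equal(cross_sim, cross_oracle, tolerance = 0.02)
})

test_that("two-trace update has the published sign structure", {
  W <- matrix(0.5, 2, 2)
  Tp <- matrix(c(2, 1, 2, 1) * 1e-3, 2, 2)
  Td <- matrix(1.5e-3, 2, 2)
  # D = 0: no learning at all
  expect_equal(dttl_weight_update(W, 0, Tp, Td, eta = 1), W)
  # D > 0: potentiation where Tp > Td, depression where Tp < Td
  W2 <- dttl_weight_update(W, 2, Tp, Td, eta = 1)
  expect_true(all(W2[, 1][Tp[, 1] > Td[, 1]] > 0.5))
  expect_true(all(W2[2, ] < 0.5))
  # floor at zero and optional cap
  expect_equal(dttl_weight_update(matrix(1e-6, 1, 1), -10,
                                  matrix(1e-3, 1, 1), matrix(0, 1, 1),
                                  eta = 1),
               matrix(0, 1, 1))
  expect_equal(dttl_weight_update(matrix(1, 1, 1), 10, matrix(1e-3, 1, 1),
                                  matrix(0, 1, 1), eta = 10, w_max = 1.005),
               matrix(1.005, 1, 1))
})

test_that("trial-integrated two-trace update matches quadrature oracle", {
  set.seed(8)
  n_steps <- 500
  D <- pmax(rnorm(n_steps, 0, 2), -3)
  Tp <- abs(sin(seq_len(n_steps) / 80)) * 2e-3
  Td <- abs(cos(seq_len(n_steps) / 95)) * 1.8e-3
  eta <- 0.01
  W <- 5          # large start so the zero floor never binds
  for (t in seq_len(n_steps)) {
    W <- dttl_weight_update(matrix(W, 1, 1), D[t],
                            matrix(Tp[t], 1, 1), matrix(Td[t], 1, 1),
                            eta, dt = 1)[1, 1]
  }
  riemann <- 5 + eta * sum(D * (Tp - Td))
  expect_equal(W, riemann, tolerance = 1e-10)
})

test_that("dopamine-modulated Hebbian rule: sign, floor, permutation symmetry", {
  r_pre <- c(0.5, 0.1); r_post <- c(0.3, 0.2)
  W <- matrix(0.1, 2, 2)
  expect_equal(da_hebbian_update(W, 0, r_pre, r_post, eta = 1), W)
  up <- da_hebbian_update(W, 2, r_pre, r_post, eta = 1)
  expect_true(all(up >= W))
  dn <- da_hebbian_update(W, -2, r_pre, r_post, eta = 1)
  expect_true(all(dn <= W))
  expect_true(all(da_hebbian_update(W, -100, r_pre, r_post, eta = 1) >= 0))
  # permutation of synapses commutes with the update
  perm <- c(2, 1)
  up_perm <- da_hebbian_update(W[perm, perm], 2, r_pre[perm], r_post[perm],
                               eta = 1)
  expect_equal(up_perm, up[perm, perm])
})

test_that("value-variant update equals the two-trace form and guards its flag", {
  W <- matrix(0.2, 1, 1); Tp <- matrix(2e-3, 1, 1); Td <- matrix(1e-3, 1, 1)
  expect_equal(value_variant_update(W, 1.5, Tp, Td, eta = 1),
               dttl_weight_update(W, 1.5, Tp, Td, eta = 1))
  expect_equal(value_variant_update(W, 0, Tp, Td, eta = 1), W)
  expect_error(value_variant_update(W, 1, Tp, Td, eta = 1, enabled = FALSE),
               "disabled")
})

test_that("fixed-point residual matches the brute-force sum and its windows", {
  set.seed(3)
  D <- rnorm(400)
  Tp <- runif(400) * 1e-3
  Td <- runif(400) * 1e-3
  res <- fixed_point_residual(D, Tp, Td, dt = 1, cs_window = c(100, 200),
                              us_window = c(300, 400))
  brute <- sum(D * (Tp - Td))
  expect_equal(res$residual, brute, tolerance = 1e-12)
  expect_equal(res$cs_part + res$us_part,
               sum((D * (Tp - Td))[c(101:200, 301:400)]), tolerance = 1e-12)
  # trivial fixed point at D == 0 and at trace crossing under an impulse
  expect_equal(fixed_point_residual(numeric(10), runif(10),
                                    runif(10))$residual, 0)
  D_imp <- c(rep(0, 9), 1)
  expect_equal(fixed_point_residual(D_imp, rep(0.3, 10),
                                    rep(0.3, 10))$residual, 0)
})
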