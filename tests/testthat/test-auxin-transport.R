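test_that("saturation function has its Michaelis-Menten properties", {
  expect_equal(saturation(0, 2), 0)
  expect_equal(saturation(2, 2), 0.5)
  expect_lt(abs(saturation(1e6 * 3, 3) - 1), 1e-6)
  expect_error(saturation(-1, 1))
  expect_error(saturation(1, 0))
  x <- seq(0, 10, 0.5)
  expect_true(all(diff(saturation(x, 1)) > 0))            # monotone
  expect_true(all(diff(diff(saturation(x, 1))) < 0))      # concave
})

test_that("influx is gated by the cell-count window, inclusive", {
  tp <- transport_params(influx_window = c(50, 100))
  expect_false(influx_active(49, tp))
  expect_true(influx_active(50, tp))
  expect_true(influx_active(75, tp))
  expect_true(influx_active(100, tp))
  expect_false(influx_active(101, tp))
})

test_that("derivatives match a hand-coded term-by-term oracle", {
  ## isolated cell: only production/decay plus PIN relaxation
  tp <- transport_params(p_production = 0, d_decay = 0, f_influx = 0)
  m1 <- init_state(build_initial_tissue(1), tp)
  m1$auxin <- 1.5
  d1 <- transport_derivatives(m1, params = tp)
  expect_equal(d1$dA, 0)
  expect_equal(d1$dP_endo, 0)                             # no walls to cycle to

  ## two equal cells: no net transport, dA = p - d*A for both
  tp2 <- transport_params(p_production = 0.3, d_decay = 0.1, f_influx = 0)
  m2 <- init_state(build_grid_tissue(1, 2), tp2)
  m2$auxin <- c(1.2, 1.2)
  m2$pin_edge[] <- 0.7
  d2 <- transport_derivatives(m2, params = tp2)
  expect_equal(d2$dA, rep(0.3 - 0.1 * 1.2, 2))

  ## random 3x3 fixture vs the oracle, including influx and differentiation
  tp3 <- transport_params(T_active = 2.4, D_passive = 0.6, p_production = 0.05,
                          d_decay = 0.03, A_threshold = 10, k1 = 1.7, k2 = 0.4,
                          K_mm = 0.8, f_influx = 0.9, influx_window = c(5, 20))
  m3 <- random_state_mesh(3, 3, 42, tp3)
  m3$differentiated[c(2, 7)] <- TRUE
  d3 <- transport_derivatives(m3, params = tp3)
  o3 <- oracle_derivs(m3, oracle_state(m3), tp3)
  expect_equal(d3$dA, o3$dA, tolerance = 1e-12)
  expect_equal(d3$dP_endo, o3$dPe, tolerance = 1e-12)
  for (e in seq_along(m3$edge_from))
    expect_equal(d3$dP_edge[e], o3$dP[m3$edge_from[e], m3$edge_to[e]],
                 tolerance = 1e-12)
})

test_that("PIN derivatives conserve each cell's pool; transport is antisymmetric", {
  tp <- transport_params(T_active = 3, D_passive = 1, p_production = 0,
                         d_decay = 0, f_influx = 0)
  m <- random_state_mesh(2, 3, 77, tp)
  d <- transport_derivatives(m, params = tp)
  ## per-cell PIN balance: endosome derivative cancels the wall derivatives
  for (i in seq_along(m$cells)) {
    out <- which(m$edge_from == i)
    expect_equal(d$dP_endo[i] + sum(d$dP_edge[out]), 0, tolerance = 1e-12)
  }
  ## with p = d = influx = 0 the total auxin is in balance (antisymmetry)
  expect_equal(sum(d$dA), 0, tolerance = 1e-12)
})

test_that("the integrator shows fifth-order convergence on exponential decay", {
  tp <- transport_params(T_active = 0, D_passive = 0, p_production = 0,
                         d_decay = 1, f_influx = 0, k1 = 0, k2 = 0)
  m <- init_state(build_initial_tissue(1), tp)
  m$auxin <- 2
  run_fixed <- function(h) {
    st <- list(A = m$auxin, P_endo = m$pin_endo, P_edge = m$pin_edge)
    for (k in seq_len(round(3 / h)))
      st <- rk5_step(m, st, tp, h)$state
    st$A
  }
  exact <- 2 * exp(-3)
  e1 <- abs(run_fixed(0.3) - exact)
  e2 <- abs(run_fixed(0.15) - exact)
  expect_gt(e1 / e2, 20)                                  # ~32 for order 5
  expect_lt(e1 / e2, 48)
})

test_that("zero-rate parameters leave the state untouched", {
  tp <- transport_params(T_active = 0, D_passive = 0, p_production = 0,
                         d_decay = 0, f_influx = 0, k1 = 0, k2 = 0)
  m <- random_state_mesh(2, 2, 5, tp)
  out <- integrate_transport(m, tp, dt = 2)
  expect_equal(out$auxin, m$auxin)
  expect_equal(out$pin_endo, m$pin_endo)
  expect_equal(out$pin_edge, m$pin_edge)
})

test_that("PIN totals and closed-system auxin mass survive integration", {
  tp <- transport_params(T_active = 2, D_passive = 0.5, p_production = 0,
                         d_decay = 0, f_influx = 0)
  m <- random_state_mesh(3, 3, 9, tp)
  pin0 <- vapply(seq_along(m$cells), function(i) cell_pin_total(m, i), numeric(1))
  mass0 <- sum(m$auxin)
  out <- m
  for (k in 1:20) out <- integrate_transport(out, tp, dt = 0.5)
  pin1 <- vapply(seq_along(out$cells), function(i) cell_pin_total(out, i), numeric(1))
  expect_equal(pin1, pin0, tolerance = 1e-10)
  expect_equal(sum(out$auxin), mass0, tolerance = 1e-8)
  expect_true(all(out$auxin >= -1e-12))
})

test_that("carrier-driven transport amplifies a two-cell difference; diffusion decays it", {
  ## pre-polarized PIN toward the richer cell, as left by an earlier gradient
  tp_on <- transport_params(T_active = 5, D_passive = 0.05, p_production = 0,
                            d_decay = 0, f_influx = 0, k1 = 1, k2 = 0.1)
  m <- init_state(build_grid_tissue(1, 2), tp_on)
  m$auxin <- c(2, 1)
  P <- matrix(0, 2, 2); P[2, 1] <- 1.5; P[1, 2] <- 0.1
  m <- set_pin_state(m, Pe = c(0.4, 0.4), P = P)

  d0 <- transport_derivatives(m, params = tp_on)
  expect_gt(d0$dA[1] - d0$dA[2], 0)                       # difference grows at t0

  out <- integrate_transport(m, tp_on, dt = 0.5)
  expect_gt(out$auxin[1] - out$auxin[2], 1)
  ## cross-check the trajectory against the independent RK4 reference
  ref <- oracle_integrate_rk4(m, tp_on, t_total = 0.5, h = 1e-3)
  expect_equal(out$auxin, ref$A, tolerance = 1e-7)

  ## with no active transport the difference decays monotonically to zero
  tp_off <- transport_params(T_active = 0, D_passive = 0.5, p_production = 0,
                             d_decay = 0, f_influx = 0, k1 = 0, k2 = 0)
  m2 <- m
  diffs <- numeric(12)
  for (k in 1:12) {
    m2 <- integrate_transport(m2, tp_off, dt = 0.5)
    diffs[k] <- m2$auxin[1] - m2$auxin[2]
  }
  expect_true(all(diff(c(1, diffs)) < 0))
  expect_lt(diffs[12], 0.1)
  ref2 <- oracle_integrate_rk4(m, tp_off, t_total = 6, h = 1e-3)
  expect_equal(m2$auxin, ref2$A, tolerance = 1e-7)
})

test_that("package integration matches the independent reference to 6 digits", {
  tp <- transport_params(T_active = 1.5, D_passive = 0.4, p_production = 0.02,
                         d_decay = 0.05, f_influx = 0.3, influx_window = c(5, 20),
                         k1 = 1.2, k2 = 0.5)
  m <- random_state_mesh(2, 5, 123, tp)                   # 10-cell fixture
  out <- m
  for (k in 1:100) out <- integrate_transport(out, tp, dt = 0.02, atol = 1e-10)
  ref <- oracle_integrate_rk4(m, tp, t_total = 2, h = 5e-4)
  expect_equal(out$auxin, ref$A, tolerance = 1e-7)
  expect_equal(out$pin_endo, ref$Pe, tolerance = 1e-7)
})

test_that("differentiation is a strict, monotone threshold switch", {
  tp <- transport_params(A_threshold = 2)
  m <- init_state(build_grid_tissue(1, 3), tp)
  m$auxin <- c(2, 2.2, 0.5)
  m <- update_differentiation(m, tp, t = 7)
  expect_equal(m$differentiated, c(FALSE, TRUE, FALSE))   # strict inequality
  expect_equal(m$diff_time, c(NA, 7, NA))
  ## auxin collapse does not revert the flag
  m$auxin <- c(0, 0, 0)
  m <- update_differentiation(m, tp, t = 9)
  expect_equal(m$differentiated, c(FALSE, TRUE, FALSE))
  expect_equal(m$diff_time[2], 7)
})

test_that("peak spacing on a ring does not grow with the active:passive ratio", {
  count_peaks <- function(T_act, seed) {
    set.seed(seed)
    n <- 40
    r <- build_ring_tissue(n)
    tp <- transport_params(T_active = T_act, D_passive = 0.5, p_production = 0,
                           d_decay = 0, f_influx = 0, A_threshold = 1e6)
    r <- init_state(r, tp)
    r$auxin <- runif(n, 0.5, 1.5)
    for (i in 1:30) r <- integrate_transport(r, tp, dt = 5)
    A <- r$auxin; nb <- cell_neighbors(r)
    max(1L, sum(vapply(seq_len(n), function(i)
      A[i] > max(A[nb[[i]]]) && A[i] > mean(A), logical(1))))
  }
  ratios <- c(1, 3, 9)
  mean_spacing <- vapply(ratios, function(T_act)
    mean(vapply(1:10, function(s) 40 / count_peaks(T_act, s), numeric(1))),
    numeric(1))
  expect_true(all(diff(mean_spacing) <= 1e-9))
})
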