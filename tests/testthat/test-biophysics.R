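test_that("steady-state gates follow the logistic forms", {
  p <- global_params()
  # midpoints
  expect_equal(steady_state_gates(-34, p)$m_inf, 0.5)
  expect_equal(steady_state_gates(-48, p)$h_inf, 0.5)
  expect_equal(steady_state_gates(-29, p)$n_inf, 0.5)
  expect_equal(steady_state_gates(-40, p)$m_NaP_inf, 0.5)
  # five slopes below the activation midpoint (sigma_m = -5)
  expect_equal(steady_state_gates(-59, p)$m_inf, 1 / (1 + exp(5)),
               tolerance = 1e-12)
  # all in (0, 1), monotone in the expected direction
  V <- seq(-100, 20, by = 1)
  ss <- steady_state_gates(V, p)
  for (g in ss) expect_true(all(g > 0 & g < 1))
  expect_true(all(diff(ss$m_inf) > 0))   # activation increases with V
  expect_true(all(diff(ss$h_inf) < 0))   # inactivation decreases with V
  expect_error(steady_state_gates(NA_real_), "finite")
})

test_that("gate time constants peak at the half-(in)activation voltages", {
  p <- global_params()
  expect_equal(gate_time_constants(-29, p)$tau_n, 10)
  expect_equal(gate_time_constants(-48, p)$tau_h, 10000)
  # E_n + 2*sigma_n puts the cosh argument at 1
  expect_equal(gate_time_constants(-29 + 2 * (-4), p)$tau_n, 10 / cosh(1),
               tolerance = 1e-12)
  V <- seq(-100, 20, by = 0.5)
  tc <- gate_time_constants(V, p)
  expect_true(all(tc$tau_n > 0 & tc$tau_n <= 10))
  expect_true(all(tc$tau_h > 0 & tc$tau_h <= 10000))
  expect_equal(V[which.max(tc$tau_n)], -29)
  expect_equal(V[which.max(tc$tau_h)], -48)
})

test_that("membrane currents obey the printed forms and sign conventions", {
  p <- global_params()
  # zero driving force for sodium currents at E_Na
  I <- membrane_currents(V = 50, n = 0.3, h = 0.5, g_leak = 1, g_NaP = 0.8,
                         D_op = 1, params = p)
  expect_equal(unname(I["I_Na"]), 0)
  expect_equal(unname(I["I_NaP"]), 0)
  # leak vanishes at its reversal
  I <- membrane_currents(V = -58, n = 0, h = 1, g_leak = 1.2, g_NaP = 0,
                         D_op = 0, params = p)
  expect_equal(unname(I["I_leak"]), 0)
  # MOR- neurons never receive the hyperpolarizing current
  I <- membrane_currents(V = -50, n = 0, h = 1, g_leak = 1, g_NaP = 0.8,
                         D_op = 0, mod = modulation_state(I_hyp_op = 8))
  expect_equal(unname(I["I_hyp"]), 0)
  I <- membrane_currents(V = -50, n = 0, h = 1, g_leak = 1, g_NaP = 0.8,
                         D_op = 1, mod = modulation_state(I_hyp_op = 8))
  expect_equal(unname(I["I_hyp"]), 8)
  # hand-computed values at a generic state
  V <- -50; n <- 0.1; h <- 0.7
  ss <- steady_state_gates(V, p)
  I <- membrane_currents(V, n, h, g_leak = 1.1, g_NaP = 0.9, D_op = 1,
                         mod = modulation_state(D_NaP = 1.3, D_leak = 0.5),
                         g_exc = 0.2, g_inh = 0.3, g_op = 0.4, params = p)
  expect_equal(unname(I["I_Na"]), 28 * ss$m_inf^3 * 0.9 * (-100))
  expect_equal(unname(I["I_NaP"]), 0.9 * 1.3 * ss$m_NaP_inf * 0.7 * (-100))
  expect_equal(unname(I["I_leak"]), 1.1 * 0.5 * (-50 + 58))
  expect_equal(unname(I["I_K"]), 11.2 * 0.1^4 * (-50 + 85))
  expect_equal(unname(I["I_syn_exc"]), 0.2 * (-50))
  expect_equal(unname(I["I_syn_inh"]), 0.3 * (-50 + 70))
  expect_equal(unname(I["I_syn_op"]), 0.4 * (-50))
  expect_error(membrane_currents(V, n, h, g_leak = -1, g_NaP = 0.8, D_op = 0),
               "nonnegative")
})

test_that("derivatives vanish at a constructed fixed point and scale with 1/C_m", {
  p <- global_params()
  # edgeless neuron: put gates at steady state, then find a V where the
  # current sum crosses zero and verify all derivatives vanish there
  net <- tiny_network(1.2, 0.8, TRUE, 0L)
  f <- function(V) {
    ss <- steady_state_gates(V, p)
    st <- list(V = V, n = ss$n_inf, h = ss$h_inf, s = numeric(0))
    derivatives(st, net, params = p)$dV
  }
  Vstar <- uniroot(f, c(-60, -45), tol = 1e-12)$root
  ss <- steady_state_gates(Vstar, p)
  d <- derivatives(list(V = Vstar, n = ss$n_inf, h = ss$h_inf,
                        s = numeric(0)), net, params = p)
  expect_equal(d$dV, 0, tolerance = 1e-9)
  expect_equal(d$dn, 0, tolerance = 1e-12)
  expect_equal(d$dh, 0, tolerance = 1e-12)
  # doubling C_m halves dV/dt, all else fixed
  st <- list(V = -50, n = 0.05, h = 0.6, s = numeric(0))
  d1 <- derivatives(st, net, params = p)
  d2 <- derivatives(st, net, params = global_params(C_m = 42))
  expect_equal(d2$dV, d1$dV / 2, tolerance = 1e-12)
  expect_equal(d2$dn, d1$dn)
})

test_that("synapse gate dynamics follow the first-order kinetics", {
  p <- global_params()
  # edge whose presynaptic neuron sits exactly at E_s = 0 mV: m_syn = 1/2,
  # so from s = 0, ds/dt = (1 * 0.5 - 0) / 15 = 1/30 per ms
  net <- tiny_network(c(1, 1), c(0.8, 0.8), c(TRUE, TRUE), c(0L, 0L),
                      edges = data.frame(pre = 1L, post = 2L))
  st <- list(V = c(0, -60), n = c(0.1, 0.1), h = c(0.9, 0.9), s = 0)
  d <- derivatives(st, net, params = p)
  expect_equal(d$ds, 1 / 30, tolerance = 1e-12)
  # routing: presynaptic class determines which conductance the synapse feeds
  net2 <- tiny_network(rep(1, 4), rep(0.8, 4),
                       is_exc = c(TRUE, TRUE, FALSE, TRUE),
                       d_op = c(0L, 1L, 0L, 0L),
                       edges = data.frame(pre = c(1L, 2L, 3L), post = 4L),
                       g_syn_max = 1)
  st2 <- list(V = c(-60, -60, -60, -50), n = rep(0.1, 4), h = rep(0.9, 4),
              s = c(0.5, 0.5, 0.5))
  mod <- modulation_state(g_syn_op = 0.25)
  d_on <- derivatives(st2, net2, mod = mod, params = p)
  # reconstruct the three synaptic currents from the voltage derivative
  # difference against a blocked run
  d_off <- derivatives(st2, net2, mod = mod, params = p,
                       synaptic_block = TRUE)
  I_syn <- -(d_on$dV[4] - d_off$dV[4]) * p$C_m
  g_exc <- 0.5; g_op <- 0.5 * 0.25; g_inh <- 0.5
  expect_equal(I_syn, g_exc * (-50) + g_op * (-50) + g_inh * (-50 + 70),
               tolerance = 1e-12)
  expect_error(derivatives(list(V = 1, n = 1, h = 1, s = numeric(0)), net2),
               "dimensions")
})

test_that("compiled integrator agrees with an adaptive ODE solve of the R right-hand side", {
  p <- global_params()
  # quiescent neuron: both routes settle on the same resting potential
  net <- tiny_network(1.2, 0.8, TRUE, 0L)
  rhs <- function(t, y, parms) {
    st <- list(V = y[1], n = y[2], h = y[3], s = numeric(0))
    d <- derivatives(st, net, params = p, synaptic_block = TRUE)
    list(c(d$dV, d$dn, d$dh) * 1000)   # time in seconds
  }
  ss <- steady_state_gates(-60, p)
  y0 <- c(-60, ss$n_inf, ss$h_inf)
  out <- deSolve::lsoda(y0, seq(0, 40, by = 0.05), rhs, NULL,
                        rtol = 1e-8, atol = 1e-8)
  st0 <- list(V = -60, n = ss$n_inf, h = ss$h_inf, s = numeric(0))
  sim <- integrate_network(net, constant_schedule(duration = 40,
                                                  transient_s = 0),
                           dt = 0.05, init_state = st0, params = p)
  last <- out[nrow(out), ]
  expect_equal(sim$final_state$V, unname(last[2]), tolerance = 1e-3)
  expect_equal(sim$final_state$h, unname(last[4]), tolerance = 1e-3)
})
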