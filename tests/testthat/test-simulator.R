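test_that("spike detection finds threshold crossings with refractory lockout", {
  expect_length(detect_spikes(rep(-60, 1000), dt = 0.1), 0)
  # sawtooth crossing -20 mV ten times in 1 s
  saw <- rep(c(rep(-60, 90), seq(-60, 10, length.out = 10)), 10)
  expect_length(detect_spikes(saw, dt = 1), 10)
  # two crossings 1 ms apart: the second falls in the lockout
  v <- rep(-60, 20); v[5] <- 0; v[7] <- 0
  expect_length(detect_spikes(v, dt = 0.5), 1)
  expect_length(detect_spikes(v, dt = 2), 2)
})

test_that("ramp schedule is the 0.5%-per-3-s staircase over 10 minutes", {
  sch <- make_ramp_schedule()
  expect_equal(attr(sch, "duration"), 600)
  expect_equal(schedule_value(sch, 0, "I_hyp_op"), 0)
  expect_equal(schedule_value(sch, 0, "g_syn_op"), 1)
  expect_equal(schedule_value(sch, 300, "I_hyp_op"), 4)
  expect_equal(schedule_value(sch, 300, "g_syn_op"), 0.5)
  expect_equal(schedule_value(sch, 600, "I_hyp_op"), 8)
  expect_equal(schedule_value(sch, 600, "g_syn_op"), 0)
  # staircase: I_hyp_op(t) = 8 * 0.005 * floor(t / 3)
  tt <- c(1, 2.99, 3, 44, 599)
  expect_equal(schedule_value(sch, tt, "I_hyp_op"), 8 * 0.005 * floor(tt / 3))
  expect_error(schedule_value(sch, 601), "duration")
})

test_that("perturbation schedule implements the 200-s segment sequence", {
  sch <- make_perturbation_schedule("gnap", factor = 1.3)
  expect_equal(attr(sch, "duration"), 200)
  expect_equal(nrow(sch), 10)
  w <- schedule_windows(sch)
  expect_equal(w$segment, c("control", "opioid", "wash", "drug", "opioid_drug"))
  expect_equal(w$start, c(10, 50, 90, 130, 170))
  expect_equal(w$end - w$start, rep(30, 5))
  # opioid level in opioid segments
  expect_equal(schedule_value(sch, 60, "I_hyp_op"), 4)
  expect_equal(schedule_value(sch, 60, "g_syn_op"), 0.5)
  expect_equal(schedule_value(sch, 100, "I_hyp_op"), 0)
  # drug factor applies in segments 8 (drug) and 10 (opioid+drug) only
  expect_equal(schedule_value(sch, c(20, 60, 100, 140, 180), "D_NaP"),
               c(1, 1, 1, 1.3, 1.3))
  sch2 <- make_perturbation_schedule("gleak", factor = 0.5)
  expect_equal(schedule_value(sch2, c(20, 60, 100, 140, 180), "D_leak"),
               c(1, 1, 1, 0.5, 0.5))
  expect_equal(schedule_value(sch2, 180, "D_NaP"), 1)
  expect_error(make_perturbation_schedule("caffeine"))
})

test_that("silent-region neurons stay quiescent and rasters are deterministic", {
  # zero-edge network placed in the silent region, started near rest with
  # gates at steady state (a strongly hyperpolarized start with high h can
  # produce a genuine initial burst even in the silent region)
  net <- tiny_network(rep(1.2, 12), rep(0.8, 12), rep(TRUE, 12), rep(0L, 12))
  sch <- constant_schedule(duration = 30, transient_s = 0)
  V0 <- seq(-53, -52, length.out = 12)
  ss0 <- steady_state_gates(V0)
  st0 <- list(V = V0, n = ss0$n_inf, h = ss0$h_inf, s = numeric(0))
  sim <- integrate_network(net, sch, dt = 0.05, init_state = st0)
  expect_equal(nrow(sim$spikes), 0)
  # the dt/10 high-order oracle confirms quiescence from the same start
  ref <- integrate_neuron_reference(1.2, 0.8, V0 = -53, dt = 0.005,
                                    duration = 30)
  expect_length(ref$spike_times, 0)
  # byte-identical reproducibility on a coupled network
  net2 <- build_network(N = 60, d_avg = 6, frac_inhibitory = 0.2, seed = 4)
  sch2 <- constant_schedule(duration = 5, transient_s = 0)
  a <- integrate_network(net2, sch2, dt = 0.05, init_seed = 8)
  b <- integrate_network(net2, sch2, dt = 0.05, init_seed = 8)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$final_state, b$final_state)
  c2 <- integrate_network(net2, sch2, dt = 0.05, init_seed = 9)
  expect_false(identical(a$spikes, c2$spikes))
})

test_that("spike counts converge between dt and dt/2 on isolated neurons", {
  # one tonic and one bursting neuron, no synapses
  net <- tiny_network(c(0.5, 1.05), c(0.8, 0.9), c(TRUE, TRUE), c(0L, 0L))
  sch <- constant_schedule(duration = 30, transient_s = 0)
  st <- initial_state(net, init_seed = 2)
  a <- integrate_network(net, sch, dt = 0.05, init_state = st)
  b <- integrate_network(net, sch, dt = 0.025, init_state = st)
  na <- tabulate(a$spikes$neuron, 2)
  nb <- tabulate(b$spikes$neuron, 2)
  expect_true(all(abs(na - nb) <= pmax(0.02 * nb, 1)))
})

test_that("synaptic block decouples neurons exactly", {
  net <- build_network(N = 30, d_avg = 8, frac_inhibitory = 0.2, seed = 6)
  sch <- constant_schedule(duration = 10, synaptic_block = TRUE,
                           transient_s = 0)
  st <- initial_state(net, init_seed = 3)
  full <- integrate_network(net, sch, dt = 0.05, init_state = st)
  # each neuron alone reproduces its spike train exactly
  for (i in c(1, 7, 19)) {
    ni <- tiny_network(net$neurons$g_leak[i], net$neurons$g_NaP[i],
                       net$neurons$is_excitatory[i], net$neurons$D_op[i])
    sti <- list(V = st$V[i], n = st$n[i], h = st$h[i], s = numeric(0))
    one <- integrate_network(ni, sch, dt = 0.05, init_state = sti)
    expect_identical(one$spikes$time,
                     full$spikes$time[full$spikes$neuron == i])
  }
})

test_that("with only a leak current V relaxes exponentially to E_leak", {
  p <- global_params(g_Na = 0, g_K = 0)
  net <- tiny_network(1.25, 0, TRUE, 0L)
  sch <- constant_schedule(duration = 0.2, transient_s = 0)
  st <- list(V = -90, n = 0.2, h = 0.8, s = numeric(0))
  sim <- integrate_network(net, sch, dt = 0.05, init_state = st, params = p,
                           record_v = 1, record_stride_ms = 0.05)
  tau <- p$C_m / 1.25  # ms
  expected <- -58 + (-90 + 58) * exp(-sim$v_times * 1000 / tau)
  expect_lt(max(abs(sim$v[, 1] - expected) / abs(expected)), 1e-6)
})

test_that("time-averaged V of an isolated MOR+ neuron falls with I_hyp_op", {
  vbar <- vapply(c(0, 2, 4, 8), function(I) {
    sim <- simulate_single_neuron(1.2, 0.8, modulation_state(I_hyp_op = I),
                                  duration = 20, record_v = TRUE)
    mean(sim$v[sim$v_times > 10, 1])
  }, numeric(1))
  expect_true(all(diff(vbar) < 0))
})

test_that("production integrator matches the RK4 dt/10 oracle on a burster", {
  # bursting neuron; spike-time discrepancy < 1 ms over 30 s
  gl <- 1.05; gn <- 0.9
  sim <- simulate_single_neuron(gl, gn, duration = 30, dt = 0.005)
  ref <- integrate_neuron_reference(gl, gn, V0 = -60, dt = 0.0005,
                                    duration = 30)
  expect_gt(length(ref$spike_times), 20)
  expect_equal(nrow(sim$spikes), length(ref$spike_times))
  expect_lt(max(abs(sim$spikes$time - ref$spike_times)), 0.001)
  # and burst-level agreement already at the default step
  sim2 <- simulate_single_neuron(gl, gn, duration = 30, dt = 0.05)
  expect_equal(nrow(sim2$spikes), length(ref$spike_times))
})

test_that("numerical blow-up is reported as an integration failure", {
  # a MOR+ neuron with vanishing conductances and a sustained applied
  # current has no bounded equilibrium: V runs off past -200 mV
  p <- global_params(g_K = 0, g_Na = 0)
  netbad <- tiny_network(1e-6, 0, TRUE, 1L)
  sch <- constant_schedule(modulation_state(I_hyp_op = 8), duration = 2,
                           transient_s = 0)
  st <- list(V = -60, n = 0.1, h = 0.5, s = numeric(0))
  expect_error(
    integrate_network(netbad, sch, dt = 0.1, init_state = st, params = p),
    "integration failure")
})

test_that("simulation results serialize to plain text", {
  net <- build_network(N = 20, d_avg = 4, frac_inhibitory = 0.2, seed = 3)
  sim <- integrate_network(net, constant_schedule(duration = 2,
                                                  transient_s = 0),
                           dt = 0.1, record_v = c(1, 2))
  stem <- file.path(tempdir(), "sim_rt")
  write_simulation(sim, stem)
  raster <- read.table(paste0(stem, "_raster.txt"), header = TRUE)
  expect_equal(nrow(raster), nrow(sim$spikes))
  sched <- read.csv(paste0(stem, "_schedule.csv"))
  expect_equal(nrow(sched), nrow(sim$schedule_samples))
  v <- read.csv(paste0(stem, "_v.csv"))
  expect_equal(dim(v), c(length(sim$v_times), 3))
})
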