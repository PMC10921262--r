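#' Initial network state
#'
#' Desynchronized start: each membrane potential is drawn uniformly from
#' `[-65, -55]` mV (from the init seed); the gates start at their
#' steady-state values for that voltage, `n = n_inf(V0)`, `h = h_inf(V0)`,
#' and all synaptic gates at 0, which avoids startup artifacts.
#'
#' @param network a `prebotc_network`.
#' @param init_seed integer seed (defaults to the network's derived init
#'   seed).
#' @param params shared parameters.
#' @param v_range range of the uniform initial-voltage draw (mV).
#' @return list with `V`, `n`, `h` (length N) and `s` (length = edge count).
#' @export
initial_state <- function(network, init_seed = network$seeds$init,
                          params = global_params(), v_range = c(-65, -55)) {
  if (is.null(init_seed)) init_seed <- 1L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(init_seed))
  V <- runif(network$N, v_range[1], v_range[2])
  ss <- steady_state_gates(V, params)
  list(V = V, n = ss$n_inf, h = ss$h_inf, s = numeric(nrow(network$edges)))
}

#' Integrate a network under a modulation schedule
#'
#' Advances the full network state with the fixed-step exponential-Euler
#' scheme (default dt = 0.05 ms, configurable up to 0.1 ms), applying the
#' schedule's piecewise-constant modulation. While the schedule's
#' `synaptic_block` flag is on, all synaptic conductances are forced to zero
#' (and the synapse gates are frozen), so every neuron expresses its
#' intrinsic activity. Spikes are detected online as upward crossings of the
#' spike threshold with a refractory lockout. The result is a deterministic
#' function of (network, schedule, dt, init seed).
#'
#' @param network a `prebotc_network`.
#' @param schedule a `prebotc_schedule`.
#' @param dt integration step (ms), at most 0.1 ms.
#' @param init_seed seed for the initial state (defaults to the network's
#'   derived init seed); alternatively supply `init_state` directly.
#' @param init_state optional explicit state list (`V`, `n`, `h`, `s`)
#'   overriding the seeded draw.
#' @param params shared parameters.
#' @param record_v integer vector of neuron ids whose voltage traces are
#'   kept (empty = none).
#' @param record_stride_ms voltage-trace sampling interval (ms).
#' @param spike_threshold spike detection threshold (mV).
#' @param lockout_ms refractory lockout for spike detection (ms).
#' @param sample_interval_s sampling interval (s) of the stored schedule
#'   trace.
#' @return A `prebotc_sim` object: list with `spikes` (data.frame `neuron`,
#'   `time` in s, ordered by time), `schedule_samples` (data.frame of the
#'   modulation values on a regular grid), `final_state`, `gate_range`,
#'   `dt`, `duration`, `seeds`, and optionally `v` (matrix, one column per
#'   recorded neuron) with `v_times` (s).
#' @examples
#' net <- build_network(N = 5, d_avg = 2, frac_inhibitory = 0.2, seed = 1)
#' sim <- integrate_network(net, constant_schedule(duration = 1), dt = 0.1)
#' @export
integrate_network <- function(network, schedule, dt = 0.05,
                              init_seed = network$seeds$init,
                              init_state = NULL,
                              params = global_params(),
                              record_v = integer(0), record_stride_ms = 1,
                              spike_threshold = -20, lockout_ms = 2,
                              sample_interval_s = 0.01) {
  stopifnot(inherits(network, "prebotc_network"),
            inherits(schedule, "prebotc_schedule"))
  if (dt <= 0 || dt > 0.1) stop("dt must be in (0, 0.1] ms")
  duration_s <- attr(schedule, "duration")
  st <- if (is.null(init_state))
    initial_state(network, init_seed, params) else init_state
  edges <- network$edges
  cls <- if (nrow(edges)) edge_class(network) else integer(0)

  res <- .integrate_cpp(
    params = unclass(params),
    g_leak = network$neurons$g_leak, g_NaP = network$neurons$g_NaP,
    d_op = as.integer(network$neurons$D_op),
    edge_pre = as.integer(edges$pre) - 1L,
    edge_post = as.integer(edges$post) - 1L,
    edge_g = as.numeric(edges$g_syn_max),
    edge_cls = as.integer(cls),
    g_syn_op_control = attr(schedule, "g_syn_op_control") %||% 1,
    sch_t_ms = schedule$time * 1000, sch_DNaP = schedule$D_NaP,
    sch_Dleak = schedule$D_leak, sch_gop = schedule$g_syn_op,
    sch_Ihyp = schedule$I_hyp_op, sch_block = schedule$synaptic_block,
    dt = dt, duration_ms = duration_s * 1000,
    V0 = st$V, n0 = st$n, h0 = st$h, s0 = st$s,
    spike_threshold = spike_threshold, lockout_ms = lockout_ms,
    record_idx = as.integer(record_v) - 1L,
    record_stride = max(1L, as.integer(round(record_stride_ms / dt)))
  )

  ts <- seq(0, duration_s, by = sample_interval_s)
  samples <- data.frame(
    time = ts,
    I_hyp_op = schedule_value(schedule, ts, "I_hyp_op"),
    g_syn_op = schedule_value(schedule, ts, "g_syn_op"),
    D_NaP = schedule_value(schedule, ts, "D_NaP"),
    D_leak = schedule_value(schedule, ts, "D_leak"),
    synaptic_block = schedule_value(schedule, ts, "synaptic_block")
  )
  out <- list(
    spikes = data.frame(neuron = res$spike_neuron,
                        time = res$spike_t_ms / 1000),
    schedule_samples = samples,
    final_state = list(V = res$V, n = res$n, h = res$h, s = res$s),
    gate_range = c(res$gate_min, res$gate_max),
    dt = dt, duration = duration_s, N = network$N,
    seeds = c(network$seeds,
              list(init_used = if (is.null(init_state)) init_seed else NA))
  )
  if (length(record_v)) {
    out$v <- res$v_trace
    colnames(out$v) <- paste0("n", record_v)
    out$v_times <- res$v_times_ms / 1000
  }
  class(out) <- "prebotc_sim"
  out
}

#' @export
print.prebotc_sim <- function(x, ...) {
  cat(sprintf("preBotC simulation: %.4g s, N = %d, dt = %g ms, %d spikes\n",
              x$duration, x$N, x$dt, nrow(x$spikes)))
  invisible(x)
}

#' Write simulation results as plain text
#'
#' Writes the spike raster as two-column whitespace-separated text (neuron
#' id, time in s), the sampled modulation schedule as CSV, and any recorded
#' voltage traces as CSV (`time` plus one column per recorded neuron).
#'
#' @param sim a `prebotc_sim` from [integrate_network()].
#' @param stem file path stem; writes `<stem>_raster.txt`,
#'   `<stem>_schedule.csv` and (if voltages were recorded) `<stem>_v.csv`.
#' @return The stem, invisibly.
#' @export
write_simulation <- function(sim, stem) {
  stopifnot(inherits(sim, "prebotc_sim"))
  write.table(sim$spikes, paste0(stem, "_raster.txt"), row.names = FALSE,
              col.names = c("neuron", "time_s"), quote = FALSE)
  write.csv(sim$schedule_samples, paste0(stem, "_schedule.csv"),
            row.names = FALSE)
  if (!is.null(sim$v))
    write.csv(cbind(time = sim$v_times, as.data.frame(sim$v)),
              paste0(stem, "_v.csv"), row.names = FALSE)
  invisible(stem)
}

#' Detect spikes in a voltage trace
#'
#' A spike is an upward crossing of the threshold (previous sample below,
#' current sample at or above) with a refractory lockout suppressing
#' crossings closer than `lockout_ms` to the previous spike. Action
#' potentials in this model overshoot -20 mV by a wide margin, so the
#' default threshold is insensitive over roughly \[-30, -10\] mV.
#'
#' @param v numeric voltage trace (mV), contiguous samples.
#' @param dt sampling interval (ms).
#' @param threshold spike threshold (mV).
#' @param lockout_ms refractory lockout (ms).
#' @return Numeric vector of spike times in seconds (time of the sample
#'   before the crossing, matching the online detector).
#' @examples
#' detect_spikes(rep(-60, 100), dt = 1)  # no spikes
#' @export
detect_spikes <- function(v, dt, threshold = -20, lockout_ms = 2) {
  n <- length(v)
  if (n < 2) return(numeric(0))
  cross <- which(v[-n] < threshold & v[-1] >= threshold)
  times <- (cross - 1) * dt
  keep <- numeric(0)
  last <- -Inf
  for (t in times) {
    if (t - last >= lockout_ms) {
      keep <- c(keep, t)
      last <- t
    }
  }
  keep / 1000
}

#' Single-neuron reference integration (RK4 oracle)
#'
#' Integrates one isolated neuron with a classic fourth-order Runge-Kutta
#' scheme and direct (untabulated) evaluation of every gating function. This
#' is an independent high-order reference used to validate the production
#' exponential-Euler integrator; it is not used by any analysis path.
#'
#' @param g_leak,g_NaP neuron conductances (nS).
#' @param mod a [modulation_state()] (synaptic values ignored; no synapses).
#' @param D_op 1 if the neuron receives `I_hyp_op`.
#' @param V0,n0,h0 initial state; gates default to their steady states.
#' @param dt step (ms); use a small value (e.g. dt/10 of production).
#' @param duration duration (s).
#' @param params shared parameters.
#' @param spike_threshold,lockout_ms spike detection settings.
#' @return list with `spike_times` (s) and the final `V`, `n`, `h`.
#' @export
integrate_neuron_reference <- function(g_leak, g_NaP,
                                       mod = modulation_state(), D_op = 1,
                                       V0 = -60, n0 = NULL, h0 = NULL,
                                       dt = 0.005, duration = 30,
                                       params = global_params(),
                                       spike_threshold = -20,
                                       lockout_ms = 2) {
  ss <- steady_state_gates(V0, params)
  if (is.null(n0)) n0 <- ss$n_inf
  if (is.null(h0)) h0 <- ss$h_inf
  res <- .integrate_neuron_rk4_cpp(
    unclass(params), g_leak, g_NaP, as.integer(D_op),
    mod$D_NaP, mod$D_leak, mod$I_hyp_op,
    V0, n0, h0, dt, duration * 1000, spike_threshold, lockout_ms)
  list(spike_times = res$spike_t_ms / 1000, V = res$V, n = res$n, h = res$h)
}

#' Run one isolated neuron through the production integrator
#'
#' Convenience wrapper building a one-neuron, zero-edge network with the
#' given conductances and MOR status and integrating it under a constant
#' modulation state with synapses blocked.
#'
#' @inheritParams integrate_neuron_reference
#' @param dt production step (ms).
#' @param record_v if `TRUE`, keep the voltage trace.
#' @return A `prebotc_sim`.
#' @export
simulate_single_neuron <- function(g_leak, g_NaP, mod = modulation_state(),
                                   D_op = 1, V0 = -60, dt = 0.05,
                                   duration = 30, params = global_params(),
                                   record_v = FALSE) {
  net <- single_neuron_network(g_leak, g_NaP, D_op)
  sch <- constant_schedule(mod, duration = duration, synaptic_block = TRUE,
                           transient_s = 0)
  ss <- steady_state_gates(V0, params)
  st <- list(V = V0, n = ss$n_inf, h = ss$h_inf, s = numeric(0))
  integrate_network(net, sch, dt = dt, init_state = st, params = params,
                    record_v = if (record_v) 1L else integer(0))
}

single_neuron_network <- function(g_leak, g_NaP, D_op = 1) {
  structure(list(
    N = 1L,
    neurons = data.frame(g_leak = g_leak, g_NaP = g_NaP,
                         is_excitatory = TRUE, D_op = as.integer(D_op)),
    edges = data.frame(pre = integer(0), post = integer(0),
                       g_syn_max = numeric(0), is_op_modulated = logical(0)),
    g_syn_op_control = 1, d_avg = 0, mor_policy = "random",
    seeds = list(init = 1L)
  ), class = "prebotc_network")
}
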