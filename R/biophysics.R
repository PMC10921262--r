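#' Voltage-dependent steady-state gating values
#'
#' Evaluates the logistic steady states of the fast-sodium activation gate
#' (`m_inf`), the persistent-sodium activation gate (`m_NaP_inf`), the
#' delayed-rectifier activation gate (`n_inf`) and the persistent-sodium
#' inactivation gate (`h_inf`): each is
#' `1 / (1 + exp((V - E_x) / sigma_x))` with its own half-(in)activation
#' voltage and slope. Vectorized over `V`.
#'
#' @param V membrane potential (mV), finite, any length.
#' @param params shared parameters from [global_params()].
#' @return A list with numeric components `m_inf`, `m_NaP_inf`, `n_inf`,
#'   `h_inf`, each in (0, 1).
#' @examples
#' steady_state_gates(-34)$m_inf  # 0.5 at the activation midpoint
#' @export
steady_state_gates <- function(V, params = global_params()) {
  if (!all(is.finite(V))) stop("V must be finite")
  lg <- function(E, sigma) 1 / (1 + exp((V - E) / sigma))
  list(
    m_inf = lg(params$E_m, params$sigma_m),
    m_NaP_inf = lg(params$E_m_NaP, params$sigma_m_NaP),
    n_inf = lg(params$E_n, params$sigma_n),
    h_inf = lg(params$E_h, params$sigma_h)
  )
}

#' Voltage-dependent gating time constants
#'
#' `tau_n = tau_nb / cosh((V - E_n) / (2 sigma_n))` and
#' `tau_h = tau_hb / cosh((V - E_h) / (2 sigma_h))`; both peak at their
#' half-(in)activation voltage and fall off symmetrically.
#'
#' @inheritParams steady_state_gates
#' @return A list with `tau_n` (ms) and `tau_h` (ms; the base value is 10 s).
#' @examples
#' gate_time_constants(-29)$tau_n  # = tau_nb (10 ms) at V = E_n
#' @export
gate_time_constants <- function(V, params = global_params()) {
  if (!all(is.finite(V))) stop("V must be finite")
  list(
    tau_n = params$tau_nb / cosh((V - params$E_n) / (2 * params$sigma_n)),
    tau_h = params$tau_hb / cosh((V - params$E_h) / (2 * params$sigma_h))
  )
}

#' Membrane currents of a single neuron
#'
#' Evaluates the eight currents of the membrane balance equation, in pA
#' (nS x mV), with the outward-positive sign convention:
#' fast sodium `I_Na = g_Na m_inf^3 (1 - n) (V - E_Na)`, persistent sodium
#' `I_NaP = g_NaP D_NaP m_NaP_inf h (V - E_Na)`, leak
#' `I_leak = g_leak D_leak (V - E_leak)`, delayed rectifier
#' `I_K = g_K n^4 (V - E_K)`, synaptic currents from the summed incoming
#' excitatory / inhibitory / opioid-modulated conductances, and the opioid
#' hyperpolarizing current `I_hyp = D_op * I_hyp_op` (applied only when the
#' neuron is MOR+).
#'
#' @param V,n,h state of the neuron (mV, unitless gates in \[0, 1\]).
#' @param g_leak,g_NaP neuron conductances (nS).
#' @param D_op 1 if the neuron is opioid-sensitive (MOR+), else 0.
#' @param mod a [modulation_state()].
#' @param g_exc,g_inh,g_op summed incoming synaptic conductances (nS) from
#'   excitatory MOR-, inhibitory, and excitatory MOR+ presynaptic neurons.
#' @param params shared parameters.
#' @return Named numeric vector with components `I_Na`, `I_NaP`, `I_leak`,
#'   `I_K`, `I_syn_exc`, `I_syn_inh`, `I_syn_op`, `I_hyp` (pA).
#' @export
membrane_currents <- function(V, n, h, g_leak, g_NaP, D_op,
                              mod = modulation_state(),
                              g_exc = 0, g_inh = 0, g_op = 0,
                              params = global_params()) {
  if (g_exc < 0 || g_inh < 0 || g_op < 0 || g_leak < 0 || g_NaP < 0)
    stop("conductances must be nonnegative")
  stopifnot(n >= 0, n <= 1, h >= 0, h <= 1)
  ss <- steady_state_gates(V, params)
  c(
    I_Na = params$g_Na * ss$m_inf^3 * (1 - n) * (V - params$E_Na),
    I_NaP = g_NaP * mod$D_NaP * ss$m_NaP_inf * h * (V - params$E_Na),
    I_leak = g_leak * mod$D_leak * (V - params$E_leak),
    I_K = params$g_K * n^4 * (V - params$E_K),
    I_syn_exc = g_exc * (V - params$E_exc),
    I_syn_inh = g_inh * (V - params$E_inh),
    I_syn_op = g_op * (V - params$E_exc),
    I_hyp = D_op * mod$I_hyp_op
  )
}

#' Time derivatives of the full network state
#'
#' Reference (pure R) evaluation of the right-hand side of the model: for
#' each neuron `dV/dt = -(sum of the eight currents) / C_m`; the gates relax
#' as `dn/dt = (n_inf - n)/tau_n`, `dh/dt = (h_inf - h)/tau_h`; each directed
#' synapse gate follows `ds/dt = ((1 - s) m_syn_inf - s) / tau_syn` with
#' `m_syn_inf = 1 / (1 + exp((V_pre - E_s)/sigma_syn))` of its presynaptic
#' neuron. Incoming conductances are sums of `g_syn_max * s` over edges,
#' routed by presynaptic class: excitatory MOR- to `g_exc`, inhibitory to
#' `g_inh`, excitatory MOR+ to `g_op`, the last with maximum conductance
#' rescaled by `mod$g_syn_op` relative to its control value.
#'
#' This evaluator is the slow, transparent counterpart of the compiled
#' integrator; it backs small-network oracle integrations and tests.
#'
#' @param state list with numeric `V`, `n`, `h` (length N) and `s` (one per
#'   directed edge, in the row order of `network$edges`).
#' @param network a [build_network()] object.
#' @param mod a [modulation_state()].
#' @param params shared parameters.
#' @param g_syn_op_control control value of the opioid-sensitive synaptic
#'   conductance that `mod$g_syn_op` is relative to (nS).
#' @param synaptic_block if `TRUE`, all synaptic conductances are forced to
#'   zero (synapse gates still evolve).
#' @return list with `dV` (mV/ms), `dn`, `dh`, `ds` (1/ms).
#' @export
derivatives <- function(state, network, mod = modulation_state(),
                        params = global_params(), g_syn_op_control = 1,
                        synaptic_block = FALSE) {
  N <- network$N
  edges <- network$edges
  if (length(state$V) != N || length(state$n) != N || length(state$h) != N)
    stop("state dimensions do not match network size")
  if (length(state$s) != nrow(edges))
    stop("state$s length does not match edge count")
  V <- state$V; n <- state$n; h <- state$h; s <- state$s
  ss <- steady_state_gates(V, params)
  tc <- gate_time_constants(V, params)

  g_exc <- g_inh <- g_op <- numeric(N)
  if (nrow(edges) > 0 && !synaptic_block) {
    cls <- edge_class(network)
    w <- edges$g_syn_max * s
    w[cls == 2L] <- w[cls == 2L] * (mod$g_syn_op / g_syn_op_control)
    g_exc <- as.numeric(rowsum_by(w[cls == 0L], edges$post[cls == 0L], N))
    g_inh <- as.numeric(rowsum_by(w[cls == 1L], edges$post[cls == 1L], N))
    g_op <- as.numeric(rowsum_by(w[cls == 2L], edges$post[cls == 2L], N))
  }

  at <- network$neurons
  gna_eff <- params$g_Na * ss$m_inf^3 * (1 - n)
  gnap_eff <- at$g_NaP * mod$D_NaP * ss$m_NaP_inf * h
  gl_eff <- at$g_leak * mod$D_leak
  gk_eff <- params$g_K * n^4
  Isum <- gna_eff * (V - params$E_Na) + gnap_eff * (V - params$E_Na) +
    gl_eff * (V - params$E_leak) + gk_eff * (V - params$E_K) +
    g_exc * (V - params$E_exc) + g_inh * (V - params$E_inh) +
    g_op * (V - params$E_exc) + at$D_op * mod$I_hyp_op

  ds <- numeric(nrow(edges))
  if (nrow(edges) > 0) {
    m_syn <- 1 / (1 + exp((V[edges$pre] - params$E_s) / params$sigma_syn))
    ds <- ((1 - s) * m_syn - s) / params$tau_syn
  }
  list(
    dV = -Isum / params$C_m,
    dn = (ss$n_inf - n) / tc$tau_n,
    dh = (ss$h_inf - h) / tc$tau_h,
    ds = ds
  )
}

# sum w into N bins indexed by idx (1-based); returns length-N vector
rowsum_by <- function(w, idx, N) {
  out <- numeric(N)
  if (length(w)) {
    t <- tapply(w, factor(idx, levels = seq_len(N)), sum)
    out[!is.na(t)] <- t[!is.na(t)]
  }
  out
}

# per-edge presynaptic class: 0 excitatory MOR-, 1 inhibitory, 2 excitatory MOR+
edge_class <- function(network) {
  pre <- network$edges$pre
  at <- network$neurons
  ifelse(!at$is_excitatory[pre], 1L, ifelse(at$D_op[pre] == 1L, 2L, 0L))
}
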