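#' Classify a spike train as silent, bursting or tonic
#'
#' Rule for intrinsic activity under synaptic block: a neuron is `silent`
#' with fewer than `min_spikes` spikes in the window; otherwise `bursting`
#' when the inter-spike intervals show grouped structure (maximum ISI larger
#' than `isi_ratio` times the median ISI AND at least two spike groups
#' separated by gaps longer than `gap_s`); otherwise `tonic`. The defaults
#' (3 spikes, ratio 5, gap 1 s) match the canonical appearance of
#' persistent-sodium bursting in this model: intraburst ISIs of tens of ms
#' and interburst intervals of seconds (the slow inactivation time constant
#' is 10 s).
#'
#' @param spike_times numeric spike times (s) within the analysis window.
#' @param min_spikes fewer spikes than this is `silent`.
#' @param isi_ratio bursting requires `max(ISI) > isi_ratio * median(ISI)`.
#' @param gap_s bursting requires at least 2 groups separated by gaps longer
#'   than this (s).
#' @return One of `"silent"`, `"bursting"`, `"tonic"`.
#' @examples
#' classify_spike_train(numeric(0))              # silent
#' classify_spike_train(seq(0, 10, by = 0.2))    # tonic
#' classify_spike_train(c(0, .03, .06, 4, 4.03, 4.06))  # bursting
#' @export
classify_spike_train <- function(spike_times, min_spikes = 3,
                                 isi_ratio = 5, gap_s = 1) {
  if (length(spike_times) < min_spikes) return("silent")
  isi <- diff(sort(spike_times))
  grouped <- max(isi) > isi_ratio * median(isi) && sum(isi > gap_s) >= 1
  if (grouped) "bursting" else "tonic"
}

#' Classify every neuron's intrinsic activity under synaptic block
#'
#' Integrates the network with all synapses blocked for
#' `transient + window` seconds under the given modulation state (the
#' hyperpolarizing current reaches MOR+ neurons only; `g_syn_op` is
#' irrelevant under block), discards the transient, classifies each neuron's
#' spike train, and tabulates the labels by subpopulation.
#'
#' @param network a `prebotc_network`.
#' @param mod a [modulation_state()] (e.g. `modulation_state(I_hyp_op = 4)`
#'   for a moderate opioid dose).
#' @param window classification window (s) after the transient; 60 s covers
#'   at least three cycles of the slowest plausible burst period.
#' @param transient discarded initial transient (s).
#' @param dt integration step (ms).
#' @param init_seed initial-state seed (defaults to the network's).
#' @param params shared parameters.
#' @param ... further arguments passed to [classify_spike_train()].
#' @return A `prebotc_labels` object: list with `labels` (factor of
#'   silent/bursting/tonic per neuron), `subpopulation` (factor:
#'   `exc_morp`, `exc_morm`, `inhibitory`), `counts` (label x subpopulation
#'   table), `window`, `mod`.
#' @export
classify_network <- function(network, mod = modulation_state(), window = 60,
                             transient = 10, dt = 0.05,
                             init_seed = network$seeds$init,
                             params = global_params(), ...) {
  sch <- constant_schedule(mod, duration = transient + window,
                           synaptic_block = TRUE, transient_s = transient)
  sim <- integrate_network(network, sch, dt = dt, init_seed = init_seed,
                           params = params)
  sp <- sim$spikes[sim$spikes$time >= transient, ]
  trains <- split(sp$time, factor(sp$neuron, levels = seq_len(network$N)))
  labels <- vapply(trains, classify_spike_train, character(1), ...)
  labels <- factor(labels, levels = c("silent", "bursting", "tonic"))
  at <- network$neurons
  subpop <- factor(ifelse(!at$is_excitatory, "inhibitory",
                          ifelse(at$D_op == 1, "exc_morp", "exc_morm")),
                   levels = c("exc_morp", "exc_morm", "inhibitory"))
  structure(list(labels = labels, subpopulation = subpop,
                 counts = table(label = labels, subpopulation = subpop),
                 window = window, mod = mod),
            class = "prebotc_labels")
}

#' @export
print.prebotc_labels <- function(x, ...) {
  cat("Intrinsic activity under synaptic block (window", x$window, "s):\n")
  print(x$counts)
  invisible(x)
}

#' Intrinsic composition percentages
#'
#' Percentage of neurons with each intrinsic label. Because only excitatory
#' neurons can be opioid-sensitive (inhibitory neurons never express MOR),
#' opioid-induced composition shifts are reported over the excitatory
#' population by default; control compositions are statistically identical
#' under either denominator since all neurons draw conductances from the
#' same distributions.
#'
#' @param cl a `prebotc_labels` from [classify_network()].
#' @param over `"excitatory"` (default) or `"all"`.
#' @return Named numeric vector of percentages (`silent`, `bursting`,
#'   `tonic`), summing to 100.
#' @export
intrinsic_composition <- function(cl, over = c("excitatory", "all")) {
  over <- match.arg(over)
  sel <- if (over == "excitatory")
    cl$subpopulation != "inhibitory" else rep(TRUE, length(cl$labels))
  100 * prop.table(table(cl$labels[sel]))[c("silent", "bursting", "tonic")]
}

#' Conductance phase diagram of intrinsic activity
#'
#' Simulates one isolated neuron per grid point of (g_leak, g_NaP) under
#' synaptic block and the given modulation state (each grid neuron is MOR+,
#' so `I_hyp_op` applies) and labels its intrinsic activity. The default
#' grid is g_leak 0.2-1.5 nS and g_NaP 0.6-1.5 nS in 0.1 nS steps.
#'
#' @param mod a [modulation_state()].
#' @param g_leak_grid,g_NaP_grid grid values (nS).
#' @param window,transient,dt,params,init_V as in [classify_network()];
#'   every grid neuron starts at `init_V` mV with gates at steady state.
#' @param ... passed to [classify_spike_train()].
#' @return data.frame with `g_leak`, `g_NaP`, `label` covering the full
#'   grid.
#' @export
phase_diagram <- function(mod = modulation_state(),
                          g_leak_grid = seq(0.2, 1.5, by = 0.1),
                          g_NaP_grid = seq(0.6, 1.5, by = 0.1),
                          window = 60, transient = 10, dt = 0.05,
                          params = global_params(), init_V = -60, ...) {
  grid <- expand.grid(g_leak = g_leak_grid, g_NaP = g_NaP_grid)
  n <- nrow(grid)
  net <- structure(list(
    N = n,
    neurons = data.frame(g_leak = grid$g_leak, g_NaP = grid$g_NaP,
                         is_excitatory = TRUE, D_op = 1L),
    edges = data.frame(pre = integer(0), post = integer(0),
                       g_syn_max = numeric(0), is_op_modulated = logical(0)),
    g_syn_op_control = 1, d_avg = 0, mor_policy = "random",
    seeds = list(init = 1L)
  ), class = "prebotc_network")
  sch <- constant_schedule(mod, duration = transient + window,
                           synaptic_block = TRUE, transient_s = transient)
  ss <- steady_state_gates(init_V, params)
  st <- list(V = rep(init_V, n), n = rep(ss$n_inf, n), h = rep(ss$h_inf, n),
             s = numeric(0))
  sim <- integrate_network(net, sch, dt = dt, init_state = st,
                           params = params)
  sp <- sim$spikes[sim$spikes$time >= transient, ]
  trains <- split(sp$time, factor(sp$neuron, levels = seq_len(n)))
  grid$label <- factor(vapply(trains, classify_spike_train, character(1), ...),
                       levels = c("silent", "bursting", "tonic"))
  grid
}
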