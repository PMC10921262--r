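#' Shared single-neuron model parameters
#'
#' Returns the biophysical parameters shared by every neuron in the model:
#' membrane capacitance, reversal potentials, gating half-(in)activation
#' voltages and slopes, base time constants and the fixed fast-sodium and
#' delayed-rectifier potassium conductances. Internal units are mV, ms, nS,
#' pF and pA throughout (so nS x mV = pA and pA / pF = mV / ms); the base
#' inactivation time constant `tau_hb` is stored as 10,000 ms (10 s).
#'
#' @param ... named overrides of individual defaults, e.g. `g_Na = 0` to
#'   remove the fast sodium current.
#'
#' @return A named list of class `prebotc_params`.
#'
#' @details Defaults (capacitance 21 pF; E_K -85, E_leak -58, E_Na 50,
#'   E_exc 0, E_inh -70, E_s 0 mV; sigma_h 5, sigma_m -5, sigma_m_NaP -6,
#'   sigma_n -4, sigma_syn -3 mV; E_h -48, E_m -34, E_m_NaP -40, E_n -29 mV;
#'   tau_syn 15 ms, tau_nb 10 ms, tau_hb 10 s; g_Na 28 nS, g_K 11.2 nS) are
#'   the standard parameter set for persistent-sodium (Butera-type) preBotC
#'   neurons with fast spiking currents.
#'
#' @examples
#' p <- global_params()
#' p$C_m
#' global_params(g_Na = 0, g_K = 0)$g_Na
#' @export
global_params <- function(...) {
  p <- list(
    C_m = 21,          # pF
    E_K = -85,         # mV
    E_leak = -58,      # mV
    E_Na = 50,         # mV
    E_exc = 0,         # mV
    E_inh = -70,       # mV
    E_s = 0,           # mV (synaptic gate half-activation of presynaptic V)
    sigma_h = 5,       # mV
    sigma_m = -5,      # mV
    sigma_m_NaP = -6,  # mV
    sigma_n = -4,      # mV
    sigma_syn = -3,    # mV
    E_h = -48,         # mV
    E_m = -34,         # mV
    E_m_NaP = -40,     # mV
    E_n = -29,         # mV
    tau_syn = 15,      # ms
    tau_nb = 10,       # ms
    tau_hb = 10000,    # ms (10 s)
    g_Na = 28,         # nS
    g_K = 11.2         # nS
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  stopifnot(p$C_m > 0, p$tau_syn > 0, p$tau_nb > 0, p$tau_hb > 0,
            p$g_Na >= 0, p$g_K >= 0)
  sig <- unlist(p[c("sigma_h", "sigma_m", "sigma_m_NaP", "sigma_n", "sigma_syn")])
  if (any(sig == 0)) stop("gating slopes sigma must be nonzero")
  class(p) <- "prebotc_params"
  p
}

#' Opioid / drug modulation state
#'
#' Bundles the four exogenously set modulation variables: the multiplicative
#' drug factors on the persistent-sodium and leak conductances, the maximum
#' conductance of opioid-sensitive excitatory synapses, and the magnitude of
#' the opioid hyperpolarizing current applied to MOR+ neurons.
#'
#' @param D_NaP multiplicative factor on g_NaP (unitless, >= 0). 1 = control.
#' @param D_leak multiplicative factor on g_leak (unitless, >= 0). 1 = control.
#' @param g_syn_op maximum conductance of opioid-sensitive synapses
#'   (nS, nonnegative). The control value is 1.0 nS; opioid reduces it.
#' @param I_hyp_op opioid hyperpolarizing current (pA, nonnegative) applied only to
#'   MOR+ neurons (`D_op = 1`).
#'
#' @return A named list of class `prebotc_mod`.
#' @examples
#' modulation_state()                      # control
#' modulation_state(I_hyp_op = 4, g_syn_op = 0.5)  # moderate opioid
#' @export
modulation_state <- function(D_NaP = 1, D_leak = 1, g_syn_op = 1, I_hyp_op = 0) {
  stopifnot(is.finite(D_NaP), is.finite(D_leak), is.finite(g_syn_op),
            is.finite(I_hyp_op))
  if (D_NaP < 0 || D_leak < 0 || g_syn_op < 0 || I_hyp_op < 0)
    stop("modulation values must be nonnegative")
  structure(list(D_NaP = D_NaP, D_leak = D_leak,
                 g_syn_op = g_syn_op, I_hyp_op = I_hyp_op),
            class = "prebotc_mod")
}

#' Read or write a flat key/value parameter configuration
#'
#' Parameter sets are serialized as plain `key: value` text (one pair per
#' line), so runs are reproducible from a human-readable config.
#'
#' @param params a `prebotc_params` list.
#' @param file path to write to / read from.
#' @return `read_params()` returns a `prebotc_params` list.
#' @export
write_params <- function(params, file) {
  stopifnot(inherits(params, "prebotc_params"))
  writeLines(sprintf("%s: %.17g", names(params), unlist(params)), file)
  invisible(file)
}

#' @rdname write_params
#' @export
read_params <- function(file) {
  ln <- readLines(file)
  ln <- ln[nzchar(trimws(ln))]
  kv <- strsplit(ln, ":", fixed = TRUE)
  vals <- lapply(kv, function(x) as.numeric(trimws(x[2])))
  names(vals) <- trimws(vapply(kv, `[`, "", 1))
  do.call(global_params, vals)
}
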