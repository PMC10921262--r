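# Independent oracles and shared fixtures for the test suite.

# Brute-force topographic prominence: for every strict local maximum, scan
# left to the nearest sample >= peak (ties defer to the earlier peak) and
# right to the nearest sample > peak, take the minimum on each flank, and
# measure the drop to the higher of the two minima. Written independently of
# detect_bursts() as its oracle.
brute_force_peaks <- function(x, min_height, min_prominence) {
  n <- length(x)
  out <- data.frame(index = integer(0), amplitude = numeric(0),
                    prominence = numeric(0))
  for (p in seq_len(n)) {
    if (p == 1 || p == n) next
    if (!(x[p] > x[p - 1])) next
    j <- p
    while (j < n && x[j + 1] == x[p]) j <- j + 1
    if (j == n || x[j + 1] >= x[p]) next
    if (x[p] < min_height) next
    left <- x[seq_len(p - 1)]
    stop_l <- which(left >= x[p])
    lmin <- min(left[seq(from = if (length(stop_l)) max(stop_l) + 1 else 1,
                         to = p - 1)])
    right <- x[seq(p + 1, n)]
    stop_r <- which(right > x[p])
    rmin <- min(right[seq_len(if (length(stop_r)) min(stop_r) - 1 else
                              length(right))])
    prom <- x[p] - max(lmin, rmin)
    if (prom >= min_prominence)
      out <- rbind(out, data.frame(index = p, amplitude = x[p],
                                   prominence = prom))
  }
  out
}

# small fully-specified network: n neurons, explicit edges
tiny_network <- function(g_leak, g_NaP, is_exc, d_op, edges = NULL,
                         g_syn_max = 3) {
  n <- length(g_leak)
  if (is.null(edges))
    edges <- data.frame(pre = integer(0), post = integer(0))
  edges$g_syn_max <- rep(g_syn_max, nrow(edges))
  edges$is_op_modulated <- d_op[edges$pre] == 1L
  structure(list(
    N = n,
    neurons = data.frame(g_leak = g_leak, g_NaP = g_NaP,
                         is_excitatory = is_exc, D_op = as.integer(d_op)),
    edges = edges, g_syn_op_control = g_syn_max, d_avg = NA_real_,
    mor_policy = "random", seeds = list(init = 1L)
  ), class = "prebotc_network")
}

# cache for expensive shared simulations (classifications reused across
# acceptance tests); computed once per test run
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

classify_cached <- function(key, network, mod, window = 60, dt = 0.05) {
  cached(key, classify_network(network, mod, window = window, dt = dt))
}

precomputed_path <- function(file) {
  p <- system.file("extdata", "precomputed", file, package = "prebotc")
  if (!nzchar(p)) stop("missing precomputed table: ", file)
  p
}
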