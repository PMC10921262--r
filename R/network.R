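#' Draw heterogeneous leak and persistent-sodium conductances
#'
#' `g_leak` is drawn from a mixture of three Gaussians with weights
#' (0.35, 0.1, 0.55), means (0.5, 0.7, 1.2) nS and common standard deviation
#' 0.05 nS; `g_NaP` from a Gaussian with mean 0.8 nS and sd 0.05 nS. This
#' two-population leak distribution keeps the fraction of intrinsic bursters
#' in a network at the experimentally observed 5-10%. Draws that are not
#' strictly positive are redrawn (conductances are physical).
#'
#' @param n number of neurons (>= 1).
#' @param seed integer RNG seed; the draw is a pure function of `(n, seed)`.
#' @param mixture_weights,mixture_means,mixture_sd g_leak mixture parameters
#'   (nS).
#' @param g_NaP_mean,g_NaP_sd g_NaP Gaussian parameters (nS).
#' @return list with numeric vectors `g_leak` and `g_NaP` (nS, length `n`).
#' @examples
#' g <- sample_conductances(300, seed = 1)
#' mean(g$g_NaP)  # ~0.8
#' @export
sample_conductances <- function(n, seed,
                                mixture_weights = c(0.35, 0.1, 0.55),
                                mixture_means = c(0.5, 0.7, 1.2),
                                mixture_sd = 0.05,
                                g_NaP_mean = 0.8, g_NaP_sd = 0.05) {
  if (n < 1) stop("n must be >= 1")
  stopifnot(length(mixture_weights) == length(mixture_means))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  comp <- sample.int(length(mixture_weights), n, replace = TRUE,
                     prob = mixture_weights)
  g_leak <- rnorm(n, mixture_means[comp], mixture_sd)
  g_NaP <- rnorm(n, g_NaP_mean, g_NaP_sd)
  # redraw non-positive values (possible in the lowest mixture component)
  while (any(bad <- g_leak <= 0))
    g_leak[bad] <- rnorm(sum(bad), mixture_means[comp[bad]], mixture_sd)
  while (any(bad <- g_NaP <= 0))
    g_NaP[bad] <- rnorm(sum(bad), g_NaP_mean, g_NaP_sd)
  list(g_leak = g_leak, g_NaP = g_NaP)
}

#' Random directed topology
#'
#' Directed Erdos-Renyi graph: each ordered pair (i, j), i != j, is an edge
#' independently with probability `(d_avg / 2) / (N - 1)`, where `d_avg` is
#' the target average total (in + out) degree. The default `d_avg = 6` on
#' N = 300 gives a connection density of about 1%. No self-edges; at most
#' one edge per ordered pair.
#'
#' @param N neuron count.
#' @param d_avg target average total degree; must satisfy
#'   `(d_avg/2)/(N-1) <= 1`.
#' @param seed integer RNG seed.
#' @return data.frame with integer columns `pre`, `post` (1-based).
#' @export
build_topology <- function(N, d_avg = 6, seed = 1) {
  if (d_avg <= 0) stop("d_avg must be positive")
  p <- (d_avg / 2) / (N - 1)
  if (p > 1) stop("connection probability exceeds 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  # fixed enumeration order (pre-major) so the edge set is reproducible
  pre <- rep(seq_len(N), each = N)
  post <- rep(seq_len(N), times = N)
  keep <- pre != post
  pre <- pre[keep]; post <- post[keep]
  sel <- runif(length(pre)) < p
  data.frame(pre = pre[sel], post = post[sel])
}

#' Assign excitatory/inhibitory identity and MOR expression
#'
#' A uniform random subset of `frac_inhibitory * N` neurons is inhibitory;
#' the rest are excitatory. Exactly half of the excitatory neurons are
#' opioid-sensitive (MOR+, `D_op = 1`): chosen uniformly at random under the
#' `"random"` policy, or as the excitatory neurons below (`"low_gleak"`) /
#' above (`"high_gleak"`) the excitatory g_leak median. Median ties are
#' broken by stable sort on (g_leak, index) so the split is always exactly
#' half. Inhibitory neurons are never MOR+. Every edge gets the baseline
#' maximum conductance `g_syn_max`, and edges from MOR+ neurons are flagged
#' as opioid-modulated.
#'
#' @param edges data.frame from [build_topology()].
#' @param conductances list from [sample_conductances()].
#' @param frac_inhibitory fraction of inhibitory neurons; `frac_inhibitory*N`
#'   must be integral (default 60/300).
#' @param mor_policy `"random"`, `"low_gleak"` or `"high_gleak"`.
#' @param seed integer RNG seed for the inhibitory and (random-policy) MOR
#'   draws; independent of the topology and conductance seeds.
#' @param g_syn_max baseline synaptic maximum conductance (nS) given to every
#'   synapse (excitatory MOR-, excitatory MOR+ and inhibitory alike). Opioid
#'   rescales MOR+ synapses relative to this baseline via the schedule's
#'   fractional `g_syn_op(t)`.
#' @return A `prebotc_network` object: list with `N`, `neurons` (data.frame
#'   `g_leak`, `g_NaP`, `is_excitatory`, `D_op`), `edges` (data.frame `pre`,
#'   `post`, `g_syn_max`, `is_op_modulated`), `g_syn_op_control`, `d_avg`,
#'   `mor_policy` and a `seeds` record.
#' @export
assign_populations <- function(edges, conductances, frac_inhibitory = 0.2,
                               mor_policy = c("random", "low_gleak", "high_gleak"),
                               seed = 1, g_syn_max = 3) {
  mor_policy <- match.arg(mor_policy)
  N <- length(conductances$g_leak)
  n_inh <- frac_inhibitory * N
  if (abs(n_inh - round(n_inh)) > 1e-9)
    stop("frac_inhibitory * N must be an integer")
  n_inh <- as.integer(round(n_inh))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  inh <- sample.int(N, n_inh)
  is_exc <- rep(TRUE, N); is_exc[inh] <- FALSE
  exc_ids <- which(is_exc)
  n_mor <- length(exc_ids) %/% 2L
  D_op <- integer(N)
  if (mor_policy == "random") {
    D_op[sample(exc_ids, n_mor)] <- 1L
  } else {
    ord <- exc_ids[order(conductances$g_leak[exc_ids], exc_ids)]
    tgt <- if (mor_policy == "low_gleak") head(ord, n_mor) else tail(ord, n_mor)
    D_op[tgt] <- 1L
  }
  neurons <- data.frame(
    g_leak = conductances$g_leak,
    g_NaP = conductances$g_NaP,
    is_excitatory = is_exc,
    D_op = D_op
  )
  edges$g_syn_max <- rep(g_syn_max, nrow(edges))
  edges$is_op_modulated <- D_op[edges$pre] == 1L
  structure(list(N = N, neurons = neurons, edges = edges,
                 g_syn_op_control = g_syn_max,
                 d_avg = NA_real_, mor_policy = mor_policy,
                 seeds = list(populations = as.integer(seed))),
            class = "prebotc_network")
}

#' Generate a complete random preBotC network
#'
#' Convenience constructor combining [build_topology()],
#' [sample_conductances()] and [assign_populations()] with independent,
#' reproducibly derived RNG streams for topology, conductances, population
#' identity and (downstream) initial conditions. The default is the study
#' condition: N = 300 (240 excitatory / 60 inhibitory, 120 MOR+), average
#' degree 6 (about 1% density), uniform baseline synaptic conductance 3 nS
#' (the smallest value at which every random network sustains a rhythmic
#' population burst at control; see the methods vignette).
#'
#' @param N neuron count.
#' @param d_avg target average total degree.
#' @param frac_inhibitory inhibitory fraction.
#' @param mor_policy MOR+ assignment policy (see [assign_populations()]).
#' @param g_syn_max baseline synaptic maximum conductance (nS).
#' @param seed master integer seed; four sub-seeds (topology, conductances,
#'   populations, initial state) are derived from it deterministically.
#' @param seeds optional named list overriding any of the derived sub-seeds
#'   (`topology`, `conductances`, `populations`, `init`).
#' @return A `prebotc_network` (see [assign_populations()]).
#' @examples
#' net <- build_network(seed = 1)
#' table(net$neurons$is_excitatory, net$neurons$D_op)
#' @export
build_network <- function(N = 300, d_avg = 6, frac_inhibitory = 0.2,
                          mor_policy = "random", g_syn_max = 3,
                          seed = 1, seeds = list()) {
  s <- derive_seeds(seed)
  s[names(seeds)] <- seeds
  edges <- build_topology(N, d_avg, seed = s$topology)
  cond <- sample_conductances(N, seed = s$conductances)
  net <- assign_populations(edges, cond, frac_inhibitory, mor_policy,
                            seed = s$populations, g_syn_max = g_syn_max)
  net$d_avg <- d_avg
  net$seeds <- s
  net
}

#' Derive independent sub-seeds from a master seed
#'
#' @param seed master integer seed.
#' @return named list of integer sub-seeds (`topology`, `conductances`,
#'   `populations`, `init`), each below 2^31.
#' @export
derive_seeds <- function(seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  v <- sample.int(.Machine$integer.max - 1L, 4L)
  list(topology = v[1], conductances = v[2], populations = v[3], init = v[4])
}

#' Rescale connection density at constant total synaptic strength
#'
#' Regenerates the topology with average degree `d_avg * factor` (using a
#' fresh topology seed derived from the original) and divides every synaptic
#' maximum conductance, including the control value of the opioid-sensitive
#' conductance, by `factor`, so the expected total synaptic strength
#' (sum of `g_syn_max` over edges) is unchanged. Used to compare densities
#' of 1, 2, 4, 8 and 16%.
#'
#' @param network a `prebotc_network` built by [build_network()].
#' @param factor positive density multiplier; the resulting connection
#'   probability must not exceed 1.
#' @return A new `prebotc_network` with identical neurons and rescaled edges.
#' @export
scale_density <- function(network, factor) {
  stopifnot(inherits(network, "prebotc_network"), factor > 0)
  d_new <- network$d_avg * factor
  if ((d_new / 2) / (network$N - 1) > 1)
    stop("rescaled connection probability exceeds 1")
  if (factor == 1) return(network)
  edges <- build_topology(network$N, d_new, seed = network$seeds$topology)
  g_new <- network$g_syn_op_control / factor
  edges$g_syn_max <- rep(g_new, nrow(edges))
  edges$is_op_modulated <- network$neurons$D_op[edges$pre] == 1L
  out <- network
  out$edges <- edges
  out$d_avg <- d_new
  out$g_syn_op_control <- g_new
  out
}

#' @export
print.prebotc_network <- function(x, ...) {
  at <- x$neurons
  cat(sprintf(
    "preBotC network: %d neurons (%d exc / %d inh; %d MOR+), %d edges (d_avg %.3g, density %.2f%%)\n",
    x$N, sum(at$is_excitatory), sum(!at$is_excitatory), sum(at$D_op),
    nrow(x$edges), x$d_avg, 100 * nrow(x$edges) / (x$N * (x$N - 1))))
  invisible(x)
}

#' Write / read a network as plain text
#'
#' The node attribute table and the edge list are written as two CSV files
#' (`<stem>_nodes.csv`, `<stem>_edges.csv`); the round trip is lossless.
#'
#' @param network a `prebotc_network`.
#' @param stem file path stem (without suffix).
#' @return `read_network()` returns the reconstructed `prebotc_network`.
#' @export
write_network <- function(network, stem) {
  nodes <- cbind(id = seq_len(network$N), network$neurons)
  write.csv(nodes, paste0(stem, "_nodes.csv"), row.names = FALSE)
  write.csv(network$edges, paste0(stem, "_edges.csv"), row.names = FALSE)
  meta <- c(N = network$N, g_syn_op_control = network$g_syn_op_control,
            d_avg = network$d_avg)
  writeLines(c(sprintf("%s: %.17g", names(meta), meta),
               paste0("mor_policy: ", network$mor_policy)),
             paste0(stem, "_meta.txt"))
  invisible(stem)
}

#' @rdname write_network
#' @export
read_network <- function(stem) {
  nodes <- read.csv(paste0(stem, "_nodes.csv"))
  edges <- read.csv(paste0(stem, "_edges.csv"))
  meta <- readLines(paste0(stem, "_meta.txt"))
  val <- function(key) sub(paste0(key, ": "), "", meta[startsWith(meta, key)])
  structure(list(
    N = as.integer(val("N")),
    neurons = nodes[, c("g_leak", "g_NaP", "is_excitatory", "D_op")],
    edges = edges,
    g_syn_op_control = as.numeric(val("g_syn_op_control")),
    d_avg = as.numeric(val("d_avg")),
    mor_policy = val("mor_policy"),
    seeds = list()
  ), class = "prebotc_network")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
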