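#' Directed connection counts between labeled subpopulations
#'
#' Partitions the neurons by one of three schemes and counts directed edges
#' from each group to each group: `"ei"` (excitatory / inhibitory), `"mor"`
#' (excitatory MOR+ / excitatory MOR- / inhibitory) or `"intrinsic_mor"`
#' (tonic / bursting / silent crossed with MOR+ / MOR- for excitatory
#' neurons, plus inhibitory as one group). Intrinsic labels should come from
#' control-condition classification.
#'
#' @param network a `prebotc_network`.
#' @param scheme partition scheme.
#' @param labels a `prebotc_labels` from [classify_network()]; required for
#'   `scheme = "intrinsic_mor"`.
#' @return A square integer matrix; entry (r, c) is the number of directed
#'   edges from group r to group c. The grand total equals the edge count.
#' @examples
#' net <- build_network(N = 20, d_avg = 4, frac_inhibitory = 0.2, seed = 2)
#' sum(subgroup_connection_counts(net, "ei")) == nrow(net$edges)
#' @export
subgroup_connection_counts <- function(network,
                                       scheme = c("ei", "mor", "intrinsic_mor"),
                                       labels = NULL) {
  scheme <- match.arg(scheme)
  at <- network$neurons
  grp <- switch(scheme,
    ei = factor(ifelse(at$is_excitatory, "E", "I"), levels = c("E", "I")),
    mor = factor(ifelse(!at$is_excitatory, "I",
                        ifelse(at$D_op == 1, "MOR+", "MOR-")),
                 levels = c("MOR+", "MOR-", "I")),
    intrinsic_mor = {
      if (is.null(labels)) stop("scheme 'intrinsic_mor' requires labels")
      lab <- as.character(labels$labels)
      if (anyNA(lab)) stop("every neuron must carry an intrinsic label")
      code <- substr(toupper(ifelse(lab == "silent", "S", lab)), 1, 1)
      factor(ifelse(!at$is_excitatory, "I",
                    paste0(code, ifelse(at$D_op == 1, "_MOR+", "_MOR-"))),
             levels = c(paste0(rep(c("T", "B", "S"), each = 2),
                               c("_MOR+", "_MOR-")), "I"))
    })
  e <- network$edges
  m <- table(from = grp[e$pre], to = grp[e$post])
  unclass(m)
}

#' Pearson correlation with two-tailed p-value
#'
#' Correlates a per-network quantity (e.g. a connection count) with the
#' per-network opioid shutdown dose; the p-value is two-tailed from the t
#' distribution on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3), both with nonzero
#'   variance.
#' @return list with `r`, `p` and `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlate subgroup connectivity with shutdown dose across networks
#'
#' For a batch of networks with measured shutdown doses, computes the
#' connection-count matrix of each network under a partition scheme and the
#' Pearson correlation (with two-tailed p) between each count and the dose.
#' No multiple-testing correction is applied across the grid of cells;
#' per-cell p-values are reported as-is.
#'
#' @param networks list of `prebotc_network` objects.
#' @param doses numeric shutdown doses, one per network (pA).
#' @param scheme partition scheme (see [subgroup_connection_counts()]).
#' @param labels_list list of `prebotc_labels`, one per network (required
#'   for `scheme = "intrinsic_mor"`).
#' @return data.frame with one row per (from, to) cell: `from`, `to`, `r`,
#'   `p`, `n`.
#' @export
connectivity_dose_correlation <- function(networks, doses,
                                          scheme = "mor",
                                          labels_list = NULL) {
  stopifnot(length(networks) == length(doses))
  mats <- lapply(seq_along(networks), function(i)
    subgroup_connection_counts(networks[[i]], scheme,
                               labels = if (is.null(labels_list)) NULL
                                        else labels_list[[i]]))
  gn <- rownames(mats[[1]])
  cells <- expand.grid(from = gn, to = gn, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(k) {
    cnt <- vapply(mats, function(m) m[cells$from[k], cells$to[k]], numeric(1))
    out <- tryCatch(pearson_correlation(cnt, doses),
                    error = function(e) list(r = NA_real_, p = NA_real_,
                                             n = length(doses)))
    data.frame(from = cells$from[k], to = cells$to[k],
               r = out$r, p = out$p, n = out$n)
  })
  do.call(rbind, res)
}
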