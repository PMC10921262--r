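#' Population firing-rate trace
#'
#' Bins all spikes into a uniform grid, divides by `N * bin` to obtain a
#' population rate in Hz per cell, and smooths with a Gaussian kernel. The
#' unsmoothed histogram conserves the total spike count (sum of rate * bin
#' * N = number of spikes) and the kernel is normalized to sum 1, so
#' smoothing preserves the integral of the trace.
#'
#' @param spikes data.frame with a `time` column (s), e.g. from
#'   [integrate_network()], or a numeric vector of spike times.
#' @param N number of neurons in the population.
#' @param duration trace duration (s).
#' @param bin_ms bin width (ms).
#' @param smooth_sigma_ms Gaussian smoothing width (ms); 0 disables
#'   smoothing.
#' @return A `prebotc_rate`: data.frame with `time` (bin centers, s) and
#'   `rate` (Hz/cell), with `bin_ms`, `smooth_sigma_ms`, `N` attributes.
#' @examples
#' r <- population_rate(data.frame(time = rep(0.105, 300)), N = 300,
#'                      duration = 1, smooth_sigma_ms = 0)
#' max(r$rate)  # 100 Hz/cell: 300 spikes in one 10 ms bin
#' @export
population_rate <- function(spikes, N, duration, bin_ms = 10,
                            smooth_sigma_ms = 25) {
  if (N < 1) stop("N must be >= 1")
  times <- if (is.data.frame(spikes)) spikes$time else spikes
  bin_s <- bin_ms / 1000
  n_bins <- max(1L, as.integer(ceiling(duration / bin_s - 1e-9)))
  edges <- (0:n_bins) * bin_s
  counts <- if (length(times)) {
    idx <- pmin(pmax(findInterval(times, edges, rightmost.closed = TRUE), 1L),
                n_bins)
    tabulate(idx, nbins = n_bins)
  } else integer(n_bins)
  rate <- counts / (N * bin_s)
  if (smooth_sigma_ms > 0) {
    half <- as.integer(ceiling(4 * smooth_sigma_ms / bin_ms))
    kern <- exp(-0.5 * ((-half:half) * bin_ms / smooth_sigma_ms)^2)
    kern <- kern / sum(kern)
    # mass-conserving smoothing: each bin's kernel is renormalized by the
    # fraction of its mass that falls inside the trace, so the integral is
    # preserved exactly (no leakage at the edges)
    zconv <- function(x) {
      sm <- as.numeric(stats::filter(c(numeric(half), x, numeric(half)),
                                     kern, sides = 2))
      sm[(half + 1):(half + n_bins)]
    }
    inside <- zconv(rep(1, n_bins))
    rate <- zconv(rate / inside)
  }
  out <- data.frame(time = (seq_len(n_bins) - 0.5) * bin_s, rate = rate)
  attr(out, "bin_ms") <- bin_ms
  attr(out, "smooth_sigma_ms") <- smooth_sigma_ms
  attr(out, "N") <- N
  class(out) <- c("prebotc_rate", "data.frame")
  out
}

#' Detect population bursts
#'
#' Peak finding on a uniform rate trace: local maxima with height at least
#' `min_height` (4 Hz/cell) and topographic prominence at least
#' `min_prominence` (10 Hz/cell). The prominence of a peak is its height
#' minus the higher of the two flanking minima, where each flank extends to
#' the nearest sample exceeding the peak (or the trace edge). Between two
#' equal-height peaks the earlier one takes the full prominence and the
#' later is measured against their shared saddle.
#'
#' @param rate a `prebotc_rate` (or data.frame with `time` and `rate`).
#' @param min_height minimum peak height (Hz/cell).
#' @param min_prominence minimum prominence (Hz/cell).
#' @return data.frame of bursts with `peak_time` (s), `amplitude` (Hz/cell)
#'   and `prominence` (Hz/cell), sorted by time.
#' @export
detect_bursts <- function(rate, min_height = 4, min_prominence = 10) {
  x <- rate$rate
  n <- length(x)
  empty <- data.frame(peak_time = numeric(0), amplitude = numeric(0),
                      prominence = numeric(0))
  if (n < 3) return(empty)
  # strict local maxima; on a plateau take its first sample
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) peaks <- c(peaks, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  peaks <- peaks[x[peaks] >= min_height]
  if (!length(peaks)) return(empty)
  prom <- vapply(peaks, function(p) {
    v <- x[p]
    # left flank: scan to the nearest sample >= peak (ties defer to the
    # earlier peak); right flank: nearest sample strictly > peak
    l <- p - 1L
    lmin <- Inf
    while (l >= 1L && x[l] < v) {
      lmin <- min(lmin, x[l])
      l <- l - 1L
    }
    r <- p + 1L
    rmin <- Inf
    while (r <= n && x[r] <= v) {
      rmin <- min(rmin, x[r])
      r <- r + 1L
    }
    v - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  data.frame(peak_time = rate$time[peaks[keep]],
             amplitude = x[peaks[keep]], prominence = prom[keep])
}

#' Opioid shutdown dose
#'
#' For each amplitude threshold (default 10, 11, ..., 15 Hz/cell), finds the
#' last detected burst with amplitude at or above the threshold and looks up
#' the hyperpolarizing current `I_hyp_op` at its peak time on the attached
#' ramp schedule. The shutdown dose is the mean of these currents over the
#' thresholds that are reached; unreached thresholds are dropped with a
#' warning, and if no threshold is reached the dose is undefined (error).
#'
#' @param bursts data.frame from [detect_bursts()].
#' @param schedule the `prebotc_schedule` ramp the bursts were recorded
#'   under.
#' @param thresholds amplitude thresholds (Hz/cell).
#' @return Shutdown dose (pA), with a `per_threshold` attribute giving the
#'   per-threshold currents.
#' @export
shutdown_dose <- function(bursts, schedule, thresholds = 10:15) {
  doses <- vapply(thresholds, function(th) {
    hit <- which(bursts$amplitude >= th)
    if (!length(hit)) return(NA_real_)
    t_last <- max(bursts$peak_time[hit])
    schedule_value(schedule, t_last, "I_hyp_op")
  }, numeric(1))
  names(doses) <- thresholds
  if (all(is.na(doses)))
    stop("shutdown dose undefined: no burst reaches any amplitude threshold")
  if (anyNA(doses))
    warning("threshold(s) never reached, excluded from the dose: ",
            paste(thresholds[is.na(doses)], collapse = ", "))
  structure(mean(doses, na.rm = TRUE), per_threshold = doses)
}

#' Burst frequency and amplitude in an analysis window
#'
#' @param bursts data.frame from [detect_bursts()].
#' @param window numeric `c(start, end)` in seconds; only bursts whose peak
#'   falls inside are counted. Transient segments should be excluded via
#'   [schedule_windows()].
#' @return list with `frequency` (bursts/s), `amplitude` (mean Hz/cell;
#'   `NA` if the window holds no bursts) and `n_bursts`.
#' @export
burst_stats <- function(bursts, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  sel <- bursts$peak_time >= window[1] & bursts$peak_time < window[2]
  n <- sum(sel)
  list(frequency = n / (window[2] - window[1]),
       amplitude = if (n) mean(bursts$amplitude[sel]) else NA_real_,
       n_bursts = n)
}
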