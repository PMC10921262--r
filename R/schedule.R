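#' Piecewise-constant modulation schedule
#'
#' A schedule is a table of segment start times with the modulation values
#' holding from each start time until the next (and the last until
#' `duration`): the drug factors `D_NaP(t)`, `D_leak(t)`, the
#' opioid-sensitive synaptic conductance `g_syn_op(t)` (nS, relative to the
#' control value 1.0 nS), the opioid hyperpolarizing current `I_hyp_op(t)`
#' (pA), a synaptic-block flag, a transient flag marking segments excluded
#' from analysis, and a segment label.
#'
#' @param times segment start times (s), starting at 0, strictly increasing.
#' @param D_NaP,D_leak,g_syn_op,I_hyp_op per-segment values (recycled).
#' @param synaptic_block logical per segment (recycled).
#' @param transient logical per segment (recycled); transient data are
#'   excluded from analysis windows.
#' @param segment character labels (recycled).
#' @param duration total schedule duration (s).
#' @param g_syn_op_control the control (no-opioid) value that the schedule's
#'   `g_syn_op` entries are relative to (nS). Opioid-sensitive synapses run
#'   at the fraction `g_syn_op(t) / g_syn_op_control` of their baseline
#'   maximum conductance.
#' @return A `prebotc_schedule`: data.frame of segments with a `duration`
#'   attribute.
#' @export
make_schedule <- function(times, D_NaP = 1, D_leak = 1, g_syn_op = 1,
                          I_hyp_op = 0, synaptic_block = FALSE,
                          transient = FALSE, segment = "seg", duration,
                          g_syn_op_control = 1) {
  stopifnot(times[1] == 0, !is.unsorted(times, strictly = TRUE),
            duration >= max(times))
  k <- length(times)
  sch <- data.frame(
    time = times,
    D_NaP = rep_len(D_NaP, k), D_leak = rep_len(D_leak, k),
    g_syn_op = rep_len(g_syn_op, k), I_hyp_op = rep_len(I_hyp_op, k),
    synaptic_block = rep_len(synaptic_block, k),
    transient = rep_len(transient, k),
    segment = rep_len(segment, k)
  )
  if (any(sch$D_NaP < 0 | sch$D_leak < 0 | sch$g_syn_op < 0 | sch$I_hyp_op < 0))
    stop("schedule values must be nonnegative")
  attr(sch, "duration") <- duration
  # g_syn_op values are expressed relative to this control value: opioid
  # synapses run at g_syn_max * g_syn_op(t) / g_syn_op_control
  attr(sch, "g_syn_op_control") <- g_syn_op_control
  class(sch) <- c("prebotc_schedule", "data.frame")
  sch
}

#' Constant schedule from a modulation state
#'
#' @param mod a [modulation_state()].
#' @param duration duration (s).
#' @param synaptic_block force all synapses to zero conductance.
#' @param transient_s initial transient (s) flagged for exclusion.
#' @return A `prebotc_schedule`.
#' @export
constant_schedule <- function(mod = modulation_state(), duration = 70,
                              synaptic_block = FALSE, transient_s = 10) {
  tt <- if (transient_s > 0 && transient_s < duration) c(0, transient_s) else 0
  make_schedule(tt, D_NaP = mod$D_NaP, D_leak = mod$D_leak,
                g_syn_op = mod$g_syn_op, I_hyp_op = mod$I_hyp_op,
                synaptic_block = synaptic_block,
                transient = if (length(tt) == 2) c(TRUE, FALSE) else FALSE,
                segment = if (length(tt) == 2) c("transient", "steady") else "steady",
                duration = duration)
}

#' Gradual opioid ramp schedule
#'
#' Staircase opioid application: `I_hyp_op` rises from 0 toward `I_max` and
#' `g_syn_op` falls from `g0` toward 0, each changing by `step_fraction` of
#' its full range every `step_interval` seconds. With the defaults (0.5%
#' every 3 s) the ramp has 200 steps and the simulation lasts 10 minutes:
#' `I_hyp_op(t) = I_max * step_fraction * floor(t / step_interval)` capped at
#' `I_max`, and `g_syn_op(t) = g0 * (1 - step_fraction * floor(t /
#' step_interval))` floored at 0.
#'
#' @param I_max maximum hyperpolarizing current (pA).
#' @param g0 control opioid-sensitive synaptic conductance (nS).
#' @param step_fraction fractional change per step.
#' @param step_interval seconds between steps.
#' @return A `prebotc_schedule` of duration `step_interval / step_fraction`.
#' @examples
#' sch <- make_ramp_schedule()
#' attr(sch, "duration")        # 600 s
#' schedule_value(sch, 300, "I_hyp_op")  # 4 pA at the midpoint
#' @export
make_ramp_schedule <- function(I_max = 8, g0 = 1.0, step_fraction = 0.005,
                               step_interval = 3) {
  stopifnot(I_max > 0, g0 > 0, step_fraction > 0, step_interval > 0)
  n_steps <- ceiling(1 / step_fraction)
  k <- 0:n_steps
  frac <- pmin(k * step_fraction, 1)
  make_schedule(k * step_interval,
                I_hyp_op = I_max * frac, g_syn_op = g0 * (1 - frac),
                segment = "ramp",
                duration = n_steps * step_interval,
                g_syn_op_control = g0)
}

#' Timed all-or-nothing perturbation schedule
#'
#' The 200 s protocol: 10 s transient / 30 s control / 10 s transient / 30 s
#' opioid / 10 s transient / 30 s wash / 10 s transient / 30 s drug alone /
#' 10 s transient / 30 s opioid + drug. Opioid segments apply `I_hyp_op` =
#' `opioid_I_hyp` and `g_syn_op` = `opioid_g_syn`; drug segments scale
#' `g_NaP` (`drug = "gnap"`) or `g_leak` (`drug = "gleak"`) by `factor` for
#' every neuron. Transient segments are flagged so analysis excludes them.
#'
#' @param drug `"none"`, `"gnap"` or `"gleak"`.
#' @param factor multiplicative drug factor (e.g. 1.1/1.3/1.5 for g_NaP,
#'   0.9/0.7/0.5 for g_leak).
#' @param opioid_I_hyp opioid hyperpolarizing current in opioid segments (pA).
#' @param opioid_g_syn opioid-sensitive synaptic conductance in opioid
#'   segments (nS).
#' @return A `prebotc_schedule` of duration 200 s with segment labels
#'   `control`, `opioid`, `wash`, `drug`, `opioid_drug` (plus transients).
#' @export
make_perturbation_schedule <- function(drug = c("none", "gnap", "gleak"),
                                       factor = 1, opioid_I_hyp = 4,
                                       opioid_g_syn = 0.5) {
  drug <- match.arg(drug)
  if (factor <= 0) stop("drug factor must be positive")
  labs <- c("control", "opioid", "wash", "drug", "opioid_drug")
  times <- seq(0, 160, by = 40)
  op_on <- c(FALSE, TRUE, FALSE, FALSE, TRUE)
  dg_on <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  d_nap <- ifelse(dg_on & drug == "gnap", factor, 1)
  d_leak <- ifelse(dg_on & drug == "gleak", factor, 1)
  make_schedule(
    times = as.numeric(rbind(times, times + 10)),
    D_NaP = rep(d_nap, each = 2), D_leak = rep(d_leak, each = 2),
    g_syn_op = rep(ifelse(op_on, opioid_g_syn, 1), each = 2),
    I_hyp_op = rep(ifelse(op_on, opioid_I_hyp, 0), each = 2),
    transient = rep(c(TRUE, FALSE), times = 5),
    segment = as.character(rbind(paste0(labs, "_transient"), labs)),
    duration = 200
  )
}

#' Evaluate a schedule at given times
#'
#' @param schedule a `prebotc_schedule`.
#' @param t times (s) within `[0, duration]`.
#' @param what column name (e.g. `"I_hyp_op"`).
#' @return Values of the piecewise-constant schedule at `t`.
#' @export
schedule_value <- function(schedule, t, what = "I_hyp_op") {
  if (any(t < 0 | t > attr(schedule, "duration")))
    stop("t outside schedule duration")
  idx <- findInterval(t, schedule$time)
  schedule[[what]][idx]
}

#' Analysis windows of a schedule
#'
#' Start/end times of the non-transient segments, used to restrict burst
#' statistics to analyzable data.
#'
#' @param schedule a `prebotc_schedule`.
#' @return data.frame with `segment`, `start`, `end` (s).
#' @export
schedule_windows <- function(schedule) {
  ends <- c(schedule$time[-1], attr(schedule, "duration"))
  keep <- !schedule$transient
  data.frame(segment = schedule$segment[keep],
             start = schedule$time[keep], end = ends[keep])
}
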