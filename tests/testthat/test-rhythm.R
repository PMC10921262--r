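test_that("population rate implements the Hz-per-cell histogram convention", {
  # 300 neurons firing once in the same 10 ms bin -> 100 Hz/cell unsmoothed
  sp <- data.frame(neuron = 1:300, time = rep(0.105, 300))
  r <- population_rate(sp, N = 300, duration = 1, bin_ms = 10,
                       smooth_sigma_ms = 0)
  expect_equal(max(r$rate), 100)
  expect_equal(sum(r$rate > 0), 1)
  # empty raster -> all-zero trace, not an error
  r0 <- population_rate(data.frame(neuron = integer(0), time = numeric(0)),
                        N = 300, duration = 1)
  expect_true(all(r0$rate == 0))
  expect_equal(nrow(r0), 100)
  # unsmoothed histogram conserves the spike count
  set.seed(42)
  sp2 <- data.frame(time = runif(5000, 0, 20))
  r2 <- population_rate(sp2, N = 300, duration = 20, smooth_sigma_ms = 0)
  expect_equal(sum(r2$rate) * 0.01 * 300, 5000)
  # smoothing preserves the integral of the trace
  r3 <- population_rate(sp2, N = 300, duration = 20, smooth_sigma_ms = 25)
  expect_equal(sum(r3$rate), sum(r2$rate), tolerance = 1e-6)
  expect_error(population_rate(sp2, N = 0, duration = 20), ">= 1")
})

test_that("burst detection applies height and prominence thresholds", {
  tt <- seq(0, 30, by = 0.01)
  bump <- function(center, height, w = 0.3)
    height * exp(-0.5 * ((tt - center) / w)^2)
  mk <- function(rate) {
    out <- data.frame(time = tt, rate = rate)
    class(out) <- c("prebotc_rate", "data.frame")
    out
  }
  # single bump over a zero baseline: amplitude = prominence = 12
  b <- detect_bursts(mk(bump(15, 12)))
  expect_equal(nrow(b), 1)
  expect_equal(b$amplitude, 12, tolerance = 1e-6)
  expect_equal(b$prominence, 12, tolerance = 1e-6)
  expect_equal(b$peak_time, 15, tolerance = 0.01)
  # 3 Hz/cell bump fails the 4 Hz/cell height threshold
  expect_equal(nrow(detect_bursts(mk(bump(15, 3)))), 0)
  # two 12 Hz peaks with a 5 Hz valley: the later peak has prominence 7
  # (to the shared saddle) and fails the 10 Hz prominence threshold
  two <- pmax(bump(10, 12), bump(20, 12), 5 * (tt > 10 & tt < 20))
  b2 <- detect_bursts(mk(two))
  expect_equal(nrow(b2), 1)
  expect_equal(b2$peak_time, 10, tolerance = 0.01)
})

test_that("burst detection agrees with a brute-force prominence oracle", {
  set.seed(7)
  for (k in 1:100) {
    n <- sample(50:400, 1)
    x <- pmax(0, cumsum(rnorm(n, 0, 2)))
    x <- x + 15 * (runif(n) < 0.02)          # occasional sharp peaks
    rate <- data.frame(time = seq_along(x) * 0.01, rate = x)
    class(rate) <- c("prebotc_rate", "data.frame")
    got <- detect_bursts(rate, min_height = 4, min_prominence = 10)
    want <- brute_force_peaks(x, min_height = 4, min_prominence = 10)
    expect_equal(nrow(got), nrow(want), info = paste("fixture", k))
    if (nrow(got)) {
      expect_equal(got$amplitude, want$amplitude, info = paste("fixture", k))
      expect_equal(got$prominence, want$prominence,
                   info = paste("fixture", k))
    }
  }
})

test_that("shutdown dose averages the last-burst currents over thresholds", {
  sch <- make_ramp_schedule()
  # construct bursts whose last crossings give the known current sequence:
  # thresholds 15,14 end at I_hyp = 4.0, 13 at 4.2, 12,11 at 4.4, 10 at 4.6
  # (I_hyp(t) = 8 * 0.005 * floor(t/3))
  # one second into the staircase step where I_hyp equals I (avoids
  # floating-point landing exactly on a step boundary)
  t_for <- function(I) 3 * round(I / 0.04) + 1
  bursts <- data.frame(
    peak_time = t_for(c(4.0, 4.2, 4.4, 4.6)),
    amplitude = c(15.5, 13.5, 12.5, 10.5),
    prominence = 20)
  d <- shutdown_dose(bursts, sch)
  expect_equal(as.numeric(d), mean(c(4.0, 4.0, 4.2, 4.4, 4.4, 4.6)),
               tolerance = 1e-12)
  expect_equal(round(as.numeric(d), 2), 4.27)
  # identical last crossings: the mean of identical values
  b5 <- data.frame(peak_time = t_for(5), amplitude = 20, prominence = 20)
  expect_equal(as.numeric(shutdown_dose(b5, sch)), 5)
  # unreached thresholds are excluded with a warning
  b11 <- data.frame(peak_time = t_for(c(4, 5)), amplitude = c(11.5, 10.5),
                    prominence = 20)
  expect_warning(d2 <- shutdown_dose(b11, sch), "excluded")
  expect_equal(as.numeric(d2), mean(c(5, 4)))
  # no threshold reached -> undefined dose
  expect_error(shutdown_dose(data.frame(peak_time = 1, amplitude = 8,
                                        prominence = 8), sch),
               "undefined")
})

test_that("threshold monotonicity: restricting to higher thresholds cannot raise the last-burst time", {
  sch <- make_ramp_schedule()
  set.seed(31)
  for (k in 1:20) {
    nb <- sample(5:40, 1)
    bursts <- data.frame(peak_time = sort(runif(nb, 0, 599)),
                         amplitude = runif(nb, 4, 30), prominence = 20)
    if (max(bursts$amplitude) < 15) next
    last_t <- vapply(10:15, function(th) {
      hit <- bursts$peak_time[bursts$amplitude >= th]
      if (length(hit)) max(hit) else NA_real_
    }, numeric(1))
    expect_true(all(diff(last_t[!is.na(last_t)]) <= 0))
    if (max(bursts$amplitude) >= 15) {
      d15 <- shutdown_dose(bursts, sch, thresholds = 15)
      d10 <- shutdown_dose(bursts, sch, thresholds = 10)
      expect_lte(as.numeric(d15), as.numeric(d10))
    }
  }
})

test_that("burst statistics summarize frequency and amplitude per window", {
  bursts <- data.frame(peak_time = seq(12, 37, by = 5),
                       amplitude = c(10, 12, 14, 16, 18, 20),
                       prominence = 15)
  st <- burst_stats(bursts, c(10, 40))
  expect_equal(st$frequency, 6 / 30)
  expect_equal(st$amplitude, 15)
  # empty window: frequency 0, amplitude missing (not zero)
  st0 <- burst_stats(bursts, c(100, 130))
  expect_equal(st0$frequency, 0)
  expect_true(is.na(st0$amplitude))
  # merging two windows with equal counts leaves frequency unchanged
  stA <- burst_stats(bursts, c(10, 25))
  stB <- burst_stats(bursts, c(25, 40))
  expect_equal(stA$n_bursts, stB$n_bursts)
  expect_equal(burst_stats(bursts, c(10, 40))$frequency, stA$frequency)
})
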