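#' Measure the opioid shutdown dose of one network
#'
#' Runs the gradual opioid ramp on a network, converts the spike raster to a
#' smoothed population-rate trace, detects bursts, and computes the shutdown
#' dose (mean `I_hyp_op` at the last bursts crossing the 10-15 Hz/cell
#' amplitude thresholds).
#'
#' @param network a `prebotc_network`.
#' @param schedule ramp schedule (default [make_ramp_schedule()], 600 s).
#' @param dt integration step (ms).
#' @param bin_ms,smooth_sigma_ms rate-estimator settings.
#' @param thresholds amplitude thresholds (Hz/cell).
#' @param init_seed initial-state seed.
#' @return list with `dose` (pA), `bursts`, `rate` and the simulation's
#'   `gate_range`.
#' @export
measure_shutdown_dose <- function(network, schedule = make_ramp_schedule(),
                                  dt = 0.05, bin_ms = 10,
                                  smooth_sigma_ms = 25, thresholds = 10:15,
                                  init_seed = network$seeds$init) {
  sim <- integrate_network(network, schedule, dt = dt, init_seed = init_seed)
  rate <- population_rate(sim$spikes, N = network$N,
                          duration = sim$duration, bin_ms = bin_ms,
                          smooth_sigma_ms = smooth_sigma_ms)
  bursts <- detect_bursts(rate)
  dose <- shutdown_dose(bursts, schedule, thresholds)
  list(dose = as.numeric(dose), per_threshold = attr(dose, "per_threshold"),
       bursts = bursts, rate = rate, gate_range = sim$gate_range)
}

#' Experiment configuration
#'
#' @param experiment one of `ramp_batch`, `sensitivity_split`,
#'   `density_sweep`, `topology_correlation`, `mor_policy`, `gnap_rescue`,
#'   `gleak_rescue`, `phase_diagram`.
#' @param n_networks batch size (the full study condition is 40; scaled-down
#'   runs use fewer).
#' @param base_seed master seed; network i uses seed `base_seed + i - 1`.
#' @param dt integration step (ms).
#' @param d_avg,mor_policy,g_syn_max network-builder settings.
#' @param density_factors density multipliers for `density_sweep`.
#' @param drug_factors drug factors for the rescue experiments.
#' @param window classification window (s).
#' @param ramp ramp schedule for dose measurements.
#' @param outdir optional output directory for CSV/JSON results.
#' @return list of class `prebotc_config`.
#' @export
experiment_config <- function(experiment, n_networks = 40, base_seed = 1,
                              dt = 0.05, d_avg = 6, mor_policy = "random",
                              g_syn_max = 3,
                              density_factors = c(1, 2, 4, 8, 16),
                              drug_factors = NULL, window = 60,
                              ramp = make_ramp_schedule(), outdir = NULL) {
  experiment <- match.arg(experiment,
    c("ramp_batch", "sensitivity_split", "density_sweep",
      "topology_correlation", "mor_policy", "gnap_rescue", "gleak_rescue",
      "phase_diagram"))
  if (is.null(drug_factors))
    drug_factors <- if (experiment == "gleak_rescue") c(0.9, 0.7, 0.5)
                    else c(1.1, 1.3, 1.5)
  structure(list(experiment = experiment, n_networks = n_networks,
                 base_seed = base_seed, dt = dt, d_avg = d_avg,
                 mor_policy = mor_policy, g_syn_max = g_syn_max,
                 density_factors = density_factors,
                 drug_factors = drug_factors, window = window, ramp = ramp,
                 outdir = outdir),
            class = "prebotc_config")
}

batch_networks <- function(cfg, mor_policy = cfg$mor_policy) {
  lapply(seq_len(cfg$n_networks), function(i)
    build_network(d_avg = cfg$d_avg, mor_policy = mor_policy,
                  g_syn_max = cfg$g_syn_max, seed = cfg$base_seed + i - 1))
}

batch_doses <- function(nets, cfg) {
  vapply(seq_along(nets), function(i) {
    d <- tryCatch(
      measure_shutdown_dose(nets[[i]], schedule = cfg$ramp,
                            dt = cfg$dt)$dose,
      error = function(e) {
        message(sprintf("network %d: %s", i, conditionMessage(e)))
        NA_real_
      })
    d
  }, numeric(1))
}

#' Run a full experiment
#'
#' Orchestrates the batch experiments end-to-end from a configuration:
#' network generation, protocol execution, analysis, and result tables.
#' Per-network failures are reported as `NA` rows with a message, never
#' silently dropped. If `cfg$outdir` is set, every table is also written as
#' CSV together with a JSON summary and a config echo.
#'
#' @param cfg an [experiment_config()].
#' @return list of result data.frames (contents depend on the experiment)
#'   plus a `summary` element.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "prebotc_config"))
  res <- switch(cfg$experiment,
    ramp_batch = exp_ramp_batch(cfg),
    sensitivity_split = exp_sensitivity_split(cfg),
    density_sweep = exp_density_sweep(cfg),
    topology_correlation = exp_topology_correlation(cfg),
    mor_policy = exp_mor_policy(cfg),
    gnap_rescue = exp_rescue(cfg, "gnap"),
    gleak_rescue = exp_rescue(cfg, "gleak"),
    phase_diagram = exp_phase_diagram(cfg))
  if (!is.null(cfg$outdir)) write_experiment(res, cfg)
  res
}

exp_ramp_batch <- function(cfg) {
  nets <- batch_networks(cfg)
  doses <- batch_doses(nets, cfg)
  per_network <- data.frame(seed = cfg$base_seed + seq_len(cfg$n_networks) - 1,
                            dose = doses)
  list(doses = per_network,
       summary = data.frame(n = sum(!is.na(doses)),
                            mean = mean(doses, na.rm = TRUE),
                            min = min(doses, na.rm = TRUE),
                            max = max(doses, na.rm = TRUE),
                            sd = sd(doses, na.rm = TRUE)))
}

exp_sensitivity_split <- function(cfg) {
  nets <- batch_networks(cfg)
  doses <- batch_doses(nets, cfg)
  med <- median(doses, na.rm = TRUE)
  # high sensitivity = rhythm lost at a LOW dose (below-median shutdown dose)
  sens <- ifelse(doses <= med, "high", "low")
  comp <- lapply(seq_along(nets), function(i) {
    for_mod <- list(control = modulation_state(),
                    opioid = modulation_state(I_hyp_op = 4, g_syn_op = 0.5))
    do.call(rbind, lapply(names(for_mod), function(cond) {
      cl <- classify_network(nets[[i]], for_mod[[cond]], window = cfg$window,
                             dt = cfg$dt)
      cnt <- table(cl$labels)
      data.frame(seed = cfg$base_seed + i - 1, sensitivity = sens[i],
                 condition = cond, dose = doses[i],
                 silent = cnt[["silent"]], bursting = cnt[["bursting"]],
                 tonic = cnt[["tonic"]])
    }))
  })
  list(doses = data.frame(seed = cfg$base_seed + seq_along(nets) - 1,
                          dose = doses, sensitivity = sens),
       composition = do.call(rbind, comp),
       summary = data.frame(median_dose = med))
}

exp_density_sweep <- function(cfg) {
  nets <- batch_networks(cfg)
  rows <- lapply(seq_along(nets), function(i) {
    do.call(rbind, lapply(cfg$density_factors, function(f) {
      net <- scale_density(nets[[i]], f)
      d <- tryCatch(measure_shutdown_dose(net, schedule = cfg$ramp,
                                          dt = cfg$dt)$dose,
                    error = function(e) NA_real_)
      data.frame(seed = cfg$base_seed + i - 1, factor = f,
                 density_pct = 100 * (net$d_avg / 2) / (net$N - 1),
                 total_strength = sum(net$edges$g_syn_max), dose = d)
    }))
  })
  doses <- do.call(rbind, rows)
  list(doses = doses,
       summary = do.call(rbind, lapply(split(doses, doses$factor), function(d)
         data.frame(factor = d$factor[1], n = sum(!is.na(d$dose)),
                    mean = mean(d$dose, na.rm = TRUE)))))
}

exp_topology_correlation <- function(cfg) {
  nets <- batch_networks(cfg)
  doses <- batch_doses(nets, cfg)
  labs <- lapply(nets, classify_network, mod = modulation_state(),
                 window = cfg$window, dt = cfg$dt)
  ok <- !is.na(doses)
  grids <- lapply(c(ei = "ei", mor = "mor", intrinsic_mor = "intrinsic_mor"),
                  function(sc)
    connectivity_dose_correlation(nets[ok], doses[ok], scheme = sc,
                                  labels_list = labs[ok]))
  c(grids, list(doses = data.frame(seed = cfg$base_seed + seq_along(nets) - 1,
                                   dose = doses),
                summary = data.frame(n = sum(ok))))
}

exp_mor_policy <- function(cfg) {
  policies <- c("random", "low_gleak", "high_gleak")
  rows <- list()
  for (i in seq_len(cfg$n_networks)) {
    seed <- cfg$base_seed + i - 1
    for (pol in policies) {
      # matched seeds: the three policies share topology and conductances
      net <- build_network(d_avg = cfg$d_avg, mor_policy = pol,
                           g_syn_max = cfg$g_syn_max, seed = seed)
      d <- tryCatch(measure_shutdown_dose(net, schedule = cfg$ramp,
                                          dt = cfg$dt)$dose,
                    error = function(e) NA_real_)
      cl_op <- classify_network(net, modulation_state(I_hyp_op = 4,
                                                      g_syn_op = 0.5),
                                window = cfg$window, dt = cfg$dt)
      cl_ct <- classify_network(net, modulation_state(),
                                window = cfg$window, dt = cfg$dt)
      rows[[length(rows) + 1]] <- data.frame(
        seed = seed, policy = pol, dose = d,
        silent_control = intrinsic_composition(cl_ct)[["silent"]],
        silent_opioid = intrinsic_composition(cl_op)[["silent"]],
        tonic_control = intrinsic_composition(cl_ct)[["tonic"]],
        tonic_opioid = intrinsic_composition(cl_op)[["tonic"]])
    }
  }
  tab <- do.call(rbind, rows)
  list(doses = tab,
       summary = do.call(rbind, lapply(split(tab, tab$policy), function(d)
         data.frame(policy = d$policy[1], mean_dose = mean(d$dose, na.rm = TRUE),
                    mean_silent_opioid = mean(d$silent_opioid)))))
}

exp_rescue <- function(cfg, drug) {
  rows <- list()
  comp_rows <- list()
  for (i in seq_len(cfg$n_networks)) {
    seed <- cfg$base_seed + i - 1
    net <- build_network(d_avg = cfg$d_avg, mor_policy = cfg$mor_policy,
                         g_syn_max = cfg$g_syn_max, seed = seed)
    for (f in cfg$drug_factors) {
      sch <- make_perturbation_schedule(drug = drug, factor = f)
      sim <- integrate_network(net, sch, dt = cfg$dt)
      rate <- population_rate(sim$spikes, net$N, sim$duration)
      bursts <- detect_bursts(rate)
      win <- schedule_windows(sch)
      for (k in seq_len(nrow(win))) {
        st <- burst_stats(bursts, c(win$start[k], win$end[k]))
        rows[[length(rows) + 1]] <- data.frame(
          seed = seed, drug = drug, factor = f, segment = win$segment[k],
          frequency = st$frequency, amplitude = st$amplitude,
          n_bursts = st$n_bursts)
      }
      # intrinsic composition under the combined opioid + drug state
      mod <- modulation_state(
        D_NaP = if (drug == "gnap") f else 1,
        D_leak = if (drug == "gleak") f else 1,
        g_syn_op = 0.5, I_hyp_op = 4)
      cl <- classify_network(net, mod, window = cfg$window, dt = cfg$dt)
      pc <- intrinsic_composition(cl)
      comp_rows[[length(comp_rows) + 1]] <- data.frame(
        seed = seed, drug = drug, factor = f,
        silent = pc[["silent"]], bursting = pc[["bursting"]],
        tonic = pc[["tonic"]])
    }
  }
  stats <- do.call(rbind, rows)
  comp <- do.call(rbind, comp_rows)
  list(burst_stats = stats, composition = comp,
       summary = do.call(rbind,
         lapply(split(stats, list(stats$factor, stats$segment), drop = TRUE),
                function(d) data.frame(factor = d$factor[1],
                                       segment = d$segment[1],
                                       mean_frequency = mean(d$frequency),
                                       mean_amplitude = mean(d$amplitude,
                                                             na.rm = TRUE)))))
}

exp_phase_diagram <- function(cfg) {
  ctl <- phase_diagram(modulation_state(), window = cfg$window, dt = cfg$dt)
  op <- phase_diagram(modulation_state(I_hyp_op = 8), window = cfg$window,
                      dt = cfg$dt)
  ctl$condition <- "control"
  op$condition <- "opioid"
  grid <- rbind(ctl, op)
  list(grid = grid,
       summary = as.data.frame(table(condition = grid$condition,
                                     label = grid$label)))
}

write_experiment <- function(res, cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res)) {
    if (is.data.frame(res[[nm]]))
      write.csv(res[[nm]], file.path(cfg$outdir,
                                     paste0(cfg$experiment, "_", nm, ".csv")),
                row.names = FALSE)
  }
  echo <- cfg
  echo$ramp <- NULL
  writeLines(paste(names(echo), vapply(echo, function(x)
    paste(format(x), collapse = ","), ""), sep = ": "),
    file.path(cfg$outdir, paste0(cfg$experiment, "_config.txt")))
  if (requireNamespace("jsonlite", quietly = TRUE) &&
      !is.null(res$summary)) {
    jsonlite::write_json(res$summary,
                         file.path(cfg$outdir,
                                   paste0(cfg$experiment, "_summary.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(cfg$outdir)
}

#' Synthetic population-rate fixture with known shutdown dose
#'
#' Builds a rate trace as a sum of Gaussian bumps at given times and heights
#' (plus optional white noise) together with the analytically known shutdown
#' dose under an attached ramp schedule: for each amplitude threshold the
#' last bump at or above it determines the `I_hyp_op` lookup, exactly as in
#' [shutdown_dose()]. Used to test the analysis layer against ground truth.
#'
#' @param burst_times bump centers (s).
#' @param heights bump heights (Hz/cell, recycled).
#' @param ramp a ramp schedule (default [make_ramp_schedule()]).
#' @param width_s Gaussian bump width (s).
#' @param noise_sd white-noise sd (Hz/cell); 0 for a clean trace.
#' @param bin_s trace resolution (s).
#' @param thresholds amplitude thresholds for the ground-truth dose.
#' @param seed RNG seed for the noise.
#' @return list with `rate` (a `prebotc_rate`-shaped data.frame),
#'   `true_dose` (pA; `NA` if no bump reaches any threshold) and the
#'   attached `ramp`.
#' @export
make_synthetic_rate_fixture <- function(burst_times, heights, ramp = NULL,
                                        width_s = 0.15, noise_sd = 0,
                                        bin_s = 0.01, thresholds = 10:15,
                                        seed = 1) {
  if (any(heights < 0)) stop("burst heights must be nonnegative")
  if (is.null(ramp)) ramp <- make_ramp_schedule()
  heights <- rep_len(heights, length(burst_times))
  duration <- attr(ramp, "duration")
  # sample on multiples of bin_s so bump centers placed on the grid attain
  # their exact heights and times
  tt <- seq(0, duration, by = bin_s)
  rate <- numeric(length(tt))
  for (k in seq_along(burst_times))
    rate <- rate + heights[k] * exp(-0.5 * ((tt - burst_times[k]) / width_s)^2)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    rate <- pmax(0, rate + rnorm(length(tt), 0, noise_sd))
  }
  per_th <- vapply(thresholds, function(th) {
    hit <- burst_times[heights >= th]
    if (!length(hit)) NA_real_
    else schedule_value(ramp, max(hit), "I_hyp_op")
  }, numeric(1))
  out <- data.frame(time = tt, rate = rate)
  attr(out, "bin_ms") <- bin_s * 1000
  attr(out, "smooth_sigma_ms") <- 0
  class(out) <- c("prebotc_rate", "data.frame")
  list(rate = out,
       true_dose = if (all(is.na(per_th))) NA_real_
                   else mean(per_th, na.rm = TRUE),
       ramp = ramp)
}
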