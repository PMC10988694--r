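#' Full model configuration
#'
#' Bundles every tunable of the pipeline: stimulus, intrafusal fibre rate
#' scales, transduction weights, morphology multipliers, channel-density
#' table, solver settings and spike-detection settings.  The default is
#' the calibrated base model: transduction weights were fitted once (see
#' [fit_base_model()]) so that the default 20 mm/s ramp produces the
#' prototypical Ia profile (initial burst > 100 pps, peak dynamic >
#' static average > 0) and are held fixed for all simulations.
#'
#' @param stimulus A [ramp_spec()].
#' @param bag,chain Lists with `rate_scale` multipliers on the
#'   cross-bridge rates.
#' @param transduction List of receptor-potential parameters (see
#'   [receptor_params()]).
#' @param morphology List with `terminal_length_multiplier` and
#'   `preterminal_length_multiplier`.
#' @param densities Region-to-density table (see
#'   [default_density_table()]).
#' @param channels Named list of per-channel parameter overrides passed
#'   to [spindle_channels()].
#' @param sim List with `dt_ms`, `settle_ms` and the calcium-pool
#'   coupling (`ca_tau_ms`, `ca_phi`).
#' @param features List with spike `threshold_mV` and `min_isi_ms`.
#' @return An object of class `spindle_config`.
#' @export
base_config <- function(stimulus = ramp_spec(),
                        bag = list(rate_scale = 1),
                        chain = list(rate_scale = 8),
                        transduction = list(kfb = 0.06, kyb = 0.0017,
                                            kfc = 0.06, scale = 2e5,
                                            e_rev_mV = 0),
                        morphology = list(terminal_length_multiplier = 1,
                                          preterminal_length_multiplier = 1),
                        densities = default_density_table(),
                        channels = list(),
                        sim = list(dt_ms = 0.0125, settle_ms = 500,
                                   ca_tau_ms = 50, ca_phi = 0.27),
                        features = list(threshold_mV = -20,
                                        min_isi_ms = 1)) {
  structure(list(stimulus = stimulus, bag = bag, chain = chain,
                 transduction = transduction, morphology = morphology,
                 densities = densities, channels = channels, sim = sim,
                 features = features),
            class = "spindle_config")
}

#' Short provenance hash of a configuration
#'
#' Polynomial hash over the serialized object; embedded in every sweep
#' point so a result can be traced to the exact configuration.
#'
#' @param x Any R object.
#' @return 8-hex-digit string.
#' @export
config_hash <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (i in seq(1, length(b), by = 64)) {
    chunk <- b[i:min(i + 63, length(b))]
    h <- (h * 33 + sum(chunk * seq_along(chunk))) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Compute the receptor drive for a configuration
#'
#' Runs the bag and chain cross-bridge simulations for the stimulus and
#' applies the transduction stage.  The drive depends only on the
#' stimulus, fibre and transduction settings, so morphology and
#' conductance sweeps can reuse one precomputed drive.
#'
#' @param config A `spindle_config`.
#' @param stim Optional precomputed `stretch_stimulus`.
#' @return A `drive_signal`.
#' @export
compute_drive <- function(config, stim = NULL) {
  if (is.null(stim)) stim <- make_ramp_hold_release(config$stimulus)
  bag <- simulate_fiber(bag_fiber_params(config$bag$rate_scale), stim)
  chain <- simulate_fiber(chain_fiber_params(config$chain$rate_scale), stim)
  tp <- config$transduction
  compute_receptor_drive(bag, chain,
                         receptor_params(kfb = tp$kfb, kyb = tp$kyb,
                                         kfc = tp$kfc, scale = tp$scale,
                                         e_rev_mV = tp$e_rev_mV))
}

#' Run the full spindle pipeline for one configuration
#'
#' Stimulus -> intrafusal forces -> receptor drive -> multicompartment
#' simulation -> spike detection at the output node (node5) -> encoding
#' features.  Identical configurations give byte-identical features (the
#' pipeline is fully deterministic).
#'
#' @param config A `spindle_config`.
#' @param stim,drive Optional precomputed stimulus/drive (reused across
#'   sweep points).
#' @param record Probe sites to record.
#' @return List with `features`, `spikes`, `ifr`, `sim` (the
#'   `sim_result`), `irregular` (hold-phase ISI coefficient of variation
#'   > 0.3), `hold_cv`, `stim`, `drive` and `config_hash`.
#' @export
run_spindle <- function(config, stim = NULL, drive = NULL,
                        record = c("terminal", "heminode", "node5")) {
  stopifnot(inherits(config, "spindle_config"))
  if (is.null(stim)) stim <- make_ramp_hold_release(config$stimulus)
  if (is.null(drive)) drive <- compute_drive(config, stim)
  graph <- build_morphology(morphology_config(
    terminal_length_multiplier = config$morphology$terminal_length_multiplier,
    preterminal_length_multiplier = config$morphology$preterminal_length_multiplier))
  graph <- assign_channels(graph, config$densities,
                           channels = spindle_channels(
                             if (is.null(config$channels)) list()
                             else config$channels))
  scfg <- sim_config(dt_ms = config$sim$dt_ms,
                     settle_ms = config$sim$settle_ms, record = record)
  if (!is.null(config$sim$ca_tau_ms)) scfg$ca_tau_ms <- config$sim$ca_tau_ms
  if (!is.null(config$sim$ca_phi)) scfg$ca_phi <- config$sim$ca_phi
  sim <- simulate_afferent(graph, drive, scfg)
  spikes <- detect_spikes(sim$t_s, sim$V[, "node5"],
                          threshold_mV = config$features$threshold_mV,
                          min_isi_ms = config$features$min_isi_ms)
  feats <- extract_features(spikes, config$stimulus)
  ph <- stimulus_phases(config$stimulus)
  hold_isi <- diff(spikes$times[spikes$times > ph$hold_on &
                                  spikes$times <= ph$release_on])
  cv <- if (length(hold_isi) >= 3)
    stats::sd(hold_isi) / mean(hold_isi) else NA_real_
  list(features = feats, spikes = spikes,
       ifr = instantaneous_rate(spikes), sim = sim,
       irregular = is.na(cv) || cv > 0.3, hold_cv = cv,
       stim = stim, drive = drive, config_hash = config_hash(config))
}

feature_vec <- function(f) {
  c(initial_burst_pps = f$initial_burst_pps,
    peak_dynamic_pps = f$peak_dynamic_pps,
    static_avg_pps = f$static_avg_pps)
}

#' Calibrate the base model to a prototypical Ia response
#'
#' Bounded derivative-free (Nelder-Mead on log-parameters) minimization
#' of the summed squared relative feature errors against a prototypical
#' response target.  If the starting configuration already meets the
#' targets within `rel_tol` it is returned unchanged (zero iterations).
#' The fitted configuration must produce an initial burst above 100 pps
#' and peak dynamic > static average > 0; otherwise a calibration-failure
#' report (with the best point found) is returned with
#' `converged = FALSE`.
#'
#' @param targets Named vector with `initial_burst_pps`,
#'   `peak_dynamic_pps`, `static_avg_pps`.
#' @param free Character vector of free parameters, a subset of
#'   `c("kfb", "kyb", "kfc", "scale", "bag_rate_scale",
#'   "chain_rate_scale")`.
#' @param config Starting `spindle_config`.
#' @param rel_tol Acceptable relative error per feature.
#' @param maxit Nelder-Mead iteration cap.
#' @return List with `config`, `features`, `converged`, `iterations`,
#'   `objective`.
#' @export
fit_base_model <- function(targets = c(initial_burst_pps = 150,
                                       peak_dynamic_pps = 120,
                                       static_avg_pps = 70),
                           free = c("kfb", "kyb", "kfc"),
                           config = base_config(),
                           rel_tol = 0.15, maxit = 40) {
  allowed <- c("kfb", "kyb", "kfc", "scale", "bag_rate_scale",
               "chain_rate_scale")
  stopifnot(all(free %in% allowed))
  get_par <- function(cfg, nm) switch(nm,
    bag_rate_scale = cfg$bag$rate_scale,
    chain_rate_scale = cfg$chain$rate_scale,
    cfg$transduction[[nm]])
  set_par <- function(cfg, nm, v) {
    if (nm == "bag_rate_scale") cfg$bag$rate_scale <- v
    else if (nm == "chain_rate_scale") cfg$chain$rate_scale <- v
    else cfg$transduction[[nm]] <- v
    cfg
  }
  stim <- make_ramp_hold_release(config$stimulus)
  objective <- function(cfg) {
    f <- feature_vec(run_spindle(cfg, stim = stim)$features)
    rel <- (f[names(targets)] - targets) / targets
    list(obj = sum(rel^2), feats = f, rel = rel)
  }
  o0 <- objective(config)
  if (all(abs(o0$rel) <= rel_tol)) {
    return(list(config = config, features = o0$feats, converged = TRUE,
                iterations = 0L, objective = o0$obj))
  }
  x0 <- log(vapply(free, function(nm) get_par(config, nm), 0))
  fn <- function(x) {
    cfg <- config
    for (i in seq_along(free)) cfg <- set_par(cfg, free[i], exp(x[i]))
    tryCatch(objective(cfg)$obj, error = function(e) 1e6)
  }
  opt <- stats::optim(x0, fn, method = "Nelder-Mead",
                      control = list(maxit = maxit))
  cfg <- config
  for (i in seq_along(free)) cfg <- set_par(cfg, free[i], exp(opt$par[i]))
  of <- objective(cfg)
  ok <- of$feats["initial_burst_pps"] > 100 &&
    of$feats["peak_dynamic_pps"] > of$feats["static_avg_pps"] &&
    of$feats["static_avg_pps"] > 0 && all(abs(of$rel) <= rel_tol)
  list(config = cfg, features = of$feats, converged = ok,
       iterations = opt$counts[["function"]], objective = of$obj)
}

#' Sweep terminal or preterminal length
#'
#' One full simulation per multiplier, reusing a single precomputed
#' receptor drive (architecture does not feed back onto the intrafusal
#' mechanics).  Percent changes use the reduction-positive convention.
#'
#' @param param `"terminal"` or `"preterminal"`.
#' @param multipliers Length multipliers (the base point 1 is added if
#'   absent).
#' @param config Base `spindle_config`.
#' @param drive Optional precomputed drive.
#' @return A `sweep_result` data frame with features, percent changes vs
#'   base, failure/irregularity flags and per-point config hashes; the
#'   base features are attached as attribute `base`.
#' @export
sweep_morphology <- function(param = c("terminal", "preterminal"),
                             multipliers, config = base_config(),
                             drive = NULL) {
  param <- match.arg(param)
  stopifnot(length(multipliers) >= 1, all(is.finite(multipliers)))
  if (!any(multipliers == 1)) multipliers <- sort(c(1, multipliers))
  if (is.null(drive)) drive <- compute_drive(config)
  field <- paste0(param, "_length_multiplier")
  rows <- lapply(multipliers, function(m) {
    cfg <- config
    cfg$morphology[[field]] <- m
    out <- tryCatch(run_spindle(cfg, drive = drive), error = identity)
    if (inherits(out, "error")) {
      data.frame(multiplier = m, initial_burst_pps = NA,
                 peak_dynamic_pps = NA, static_avg_pps = NA,
                 static_failure = NA, irregular = NA, hold_cv = NA,
                 error = conditionMessage(out),
                 config_hash = config_hash(cfg))
    } else {
      f <- out$features
      data.frame(multiplier = m,
                 initial_burst_pps = f$initial_burst_pps,
                 peak_dynamic_pps = f$peak_dynamic_pps,
                 static_avg_pps = f$static_avg_pps,
                 static_failure = "static failure" %in% f$flags,
                 irregular = out$irregular, hold_cv = out$hold_cv,
                 error = NA_character_,
                 config_hash = out$config_hash)
    }
  })
  res <- do.call(rbind, rows)
  base <- res[res$multiplier == 1, ]
  for (nm in c("initial_burst_pps", "peak_dynamic_pps", "static_avg_pps")) {
    res[[paste0("pct_", nm)]] <-
      ifelse(base[[nm]] > 0, 100 * (base[[nm]] - res[[nm]]) / base[[nm]], NA)
  }
  attr(res, "base") <- base
  attr(res, "param") <- param
  class(res) <- c("sweep_result", class(res))
  res
}

#' 2-D sweep over terminal Nav1.6 and KCNQ densities
#'
#' Simulates every grid cell with the terminal Nav1.6 density (pS/um2)
#' and terminal KCNQ density (S/cm2) replaced by the grid values, all
#' else held at the configuration's values.
#'
#' @param nav16_grid Terminal Nav1.6 densities (pS/um2).
#' @param kcnq_grid Terminal KCNQ densities (S/cm2).
#' @param config Base `spindle_config`.
#' @param drive Optional precomputed drive.
#' @return A `sweep_result` data frame (one row per cell) with the base
#'   cell features attached as attribute `base`.
#' @export
sweep_conductance_2d <- function(nav16_grid, kcnq_grid,
                                 config = base_config(), drive = NULL) {
  stopifnot(length(nav16_grid) >= 1, length(kcnq_grid) >= 1)
  if (is.null(drive)) drive <- compute_drive(config)
  base_out <- run_spindle(config, drive = drive)
  bf <- feature_vec(base_out$features)
  cells <- expand.grid(nav16 = nav16_grid, kcnq = kcnq_grid)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- conductance_cell_config(config, cells$nav16[i], cells$kcnq[i])
    out <- tryCatch(run_spindle(cfg, drive = drive), error = identity)
    if (inherits(out, "error")) {
      data.frame(nav16 = cells$nav16[i], kcnq = cells$kcnq[i],
                 initial_burst_pps = NA, peak_dynamic_pps = NA,
                 static_avg_pps = NA, static_failure = NA,
                 irregular = NA, error = conditionMessage(out),
                 config_hash = config_hash(cfg))
    } else {
      f <- out$features
      data.frame(nav16 = cells$nav16[i], kcnq = cells$kcnq[i],
                 initial_burst_pps = f$initial_burst_pps,
                 peak_dynamic_pps = f$peak_dynamic_pps,
                 static_avg_pps = f$static_avg_pps,
                 static_failure = "static failure" %in% f$flags,
                 irregular = out$irregular, error = NA_character_,
                 config_hash = out$config_hash)
    }
  })
  res <- do.call(rbind, rows)
  for (nm in names(bf))
    res[[paste0("pct_", nm)]] <-
      ifelse(bf[nm] > 0, 100 * (bf[nm] - res[[nm]]) / bf[nm], NA)
  attr(res, "base") <- bf
  class(res) <- c("sweep_result", class(res))
  res
}

#' Configuration for one cell of the terminal-conductance grid
#'
#' @param config Base `spindle_config`.
#' @param nav16_ps_um2 Terminal Nav1.6 density (pS/um2).
#' @param kcnq_S_cm2 Terminal KCNQ density (S/cm2).
#' @return The modified configuration.
#' @export
conductance_cell_config <- function(config, nav16_ps_um2, kcnq_S_cm2) {
  cfg <- config
  cfg$densities$terminal["nav16"] <- nav16_ps_um2
  cfg$densities$terminal["kcnq"] <- kcnq_S_cm2
  cfg
}

#' Locate and measure the static-firing phase transition
#'
#' For each KCNQ level of a 2-D sweep that contains both static-failed
#' and static-competent cells, bisects the Nav1.6 density between the
#' last failed and first competent cell down to `tol` (pS/um2), then
#' measures the transition width: the Nav1.6 span over which the static
#' rate rises from 10% to 90% of its local plateau (the rate at the top
#' of the scanned range).
#'
#' @param grid A `sweep_result` from [sweep_conductance_2d()] (or any
#'   data frame with `nav16`, `kcnq`, `static_avg_pps`,
#'   `static_failure`).
#' @param simulate_fn Function `(nav16, kcnq) -> static rate (pps)` used
#'   for refinement; defaults to running the model from `config`.
#' @param config,drive Base configuration/drive for the default
#'   `simulate_fn`.
#' @param tol Bisection tolerance (pS/um2).
#' @return List of per-KCNQ-row reports (`kcnq`, `boundary_ps_um2`,
#'   `width_ps_um2`, `plateau_pps`), or a `"not found"` report when no
#'   row contains a transition.
#' @export
find_phase_transition <- function(grid, simulate_fn = NULL,
                                  config = base_config(), drive = NULL,
                                  tol = 0.1) {
  if (is.null(simulate_fn)) {
    if (is.null(drive)) drive <- compute_drive(config)
    simulate_fn <- function(nav16, kcnq) {
      cfg <- conductance_cell_config(config, nav16, kcnq)
      out <- run_spindle(cfg, drive = drive)
      out$features$static_avg_pps
    }
  }
  memo <- new.env(parent = emptyenv())
  s_at <- function(nav16, kcnq) {
    key <- paste(nav16, kcnq)
    if (is.null(memo[[key]])) memo[[key]] <- simulate_fn(nav16, kcnq)
    memo[[key]]
  }
  reports <- list()
  for (kv in sort(unique(grid$kcnq))) {
    row <- grid[grid$kcnq == kv, ]
    row <- row[order(row$nav16), ]
    failed <- row$static_failure | row$static_avg_pps <= 0
    if (all(failed, na.rm = TRUE) || !any(failed, na.rm = TRUE)) next
    i_fail <- max(which(failed))
    if (i_fail == nrow(row)) next       # fails at the top: no upward transition
    lo <- row$nav16[i_fail]; hi <- row$nav16[i_fail + 1]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (s_at(mid, kv) > 0) hi <- mid else lo <- mid
    }
    boundary <- (lo + hi) / 2
    top <- max(row$nav16)
    plateau <- s_at(top, kv)
    if (plateau <= 0) next
    # width: Nav1.6 span carrying the static rate from 10% to 90% of the
    # local plateau, each located by bisection (assumes a monotone rise)
    x_at <- function(frac) {
      target <- frac * plateau
      lo2 <- max(boundary - tol, min(row$nav16)); hi2 <- top
      if (s_at(lo2, kv) >= target) return(lo2)
      while (hi2 - lo2 > tol) {
        mid <- (lo2 + hi2) / 2
        if (s_at(mid, kv) >= target) hi2 <- mid else lo2 <- mid
      }
      (lo2 + hi2) / 2
    }
    reports[[length(reports) + 1L]] <-
      list(kcnq = kv, boundary_ps_um2 = boundary,
           width_ps_um2 = x_at(0.9) - x_at(0.1),
           plateau_pps = plateau)
  }
  if (!length(reports)) return(list(found = FALSE, reason = "not found"))
  c(list(found = TRUE), reports = list(reports))
}

#' Remove a channel from every region of a configuration
#'
#' @param config A `spindle_config`.
#' @param channel_name One of the channel names in the density table.
#' @return The modified configuration.
#' @export
channel_knockout <- function(config, channel_name) {
  known <- unique(unlist(lapply(config$densities, names)))
  if (!channel_name %in% known)
    stop("unknown channel: ", channel_name)
  for (reg in names(config$densities))
    config$densities[[reg]][channel_name] <- 0
  config
}

#' Read/write a configuration as YAML
#'
#' @param path File path.
#' @param config A `spindle_config`.
#' @return `read_spindle_config` returns a `spindle_config`;
#'   `write_spindle_config` returns `path` invisibly.
#' @export
write_spindle_config <- function(config, path) {
  x <- unclass(config)
  x$stimulus <- unclass(x$stimulus)
  x$densities <- lapply(x$densities, as.list)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_spindle_config
#' @export
read_spindle_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$stimulus <- do.call(ramp_spec, x$stimulus)
  x$densities <- lapply(x$densities, unlist)
  do.call(base_config, x)
}
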