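# Memoised simulation cache shared across test files.  Full afferent
# simulations take ~10 s each; every test that needs one goes through
# this cache so repeated use is free.

.sim_cache <- new.env(parent = emptyenv())

cache_get <- function(key, fn) {
  if (!exists(key, envir = .sim_cache)) assign(key, fn(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

cached_drive <- function() {
  cache_get("drive", function() compute_drive(base_config()))
}

cached_run <- function(key, mutate = identity) {
  cache_get(key, function() {
    cfg <- mutate(base_config())
    run_spindle(cfg, drive = cached_drive())
  })
}

cached_base <- function() cached_run("base")

# shortened protocol used for the dt-convergence check (full spatial
# resolution, shorter hold)
short_spec <- function() ramp_spec(baseline_s = 0.1, amplitude_mm = 3,
                                   velocity_mm_per_s = 20, hold_s = 0.3,
                                   post_s = 0.1)

cached_dt_pair <- function() {
  cache_get("dt_pair", function() {
    cfg <- base_config(stimulus = short_spec())
    drv <- compute_drive(cfg)
    run_at <- function(dt) {
      cfg$sim$dt_ms <- dt
      run_spindle(cfg, drive = drv)
    }
    list(coarse = run_at(0.0125), fine = run_at(0.00625))
  })
}

feats3 <- function(out) {
  f <- out$features
  c(burst = f$initial_burst_pps, dyn = f$peak_dynamic_pps,
    static = f$static_avg_pps)
}

pct3 <- function(test_out, base_out) {
  b <- feats3(base_out)
  100 * (b - feats3(test_out)) / b
}

corner_mutate <- function(nav16, kcnq) {
  function(cfg) conductance_cell_config(cfg, nav16, kcnq)
}

terminal_mutate <- function(m) function(cfg) {
  cfg$morphology$terminal_length_multiplier <- m
  cfg
}

preterminal_mutate <- function(m) function(cfg) {
  cfg$morphology$preterminal_length_multiplier <- m
  cfg
}
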