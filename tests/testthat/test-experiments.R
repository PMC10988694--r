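test_that("channel knockout zeroes every region and validates names", {
  cfg <- base_config()
  ko <- channel_knockout(cfg, "nav17")
  for (reg in names(ko$densities))
    expect_equal(unname(ko$densities[[reg]]["nav17"]), 0)
  expect_equal(ko$densities$terminal["nav11"],
               cfg$densities$terminal["nav11"])
  expect_error(channel_knockout(cfg, "navX"), "unknown channel")
  # knocking out a channel that is zero everywhere changes nothing
  kv1_free <- channel_knockout(cfg, "kv1")
  kv1_free$densities$paranode["kv1"] <- 0
  again <- channel_knockout(kv1_free, "kv1")
  expect_identical(again$densities, kv1_free$densities)
})

test_that("configuration YAML round-trips", {
  cfg <- base_config()
  path <- tempfile(fileext = ".yaml")
  write_spindle_config(cfg, path)
  back <- read_spindle_config(path)
  expect_equal(back$transduction, cfg$transduction)
  expect_equal(back$densities, cfg$densities)
  expect_equal(back$stimulus, cfg$stimulus)
  expect_equal(back$morphology, cfg$morphology)
})

test_that("config hash is stable and sensitive", {
  cfg <- base_config()
  expect_identical(config_hash(cfg), config_hash(base_config()))
  cfg2 <- cfg; cfg2$transduction$kfb <- cfg2$transduction$kfb * 1.01
  expect_false(identical(config_hash(cfg), config_hash(cfg2)))
})

test_that("phase-transition search recovers a synthetic step boundary", {
  step_at <- 17.3
  fake_sim <- function(nav16, kcnq) if (nav16 > step_at) 50 else 0
  grid <- expand.grid(nav16 = seq(0, 50, by = 5), kcnq = c(0.003))
  grid$static_avg_pps <- ifelse(grid$nav16 > step_at, 50, 0)
  grid$static_failure <- grid$static_avg_pps == 0
  rep <- find_phase_transition(grid, simulate_fn = fake_sim, tol = 0.1)
  expect_true(rep$found)
  expect_equal(rep$reports[[1]]$boundary_ps_um2, step_at, tolerance = 0.1)
  # a hard step has (near-)zero 10-90% width
  expect_lt(rep$reports[[1]]$width_ps_um2, 0.5)
})

test_that("phase-transition search reports not-found on an all-competent grid", {
  grid <- expand.grid(nav16 = seq(0, 50, by = 10), kcnq = c(0.001, 0.002))
  grid$static_avg_pps <- 60
  grid$static_failure <- FALSE
  rep <- find_phase_transition(grid, simulate_fn = function(a, b) 60)
  expect_false(rep$found)
})

test_that("morphology sweep reports 0% change at the base point", {
  sweep <- cache_get("sweep_m1", function()
    sweep_morphology("terminal", multipliers = 1, config = base_config(),
                     drive = cached_drive()))
  base_row <- sweep[sweep$multiplier == 1, ]
  expect_equal(base_row$pct_initial_burst_pps, 0)
  expect_equal(base_row$pct_peak_dynamic_pps, 0)
  expect_equal(base_row$pct_static_avg_pps, 0)
  expect_false(base_row$static_failure)
  expect_match(base_row$config_hash, "^[0-9a-f]{8}$")
})

test_that("calibration returns the starting configuration when targets are met", {
  base <- cached_base()
  f <- base$features
  targets <- c(initial_burst_pps = f$initial_burst_pps,
               peak_dynamic_pps = f$peak_dynamic_pps,
               static_avg_pps = f$static_avg_pps)
  fit <- fit_base_model(targets = targets,
                        free = c("kfb", "kyb", "kfc"),
                        config = base_config(), rel_tol = 0.01)
  expect_true(fit$converged)
  expect_identical(fit$iterations, 0L)
  expect_identical(fit$config, base_config())
})

test_that("identical configurations give identical features", {
  a <- cached_base()
  b <- run_spindle(base_config(), drive = cached_drive())
  expect_identical(feats3(a), feats3(b))
  expect_identical(a$spikes$times, b$spikes$times)
  expect_identical(a$config_hash, b$config_hash)
})
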