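const_rate_params <- function(f, g, ...) {
  fiber_params(f_attach = function(x) rep(f, length(x)),
               g_detach = function(x) rep(g, length(x)), ...)
}

test_that("isometric bound fraction matches the constant-rate closed form", {
  expect_equal(isometric_bound_fraction(const_rate_params(3, 1)), 0.75)
  expect_equal(isometric_bound_fraction(const_rate_params(2, 2)), 0.5)
  expect_error(isometric_bound_fraction(const_rate_params(0, 0)), "> 0")
  expect_error(isometric_bound_fraction(fiber_params()),
               "strain-independent")
})

test_that("all-zero state with zero activation is a fixed point", {
  p <- fiber_params(activation = 0)
  st <- fiber_state_init(p)
  expect_true(all(st$bound == 0))
  st2 <- step_fiber(st, p, delta_hsl = 0, dt = 1e-4)
  expect_equal(st2$bound, st$bound)
  expect_equal(st2$a_on, 0)
})

test_that("simulation relaxes to f/(f+g) bound fraction at full activation", {
  # a_on -> 1 requires k_off = 0 at activation 1
  p <- const_rate_params(3, 1, activation = 1, k_off = 0, k_coop = 0)
  st <- fiber_state_init(p)
  st$bound <- st$bound * 0.4             # perturb away from the fixed point
  for (i in 1:20000) st <- step_fiber(st, p, 0, 1e-4)
  B <- sum(st$bound * p$dx)
  expect_equal(B, isometric_bound_fraction(p), tolerance = 1e-3)
})

test_that("length change advects the bound density along the strain axis", {
  p <- const_rate_params(1e-6, 1e-6)     # kinetics negligible over one step
  st <- fiber_state_init(fiber_params())
  st$bound <- exp(-(fiber_params()$x - 1)^2 / 4)
  mean_strain <- function(b) sum(b * p$x) / sum(b)
  m0 <- mean_strain(st$bound)
  st2 <- step_fiber(st, p, delta_hsl = 2, dt = 1e-6)
  expect_equal(mean_strain(st2$bound), m0 + 2, tolerance = 0.02)
  # oracle: direct interpolation shift
  oracle <- approx(p$x + 2, st$bound, xout = p$x, rule = 1,
                   yleft = 0, yright = 0)$y
  expect_equal(st2$bound, oracle, tolerance = 1e-6)
})

test_that("zero stimulus gives constant isometric force and zero yank", {
  stim <- make_ramp_hold_release(ramp_spec(amplitude_mm = 0, baseline_s = 0.1,
                                           hold_s = 0, post_s = 0.1))
  tr <- simulate_fiber(bag_fiber_params(), stim)
  expect_gt(tr$force[1], 0)
  expect_lt(diff(range(tr$force)) / tr$force[1], 1e-6)
  expect_lt(max(abs(tr$yank)) / tr$force[1], 1e-3)
})

test_that("force is exactly linear in the cross-bridge number scale", {
  stim <- make_ramp_hold_release(ramp_spec(baseline_s = 0.05, hold_s = 0.1,
                                           post_s = 0.05))
  f1 <- simulate_fiber(bag_fiber_params(n_xb = 1), stim)
  f2 <- simulate_fiber(bag_fiber_params(n_xb = 2), stim)
  expect_equal(f2$force, 2 * f1$force, tolerance = 1e-12)
})

test_that("chain relaxes to its post-ramp force faster than bag", {
  stim <- make_ramp_hold_release(ramp_spec(baseline_s = 0.05, hold_s = 0.6,
                                           post_s = 0.05))
  ph <- stimulus_phases(ramp_spec(baseline_s = 0.05, hold_s = 0.6,
                                  post_s = 0.05))
  settle_time <- function(tr) {
    hold <- tr$t >= ph$hold_on & tr$t < ph$release_on
    f <- tr$force[hold]; tt <- tr$t[hold]
    target <- f[length(f)]
    dev0 <- abs(f[1] - target)
    i <- which(abs(f - target) <= 0.1 * dev0)[1]
    tt[i] - ph$hold_on
  }
  t_bag <- settle_time(simulate_fiber(bag_fiber_params(), stim))
  t_chain <- settle_time(simulate_fiber(chain_fiber_params(), stim))
  expect_lt(t_chain, t_bag)
})

test_that("bound mass stays within [0, a_on] throughout a ramp simulation", {
  p <- bag_fiber_params()
  stim <- make_ramp_hold_release(ramp_spec(baseline_s = 0.05, hold_s = 0.2,
                                           post_s = 0.05))
  dl <- c(0, diff(stim$length_mm)) * p$length_gain
  st <- fiber_state_init(p)
  ok <- TRUE
  for (i in 2:length(stim$t)) {
    st <- step_fiber(st, p, dl[i], stim$dt_s)
    B <- sum(st$bound * p$dx)
    ok <- ok && all(st$bound >= 0) && B <= st$a_on + 1e-9 && st$a_on <= 1
  }
  expect_true(ok)
})

test_that("bag ramp force exceeds the subsequent static plateau", {
  stim <- make_ramp_hold_release(ramp_spec())
  ph <- stimulus_phases(ramp_spec())
  tr <- simulate_fiber(bag_fiber_params(), stim)
  ramp <- tr$t >= ph$ramp_on & tr$t < ph$hold_on
  late_hold <- tr$t >= ph$release_on - 0.2 & tr$t < ph$release_on
  expect_gt(max(tr$force[ramp]), 1.2 * mean(tr$force[late_hold]))
})

test_that("halving dt and strain-bin width changes force by <1%", {
  spec <- ramp_spec(baseline_s = 0.05, hold_s = 0.2, post_s = 0.05)
  f_coarse <- simulate_fiber(bag_fiber_params(), make_ramp_hold_release(spec))
  spec_f <- spec; spec_f$dt_s <- spec$dt_s / 2
  f_fine <- simulate_fiber(bag_fiber_params(strain_grid = c(-10, 10, 321)),
                           make_ramp_hold_release(spec_f))
  # compare on the coarse grid
  ff <- approx(f_fine$t, f_fine$force, xout = f_coarse$t)$y
  expect_lt(max(abs(ff - f_coarse$force)) / max(f_coarse$force), 0.01)
})
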