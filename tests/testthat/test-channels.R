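test_that("HH gate steady states behave canonically", {
  kv1 <- chan_kv1()
  act <- kv1$gates[[1]]
  expect_equal(gate_steady_state(act, act$v_half)$x_inf, 0.5)
  expect_gt(gate_steady_state(act, 100)$x_inf, 0.999)
  V <- seq(-100, 40, 5)
  expect_true(all(diff(gate_steady_state(act, V)$x_inf) > 0))
  inact <- kv1$gates[[2]]                 # negative slope: decreasing
  expect_true(all(diff(gate_steady_state(inact, V)$x_inf) < 0))
  expect_true(all(gate_steady_state(act, V)$tau_ms > 0))
})

test_that("generator matrices have zero row sums and non-negative rates", {
  for (chan in spindle_channels()[c("nav11", "nav16", "nav17")]) {
    for (V in c(-90, -60, -30, 0, 40)) {
      Q <- markov_rate_matrix(chan, V)
      expect_lt(max(abs(rowSums(Q))), 1e-12)
      offdiag <- Q - diag(diag(Q))
      expect_true(all(offdiag >= 0))
    }
  }
})

test_that("two-state open/closed scheme has stationary open fraction a/(a+b)", {
  two <- markov_channel("two", c("C", "O"),
                        from = c(1, 2), to = c(2, 1),
                        rate_fns = list(function(V) rep(0.3, length(V)),
                                        function(V) rep(0.1, length(V))),
                        conducting = 2)
  p <- stationary_distribution(two, -50)
  expect_equal(unname(p[2]), 0.3 / 0.4, tolerance = 1e-12)
})

test_that("backward-Euler stepping converges to the linear-solve stationary state", {
  # backward Euler shares the generator's fixed point at any dt, so an
  # iterated relaxation must land on the direct solve to 1e-6.  Test
  # voltages span the afferent's operating range; at strongly
  # depolarized potentials the slow-inactivated pool becomes nearly
  # absorbing (recovery time constants of minutes), so equilibration by
  # stepping is not physically meaningful there.
  for (nm in c("nav16", "nav17")) {
    chan <- spindle_channels()[[nm]]
    for (V in c(-80, -65, -60, -50, -45)) {
      p <- channel_init(chan, -100)
      for (i in 1:500) p <- step_channel(p, chan, V, dt = 20)
      for (i in 1:2500) p <- step_channel(p, chan, V, dt = 200)
      expect_lt(max(abs(p - stationary_distribution(chan, V))), 1e-6)
    }
  }
})

test_that("stationary occupancy is a fixed point of the step operator", {
  chan <- chan_nav16()
  p0 <- stationary_distribution(chan, -55)
  p1 <- step_channel(p0, chan, -55, dt = 0.025)
  expect_lt(max(abs(p1 - p0)), 1e-9)
})

test_that("occupancy is conserved over a 10-s fluctuating-voltage trace", {
  # raw backward-Euler mass drift (before renormalization) stays tiny
  chan <- chan_nav16()
  dt <- 0.025
  n <- 400000L                     # 10 s at dt = 0.025 ms
  Vt <- -60 + 30 * sin(2 * pi * (1:n) * dt / 15)
  tr <- chan$transitions
  nt <- length(tr$from)
  ns <- chan$n
  # vectorized rate evaluation for all steps at once
  rates <- vapply(seq_len(nt), function(k) tr$fn[[k]](Vt), numeric(n))
  p <- stationary_distribution(chan, Vt[1])
  A0 <- diag(ns)
  ij_off <- cbind(tr$from, tr$to)
  worst <- 0
  for (i in seq_len(n)) {
    Q <- matrix(0, ns, ns)
    Q[ij_off] <- rates[i, ]
    diag(Q) <- -rowSums(Q)
    p <- solve(A0 - dt * t(Q), p)
    drift <- abs(sum(p) - 1)
    if (drift > worst) worst <- drift
  }
  expect_lt(worst, 1e-9)
  expect_true(all(p >= -1e-12))
})

test_that("HH update converges under dt halving on a voltage ramp", {
  chan <- chan_kcnq()
  run <- function(dt) {
    x <- channel_init(chan, -70)
    for (k in seq_len(round(20 / dt))) {
      x <- step_channel(x, chan, -70 + 2 * k * dt, dt = dt)  # 2 mV/ms ramp
    }
    x
  }
  e1 <- abs(run(0.2) - run(0.05))
  e2 <- abs(run(0.05) - run(0.0125))
  expect_lt(e2, e1 / 2)            # at least first-order convergence
})

test_that("SK activation follows calcium and decays at zero calcium", {
  sk <- chan_sk2()
  a <- channel_init(sk, -65, Ca = 0.4)
  expect_equal(a, 0.5)             # at the half-activation point
  for (i in 1:200) a <- step_channel(a, sk, -65, Ca = 0, dt = 5)
  expect_lt(a, 1e-6)
  expect_equal(channel_init(sk, -65, Ca = 0), 0)
})

test_that("channel current is zero at reversal and linear in area", {
  kv <- chan_kv33()
  st <- channel_init(kv, 0)
  expect_equal(channel_current(kv, st, V = kv$e_rev, g_density = 0.01,
                               area = 1e-6), 0)
  expect_equal(channel_current(kv, c(0), V = 0, g_density = 0.01,
                               area = 1e-6), 0)
  i1 <- channel_current(kv, st, V = 0, g_density = 0.01, area = 1e-6)
  i2 <- channel_current(kv, st, V = 0, g_density = 0.01, area = 2e-6)
  expect_equal(i2, 2 * i1)
  expect_error(channel_current(kv, st, 0, 0.01, area = 0), "area")
})

test_that("Kv3.3 activates at more depolarized potentials than Kv1", {
  open_at <- function(chan, V) {
    st <- channel_init(chan, V)
    channel_open_fraction(chan, st)
  }
  # at -35 mV Kv1 is substantially open, Kv3.3 nearly closed
  expect_gt(open_at(chan_kv1(), -35), 10 * open_at(chan_kv33(), -35))
  expect_gt(open_at(chan_kv33(), 20), 0.5)
})

test_that("KCNQ deactivates far more slowly than Kv3.3 at -60 mV", {
  relax <- function(chan, t_ms) {
    tr <- voltage_clamp(chan, holding_mV = 0,
                        steps = list(c(-60, t_ms)), dt_ms = 0.025)
    tr$open[nrow(tr)] / tr$open[1]
  }
  expect_lt(relax(chan_kv33(), 5), 0.05)   # gone within 5 ms
  expect_gt(relax(chan_kcnq(), 5), 0.7)    # mostly retained
})

test_that("voltage clamp is deterministic", {
  prot <- list(c(-20, 5), c(-80, 5), c(0, 5))
  a <- voltage_clamp(chan_nav16(), -80, prot)
  b <- voltage_clamp(chan_nav16(), -80, prot)
  expect_identical(a, b)
  expect_error(voltage_clamp(chan_nav16(), -80, list(c(0, 0))), "duration")
})

test_that("Nav1.6 enters slow inactivation from the open state", {
  # long depolarization, brief recovery, re-step: peak open reduced
  dt <- 0.025
  first <- voltage_clamp(chan_nav16(), -80, list(c(0, 5)), dt_ms = dt)
  paired <- voltage_clamp(chan_nav16(), -80,
                          list(c(0, 2000), c(-80, 20), c(0, 5)),
                          dt_ms = dt)
  seg <- paired[paired$t_ms > 2020, ]
  expect_lt(max(seg$open), 0.75 * max(first$open))
})

test_that("recovery from slow inactivation is slower than from fast inactivation", {
  recovered_peak <- function(depol_ms) {
    tr <- voltage_clamp(chan_nav16(), -80,
                        list(c(0, depol_ms), c(-80, 20), c(0, 5)),
                        dt_ms = 0.025)
    seg <- tr[tr$t_ms > depol_ms + 20, ]
    max(seg$open)
  }
  # 20 ms at -80 reprimes fast inactivation almost fully after a brief
  # pulse, but barely touches slow inactivation after a long one
  expect_gt(recovered_peak(5), 1.5 * recovered_peak(2000))
})

test_that("custom scheme rejects negative rates", {
  bad <- markov_channel("bad", c("C", "O"), from = c(1, 2), to = c(2, 1),
                        rate_fns = list(function(V) rep(-1, length(V)),
                                        function(V) rep(1, length(V))),
                        conducting = 2)
  expect_error(markov_rate_matrix(bad, -50), "negative")
})
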