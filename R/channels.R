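#' @name channels
#' @title Voltage-gated and calcium-dependent channel models
#'
#' @description
#' The Ia afferent model carries seven conductances with region-specific
#' densities: three sodium isoforms with Markov gating schemes (a 10-state
#' Nav1.1 and a 10-state Nav1.6, each with two slow-inactivated states --
#' for Nav1.6 one entered from the open state and one from the
#' fast-inactivated state -- and a 6-state Nav1.7), three
#' Hodgkin-Huxley-type potassium channels (low-threshold slowly
#' inactivating Kv1, high-threshold fast Kv3.3, and the slow
#' non-inactivating KCNQ M-current), and a calcium-gated SK2 conductance
#' with Hill activation.  Channel topologies follow the published
#' descriptions; rate parameters are standard mammalian kinetics (a 3x
#' temperature factor over the classical squid rates for the Na ladders)
#' and are fully exposed so the calibration layer can retune them.
#'
#' All rates are in 1/ms, voltages in mV, time constants in ms.
NULL

# temperature-adjusted activation/inactivation rates for the Na ladders;
# fast inactivation sits 10 mV depolarized relative to the classical
# rates (nodal phenotype), which sustains tonic firing under a
# maintained depolarizing conductance.
nav_rates <- function(shift = 0, phi = 3, h_shift = 10) {
  vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2), x / (exp(x / y) - 1))
  sh <- shift + h_shift
  list(
    am = function(V) phi * 0.1 * vtrap(-(V - shift + 40), 10),
    bm = function(V) phi * 4 * exp(-(V - shift + 65) / 18),
    ah = function(V) phi * 0.07 * exp(-(V - sh + 65) / 20),
    bh = function(V) phi * 1 / (1 + exp(-(V - sh + 35) / 10))
  )
}

sigmoid_rate <- function(a, v_half, slope) {
  force(a); force(v_half); force(slope)
  function(V) a / (1 + exp(-(V - v_half) / slope))
}

#' Construct a custom Markov channel scheme
#'
#' @param name Channel name.
#' @param states Character vector of state names.
#' @param from,to Integer state indices of each transition.
#' @param rate_fns List of vectorized rate functions of voltage (1/ms),
#'   one per transition.
#' @param conducting Integer indices of conducting states.
#' @param e_rev Reversal potential (mV).
#' @return A Markov `spindle_channel`.
#' @export
markov_channel <- function(name, states, from, to, rate_fns, conducting,
                           e_rev = 0) {
  stopifnot(length(from) == length(to), length(from) == length(rate_fns))
  new_markov_channel(name, states,
                     list(from = as.integer(from), to = as.integer(to),
                          fn = rate_fns),
                     conducting = as.integer(conducting), e_rev = e_rev)
}

new_markov_channel <- function(name, states, transitions, conducting, e_rev) {
  n <- length(states)
  stopifnot(all(transitions$from %in% seq_len(n)),
            all(transitions$to %in% seq_len(n)))
  structure(list(name = name, kind = "markov", states = states,
                 n = n, transitions = transitions,
                 conducting = conducting, e_rev = e_rev),
            class = "spindle_channel")
}

markov_transitions <- function(from, to, fn) {
  list(from = from, to = to, fn = fn)
}

# m^3 h - equivalent ladder (exactly the HH product dynamics) with two
# appended slow-inactivated states.
nav_10state <- function(name, shift, slow_entry_o, slow_entry_i,
                        slow_rec, phi = 3, h_rec_scale = 1,
                        slow_v_half = -45) {
  r <- nav_rates(shift, phi)
  ah <- function(V) h_rec_scale * r$ah(V)
  # states: 1:C1 2:C2 3:C3 4:O 5:I1 6:I2 7:I3 8:IO 9:SO 10:SI
  tr <- list(
    markov_transitions(1, 2, function(V) 3 * r$am(V)),
    markov_transitions(2, 1, function(V) 1 * r$bm(V)),
    markov_transitions(2, 3, function(V) 2 * r$am(V)),
    markov_transitions(3, 2, function(V) 2 * r$bm(V)),
    markov_transitions(3, 4, function(V) 1 * r$am(V)),
    markov_transitions(4, 3, function(V) 3 * r$bm(V)),
    markov_transitions(5, 6, function(V) 3 * r$am(V)),
    markov_transitions(6, 5, function(V) 1 * r$bm(V)),
    markov_transitions(6, 7, function(V) 2 * r$am(V)),
    markov_transitions(7, 6, function(V) 2 * r$bm(V)),
    markov_transitions(7, 8, function(V) 1 * r$am(V)),
    markov_transitions(8, 7, function(V) 3 * r$bm(V)),
    markov_transitions(1, 5, r$bh), markov_transitions(5, 1, ah),
    markov_transitions(2, 6, r$bh), markov_transitions(6, 2, ah),
    markov_transitions(3, 7, r$bh), markov_transitions(7, 3, ah),
    markov_transitions(4, 8, r$bh), markov_transitions(8, 4, ah),
    # slow inactivation: SO entered from the open state, SI from the
    # fast-inactivated (IO) state; recovery is much slower than
    # fast-inactivation recovery.
    markov_transitions(4, 9, sigmoid_rate(slow_entry_o, slow_v_half, 6)),
    markov_transitions(9, 4, sigmoid_rate(slow_rec, -75, -8)),
    markov_transitions(8, 10, sigmoid_rate(slow_entry_i, slow_v_half, 6)),
    markov_transitions(10, 8, sigmoid_rate(slow_rec, -75, -8))
  )
  trs <- list(from = as.integer(vapply(tr, `[[`, 0, "from")),
              to = as.integer(vapply(tr, `[[`, 0, "to")),
              fn = lapply(tr, `[[`, "fn"))
  new_markov_channel(name,
                     c("C1", "C2", "C3", "O", "I1", "I2", "I3", "IO",
                       "SO", "SI"),
                     trs, conducting = 4L, e_rev = 60)
}

#' @rdname channels
#' @param e_rev Reversal potential override (mV).
#' @param shift Activation voltage shift (mV; negative = hyperpolarized).
#' @param slow_entry_o,slow_entry_i,slow_rec Slow-inactivation entry
#'   (from open / from fast-inactivated) and recovery rate scales (1/ms).
#' @param v_half,slope KCNQ activation midpoint and slope (mV).
#' @export
chan_nav11 <- function(e_rev = 60, shift = 7, slow_entry_o = 0.004,
                       slow_entry_i = 0.006, slow_rec = 0.002,
                       slow_v_half = -55) {
  # terminal-specific isoform with pronounced slow inactivation: it
  # supports the onset and dynamic response and washes out during
  # maintained depolarization.
  ch <- nav_10state("nav11", shift = shift, slow_entry_o = slow_entry_o,
                    slow_entry_i = slow_entry_i, slow_rec = slow_rec,
                    slow_v_half = slow_v_half)
  ch$e_rev <- e_rev
  ch
}

#' @rdname channels
#' @export
chan_nav16 <- function(e_rev = 60, shift = 0, slow_entry_o = 4e-4,
                       slow_entry_i = 8e-4, slow_rec = 0.004) {
  # comparatively resistant to slow inactivation: Nav1.6 sustains
  # repetitive firing through the static phase
  ch <- nav_10state("nav16", shift = shift, slow_entry_o = slow_entry_o,
                    slow_entry_i = slow_entry_i, slow_rec = slow_rec)
  ch$e_rev <- e_rev
  ch
}

#' @rdname channels
#' @export
chan_nav17 <- function(e_rev = 60, shift = 3, h_rec_scale = 0.3) {
  r <- nav_rates(shift = shift, phi = 3)
  # slow repriming and low steady availability at depolarized
  # potentials: Nav1.7 boosts transients but washes out tonically
  ah <- function(V) h_rec_scale * r$ah(V)
  # states: 1:C1 2:C2 3:O 4:I1 5:I2 6:IO  (m^2 h equivalent)
  tr <- list(
    markov_transitions(1, 2, function(V) 2 * r$am(V)),
    markov_transitions(2, 1, function(V) 1 * r$bm(V)),
    markov_transitions(2, 3, function(V) 1 * r$am(V)),
    markov_transitions(3, 2, function(V) 2 * r$bm(V)),
    markov_transitions(4, 5, function(V) 2 * r$am(V)),
    markov_transitions(5, 4, function(V) 1 * r$bm(V)),
    markov_transitions(5, 6, function(V) 1 * r$am(V)),
    markov_transitions(6, 5, function(V) 2 * r$bm(V)),
    markov_transitions(1, 4, r$bh), markov_transitions(4, 1, ah),
    markov_transitions(2, 5, r$bh), markov_transitions(5, 2, ah),
    markov_transitions(3, 6, r$bh), markov_transitions(6, 3, ah)
  )
  trs <- list(from = as.integer(vapply(tr, `[[`, 0, "from")),
              to = as.integer(vapply(tr, `[[`, 0, "to")),
              fn = lapply(tr, `[[`, "fn"))
  new_markov_channel("nav17", c("C1", "C2", "O", "I1", "I2", "IO"),
                     trs, conducting = 3L, e_rev = 60)
}

new_hh_gate <- function(name, v_half, slope, power, tau_fun) {
  structure(list(name = name, v_half = v_half, slope = slope,
                 power = power, tau_fun = tau_fun),
            class = "hh_gate")
}

new_hh_channel <- function(name, gates, e_rev) {
  structure(list(name = name, kind = "hh", gates = gates, e_rev = e_rev),
            class = "spindle_channel")
}

#' @rdname channels
#' @export
chan_kv1 <- function(e_rev = -90, v_half = -48) {
  # low activation threshold: juxtaparanodal Kv1 damps subthreshold
  # depolarizing creep and re-excitation around the nodes
  new_hh_channel("kv1", list(
    new_hh_gate("n", v_half = v_half, slope = 7, power = 1,
                tau_fun = function(V) 1 + 9 / (1 + exp((V + 45) / 12))),
    new_hh_gate("h", v_half = -55, slope = -7, power = 1,
                tau_fun = function(V) rep(800, length(V)))
  ), e_rev = e_rev)
}

#' @rdname channels
#' @export
chan_kv33 <- function(e_rev = -90) {
  new_hh_channel("kv33", list(
    new_hh_gate("n", v_half = -8, slope = 8, power = 2,
                tau_fun = function(V) 0.4 + 3 * exp(-((V + 20) / 25)^2))
  ), e_rev = e_rev)
}

#' @rdname channels
#' @export
chan_kcnq <- function(e_rev = -90, v_half = -60, slope = 6) {
  new_hh_channel("kcnq", list(
    new_hh_gate("n", v_half = v_half, slope = slope, power = 1,
                tau_fun = function(V) 20 + 180 * exp(-((V + 45) / 30)^2))
  ), e_rev = e_rev)
}

#' @rdname channels
#' @param k_half_uM Half-activation calcium concentration (uM).
#' @param hill Hill coefficient.
#' @param tau_ms Activation time constant (ms).
#' @export
chan_sk2 <- function(e_rev = -90, k_half_uM = 0.4, hill = 4, tau_ms = 30) {
  if (k_half_uM <= 0) stop("k_half_uM must be > 0")
  if (hill <= 0) stop("Hill coefficient must be > 0")
  structure(list(name = "sk2", kind = "sk", k_half_uM = k_half_uM,
                 hill = hill, tau_ms = tau_ms, e_rev = e_rev),
            class = "spindle_channel")
}

#' @rdname channels
#' @param overrides Named list of per-channel constructor argument lists,
#'   e.g. `list(sk2 = list(k_half_uM = 0.6))`.
#' @return `spindle_channels()` returns the named list of all seven
#'   channel models.
#' @export
spindle_channels <- function(overrides = list()) {
  ctors <- list(nav11 = chan_nav11, nav16 = chan_nav16,
                nav17 = chan_nav17, kv1 = chan_kv1, kv33 = chan_kv33,
                sk2 = chan_sk2, kcnq = chan_kcnq)
  unknown <- setdiff(names(overrides), names(ctors))
  if (length(unknown))
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "))
  mapply(function(ctor, nm) do.call(ctor, as.list(overrides[[nm]])),
         ctors, names(ctors), SIMPLIFY = FALSE)
}

#' Steady state and time constant of an HH gate
#'
#' `x_inf(V) = 1/(1 + exp(-(V - v_half)/slope))`; a negative slope makes
#' the gate an inactivation gate (decreasing in V).
#'
#' @param gate An `hh_gate` (element of an HH channel's `gates` list).
#' @param V Membrane potential (mV), vectorized.
#' @return List with `x_inf` and `tau_ms`.
#' @export
gate_steady_state <- function(gate, V) {
  stopifnot(inherits(gate, "hh_gate"))
  list(x_inf = 1 / (1 + exp(-(V - gate$v_half) / gate$slope)),
       tau_ms = gate$tau_fun(V))
}

#' Generator (rate) matrix of a Markov channel at a fixed voltage
#'
#' @param chan A Markov `spindle_channel`.
#' @param V Membrane potential (mV).
#' @return `n x n` matrix `Q` with `Q[i, j]` the i->j rate (1/ms) and
#'   rows summing to zero.
#' @export
markov_rate_matrix <- function(chan, V) {
  stopifnot(inherits(chan, "spindle_channel"), chan$kind == "markov")
  n <- chan$n
  Q <- matrix(0, n, n, dimnames = list(chan$states, chan$states))
  tr <- chan$transitions
  for (k in seq_along(tr$from)) {
    r <- tr$fn[[k]](V)
    if (!is.finite(r) || r < 0)
      stop(sprintf("negative/non-finite rate in scheme '%s' at V = %g",
                   chan$name, V))
    Q[tr$from[k], tr$to[k]] <- Q[tr$from[k], tr$to[k]] + r
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary occupancy of a Markov channel at a fixed voltage
#'
#' Solves `t(Q) p = 0`, `sum(p) = 1` by least squares.
#'
#' @inheritParams markov_rate_matrix
#' @return Occupancy vector on the state simplex.
#' @export
stationary_distribution <- function(chan, V) {
  Q <- markov_rate_matrix(chan, V)
  # replace one balance equation with the normalization constraint
  # (exact square solve; the balance equations are rank n-1)
  A <- t(Q)
  A[chan$n, ] <- 1
  b <- c(rep(0, chan$n - 1), 1)
  p <- solve(A, b)
  p[p < 0] <- 0
  p / sum(p)
}

#' Initialize a channel state at a holding potential
#'
#' HH gates at their steady state, Markov occupancies at the stationary
#' distribution, SK activation at the Hill steady state.
#'
#' @param chan A `spindle_channel`.
#' @param V Holding potential (mV).
#' @param Ca Calcium concentration (uM), for SK.
#' @return A channel state (numeric vector).
#' @export
channel_init <- function(chan, V, Ca = 0) {
  switch(chan$kind,
         hh = vapply(chan$gates,
                     function(g) gate_steady_state(g, V)$x_inf, 0),
         markov = stationary_distribution(chan, V),
         sk = sk_inf(chan, Ca))
}

sk_inf <- function(chan, Ca) {
  if (Ca <= 0) return(0)
  Ca^chan$hill / (Ca^chan$hill + chan$k_half_uM^chan$hill)
}

#' Advance a channel state by one time step
#'
#' HH gates use the exact exponential update
#' `x <- x_inf + (x - x_inf) exp(-dt/tau)`; Markov occupancies use a
#' backward (implicit) Euler step on the generator, renormalized onto the
#' simplex; SK activation relaxes exponentially toward its Hill steady
#' state.
#'
#' @param state Channel state from [channel_init()] or a previous step.
#' @param chan The `spindle_channel`.
#' @param V Membrane potential over the step (mV).
#' @param Ca Calcium concentration (uM).
#' @param dt Time step (ms).
#' @return Updated state vector.
#' @export
step_channel <- function(state, chan, V, Ca = 0, dt) {
  if (dt <= 0) stop("dt must be > 0")
  switch(chan$kind,
         hh = {
           x <- numeric(length(chan$gates))
           for (i in seq_along(chan$gates)) {
             ss <- gate_steady_state(chan$gates[[i]], V)
             x[i] <- ss$x_inf + (state[i] - ss$x_inf) * exp(-dt / ss$tau_ms)
           }
           x
         },
         markov = {
           Q <- markov_rate_matrix(chan, V)
           p <- solve(diag(chan$n) - dt * t(Q), state)
           if (any(p < -1e-6) || abs(sum(p) - 1) > 1e-3)
             stop("Markov occupancy left the simplex beyond tolerance")
           p[p < 0] <- 0
           p / sum(p)
         },
         sk = {
           a_inf <- sk_inf(chan, Ca)
           a_inf + (state - a_inf) * exp(-dt / chan$tau_ms)
         })
}

#' Open fraction of a channel state
#'
#' Product of gates raised to their powers (HH), summed occupancy of
#' conducting states (Markov), or the SK activation variable.
#'
#' @inheritParams step_channel
#' @return Open fraction in `[0, 1]`.
#' @export
channel_open_fraction <- function(chan, state) {
  switch(chan$kind,
         hh = prod(vapply(seq_along(chan$gates),
                          function(i) state[i]^chan$gates[[i]]$power, 0)),
         markov = sum(state[chan$conducting]),
         sk = as.numeric(state))
}

#' Membrane current through a channel
#'
#' `I = g_density * area * open * (V - e_rev)`, returned in nA for
#' `g_density` in S/cm2 and `area` in cm2.
#'
#' @inheritParams step_channel
#' @param g_density Maximal conductance density (S/cm2).
#' @param area Membrane area (cm2).
#' @param e_rev Reversal potential (mV); defaults to the channel's.
#' @return Current in nA (positive outward).
#' @export
channel_current <- function(chan, state, V, g_density, area,
                            e_rev = chan$e_rev) {
  if (area <= 0) stop("area must be > 0")
  g_density * area * channel_open_fraction(chan, state) *
    (V - e_rev) * 1e6
}

#' Voltage-clamp a channel model
#'
#' Initializes the channel at the stationary state for the holding
#' potential and integrates through a sequence of voltage steps,
#' returning the simulated current trace.  This is the validation harness
#' for the kinetic phenotypes (activation thresholds, fast vs. slow
#' inactivation, deactivation speed).
#'
#' @param chan A `spindle_channel`.
#' @param holding_mV Holding potential (mV).
#' @param steps List of `c(mV, ms)` pairs (or a 2-column matrix).
#' @param dt_ms Integration step (ms).
#' @param g_density,area Conductance density (S/cm2) and area (cm2) used
#'   to scale the reported current.
#' @param Ca Calcium (uM) seen by SK channels.
#' @return Data frame with `t_ms`, `V_mV`, `open`, `I_nA`.
#' @export
voltage_clamp <- function(chan, holding_mV, steps, dt_ms = 0.025,
                          g_density = 1e-3, area = 1e-6, Ca = 0) {
  if (is.matrix(steps)) steps <- asplit(steps, 1)
  durs <- vapply(steps, `[`, 0, 2)
  if (any(durs <= 0)) stop("protocol durations must be > 0")
  st <- channel_init(chan, holding_mV, Ca)
  t_all <- numeric(0); v_all <- numeric(0); open_all <- numeric(0)
  t0 <- 0
  for (s in steps) {
    nsteps <- max(1L, round(s[2] / dt_ms))
    op <- numeric(nsteps)
    for (i in seq_len(nsteps)) {
      st <- step_channel(st, chan, s[1], Ca, dt_ms)
      op[i] <- channel_open_fraction(chan, st)
    }
    t_all <- c(t_all, t0 + dt_ms * seq_len(nsteps))
    v_all <- c(v_all, rep(s[1], nsteps))
    open_all <- c(open_all, op)
    t0 <- t0 + dt_ms * nsteps
  }
  data.frame(t_ms = t_all, V_mV = v_all, open = open_all,
             I_nA = g_density * area * open_all * (v_all - chan$e_rev) * 1e6)
}
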