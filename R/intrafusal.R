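#' Intrafusal fibre parameters (two-state cross-bridge half-sarcomere)
#'
#' The intrafusal bag and chain fibres are each modelled as a single
#' half-sarcomere whose force is generated by a strain-distributed
#' population of two-state (attached/detached) cross-bridges, gated by a
#' cooperative thin-filament on/off variable.  Attached bridges are
#' advected along the strain axis by filament sliding, which produces the
#' history-dependent (dynamic) force responses that drive the Ia initial
#' burst.
#'
#' @param f_attach Attachment rate as a function of cross-bridge strain x
#'   (nm), in 1/s.  Attachment is additionally weighted by a normalized
#'   Gaussian window of width `w_sigma` centred on zero strain.
#' @param g_detach Detachment rate as a function of strain (1/s).
#' @param w_sigma Width (nm) of the attachment strain window.
#' @param k_cb Cross-bridge stiffness (force units per nm of strain).
#' @param x_ps Power-stroke displacement (nm); attached bridges bear force
#'   proportional to `x + x_ps`.
#' @param n_xb Cross-bridge number scale (force is linear in this).
#' @param k_on,k_off Thin-filament site on/off base rates (1/s).
#' @param k_coop Cooperativity coefficient (dimensionless).
#' @param activation Fixed activating drive in `[0, 1]` (no fusimotor
#'   modulation is modelled; the default represents constant background
#'   intrafusal tone).
#' @param hsl0 Resting half-sarcomere length (nm); bookkeeping only.
#' @param length_gain Conversion from whole-muscle stretch (mm) to
#'   half-sarcomere length change (nm/mm).
#' @param strain_grid Numeric `c(x_min, x_max, n_bins)` for the strain
#'   axis (nm); `n_bins >= 20` and `x_min < 0 < x_max`.
#' @return An object of class `fiber_params`.
#' @export
fiber_params <- function(f_attach = function(x) rep(40, length(x)),
                         g_detach = function(x) 10 + 3 * abs(x),
                         w_sigma = 1.5,
                         k_cb = 1, x_ps = 5, n_xb = 1,
                         k_on = 100, k_off = 100, k_coop = 4,
                         activation = 0.3,
                         hsl0 = 1100, length_gain = 5,
                         strain_grid = c(-10, 10, 161)) {
  stopifnot(is.function(f_attach), is.function(g_detach))
  if (activation < 0 || activation > 1) stop("activation must be in [0, 1]")
  if (strain_grid[3] < 20) stop("strain grid needs >= 20 bins")
  if (!(strain_grid[1] < 0 && strain_grid[2] > 0))
    stop("strain grid must straddle zero")
  x <- seq(strain_grid[1], strain_grid[2], length.out = strain_grid[3])
  fx <- f_attach(x); gx <- g_detach(x)
  if (any(fx < 0) || any(gx < 0)) stop("rates must be >= 0 on the grid")
  w <- exp(-x^2 / (2 * w_sigma^2))
  dx <- x[2] - x[1]
  w <- w / sum(w * dx)                      # normalized attachment window
  structure(list(f_attach = f_attach, g_detach = g_detach,
                 w_sigma = w_sigma, k_cb = k_cb, x_ps = x_ps, n_xb = n_xb,
                 k_on = k_on, k_off = k_off, k_coop = k_coop,
                 activation = activation, hsl0 = hsl0,
                 length_gain = length_gain, strain_grid = strain_grid,
                 x = x, dx = dx, w = w, fx = fx, gx = gx),
            class = "fiber_params")
}

#' Bag-fibre parameter set
#'
#' Slow cross-bridge kinetics: force relaxes over hundreds of ms after a
#' ramp, sustaining an elevated plateau (static sensitivity) and a large
#' dynamic overshoot.
#' @param rate_scale Multiplier on the attach/detach rates.
#' @param ... Further overrides passed to [fiber_params()].
#' @export
bag_fiber_params <- function(rate_scale = 1, ...) {
  fiber_params(f_attach = function(x) rep(40 * rate_scale, length(x)),
               g_detach = function(x) rate_scale * (10 + 3 * abs(x)),
               ...)
}

#' Chain-fibre parameter set
#'
#' Fast cross-bridge kinetics (8x the bag rates): the chain force tracks
#' length with little history dependence and contributes mainly to the
#' sustained component of the receptor potential.
#' @inheritParams bag_fiber_params
#' @export
chain_fiber_params <- function(rate_scale = 8, ...) {
  bag_fiber_params(rate_scale = rate_scale, ...)
}

# steady-state thin-filament activation for constant drive
a_on_steady <- function(p) {
  act <- p$activation
  if (act == 0) return(0)
  fn <- function(a) p$k_on * act * (1 - a) * (1 + p$k_coop * a) -
    p$k_off * a * (1 + p$k_coop * (1 - a))
  stats::uniroot(fn, c(0, 1), tol = 1e-12)$root
}

#' Initial (isometric steady-state) fibre state
#'
#' Solves the isometric fixed point analytically: bound density
#' `b(x) = f(x) w(x) (a - B) / g(x)` with total mass
#' `B = a F S / (1 + F S)` where `S = integral of f w / g` (for the
#' strain-uniform attachment rate this reduces to `a f/(f+g)` with
#' constant detachment).
#'
#' @param p A [fiber_params()].
#' @return A `fiber_state` list with fields `bound` (density over the
#'   strain grid, 1/nm), `a_on` and `hsl` (nm).
#' @export
fiber_state_init <- function(p) {
  a <- a_on_steady(p)
  q <- p$fx * p$w / pmax(p$gx, 1e-12)       # b(x) per unit (a - B)
  S <- sum(q * p$dx)
  B <- a * S / (1 + S)
  bound <- q * (a - B)
  structure(list(bound = bound, a_on = a, hsl = p$hsl0, x_offset = 0),
            class = "fiber_state")
}

#' Advance the cross-bridge model by one time step
#'
#' Three sub-steps: (1) the bound-bridge density is advected along the
#' strain axis by the imposed half-sarcomere length change (bridges
#' carried beyond the grid detach); (2) the cooperative thin-filament
#' on/off fraction is updated; (3) attachment/detachment kinetics are
#' integrated with an explicit Euler step (stable for `dt * max(g) << 1`).
#'
#' Advection is semi-Lagrangian without interpolation: whole strain bins
#' are shifted exactly and the sub-bin remainder is carried as a grid
#' offset (`x_offset`), so the scheme introduces no numerical diffusion;
#' rates, the attachment window and the force integral are evaluated at
#' the true strains `x + x_offset`.
#'
#' @param state A `fiber_state`.
#' @param p A [fiber_params()].
#' @param delta_hsl Half-sarcomere length change over the step (nm).
#' @param dt Time step (s).
#' @return Updated `fiber_state`.
#' @export
step_fiber <- function(state, p, delta_hsl, dt) {
  if (dt <= 0) stop("dt must be > 0")
  if (!is.finite(delta_hsl)) stop("delta_hsl must be finite")
  bound <- state$bound
  off <- if (is.null(state$x_offset)) 0 else state$x_offset
  if (delta_hsl != 0) {
    off <- off + delta_hsl
    n_shift <- round(off / p$dx)
    if (n_shift != 0) {
      nb <- length(bound)
      shifted <- numeric(nb)
      src <- seq_len(nb) - n_shift
      ok <- src >= 1 & src <= nb
      shifted[ok] <- bound[src[ok]]
      bound <- shifted
      off <- off - n_shift * p$dx
    }
  }
  xt <- p$x + off                       # true strain of each bin
  w <- exp(-xt^2 / (2 * p$w_sigma^2))
  w <- w / sum(w * p$dx)
  fx <- p$f_attach(xt)
  gx <- p$g_detach(xt)
  a <- state$a_on
  act <- p$activation
  da <- p$k_on * act * (1 - a) * (1 + p$k_coop * a) -
    p$k_off * a * (1 + p$k_coop * (1 - a))
  a <- min(1, max(0, a + dt * da))
  B <- sum(bound * p$dx)
  bound <- bound + dt * (fx * w * max(a - B, 0) - gx * bound)
  if (any(!is.finite(bound)) || any(bound < -1e-9))
    stop(sprintf("cross-bridge density left [0,1] (unstable at dt = %g s)", dt))
  bound[bound < 0] <- 0
  structure(list(bound = bound, a_on = a, hsl = state$hsl + delta_hsl,
                 x_offset = off),
            class = "fiber_state")
}

fiber_force <- function(bound, p, x_offset = 0) {
  p$n_xb * p$k_cb * sum(bound * (p$x + x_offset + p$x_ps) * p$dx)
}

#' Simulate intrafusal fibre force for a stretch stimulus
#'
#' Starts from the isometric steady state at baseline length, drives the
#' half-sarcomere with `length_gain * stimulus length`, and returns force
#' and yank (first time derivative of force, central differences).
#'
#' @param p A [fiber_params()].
#' @param stim A `stretch_stimulus`.
#' @return A `force_trace` list with `t` (s), `force`, `yank` (force/s).
#' @export
simulate_fiber <- function(p, stim) {
  stopifnot(inherits(stim, "stretch_stimulus"))
  n <- length(stim$t)
  dt <- stim$dt_s
  dl_nm <- c(0, diff(stim$length_mm)) * p$length_gain
  st <- fiber_state_init(p)
  force <- numeric(n)
  force[1] <- fiber_force(st$bound, p)
  for (i in 2:n) {
    st <- step_fiber(st, p, dl_nm[i], dt)
    force[i] <- fiber_force(st$bound, p, st$x_offset)
  }
  yank <- numeric(n)
  yank[2:(n - 1)] <- (force[3:n] - force[1:(n - 2)]) / (2 * dt)
  yank[1] <- (force[2] - force[1]) / dt
  yank[n] <- (force[n] - force[n - 1]) / dt
  structure(list(t = stim$t, force = force, yank = yank),
            class = "force_trace")
}

#' Isometric bound fraction of the reduced constant-rate model
#'
#' For strain-independent attachment and detachment rates the two-state
#' model has the closed-form isometric bound fraction `f/(f+g)` (per unit
#' thin-filament activation).  Used as an analytic oracle for the
#' time-stepping simulation.
#'
#' @param p A [fiber_params()] whose rate functions are constant over the
#'   strain grid.
#' @return The fraction `f/(f+g)`.
#' @export
isometric_bound_fraction <- function(p) {
  stopifnot(inherits(p, "fiber_params"))
  if (diff(range(p$fx)) > 1e-9 || diff(range(p$gx)) > 1e-9)
    stop("isometric_bound_fraction requires strain-independent rates")
  f <- p$fx[1]; g <- p$gx[1]
  if (f + g == 0) stop("f + g must be > 0")
  f / (f + g)
}
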