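# spindlesim

An integrative biophysical model of mammalian muscle spindle primary
(Ia) afferent encoding, for computational neuroscientists studying
mechanosensory signalling and for experimentalists who want a
reconfigurable in-silico spindle to generate testable hypotheses about
neuronal architecture and ion-channel distribution.

The model chains three stages:

1. **Intrafusal fibre mechanics** — bag (slow) and chain (fast) fibres,
   each a half-sarcomere whose force follows two-state cross-bridge
   kinetics on a strain grid: attached-bridge density `b(x)` obeys

   ```
   db(x)/dt = f(x) w(x) (a_on − ∫b dx) − g(x) b(x)
   F = n k_cb ∫ b(x)(x + x_ps) dx
   ```

   with filament sliding advecting `b` along the strain axis and a
   cooperative thin-filament variable `a_on`.

2. **Receptor potential** — a mechanotransduction conductance computed
   from rectified force and yank (dF/dt):
   `g_drive = 2e5 · (kfb[F_bag]⁺ + kyb[Y_bag]⁺ + kfc[F_chain]⁺)`,
   injected into the terminal compartments.

3. **Spiking afferent** — a multicompartment cable model
   (Crank–Nicolson, Hines-ordered tree solve, Rcpp core): two annulospiral
   terminal branches → preterminal axon → heminode → four further nodes
   of Ranvier with flanking paranodes and myelinated internodes.
   Channels: 10-state Markov Nav1.1 and Nav1.6 (two slow-inactivated
   states each; for Nav1.6 one entered from the open and one from the
   fast-inactivated state), 6-state Nav1.7, HH-type Kv1, Kv3.3 and KCNQ
   (M-current), and calcium-gated SK2, at region-specific densities.

Output spike trains are summarized by the three classic Ia encoding
features: initial burst, peak dynamic rate and static average rate
(pulses per second, pps).

## Worked example

```r
library(spindlesim)

cfg <- base_config()          # calibrated base model
out <- run_spindle(cfg)       # stimulus -> forces -> drive -> spikes
out$features
#> <firing_features: burst 130.4 pps, peak dynamic 130.4 pps, static 66.1 pps>

initiation_order(out$sim)[[1]]
#> [1] "terminal" "heminode" "node5"
```

The base model, driven by a 3 mm, 20 mm/s ramp–hold–release stretch,
fires repetitively with an onset burst above 100 pps (the classical Ia
identification criterion), dynamic-phase firing above the adapted
static rate, and every action potential initiating in the receptor
terminal before the heminode and the distal node — the model's central
architectural prediction.

Experiments are config-driven and deterministic:

```r
# terminal / preterminal length experiments
sweep_morphology("terminal", multipliers = c(0.1, 1, 10), config = cfg)

# 2-D terminal conductance sweep (Nav1.6 pS/um2 x KCNQ S/cm2)
grid <- sweep_conductance_2d(seq(0, 50, length.out = 5),
                             seq(5e-4, 5e-3, length.out = 5), cfg)
find_phase_transition(grid, config = cfg)

# channel knockouts
run_spindle(channel_knockout(cfg, "nav17"))
```

A thin CLI wraps the same functions
(`inst/cli/spindlesim stimulus ramp --amplitude 3 --velocity 20 ...`).

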