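---
title: "An integrative biophysical model of muscle spindle Ia encoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrative biophysical model of muscle spindle Ia encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spindlesim)
```

## The model

Muscle spindles report muscle length and its rate of change through the
spike trains of primary (Ia) afferents.  `spindlesim` implements the
full encoding chain as three coupled stages:

1. **Intrafusal mechanics.**  Two intrafusal fibres — a slow *bag* and a
   fast *chain* — are each modelled as a half-sarcomere whose force
   comes from a strain-distributed population of two-state
   (attached/detached) cross-bridges gated by a cooperative
   thin-filament on/off variable.  Muscle stretch slides the filaments
   and advects the attached-bridge strain distribution, producing the
   history-dependent force and yank (dF/dt) that underlie dynamic
   sensitivity.

2. **Transduction.**  The receptor potential is a phenomenological
   mechanotransduction conductance:
   `g_drive = scale * (kfb [F_bag]+ + kyb [Y_bag]+ + kfc [F_chain]+)`,
   each component half-wave rectified, with `scale = 2e5` and a 0 mV
   reversal (non-selective cation current).  The drive enters the
   terminal compartments of the afferent.

3. **Spiking afferent.**  A multicompartment cable model of the Ia
   ending: two terminal (annulospiral) branches converge on a single
   preterminal axon, then a heminode and four further nodes of Ranvier
   separated by myelinated internodes, with paranodes flanking every
   node.  Seven conductances are distributed asymmetrically across
   regions (densities in `default_density_table()`): Markov-scheme
   Nav1.1, Nav1.6 (10 states each, two slow-inactivated states — one
   entered from the open state, one from the fast-inactivated state)
   and Nav1.7 (6 states); Hodgkin–Huxley Kv1 (low-threshold, slowly
   inactivating), Kv3.3 (high-threshold, fast) and KCNQ (M-current);
   and a calcium-gated SK2 conductance.

The cable equations are integrated with a Crank-Nicolson scheme with
staggered gating (`dt = 0.0125` ms; backward Euler available as an
option): channel states advance first (HH gates by exact exponential
update, Markov occupancies by a theta-weighted implicit solve on the
generator matrix — exactly mass-conserving — renormalized to the
simplex), then the voltage system is solved implicitly over the
compartment tree in one O(n) pass (Hines ordering).  Crank-Nicolson is
the default because the first-order period error of backward Euler
accumulates visible spike-phase drift over a tonic train.  Channel kinetics
are shared between the R channel library and the compiled solver
through voltage lookup tables (0.05 mV grid), so the clamp harness and
the cable model use literally the same rate functions.

## Parameters and their provenance

The published description of this model class names channel topologies
and region-wise maximal densities but no rate constants, base
dimensions, or stimulus amplitudes.  Everything not printed is a
calibration choice of this package, made once and frozen:

* **Stimulus.**  Ramp–hold–release, amplitude 3 mm, velocity 20 mm/s
  (the classical Ia identification ramp), hold 1 s, 0.2 s baseline and
  tail, `dt = 1e-4` s.
* **Cross-bridge rates.**  Attachment 40 /s inside a Gaussian strain
  window (sigma 1.5 nm), detachment `10 + 3|x|` /s, power-stroke 5 nm,
  strain grid ±10 nm in 41 bins.  Rates were chosen so the
  attached-bridge lifetime corresponds to a few nanometres of strain
  drag at the 20 mm/s ramp; this puts the fibre in the short-range
  stiffness regime where ramp force exceeds the hold plateau.  The
  chain fibre uses 8× faster rates, muscle-to-sarcomere coupling is a
  fixed 5 nm/mm.  A pure two-state model has no length-dependent
  equilibrium force, so the hold-phase plateau relaxes toward the
  isometric value; static firing consequently approximates baseline
  firing, which is consistent with tonically active Ia afferents.
* **Channel kinetics.**  The Na ladders are the HH-equivalent m³h (m²h
  for the 6-state scheme) Markov expansions of classical mammalian-rate
  kinetics (3× temperature factor), with fast inactivation 10 mV
  depolarized — the nodal phenotype required for tonic firing under a
  maintained depolarizing conductance.  Isoform phenotypes: Nav1.1
  activates 7 mV depolarized and slow-inactivates strongly (onset and
  dynamic role); Nav1.6 is slow-inactivation–resistant and sustains
  static firing; Nav1.7 activates 5 mV hyperpolarized with slow
  repriming (transient amplifier that washes out tonically).  KCNQ
  activates from −60 mV with ~100 ms kinetics, which places the
  high-KCNQ static-failure regime inside the 0.0005–0.005 S/cm²
  density range explored by the conductance experiments.
* **Morphology.**  Terminals 80 µm × 1.5 µm (two branches),
  preterminal 10 µm × 0.6 µm, nodes 1.5 µm, paranodes 3 µm, internodes
  100 µm with capacitance and leak reduced 50-fold; Ra 100 Ω·cm, leak
  1e-4 S/cm² (1e-3 at nodes, 2e-6 at internodes), E_leak −65 mV,
  E_Na +60 mV, E_K −90 mV.  Segment counts keep every segment under
  0.1 electrotonic length.  The thin preterminal makes it a
  propagation bottleneck, which is what gives preterminal elongation
  its selective effect on high-frequency (burst) firing.
* **Drive placement.**  The transduction conductance lives where the
  terminal contacts the intrafusal sensory (equatorial) zone, which the
  base terminal covers exactly: shrinking the terminal loses
  mechanosensitive channels in proportion to membrane area, while
  terminal growth beyond the zone adds excitable membrane but no
  additional drive.  This choice reproduces the observed asymmetry of
  terminal-length effects (shortening attenuates firing, lengthening is
  comparatively nominal) — with a fixed total drive the impedance
  increase of a shrinking terminal would *raise* firing instead.
* **SK2 calcium source.**  No calcium channel is specified for the
  model, so SK2 sees a per-compartment calcium pool driven by the
  rectified inward sodium current (tau 50 ms, coupling 0.4 µM·cm²/nA/ms
  scale), documented as a modelling surrogate.
* **Calibration.**  With everything above fixed, the three transduction
  weights were fitted once to a prototypical rat Ia response (targets:
  initial burst 150 pps, peak dynamic 120 pps, static 70 pps, 15%
  relative tolerance) and frozen at `kfb = 0.06`, `kyb = 0.0017`,
  `kfc = 0.06`.  The shipped defaults give 130.4 / 130.4 / 66.1 pps.
  Note the burst window is a subset of the dynamic window, so peak
  dynamic ≥ initial burst by construction; the two targets therefore
  meet in the middle.

## Feature definitions

Spikes are upward crossings of −20 mV at node5 (the output toward the
CNS) with a 1 ms refractory floor and linear-interpolated crossing
times.  *Initial burst* is the maximum instantaneous firing rate (IFR,
reciprocal inter-spike interval) within 100 ms of ramp onset; *peak
dynamic* the maximum IFR during the ramp; *static average* the mean IFR
over the central 80% of the hold.  An empty static window yields a 0
with a `"static failure"` flag.  Hold-phase ISI coefficient of
variation above 0.3 flags irregular firing.

## What the generator emulates — and what it does not

The stimulus generator and intrafusal stage stand in for in vivo
recorded muscle kinetics: they reproduce ramp geometry, velocity
scaling, vibration protocols, and the force/yank decomposition, but not
fusimotor drive, force-controlled protocols, tendon compliance, or
inter-trial variability (the pipeline is fully deterministic — a fixed
configuration yields byte-identical spike trains).  Passing tests
therefore demonstrate internal consistency and the mechanistic
directions of the architecture and conductance experiments, not
quantitative agreement with any particular biological recording.

## Numerical choices and degenerate inputs

The implicit schemes are unconditionally stable; halving `dt` leaves
the spike count unchanged and onset/dynamic-phase spike times agree to
~0.02 ms, while late hold-phase spikes accumulate up to ~2 ms of phase
through the SK-calcium feedback loop (the adapted limit cycle has
near-neutral phase stability, so phase error grows along the train at
any practical step size).  Markov
occupancy is conserved to ~1e-15 per step and renormalized; a
non-finite or >200 mV voltage aborts with a suggestion to reduce
`dt_ms`.  Degenerate cases are defined: zero-amplitude stimuli produce
the isometric fixed point, empty spike trains produce zero features
with flags, all-zero channel densities produce a passive cable (whose
steady profile matches the finite-cable closed form within 1%).

## Design choices where the design was open

* Nodes of Ranvier beyond the heminode carry the heminode channel
  complement (the density table lists four regions only).
* The `"mho/cm"` unit printed for KCNQ is treated as S/cm².
* Internodes carry leak at 1/50 density and no voltage-gated channels.
* The Nav1.1 slow-inactivation entry paths mirror those stated for
  Nav1.6 (open-state and fast-inactivated-state entry); only the
  Nav1.6 topology is specified explicitly.
* Sweep grids default to the published ranges (terminal length ×0.1 to
  ×10; preterminal ×0.25 to ×12.5 plus small increments beyond;
  terminal Nav1.6 0–50 pS/µm² × KCNQ 0.0005–0.005 S/cm²).

## Known limitations

Honest discrepancies of the frozen calibration, measured by the
acceptance suite:

* 10× terminal *lengthening* reduces firing by ~40% instead of being
  nominal.  With the published densities, the added terminal membrane
  carries SK2/Kv3.3/KCNQ load that outweighs sodium amplification;
  parameterizations that nulled this balance either became bistable,
  broke the terminal-first spike-initiation order, or made the cell a
  spontaneous pacemaker at rest — all phenotypes this package treats as
  higher-priority.
* Terminal shortening reduces all three features (correct direction)
  but 1.3–4.5× more strongly than the published percentages — the
  calibrated rate-versus-drive curve is steeper than the original
  model's.
* Preterminal elongation mildly boosts rather than filters the initial
  burst in the final calibration, and no dynamic collapse occurs out to
  +40 µm: the preterminal remains regenerative.  (Calibrations with a
  stronger SK2 brake did reproduce the burst filtering, but fired
  spontaneously at zero drive; resting quiescence was kept instead.)
* At the highest KCNQ density, static firing fails for *all* terminal
  Nav1.6 densities up to 50 pS/µm² and the dynamic response is nearly
  abolished; the restoration of static firing by Nav1.6 alone is not
  reproduced, and the static-failure boundary is KCNQ-dominated with
  only a weak Nav1.6 tilt.

Problem sizes: every simulation in the tests and the acceptance script
runs the full spatial model (35 compartments) with a 0.5 s settling
period and the 1.7 s default protocol at `dt = 0.0125` ms; the
convergence check uses a shortened 0.8 s protocol at full resolution.

## Running the model

```{r}
cfg <- base_config()
out <- run_spindle(cfg)
out$features
initiation_order(out$sim)[1:3]

# architecture experiment
sw <- sweep_morphology("terminal", multipliers = c(0.1, 1, 10),
                       config = cfg)

# conductance experiment
grid <- sweep_conductance_2d(nav16_grid = seq(0, 50, length.out = 5),
                             kcnq_grid = seq(5e-4, 5e-3, length.out = 5),
                             config = cfg)
find_phase_transition(grid, config = cfg)
```
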