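---
title: "The energy-dissipation model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The energy-dissipation model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enerdiss)
```

## The model and its assumptions

Allosteric signal transduction can be viewed as an energy-dissipation
process: ligand binding injects energy at a regulatory site, and that
energy spreads through intramolecular interactions until the catalytic
site responds. `enerdiss` operationalizes this picture in four steps.

1. **Perturbation.** After thermal equilibration, the velocity vectors
   of the chosen residues are multiplied by a factor *f* (their kinetic
   energy by *f*²). Kinetic energy is used because it is the quantity a
   simulation can change cleanly, and kinetic and potential energy
   interconvert rapidly on the timescales of interest.
2. **Paired propagation.** Two microcanonical (NVE) trajectories are run
   from the *identical* equilibrated state — one perturbed at t = 0, one
   not. Subtracting the reference run's per-residue energies isolates
   the perturbation's effect exactly; with *f* = 1 the pair is
   bit-identical and the difference is exactly zero everywhere.
3. **Response detection.** Residue *i* responds at the earliest saved
   frame where |ΔE_i| stays at or above a threshold for a sustained
   number of frames (defaults below). Perturbed residues respond at
   t = 0 by definition, so NR(0) equals the perturbed count NR₁.
4. **Characterization.** The cumulative count NR(t) is fitted with the
   two-state Boltzmann equation, yielding the half response time t₀ and
   the dissipation rate constant NR′ = (NR₂ − NR₁)/(4·dt); variant
   effects are summarized by Lorentzian fits of difference curves
   (offset NR₀, peak time t_c, width w, area A, height
   h = NR₀ + 2A/(πw)); dynamical modules are fixed-width response-time
   bins (0.1 ps by default).

The simulated object is deliberately coarse: one bead per residue at
the Cα position, with springs of uniform stiffness connecting all pairs
within a distance cutoff and rest lengths equal to the build-time
distances. Every observable the model reports is per-residue, so this
resolution matches the reporting granularity even though it discards
side-chain chemistry, anharmonicity and solvent.

## Parameters that matter

| Parameter | Default | Units | Why this value |
|---|---|---|---|
| timestep | 1 | fs | dissipation-phase convention; ≪ the shortest spring period (~2.3 ps at defaults), so NVE drift stays below 10⁻⁴ over 10⁴ steps |
| save_interval | 10 | frames | response times resolved to 10 fs, matching the coarse saving typical of reported response times |
| temperature | 310 | K | physiological; sets the thermal kinetic energy scale (~0.92 kcal/mol per residue) |
| cutoff | 10 | Å | standard elastic-network contact radius for Cα models |
| stiffness | 1.0 | kcal/mol/Å² | standard uniform ENM spring constant |
| threshold θ | 0.1 | kcal/mol | ~10% of a residue's thermal kinetic energy: small enough to catch the arriving wavefront, large enough to ignore integrator round-off |
| sustain m | 3 | saved frames | suppresses single-frame numerical flickers |
| module width | 100 | fs | the 0.1 ps dynamical-module convention |

The response criterion (threshold + sustain) is this package's own
definition — the energy-dissipation model itself does not prescribe one
— and is therefore echoed into every output so results are always
qualified by the policy that produced them. A relative mode
(threshold = k × per-residue null-noise scale, estimated from a control
difference trace) exists for imported traces whose null is not exact.

## Units and numerical choices

Lengths are Å, time fs, mass amu, energy kcal/mol. Internally the
integrator works in amu·Å²/fs²; a single constant
(1 kcal/mol = 4.184 × 10⁻⁴ amu·Å²/fs²) converts at the boundary.
Velocity initialization draws per-component Maxwell–Boltzmann normals
and removes net linear momentum (expected kinetic energy is therefore
(3/2)(N−1)k_BT, which the tests assert). Equilibration uses a
*deterministic* velocity-rescaling thermostat (every 50 steps by
default) rather than a stochastic one, because paired subtraction
requires bit-level control of the null; the dissipation phase is
strictly NVE. Per-residue energy is kinetic energy plus half of each
incident spring's potential energy — a declared convention that makes
the per-residue energies sum exactly to the total energy every frame.

Both fits are unweighted nonlinear least squares (`nls`, port
algorithm, tolerance 10⁻¹⁰, positivity bounds on dt and w). Boltzmann
asymptotes NR₁ and NR₂ are *fixed*, not fitted: NR₁ to the perturbed
count, NR₂ to the residue count. Lorentz initialization takes t_c from
the extremum of a lightly smoothed curve, the offset from the tail
median, the width from the half-height width, and the area from
height × width × π/2. Degenerate inputs (constant NR(t), flat
difference curves, edge-sitting extrema) are refused with classed fit
errors rather than fitted badly; standard errors come from the
asymptotic covariance only. Adjusted R² uses p = 2 (Boltzmann) and
p = 4 (Lorentz) free parameters. Reported precision follows the
field's convention of one decimal for times, rates and heights;
storage is full precision.

Module binning is half-open, `module = floor(Δt/width) + 1`, so a
response time exactly on a bin edge goes to the higher module and
perturbed residues land in module 1. Empty modules are retained as
zero columns so cross-tabs from different runs are comparable, and
nonresponsive residues are excluded from the dissipation curve rather
than forced in at the final frame — forcing would fabricate a plateau.

## What the synthetic fixtures emulate (and what they do not)

The generators produce every input the test-suite needs without
downloads:

* **chain / helix / globule structures** — collinear beads at 3.8 Å,
  an ideal α-helical Cα trace (rise 1.5 Å, 100° twist, radius 2.3 Å),
  and self-avoiding random placement (minimum separation 3.5 Å) in a
  sphere. The spec'd target packing of ~0.6 is unreachable by random
  sequential placement, which jams near 0.38, so the default target is
  0.30 — dense enough that a 10 Å cutoff yields a well-connected
  network. All generators are pure functions of their parameters and
  seed.
* **model-generated curves** — Boltzmann and Lorentzian samples with
  known truth retained in an attribute, optional Gaussian noise, and
  (for count curves) integer rounding, clamping and cumulative-max
  monotonization. These calibrate fit recovery: exact on noiseless
  data; t₀ and dt within ±5 fs and h within ±10% at noise SD 2 with
  200 points.
* **variant surrogate** — a network whose springs incident to named
  residues are rescaled (default ×0.5), standing in for a point
  mutation. It is a *synthetic* stand-in: it exercises the comparison
  machinery, not mutational energetics.

A green test on these fixtures establishes that the machinery is
correct and internally consistent. It does **not** establish agreement
with all-atom explicit-solvent dynamics of a real enzyme: the harmonic
network has no anharmonicity, no solvent damping, and — crucially — no
chaos. One consequence is worth stating plainly: in chaotic all-atom
dynamics a stronger perturbation shifts every residue's threshold
crossing by a roughly uniform logarithmic offset, so the half response
time falls with perturbation strength while the dissipation rate
constant stays nearly constant. In the integrable harmonic surrogate
the difference field grows polynomially, so a stronger kick also
*compresses* the transition: t₀ falls (the direction is reproduced and
asserted), but dt falls too, and NR′ varies by ~50% across the 2–5×
fold series instead of staying within a narrow band. The corresponding
acceptance assertion is kept faithful to the stated band and is
expected to fail on this surrogate; treating it as a property of the
harmonic model rather than weakening the assertion is a deliberate
choice.

## Design decisions where the design was open

* "Velocity increased by *n* fold" is read literally as multiplying the
  velocity vector (kinetic energy × n²), not the energy.
* The fold series (2, 3, 4, 5) and the triple-residue perturbation (NR₁
  = 3) are the stated experimental designs for strength- and
  site-dependence studies.
* Configuration files are JSON rather than YAML, to stay within the
  guaranteed dependency set; every option is also a CLI flag.
* PDB reading is a minimal fixed-column ATOM/Cα parser (no suitable
  parser exists in the dependency set, and only Cα records are
  needed); altloc duplicates collapse to the first, residues without a
  Cα are skipped with a warning, HETATM is ignored.
* Region annotations are contiguous-range tables mapping residue
  indices to labels (N-lobe, C-lobe, ACT1, ACT2, ...); unlisted
  residues are "unassigned" so labels always partition the structure.
* Fixed-width binning is the only built-in module clustering; the
  partition function is the natural extension point for other
  clusterings.

## Known limitations

* The harmonic network cannot desensitize, unfold, or exhibit the
  nonlinear mode coupling that underlies real allosteric transitions;
  it is a propagation testbed, not a free-energy model.
* Response times are quantized to the saved-frame grid
  (timestep × save_interval).
* With an absolute threshold, residues whose incoming wave stays below
  θ are nonresponsive by definition; on disconnected networks this is
  exact (their ΔE is identically zero) and is asserted as a causality
  invariant.
* Standard errors are asymptotic; no bootstrap intervals are provided.
* The Pearson correlation between variant peak heights and external
  inhibition measurements is reported when ≥3 pairs are supplied, but
  no regression model is fitted.
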