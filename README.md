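# enerdiss

Energy-dissipation modelling of perturbation propagation in proteins.

## What this package is for

When an effector binds an allosteric enzyme, the binding energy does not
act at a distance: it dissipates residue by residue through the
intramolecular interaction network until the catalytic site feels it.
`enerdiss` implements the energy-dissipation model of that process for
structural bioinformaticians who want to characterize intramolecular
signal transduction quantitatively rather than anecdotally:

* simulate a kinetic-energy perturbation at chosen residues of a
  coarse-grained (Cα elastic-network) protein model, as a surrogate for
  ligand binding at a regulatory site;
* track, via paired perturbed/reference microcanonical trajectories,
  when every residue's energy first responds;
* condense the process into the cumulative dissipation curve NR(t) and a
  small number of interpretable parameters;
* partition residues into *dynamical modules* by response time and
  cross-tabulate them against structural regions;
* compare variants (e.g. point mutants, modelled as locally softened
  springs) against the wild-type through difference curves.

Externally produced per-residue energy traces (e.g. from all-atom MD)
can be imported in the package's delimited-text trace format and pushed
through the same analysis chain.

## The model

The cumulative count of responded residues follows a sigmoid described
by the two-state Boltzmann equation

```
NR(t) = NR2 + (NR1 − NR2) / (1 + exp((t − t0)/dt))
```

where `NR1` is the initial number of affected residues (the perturbed
set), `NR2` the final number, `t0` the **half response time**, and `dt`
a time constant. The **dissipation rate constant**, the slope at the
curve's centre, has the closed form

```
NR' = (NR2 − NR1) / (4·dt)        [residues/fs]
```

A variant-minus-wild-type difference curve ΔNR(t) is a peak described by
the Lorentz equation

```
ΔNR(t) = NR0 + (2A/π) · w / (4(t − tc)² + w²),   h = NR0 + 2A/(π·w)
```

with offset `NR0`, peak time `tc`, width `w`, area `A` and peak height
`h` — the summary statistic for how strongly the variant perturbs the
dissipation process.

Response times themselves are detected from the perturbed-minus-reference
energy difference with a configurable threshold-plus-sustain criterion
(default: |ΔE| ≥ 0.1 kcal/mol over 3 consecutive saved frames; perturbed
residues respond at t = 0 by definition).

## Worked example

A 100-residue synthetic globule, springs within 10 Å, perturbed by
quadrupling the velocity of residue 1 after thermal equilibration at
310 K:

```r
library(enerdiss)

s   <- synth_structure(100, "globule", seed = 42)
net <- build_network(s, cutoff = 10, stiffness = 1)
cfg <- simulation_config(n_steps = 4000, equilibration_steps = 500, seed = 7)
st  <- equilibrate(net, init_state(net, temperature = 310, seed = 7), cfg)

pair <- run_pair(net, st, residues = 1, factor = 4, cfg)
prof <- detect_response_times(delta_energy(pair$perturbed, pair$reference),
                              detection_policy(), perturbed_set = 1)
fit  <- fit_boltzmann(dissipation_curve(prof), NR1 = 1, NR2 = 100)
print(fit)
```

```
Two-state Boltzmann fit (NR1 = 1, NR2 = 100 fixed)
  t0 (half response time): 1086.1 +/- 2.3 fs
  dt (time constant):      279.8 +/- 2.2 fs
  NR' (dissipation rate):  0.1 residues/fs
  adj-R2: 0.996  (n = 401)
```

Half of the globule's residues have responded by ~1.09 ps, and during
the exponential stage roughly one residue responds every 10 fs. The
region summary and the dynamical-module cross-tab come from the same
profile:

```r
ann <- synth_annotation(100, c(0.5, 1), c("regulatory", "catalytic"))
region_mean_response(prof, ann)
#>       region n_responsive n_nonresponsive   mean       sd
#> 1        All          100               0 1124.6 476.4607
#> 2 regulatory           50               0 1124.0 538.8989
#> 3  catalytic           50               0 1125.2 404.4959

module_region_table(partition_modules(prof, width = 100), ann)
```

The closed-form helpers reproduce published-style table arithmetic
directly, with no simulation:

```r
round(dissipation_rate_constant(1, 447, 100.3), 1)   # 1.1 residues/fs
round(lorentz_height(-12.8, 502.0, 45763.5), 1)      # 45.2 residues
```

## Command line

An executable `enerdiss` script (installed under `exec/`) exposes the
pipeline as subcommands:

```sh
enerdiss simulate --out run --residues 1 --factor 4 --steps 4000 toy.pdb
enerdiss analyze  --out analysis run_perturbed.tsv run_reference.tsv
enerdiss compare  --out cmp wt_curve.tsv variant_curve.tsv
enerdiss fit      --out fit.json curve.tsv
enerdiss synth    --out fixture.pdb spec.json
```

Exit codes: 0 success, 2 input/format error, 3 numerical/fit error.
Every run writes a JSON manifest (config echo, input hashes, seed)
sufficient to reproduce it bit-identically.

## Further reading

See the methods vignette (`vignettes/energy-dissipation.Rmd`) for the
model's assumptions, the detection-policy and synthetic-fixture design
choices, numerical details, and known limitations of the elastic-network
surrogate.
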