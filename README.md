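# cfmstack

Analysis of centrifuge force microscope (CFM) force-clamp experiments on
DNA tethers, from raw bead movies (or pre-extracted dissociation tables)
to single base-stacking free energies.

A CFM spins a miniature video microscope inside a centrifuge bucket,
applying a calibrated constant force `F = m ω² r` to hundreds of
bead-tethered DNA duplexes in parallel. Each duplex dissociates as a
first-order process; the fraction of tethers remaining is fit with the
single-exponential decay

```
y(t) = y0 + A exp(-k t)
```

to give the off-rate `k` at the applied force. Comparing a construct with
a single terminal base stack against a no-stack control — identical base
pairing, equal on-rates — isolates the stacking free energy

```
ΔG_stack = RT ln(k_stack / k_control)      (kcal/mol, negative = stabilising)
```

and the Bell-Evans model `k(F) = k_thermal exp(F/f)` relates the force
dependence of the off-rates to the transition-state distance
`x‡ = k_B T / f`.

The package implements every stage: force calibration from centrifuge RPM,
bead detection by a circular Hough transform with variance-drop
dissociation calling, survival-curve construction and bounded nonlinear
fitting, replicate aggregation, Bell-Evans fitting, and ΔG extraction with
propagated errors. Because the raw movies behind the published datasets are
too large to be distributed, a first-class synthetic-data module generates
dissociation datasets and rendered bead movies with known ground truth
(exponential dissociation, stuck-bead and multi-tether fractions, paired
stack/control arms whose off-rate ratio encodes a chosen ΔG), so the whole
pipeline is testable end to end. For whom: single-molecule biophysicists
running CFM (or other force-clamp) dissociation assays, and anyone needing
a tested survival-curve → off-rate → energy pipeline.

## Worked example

A paired experiment at 15 pN: a stacked construct simulated at
ΔG = −1.9 kcal/mol against its no-stack control (off-rate 0.02 s⁻¹),
3 replicates × 500 tethers per arm, 5 s saved frames.

```r
library(cfmstack)

cfg <- acquisition_config(rpm = 1221)
cfg
#> CFM acquisition config
#>   rpm: 1221  (force 15.00 pN, RCF 222 g)
#>   rotor radius: 0.133 m, bead mass (eff): 6.9e-15 kg
#>   temperature: 294.15 K, frame interval: 5 s

pe <- paired_experiment(dG_stack = -1.9, control_rate = 0.02,
                        n_replicates = 3, seed = 8)
stack <- fit_replicates(pe$stack, frame_interval = 5,
                        construct = "A|C", force = 15)
ctrl  <- fit_replicates(pe$control, frame_interval = 5,
                        construct = "control", force = 15)

stack$fits[[1]]
#> Single-exponential fit y = y0 + A exp(-k t): k = 0.0007753 /s, A = 0.980, y0 = 0.036, R^2 = 0.9994 (n = 500)

stack$estimate
#> Off-rate A|C at 15 pN: k = 0.0007603 +/- 2.3e-05 /s (3 replicates, n = 1500 tethers)
ctrl$estimate
#> Off-rate control at 15 pN: k = 0.01989 +/- 0.00011 /s (3 replicates, n = 1500 tethers)

delta_g_stack(stack$estimate, ctrl$estimate)
#> dG_stack (A|C vs control, 15 pN): -1.91 +/- 0.02 kcal/mol (RT = 0.5845 at 294.15 K)
```

Reading the output: each replicate's survival curve is fit for `k` (the
`y0 = 0.036` offset absorbs the stuck-bead fraction); replicates aggregate
to mean ± sd; the off-rate ratio gives back the configured −1.9 kcal/mol
within the propagated error. The stack arm dissociates ~26× slower than
the control — a factor `exp(1.9/RT)` with RT = 0.5845 kcal/mol at 294.15 K.

To run from image stacks instead, `track_experiment()` (or the `track`
subcommand of `inst/scripts/cfm-pipeline.R`) turns a multi-page TIFF into
the same dissociation-dataset format, with attrition counts (clustered /
edge / off-focus / multiple-drop exclusions) in a run log.
`run_pipeline()` chains every stage from a single YAML config (a demo
config ships in `inst/extdata/`) and writes per-stage CSVs plus a JSON
run manifest for bit-identical reruns.

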