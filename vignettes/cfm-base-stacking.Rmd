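---
title: "Methods: force-clamp dissociation analysis of single base stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: force-clamp dissociation analysis of single base stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmstack)
```

## The measurement

A centrifuge force microscope (CFM) spins a miniature video microscope in a
centrifuge bucket, applying a calibrated, constant centrifugal force to
hundreds of DNA tethers in parallel. Each tether links a microsphere to a
cover glass through a weak central duplex; when that duplex dissociates, the
bead leaves the field of view. The fraction of tethers remaining over time
is a survival curve whose exponential decay rate is the off-rate at the
applied force.

Two constructs differing only by a single terminal base stack dissociate at
different rates. Under the standard assumption that their on-rates and
transition states are unchanged by the terminal base, the stacking free
energy is the difference in activation energy,

$$\Delta G_\mathrm{stack} = RT \ln\!\frac{k_\mathrm{stack}}{k_\mathrm{control}},$$

negative when the stack stabilises the duplex. The logarithmic dependence
is what makes kinetic measurement sensitive enough for energies of order
1 kcal/mol.

## Force calibration

The force on a bead is $F = m\,\omega^2 r$, with $m$ the buoyancy-corrected
bead mass, $\omega$ the angular velocity from the spin rate, and $r$ the
rotor radius. Defaults are $m = 6.9\times10^{-15}$ kg (2.8 µm streptavidin
beads) and $r = 0.133$ m:

```{r}
cfg <- acquisition_config()
rpm_to_force(c(1410, 1221, 997, 705), cfg)  # pN
rpm_to_rcf(c(1410, 705), cfg)               # multiples of g
```

Units are SI internally; the interface speaks pN, nm and kcal/mol, and the
conversion factors appear only in the converter functions. The default
temperature is 294.15 K (21 °C room temperature); published transition
distances round consistently for any choice in 294–298 K, so the
temperature is configurable everywhere it enters.

## Bead tracking and dissociation calling

Tracking operates on the first frame at final spin rate (time zero; spin-up
frames are ignored):

1. **Detection** — a gradient-accumulator circular Hough transform. Strong
   gradient pixels vote along their gradient direction at each candidate
   radius (3–6 px by default); accumulator peaks are normalised by
   circumference so the score is the fraction of a circle's edge that
   voted (`sensitivity`, default 0.3, is the acceptance threshold). A
   polarity check — the candidate centre must be brighter than its
   surround by twice the frame's robust noise scale — rejects diffuse
   accumulator ridges cast outside real beads by the dark annulus.
2. **Exclusions** — pairs closer than `min_separation_px` (default 10 px)
   are both excluded ("clustered"); beads whose ROI clips the frame edge
   are excluded ("edge", variance statistics would be biased); beads whose
   first-frame Laplacian energy falls outside median ± 3×MAD of all
   detections are excluded ("off_focus"), since atypical focus suggests
   multiple tethers. The outcome is order-independent.
3. **Variance trace** — per-frame intensity variance in a fixed
   (2w+1)² ROI at the first-frame position, with
   w = ceiling(1.5 × detected radius). Tethered beads are laterally
   confined, so the ROI never re-centres.
4. **Calling** — the baseline is the 90th percentile of the first 5
   frames' variance. A dissociation is called at the first frame where the
   variance drops below `theta` × baseline (default 0.5) and stays below
   for `persistence` frames (default 3); a trace that never drops is
   censored; a sustained drop followed by recovery is excluded
   ("multiple_drops", possible multiple tethers). The upper-quantile
   baseline (rather than a median) still anchors to the bead-present level
   when the bead dissociates inside the baseline window itself, so very
   early events are called rather than silently censored. Lowering `theta`
   can only delay a call, never advance it.

None of the thresholds comes from a published value — the original
analysis used visual pre-screening and an unquantified "sharp drop" — so
all are parameters with the defaults above, chosen so that a disappearing
bead at contrast/noise ≥ 5 clears the threshold several-fold.

## Survival curves and the single-exponential fit

The survival curve is the fraction of tethers remaining on the saved-frame
grid; censored beads count as remaining throughout, and points after the
last event are retained to the experiment end so the baseline offset stays
identifiable. The model

$$y(t) = y_0 + A\,e^{-kt}$$

is fit by bounded Levenberg–Marquardt least squares (`minpack.lm::nls.lm`)
with $y_0 \in [0,1]$ absorbing stuck beads, $A \in (0, 1.5]$, $k > 0$.
Initialisation: $y_0$ from the curve's final value, $A = 1 - y_0$, and $k$
from the area under the baseline-corrected curve (the mean lifetime); a
deterministic ladder of up to five perturbed restarts handles the rare
non-convergence, and failures are reported, never silently defaulted. The
fit target is the full survival curve, not the binned histogram — the
histogram (span-scaled bin widths, floored at one frame) is kept for
display and QC only, which avoids any bin-width sensitivity in the rates.
$R^2$ is computed as $1 - SS_\mathrm{res}/SS_\mathrm{tot}$ against the
empirical curve; no weighting is applied.

Replicate off-rates are aggregated as the unweighted mean ± sample
standard deviation across replicates (conditions are normally at least
triplicate; fewer replicates warn and are flagged).

## Bell-Evans analysis and stacking energies

Force-dependent off-rates follow $k(F) = k_\mathrm{thermal}\,e^{F/f}$ with
force scale $f = k_BT/x^\ddagger$. The fit is weighted linear least
squares of $\ln k$ on $F$. Delta-method inverse-variance weights
$1/\mathrm{se}^2$ with $\mathrm{se} = k_{sd}/k_{mean}$ are regularised by
the median, $w = 1/(\mathrm{se}^2 + \mathrm{median}(\mathrm{se}^2))$:
variance estimates from three replicates are themselves noisy, and an
accidentally tiny sd would otherwise pin the whole line to one force
(simulations showed the unregularised weights inflate the force-scale
error tail noticeably). Unit weights are used when any sd is zero. The
transition distance is $x^\ddagger = k_BT/f$, tied to the force scale
exactly by construction.

```{r}
transition_distance(8.8)  # nm, at the default 294.15 K
```

Stacking energies use first-order (delta-method) error propagation on the
rate ratio,
$\sigma_{\Delta G} = RT\sqrt{(k_{sd}/k)^2_\mathrm{stack} +
(k_{sd}/k)^2_\mathrm{control}}$, with the stacked construct in the
numerator so stabilising stacks are negative. `delta_g_by_force()` checks
the force-independence expected of an equilibrium quantity: energies
computed at different forces should overlap within their propagated
errors, and any pair that does not is flagged.

## What the synthetic generator emulates

`tether_population_model()` encodes the statistical structure the analysis
assumes: single tethers dissociating exponentially, a small stuck fraction
(default 2%) censored for the whole run, and a rare slow phase (default
1%, at one tenth the off-rate) standing in for multi-tether beads. The
published account describes both non-idealities only qualitatively ("small
percentage", "rarely observed"), so the defaults are exposed parameters,
not asserted facts. The default study conditions — control off-rate
0.02 s⁻¹ at a nominal 15 pN, 7200 s recordings, 5 s saved frames, 3
replicates of 500 tethers — reproduce the published experiment scale
(runs of 10–100 min, up to 2 h, tens to hundreds of tethers per run).

`render_movie()` draws each bead as a bright-centred disc with a dark
annulus (high local intensity variance, matching the variance-based
dissociation call) that vanishes instantaneously between consecutive saved
frames, on a flat background with additive Gaussian noise. A `blur_sigma`
flag renders a bead defocused for testing the focus exclusion. Everything
is deterministic given the seed; replicate seeds derive from a master seed
by a fixed multiplicative-congruential mixing rule (`derive_seed()`).

Deliberately **not** simulated: Brownian bead motion, spin-up force ramps,
tether elasticity, optical point-spread physics, gradual defocus, camera
shot noise or vignetting. Passing tests therefore demonstrate that the
analysis recovers the assumed kinetic structure from idealised images and
event data — they do not certify performance on real movies with drift,
uneven illumination, or debris, where the visual pre-screening the
original workflow used would still earn its keep.

## Numerical choices and degenerate inputs

- Dissociation times exceeding the recording are censored at the
  recording end, never discarded; the fit's $y_0$ absorbs them.
- A dissociation time is always a whole number of saved frames; a
  continuous true time $t$ is recovered as the first absent frame,
  $\Delta\,\lceil t/\Delta \rceil$.
- A below-threshold run shorter than `persistence` at the end of a trace
  is censored (conservative: no event time from an unconfirmed drop).
- Zero detections on a frame is an empty result, not an error; an empty
  dataset, a survival curve with no events, or fewer than three forces in
  the Bell-Evans fit are errors.
- Non-positive Bell-Evans slopes are flagged and given no barrier
  interpretation.
- Test and acceptance runs use 3 × 500 tethers per arm for energy
  recovery, 100-bead movies for tracking, n = 1000 for fit-vs-MLE
  comparisons, and 20-seed batches for distributional checks — sizes at
  which the sampling error of each check is several times smaller than
  the tolerance it asserts.

## Known limitations

- The stacking energy rests on the equal-on-rate assumption; the package
  checks internal consistency (parallel Bell-Evans slopes, force-independent
  ΔG) but cannot test the assumption itself.
- The slow (multi-tether) phase is treated as a non-ideality, not a model
  term; no double-exponential or mixture fit is provided.
- No sub-pixel localisation or drift correction: the tracker assumes
  laterally confined beads and a stable stage.
- Temperature extrapolation of ΔG (enthalpy/entropy decomposition) is out
  of scope.
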