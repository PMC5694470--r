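---
title: "Two-step TdP risk classification from multi-channel block at EAD-generating concentrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step TdP risk classification from multi-channel block at EAD-generating concentrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mcbead)
```

## The problem

Drug-induced Torsades de Pointes (TdP) is classically linked to block of the
hERG channel (the rapid delayed-rectifier current $I_{Kr}$), but hERG block
alone is a mediocre predictor: block of depolarizing currents — the L-type
calcium current $I_{CaV}$ and the late sodium current $I_{NaL}$ — mitigates
torsadogenic risk, while block of repolarizing currents such as $I_{Ks}$
enhances it. `mcbead` implements a two-step classifier that encodes this
mechanism, together with the biophysical layer used to motivate and
calibrate it.

## Dose–response layer

Channel assays enter as IC50 (in nM) and Hill coefficient $h$ per channel.
Fractional block at a free drug concentration $C$ is

$$\mathrm{Block} = 100\,\frac{C^h}{IC_{50}^h + C^h},$$

and a blocked channel's maximal conductance is scaled by
$(1-\mathrm{Block}/100)$. The concentration producing a fraction $f$ of
block has the closed form $IC_{50}\,(f/(1-f))^{1/h}$; `ic60_herg()` always
derives the 60%-block concentration from IC50 and $h$, never from input
columns. Both directions are evaluated in log space so extreme
concentration/IC50 ratios cannot overflow, and they round-trip to a relative
tolerance of 1e-10 (asserted in the test suite). Missing Hill coefficients
default to 1; missing channel assays are treated as zero block and recorded
in the panel's provenance sidecar.

The step-1 statistic is the **hERG ratio** $IC_{60,hERG}/\mathrm{EFTPC}$:
how far the effective free therapeutic plasma concentration sits below the
concentration producing the EAD-generating degree of hERG block. A drug with
$IC_{60,hERG}$ = 500 nM and EFTPC = 1 nM has ratio 500 and is never
torsadogenic in this framework.

## The myocyte models

`cell_spec()` builds one of two human ventricular myocyte models:

* `OHR` — the O'Hara–Rudy (2011) epicardial/endocardial/mid-myocardial
  formulation, transcribed in full (41 state variables) in compiled code;
* `OHRmv` — the same model with the maximal conductances of $I_{Kr}$,
  $I_{Ks}$, $I_{K1}$, $I_{CaL}$ and $I_{NaL}$ rescaled by the published
  Dutta et al. optimisation factors (1.013, 1.870, 1.698, 1.007, 2.661).

`gnal_scale = 2` doubles the late-sodium conductance before drug scaling and
is used as an LQT3-like sensitised configuration. Drug effects enter
exclusively as per-channel conductance multipliers (conductance-block model;
no state-dependent binding).

The mid cell is the EAD-prone cell type and is the default for all EAD
work. Baseline physiology was checked against the published model: resting
potential ≈ −88 mV, steady-state APD90 at 1 Hz ≈ 268 ms (endo), ≈ 227 ms
(epi) and ≈ 330–337 ms (mid), with the mid cell showing the largest calcium
transient.

### Integration

Two schemes are provided (`integrator_config()`):

* `forward_euler_fixed`, default step 0.001 ms — the gold standard, and
  mandatory for any run whose outcome is an EAD call; halving the step
  changes APD90 by well under 0.5 ms.
* `hybrid_rapid`, default step 0.01 ms — forward Euler for concentrations
  and membrane voltage plus Rush–Larsen exponential updates for the 28
  gating variables. About an order of magnitude faster; used for
  steady-state biomarker runs and for conditioning phases.

Voltage-dependent rate expressions are tabulated on a 0.01 mV grid with
linear interpolation; the interpolation error is orders of magnitude below
solver error. Reversal potentials and the IKs calcium-sensitivity factor
are refreshed every 0.01 ms of simulated time (the underlying ion pools
drift by <1e-5 mM over that horizon).

One numerical guard matters scientifically: the junctional-SR release
equations are unprotected as $Ca_{JSR}\to 0$, and in the strongly driven
mid cell an explicit step can push $Ca_{JSR}$ (non-physically) below zero,
after which the release machinery locks into a degenerate becalmed state.
The integrator therefore floors the calcium pools at tiny positive values.
Without the floor the mid cell's calcium cycling collapses over long
2-Hz trains and EAD propensity is grossly understated.

## The pause protocol and EAD detection

TdP onset is classically preceded by a short–long cycle; `pause_protocol()`
implements the corresponding cellular protocol: 200 stimuli at a 500 ms
cycle length, then a single stimulus after a quiescent interval (`pause`).
Two readings of "a stimulus following a pause of X ms" are possible; here
`pause` is the interval between the final two stimuli, so
`pause = cycle_length` degenerates to uninterrupted pacing. This reading
reproduces the models' published pause-EAD thresholds; appending the pause
to a full final cycle shifts all thresholds several points lower.

EAD induction is sensitive to the slow state (intracellular Na, SR load,
CaMK activation), which takes hundreds of beats to approach its 2-Hz
steady state. The protocol therefore conditions the cell for 800 beats at
the protocol cycle length (drug applied) before the documented 200-stimulus
train — a fixed-count, 1000-beat approach to steady state, mirroring the
fixed-count convention used for biomarker runs. The conditioning phase may
run under the rapid integrator; the final 200 beats, the pause and the
post-pause beat always run under fixed-step Euler. Threshold estimates with
fully-Euler conditioning agree with the hybrid default.

`detect_ead()` flags a beat when, after the primary upstroke has turned
into repolarization, the voltage — while still above −60 mV — depolarizes
again at more than +0.01 mV/ms sustained for at least 1 ms. The three
numbers are exposed in `ead_config`; with the defaults the detector
reproduces the models' published integer thresholds, and the calls it makes
near threshold are unambiguous re-upstrokes of tens of mV, not borderline
wiggles.

`ead_herg_threshold()` reports the minimal integer hERG block that triggers
a pause-induced EAD. It scans upward (5% steps, then 1% refinement) rather
than bisecting: well above the onset, strong block can push the 2-Hz
conditioning train into alternans and the EAD call flickers with block
percentage, so the response is not globally monotone and a bisection can
skip the onset region entirely. With this machinery:

* OHR mid: EADs from ~55% hERG block at a 700 ms pause, ~47% at 1000 ms.
* OHRmv onsets a couple of points below OHR at the short pause (~53%) and
  more at the long pause (~39%) — the rescaled variant's stronger late
  sodium current makes it markedly more pause-sensitive here.
* With `gnal_scale = 2` the sensitised model is far more vulnerable: on a
  10% grid, EADs appear from ~10% hERG block, and at 30% block ICaV block
  up to ~30% leaves them intact.

At fixed 60% hERG block, `ead_persistence_limit()` sweeps one channel on a
10% grid: $I_{CaV}$ block above ~30% suppresses EADs in both variants, and
$I_{NaL}$ block suppresses them in OHRmv only above ~60%. EAD status
changes at most once along these axes; the full 3-axis scan
(`scan_grid()`, 11³ points at 10% steps) is expensive and is typically run
at a 25% step or on explicit axis subsets.

## The two-step classifier

Step 1 gates on the hERG ratio: drugs at or above a threshold (candidates
50, 100, 150, 200) are declared TdP−. Step 2 fits a logistic regression on
channel-block features evaluated at $IC_{60,hERG}$ — deliberately
independent of EFTPC — for the remaining drugs; overall training accuracy
(gated drugs counted as TdP− predictions) selects the threshold, ties going
to the smallest candidate. The EFTPC thus only matters for step 1, which
makes predictions robust to the notorious variability of reported EFTPCs:
perturbations that keep a drug on the same side of the gate provably cannot
change its prediction.

The logistic fit uses IRLS with a very weak, scale-relative ridge penalty
(1e-6; intercept unpenalised). Step-2 feature sets at EAD-generating
concentrations are often linearly separable, where the unpenalised MLE
diverges; the ridge keeps coefficients finite while leaving
well-conditioned fits indistinguishable from `glm` (asserted in tests).
The one-step baseline (`fit_one_step()`) is the same logistic fit on block
features at EFTPC, with no gate.

`loo_accuracy()` re-runs the whole procedure — including threshold
re-selection — inside every leave-one-out fold. Folds whose training set
degenerates to one class score with the majority-class prediction.

For three-class (CiPA-style) labels, `fit_ternary()` collapses the features
into an equal-weight sum (% $I_{CaV}$ block + % $I_{NaL}$ block + the
drug-trapping scalar) and fits two one-dimensional logistic boundaries on
it — high vs rest and low vs rest — among drugs below the upper hERG-ratio
gate; two fixed ratio thresholds (25 and 150 by default) complete the
partition of the risk plane.

## Risk maps

`build_risk_map()` rewrites the fitted step-2 hyperplane
$\beta_0 + \beta_{CaV}\,b_{CaV} + \sum_i \beta_i f_i = 0$ in
$\beta_{CaV}$-normalised form, so the y-axis is
$b_{CaV} + \sum_i (\beta_i/\beta_{CaV}) f_i$ with threshold
$-\beta_0/\beta_{CaV}$ and the x-axis is the hERG ratio (log scale) with
the model's gate. Which side of the y-threshold is high-risk follows the
sign of $\beta_{CaV}$ rather than an assumed orientation, and the region
classification is asserted (per drug, in tests) to be algebraically
identical to the model's predictions. `plot_risk_map()` returns the
coordinates table alongside the figure so the geometry is testable without
rendering; the EAD suppression boundary (e.g. 30% $I_{CaV}$ block) can be
overlaid as a rectangle outline.

## Synthetic panels

`generate_synthetic_panel()` draws hERG IC50s log-uniformly over
10 nM–100 µM with Hill coefficients in 0.8–1.6, hERG ratios log-uniformly
over 1–10⁴ (EFTPC back-computed), and the $I_{CaV}$ block at
$IC_{60,hERG}$ uniformly over 0–100%; the ground truth is TdP+ iff
ratio < `ratio_threshold` and CaV block < `cav_cutoff`, with optional
label-flip noise. The class regions are separated by a 2-percentage-point
margin around the CaV cutoff so that noise-free panels remain strictly
separable under leave-one-out refits of the boundary — without a margin
the refitted boundary can land exactly on a held-out boundary drug. These
defaults are the study conditions for the property suite: threshold
recovery, 100% LOO at n = 200, near-null accuracy under label permutation
(interpreted against the majority-class rate for unbalanced panels).

What the generator deliberately does not emulate: correlated multi-channel
pharmacology (real hERG blockers often also block CaV), assay noise and
inter-laboratory IC50 variability, and label noise structure beyond
independent flips. Passing tests on synthetic panels therefore validate
the machinery, not field performance on real assay data.

## Problem sizes and runtime

The package's own test and benchmark runs use: 1000-beat conditioning for
EAD thresholds (800 rapid + 200 gold-standard beats), an upward scan in 5%
steps refined to 1% for the hERG thresholds (~15 simulations per
threshold, heavily memoised across pause lengths), 10%-grid persistence
sweeps resolved by monotone binary search, and reduced (3–5 point) grid
probes for the scan smoke test. Steady-state biomarker examples use the
rapid integrator and fixed beat counts stated inline.

## Known limitations

* Conductance-block pharmacology only; no state-dependent or kinetic drug
  binding (the drug-trapping scalar enters as a classifier feature, not as
  channel kinetics).
* Single-cell only; no tissue-level dispersion metrics.
* The mid cell under strong drive operates at the edge of its calcium
  subsystem's validity (see the positivity guard above); biomarkers from
  long mid-cell trains should be interpreted with that in mind.
* Reported EAD thresholds are model properties; they shift by a few
  percentage points under alternative readings of the conditioning state
  and pause bookkeeping, which is why the detector's criterion and the
  protocol are exposed as configuration rather than constants.
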