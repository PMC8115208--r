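---
title: "Methods: lateral foot-placement control analysis and the frontal-plane walker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lateral foot-placement control analysis and the frontal-plane walker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package addresses

During walking, lateral balance is maintained largely by choosing where to
put the next foot. A standard way to quantify this coordination is to
regress the lateral foot placement of each step on the lateral
center-of-mass (COM) state — position relative to the stance foot, and
velocity — sampled at successive instants of the preceding swing phase:

\[
FP_x(i) = \beta_1(i)\,COM_x(i) + \beta_2(i)\,COM_v(i) + \varepsilon(i),
\]

where \(i\) indexes the swing phase on a 0–100% grid in 2% increments (51
nodes). The predictors are demeaned before fitting, and the per-node
coefficient of determination \(R^2(i)\) — the fraction of foot-placement
variance explained by the COM state — is the primary outcome. In
unimpaired gait \(R^2\) rises across the swing and approaches 1 by initial
contact; weaker or flatter curves indicate stepping that is less tightly
coupled to the COM state, as reported after stroke. `stridefield`
implements this analysis chain from raw marker trajectories to
R²-time-series inference, together with step-width metrics and a
frontal-plane walker simulator that generates marker-level synthetic data
with known ground truth, including a lateral velocity-damping force field
(gain 50 N·s/m) applied to the pelvis.

## Analysis conventions

* **Filtering.** 4th-order Butterworth low-pass at 6 Hz, applied forward
  and backward (zero phase) so event timing is not lagged. The
  forward–backward pass squares the magnitude response; tests check the
  analytic \(|H(f)|^2\) at 1 Hz and 20 Hz. Ends are padded by odd
  reflection (up to 200 samples) so start-up transients fall outside the
  signal. Gap-filling (cubic spline, interior gaps only, default max 10
  frames) precedes filtering, which requires contiguous samples; gaps are
  never extrapolated beyond a marker's observed span.
* **Events.** Gait events in clinical mocap practice are often checked
  or placed manually, so no single algorithm is canonical. The rule used
  here works on the vertical positions of the two foot markers: a swing
  excursion is a run where the marker exceeds its stance baseline by a
  tolerance (default 5 mm); foot-off is the last frame still settled at
  the baseline (settle tolerance 0.05 mm) before a 5th-metatarsal
  excursion, and initial contact the first settled frame after a
  calcaneus excursion. Earliest-frame tie-breaking makes the rule
  deterministic; both tolerances are arguments. On clean synthetic
  profiles the rule recovers ground-truth frames exactly; the acceptance
  checks allow ±2 frames.
* **COM state.** Centroid of four pelvis markers (`LASIS`, `RASIS`,
  `LGT`, `RGT` by default; the label set is configurable). Velocity is a
  central finite difference of the absolute lateral position — on a
  treadmill the lateral axis has no belt motion, and the stance foot is
  fixed within a swing, so stance-relative and absolute derivatives
  coincide.
* **Sign convention.** Each swing's COM position (relative to the stance
  calcaneus at its own initial contact), COM velocity and foot placement
  are signed positive toward the swing side. Left and right swings then
  pool into one regression; a single series is fit for unimpaired
  (control) trials while paretic and non-paretic series are fit on the
  steps where that limb swings.
* **Regression.** The model above has no intercept; with demeaned
  predictors an uncentered response would push its mean into
  \(\varepsilon\), so the response is centered per cell as well, making
  the intercept-free model exact. \(R^2\) is the regression sum of
  squares over the total (centered) sum of squares; raw, not adjusted.
  `resid_var` is RSS/n so that \(R^2 = 1 - \mathrm{resid\_var}\cdot
  n/\mathrm{TSS}\) holds identically. Coefficient tests use normal-theory
  t statistics on \(n-3\) degrees of freedom. Steps with any unusable
  node are dropped listwise so all 51 nodes fit on the same step set.
* **Step selection.** Only the last 50 valid steps of a trial are
  analyzed, counting both sides jointly in time order; short trials are
  used in full with a warning. Repeated trials of the same condition are
  pooled at the step level before fitting.
* **Step width.** Magnitude of the lateral distance between the
  contacting calcaneus at its initial contact and the contralateral
  calcaneus at the contralateral side's *preceding* initial contact. The
  preceding-contact rule — the natural reading of a per-limb step width —
  is applied uniformly to all limbs. Variability is the sample
  SD. Group-level mixed models are deliberately out of scope; the module
  emits per-subject summaries and a simple paired comparison.

## Statistical parametric mapping

The 51-node R² series are compared with a fixed-effects two-way ANOVA
(limb × field) computed per node and thresholded as a 1D random field.

* **Design.** A three-level limb factor with mixed between/within
  structure (control subjects contribute one curve, stroke subjects two)
  has no clean classical two-way ANOVA, so the implementation uses a
  cell-means fixed-effects ANOVA treating subject-limb curves as
  independent samples and notes the approximation; the post-hoc
  pairing rule (paired for paretic vs non-paretic, two-sample against
  control) restores the key within-subject dependence. Per-node F values
  are validated against `aov` to 1e-8.
* **Smoothness.** Residual fields are variance-normalized per node;
  forward-difference gradients pooled across fields give
  \(\widehat{FWHM} = 1/\overline{\sqrt{v/4\ln 2}}\) (for white noise this
  converges to \(\sqrt{2\ln 2}\approx 1.18\) nodes; fields smoothed with
  a known kernel are recovered within 15% in tests). Spatially constant
  fields are flagged maximally smooth.
* **Threshold.** The critical value solves
  \(\alpha = P_{\text{tail}}(u) + R\,\rho_1(u)\) with resel count
  \(R = (n_{\text{nodes}}-1)/FWHM\) and the 1D Euler-characteristic
  densities of t and F fields. t thresholds are two-sided (they control
  \(\max|t|\)). Monte-Carlo max-statistic oracles in the test suite hold
  the t threshold to 3% of the empirical 95th percentile (10,000 fields)
  and the F-field family-wise error to the nominal level plus two
  Monte-Carlo standard errors (2,000 null cohorts of 18 fields each).
* **Reporting.** Suprathreshold clusters are maximal runs above the
  threshold, reported in % of swing. Cluster-level p values are not
  computed. Post-hoc pairwise t fields use Bonferroni-corrected per-pair
  levels (`alpha_family`/3 = 0.0167 for three limb pairs).

## The frontal-plane walker

Within each step the lateral COM follows a linear inverted pendulum about
the stance foot, with the damping field as a velocity-proportional force
on the COM (the device it models applies forces at the pelvis):

\[
\ddot x = \omega^2 (x - u) - (b/m)\,\dot x, \qquad \omega^2 = g/L,
\]

with mass 75 kg and leg length 0.9 m (\(\omega \approx 3.3\) s\(^{-1}\))
by default, and \(b \in \{0, 50\}\) N·s/m. Double support is collapsed to
an instantaneous transition; placement is imposed kinematically. At a
configurable control node (default: end of swing) the walker commands

\[
FP = W + g_p\,(p - p^\*) + g_v\,(w - w^\*) + \varepsilon,
\]

where \((p, w)\) is the stance-relative COM state signed toward the swing
side and \((p^\*, w^\*)\) its periodic-gait reference at that node,
obtained in closed form from \((I + M_T)z_0^\* = (W, 0)^\top\) with
\(M_T\) the step transition matrix.

**Stability dictates the gains.** In signed coordinates the step-to-step
return map has determinant \(1-g_p\) and trace \((g_p-1)\cosh\omega T +
g_v\,\omega\sinh\omega T - \cosh\omega T\); the dead-beat solution for
end-of-swing control is \(g_p = 1\), \(g_v = \cosh\omega T/(\omega
\sinh\omega T)\). Two consequences shaped the presets:

* The regression gains reported for human mid-stance in the literature
  (≈2.01 and 0.44) lie far outside the stability region of this reduced
  model — a pendulum stabilized *only* by foot placement diverges under
  them. Coefficient-recovery experiments therefore use
  `simulate_step_ensemble()`, which integrates each step independently
  from a randomized initial state near the periodic gait; refitting the
  placement law at the control node recovers the configured gains
  without bias (checked with 200 replicate cells and with the literature
  gains over 500 steps).
* The `stroke_like` preset halves the position gain (0.5), which forces
  the return map's determinant to 0.5; its velocity gain is set near the
  center of the remaining stability window (0.46 at the preset's 0.7 s
  steps) rather than also being halved — a halved velocity gain simply
  falls over. Slower (0.7 s vs 0.5 s), wider (0.18 m vs 0.12 m) and
  noisier (placement noise 8 mm vs 4 mm) steps complete the preset.

**Noise model and defaults.** Three seeded sources create step-to-step
variability: placement noise \(\varepsilon\) (control 4 mm), a velocity
perturbation at each transition (state noise; control 4 mm/s), and white
acceleration noise within the step (process noise; control
0.03 m/s²). Perturbations are amplified within a step by roughly
\(e^{\omega T}\) (≈5 at 0.5 s, ≈10 at 0.7 s), so the stroke preset uses
*smaller* raw perturbations (2 mm/s, 0.015 m/s²) and still ends up more
variable; scales were chosen once so that step-width SDs land in
physiological ranges (a few cm) rather than to reproduce any reported
value. The transition kick is applied just after the transition sample so
that the central-difference velocity at initial contact remains a
function of the within-step state only; with placement and process noise
off, the placement law is then an exact linear function of the
end-of-swing COM state and the full pipeline returns \(R^2 = 1\) at the
contact node to numerical precision — the passive-dynamics limit used as
an acceptance anchor.

**Integration.** Fixed-step RK4 at the 100 Hz output rate with 5
substeps per sample; against the cosh/sinh closed form the trajectory is
accurate to better than 1e-8 m over a step, the tolerance asserted in
tests. Trials abort with a diagnostic if |COM − stance| exceeds 1 m.

**Markers.** Six pelvis markers are rigidly offset from the COM with
laterally symmetric offsets, so the four-marker centroid reproduces the
simulated COM to numerical precision. Foot markers are flat at height 0
in stance with a smooth sin² arc (5 cm peak) in swing. The swing foot's
lateral path is a cosmetic interpolation that settles on the commanded
placement at 95% of swing: the analysis uses foot markers only during
stance and at landing, and an anticipatory path keeps extracted
placements exact under small event-timing error. Anterior-posterior foot
motion and a swing-leg model are omitted.

## What the simulator does and does not emulate

The generator reproduces the *structure* the analysis assumes — COM-state
feedback with noise, two force fields, control and stroke-like profiles,
50-step trials at 100 Hz — and is the ground truth for event timing,
placements and controller gains. It does not emulate soft-tissue or
marker noise (filtering is therefore off by default for simulated
cohorts and on for file input), belt mechanics, sagittal dynamics, the
device's motor-excursion COM sensing, or stabilization routed through
anything other than foot placement. Two visible consequences:

* Because foot placement is the *only* stabilizer, placement errors are
  corrected almost entirely by the next step, which makes late-swing R²
  approach 1 for any stable configuration; group contrasts appear mainly
  in the R² rise from foot-off to contact (smaller in `stroke_like`
  walks) and in width variability, not in depressed contact-node levels.
* With step width and timing held, the damped pendulum's periodic orbit
  ends its steps only slightly slower (≈0.5% at the default gains), and
  dissipation of velocity fluctuations adds modestly to that; the large
  within-swing velocity reductions seen experimentally involve COM
  trajectory reshaping this reduced model does not attempt. The
  qualitative direction — damping lowers end-of-swing lateral COM speed —
  holds deterministically and is what the acceptance check asserts.

## Problem sizes and numerical choices

Validation runs use sizes small enough to re-run routinely: 60-step
trials (≥50 valid steps after boundary exclusions), 9+9-subject cohorts,
2,000 null cohorts for the family-wise error check, 10,000 fields for
the max-statistic threshold oracle, 100 random instances for the
least-squares oracle, 200 replicate cells for bias checks. Collinear or
zero-variance nodes yield flagged missing values, never zeros; swing
segments shorter than 5 frames, swings without a stance reference, and
placements beyond 1 m are excluded with reasons that propagate to the
report. All randomness flows from explicit integer seeds; identical
seeds give bit-identical trials, reports and files (timestamps aside).
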