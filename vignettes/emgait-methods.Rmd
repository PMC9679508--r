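---
title: "Methods: quantifying gait asymmetry and muscle-activation change with emgait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying gait asymmetry and muscle-activation change with emgait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`emgait` analyses synchronized motion-capture (200 Hz) and surface-EMG
(2,000 Hz) recordings of trotting quadrupeds to quantify, per stride, how
lameness changes (i) upper-body movement symmetry and (ii) appendicular
muscle activation. This vignette documents the models and procedures, the
parameters that matter, the synthetic-data generator that backs the test
suite, and the numerical choices made where the design was genuinely open.

## The measurement model

Trot is a two-beat diagonal gait: each stride (impact to impact of a
reference hindlimb, here the right hind by default) contains two diagonal
stance phases, so the vertical displacement of poll, withers and pelvis
oscillates twice per stride. In a sound, symmetric trot the two minima
(and the two maxima) within a stride are equal; lameness makes the body
"give way" differently on the two diagonals.

**Asymmetry indices.** After cubic interpolation of marker gaps (at most
10 frames; longer gaps stay masked and flag their strides) the vertical
displacement is high-pass filtered with a zero-phase 4th-order Butterworth
whose cut-off adapts to the recording's stride frequency, then each stride
is split at the contralateral hindlimb impact into its two stance halves:

- `MinDiff` = (left-associated minimum) − (right-associated minimum), mm;
- `MaxDiff` analogously on maxima;
- association is by the stance half of the relevant limb pair: forelimb
  halves for poll and withers, hindlimb halves for the pelvis;
- `hip hike` = (left tuber coxae upward excursion during left hindlimb
  swing) − (right during right swing), with swing taken as lift-off to
  next impact.

All indices are antisymmetric under left–right relabeling (a property the
test suite checks end-to-end). For right-sided inductions the signed
indices are multiplied by −1 and sides mapped to lame side (LS) /
non-lame side (NLS), so subjects pool as if all were left-lame; mirroring
is an involution.

**Induction sufficiency.** An induced lameness is accepted as a working
model when the baseline-to-induced change strictly exceeds the standard
reference values — 13 mm for head asymmetry (poll MinDiff or MaxDiff) and
5 mm for pelvic asymmetry (pelvis MinDiff and/or MaxDiff) — and the
induced condition's stride SD of the qualifying index is smaller than the
magnitude of its mean. The variability clause is applied to the induced
condition: that is the condition whose stability the rule is meant to
certify, and the baseline near-zero means would make the clause vacuous
or ill-posed there.

**sEMG chain.** Per channel: DC-offset (channel mean) removal; zero-phase
4th-order Butterworth 40 Hz high-pass; full-wave rectification; 25 Hz
envelope (amplitude analysis) and 10 Hz envelope (timing analysis). The
stride ARV is the mean rectified value over each stride, with strides cut
at the hindlimb contralateral to the muscle's side (that hindlimb's
impacts phase-lock the limb the muscle acts on). ARV outliers are flagged
once per (subject, muscle-side, condition) group outside mean ± 2 SD
(n−1 SD, strictly outside, no re-iteration); amplitudes are normalized to
the RVC — the largest surviving baseline value (ARV for discrete data,
envelope peak for continuous data, the latter after an additional 2-SD
pass on baseline stride peaks). Because the RVC is submaximal, induced
values above 100 % are expected and meaningful.

**Activation timing.** The double-threshold detector marks candidate
active regions where the 10 Hz envelope strictly exceeds 10 % of the
signal's peak envelope value, merges sub-threshold dips shorter than the
timing threshold (5 % of the baseline mean stride duration), discards
bursts shorter than that same threshold, and reports linearly
interpolated onset/offset in % of the containing stride. The dip-merge
rule reuses the burst-duration threshold because the two express the same
physiological smoothing scale; both fractions are exposed as parameters
(`amp_fraction` ± 0.05 as a per-channel override, never auto-applied).

A systematic property worth knowing: the 10 Hz envelope smears every
burst edge outward by roughly 1.5–3 % stride, so detected onsets precede
the underlying burst support slightly and offsets follow it. This is
inherent to defining timing on a smoothed envelope and affects real data
identically. The generator therefore records, alongside each injected
burst, its *detectable* timings — the threshold crossings of the ideal
noise-free envelope under the same 10 Hz smoothing — and recovery is
asserted against those (±1 % stride noiseless, ±2 % at preset noise).

## Discrete statistics

Stride-level values enter a linear mixed model per variable: condition
fixed, subject random intercept. The optional speed correction adds a
fixed speed effect plus a per-subject random slope and evaluates the
estimated marginal means at the mean speed; a pure random slope (mean
zero by construction) cannot absorb a speed effect common to all
subjects, which is exactly the confound the correction targets.
Estimated marginal means and the condition contrast come from `emmeans`
with Satterthwaite degrees of freedom; non-convergence falls back to a
paired contrast of subject means with a logged note. p-values are
Benjamini–Hochberg adjusted across the variables of one induction
contrast (the family is configurable). Percentage differences use the
baseline EM mean as denominator and are reported `NA` for signed
asymmetry indices, whose baseline means are near zero by design.

## Continuous statistics: 1D SPM

For each variable, strides are linearly resampled onto 101 nodes
(node 0 and node 100 at consecutive segmentation impacts) and each
subject contributes the node-wise median across non-excluded strides per
condition. The paired t field over the 101 nodes is thresholded at the
random-field-theory critical value: the smallest $t^\*$ at which the
expected Euler characteristic of the excursion set,
$$\mathbb{E}[\mathrm{EC}] = P(T_\nu > t) + R\,\frac{\sqrt{4\ln 2}}{2\pi}\,(1 + t^2/\nu)^{-(\nu-1)/2},$$
falls to the per-tail level $\alpha/(2m)$, with resels
$R = 100/\mathrm{FWHM}$ and $m$ the Bonferroni family size (default: the
variables jointly tested in the limb panel). Smoothness (FWHM) is
estimated from the variance of normalized residual gradients
(Kiebel-style); constant residuals return `Inf`, signalling the ordinary
pointwise t quantile. Suprathreshold clusters are maximal runs with
$|t| > t^\*$, endpoints linearly interpolated to fractional % stride;
cluster p-values use the RFT expected-cluster-extent approximation,
capped at $\alpha$. An exhaustive sign-flip permutation oracle
(deterministic for $n \le \log_2$ of the permutation budget) validates
the RFT threshold; under the calibration conditions used in the tests
(8 subjects, FWHM 20) the two agree within a few percent and the
empirical family-wise error of the full chain matches the nominal 0.05
within its 95 % binomial interval.

With fewer than three subjects the pipeline falls back to pairing
stride-level fields by stride index within a subject — the same analysis
the study design applies to an individual animal.

## The synthetic-data generator

The generator is first-class, tested code; it emulates exactly the
features the pipeline measures:

- **Stride timing.** Lognormal stride durations (positive, mildly
  skewed) with configurable mean and CV; defaults follow the published
  conditions: 0.77 s baseline, 0.75 s forelimb induction, 0.71 s hindlimb
  induction; speed 3.3 m/s (in-hand trot); 45 % duty factor.
- **Upper body.** Each landmark's vertical displacement is
  $z(t) = P_h \sin^+(4\pi t/T) - N_h \sin^-(4\pi t/T)$ with separate
  positive/negative lobe amplitudes per half-stride, so scaling alternate
  half-cycles injects MinDiff/MaxDiff *exactly* as those indices are
  defined. Default lobe amplitudes: poll 60, withers 35, pelvis 45 mm.
- **Tubera coxae.** A raised-cosine elevation bump inside each
  ipsilateral hindlimb swing window whose height difference equals the
  injected hip hike (baseline excursion 70 mm). The biphasic pelvic
  component is deliberately omitted from these two markers so the
  swing-window excursion is the injected quantity and nothing else.
- **Hooves.** Ground contact (z = 0) through stance, a smooth
  $\sin^2$ arc (120 mm) through swing, touching down at the true impact
  times recorded in the ground truth; horizontal position advances one
  step length per stride.
- **sEMG.** Per channel, 20–450 Hz band-limited Gaussian noise (the
  sensor's hardware band, so the 40 Hz analysis high-pass has realistic
  work to do) amplitude-modulated by raised-cosine-edged burst envelopes
  (taper 2 % stride) plus a noise floor and a small DC offset. The
  semitendinosus preset carries a second burst (60–80 % stride) to
  exercise multi-burst detection. Injected preset magnitudes mirror the
  published estimated-marginal-mean differences for moderate inductions
  (poll MinDiff −53.73 mm for the forelimb preset; pelvis MinDiff
  −22.25 mm, MaxDiff −27.87 mm, hip hike −61.73 mm for the hindlimb
  preset); burst amplitude scalings are illustrative, proportional to the
  reported ARV changes, since no quantitative burst amplitudes are
  published.

Identical seeds give identical trials; the generator restores the
caller's RNG state.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: soft-tissue artifact and marker occlusion
patterns, out-of-sagittal motion, inter-stride correlation of asymmetry
(strides are conditionally independent given the scenario), EMG crosstalk
and electrode-impedance drift, and physiologically coupled changes in
joint-angle waveforms (the limb-chain markers move with a simple
pro-retraction/flexion oscillation intended for geometric validation of
the angle code, not biological realism).

## Numerical choices

- **Zero-phase filtering** everywhere (forward–backward 4th-order
  Butterworth): activation-timing comparisons need zero group delay.
  Edges are odd-reflection padded by about three settling lengths. The
  stride-adaptive high-pass has its cut-off far below the signal band
  (0.5 × stride frequency, ~0.65 Hz), where reflective padding leaves
  transients decaying over seconds; because gait displacement is
  quasi-periodic, that filter instead pads periodically with one stride
  period, which continues the signal almost exactly. The 0.5 factor
  passes the stride fundamental and its asymmetry-bearing two-per-stride
  harmonic (≥ 98 % amplitude) while removing drift.
- **Impact detection** (the cited event method is not restated in the
  source literature): per hoof, stance is the run of 10 Hz-low-passed
  height below minimum + 5 % of the vertical range; the impact is the
  zero crossing of vertical velocity at the end of the preceding descent.
  Because the low-pass smears the touchdown kink symmetrically, the
  implementation extrapolates the straight mid-section of the descent
  (40–80 % of peak descent speed) to zero, recovering impacts within
  ±1 frame (≤ 5 ms noiseless) of the generator's truth. Lift-off is the
  upward threshold crossing ending the stance run.
- **Stride speed**: central differences of the 10 Hz-low-passed
  horizontal tubera sacrale coordinates, averaged per stride.
- **Joint angles** are sagittal-plane (x–z) interior angles of adjacent
  segment vectors; pro-retraction is the signed angle between the limb
  line (spina scapulae→MCP; tuber coxae→MTP) and the downward normal of
  the trunk line (T6→tubera sacrale), protraction positive, minus the
  same quantity in the standing reference trial. Full 3D Cardan angles
  are out of scope; the reported flexion/extension content is sagittal.
- **Time normalization** is linear interpolation onto exactly 101 nodes;
  at 200 Hz the worst-case error against a closed-form stride-scale
  sinusoid is below 10⁻³ of amplitude.
- **Degenerate inputs**: constant envelopes yield zero bursts (not an
  error); a zero-variance node with nonzero mean difference raises a
  degenerate-field error; groups of fewer than three strides skip outlier
  flagging with a warning; strides overlapping masked samples are flagged
  and excluded, never silently dropped.

## Problem sizes used in the tests

The suite runs simulations sized for tight feedback while keeping every
estimate stable: 6–8 strides per synthetic trial, 2–3 subjects in
pipeline tests, 1000 replicates for the SPM null calibration, 50 for the
permutation–RFT comparison, and 20 seeds for noisy-recovery checks.
These sizes are stated here as the package's chosen study conditions for
its own verification.

## Known limitations

- The hip-hike swing window uses the full ipsilateral swing
  (lift-off to impact); sub-window variants found in the literature are
  not implemented.
- Cluster p-values use the stationary-smoothness expected-extent
  approximation; non-stationary smoothness correction is out of scope.
- The mixed-model stage assumes Gaussian residuals; diagnostics are
  logged, not automated.
- Envelope-based activation timing carries the systematic edge smear
  discussed above; comparisons should always be within-method.
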