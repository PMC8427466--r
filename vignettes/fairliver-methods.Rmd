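---
title: "Methods: liver FAIR ASL perfusion and caval-subtraction PCMRI in fairliver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: liver FAIR ASL perfusion and caval-subtraction PCMRI in fairliver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairliver)
```

## What the package computes

`fairliver` implements the analysis chain for a rodent study of hepatic
haemodynamics built on two independent MRI measurements:

1. **FAIR ASL tissue perfusion.** Paired Look-Locker inversion-recovery
   experiments — a global (control) inversion and a slice-selective
   (flow-sensitised) inversion — are fitted pixel-wise, and perfusion is
   derived from the T1 difference between the two maps.
2. **Caval-subtraction PCMRI bulk flow.** Cardiac-gated cine
   phase-contrast images of the inferior vena cava above and below the
   liver give vessel flows whose difference, normalised to liver weight,
   estimates total liver blood flow (TLBF).

Because the two methods measure related but distinct quantities (tissue
perfusion vs organ bulk flow), the statistical layer centres on method
agreement (Bland–Altman), relative variability (CoV with Forkman's
equality test), and a split-plot group × time analysis of the response to
an endotoxin (LPS) challenge in sham-operated vs bile-duct-ligated (BDL,
cirrhotic) cohorts.

## Signal model and its inverse

The recovery model fitted at each pixel is

$$M_z(TI) = M_0\,(1 - \alpha\,e^{-TI/T_1^*}),$$

with the Look-Locker correction $T_1 = T_1^*(\alpha - 1)$. The
**simulator generates data from exactly this model**, setting
$T_1^* = T_1^{\mathrm{eff}}/(\alpha-1)$, with
$T_1^{\mathrm{eff}}$ the tissue T1 for the global mode and the
perfusion-shortened

$$T_1^{ss} = \frac{T_1^{\mathrm{global}}}{1 + P\,T_{1,blood}/(\lambda \cdot 6\times10^6)}$$

for the slice-selective mode. This is a deliberate design choice rather
than a physical claim: the published analysis chain specifies the fitting
model and correction but not a full Bloch-level acquisition model, so the
phantom is built to make the analysis chain *exactly invertible*. Every
noiseless simulate → fit → map → ROI-mean round trip must therefore
return the ground truth to numerical precision (the suite checks 1e-4
relative at 128 × 128), which turns parameter recovery into a strict
oracle. The corollary is stated plainly: passing round trips validate the
implementation of the analysis, not the biophysical fidelity of the
forward model.

Perfusion mapping applies

$$P = \frac{\lambda}{T_{1,blood}}\left(\frac{T_1^{\mathrm{global}}}{T_1^{ss}} - 1\right),$$

with the unit conversion to ml/min/100 g computed from `lambda_` and
`t1_blood` at call time (3000 × the T1-ratio excess at the defaults), so
overriding either constant — both plausibly altered in liver disease —
propagates consistently. Negative perfusion is clamped to zero; values
above 2000 ml/min/100 g are treated as non-physiological. Whether such
pixels should be excluded or capped is ambiguous; `fairliver` **excludes**
them (validity mask) so they cannot bias ROI means.

## Key parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `lambda_` | 0.95 | ml/g | blood–tissue partition coefficient |
| `t1_blood` | 1900 | ms | blood T1 at field |
| `upper_threshold` | 2000 | ml/min/100 g | perfusion validity ceiling |
| TI spacing / readouts | 110 / 50 | ms / – | Look-Locker train |
| smoothing sigma | 1.6 | pixels | pre-fit Gaussian window |
| T1* bounds | 50–5000 | ms | physiological rodent range at 9.4 T |
| alpha bound | (1, 2.2] | – | apparent inversion efficiency |
| venc (infra / supra) | 33 / 66 | cm/s | velocity encoding per station |
| cine matrix | 192 over 40 mm | – | 0.208 mm voxels |
| vessel radius | 1.75 | mm | caval diameter 3.5 mm |
| heart rate | 300–400 | bpm | cardiac period for cycle averaging |

The TI grid starts at one spacing after the inversion
(TIs = 110, 220, …, 5500 ms). The first-sample offset is not derivable
from the protocol description; starting at one spacing (not zero) is a
recorded convention, and nothing downstream depends on it beyond the TI
vector itself.

## T1 fitting: variable projection

The recovery model is linear in $(M_0, M_0\alpha)$ once $T_1^*$ is fixed,
so the fitter profiles the single nonlinear parameter: a dense log-spaced
candidate sweep over $T_1^*$ (exact linear least squares at each
candidate, vectorised across all pixels of a map) followed by per-pixel
Brent refinement in the bracketing interval. Compared with a generic
3-parameter Levenberg-style fit, this removes starting-value sensitivity,
cannot converge to a local optimum in the two linear parameters, and
makes the brute-force grid-search comparison in the test suite a clean
like-for-like check on the same objective. Validity requires
$M_0 > 0$, $\alpha \in (1, 2.2]$ and $T_1^*$ strictly inside its bounds;
failures are invalid pixels, never errors.

**Magnitude polarity.** Magnitude data lose the sign of the pre-null
samples. When an input curve contains no negative values, polarity is
restored by flipping samples before the curve minimum; the sample at the
minimum itself sits on the null crossing and its sign is ambiguous, so
both polarities of that one sample are fitted and the lower-RSS solution
kept. Signed input (the simulator default, Gaussian noise on the signed
signal) is fitted as-is. A direct magnitude-model fit
($|M_0(1-\alpha e^{-TI/T_1^*})|$, Nelder-Mead) is available behind
`model = "magnitude"`.

**Smoothing** uses a separable Gaussian kernel truncated at 4σ with
reflect padding and exact unit sum, applied identically to both inversion
modes. The kernel is implemented in the package because the truncation
and boundary conventions are pinned; a σ = 1.6 px window at 0.469 mm
pixels has σ ≈ 750 μm, which matches the acquisition's stated final
resolution if that figure is read as σ rather than FWHM — the resolution
claim is not used as a constraint anywhere.

## Respiratory gating

The phantom's breathing cycle ends in a quiescent end-expiration plateau
occupying `quiescent_fraction` (default 0.4) of each cycle; cycle
durations jitter log-normally (5%). Segments of 4 k-space lines are
triggered at quiescent-window starts, but the 50-readout train spans
~5.5 s ≈ 5 breaths, so roughly half of all lines inevitably fall outside
quiescent windows — this is the work retrospective gating is meant to do,
not an artefact. What "during inspiration/expiration" means on a logged
trace is a package decision: quiescent windows are **closed intervals**
(a line exactly on a boundary is kept), and a line is kept iff its
instant ± a configurable margin lies inside one window.

Motion is modelled as rigid cranio-caudal translation (default 2 mm
amplitude, half-sine excursion across each non-quiescent span), applied
per k-space line through the Fourier shift theorem. Two rebuild policies
exist: `reacquire` (default) replaces discarded lines with the same line
acquired in a quiescent window — the effectively-complete-k-space regime
the retrospectively optimised acquisition approximates — and `zero_fill`
zeroes them. With ~50% of lines discarded, zero-filling removes more
k-space energy than the motion corrupts, so the "gating never hurts"
property is a property of the reacquire policy and is tested with it.

## Flow integration choices

Phase decodes to velocity linearly (v = venc·φ/π, φ ∈ (−π, π]); wrapping
is **flagged, never corrected** — the aliasing flag fires when any
vessel-ROI phase lies within 5% of ±π. The cycle average divides the
periodic trapezoidal AUC by the cardiac period; for uniform frame
sampling this is identical to summing per beat and scaling by heart rate,
and it is exact for single-harmonic waveforms (the phantom's pulsatility
model: a zero-mean sinusoid scaling the Poiseuille centreline velocity).
Negative TLBF from caval subtraction is reported as-is with a warning,
since error propagation across two vessel measurements can legitimately
produce it.

## The synthetic cohort

Group distributions default to the study conditions: printed group
summaries are means ± **standard errors**, converted to SDs with √n
(n = 10 sham, 9 BDL at baseline; 7 BDL completed the post-LPS time
point). Baseline sham perfusion is N(316, 75.9) ml/min/100 g, BDL
N(199, 96); tissue T1 sham N(1256, 56.9) ms, BDL N(1533, 150); liver
weight 14 ± 3.2 g vs 30 ± 6 g. The LPS challenge is a single additive
per-animal shift (+78 ± 104.4 sham, −49 ± 105.8 BDL for perfusion) — a
snapshot, with no dynamics within the acquisition. BDL attrition is 2/9.
Per-animal TLBF is generated as perfusion plus a method-difference offset
(sham +144, BDL −54, SDs back-computed from the per-cohort limits of
agreement), emulating the observed FAIR-vs-PCMRI disagreement structure;
the inversion efficiency α is equal across cohorts (no evidence either
way; default 1.95).

What the phantom does **not** emulate: B0/B1 inhomogeneity, a Bloch-level
segmented readout, multi-slice or 3-D geometry, non-rigid motion,
eddy-current phase offsets, hepatic-artery/portal-vein separation, and
any within-session physiological drift. Consequently, passing tests
demonstrate correctness of the analysis chain and calibration of the
statistics under the stated generative model — not robustness to every
artefact of real acquisitions.

Extreme cohort draws can push the pulsatile supra-caval peak velocity
past the 66 cm/s encoding velocity; the decoder then flags aliasing and
flow is underestimated, exactly as it would be in practice. This is
intended behaviour of the generator, and recovery tests therefore run
within the encoding envelope.

## Statistical layer

- Limits of agreement use the fixed 1.96 multiplier (consistent with the
  headline LoA relationship 1.96 × √19 × 30 ≈ 258), not a small-sample t
  quantile.
- Forkman's F uses $c_i^2/(1 + c_i^2(n_i-1)/n_i)$ terms on
  F(n₁−1, n₂−1). The result carries a two-sided p
  (2·min of the tails) and also the one-sided tail, since published
  CoV comparisons sometimes quote the latter.
- Normality testing estimates mean/SD from the sample, so the KS null is
  Lilliefors-corrected, by seeded Monte-Carlo (10⁴ replicates by
  default) rather than an asymptotic approximation.
- The Mann–Whitney p is computed by full enumeration of group
  assignments for n₁+n₂ ≤ 20 (exact under ties), otherwise by the
  tie-corrected normal approximation.
- The 2 (group) × 2 (time) split-plot interaction is computed through
  the change-score equivalence: F(1, n−2) equals the squared pooled
  two-sample t on per-subject changes. This is exact for this design,
  sidesteps sums-of-squares-type choices under unbalanced groups, and
  drops subjects missing a time point with a warning. Post hoc paired
  comparisons use Bonferroni m = 2.
- All tests are two-sided at the 5% threshold.

## Problem sizes and calibration

The suite sizes were chosen as the package's own verification design:
exact round trips at the acquisition's 128 × 128 matrix; statistical
calibration with 2000 replicates each for the Forkman and interaction
type-I error (accepted band 3.5–6.5% at nominal 5%), 500 replicates for
Bland–Altman recovery at n = 19; 50 simulated studies for the
interaction-detection property (the generator's effect sizes give
detection in a majority of replicates, consistent with a design powered
at ~90% for a larger effect and then eroded by attrition); and 20
repeated acquisitions for the gating comparison. `run_study()` defaults
to a 64 × 64 matrix with SNR-100 noise; the detection-power property is
computed at the cohort level (`simulate_power()`), because the imaging
chain is exact in the noiseless limit and adds no information to that
particular property.

## Known limitations

- The phantom's liver is a two-region ellipse (parenchyma + one in-slice
  vessel); there is no intra-lobe perfusion heterogeneity, so ROI
  placement effects cannot be studied beyond the mean-of-means vs pooled
  distinction (the package implements the **mean of three ROI means**,
  which differs from a pooled mean for unequal valid-pixel counts).
- Velocity aliasing is flagged but not unwrapped.
- The Forkman test assumes normal samples; its calibration is verified
  under that assumption only.
- No DICOM ingestion; images move through NIfTI and plain tables.
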