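# fairliver

Quantitative liver perfusion and bulk-flow analysis for rodent MRI:
flow-sensitive alternating inversion recovery (FAIR) arterial spin
labelling with a Look-Locker readout, and caval-subtraction phase-contrast
MRI (PCMRI), together with the statistical layer needed to compare the two
methods and to analyse cohort responses to an inflammatory challenge.

The package is aimed at preclinical imaging scientists who need a tested,
ground-truth-verifiable implementation of this analysis chain. Because raw
in-vivo series for this kind of study are rarely deposited, the package
ships a digital rodent-liver phantom that simulates every raw input —
inversion-recovery image series, velocity-encoded cines, respiratory
traces and segmented k-space timetables — with known parameters, so every
stage of the pipeline can be checked by exact parameter recovery.

## The models

**T1 mapping.** Each pixel's post-inversion Look-Locker recovery is fitted
with the three-parameter model

    Mz(TI) = M0 (1 − α e^(−TI/T1*))

for the equilibrium signal M0, apparent inversion efficiency α (2 for a
perfect inversion) and apparent relaxation time T1*, followed by the
small-angle Look-Locker correction

    T1 = T1* (α − 1).

**Perfusion.** FAIR ASL derives perfusion from the difference between
slice-selective (flow-sensitised) and global (control) inversions: inflow
of non-inverted blood shortens the slice-selective T1, giving

    P = (λ / T1_blood) (T1_global / T1_ss − 1)

with λ = 0.95 ml/g (blood–tissue partition coefficient) and
T1_blood = 1900 ms, converted to ml/min/100 g (a factor of 3000 on the
T1-ratio excess at these defaults). Negative P is clamped to zero;
P > 2000 ml/min/100 g is non-physiological and excluded.

**Bulk flow.** Through-plane PCMRI velocity is decoded from phase as
v = venc·φ/π, per-frame vessel flow is the ROI sum of voxel area ×
velocity, the cardiac-cycle flow is the periodic trapezoidal time-average,
and total liver blood flow (TLBF) is the supra-hepatic minus infra-hepatic
IVC flow normalised to liver weight.

**Statistics.** Bland–Altman 95% limits of agreement, inter-subject
coefficients of variation compared with Forkman's F test, Welch t and
Mann–Whitney U group comparisons with Lilliefors-corrected
Kolmogorov–Smirnov normality checks, split-plot two-way ANOVA
(group × time) with Bonferroni post hoc tests, and attrition-adjusted
sample-size inflation.

## Worked example

```r
library(fairliver)

phantom <- phantom_spec(grid_shape = c(64L, 64L), perfusion_liver = 316,
                        t1_liver_ms = 1256, seed = 1)
ctrl  <- simulate_fair_series(phantom, "global",          noise_sd = 10, seed = 1)
label <- simulate_fair_series(phantom, "slice_selective", noise_sd = 10, seed = 2)
t1_ctrl  <- fit_t1_map(ctrl,  mask = phantom$region > 0)
t1_label <- fit_t1_map(label, mask = phantom$region > 0)
t1_ctrl
#> T1 map (global): 64 x 64, 1615 valid pixels, median T1 1256 ms

pmap <- perfusion_map(t1_ctrl, t1_label)
rois <- default_rois(phantom)
roi_mean(pmap, rois)     # 313.5  (ml/min/100 g; truth 316, SNR-100 noise)
roi_mean(t1_ctrl, rois)  # 1256.4 (ms; truth 1256)

supra <- simulate_pc_cine(phantom, "supra_IVC", noise_sd = 0.02, seed = 3)
infra <- simulate_pc_cine(phantom, "infra_IVC", noise_sd = 0.02, seed = 4)
flow_result(supra, infra, phantom$liver_weight_g)
#> Caval flows: supra 104.7, infra 57.8 ml/min; TLBF 335.4 ml/min/100 g

forkman_cov_test(0.293, 19, 0.501, 19)
#> Forkman CoV test: 29.3% vs 50.1%, F[18, 18] = 0.392, p = 0.0539
```

The ROI-mean perfusion (313.5 ml/min/100 g) recovers the phantom's ground
truth of 316 to within the measurement noise; the caval subtraction
recovers the configured TLBF of 335 ml/min/100 g to within flow-disc
discretisation error. A full simulated study (cohort → baseline FAIR →
PCMRI → endotoxin shift → post FAIR → statistics) runs through
`run_study(run_config())` and renders with `report_render()`; a thin CLI
wrapper lives at `inst/scripts/run_study.R`.

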