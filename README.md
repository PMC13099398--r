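# lrtcmr

Free-running, non-ECG-gated, whole-heart cardiac MRI — simulated,
reconstructed and quantified end to end in R.

Staging irreversible tissue injury after a reperfused myocardial
infarction needs several MRI contrasts: cine for ventricular function,
late gadolinium enhancement (LGE) for infarct size and transmurality,
early/late enhancement for microvascular obstruction (MVO), and
T2\*-weighted imaging for intramyocardial hemorrhage (IMH). A free-running
acquisition replaces the conventional stack of breath-held, ECG-gated
scans with one continuous inversion-prepared multi-echo spoiled
gradient-echo sequence (TR 13.2 ms, six echoes 1.47–11.42 ms, 5°
excitations, 192 segments per inversion block, ~14 min) with randomized
Gaussian Cartesian phase encoding and an interleaved k-space-center
training line every sixth readout. The image set is modeled as a
six-dimensional low-rank tensor — one spatial and five temporal dimensions
(cardiac phase, respiratory position, inversion time τ, echo time,
gadolinium dynamics):

    X(voxel, c, r, τ, e, g) = U_x Φ ,

with a complex spatial factor `U_x` (one row per voxel, L columns) and an
orthonormal-row joint temporal basis `Φ` estimated from the training
lines. Cardiac and respiratory phases come from self-navigation of the
training series; `U_x` solves a Tikhonov-regularized data-consistency
least-squares problem by preconditioned conjugate gradient.

The package provides, as testable modules: a deformable analytic
left-ventricle phantom with infarct/MVO/IMH substructure, motion and
per-tissue gadolinium kinetics (the generator of exact ground truth); the
acquisition-schedule generator; a multi-coil k-space simulator plus an
idealized gated comparator study; self-navigated binning; subspace
estimation and the LRT reconstruction; voxel-wise T1/T2\* mapping;
semi-automatic quantification of LVEF, infarct size/transmurality, MVO and
IMH; and the comparison statistics (Bland–Altman bias / limits of
agreement / reproducibility coefficient RPC = 1.96·SD of paired
differences, regression with 95% CIs, paired t, ROC/AUC). A 12-subject
synthetic cohort runs both arms per subject and tabulates agreement, the
way a two-exam method-comparison study is analyzed.

## Worked example

```r
library(lrtcmr)

ph <- buildPhantom(phantomConfig(), seed = 1)
ph
#> DigitalPhantom 192x192x14 @ 1.41x1.41x6.0 mm
#>   LV radii 15.0/24.0 mm; MI wedge 100 deg, transmural 65%
#>   truth: LVEF 32.8%, MI 16.6%, MVO 5.9%, IMH 4.5% of LV

sched <- buildSchedule(seqParams(), seed = 1)
sched
#> SamplingSchedule: 65151 readouts (10859 training) over 860.0 s
#>   340 IR blocks, 192 segments/block, TR 13.2 ms, 6 echoes
#>   phase encodes 192 x 14, seed 1

## fraction of the (ky, kz, cardiac, resp, gd) tensor actually sampled
100 * samplingFraction(sched, binConfig())
#> 1.29  # percent

## agreement between two arms measuring the same quantity
ba <- blandAltman(pairedMeasurements(
  x = c(15.2, 8.1, 22.4, 30.0, 12.7, 18.3),   # conventional
  y = c(15.8, 7.6, 23.1, 30.9, 12.1, 19.0)))  # proposed
sprintf("bias %.2f, LoA [%.2f, %.2f], RPC %.2f",
        ba$bias, ba$loaLow, ba$loaHigh, ba$rpc)
#> "bias 0.30, LoA [-1.01, 1.61], RPC 1.31"
```

The phantom header numbers are the closed-form ground truth the
quantification chain is measured against: ejection fraction from the
contraction model, and infarct/MVO/IMH as percent of LV myocardial volume
from the wedge geometry. The sampling fraction is why the low-rank model
is needed at all: only ~1.3% of the five-way sampling tensor is visited in
14 minutes. The Bland–Altman line shows the convention used throughout:
differences are proposed − conventional, and the reproducibility
coefficient is exactly the LoA half-width.

A full single-subject run is
`runCohort(cohortConfig(nSubjects = 1))`; the default
`runCohort(cohortConfig())` simulates, reconstructs and quantifies 12
subjects in both arms (about a minute per subject at the desk-scale
96×96×6 grid) and returns the per-metric agreement table.

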