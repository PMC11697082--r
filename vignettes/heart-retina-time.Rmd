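---
title: "Heart-retina time from ECG-coupled dynamic OCT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-retina time from ECG-coupled dynamic OCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hrtoct)
```

## The measurement

When blood accelerates through a retinal arteriole during systole, the axial
motion of the scatterers during the OCT detector's integration time washes
out the interference fringes. The vessel lumen therefore darkens and
brightens with the cardiac cycle in a time-resolved B-scan series. `hrtoct`
turns that intensity pulsation into an axial-velocity waveform, detects the
arrival time of each pulse wave at the retina, and measures its lag behind
the ECG R-peak (the ventricular contraction). That lag — the heart-retina
time (HRT) — is a pulse-transit-time in the heart-to-eye pathway and a
candidate biomarker for cardiovascular health.

## Fringe-washout velocimetry

For a scatterer moving axially at velocity $v$ during an integration time
$t$, the SNR drops by

$$\mathrm{SNR_{Drop}}(v) \;=\; \operatorname{sinc}^2(k_0\,\Delta z),
\qquad k_0 = \frac{2\pi}{\lambda}, \quad \Delta z = n\,v\,t,$$

with $\lambda$ the central wavelength (880 nm), $n$ the bulk refractive
index (1.36 as an ocular average), and the removable singularity at $v = 0$
defined as 1. `forward_washout()` evaluates this; `invert_washout()` solves
it numerically for $v$.

The observable driving the inversion is the per-frame vessel-subarea SNR. A
7×7-pixel window (about 20 µm × 27 µm at the clinical raster of 1024×496 px
over ≈2.9 mm × 1.9 mm) is centred on the annotated vessel centre. Assuming
shot-noise-limited detection, the frame noise level is the maximum raw
intensity divided by the device quality score $Q$ converted from dB to a
linear power ratio, so

$$\mathrm{SNR}_i = \frac{\overline{I}_i \cdot \mathrm{max\_raw}_i}
{\mathrm{max\_raw}_i / 10^{Q_i/10}} = \overline{I}_i\, 10^{Q_i/10}.$$

The per-frame SNR is normalised by the *reference SNR* — the peak
single-pixel SNR over the whole series within the window — to give
$\mathrm{SNR_{Drop}} \in (0, 1]$ (noise can push the ratio above 1; it is
clipped). Note the consequence: the recovered velocity series is a monotone
distortion of the true waveform (arbitrary units), because the reference is
itself a washed-out observation. Rise *timing*, which is all the HRT needs,
is preserved.

Because $\operatorname{sinc}^2$ is not injective, each drop maps to several
candidate velocities, indexed by the numerical solution index (NSI): branch
0 is the unique root in the principal lobe $x \in [0, \pi)$, and each side
lobe whose peak exceeds the drop contributes its falling-flank root so that
velocity increases with NSI (both flanks are available via
`branch_mode = "both"`). Roots are bracketed by bisection to an absolute
tolerance of $10^{-12}$ in $x$ and polished with a few guarded Newton steps.
The default of 5 branches is configurable. A useful exact property follows
from $v = x/(k_0 n t)$: for equal drop, velocities scale as $1/t$, so the
11.2 µs (85 kHz) integration yields exactly 4× the 44.8 µs (20 kHz)
velocities.

The *envelope* of the per-frame maximal solution is differentiated with
central differences on the actual frame timestamps (one-sided at the ends);
frame intervals differ between regimes, so index-based differences would be
wrong. An optional moving-average smoother for the envelope exists but is
off by default — the raw maximal-solution series is used as-is.

## Event trains and the cross-correlation

Pulse arrivals are the sharpest velocity rises: the profile's span is split
into consecutive bins of one mean cardiac cycle (from the ECG), anchored at
the first frame, and each bin with at least 3 frames emits the frame of
maximal gradient (ties to the earlier frame). Requiring 3 frames avoids
endpoint artifacts of the finite-difference gradient in sliver bins.

ECG R-peaks come from an Engelse–Zeelenberg detector (band-stop around
mains, four-sample differentiator, binomial low-pass, adaptive threshold
with the Lourenço-style update). Two implementation choices matter:

* the pipeline is offline, so the adaptive threshold is initialised from
  the feature-signal maximum over the first five seconds instead of a
  causal running maximum. The streaming formulation must discard its first
  detection (often a P-wave crossing a near-zero warm-up threshold); the
  offline initialisation keeps the first true beat and produces no warm-up
  false positives;
* the detected crossing is refined to the local amplitude maximum of the
  resampled signal, i.e. the R-peak itself. A positive R deflection is
  assumed (lead II-like).

Both trains are binarised as single time points on a common analysis grid
(default 125 Hz, the ECG rate — 8 ms lag resolution), convolved with a
discrete Gaussian, normalised to $[0,1]$, and cross-correlated with the OCT
train as the baseline. The ECG window runs from 10 s before the first
B-scan to 1 s after the last, so that every lag within one cardiac cycle is
fully covered. The energy-normalised correlation
$cc(\ell) = \sum_t O(t)E(t+\ell)/\sqrt{\sum O^2 \sum E^2}$ is used (the
trains are non-negative bump sequences; no mean subtraction by default).
The most probable ECG-to-OCT offset is the argmax restricted to
$[-\overline{RR}, 0]$; the HRT is its additive inverse. When the
*unrestricted* argmax falls outside one cardiac cycle the estimate is
flagged as an outlier (and excluded from reproducibility statistics, though
kept in the outputs).

### Smoothing width and detection uncertainty

The Gaussian width is $\sigma = 1.25$ in units of each train's *native*
sampling. For the ECG train the native grid is the analysis grid, giving
10 ms bumps. The pulse-arrival times, however, are only resolved to the
B-scan frame interval (≈49 ms at 20 kHz, ≈13 ms at 85 kHz), so the arrival
train's width is scaled by the frame interval (`event_res_ms` in
`estimate_hrt()`). This is what the smoothing is for — representing the
uncertainty of each detection. With a fixed 10 ms width the arrival bumps
at the 20 kHz regime are much narrower than their own timing uncertainty;
the true-lag correlation then collapses and random coincidences anywhere in
the 11 s lag range win the argmax for a large fraction of exams.

Even with matched smoothing, the 20 kHz regime keeps a noticeable rate of
out-of-cycle argmaxes: with ~8 beats in 7 s and ±half-frame arrival
quantisation, several periodic correlation peaks tie to within ~0.002.
That is a property of the method at 49 ms frame intervals — it is precisely
why the one-cycle outlier rule exists — and the within-cycle estimate
remains accurate in those exams. Validation of the outlier rule itself is
therefore run in the 85 kHz regime, where arrival timing is well resolved.

## Rigid registration

Frames are aligned to the average of the first ten frames with a rigid
transform. Translation is estimated by phase correlation with a parabolic
sub-pixel fit — the phase peak stays sharp in the presence of the
zero-filled borders that large drifts leave, where plain cross-correlation
is biased by the border bands. When rotation search is enabled the angle is
scored by the real-space masked correlation of the fully back-warped frame
(smooth in the angle, unlike the phase-peak height) over a coarse grid
refined by golden-section search.

Two structural points:

* **Bootstrap.** The raw first-ten average is blurred when drift is large,
  degrading the correlation peak. The stack is therefore first aligned to
  the (sharp) first frame, the first-ten average is rebuilt from the
  aligned frames, and the stack is re-registered to it. The final reference
  is still the mean of the first ten (aligned) frames.
* **Gauge.** Only relative poses are observable; the absolute pose of a
  stack is not. The reported transforms are re-centred so that the mean
  transform over the reference window is the identity, anchoring the output
  at the mean pose of the frames that define the reference. The synthetic
  generator draws its drift zero-mean over the same window, which makes
  ground-truth transforms identifiable for round-trip tests.

Rotation search defaults to off (`max_rotation_deg = 0`): the eye motion
visible in these acquisitions is predominantly translation along the fast
scanning and anterior-posterior axes, and in-plane rotation costs an order
of magnitude more compute. It is enabled explicitly where rotational drift
is simulated. A geometric caveat: at a 96×72-pixel raster a 0.2° rotation
moves even edge pixels by only ~0.2 px, below what any estimator can
resolve; rotation-recovery studies therefore use a 224×160 crop at the
clinical pixel pitch, where 0.2° is resolvable.

## The synthetic forward model

`sim_config()` / `generate_exam()` emulate the acquisition end to end with
known ground truth:

* **ECG** — beats at RR intervals jittered uniformly (default ±3%), a
  P-QRS-T sum-of-Gaussians template with a dominant R spike, sampled at
  125 Hz with ≤1 ms timestamp jitter (to exercise the resampling), plus
  Gaussian noise at a configurable SNR (default 20 dB). The template is
  parametric, not biophysical: only R-peak timing matters downstream.
* **Flow waveform** — each beat launches a pulse at
  $r_k + \mathrm{HRT}$: a saturating-exponential rise whose maximal slope
  sits exactly at onset (10–90% within two frame intervals), then an
  exponential decay (τ = 280 ms) toward a diastolic baseline of 25% of the
  systolic peak. The default peak velocity keeps the washout argument at
  1.4 rad < π/2, inside the principal lobe, so the inversion is unique.
* **B-scans** — a layered background with speckle-like static texture, a
  circular vessel with hyperreflective walls, a hypointense shadow column
  beneath it, and a lumen rendered as a constant baseline multiplied by
  $\operatorname{sinc}^2(k_0 n v(t_i) t)$. Per-frame rigid drift (default
  ±6 px translation, no rotation) and additive Gaussian sensor noise
  (default sd 1e-4) follow; the per-frame quality score is set to
  $-10\log_{10}(\mathrm{noise\ sd})$, i.e. 40 dB at the default, so that
  the subarea SNR computation sees a noise level consistent with the
  injected noise. The raster defaults to a 96×72 px crop at
  the clinical pixel pitch so that full pipelines run at desk scale.
* **Cohorts** — per-subject mean HRTs are drawn
  $\mathcal N(\mathrm{base}, 0.09\,\mathrm{base})$ and per-exam HRTs
  $\mathcal N(\mathrm{subject}, 0.11\,\mathrm{base})$ by default; vessels
  within an exam share the exam's HRT (pulse waves arrive synchronously at
  neighbouring arterioles).

The generator stores both the physical washout sequence and the
reference-normalised drop sequence that subarea extraction can actually
recover (see above) — round-trip tests compare against the latter.

What the generator does *not* emulate: real speckle statistics (additive
Gaussian noise stands in; the subarea mean is insensitive to the speckle
model at this window size), retinal anatomy, eye-tracking artefacts,
blinks, motion non-collinear with the fast axis, and quality-score
idiosyncrasies of any specific device. Passing the synthetic suites
therefore demonstrates the correctness of the *computation* under the
stated physics, not robustness to every artefact of clinical data.

## Problem sizes and validation design

Validation uses exam sizes mirroring the two clinical regimes — ≈7 s
acquisitions at ≈20.4 Hz (≈144 frames, 44.8 µs integration) and ≈74.4 Hz
(≈521 frames, 11.2 µs) — with HRT recovery judged against one analysis-grid
bin (8 ms) plus one frame interval. Cohort reproducibility uses 5 subjects
× 6 exams × 1 vessel over 20 seeded replicates (the clinical design had 5
subjects and ~14 acquisitions each; 6 keeps a replicate tractable), and
recovered inter-/intra-subject CoVs are compared with the generating 9% /
11% dispersions. Registration recovery uses drifts up to ±10 px / ±1° with
0.5 px / 0.2° tolerances. `scripts/acceptance.R` recomputes all of these
from scratch.

## Known limitations

* Velocities are axial components in arbitrary units — no Doppler-angle
  correction, no absolute calibration; only rise timing feeds the HRT.
* Frame-level arrival quantisation dominates the HRT error budget at
  20 kHz; estimates carry a positive bias of up to roughly half a frame
  interval (the detected frame trails the true onset).
* The one-cycle rule assumes the true delay is under one cardiac cycle;
  the estimator cannot distinguish a genuine delay of $D$ from $D + k\,RR$
  — the cohort histogram of unrestricted argmaxes is the instrument for
  checking that assumption.
* Clock alignment between the devices is reduced to a single additive
  offset (`clock_offset_ms`); asymmetric-network synchronisation drift
  within an exam is not modelled.
* Registration compensates in-plane rigid motion only.
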