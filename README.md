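# hrtoct — heart-retina time from ECG-coupled dynamic OCT

Pulsatile blood flow in retinal arterioles washes out the interference
fringes of time-resolved OCT B-scans: during systole the axial velocity of
the scatterers rises and the vessel-lumen SNR drops as

SNR_Drop = sinc²(k₀·Δz),  k₀ = 2π/λ,  Δz = n·v·t,

with λ the central wavelength (880 nm), n the ocular refractive index
(1.36), t the A-scan integration time (44.8 µs at a 20 kHz line rate,
11.2 µs at 85 kHz) and v the axial velocity. `hrtoct` inverts this relation
frame by frame into multi-branch velocity profiles, detects the sharpest
velocity rise of each cardiac cycle (the pulse-arrival time at the retina),
detects R-peaks in a synchronously recorded ECG (Engelse–Zeelenberg
detector), and cross-correlates the two event trains. The additive inverse
of the most probable ECG→OCT lag within one cardiac cycle is the
**heart-retina time (HRT)** — a heart-to-eye pulse transit time.

The package is aimed at researchers working with ECG-coupled dynamic OCT
(or building toward it): it provides the full analysis chain — ECG
resampling and R-peak detection, rigid B-scan registration, vessel-subarea
SNR extraction, washout inversion, pulse-arrival detection, HRT estimation,
and coefficient-of-variation reproducibility reports — plus a forward-model
synthetic generator that produces fully ground-truthed exams and cohorts,
so every stage is testable without acquisition hardware.

## Worked example

Simulate a 7 s exam in the 85 kHz regime with a known 150 ms delay, then
run the full pipeline on it:

```r
library(hrtoct)

cfg <- sim_config(seed = 42, true_hrt_ms = 150, frame_rate_hz = 74.4,
                  integration_time_s = 11.2e-6)
ex <- generate_exam(cfg)
ex$stack
#> <bscan_stack> 521 frames of 72 x 96 px, unregistered, 6.99 s span

res <- analyze_exam(ex$ecg, ex$stack, ex$tracks)
res
#> <exam_result> 1/1 vessels analysed, RR 863 ms
#>   A1: HRT 160.0 ms

res$vessels[["A1"]]$estimate
#> <hrt_estimate> HRT 160.0 ms (offset -160.0 ms, RR 863 ms)
```

Reading the output: the detected R-peaks give a mean cardiac cycle of
863 ms; the cross-correlation of the encoded R-peak and pulse-arrival
trains peaks at an ECG→OCT offset of −160 ms, i.e. the pulse waves arrive
at the retina an estimated 160 ms after ventricular contraction — within
one analysis-grid bin (8 ms) plus one frame interval (13.4 ms) of the
simulated 150 ms ground truth. No outlier flag is set, meaning the
unrestricted correlation argmax also fell within one cardiac cycle.

File-based workflows mirror this: `write_exam_bundle()` produces an exam as
`ecg.csv`, a `stack/` container (`meta.json` + float32 `frames.bin`) and
`annotations.csv`; `run_exam()` consumes those paths and writes
`results.json` plus signal-panel and cross-correlation figures;
`run_cohort()` aggregates a directory tree of bundles into per-vessel
records, a CoV report, and the histogram of correlation offsets. The same
operations are scriptable from a shell via `inst/cli/hrtoct`
(`simulate`, `simulate-cohort`, `ecg-peaks`, `register`, `velocity`, `hrt`,
`cohort-report`).

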