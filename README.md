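# wtfd

Detection and segmentation of fetal heart sounds (S1, S2) in noisy fetal
phonocardiogram (fPCG) recordings, by an iterative wavelet–fractal (WT–FD)
filter, together with a synthetic fPCG generator and the detection indices
needed to benchmark the whole chain without any external data.

## Who this is for

Biomedical-signal researchers working on passive (acoustic) fetal
monitoring: single-channel abdominal recordings at ~1 kHz in which the two
fetal heart sounds per cardiac cycle — S1 (systolic, louder) and S2
(diastolic, quieter and smoother) — must be located, labelled, and turned
into a fetal heart-rate (fHR) estimate despite heavy stationary background
noise.

## The method

The filter separates non-stationary transients from stationary noise:

1. **Decomposition.** An undecimated Daubechies-4 multiresolution transform
   yields `R` full-length detail signals `WT_m[n]` (finest first) plus a
   smooth, summing exactly to the input.
2. **Level selection.** On the residual-energy profile
   `η_λ = 1 − Σ_{i≤λ} E{WT_i²} / Σ_i E{WT_i²}`, the first `D` (noise) levels
   are discarded and the first `M` informative retained levels are selected
   (`η′` threshold `p = 0.01`).
3. **Fractal masking.** Per selected level, the Katz fractal dimension
   `FD = log₁₀ n_s / (log₁₀(d/L_c) + log₁₀ n_s)` is computed in a sliding
   `W = int(0.05·Fs)`-sample window; an iterative peak-peeling algorithm
   (threshold `μ + σ` per 430-ms epoch, repeat until the residual energy
   stabilizes) gathers the trace's peaks; small/weak peaks are pruned; the
   result becomes complementary binary masks `SBTH` (sounds) and
   `NBTH = 1 − SBTH` (noise).
4. **Outer iteration.** `XS_k` = sum of SBTH-masked selected details;
   `XU_k = X − XS_k` is re-fed until `|E{XU²_{k−1}} − E{XU²_k}| < ε`; the
   de-noised signal is `X_REC = Σ_k XS_k`.
5. **Segmentation.** Mask runs become sound intervals; each is labelled S2
   when its preceding gap is shorter than its following gap (systole is
   shorter than diastole), refined by an amplitude rule (S1 peak > 0.5) and
   a 130-ms minimum S2→S1 pause; fHR = 60 / median S1-to-S1 spacing.
6. **Scoring.** Against known ground truth: precision `D_R = 100·S_C/S_P`,
   sensitivity `S_F = 100·S_C/S_O`, and accuracy
   `Q_P = 100·S_C/√(S_O·S_P)` (the geometric mean of the other two).

The synthetic generator reproduces the benchmark conditions: fixed rates
140/110/180 bpm or per-cycle arrhythmia in 80–200 bpm, S1→S2 onset distance
`SSID = 210 − 0.5·fHR` ms, and additive white Gaussian noise with variance
`P_s / 10^(SNR_dB/10)`.

See `vignettes/wtfd-methods.Rmd` for the full methods account, parameter
meanings and design notes.

## Worked example

```r
library(wtfd)

rec <- simulate_fpcg("normal", snr_db = 8, duration = 10, fs = 1000, seed = 1)
rec
#> <fpcg_record> 10000 samples @ 1000 Hz (10 s), condition: normal, SNR: 8 dB, 46 true sounds

det <- detect_fhs(rec)
det
#> <fhs_detection> 46 sounds (23 S1 / 23 S2), fHR 140.2 bpm

det$denoised$diagnostics
#>   iteration d m residual_energy
#> 1         1 1 5      0.01024076
#> 2         2 1 6      0.01024076

cnt <- match_detections(rec$truth, det)
c(qp = compute_qp(cnt), dr = compute_dr(cnt), sf = compute_sf(cnt))
#>  qp  dr  sf
#> 100 100 100
```

The record holds 23 cardiac cycles (46 sounds) at 140 bpm under 8 dB white
noise. The filter converged in two outer iterations, discarding the finest
(noise-only) wavelet level (`d = 1`) and selecting five informative levels;
all 46 sounds were found, none were invented (`D_R = 100`), none were missed
(`S_F = 100`), and the estimated rate is within 0.2 bpm of the configured
140. A full benchmark table over conditions and SNRs:

```r
b <- run_benchmark(conditions = c("normal", "bradycardia"), snrs = c(8, 3),
                   n_seeds = 10)
benchmark_summary(b)
```

A command-line interface over the same functions lives in
`inst/cli/wtfd-cli.R` (`simulate`, `denoise`, `segment`, `evaluate`,
`benchmark` subcommands).

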