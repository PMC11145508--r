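# semgclean

Removal of ECG artifacts from multichannel surface EMG (sEMG) recordings.

When sEMG electrodes sit near the thorax, the heartbeat's electrical
signature contaminates every channel, and because ECG (0–100 Hz) overlaps
the sEMG band (20–250 Hz), frequency filtering alone cannot remove it
without damaging the muscle signal. `semgclean` treats the channels as an
instantaneous linear mixture `x(t) = A s(t)` of independent sources and
removes the cardiac source by blind source separation:

1. **Wavelet denoising** — per-channel multi-level Daubechies
   decomposition (default `db4`, 9 levels); detail coefficients are shrunk
   with an improved threshold rule
   `f(w) = w − 2λ/(1 + exp(w − λ))` for `w ≥ λ` (odd continuation below
   `−λ`, dead zone inside), which is continuous at `±λ`, odd, and
   asymptotically unbiased — unlike the hard rule (discontinuous) and the
   soft rule (constant `λ` bias). Thresholds default to the per-level
   universal rule `λ_j = σ̂ √(2 ln N_j)`, `σ̂ = median(|D₁|)/0.6745`.
2. **PCA whitening** — eigendecomposition of the channel covariance;
   whitened data have identity covariance.
3. **Negentropy FastICA** — deflationary fixed-point iteration with the
   log-cosh contrast, each component's random start polished by a
   backtracking steepest-ascent refinement of the negentropy surrogate.
4. **Fuzzy-entropy identification** — every separated component is scored
   with fuzzy entropy (`m = 2`, `r = 0.2·SD`); the rhythmic, regular ECG
   component scores far below muscle activity and noise. Components are
   sorted by entropy and the first shrinking consecutive gap
   `Φ(k+1) − Φ(k) < Φ(k) − Φ(k−1)` locates the boundary; everything below
   the dominant entropy jump is flagged as cardiac.
5. **Reconstruction** — flagged components are zeroed and the channels
   mapped back; the eliminated part is returned as the ECG artifact
   estimate, so `clean + artifact` equals the denoised record.

A seeded synthetic-signal module (bursting band-limited sEMG surrogate,
Gaussian-bump PQRST ECG trains, mains/wander/white interference, linear
mixing with retained ground truth) makes the whole chain testable without
recorded data, and metrics (Pearson CC, RMSE, SNR in dB, relative error,
Amari index) quantify the results.

## Worked example

Simulate a heavily contaminated recording (three channels, 0 dB
sEMG-to-ECG power ratio, 20 s at 1 kHz), clean it, and compare both
versions against the true sEMG contribution:

```r
library(semgclean)

gt  <- simulate_contaminated(seed = 42, duration = 20)
res <- remove_ecg(gt$observed, pipeline_config(seed = 42))
res$report$classification
#> <component_classification>
#>   entropies: 0.2166, 0.4088, 0.4467
#>   boundary k: 2 (exclusive mode)
#>   ECG components: 1

truth <- new_record(ecg_free_channels(gt, drop_kinds = c("ecg", "noise")),
                    1000, gt$observed$labels)
evaluate_record(gt$observed, truth, "ground_truth")   # before
#>   channel    cc  rmse snr_db    re reference_kind
#> 1     ch1 0.818 0.764   2.33 0.764   ground_truth
#> 2     ch2 0.564 0.956  -4.05 1.594   ground_truth
#> 3     ch3 0.555 0.641  -4.10 1.602   ground_truth
evaluate_record(res$clean, truth, "ground_truth")     # after
#>   channel    cc  rmse snr_db    re reference_kind
#> 1     ch1 0.922 0.510  5.847 0.510   ground_truth
#> 2     ch2 0.922 0.483  1.887 0.805   ground_truth
#> 3     ch3 0.454 0.425 -0.525 1.062   ground_truth
```

Component 1 — the lowest-entropy component, 0.217 against 0.41/0.45 for
the others — is flagged as cardiac and removed. On the two
muscle-dominated channels the correlation with the true sEMG rises from
0.82/0.56 to 0.92/0.92 and the SNR gains 3.5 and 5.9 dB. Channel 3 of
this fixture is dominated by sensor noise rather than muscle activity;
cleaning still lowers its RMSE and raises its SNR, but its waveform
correlation drops — a reminder that on noise-dominated channels the
denoiser, not the ECG remover, decides the shape of what remains.

The same pipeline is available from the shell (script installed under
`inst/cli/`):

```sh
Rscript inst/cli/semgclean.R simulate   --seed 7 --out-dir sim
Rscript inst/cli/semgclean.R remove-ecg --in sim/observed.csv --seed 7 --out-dir cleaned
Rscript inst/cli/semgclean.R evaluate   --estimate cleaned/clean.csv \
        --reference sim/ecg_free.csv --out metrics.csv
```

Records are plain CSV (time column + one column per channel) with a YAML
sidecar carrying the sampling rate, labels, units and provenance.

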