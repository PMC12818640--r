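# rppgkit

Contactless heart-rate estimation from facial video — remote
photoplethysmography (rPPG) — for researchers working on camera-based vital
signs. Ordinary RGB video of skin carries a tiny periodic colour modulation
driven by the cardiac blood-volume pulse; the hard part is recovering it
under illumination drift, sensor noise and motion artifacts. `rppgkit`
implements a complete signal-processing chain around two core ideas:
discrete-wavelet soft-threshold denoising, and a residual-based adaptive
Kalman filter (RAKF) whose correction step is weighted by a signal-quality
index.

## The method

Given per-frame spatial averages of the facial regions of interest
(forehead and cheeks, tiled into sub-ROIs),

```
g(t) = (1/N) Σ_{(i,j) ∈ ROI} I_c(i, j, t),    c ∈ {r, g, b}
```

the pipeline runs:

1. **Wavelet denoising.** `g(t)` is decomposed by an orthonormal Daubechies
   DWT; detail coefficients are soft-thresholded with the universal
   threshold `T = σ√(2 ln n)`, `σ = MAD(d₁)/0.6745`, and the signal is
   reconstructed. The approximation level is chosen so the resting cardiac
   band stays unshrunk.
2. **Dual-stage bandpass.** Zero-phase Butterworth stages at 0.6–3.5 Hz and
   0.8–2.5 Hz isolate the cardiac band while preserving peak timing.
3. **Spectral observations.** Sliding Hann windows (10 s, 1 s hop) yield
   per-window dominant frequencies, `z_k = 60·f_dom`, within 45–150 bpm.
4. **Signal quality.** `SQ_k = λ₁·SPR + λ₂·SNR + λ₃·PS` with
   λ = (0.3, 0.4, 0.3): spectral power ratio around the peak, normalised
   in-band SNR (fundamental + first harmonic), and inter-beat stability
   `PS = max(0, 1 − CV)`.
5. **Residual-adaptive Kalman filter.** A random-walk state `x_k` tracks
   heart rate: prediction `x̂_k⁻ = x̂_{k−1}`, `P_k⁻ = P_{k−1} + Q`;
   measurement noise inflates with the innovation,
   `R_k = R₀(1 + |ỹ_k|/β)`; gross outliers are replaced by a rolling
   median; the update `x̂_k = x̂_k⁻ + K_k·w_k·(z_k − x̂_k⁻)` is damped by
   `w_k = max(α, SQ_k)` while `P_k = (1 − K_k)P_k⁻` stays unweighted.
6. **Fusion.** A time-domain estimate from systolic peaks and inter-beat
   intervals (`HR = 60/mean IBI`) is fused with the filtered spectral
   estimate, weighted by the per-path signal quality.

Evaluation helpers report MAE, RMSE, and decomposition SNR in dB
(`10·log₁₀(P_signal/P_noise)`), plus ablation variants that switch the
denoising, tracking and weighting stages on and off.

A seeded synthetic generator (`synthetic_spec()`, `generate_trace()`,
`generate_video()`) produces ground-truthed fixtures — pulse with harmonic,
baseline wander, sensor noise, boxcar-gated motion bursts, skin-reflectance
gain — so the entire chain is testable offline.

## Worked example

```r
library(rppgkit)

# 60 s study fixture: 72 bpm pulse under drift, noise and two motion bursts
fx  <- generate_trace(synthetic_spec(seed = 42))
res <- run_pipeline(fx$trace, pipeline_config(), reference = fx$truth)
res
#> <rppg_result> variant=full, 51 windows, median HR 72.0 bpm
#>   MAE 0.75 bpm, RMSE 1.45 bpm (n=51)

res$evaluation
#>   mae_bpm rmse_bpm n_windows snr_raw_db snr_filtered_db snr_improvement_db
#> 1    0.75     1.45        51      -4.82           11.55              16.37

head(res$hr, 3)
#>   t_center hr_time_bpm hr_spectral_bpm hr_fused_bpm sq_time sq_spectral
#> 1        5        72.3              72         72.1   0.974       0.970
#> 2        6        72.0              72         72.0   0.979       0.974
#> 3        7        72.5              72         72.3   0.982       0.978

glance(res$rakf)
#>   n_steps x_final p_final mean_gain n_outliers
#> 1      51    72.0    3.90     0.173          0
```

The raw trace measures −4.8 dB against its narrowband cardiac reference; the
filtered output reaches +11.6 dB, a 16 dB improvement, and the fused
per-window heart rate stays within ~1 bpm of the injected 72 bpm. `tidy()`
on the filter fit exposes the full per-step trace (observations, residuals,
adaptive covariance, gains, weights); `autoplot()` and `plot_hr_series()`
draw the standard diagnostics.

A thin command-line front end lives at `inst/cli/rppg.R`
(`run`, `simulate`, `evaluate`, `ablate`, `sensitivity`).

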