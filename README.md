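# fmcwvitals

Non-contact respiration and heart-rate estimation from a 77 GHz
frequency-modulated continuous-wave (FMCW) millimeter-wave radar, for
researchers working on radar vital-sign monitoring who need a complete,
testable signal chain without radar hardware.

A person sitting in front of the sensor reflects each chirp with a delay set
by their range and a phase set, to sub-wavelength precision, by chest-wall
displacement. The I/Q beat signal of a chirp is

```
I(t) + jQ(t) = A_r exp{ j [ 4π(R0 + x(nTs))/λ + 2πKτt ] } + noise,
```

with `λ = c/fc` (≈3.9 mm at 77 GHz), chirp slope `K`, delay `τ ≈ 2R0/c` and
chest displacement `x(t)` — roughly a 1 mm breathing oscillation (0.1–0.5 Hz,
with harmonics) plus a 0.1 mm heartbeat oscillation (1–1.8 Hz). The package
implements the full chain from the raw I/Q cube to rate estimates:

1. **Simulator** (`simulate_cube`) — ground-truth-labelled I/Q cubes with
   static clutter, DC offsets, per-frame phase noise, white noise and
   impulse bursts; fully reproducible from a seed.
2. **Preprocessing** (`range_fft`, `remove_static_clutter`,
   `select_range_bin`) — fast-time FFT, slow-time mean subtraction,
   variance-based target-bin selection.
3. **Phase extraction** (`fit_circle_nlls`, `compensate_dc`,
   `extract_phase_dacm`, `phase_difference`) — DC-offset compensation by
   non-linear least-squares circle fitting, extended
   differentiate-and-cross-multiply (DACM) demodulation, first-order
   differencing to enhance the heartbeat.
4. **Impulse denoising** (`ivmd_wit`) — the iterative VMD
   wavelet-interval-thresholding algorithm: variational mode decomposition
   (ADMM, mode count chosen by a lag-1 cross-correlation criterion), sym4
   wavelet thresholding of the noise-reference mode, random circular
   shifting of the noise component, per-mode interval thresholding with a
   geometric noise-energy model (`Ti = C sqrt(2 Ei ln N)`,
   `Ei = E1/(β ρ^i)`), and averaging over `A = 30` iterations.
5. **Rate estimation** (`separate_vitals`, `bandpass_heart`,
   `notch_harmonics`, `fft_czt_rate`, `peak_seek_rate`, `fft_confidence`,
   `decide_heart_rate`) — VMD separation of the breathing waveform, FFT with
   chirp-z spectral zoom for the respiration rate; elliptic band-pass
   (0.7–3.3 Hz) plus respiratory-harmonic notches for the heartbeat, then a
   confidence-thresholded decision between the spectral estimate and
   time-domain peak counting (`fh = Np/T`).

## Worked example

```r
library(fmcwvitals)

cfg    <- radar_config()                      # 77 GHz, 4 GHz sweep, 20 Hz slow time
motion <- chest_motion(R0 = 1.0, breath_freq = 0.25, heart_freq = 1.3)
imp    <- impairment_model(dc_i = 0.3, dc_q = -0.2, phase_noise_std = 0.02,
                           awgn_std = 0.05, impulse_rate = 0.012,
                           impulse_amp = 1.5, clutter = list(c(0.4, 0.5)),
                           seed = 7)
cube   <- simulate_cube(cfg, motion, imp)
report <- run_pipeline(cube, wit = wit_params(seed = 7), verbose = TRUE,
                       refs = list(resp_bpm = 15, heart_bpm = 78))
print(report)
```

```
preprocess: selected bin 21 (0.984 m), score 1.02e+03
phase_extraction: DC offset (25.7, -35.1), radius 118
denoise: K1 = 7, K2 in [4, 8], 17 unconverged VMD runs
vitals: respiration 0.2486 Hz (14.9 bpm)
vitals: heart fft_czt -> 1.2996 Hz (78.0 bpm), s_fft = 7.73
<vitals_report> respiration 14.92 bpm | heart 77.98 bpm (fft_czt)
  SNR resp 6.06 -> 6.29 dB, heart 8.21 -> 8.10 dB (denoising)
  relative errors: resp 0.55%, heart 0.03%
```

The subject was simulated at 1 m with 15 breaths/min and 78 beats/min; the
pipeline selects range bin 21 (the analytic beat bin for 1 m), estimates
14.92 bpm respiration and 77.98 bpm heart rate, and reports that the
spectral (FFT-CZT) estimate was chosen because its confidence (7.7) was
decisive. The SNR lines compare the separated breathing/heartbeat waveforms
before and after impulse denoising.

A thin command-line front end is installed with the package
(`exec/fmcwvitals`): `simulate` writes a raw interleaved-int16 I/Q dump with
a JSON sidecar, `process` runs the pipeline on such a dump, and `evaluate`
aggregates result rows against a reference CSV.

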