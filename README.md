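# rfcomp

RF pulse distortion compensation for narrow-band (high-Q, low-frequency)
transmit coils, such as those used in low-field MRI and NMR.

A tuned transmit coil is a resonator with envelope time constant
`T = 2Q/ω` (`ω = 2πf_r`). When the coil bandwidth `f_r/Q` is comparable to
or narrower than the pulse bandwidth, square pulses rise and ring down
slowly, and shaped pulses (e.g. the sinc used for slice-selective
excitation) are low-pass filtered into distorted, delayed waveforms.
`rfcomp` implements the full correction chain:

* **Q estimation** — from ring-down traces by cycle counting
  (`Q = πN/ln 2 ≈ 4.53 N`, where `N` is carrier cycles to halve the
  envelope) or by a decimal log-peak fit; and from −3 dB bandwidth
  (`Q = f_r/(f_H − f_L)`).
* **Square-pulse compensation** — a pre-emphasis lobe
  `τ₀ = −T ln(1 − V₁/V₀)` that removes the slow rise, and a 180°-inverted
  damping lobe `τ₂ = T ln(1 + (V₁/V₂)(1 − e^{−τ₁/T}))` that cancels the
  ring-down.
* **Arbitrary-shape compensation** — a multi-square train whose amplitudes
  solve the first-order deconvolution recursion
  `V_n = (A_n − A_{n−1}E)/(1 − E)`, `E = e^{−Δt/T}`, forcing the coil
  envelope through every sample of a target (sinc targets are sampled on
  the `N_S = 4iN₀ + 1` grid that contains all peaks and zero crossings).
* **Simulation and scoring** — an exact piecewise-exponential envelope
  engine, an independent second-order series-RLC simulator, envelope
  demodulation, and an in-band spectral flatness metric (mean absolute
  deviation of the peak-normalized in-band magnitude).

Synthetic oscilloscope-style generators (`gen_ringdown_trace()`,
`gen_pulse_trace()`) make the whole chain testable offline.

## Worked example

```r
library(rfcomp)
coil <- coil_params(f_r = 1e6, Q = 49.83)

# --- Q from a (synthetic, noisy) ring-down trace --------------------------
tr <- gen_ringdown_trace(1e6, 49.83, duration_s = 40e-6,
                         noise_sd = 0.01, seed = 7)
q_from_ringdown(tr, carrier_hz = 1e6, method = "decimal-fit")
#> Ring-down Q estimate (decimal-fit): N = 11.38 cycles to halve, Q = 51.6
#>   31 peak(s) used; constant 4.5324; log-fit residual SE 0.0192

# --- compensated square pulse ---------------------------------------------
comp <- compensate_square(v1 = 40.1e-3, tau1 = 40e-6, overdrive = 3, coil = coil)
comp
#> Compensated square pulse
#>   pre-emphasis: +0.1203 for 6.431 us
#>   main pulse:   +0.0401 for 40 us
#>   damping:      -0.1203 for 4.563 us
envelope_response(comp$train, coil, train_duration(comp$train))
#> [1] 1.387779e-17         # stored energy fully cancelled at the train end

# --- sinc compensation, N_S = 37 at 90 kHz bandwidth ----------------------
tgt <- sample_sinc(n_zeros = 3, density = 3, bandwidth = 90e3)
train <- compensation_train(tgt, coil)
max(abs(envelope_response(train, coil, tgt$times) - tgt$amplitudes))
#> [1] 3.330669e-16         # envelope hits every target sample exactly
max(abs(train$amplitude))
#> [1] 2.438311             # overdrive demanded, in units of the sinc peak
```

The decimal-fit estimate (Q = 51.6 from a 40 dB-SNR trace generated at
Q = 49.83) shows the estimator's few-percent noise sensitivity; noiseless
traces recover Q essentially exactly. The end-of-train envelope near
machine zero and the exact sample interpolation are the two model-level
guarantees the compensation provides. In the end-to-end simulation at
90 kHz the in-band relative error drops from 0.199 (uncompensated sinc) to
0.086 (compensated), with the remaining error dominated by the sinc's own
truncation ripple.

A command-line wrapper with `qfactor`, `compensate`, `simulate`,
`spectrum`, `synth` and `demo` subcommands is installed at
`inst/cli/rfcomp`; see `vignettes/pulse-compensation.Rmd` for the model,
conventions and design choices.

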