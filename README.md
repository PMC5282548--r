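# slicecond

Estimation of the electrical conductivity of cortical slice tissue — and of
its frequency dependence — from multielectrode array (MEA) recordings of
extracellularly injected sinusoidal currents, with correction for electrode
polarization, plus forward modelling of extracellular potentials in causal
frequency-dependent media.

## Who this is for

Electrophysiologists and modellers who need to (i) turn MEA recordings of
known injected currents into tissue conductivity estimates σ_T(f), with the
electrode-polarization (EP) impedance removed, or (ii) quantify what a
candidate conductivity spectrum σ̃(f) would do to local field potentials
(LFPs) predicted from compartmental current sources.  No experimental data
ship with the package: a fully seeded synthetic session generator reproduces
the recording protocol with known ground truth, so the whole chain is
testable end to end.

## The model

A point current `I0` inside a slice of conductivity σ_T (thickness h,
bath conductivity σ_S above, non-conducting array plate below) produces on
the electrode plane the method-of-images potential

    φ(x,y,0) = 2 φ_h(x,y,0) + 2 Σ_{n≥1} W^n [ φ_h(x,y,2nh) + φ_h(x,y,−2nh) ],
    φ_h(r)   = I0 / (4π σ_T r),      W = (σ_T − σ_S)/(σ_T + σ_S),

truncated at 20 terms.  Each recording electrode sees this medium impedance
in series with a common EP impedance Z_EP at the ground electrode:

    φ0(r,ω) e^{jβ(r,ω)} = ( Z_medium(r) + Z_EP(ω) ) · I0 e^{jα(ω)}.

In saline (a half-space, Z_S = 1/(2πσ_S r)) the package minimizes the
residuals of this equation jointly over (σ_S, α), with Z_EP estimated inside
the objective as the electrode average of (measured − model).  The recovered
per-frequency α and Z_EP are then transferred to tissue sessions, where the
real part of the EP-corrected impedance is fitted to the image-series
distance profile, yielding σ_T per condition.  The imaginary part serves as
a built-in diagnostic of capacitive (non-ohmic) tissue behaviour.

For forward modelling, a frequency-dependent |σ̃(f)| is made causal via the
Bode magnitude–phase relation (real-cepstrum minimum phase θ(f)) and applied
as the filter e^{−jθ(f)} / (4π|σ̃(f)| r) to arbitrary current traces, e.g.
the membrane currents of the bundled passive ball-and-stick cell.

## Worked example

Simulate a full session pair (saline + tissue) whose tissue ground truth
rises from 0.37 to 0.55 S/m over 5–500 Hz, then run the complete
extract–fit–report pipeline:

```r
library(slicecond)
cfg <- pipeline_config(
  protocol = injection_protocol(frequencies = c(5, 60, 100, 300, 500),
                                amplitudes = 175e-12,       # 175 pA
                                source_distances = 100e-6,  # 100 um
                                sweeps = 10, sweep_duration = 1,
                                sample_rate = 4000),
  truth_sigma_t = c("5" = 0.37, "60" = 0.41, "100" = 0.42,
                    "300" = 0.47, "500" = 0.55),
  truth_sigma_s = 1.5, ep = ep_model("cpe"), seed = 42)
out <- run_pipeline(cfg)
print(out)
```

```
Slice conductivity pipeline (seed 42)

 medium frequency  sigma truth
 saline         5 1.4733  1.50
 tissue         5 0.3673  0.37
 saline        60 1.4981  1.50
 tissue        60 0.4102  0.41
 saline       100 1.5195  1.50
 tissue       100 0.4213  0.42
 saline       300 1.4883  1.50
 tissue       300 0.4654  0.47
 saline       500 1.5300  1.50
 tissue       500 0.5425  0.55
...
Linear trend (sigma ~ frequency):
  tissue: slope 0.00032 S/m/Hz, R^2 = 0.970, change 5 -> 500 Hz: +47.7%
```

Each `sigma` is the conductivity recovered from noisy synthetic traces by
the EP-corrected fit; `truth` is what the generator used.  At this noise
level (0.5 µV per sample, single-sweep SNR ≈ 1 at the nearest electrode) the
estimates land within a few percent of truth, and the fitted trend recovers
the generated rise.  The EP impedance itself is recovered per frequency in
`out$saline_fit$ep`, and `out$phase_diff` gives the tissue-minus-saline
phase offsets used to diagnose capacitive tissue behaviour.

To ask what such a spectrum would do to an LFP:

```r
prof <- build_profile("ramp", base = 0.48, percent = 50, f_max = 2000)
g5   <- sinusoid_gain(5,   prof, distance = 100e-6, sample_rate = 4000)
g500 <- sinusoid_gain(500, prof, distance = 100e-6, sample_rate = 4000)
g500 / g5
#> [1] 0.6667184
```

A 50% conductivity rise from 5 to 500 Hz attenuates the 500 Hz component of
the extracellular potential to ~0.67 of the 5 Hz component at equal source
current.

## Package layout

* `fit_saline()`, `fit_tissue()` — the estimators; classed objects with
  `print`/`coef`/`summary`/`residuals`/`predict` methods.
* `generate_session()`, `inject_dead_electrodes()`, `write_session()` —
  synthetic sessions with ground truth.
* `extract_phasor()`, `qc_electrodes()`, `session_phasors()` — sweep
  reduction.
* `build_profile()`, `minimum_phase()`, `filter_potential()` — causal
  frequency-dependent media.
* `passive_cell()`, `simulate_passive_cell()`, `extracellular_response()`,
  `psd_trace()`, `peak_to_peak()` — the LFP proxy.
* `run_pipeline()` — end-to-end orchestration and report bundle.

See `vignettes/conductivity-estimation.Rmd` for the methods account:
assumptions, parameter choices, numerical details, and limitations.
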