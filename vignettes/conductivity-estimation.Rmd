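---
title: "Estimating tissue conductivity spectra from MEA slice recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tissue conductivity spectra from MEA slice recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicecond)
```

## The problem

When a sinusoidal current of physiological amplitude (hundreds of pA) is
injected into the extracellular space of a cortical slice lying on a planar
multielectrode array (MEA), the potentials recorded by the array encode the
electrical conductivity of the tissue at the stimulation frequency.  Whether
that conductivity depends on frequency in the band relevant for local field
potentials (below a few hundred Hz) determines whether the tissue itself
filters extracellular signals.  Measuring it is complicated by electrode
polarization (EP): an impedance at the electrolyte–metal interface of the
current-carrying ground electrode that sits in series with the medium and,
if uncorrected, masquerades as a frequency-dependent conductivity.

`slicecond` implements the complete estimation chain — forward volume-conductor
models, synthetic data generation with known ground truth, phasor extraction,
joint estimation of saline conductivity/injection phase/EP, EP-corrected
tissue fits — plus a causal (minimum-phase) frequency-dependent medium model
for asking what a candidate conductivity spectrum would do to simulated
extracellular potentials.

## Forward models

All models treat the source as an ideal point current and electrodes as
ideal points on the plane $z = 0$; the slice occupies $0 \le z \le h$ with
an effectively infinite bath above.  Units are SI throughout.

* Infinite homogeneous medium:
  $\phi_h = I_0 / (4\pi\sigma r)$.
* Saline half-space over the non-conducting array plate:
  $\phi = I_0 / (2\pi\sigma_S r)$ — exactly twice $\phi_h$, the image of the
  insulating boundary.
* Plate–slice–bath (method of images): mirror sources at heights
  $\pm 2nh$ weighted by $W^n$, $W = (\sigma_T-\sigma_S)/(\sigma_T+\sigma_S)$:
  $$\phi_{MEA}(x,y,0) = 2\phi_h(x,y,0) + 2\sum_{n=1}^{N} W^n
    \left[\phi_h(x,y,2nh) + \phi_h(x,y,-2nh)\right].$$
  For $\sigma_T = \sigma_S$ this collapses to the half-space result.

**Series truncation.** The default `n_terms = 20` converges geometrically in
$|W|$.  For the canonical parameters ($\sigma_T = 0.4$, $\sigma_S = 1.5$,
$h = 200$ µm) the pointwise deviation from a 1000-term sum is below
$8\times10^{-6}$ relative at all lateral offsets up to 1.4 mm.  At the
strongest bath–tissue contrast used in the recovery studies
($\sigma_T = 0.37$, $|W| = 0.60$) the error grows towards the array edge,
reaching $\approx 2\times10^{-5}$ at 1.4 mm — still three orders of
magnitude below the measurement noise of any realistic session, so fits are
unaffected.  `n_terms` is a plain argument for users who want more.

Only the homogeneous anisotropic point source is provided
(`potential_homogeneous_anisotropic()`); the layered anisotropic formula is
out of scope, and MEA potentials are in any case insensitive to moderate
anisotropy.

## The synthetic session generator

`generate_session()` is first-class, tested code, not a fixture: it defines
the study conditions under which every downstream claim is verified.  Each
trace is

$$V_e(t) = \mathrm{Re}\left[(Z_{model,e} + Z_{EP})\, I_0
  e^{j(\omega t + \alpha)}\right] + \varepsilon(t),$$

with $Z_{model,e}$ the forward-model transfer impedance at the stimulation
frequency, $Z_{EP}$ a position-independent series EP impedance, and
$\varepsilon$ i.i.d. Gaussian noise.

Defaults reproduce the recording protocol: an 8×8 array with 200 µm pitch
and corners absent (60 electrodes), frequencies 5/60/100/300/500 Hz,
amplitudes 175/300/500 pA, source 100 or 125 µm above the nearest electrode,
50 sweeps of 2.5 s at 20 kHz.  Choices the protocol leaves open were fixed
once:

* **Noise.** Only "similar noise characteristics" is specified for the
  original recordings, with no number; we use i.i.d. Gaussian samples with
  `noise_sd = 0.5` µV, which gives a single-sweep SNR near one at the
  electrode closest to the source for protocol-scale currents — enough to
  make recovery non-trivial while sweep averaging restores usable phasors.
  No amplifier band-pass, line noise, or ongoing network activity is
  modelled.
* **EP model.** Default is a constant-phase element
  $Z_{EP}(\omega) = K (j\omega)^{-n}$ with $K = 5\times10^4$ Ω s$^{-n}$ and
  $n = 0.8$, typical of metal–electrolyte interfaces.  At 5 Hz its magnitude
  (≈3 kΩ) is comparable to the medium impedance at the nearest electrode and
  decays towards 500 Hz, so *uncorrected* saline sessions show exactly the
  kind of spurious rising conductivity trend that motivates the EP
  correction.  An explicit per-frequency table is also supported.
* **Source placement.** Vertically above the designated nearest electrode,
  so "distance to the closest electrode" equals the source height.  Lateral
  pipette offset is not modelled.
* **Injection phase.** $\alpha$ (default 0.2 rad) is stored as ground truth
  but never consumed by the fitting path, mirroring the experimental
  situation where it is unknown and must be recovered from saline fits.

Sessions are bit-identical under equal seeds, and exchangeable as a
directory of `metadata.json` plus one wide CSV per condition
(`write_session()` / `read_session()`).

**Desk scaling.** A full-size session is ~60 M samples per condition.  The
documentation, tests, and the acceptance script use reduced protocols
(typically 10 sweeps × 1 s at 4 kHz) chosen so that phasor noise remains
realistic; the estimation problem — same geometry, same currents, same noise
per sample — is unchanged.

## From sweeps to conductivities

1. **Averaging and phasor extraction.** Sweeps are averaged pointwise;
   the amplitude $\phi_0$ and phase $\beta$ at the stimulation frequency are
   extracted by exact least-squares projection onto $\cos/\sin$ at that
   frequency.  A nearest-FFT-bin mode exists for comparison, but the
   projection is the default because 5 Hz is a non-integer number of cycles
   (12.5) in a 2.5 s sweep and bin lookup leaks badly there.  All phase
   arithmetic is done on complex numbers; phases live in $(-\pi, \pi]$.
2. **Quality control.** An electrode is dropped when its amplitude falls
   below half the median amplitude of its (up to eight) grid neighbours.
   The 0.5 fraction is a package choice — no number exists in the protocol —
   and is a plain argument.
3. **Saline fit** (`fit_saline()`).  Per condition, measured impedances
   $M_i = (\phi_0/I_0)e^{j\beta_i}$ are modelled as
   $e^{j\alpha}(1/(2\pi\sigma_S r_i) + Z_{EP})$.  The fit minimizes the
   summed squared residual magnitude over $(\log\sigma_S, \alpha)$ with
   $Z_{EP}$ re-evaluated inside the objective as the complex mean of
   (measured − model) over QC-passing electrodes (unweighted; a weighting
   hook is deliberately not provided since the unweighted mean is what the
   centred residual algebra assumes).  Parameterizing in $\log\sigma$ keeps
   the conductivity positive.  Identifiability: the EP term absorbs any
   constant offset but not a rotation of the distance-dependent part, so
   $(\sigma_S, \alpha, Z_{EP})$ are jointly exact on noise-free data for any
   EP spectrum — verified over CPE exponents 0.2–0.9.
   Optimizer: Nelder–Mead with relative tolerance $10^{-14}$ and a restart,
   initialized at $\sigma_S = 1.5$ S/m, $\alpha = 0$.  No optimizer is named
   in the original procedure; this one needs no derivatives and the
   objective is smooth in two parameters.
4. **Tissue fit** (`fit_tissue()`).  The per-frequency $\hat\alpha$ and
   $\hat Z_{EP}$ from the matching saline session are transferred (the EP
   originates at the shared ground electrode), the corrected tissue
   impedance $Z_T = M e^{-j\hat\alpha} - \hat Z_{EP}$ is formed, and
   $\mathrm{Re}(Z_T)$ is fitted across electrodes to the method-of-images
   distance profile by 1-D least squares over $\log\sigma_T$, with the bath
   conductivity held at 1.5 S/m (the standard-saline value).  Conditions at
   the same frequency are fitted independently and pooled afterwards.
5. **Diagnostics.**  $\mathrm{Im}(Z_T)$ is not fitted: in an ohmic slice it
   carries no distance dependence.  The ratio of the Im to the Re distance
   slope estimates the conductivity phase; since a residual error
   $\delta\alpha$ in the transferred injection phase produces exactly the
   same signature (an Im slope of $-\delta\alpha$ times the Re slope), the
   flatness flag fires only for a *significant* implied phase above 0.1 rad,
   beyond what phase-transfer noise produces at protocol noise levels.  The
   same reasoning caps the resolution of `phase_difference()`: raw
   tissue-minus-saline phase offsets cancel EP exactly only when
   $Z_{EP} = 0$ (with the default CPE the mixing bias is a few hundredths of
   a radian), which is why the exact-phase tests in the suite use EP-free
   sessions.

## Causal frequency-dependent media

A frequency-dependent conductivity must be complex to respect causality.
`build_profile()` constructs magnitude profiles $|\tilde\sigma(f)|$ —
constant, or rising linearly by 25%/50% between 5 and 500 Hz and then either
saturating or continuing with the same slope.  `minimum_phase()` fills in
the phase $\theta(f)$ implied by the Bode magnitude–phase relation using the
real-cepstrum construction (cepstrum of $\log|\tilde\sigma|$, causal
folding, imaginary part of the rebuilt log-spectrum).  Sanity anchors: a
flat magnitude gives $\theta \equiv 0$; a $\sqrt{f}$ magnitude gives
$\theta \to \pi/4$ in the band interior (the grid-edge mirror symmetry bends
it near Nyquist, so "interior" means well below the grid maximum).

`filter_potential()` evaluates
$\phi(t) = \mathrm{Re}\,\mathrm{iFFT}[e^{-j\theta} I(f) / (4\pi|\tilde\sigma|r)]$
with the magnitude linearly interpolated onto the FFT grid of the
zero-padded (factor 2) trace, held constant outside the profile's range, and
$\theta$ recomputed on that working grid — which makes the filter causal at
working resolution by construction and is idempotent with respect to the
profile's stored phase.  DC is handled by $\theta(0) = 0$ and a magnitude
equal to the lowest-band value.  Steady-state gains are measured after
discarding the first 10% of the output.  Grid length, padding and
interpolation are package choices; the underlying sparse 5–500 Hz magnitude
means any such spectrum is an interpolation, not a measurement, outside that
band.

## The passive-cell proxy

The forward LFP demonstrations use a passive ball-and-stick cell
(`passive_cell()`: 10 µm soma, 1 mm × 2 µm dendrite in 10 compartments,
$r_m = 1\ \Omega\,$m², $c_m = 0.01$ F/m², $r_a = 1.5\ \Omega\,$m, rest at
−70 mV) integrated by backward Euler at 1/32 ms.  It replaces a detailed
morphological pyramidal-cell model, whose reproduction requires an external
morphology and an unstated absolute conductivity; consequently the published
absolute spike peak-to-peak amplitudes are treated as non-reproducible
context, and the package instead verifies the *laws* those numbers
instantiate: exact Kirchhoff closure of the compartment currents, the exact
PSD rescaling $(\sigma_{const}/|\tilde\sigma(f)|)^2$ between media,
causality of the medium impulse response, and monotone shrinkage of a
biphasic spike template's peak-to-peak under 25% → 50% ramps.  Externally
computed compartment-current matrices can be imported via
`read_current_sources()` for users who have a detailed model.  Synaptic
input is an exponential conductance (onset 20 ms into the retained
recording, τ = 2 ms); white-noise input is a sum of equal-amplitude
random-phase sinusoids rescaled to SD 8 pA, band 1–1000 Hz by default (the
original band is unstated).

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  protocol = injection_protocol(frequencies = c(5, 60, 100, 300, 500),
                                amplitudes = 175e-12,
                                source_distances = 100e-6,
                                sweeps = 10, sweep_duration = 1,
                                sample_rate = 4000),
  truth_sigma_t = c("5" = 0.37, "60" = 0.41, "100" = 0.42,
                    "300" = 0.47, "500" = 0.55),
  truth_sigma_s = 1.5, ep = ep_model("cpe"), seed = 42)
out <- run_pipeline(cfg)
print(out)
summary(out$tissue_fit)
```

## What passing tests do and do not show

The generator is the forward model plus white noise, so recovery tests
demonstrate the *estimator's* correctness (unbiasedness, joint
identifiability, EP invariance across CPE exponents, insensitivity to
amplitude and source height), not the realism of any particular session.
Real recordings add amplifier filtering, correlated and non-Gaussian noise,
uncertain source and electrode geometry, finite 30 µm electrode discs, and
genuinely unknown EP physics; none of these are emulated, and the original
study itself attributes the residual rising trend in saline to unexplained
setup effects.  Anisotropy can be *generated*
(`potential_homogeneous_anisotropic()`) but is not fitted.

## Known limitations

* Electrodes are points; disc averaging over the 30 µm contacts is ignored.
* The bath is infinitely thick; a finite saline layer would need a second
  image series.
* `sigma_s = 0` (two insulating boundaries) is rejected: the image series
  diverges and the potential relative to a distant ground is undefined.
* The flatness diagnostic cannot distinguish a tissue phase below ~0.1 rad
  from injection-phase transfer error — a floor inherent to the saline
  reference design, not to this implementation.
* Ionic-diffusion contributions to low-frequency impedance are not
  modelled.
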