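# Desk-scale protocol used throughout the tests: same geometry and current
# ranges as the full recording protocol, but fewer/shorter sweeps at a lower
# sampling rate so sessions stay small.  The estimation problem is unchanged.
desk_protocol <- function(frequencies = 5, amplitudes = 175e-12,
                          source_distances = 100e-6, sweeps = 10L,
                          sweep_duration = 1, sample_rate = 4000,
                          alpha = 0.2) {
  injection_protocol(frequencies = frequencies, amplitudes = amplitudes,
                     source_distances = source_distances, sweeps = sweeps,
                     sweep_duration = sweep_duration,
                     sample_rate = sample_rate, alpha = alpha)
}

# One saline + one tissue session with matching protocol, plus their fits.
recover_tissue <- function(freq, sigma_t_truth, seed,
                           ep = ep_model("cpe"), noise_sd = 5e-7,
                           sigma_bath = 1.5, protocol = desk_protocol(freq)) {
  sal <- generate_session(protocol, medium = "saline", sigma_s = sigma_bath,
                          ep = ep, noise_sd = noise_sd, seed = seed)
  geom <- slice_geometry(200e-6, sigma_t_truth, sigma_bath)
  tis <- generate_session(protocol, medium = "tissue", geometry = geom,
                          ep = ep, noise_sd = noise_sd, seed = seed + 10000L)
  fit_tissue(tis, fit_saline(sal), sigma_s_fixed = sigma_bath)
}
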