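test_that("white-noise current has exact SD, flat band spectrum, and is seeded", {
  wn <- white_noise_current(sd = 8e-12, band = c(1, 1000), duration = 0.5,
                            sample_rate = 8000, seed = 3)
  expect_equal(sd(wn), 8e-12)
  expect_identical(wn, white_noise_current(sd = 8e-12, band = c(1, 1000),
                                           duration = 0.5,
                                           sample_rate = 8000, seed = 3))
  p <- psd_trace(wn, 8000)
  inband <- p$psd[p$f >= 2 & p$f <= 999]
  outband <- p$psd[p$f > 1100]
  expect_lt(max(inband) / min(inband), 1.0001)  # equal amplitudes
  expect_lt(max(outband), 1e-12 * max(inband))
  # 0.01 s duration puts grid frequencies at multiples of 100 Hz only
  expect_error(white_noise_current(band = c(433, 434), duration = 0.01,
                                   sample_rate = 8000), "grid")
})

test_that("passive cell conserves current and rests at equilibrium", {
  cell <- passive_cell()
  n <- round(0.2 * 32000)
  src <- simulate_passive_cell(cell,
                               list(kind = "current", compartment = 1,
                                    I = rep(1e-10, n)),
                               duration = 0.2, discard = 0)
  # Kirchhoff closure at every step
  expect_lt(max(abs(rowSums(src$currents) - src$injected)),
            1e-12 * max(abs(src$injected)))
  zero <- simulate_passive_cell(cell,
                                list(kind = "current", compartment = 1,
                                     I = 0),
                                duration = 0.05, discard = 0)
  expect_lt(max(abs(zero$currents)), 1e-20)
  # synaptic conductance input: membrane currents sum to zero
  syn <- simulate_passive_cell(cell,
                               list(kind = "synapse", compartment = 10,
                                    weight = 0.01e-6),
                               duration = 0.15, discard = 0.02)
  expect_lt(max(abs(rowSums(syn$currents))),
            1e-10 * max(abs(syn$currents)))
  expect_error(simulate_passive_cell(cell,
                                     list(kind = "current",
                                          compartment = 99, I = 0),
                                     duration = 0.01, discard = 0),
               "compartment")
})

test_that("isolated soma matches the analytic RC low-pass response", {
  cell <- passive_cell(n_dend = 0L)
  R <- 1 / cell$g_leak[1]; C <- cell$c_m[1]
  dt <- 1 / 32 * 1e-3
  for (f in c(2, 50)) {
    tt <- seq(dt, 0.8, by = dt)
    I <- 50e-12 * sin(2 * pi * f * tt)
    s <- simulate_passive_cell(cell,
                               list(kind = "current", compartment = 1,
                                    I = I),
                               duration = 0.8, discard = 0.3)
    vamp <- extract_phasor(s$voltages[, 1] - mean(s$voltages[, 1]), f,
                           1 / dt)$amplitude
    expect_equal(vamp, 50e-12 * R / sqrt(1 + (2 * pi * f * R * C)^2),
                 tolerance = 0.005)
  }
})

test_that("extracellular response in a constant medium is the static superposition", {
  cell <- passive_cell(n_dend = 4L)
  syn <- simulate_passive_cell(cell,
                               list(kind = "synapse", compartment = 4,
                                    weight = 0.01e-6),
                               duration = 0.1, discard = 0.02)
  el <- electrode_setup(heights = c(0, 500e-6), lateral = 50e-6)
  prc <- build_profile("constant", base = 0.48, f_max = 16000, n = 2^12 + 1)
  v <- extracellular_response(syn, el, prc)
  direct <- sapply(seq_len(nrow(el)), function(e) {
    out <- 0
    for (s in seq_len(nrow(cell$positions))) {
      r <- sqrt(sum((el[e, ] - cell$positions[s, ])^2))
      out <- out + syn$currents[, s] / (4 * pi * 0.48 * r)
    }
    out
  })
  expect_equal(v, direct, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("changing the medium rescales each frequency by sigma_const/|sigma(f)|", {
  # impulse-response transfer functions factor exactly through the medium
  prc <- build_profile("constant", base = 0.48, f_max = 2000)
  prr <- build_profile("ramp", base = 0.48, percent = 50, f_max = 2000)
  n <- 8192; x <- rep(0, n); x[10] <- 1
  hc <- filter_potential(x, 4000, 1e-4, prc)
  hr <- filter_potential(x, 4000, 1e-4, prr)
  pc <- psd_trace(hc, 4000); pr <- psd_trace(hr, 4000)
  mag <- approx(prr$f, prr$magnitude, xout = pc$f, rule = 2)$y
  sel <- pc$f > 10 & pc$f < 1500
  expect_equal(pr$psd[sel] / pc$psd[sel], (0.48 / mag[sel])^2,
               tolerance = 1e-4)
})

test_that("normalized synaptic LFP waveforms are only weakly affected by conductivity ramps", {
  cell <- passive_cell()
  syn <- simulate_passive_cell(cell,
                               list(kind = "synapse", compartment = 10,
                                    weight = 0.01e-6),
                               duration = 0.25, discard = 0.05)
  el <- electrode_setup()
  prc <- build_profile("constant", base = 0.48, f_max = 16000, n = 2^13 + 1)
  for (pc in c(25, 50)) {
    prr <- build_profile("ramp", base = 0.48, percent = pc,
                         f_max = 16000, n = 2^13 + 1)
    vc <- extracellular_response(syn, el, prc)
    vr <- extracellular_response(syn, el, prr)
    for (e in 1:3) {
      dev <- max(abs(vc[, e] / max(abs(vc[, e])) -
                     vr[, e] / max(abs(vr[, e]))))
      expect_lt(dev, 0.2)
    }
    # soma-level electrode (slow return currents): deviation is small
    dev1 <- max(abs(vc[, 1] / max(abs(vc[, 1])) -
                    vr[, 1] / max(abs(vr[, 1]))))
    expect_lt(dev1, 0.1)
  }
})

test_that("peak-to-peak and PSD readouts behave as defined", {
  t <- seq(0, 1, length.out = 1001)
  expect_equal(peak_to_peak(sin(2 * pi * 5 * t)), 2, tolerance = 1e-4)
  expect_equal(peak_to_peak(rep(3, 10)), 0)
  # Parseval: integral of the PSD equals the variance
  set.seed(4); z <- rnorm(1000)
  p <- psd_trace(z, 250)
  expect_equal(sum(p$psd) * 250 / 1000, mean((z - mean(z))^2),
               tolerance = 1e-10)
  # pure sinusoid concentrates in one bin
  x <- sin(2 * pi * 50 * (0:999) / 1000)
  px <- psd_trace(x, 1000)
  expect_gt(px$psd[px$f == 50] / sum(px$psd), 0.999)
})

test_that("spike-template peak-to-peak shrinks monotonically with the conductivity ramp", {
  sp <- spike_current_template()
  pp <- vapply(c(0, 25, 50), function(pc) {
    pr <- if (pc == 0)
      build_profile("constant", base = 0.48, f_max = 16000, n = 2^13 + 1)
    else
      build_profile("ramp", base = 0.48, percent = pc, f_max = 16000,
                    n = 2^13 + 1)
    peak_to_peak(filter_potential(sp, 32000, 30e-6, pr))
  }, numeric(1))
  expect_true(all(diff(pp) < 0))
})

test_that("distal electrodes show stronger intrinsic dendritic low-pass filtering", {
  cell <- passive_cell()
  wn <- white_noise_current(sd = 8e-12, band = c(1, 1000), duration = 0.5,
                            sample_rate = 32000, seed = 7)
  src <- simulate_passive_cell(cell,
                               list(kind = "current", compartment = 1,
                                    I = wn),
                               duration = 0.6, discard = 0.1)
  el <- electrode_setup()
  prc <- build_profile("constant", base = 0.48, f_max = 16000, n = 2^13 + 1)
  v <- extracellular_response(src, el, prc)
  ratio <- function(e) {
    p <- psd_trace(v[, e], 32000)
    mean(p$psd[p$f >= 300 & p$f <= 500]) /
      mean(p$psd[p$f >= 10 & p$f <= 30])
  }
  expect_lt(ratio(3), ratio(1))  # distal decays faster than somatic
})

test_that("current source sets round-trip through the CSV exchange format", {
  pos <- rbind(c(0, 0, 0), c(0, 0, 5e-4))
  cur <- cbind(sin(1:50), cos(1:50)) * 1e-10
  s <- current_source_set(pos, cur, 32000)
  path <- tempfile(fileext = ".csv")
  write_current_sources(s, path)
  r <- read_current_sources(path, 32000)
  expect_equal(r$positions, pos, ignore_attr = TRUE)
  expect_equal(r$currents, cur, ignore_attr = TRUE)
  unlink(path)
})
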