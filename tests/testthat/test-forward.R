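test_that("homogeneous point source follows 1/(4 pi sigma r)", {
  src <- c(0, 0, 100e-6)
  obs <- c(0, 0, 0)
  # closed-form hand evaluation: 500 pA, 1.5 S/m, 100 um
  expect_equal(potential_homogeneous(src, 500e-12, obs, 1.5),
               500e-12 / (4 * pi * 1.5 * 100e-6))
  expect_equal(potential_homogeneous(src, 0, obs, 1.5), 0)
  # doubling distance halves the potential
  expect_equal(potential_homogeneous(c(0, 0, 200e-6), 1e-9, obs, 0.5),
               potential_homogeneous(src, 1e-9, obs, 0.5) / 2)
  # superposition: two sources add linearly
  obs2 <- c(3e-4, -2e-4, 0)
  s1 <- c(1e-4, 0, 2e-4); s2 <- c(-2e-4, 1e-4, 3e-4)
  expect_equal(potential_homogeneous(s1, 2e-10, obs2, 0.4) +
                 potential_homogeneous(s2, -1e-10, obs2, 0.4),
               sum(potential_homogeneous(s1, 2e-10, obs2, 0.4),
                   potential_homogeneous(s2, -1e-10, obs2, 0.4)))
  expect_error(potential_homogeneous(src, 1e-9, src, 1.5), "coincident")
  expect_error(potential_homogeneous(src, 1e-9, obs, 0), "positive")
})

test_that("saline half-space doubles the homogeneous potential", {
  src <- c(0, 0, 100e-6)
  obs <- rbind(c(0, 0, 0), c(4e-4, 1e-4, 0))
  expect_equal(potential_saline_halfspace(src, 500e-12, obs, 1.5),
               2 * potential_homogeneous(src, 500e-12, obs, 1.5))
  expect_equal(potential_saline_halfspace(src, 500e-12, c(0, 0, 0), 1.5),
               500e-12 / (2 * pi * 1.5 * 100e-6))
  # odd in the current
  expect_equal(potential_saline_halfspace(src, -2e-10, obs, 0.5),
               -potential_saline_halfspace(src, 2e-10, obs, 0.5))
  expect_error(potential_saline_halfspace(c(0, 0, -1e-5), 1e-9, obs, 1.5),
               "above")
  expect_error(potential_saline_halfspace(src, 1e-9, c(0, 0, 1e-5), 1.5),
               "plane")
})

test_that("MEA image series reduces to twice the homogeneous solution when the slice matches the bath", {
  g <- slice_geometry(200e-6, 1.5, 1.5)
  src <- c(0, 0, 100e-6)
  obs <- rbind(c(0, 0, 0), c(2e-4, 0, 0), c(1e-3, 8e-4, 0))
  expect_equal(potential_mea(src, 5e-10, obs, g),
               2 * potential_homogeneous(src, 5e-10, obs, 1.5))
})

test_that("20-term truncation matches a brute-force high-order image sum", {
  # independent oracle: direct summation of reflected sources
  oracle <- function(src, obs, h, st, ss, n_max) {
    w <- (st - ss) / (st + ss)
    rho2 <- (obs[1] - src[1])^2 + (obs[2] - src[2])^2
    tot <- 2 / sqrt(rho2 + src[3]^2)
    for (n in seq_len(n_max))
      tot <- tot + 2 * w^n * (1 / sqrt(rho2 + (2 * n * h - src[3])^2) +
                              1 / sqrt(rho2 + (2 * n * h + src[3])^2))
    tot / (4 * pi * st)
  }
  h <- 200e-6
  for (st in c(0.4, 0.55)) for (zp in c(100e-6, 125e-6)) {
    g20 <- slice_geometry(h, st, 1.5, n_terms = 20)
    src <- c(0, 0, zp)
    for (rho in c(0, 2e-4, 6e-4, 1.4e-3)) {
      obs <- c(rho, 0, 0)
      ref <- oracle(src, obs, h, st, 1.5, 1000)
      expect_lt(abs(potential_mea(src, 1, obs, g20) - ref) / abs(ref), 1e-5)
    }
  }
  # strongest bath-tissue contrast of the protocol (|W| = 0.60): the
  # truncation error grows towards the array edge but stays below 3e-5
  g37 <- slice_geometry(h, 0.37, 1.5, n_terms = 20)
  for (rho in c(6e-4, 1e-3, 1.4e-3)) {
    ref <- oracle(c(0, 0, 1e-4), c(rho, 0, 0), h, 0.37, 1.5, 1000)
    expect_lt(abs(potential_mea(c(0, 0, 1e-4), 1, c(rho, 0, 0), g37) - ref) /
                abs(ref), 3e-5)
  }
  # directly below the source the 20-term sum is accurate to 1e-6 relative
  g <- slice_geometry(h, 0.4, 1.5, n_terms = 20)
  ref0 <- oracle(c(0, 0, 1e-4), c(0, 0, 0), h, 0.4, 1.5, 1000)
  expect_lt(abs(potential_mea(c(0, 0, 1e-4), 1, c(0, 0, 0), g) - ref0) /
              abs(ref0), 1e-6)
})

test_that("conductive bath shunts and insulating bath boosts the MEA potential", {
  src <- c(0, 0, 100e-6)
  obs <- c(3e-4, 0, 0)
  hom2 <- 2 * potential_homogeneous(src, 1e-9, obs, 0.4)
  shunt <- potential_mea(src, 1e-9, obs, slice_geometry(2e-4, 0.4, 1.5))
  boost <- potential_mea(src, 1e-9, obs, slice_geometry(2e-4, 0.4, 0.05))
  expect_lt(shunt, hom2)   # sigma_s > sigma_t: every image term negative
  expect_gt(boost, hom2)   # sigma_s < sigma_t: terms add
  # monotone lateral decay on the plane
  xs <- seq(0, 1.4e-3, by = 1e-4)
  phi <- potential_mea(src, 1e-9, cbind(xs, 0, 0),
                       slice_geometry(2e-4, 0.4, 1.5))
  expect_true(all(diff(abs(phi)) < 0))
  expect_error(potential_mea(c(0, 0, 3e-4), 1, obs,
                             slice_geometry(2e-4, 0.4, 1.5)), "inside")
  expect_error(slice_geometry(2e-4, 0.4, 0), "positive")
})

test_that("anisotropic point source has the right symmetries and limits", {
  src <- c(0, 0, 0)
  expect_equal(
    potential_homogeneous_anisotropic(src, 1e-9, c(1e-4, 2e-4, 3e-4),
                                      c(1.5, 1.5, 1.5)),
    potential_homogeneous(src, 1e-9, c(1e-4, 2e-4, 3e-4), 1.5))
  # swapping x/y displacement with x/y conductivities leaves it unchanged
  expect_equal(
    potential_homogeneous_anisotropic(src, 1, c(1e-4, 3e-4, 2e-4),
                                      c(0.3, 0.6, 0.4)),
    potential_homogeneous_anisotropic(src, 1, c(3e-4, 1e-4, 2e-4),
                                      c(0.6, 0.3, 0.4)))
  # doubling sigma_z with a purely lateral displacement divides by sqrt(2)
  base <- potential_homogeneous_anisotropic(src, 1, c(2e-4, 0, 0),
                                            c(0.4, 0.4, 0.4))
  expect_equal(
    potential_homogeneous_anisotropic(src, 1, c(2e-4, 0, 0),
                                      c(0.4, 0.4, 0.8)),
    base / sqrt(2))
  expect_error(potential_homogeneous_anisotropic(src, 1, src, c(1, 1, 1)),
               "coincident")
})
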