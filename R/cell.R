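#' Band-limited white-noise current
#'
#' A sum of sinusoids of equal amplitude and uniform random phases at every
#' FFT grid frequency inside `band`, rescaled to an exact target standard
#' deviation (default 8 pA).  Used as a flat-spectrum probe of the
#' frequency response of a cell/medium combination.
#'
#' @param sd Target standard deviation in amperes.
#' @param band Frequency band `(f_lo, f_hi)` in Hz, inside (0, Nyquist).
#' @param duration Trace duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed for the random phases.
#' @return Numeric current trace in amperes.
#' @export
white_noise_current <- function(sd = 8e-12, band = c(1, 1000),
                                duration = 1, sample_rate = 32000,
                                seed = 1L) {
  stopifnot(sd > 0, band[1] > 0, band[2] > band[1],
            band[2] < sample_rate / 2, duration > 0)
  n <- round(duration * sample_rate)
  k <- seq_len(floor(n / 2) - 1L)
  fk <- k / duration
  sel <- k[fk >= band[1] & fk <= band[2]]
  if (length(sel) == 0L) stop("no FFT grid frequencies inside 'band'")
  set.seed(as.integer(seed))
  spec <- complex(real = rep(0, n))
  ph <- stats::runif(length(sel), -pi, pi)
  spec[sel + 1L] <- exp(1i * ph)
  spec[n - sel + 1L] <- Conj(spec[sel + 1L])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

#' Stereotyped biphasic spike-like current template
#'
#' A derivative-of-Gaussian waveform mimicking the sharp biphasic shape of
#' an extracellular spike current.  Used to probe how high-frequency signal
#' content is attenuated by frequency-dependent media.
#'
#' @param duration Trace duration, s.
#' @param sample_rate Sampling rate, Hz.
#' @param center Time of the zero crossing, s.
#' @param width Gaussian width parameter, s (default 0.3 ms).
#' @param amplitude Peak current, A.
#' @return Numeric current trace in amperes.
#' @export
spike_current_template <- function(duration = 0.02, sample_rate = 32000,
                                   center = duration / 2, width = 3e-4,
                                   amplitude = 1e-9) {
  t <- (seq_len(round(duration * sample_rate)) - 1) / sample_rate
  u <- (t - center) / width
  x <- -u * exp(-u^2 / 2)
  amplitude * x / max(abs(x))
}

#' Passive ball-and-stick cell
#'
#' A passive compartmental stand-in for a layer-V pyramidal cell: a
#' spherical soma plus a straight apical dendrite along +z, split into
#' equal cylindrical compartments.  Purely passive membranes (leak +
#' capacitance); no active conductances or spike generation.
#'
#' @param soma_radius Soma radius, m.
#' @param dend_length Dendrite length, m.
#' @param dend_diameter Dendrite diameter, m.
#' @param n_dend Number of dendritic compartments (0 gives a single
#'   isopotential soma).
#' @param r_m Specific membrane resistivity, Ohm m^2.
#' @param c_m Specific membrane capacitance, F/m^2.
#' @param r_a Axial resistivity, Ohm m.
#' @param v_rest Resting (leak reversal) potential, V.
#' @return Object of class `passive_cell`.
#' @export
passive_cell <- function(soma_radius = 10e-6, dend_length = 1000e-6,
                         dend_diameter = 2e-6, n_dend = 10L,
                         r_m = 1.0, c_m = 0.01, r_a = 1.5,
                         v_rest = -70e-3) {
  stopifnot(soma_radius > 0, dend_length > 0, dend_diameter > 0,
            n_dend >= 0L, r_m > 0, c_m > 0, r_a > 0)
  n_dend <- as.integer(n_dend)
  k <- n_dend + 1L
  seg_l <- if (n_dend > 0) dend_length / n_dend else 0
  area <- c(4 * pi * soma_radius^2,
            rep(pi * dend_diameter * seg_l, n_dend))
  ## compartment centres: soma at origin, dendrite along +z
  z <- c(0, if (n_dend > 0)
    soma_radius + (seq_len(n_dend) - 0.5) * seg_l)
  positions <- cbind(x = 0, y = 0, z = z)
  g_ax <- if (n_dend > 0)
    rep(pi * dend_diameter^2 / (4 * r_a * seg_l), n_dend) else numeric()
  structure(list(n_comp = k, area = area, positions = positions,
                 c_m = c_m * area, g_leak = area / r_m, g_ax = g_ax,
                 v_rest = v_rest,
                 soma_radius = soma_radius, dend_length = dend_length,
                 dend_diameter = dend_diameter, r_m = r_m, c_m_spec = c_m,
                 r_a = r_a),
            class = "passive_cell")
}

#' @export
print.passive_cell <- function(x, ...) {
  cat("Passive ball-and-stick cell:", x$n_comp, "compartments,",
      "dendrite", x$dend_length * 1e6, "um, tau_m =",
      x$r_m * x$c_m_spec * 1e3, "ms\n")
  invisible(x)
}

#' Simulate a passive cell and return its membrane current sources
#'
#' Integrates the passive cable equations with an implicit (backward
#' Euler) scheme and returns the per-compartment transmembrane currents
#' (capacitive + leak + synaptic) that act as extracellular current
#' sources.  For intracellular current injection the membrane currents sum
#' to the injected current at every time step (Kirchhoff closure); for a
#' synaptic conductance input they sum to zero, the synaptic current being
#' itself a membrane current.
#'
#' @param cell A [passive_cell()].
#' @param input Either `list(kind = "current", compartment, I = trace)`
#'   with `I` in amperes (recycled or cropped to the step count), or
#'   `list(kind = "synapse", compartment, onset = 0.02, tau = 0.002,
#'   weight, e_rev = 0)` describing an exponentially decaying conductance
#'   (weight in siemens).
#' @param duration Simulated time, s.
#' @param dt Time step, s (default 1/32 ms).
#' @param discard Initial transient discarded from the returned traces, s.
#' @return Object of class `current_source_set`: `positions` (n_comp x 3),
#'   `currents` (samples x n_comp, amperes, outward positive),
#'   `injected` (the input current actually applied, after discard),
#'   `voltages`, `sample_rate`, `time`.
#' @export
simulate_passive_cell <- function(cell, input, duration = 0.3,
                                  dt = 1 / 32 * 1e-3, discard = 0.1) {
  stopifnot(inherits(cell, "passive_cell"), duration > 0, dt > 0,
            discard >= 0, discard < duration)
  k <- cell$n_comp
  n <- round(duration / dt)
  comp <- input$compartment
  if (is.null(comp) || comp < 1L || comp > k)
    stop("input compartment does not exist")
  ## constant part of the system matrix
  g <- diag(cell$g_leak, k)
  if (k > 1L) for (j in seq_len(k - 1L)) {
    ga <- cell$g_ax[j]
    g[j, j] <- g[j, j] + ga; g[j + 1, j + 1] <- g[j + 1, j + 1] + ga
    g[j, j + 1] <- g[j, j + 1] - ga; g[j + 1, j] <- g[j + 1, j] - ga
  }
  cd <- cell$c_m / dt
  t_grid <- seq_len(n) * dt
  i_inj <- matrix(0, n, k)
  g_syn <- matrix(0, n, k)
  if (input$kind == "current") {
    tr <- rep_len(input$I, n)
    i_inj[, comp] <- tr
  } else if (input$kind == "synapse") {
    ## onset counts from the start of the retained recording (i.e. after
    ## the discarded startup transient)
    onset <- discard + if (is.null(input$onset)) 0.02 else input$onset
    tau <- if (is.null(input$tau)) 0.002 else input$tau
    e_rev <- if (is.null(input$e_rev)) 0 else input$e_rev
    g_syn[, comp] <- ifelse(t_grid >= onset,
                            input$weight * exp(-(t_grid - onset) / tau), 0)
  } else stop("unknown input kind: ", input$kind)
  e_rev <- if (!is.null(input$e_rev)) input$e_rev else 0

  v <- rep(cell$v_rest, k)
  volt <- matrix(0, n, k)
  imem <- matrix(0, n, k)
  const_a <- g + diag(cd, k)
  b_leak <- cell$g_leak * cell$v_rest
  any_syn <- any(g_syn != 0)
  if (!any_syn) a_lu <- solve(const_a)  # constant matrix: invert once
  for (s in seq_len(n)) {
    if (any_syn) {
      a <- const_a + diag(g_syn[s, ], k)
      rhs <- cd * v + b_leak + i_inj[s, ] + g_syn[s, ] * e_rev
      v_new <- solve(a, rhs)
    } else {
      rhs <- cd * v + b_leak + i_inj[s, ]
      v_new <- as.numeric(a_lu %*% rhs)
    }
    imem[s, ] <- cd * (v_new - v) + cell$g_leak * (v_new - cell$v_rest) +
      g_syn[s, ] * (v_new - e_rev)
    volt[s, ] <- v_new
    v <- v_new
  }
  keep <- t_grid > discard
  structure(list(positions = cell$positions,
                 currents = imem[keep, , drop = FALSE],
                 injected = rowSums(i_inj)[keep],
                 voltages = volt[keep, , drop = FALSE],
                 sample_rate = 1 / dt,
                 time = t_grid[keep] - discard),
            class = "current_source_set")
}

#' Build a current source set directly from positions and traces
#'
#' Import path for externally computed compartment-current matrices (e.g.
#' from a detailed morphological simulation): positions plus one current
#' trace per source.
#'
#' @param positions n x 3 matrix of source positions, m.
#' @param currents samples x n matrix of currents, A.
#' @param sample_rate Sampling rate, Hz.
#' @return A `current_source_set`.
#' @export
current_source_set <- function(positions, currents, sample_rate) {
  positions <- as_points(positions)
  currents <- as.matrix(currents)
  stopifnot(ncol(currents) == nrow(positions), sample_rate > 0)
  structure(list(positions = positions, currents = currents,
                 injected = NULL, voltages = NULL,
                 sample_rate = sample_rate,
                 time = (seq_len(nrow(currents)) - 1) / sample_rate),
            class = "current_source_set")
}

#' Read/write a compartment-current matrix as CSV
#'
#' Plain-text exchange format: columns `x_um`, `y_um`, `z_um` then one
#' column per time sample (amperes), one row per source.
#'
#' @param sources A `current_source_set`.
#' @param path CSV path.
#' @param sample_rate Sampling rate in Hz (needed when reading).
#' @return `write_current_sources` returns `path` invisibly;
#'   `read_current_sources` a `current_source_set`.
#' @export
write_current_sources <- function(sources, path) {
  df <- data.frame(x_um = sources$positions[, 1] * 1e6,
                   y_um = sources$positions[, 2] * 1e6,
                   z_um = sources$positions[, 3] * 1e6)
  df <- cbind(df, as.data.frame(t(sources$currents)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_current_sources
#' @export
read_current_sources <- function(path, sample_rate) {
  df <- utils::read.csv(path, check.names = FALSE)
  pos <- as.matrix(df[, c("x_um", "y_um", "z_um")]) * 1e-6
  colnames(pos) <- c("x", "y", "z")
  cur <- t(as.matrix(df[, -(1:3), drop = FALSE]))
  dimnames(cur) <- NULL
  current_source_set(pos, cur, sample_rate)
}
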