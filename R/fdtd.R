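#' Ricker source wavelet
#'
#' `(1 - 2 pi^2 fc^2 (t - t0)^2) * exp(-pi^2 fc^2 (t - t0)^2)`: the
#' standard zero-mean GPR excitation, peaking at 1 at `t = t0`.
#'
#' @param t Time(s), s.  Vectorized.
#' @param fc Center frequency, Hz.
#' @param t0 Delay, s; the default `1.5 / fc` makes the waveform start
#'   near zero at `t = 0`.
#' @return Amplitudes in `[-0.5, 1]`.
#' @export
ricker <- function(t, fc = 900e6, t0 = 1.5 / fc) {
  stopifnot(fc > 0)
  u <- (pi * fc * (t - t0))^2
  (1 - 2 * u) * exp(-u)
}

#' 2-D Courant time step
#'
#' Maximum stable FDTD time step on a square 2-D grid,
#' `dt = dx / (c * sqrt(2))`.  At the default survey discretization
#' `dx = 2.5 mm` this evaluates to `5.89664e-12 s`, the sampling interval
#' of the synthetic records.
#'
#' @param dx Grid spacing, m.
#' @return Time step, s.
#' @export
courant_dt <- function(dx) {
  stopifnot(dx > 0)
  dx / (.c0 * sqrt(2))
}

#' GPR scan acquisition geometry
#'
#' The default survey: transmitter positions from 0.025 m in 0.015 m
#' steps while below 1.375 m (90 emissions), receiver trailing 0.14 m
#' behind, both 0.005 m above the soil surface, 20 ns time window.
#'
#' @param tx_start,tx_end,step Transmitter start, end (exclusive) and
#'   increment, m.
#' @param tx_rx_offset Transmitter-receiver spacing, m.
#' @param antenna_height Height above the soil surface, m.
#' @param time_window Recording window per trace, s.
#' @return A list of class `scan_geometry` with a `tx_positions` vector.
#' @export
scan_geometry <- function(tx_start = 0.025, tx_end = 1.375, step = 0.015,
                          tx_rx_offset = 0.14, antenna_height = 0.005,
                          time_window = 20e-9) {
  # emissions strictly before tx_end (the end position is the final
  # arrival, not an emission); guard against floating-point overshoot
  k_max <- floor((tx_end - tx_start) / step - 1e-9)
  tx <- tx_start + step * (0:k_max)
  structure(list(tx_start = tx_start, tx_end = tx_end, step = step,
                 tx_rx_offset = tx_rx_offset,
                 antenna_height = antenna_height,
                 time_window = time_window,
                 tx_positions = tx, n_traces = length(tx)),
            class = "scan_geometry")
}

#' B-scan container
#'
#' @param data Numeric matrix, time sample x trace.
#' @param dt Sampling interval, s.
#' @param trace_positions Transmitter positions, m (one per column).
#' @return A `bscan` (matrix with `dt` and `trace_positions` attributes).
#' @export
bscan <- function(data, dt, trace_positions = seq_len(ncol(data))) {
  stopifnot(is.matrix(data), all(is.finite(data)), dt > 0,
            length(trace_positions) == ncol(data))
  structure(data, dt = dt, trace_positions = trace_positions,
            class = c("bscan", "matrix", "array"))
}

# build full simulation grids (air above soil) and node indices for one
# antenna pair; returns everything fdtd_trace_cpp needs
.fdtd_setup <- function(materials, dx, geometry, air_height = 0.10) {
  n_air <- round(air_height / dx)
  nz <- nrow(materials$eps_real) + n_air
  nx <- ncol(materials$eps_real)
  epsr <- rbind(matrix(1, n_air, nx), materials$eps_real)
  sigma <- rbind(matrix(0, n_air, nx), materials$conductivity)
  iz_ant <- n_air - round(geometry$antenna_height / dx) - 1L
  list(epsr = epsr, sigma = sigma, n_air = n_air, iz_ant = iz_ant, nx = nx)
}

#' Simulate a single GPR A-scan
#'
#' Runs the TM-mode FDTD solver over the material grids (a 0.10 m air
#' layer is stacked above the supplied soil grid, and a 10-cell quartic
#' split-field PML surrounds the whole domain), driving a point source at
#' the transmitter node with the Ricker waveform and recording the Ez
#' field at the receiver node.
#'
#' @param materials List with `eps_real` and `conductivity` matrices
#'   (rows = depth) as produced by [rasterize_scene()].
#' @param dx Grid spacing of `materials`, m.
#' @param tx_x,rx_x Transmitter / receiver x positions, m.
#' @param geometry A [scan_geometry()] (antenna height, time window).
#' @param fc Source center frequency, Hz.
#' @param dt Time step, s; defaults to the 2-D Courant limit at `dx`.
#' @param npml PML thickness in cells (minimum 8).
#' @param air_height Air layer thickness above the soil surface, m.
#' @return Numeric trace of length `ceiling(time_window / dt)`.
#' @export
run_ascan <- function(materials, dx, tx_x, rx_x,
                      geometry = scan_geometry(), fc = 900e6,
                      dt = courant_dt(dx), npml = 10, air_height = 0.10) {
  stopifnot(dt <= courant_dt(dx) + 1e-18, npml >= 8)
  s <- .fdtd_setup(materials, dx, geometry, air_height)
  n_steps <- ceiling(geometry$time_window / dt)
  wave <- ricker(seq_len(n_steps) * dt, fc = fc)
  src_j <- round(tx_x / dx)
  rx_j <- round(rx_x / dx)
  stopifnot(src_j >= 1, rx_j >= 1, src_j < s$nx, rx_j < s$nx)
  fdtd_trace_cpp(s$epsr, s$sigma, dx, dt, n_steps,
                 s$iz_ant, src_j, s$iz_ant, rx_j, wave, npml)
}

#' Simulate a full GPR B-scan over a scene
#'
#' Rasterizes the scene (if given a `gpr_scene`) and runs one A-scan per
#' transmitter position of the geometry, stacking the traces into a
#' B-scan.  Deterministic given the scene.
#'
#' @param scene A `gpr_scene`, or a rasterized material list from
#'   [rasterize_scene()].
#' @param geometry A [scan_geometry()].
#' @param dx Grid spacing, m (taken from the scene config when a scene is
#'   supplied).
#' @param fc Source center frequency, Hz.
#' @param npml PML cells.
#' @param frequency Material evaluation frequency for rasterization, Hz.
#' @param progress Print a progress line per trace.
#' @return A [bscan()], one column per emission.
#' @export
run_bscan <- function(scene, geometry = scan_geometry(), dx = NULL,
                      fc = 900e6, npml = 10, frequency = 0.9e9,
                      progress = FALSE) {
  if (inherits(scene, "gpr_scene")) {
    dx <- scene$config$dx
    materials <- rasterize_scene(scene, frequency)
  } else {
    stopifnot(!is.null(dx))
    materials <- scene
  }
  dt <- courant_dt(dx)
  n_steps <- ceiling(geometry$time_window / dt)
  out <- matrix(0, n_steps, geometry$n_traces)
  for (k in seq_len(geometry$n_traces)) {
    tx <- geometry$tx_positions[k]
    out[, k] <- run_ascan(materials, dx, tx, tx + geometry$tx_rx_offset,
                          geometry, fc = fc, dt = dt, npml = npml)
    if (progress) message(sprintf("trace %d / %d", k, geometry$n_traces))
  }
  bscan(out, dt, geometry$tx_positions)
}

#' Track total field energy in a closed test domain
#'
#' Diagnostic used to verify numerical stability: with `npml = 0` the
#' outer boundary is a perfect electric conductor and, in a lossless
#' medium, the discrete field energy must not grow after the source has
#' switched off.
#'
#' @param epsr,sigma Material matrices.
#' @param dx Grid spacing, m.
#' @param n_steps Total steps.
#' @param source_steps Steps during which the Ricker source is active.
#' @param fc Source center frequency, Hz.
#' @param npml PML cells (0 for a closed PEC box).
#' @param record_every Energy sampling stride in steps.
#' @return Numeric vector of sampled energies.
#' @export
field_energy_history <- function(epsr, sigma, dx, n_steps,
                                 source_steps, fc = 900e6, npml = 0,
                                 record_every = 100) {
  dt <- courant_dt(dx)
  wave <- ricker(seq_len(source_steps) * dt, fc = fc)
  fdtd_energy_cpp(epsr, sigma, dx, dt, n_steps,
                  nrow(epsr) %/% 2, ncol(epsr) %/% 2, wave, npml,
                  record_every)
}

#' First-arrival travel time of a trace
#'
#' Picks the first time sample whose absolute amplitude exceeds
#' `threshold` times the trace maximum.
#'
#' @param trace Numeric vector.
#' @param dt Sampling interval, s.
#' @param threshold Fraction of the peak amplitude.
#' @return Arrival time, s (NA when nothing exceeds the threshold).
#' @export
first_arrival <- function(trace, dt, threshold = 0.1) {
  a <- abs(trace)
  idx <- which(a >= threshold * max(a))
  if (!length(idx)) return(NA_real_)
  idx[1] * dt
}
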