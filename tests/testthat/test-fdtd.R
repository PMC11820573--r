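test_that("Ricker wavelet has unit peak, symmetry and zero mean", {
  fc <- 900e6
  t0 <- 1.5 / fc
  expect_equal(ricker(t0, fc), 1)
  tau <- seq(0, 1e-9, length.out = 11)
  expect_equal(ricker(t0 + tau, fc), ricker(t0 - tau, fc))
  expect_lt(abs(ricker(0, fc)), 1e-3)
  # discrete integral over a window much longer than 1/fc
  tt <- seq(0, 40 / fc, by = 1 / (200 * fc))
  expect_lt(abs(sum(ricker(tt, fc)) * (tt[2] - tt[1])), 1e-6 / fc)
})

test_that("Courant step reproduces the survey sampling interval and scales linearly", {
  expect_equal(courant_dt(0.0025), 5.89664e-12, tolerance = 1e-6)
  expect_equal(courant_dt(0.005), 2 * courant_dt(0.0025))
  expect_equal(courant_dt(0.005), 1.179328e-11, tolerance = 1e-6)
})

test_that("default scan geometry yields 90 traces with the fixed offset", {
  g <- scan_geometry()
  expect_identical(g$n_traces, 90L)
  expect_equal(g$tx_positions[1], 0.025)
  expect_equal(diff(g$tx_positions)[1], 0.015)
  expect_lt(max(g$tx_positions), 1.375)
  expect_equal(g$tx_rx_offset, 0.14)
})

# shared reduced test grids
dx_t <- 0.005
nz_t <- round(0.6 / dx_t); nx_t <- round(0.8 / dx_t)
sig0 <- matrix(0, nz_t, nx_t)
geom_t <- scan_geometry()

test_that("PML absorbs: vacuum trace has almost no post-direct-wave energy", {
  mat <- list(eps_real = matrix(1, nz_t, nx_t), conductivity = sig0)
  tr <- run_ascan(mat, dx_t, 0.33, 0.47, geom_t)
  dt <- courant_dt(dx_t)
  tt <- seq_along(tr) * dt
  cut <- which(tt > 0.14 / 3e8 + 1.5 / 900e6 + 3 / 900e6)[1]
  e_direct <- sum(tr[1:cut]^2)
  e_post <- sum(tr[(cut + 1):length(tr)]^2)
  expect_lt(e_post / e_direct, 0.01)
})

test_that("a strongly conducting ground returns almost no reflection", {
  eps <- matrix(4, nz_t, nx_t)
  lossy <- matrix(5, nz_t, nx_t)       # 5 S/m soil: skin depth ~ cm
  tr_ref <- run_ascan(list(eps_real = eps, conductivity = sig0),
                      dx_t, 0.33, 0.47, geom_t)
  tr_lossy <- run_ascan(list(eps_real = eps, conductivity = lossy),
                        dx_t, 0.33, 0.47, geom_t)
  dt <- courant_dt(dx_t)
  late <- seq_along(tr_ref) * dt > 4e-9
  expect_lt(sum(tr_lossy[late]^2), 1e-4 * sum(tr_ref[late]^2))
})

test_that("planar-reflector arrivals match the ray oracle within 5%", {
  dt <- courant_dt(dx_t)
  for (eps_r in c(2, 4, 9, 16)) {
    eps <- matrix(eps_r, nz_t, nx_t)
    eps[(round(0.30 / dx_t) + 1):nz_t, ] <- eps_r * 2.5
    tr1 <- run_ascan(list(eps_real = eps, conductivity = sig0),
                     dx_t, 0.33, 0.47, geom_t)
    tr0 <- run_ascan(list(eps_real = matrix(eps_r, nz_t, nx_t),
                          conductivity = sig0),
                     dx_t, 0.33, 0.47, geom_t)
    t_peak <- which.max(abs(tr1 - tr0)) * dt
    t_ray <- oracle_ray_time(0.30, 0.07, eps_r)
    expect_lt(abs(t_peak - t_ray) / t_ray, 0.05)
  }
})

test_that("field energy does not grow in a closed lossless box after switch-off", {
  eps <- matrix(1, 80, 80)
  sig <- matrix(0, 80, 80)
  e <- field_energy_history(eps, sig, 0.005, n_steps = 10000,
                            source_steps = 300, npml = 0,
                            record_every = 100)
  # the staggered-time energy oscillates within a step, so compare the
  # envelope: its maximum over the late half must not exceed the early
  # maximum beyond 1e-6 relative growth per 1000 steps
  early <- e[5:50]; late <- e[51:100]
  expect_lt(max(late) / max(early), 1 + 1e-6 * 5000 / 1000)
})

test_that("picked arrivals are grid-converged", {
  pick <- function(dx) {
    nz <- round(0.6 / dx); nx <- round(0.8 / dx)
    eps <- matrix(4, nz, nx)
    eps[(round(0.30 / dx) + 1):nz, ] <- 12
    t1 <- run_ascan(list(eps_real = eps,
                         conductivity = matrix(0, nz, nx)),
                    dx, 0.33, 0.47, geom_t)
    t0 <- run_ascan(list(eps_real = matrix(4, nz, nx),
                         conductivity = matrix(0, nz, nx)),
                    dx, 0.33, 0.47, geom_t)
    which.max(abs(t1 - t0)) * courant_dt(dx)
  }
  expect_lt(abs(pick(0.01) - pick(0.005)) / pick(0.005), 0.02)
})

test_that("laterally homogeneous scenes give laterally invariant B-scans", {
  nz <- 50; nx <- 120
  mat <- list(eps_real = matrix(4, nz, nx),
              conductivity = matrix(0.001, nz, nx))
  # traces kept well away from the side walls
  geo <- scan_geometry(tx_start = 0.45, tx_end = 0.58, step = 0.03,
                       tx_rx_offset = 0.08, time_window = 8e-9)
  bs <- run_bscan(mat, geo, dx = 0.01, npml = 16)
  expect_identical(ncol(bs), geo$n_traces)
  # residual trace-to-trace differences stem only from the finite PML
  spread <- max(apply(bs, 1, function(r) diff(range(r))))
  expect_lt(spread, 1e-4 * max(abs(bs)))
})

test_that("a centered scatterer puts the hyperbola apex at the central trace", {
  rcfg <- reduced_sim_config()
  sc <- sample_scene("single", rcfg$config, seed = 30)
  sc$scatterers[[1]] <- list(shape = "circle", size = c(radius = 0.06),
                             rotation = 0,
                             center = c(x = 0.30, z = 0.24),
                             relative_permittivity = 25,
                             conductivity = 0.001)
  ras <- rasterize_scene(sc)
  # geometry centered so that the midpoint sweep crosses x = 0.30
  geo <- scan_geometry(tx_start = 0.11, tx_end = 0.42, step = 0.03,
                       tx_rx_offset = 0.08,
                       time_window = rcfg$geometry$time_window)
  bs <- run_bscan(ras, geo, dx = rcfg$config$dx)
  # soil-only reference isolates the scatterer response
  sc0 <- sc; sc0$scatterers <- list()
  bs0 <- run_bscan(rasterize_scene(sc0), geo, dx = rcfg$config$dx)
  diffscan <- abs(bs - bs0)
  arrivals <- apply(diffscan, 2, function(tr)
    which(tr > 0.2 * max(diffscan))[1])
  apex <- which.min(arrivals)
  midpoints <- geo$tx_positions + geo$tx_rx_offset / 2
  expect_lt(abs(midpoints[apex] - 0.30), 0.05)
})

test_that("unstable configurations abort with a step-numbered error", {
  eps <- matrix(1, 60, 60)
  sig <- matrix(0, 60, 60)
  wave <- ricker(seq_len(400) * 1.2 * courant_dt(0.005))
  expect_error(
    rootgpr:::fdtd_trace_cpp(eps, sig, 0.005, 1.2 * courant_dt(0.005),
                             2500, 10, 30, 10, 40, wave, 10),
    "instability.*step")
  expect_error(run_ascan(list(eps_real = eps, conductivity = sig),
                         0.005, 0.15, 0.2, dt = 1.2 * courant_dt(0.005)))
})
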