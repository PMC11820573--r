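#' Simulate a paired (B-scan, labels) dataset
#'
#' The full data-manufacturing chain: sample a scene, rasterize it, run
#' the FDTD B-scan simulation, preprocess, and build the training labels.
#' `modes` are cycled over the samples (the reference recipe is half
#' single-scatterer scenes and a quarter each of separated / overlapping
#' two-scatterer scenes).
#'
#' At the survey's full resolution one sample costs minutes of FDTD time;
#' for tests and demonstrations use a reduced configuration (smaller
#' domain, coarser `dx`, fewer traces, smaller `size`), e.g.
#' [reduced_sim_config()].
#'
#' @param n Number of samples.
#' @param config A [scene_config()].
#' @param geometry A [scan_geometry()].
#' @param modes Character vector of scene modes to cycle through.
#' @param size Network input / label size.
#' @param seed Integer seed; sample `i` uses scene seed `seed + i`.
#' @param npml PML thickness (cells).
#' @param progress Print one line per sample.
#' @return List of `processed_sample`s.
#' @export
simulate_dataset <- function(n, config = scene_config(),
                             geometry = scan_geometry(),
                             modes = c("single", "single", "two_separate",
                                       "two_overlap"),
                             size = 128, seed = 1L, npml = 10,
                             progress = FALSE) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    mode <- modes[(i - 1) %% length(modes) + 1]
    sc <- sample_scene(mode, config, seed = seed + i)
    ras <- rasterize_scene(sc)
    bs <- run_bscan(ras, geometry, dx = config$dx, npml = npml)
    out[[i]] <- process_sample(bs, ras$map, size = size,
                               meta = list(seed = seed + i, mode = mode))
    if (progress) message(sprintf("sample %d / %d (%s)", i, n, mode))
  }
  out
}

#' Reduced-scale simulation configuration
#'
#' A desk-scale variant of the survey used for tests and examples: a
#' 0.60 x 0.50 m domain at 10 mm resolution with a short 16-trace scan
#' and a 12 ns window.  Keeps every pipeline stage identical while
#' cutting FDTD cost by orders of magnitude.
#'
#' @param size Network input size to pair with (32 recommended).
#' @return List with `config` (a [scene_config()]), `geometry` (a
#'   [scan_geometry()]) and `size`.
#' @export
reduced_sim_config <- function(size = 32) {
  cfg <- scene_config(domain_width = 0.60, domain_depth = 0.50,
                      dx = 0.01, layer_depths = c(0.18, 0.36),
                      layer_jitter = 0.02, correlation_length = 0.05,
                      radius_range = c(0.05, 0.08),
                      rect_length_range = c(0.10, 0.14),
                      rect_width_range = c(0.04, 0.06),
                      depth_range = c(0.20, 0.28))
  geom <- scan_geometry(tx_start = 0.05, tx_end = 0.53, step = 0.03,
                        tx_rx_offset = 0.08, antenna_height = 0.005,
                        time_window = 12e-9)
  list(config = cfg, geometry = geom, size = size)
}

#' Save / load a dataset
#'
#' Plain RDS persistence for sample lists, storing the normalization
#' constants and sampling interval with each sample's metadata.
#'
#' @param dataset List of `processed_sample`s.
#' @param path File path.
#' @return `load_dataset()` returns the sample list.
#' @export
save_dataset <- function(dataset, path) {
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) readRDS(path)
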