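#' Scene generation configuration
#'
#' Defaults describe the simulated survey: a 1.54 m wide, 0.6 m deep soil
#' domain at 2.5 mm resolution, three soil layers with nominal boundaries
#' at 0.20 m and 0.40 m (jittered per scene by up to +/- 0.03 m), five
#' composition variants per layer arranged in smooth patches with a 0.05 m
#' correlation length, and one or two root-like scatterers buried with
#' center depths between 0.20 m and 0.30 m.
#'
#' @param domain_width,domain_depth Domain size in m.
#' @param dx Grid spacing in m (cell-centered, x rightward, z downward).
#' @param layer_depths Nominal depths of the two layer boundaries, m.
#' @param layer_jitter Uniform per-scene jitter applied to each boundary, m.
#' @param correlation_length Patch size parameter of the intra-layer
#'   heterogeneity field, m.
#' @param n_variants Composition variants per layer.
#' @param scatterer_conductivity Conductivity assigned to scatterers, S/m.
#' @param radius_range Circle/semicircle/triangle circumradius range, m.
#' @param rect_length_range,rect_width_range Rectangle side ranges, m.
#' @param depth_range Scatterer center-depth range, m.
#' @param eps_range Scatterer relative-permittivity range.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(domain_width = 1.54, domain_depth = 0.6,
                         dx = 0.0025, layer_depths = c(0.20, 0.40),
                         layer_jitter = 0.03, correlation_length = 0.05,
                         n_variants = 5, scatterer_conductivity = 0.001,
                         radius_range = c(0.05, 0.10),
                         rect_length_range = c(0.10, 0.15),
                         rect_width_range = c(0.04, 0.06),
                         depth_range = c(0.20, 0.30),
                         eps_range = c(2, 32)) {
  stopifnot(domain_width > 0, domain_depth > 0, dx > 0,
            length(layer_depths) == 2, diff(layer_depths) > 0,
            layer_depths[2] + layer_jitter < domain_depth)
  structure(list(domain_width = domain_width, domain_depth = domain_depth,
                 dx = dx, layer_depths = layer_depths,
                 layer_jitter = layer_jitter,
                 correlation_length = correlation_length,
                 n_variants = n_variants,
                 scatterer_conductivity = scatterer_conductivity,
                 radius_range = radius_range,
                 rect_length_range = rect_length_range,
                 rect_width_range = rect_width_range,
                 depth_range = depth_range, eps_range = eps_range),
            class = "scene_config")
}

# moisture ranges (volume fraction) and temperatures (deg C) of the three
# soil layers, shallow to deep
.layer_conditions <- list(
  list(moisture_range = c(0.05, 0.10), temperature = 20),
  list(moisture_range = c(0.10, 0.13), temperature = 17),
  list(moisture_range = c(0.13, 0.15), temperature = 15))

#' Smoothed random variant-index field for intra-layer heterogeneity
#'
#' Draws a white-noise grid, low-pass filters it with a Gaussian kernel
#' whose standard deviation is `correlation_length`, and thresholds the
#' result at its quantiles into `n_variants` equal-probability levels.
#' The output is a grid of contiguous patches, each patch selecting one of
#' the per-layer composition variants; patch size grows with
#' `correlation_length`.
#'
#' @param nz,nx Grid dimensions (rows = depth).
#' @param dx Grid spacing, m.
#' @param correlation_length Gaussian smoothing length, m.
#' @param n_variants Number of index levels.
#' @param seed Optional seed.
#' @return Integer matrix (`nz` x `nx`) with values in `1:n_variants`.
#' @export
build_intralayer_field <- function(nz, nx, dx, correlation_length = 0.05,
                                   n_variants = 5, seed = NULL) {
  stopifnot(nz >= 1, nx >= 1, n_variants >= 1)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  z <- matrix(rnorm(nz * nx), nz, nx)
  s <- correlation_length / dx
  if (s > 0) {
    # periodic Gaussian smoothing via FFT
    gz <- .gauss_kernel_1d(nz, s)
    gx <- .gauss_kernel_1d(nx, s)
    K <- outer(gz, gx)
    z <- Re(fft(fft(z) * fft(K), inverse = TRUE)) / (nz * nx)
  }
  if (n_variants == 1) return(matrix(1L, nz, nx))
  q <- quantile(z, probs = seq_len(n_variants - 1) / n_variants)
  matrix(findInterval(z, q) + 1L, nz, nx)
}

.gauss_kernel_1d <- function(n, s) {
  d <- pmin(0:(n - 1), n - (0:(n - 1)))
  k <- exp(-0.5 * (d / s)^2)
  k / sum(k)
}

#' Sample a randomized layered-soil scene with buried scatterers
#'
#' Builds a three-layer heterogeneous soil scene: each layer gets a random
#' ISSS texture class, five random composition variants inside that class,
#' a moisture drawn from the layer's range and the layer's temperature;
#' layer boundaries are jittered around their nominal depths; one or two
#' scatterers (circle, semicircle, rectangle or triangle, random size,
#' rotation and relative permittivity in 2-32) are placed with center
#' depths in 0.20-0.30 m.  `mode` controls the scatterer count and, for
#' two scatterers, whether their rasterized footprints must intersect
#' (`"two_overlap"`) or be disjoint (`"two_separate"`).
#'
#' @param mode `"single"`, `"two_separate"` or `"two_overlap"`.
#' @param config A [scene_config()].
#' @param seed Optional seed; scenes are fully determined by
#'   `(mode, config, seed)`.
#' @param max_tries Retry budget for the geometric constraint.
#' @return An object of class `gpr_scene`.
#' @export
sample_scene <- function(mode = c("single", "two_separate", "two_overlap"),
                         config = scene_config(), seed = NULL,
                         max_tries = 200) {
  mode <- match.arg(mode)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  layers <- lapply(1:3, function(i) {
    cond <- .layer_conditions[[i]]
    cls <- sample(isss_classes(), 1)
    list(index = i,
         moisture_range = cond$moisture_range,
         moisture = runif(1, cond$moisture_range[1], cond$moisture_range[2]),
         temperature = cond$temperature,
         texture_class = cls,
         variants = sample_compositions(cls, config$n_variants))
  })
  boundaries <- config$layer_depths +
    runif(2, -config$layer_jitter, config$layer_jitter)

  nz <- round(config$domain_depth / config$dx)
  nx <- round(config$domain_width / config$dx)
  field <- build_intralayer_field(nz, nx, config$dx,
                                  config$correlation_length,
                                  config$n_variants)

  n_sc <- if (mode == "single") 1L else 2L
  for (try in seq_len(max_tries)) {
    scatterers <- lapply(seq_len(n_sc), function(k) .sample_scatterer(config))
    if (n_sc == 1L) break
    m1 <- scatterer_mask(scatterers[[1]], nz, nx, config$dx)
    m2 <- scatterer_mask(scatterers[[2]], nz, nx, config$dx)
    shared <- any(m1 & m2)
    if ((mode == "two_overlap") == shared) break
    if (try == max_tries)
      stop("generation failure: could not satisfy scatterer constraint",
           call. = FALSE)
  }
  structure(list(config = config, mode = mode, layers = layers,
                 layer_boundaries = boundaries, scatterers = scatterers,
                 intralayer_field = field, seed = seed),
            class = "gpr_scene")
}

.sample_scatterer <- function(config) {
  shape <- sample(c("circle", "semicircle", "rectangle", "triangle"), 1)
  rot <- runif(1, 0, 360)
  if (shape == "rectangle") {
    len <- runif(1, config$rect_length_range[1], config$rect_length_range[2])
    wid <- runif(1, config$rect_width_range[1], config$rect_width_range[2])
    margin <- sqrt(len^2 + wid^2) / 2
    size <- c(length = len, width = wid)
  } else {
    r <- runif(1, config$radius_range[1], config$radius_range[2])
    margin <- r
    size <- c(radius = r)
  }
  cx <- runif(1, margin, config$domain_width - margin)
  cz <- runif(1, config$depth_range[1], config$depth_range[2])
  list(shape = shape, size = size, rotation = rot,
       center = c(x = cx, z = cz),
       relative_permittivity = runif(1, config$eps_range[1],
                                     config$eps_range[2]),
       conductivity = config$scatterer_conductivity)
}

#' Rasterized footprint of a scatterer
#'
#' Logical mask over the cell-centered grid (`TRUE` inside the shape).
#' Cell `(i, j)` (1-based) has center `((j - 0.5) * dx, (i - 0.5) * dx)`.
#'
#' @param sc A scatterer list as produced by [sample_scene()].
#' @param nz,nx Grid dimensions.
#' @param dx Grid spacing, m.
#' @return Logical `nz` x `nx` matrix.
#' @export
scatterer_mask <- function(sc, nz, nx, dx) {
  xs <- (seq_len(nx) - 0.5) * dx
  zs <- (seq_len(nz) - 0.5) * dx
  X <- matrix(xs, nz, nx, byrow = TRUE) - sc$center[["x"]]
  Z <- matrix(zs, nz, nx) - sc$center[["z"]]
  th <- sc$rotation * pi / 180
  U <-  cos(th) * X + sin(th) * Z   # rotated frame
  V <- -sin(th) * X + cos(th) * Z
  switch(sc$shape,
    circle = {
      r <- sc$size[["radius"]]
      X^2 + Z^2 <= r^2
    },
    semicircle = {
      r <- sc$size[["radius"]]
      (X^2 + Z^2 <= r^2) & (V >= 0)
    },
    rectangle = {
      (abs(U) <= sc$size[["length"]] / 2) &
        (abs(V) <= sc$size[["width"]] / 2)
    },
    triangle = {
      r <- sc$size[["radius"]]
      ang <- th + c(90, 210, 330) * pi / 180
      px <- r * cos(ang); pz <- r * sin(ang)
      inside <- rep(TRUE, length(X))
      for (k in 1:3) {
        k2 <- k %% 3 + 1
        ex <- px[k2] - px[k]; ez <- pz[k2] - pz[k]
        cross <- ex * (Z - pz[k]) - ez * (X - px[k])
        inside <- inside & (cross <= 0)
      }
      matrix(inside, nz, nx)
    },
    stop("unknown shape: ", sc$shape))
}

#' Rasterize a scene to material grids and a permittivity map
#'
#' Each soil cell takes the Peplinski dielectric properties of its layer's
#' composition variant at the scene's frequency; cells inside a scatterer
#' footprint take the scatterer's permittivity and conductivity (the later
#' scatterer wins where footprints overlap).  The permittivity map is the
#' real-permittivity channel of the material grid.
#'
#' @param scene A [sample_scene()] result.
#' @param frequency Hz (default 0.9 GHz, the survey center frequency).
#' @return List with `eps_real` and `conductivity` matrices (`nz` x `nx`,
#'   rows = depth) and `map`, a `permittivity_map`.
#' @export
rasterize_scene <- function(scene, frequency = 0.9e9) {
  cfg <- scene$config
  nz <- nrow(scene$intralayer_field)
  nx <- ncol(scene$intralayer_field)
  eps <- matrix(NA_real_, nz, nx)
  sig <- matrix(NA_real_, nz, nx)
  zc <- (seq_len(nz) - 0.5) * cfg$dx
  layer_of_row <- findInterval(zc, scene$layer_boundaries) + 1L
  for (l in 1:3) {
    rows <- which(layer_of_row == l)
    if (!length(rows)) next
    lay <- scene$layers[[l]]
    mats <- lapply(seq_len(cfg$n_variants), function(v) {
      st <- soil_state(lay$variants[v, ], lay$moisture, lay$temperature)
      peplinski(st, frequency)
    })
    sub <- scene$intralayer_field[rows, , drop = FALSE]
    e <- vapply(mats, `[[`, numeric(1), "eps_real")
    s <- vapply(mats, `[[`, numeric(1), "conductivity")
    eps[rows, ] <- e[sub]
    sig[rows, ] <- s[sub]
  }
  for (sc in scene$scatterers) {
    m <- scatterer_mask(sc, nz, nx, cfg$dx)
    eps[m] <- sc$relative_permittivity
    sig[m] <- sc$conductivity
  }
  list(eps_real = eps, conductivity = sig,
       map = permittivity_map(eps, cfg$dx))
}

#' Permittivity map container
#'
#' A real-permittivity grid (rows = depth, cell-centered, origin at the
#' top-left soil surface) with its grid spacing.
#'
#' @param grid Numeric matrix of relative permittivities (all `>= 1`).
#' @param dx Grid spacing, m.
#' @return A `permittivity_map` (matrix with `dx` attribute).
#' @export
permittivity_map <- function(grid, dx) {
  stopifnot(is.matrix(grid), all(grid >= 1), dx > 0)
  structure(grid, dx = dx, class = c("permittivity_map", "matrix", "array"))
}

#' Serialize / restore a scene as JSON
#'
#' Lossless round-trip of a `gpr_scene` (including the heterogeneity
#' field) through JSON.
#'
#' @param scene A `gpr_scene`.
#' @param path File path.
#' @return `read_scene_json()` returns the restored `gpr_scene`.
#' @export
write_scene_json <- function(scene, path) {
  stopifnot(inherits(scene, "gpr_scene"))
  writeLines(jsonlite::serializeJSON(scene, digits = NA), path)
  invisible(path)
}

#' @rdname write_scene_json
#' @export
read_scene_json <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}

#' Export a scene as a gprMax input file
#'
#' Writes a gprMax `.in` file reproducing the scene geometry: domain,
#' discretization, time window, Ricker excitation, per-layer soil
#' materials (variant 1 of each layer) and the scatterers as native
#' gprMax geometry objects.  Intended as an external cross-validation
#' path; the intra-layer heterogeneity field is not exported.
#'
#' @param scene A `gpr_scene`.
#' @param path Output file path.
#' @param geometry A [scan_geometry()]; used for the source waveform and
#'   time window.
#' @param frequency Hz, for material evaluation.
#' @return The path, invisibly.
#' @export
write_gprmax <- function(scene, path, geometry = scan_geometry(),
                         frequency = 0.9e9) {
  cfg <- scene$config
  air <- 0.10
  lines <- c(
    sprintf("#title: rootgpr scene export (seed %s)",
            ifelse(is.null(scene$seed), "NA", scene$seed)),
    sprintf("#domain: %.4f %.4f %.4f", cfg$domain_width,
            cfg$domain_depth + air, cfg$dx),
    sprintf("#dx_dy_dz: %.4f %.4f %.4f", cfg$dx, cfg$dx, cfg$dx),
    sprintf("#time_window: %.3e", geometry$time_window),
    "#waveform: ricker 1 900e6 src_pulse",
    sprintf("#hertzian_dipole: z 0.025 %.4f 0 src_pulse", air - 0.005),
    sprintf("#rx: 0.165 %.4f 0", air - 0.005))
  # y axis points up in gprMax; soil surface at y = air offset from top
  depth_to_y <- function(z) cfg$domain_depth - z
  for (l in 1:3) {
    lay <- scene$layers[[l]]
    d <- peplinski(soil_state(lay$variants[1, ], lay$moisture,
                              lay$temperature), frequency)
    lines <- c(lines, sprintf("#material: %.6f %.6f 1 0 soil_l%d",
                              d$eps_real, d$conductivity, l))
  }
  bounds <- c(0, scene$layer_boundaries, cfg$domain_depth)
  for (l in 1:3) {
    lines <- c(lines, sprintf(
      "#box: 0 %.4f 0 %.4f %.4f %.4f soil_l%d",
      depth_to_y(bounds[l + 1]), cfg$domain_width,
      depth_to_y(bounds[l]), cfg$dx, l))
  }
  for (k in seq_along(scene$scatterers)) {
    sc <- scene$scatterers[[k]]
    lines <- c(lines, sprintf("#material: %.6f %.6f 1 0 scatterer_%d",
                              sc$relative_permittivity, sc$conductivity, k))
    cx <- sc$center[["x"]]; cy <- depth_to_y(sc$center[["z"]])
    lines <- c(lines, switch(sc$shape,
      circle = sprintf("#cylinder: %.4f %.4f 0 %.4f %.4f %.4f %.4f scatterer_%d",
                       cx, cy, cx, cy, cfg$dx, sc$size[["radius"]], k),
      semicircle = sprintf(
        "#cylindrical_sector: z %.4f %.4f 0 %.4f %.4f %.1f 180 scatterer_%d",
        cx, cy, cfg$dx, sc$size[["radius"]], sc$rotation, k),
      rectangle = sprintf(
        "#box: %.4f %.4f 0 %.4f %.4f %.4f scatterer_%d",
        cx - sc$size[["length"]] / 2, cy - sc$size[["width"]] / 2,
        cx + sc$size[["length"]] / 2, cy + sc$size[["width"]] / 2,
        cfg$dx, k),
      triangle = {
        th <- sc$rotation * pi / 180
        ang <- th + c(90, 210, 330) * pi / 180
        px <- cx + sc$size[["radius"]] * cos(ang)
        py <- cy - sc$size[["radius"]] * sin(ang)
        sprintf(paste("#triangle: %.4f %.4f 0 %.4f %.4f 0 %.4f %.4f 0",
                      "%.4f scatterer_%d"),
                px[1], py[1], px[2], py[2], px[3], py[3], cfg$dx, k)
      }))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gpr_scene <- function(x, ...) {
  cat(sprintf("GPR scene (%s): %.2f x %.2f m @ dx = %.4g m\n", x$mode,
              x$config$domain_width, x$config$domain_depth, x$config$dx))
  cat(sprintf("  layer boundaries: %.3f, %.3f m\n",
              x$layer_boundaries[1], x$layer_boundaries[2]))
  for (l in x$layers)
    cat(sprintf("  layer %d: %s, moisture %.3f, %g degC\n", l$index,
                l$texture_class, l$moisture, l$temperature))
  for (s in x$scatterers)
    cat(sprintf("  scatterer: %s at (%.2f, %.2f) m, eps_r = %.2f\n",
                s$shape, s$center[["x"]], s$center[["z"]],
                s$relative_permittivity))
  invisible(x)
}
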