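rc <- reduced_sim_config()

test_that("sampled scenes respect their mode and geometric invariants", {
  sc <- sample_scene("single", rc$config, seed = 7)
  expect_length(sc$scatterers, 1)
  d <- sc$scatterers[[1]]$center[["z"]]
  expect_true(d >= rc$config$depth_range[1] && d <= rc$config$depth_range[2])
  expect_true(all(diff(sc$layer_boundaries) > 0))
  expect_true(sc$layer_boundaries[2] < rc$config$domain_depth)
  eps <- sc$scatterers[[1]]$relative_permittivity
  expect_true(eps >= 2 && eps <= 32)

  nz <- nrow(sc$intralayer_field); nx <- ncol(sc$intralayer_field)
  ov <- sample_scene("two_overlap", rc$config, seed = 3)
  m1 <- scatterer_mask(ov$scatterers[[1]], nz, nx, rc$config$dx)
  m2 <- scatterer_mask(ov$scatterers[[2]], nz, nx, rc$config$dx)
  expect_true(any(m1 & m2))
  sp <- sample_scene("two_separate", rc$config, seed = 4)
  s1 <- scatterer_mask(sp$scatterers[[1]], nz, nx, rc$config$dx)
  s2 <- scatterer_mask(sp$scatterers[[2]], nz, nx, rc$config$dx)
  expect_false(any(s1 & s2))
  # seeded determinism
  expect_identical(sample_scene("single", rc$config, seed = 7), sc)
})

test_that("scatterer shapes are drawn near-uniformly", {
  shapes <- vapply(1:400, function(i)
    sample_scene("single", rc$config, seed = 1000 + i)$scatterers[[1]]$shape,
    character(1))
  counts <- table(factor(shapes, levels = c("circle", "semicircle",
                                            "rectangle", "triangle")))
  expect_length(counts, 4)
  # each within a generous binomial band around 100 (p = 1/4, n = 400)
  expect_true(all(counts > 60 & counts < 140))
})

test_that("intra-layer field is contiguous, complete and scales with correlation length", {
  f <- build_intralayer_field(60, 80, 0.01, 0.05, 5, seed = 2)
  expect_setequal(sort(unique(as.vector(f))), 1:5)
  expect_identical(f, build_intralayer_field(60, 80, 0.01, 0.05, 5,
                                             seed = 2))
  # degenerate: one variant -> constant field
  expect_true(all(build_intralayer_field(20, 20, 0.01, 0.05, 1) == 1L))
  # patch size grows with correlation length: compare the number of
  # horizontal runs (fewer, longer runs when smoother)
  runs <- function(m) sum(apply(m, 1, function(r) 1 + sum(diff(r) != 0)))
  withr::with_seed(5, {
    rough <- replicate(5, runs(build_intralayer_field(60, 80, 0.01, 0.02)))
    smooth <- replicate(5, runs(build_intralayer_field(60, 80, 0.01, 0.08)))
  })
  expect_gt(mean(rough), 1.5 * mean(smooth))
})

test_that("rasterization assigns scatterer and layered soil materials", {
  sc <- sample_scene("single", rc$config, seed = 12)
  ras <- rasterize_scene(sc)
  expect_true(all(ras$eps_real >= 1))
  expect_true(all(ras$conductivity >= 0))
  expect_s3_class(ras$map, "permittivity_map")
  # scatterer cells carry the scatterer permittivity
  m <- scatterer_mask(sc$scatterers[[1]], nrow(ras$eps_real),
                      ncol(ras$eps_real), rc$config$dx)
  expect_true(all(ras$eps_real[m] ==
                    sc$scatterers[[1]]$relative_permittivity))
  # idempotent
  expect_identical(ras$eps_real, rasterize_scene(sc)$eps_real)
})

test_that("rasterized circle area matches the analytic footprint", {
  sc <- sample_scene("single", rc$config, seed = 12)
  sc$scatterers[[1]] <- list(shape = "circle", size = c(radius = 0.05),
                             rotation = 0, center = c(x = 0.3, z = 0.25),
                             relative_permittivity = 20,
                             conductivity = 0.001)
  m <- scatterer_mask(sc$scatterers[[1]], 240, 240, 0.0025)
  expect_equal(sum(m) * 0.0025^2, pi * 0.05^2, tolerance = 0.05)
})

test_that("rotation is 360-degree periodic for every shape", {
  for (shape in c("circle", "semicircle", "rectangle", "triangle")) {
    sc0 <- list(shape = shape,
                size = if (shape == "rectangle")
                  c(length = 0.12, width = 0.05) else c(radius = 0.06),
                rotation = 25, center = c(x = 0.3, z = 0.25),
                relative_permittivity = 10, conductivity = 0.001)
    sc1 <- sc0; sc1$rotation <- 25 + 360
    expect_identical(scatterer_mask(sc0, 60, 60, 0.01),
                     scatterer_mask(sc1, 60, 60, 0.01))
  }
})

test_that("layer-wise mean permittivity tracks the ordered moisture profile", {
  # with a common texture across layers, the ordered moisture ranges must
  # drive the depth ordering of mean permittivity; with independently
  # random per-layer textures the texture effect can legitimately exceed
  # the moisture effect, so that is not asserted
  ok <- 0; n <- 30
  for (i in seq_len(n)) {
    sc <- sample_scene("single", rc$config, seed = 400 + i)
    sc$scatterers <- list()   # soil only
    common <- sc$layers[[1]]
    for (l in 2:3) {
      sc$layers[[l]]$texture_class <- common$texture_class
      sc$layers[[l]]$variants <- common$variants
    }
    ras <- rasterize_scene(sc)
    zc <- (seq_len(nrow(ras$eps_real)) - 0.5) * rc$config$dx
    lay <- findInterval(zc, sc$layer_boundaries) + 1
    mu <- tapply(rowMeans(ras$eps_real), lay, mean)
    if (all(diff(mu) > 0)) ok <- ok + 1
  }
  expect_gte(ok / n, 0.95)
})

test_that("scenes round-trip through JSON serialization", {
  sc <- sample_scene("two_separate", rc$config, seed = 21)
  path <- withr::local_tempfile(fileext = ".json")
  write_scene_json(sc, path)
  expect_equal(read_scene_json(path), sc)
})

test_that("gprMax export writes a well-formed input file", {
  sc <- sample_scene("single", rc$config, seed = 9)
  path <- withr::local_tempfile(fileext = ".in")
  write_gprmax(sc, path)
  lines <- readLines(path)
  for (cmd in c("#domain:", "#dx_dy_dz:", "#time_window:", "#waveform:",
                "#material:", "#box:"))
    expect_true(any(startsWith(lines, cmd)), info = cmd)
})

test_that("infeasible two-scatterer constraints fail loudly", {
  tight <- rc$config
  tight$radius_range <- c(0.05, 0.051)
  expect_error(sample_scene("two_overlap", tight, seed = 5, max_tries = 2),
               "generation failure")
})
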