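#' Soil texture composition
#'
#' Constructs and validates a sand/silt/clay mass-fraction triple.  The
#' three fractions must be non-negative and sum to one (within `1e-9`);
#' they are the `S` and `C` inputs of the Peplinski mixing model and the
#' coordinates of the ISSS texture triangle.
#'
#' @param sand,silt,clay Mass fractions in `[0, 1]`.  Vectorized.
#' @return A tibble with columns `sand`, `silt`, `clay`.
#' @seealso [classify_texture()], [sample_compositions()]
#' @export
#' @examples
#' texture_composition(0.5, 0.35, 0.15)
texture_composition <- function(sand, silt, clay) {
  n <- max(length(sand), length(silt), length(clay))
  sand <- rep_len(as.numeric(sand), n)
  silt <- rep_len(as.numeric(silt), n)
  clay <- rep_len(as.numeric(clay), n)
  if (any(!is.finite(c(sand, silt, clay))) || any(c(sand, silt, clay) < 0))
    stop("invalid composition: fractions must be finite and non-negative",
         call. = FALSE)
  if (any(abs(sand + silt + clay - 1) > 1e-9))
    stop("invalid composition: sand + silt + clay must equal 1",
         call. = FALSE)
  tibble::tibble(sand = sand, silt = silt, clay = clay)
}

# ordered ISSS rule table, read once per session from the packaged JSON
isss_rules <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "isss_texture_classes.json",
                          package = "rootgpr")
      cache <<- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    }
    cache
  }
})

#' The 12 ISSS soil texture classes
#'
#' @return Character vector of the 12 class names of the international
#'   (ISSS) texture triangle, in the canonical rule order used for
#'   boundary tie-breaking.
#' @export
isss_classes <- function() unique(isss_rules()$rules$class)

#' Classify a soil composition on the ISSS texture triangle
#'
#' Assigns each sand/silt/clay composition to exactly one of the 12 classes
#' of the international (ISSS) texture triangle.  The class boundaries are
#' shipped as a versioned JSON rule table; rules are evaluated in a fixed
#' canonical order and the first match wins, which is the documented
#' tie-break for compositions lying exactly on a boundary.
#'
#' @param composition A data frame with columns `sand`, `silt`, `clay`
#'   (fractions summing to 1), or a numeric vector `c(sand, silt, clay)`.
#' @return Character vector of class names, one per composition.
#' @export
#' @examples
#' classify_texture(c(0.90, 0.05, 0.05))  # "sand"
#' classify_texture(texture_composition(0.05, 0.05, 0.90))  # "heavy clay"
classify_texture <- function(composition) {
  if (is.numeric(composition) && is.null(dim(composition))) {
    stopifnot(length(composition) == 3)
    composition <- texture_composition(composition[1], composition[2],
                                       composition[3])
  } else {
    composition <- texture_composition(composition$sand, composition$silt,
                                       composition$clay)
  }
  rules <- isss_rules()$rules
  sand <- composition$sand * 100
  silt <- composition$silt * 100
  clay <- composition$clay * 100
  out <- rep(NA_character_, length(sand))
  for (k in seq_len(nrow(rules))) {
    ok <- is.na(out)
    if (!is.null(rules$clay_ge) && !is.na(rules$clay_ge[k]))
      ok <- ok & clay >= rules$clay_ge[k]
    if (!is.null(rules$silt_ge) && !is.na(rules$silt_ge[k]))
      ok <- ok & silt >= rules$silt_ge[k]
    if (!is.null(rules$sand_ge) && !is.na(rules$sand_ge[k]))
      ok <- ok & sand >= rules$sand_ge[k]
    out[ok] <- rules$class[k]
  }
  out
}

#' Sample random compositions from one ISSS texture class
#'
#' Draws compositions uniformly over the simplex region belonging to a
#' texture class, by rejection from the uniform (Dirichlet(1,1,1))
#' distribution on the whole triangle.  Used to pick the five per-layer
#' composition variants of a scene.
#'
#' @param class One of the 12 ISSS class names (see [isss_classes()]).
#' @param n Number of compositions to draw.
#' @param seed Optional integer seed for reproducibility; when `NULL` the
#'   current RNG stream is used.
#' @return A tibble with `n` rows and columns `sand`, `silt`, `clay`,
#'   every row classifying back to `class`.
#' @export
sample_compositions <- function(class, n, seed = NULL) {
  class <- match.arg(class, isss_classes())
  stopifnot(n >= 1)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  out <- matrix(NA_real_, 0, 3)
  # uniform-simplex rejection; every ISSS class polygon has positive area
  while (nrow(out) < n) {
    m <- max(4 * (n - nrow(out)), 64)
    e <- matrix(-log(runif(3 * m)), m, 3)
    x <- e / rowSums(e)
    keep <- classify_texture(
      tibble::tibble(sand = x[, 1], silt = x[, 2], clay = x[, 3])) == class
    out <- rbind(out, x[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  tibble::tibble(sand = out[, 1], silt = out[, 2], clay = out[, 3])
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Debye parameters of liquid water
#'
#' Static permittivity and relaxation time of free water as functions of
#' temperature, from the standard polynomial fits used with the Peplinski
#' model; the high-frequency limit is fixed at 4.9.  The relaxation time
#' evaluates to about 9.28 ps at 20 degrees C (the commonly quoted value is
#' about 9.23 ps).
#'
#' @param temperature Water temperature in degrees C (0 to 40).
#' @return List with `eps_static`, `eps_inf`, `relaxation_time` (seconds)
#'   and `temperature`.
#' @export
water_debye_params <- function(temperature) {
  stopifnot(temperature >= 0, temperature <= 40)
  t <- temperature
  eps_static <- 88.045 - 0.4147 * t + 6.295e-4 * t^2 + 1.075e-5 * t^3
  two_pi_tau <- 1.1109e-10 - 3.824e-12 * t + 6.938e-14 * t^2 -
    5.096e-16 * t^3
  list(eps_static = eps_static, eps_inf = 4.9,
       relaxation_time = two_pi_tau / (2 * pi), temperature = t)
}

#' Complex relative permittivity of free water (single Debye relaxation)
#'
#' `eps_w = eps_inf + (eps_s - eps_inf) / (1 + i * omega * tau)`, with the
#' temperature-dependent parameters of [water_debye_params()].
#'
#' @param temperature Degrees C (0 to 40).
#' @param frequency Hz, positive.
#' @return A complex scalar (or vector, if `frequency` is a vector).
#' @export
water_permittivity <- function(temperature, frequency) {
  stopifnot(all(frequency > 0))
  p <- water_debye_params(temperature)
  omega <- 2 * pi * frequency
  p$eps_inf + (p$eps_static - p$eps_inf) /
    (1 + 1i * omega * p$relaxation_time)
}

#' Relative permittivity of solid soil particles
#'
#' Empirical closed form `eps_s = (1.01 + 0.44 * rho_s)^2 - 0.062` in terms
#' of the particle (specific) density `rho_s` in g/cm^3.
#'
#' @param rho_s Particle density, g/cm^3.
#' @return Dimensionless permittivity.
#' @export
sandgrain_permittivity <- function(rho_s) {
  stopifnot(all(rho_s >= 0))
  (1.01 + 0.44 * rho_s)^2 - 0.062
}

#' Soil state for the dielectric mixing model
#'
#' Bundles the texture composition, densities, volumetric moisture and
#' temperature of a soil.  Default densities are the customary field values
#' `rho_b = 1.5` and `rho_s = 2.66` g/cm^3.
#'
#' @param composition One-row data frame from [texture_composition()].
#' @param water_volume_fraction Volumetric moisture `f_w` in `[0, 1]`.
#' @param temperature Degrees C.
#' @param bulk_density,particle_density g/cm^3, with
#'   `bulk_density < particle_density`.
#' @return An object of class `soil_state`.
#' @export
soil_state <- function(composition, water_volume_fraction,
                       temperature = 20, bulk_density = 1.5,
                       particle_density = 2.66) {
  composition <- texture_composition(composition$sand, composition$silt,
                                     composition$clay)
  stopifnot(nrow(composition) == 1,
            water_volume_fraction >= 0, water_volume_fraction <= 1,
            bulk_density > 0, bulk_density < particle_density)
  structure(list(composition = composition,
                 water_volume_fraction = water_volume_fraction,
                 temperature = temperature,
                 bulk_density = bulk_density,
                 particle_density = particle_density),
            class = "soil_state")
}

#' Peplinski soil dielectric mixing model
#'
#' Computes the complex relative permittivity and conductivity of moist
#' soil at a microwave frequency from texture, densities, volumetric
#' moisture and temperature.  The real part uses the power-law mixing form
#' with exponent `a = 0.65`; in the 0.3-1.3 GHz band the published linear
#' correction `1.15 * eps' - 0.68` is applied.  The imaginary part combines
#' the Debye loss of free water with the effective-conductivity term, using
#' the texture-dependent coefficients `beta'`, `beta''` and `sigma_f`.
#' `S` and `C` enter as mass fractions in `[0, 1]`.  Conductivity is
#' recovered as `sigma = 0.05563 * f_GHz * eps''`.
#'
#' @param state A [soil_state()].
#' @param frequency Hz; supported band 0.3-18 GHz.
#' @return A `dielectric_properties` list with `eps_real`, `eps_imag`,
#'   `conductivity` (S/m) and `frequency` (Hz).
#' @export
#' @examples
#' st <- soil_state(texture_composition(0.5, 0.35, 0.15), 0.10)
#' peplinski(st, 0.9e9)
peplinski <- function(state, frequency) {
  stopifnot(inherits(state, "soil_state"))
  if (frequency < 0.3e9 || frequency > 18e9)
    stop("unsupported band: frequency must lie in [0.3, 18] GHz",
         call. = FALSE)
  S  <- state$composition$sand
  C  <- state$composition$clay
  fw <- state$water_volume_fraction
  rb <- state$bulk_density
  rs <- state$particle_density
  a  <- 0.65
  omega <- 2 * pi * frequency
  low_band <- frequency <= 1.3e9

  eps_s <- sandgrain_permittivity(rs)
  eps_w <- water_permittivity(state$temperature, frequency)
  beta_p  <- 1.2748 - 0.519 * S - 0.152 * C
  beta_pp <- 1.33797 - 0.603 * S - 0.166 * C

  eps_real <- (1 + (rb / rs) * (eps_s^a - 1) +
                 fw^beta_p * Re(eps_w)^a - fw)^(1 / a)
  if (low_band) eps_real <- 1.15 * eps_real - 0.68

  if (fw <= 0) {
    eps_imag <- 0
  } else {
    sigma_eff <- if (low_band)
      0.0467 + 0.2204 * rb - 0.411 * S + 0.6614 * C
    else
      -1.645 + 1.939 * rb - 2.013 * S + 1.594 * C
    # sigma_eff can dip below zero for very sandy soils; clamp the
    # effective water loss at zero as is standard practice
    eps_w_im <- pmax(0, -Im(eps_w) +
                       sigma_eff * (rs - rb) / (omega * .eps0 * rs * fw))
    eps_imag <- (fw^beta_pp * eps_w_im^a)^(1 / a)
  }
  dielectric_properties(eps_real, eps_imag, frequency)
}

#' Dielectric properties container
#'
#' @param eps_real,eps_imag Real and imaginary parts of the relative
#'   permittivity (`eps_real >= 1`, `eps_imag >= 0`).
#' @param frequency Hz.
#' @return A `dielectric_properties` list; `conductivity` is derived as
#'   `0.05563 * f_GHz * eps_imag` (S/m).
#' @export
dielectric_properties <- function(eps_real, eps_imag, frequency) {
  stopifnot(eps_real >= 1, eps_imag >= 0, frequency > 0)
  structure(list(eps_real = eps_real, eps_imag = eps_imag,
                 conductivity = 0.05563 * (frequency / 1e9) * eps_imag,
                 frequency = frequency),
            class = "dielectric_properties")
}

#' @export
print.dielectric_properties <- function(x, ...) {
  cat(sprintf(
    "dielectric properties @ %.3f GHz: eps' = %.4f, eps'' = %.4f, sigma = %.5f S/m\n",
    x$frequency / 1e9, x$eps_real, x$eps_imag, x$conductivity))
  invisible(x)
}
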