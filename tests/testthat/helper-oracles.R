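# Independent oracles and small fixtures, written before the code paths
# they check and kept free of package internals.

# literal transcription of the soil mixing-model equations (0.3-1.3 GHz
# band), evaluated step by step with its own Debye water model
oracle_peplinski <- function(S, C, rho_b, rho_s, fw, temp_c, f_hz) {
  a <- 0.65
  eps0 <- 8.8541878128e-12
  omega <- 2 * pi * f_hz
  eps_s <- (1.01 + 0.44 * rho_s)^2 - 0.062
  ews <- 88.045 - 0.4147 * temp_c + 6.295e-4 * temp_c^2 +
    1.075e-5 * temp_c^3
  tau <- (1.1109e-10 - 3.824e-12 * temp_c + 6.938e-14 * temp_c^2 -
            5.096e-16 * temp_c^3) / (2 * pi)
  ewinf <- 4.9
  den <- 1 + (omega * tau)^2
  ew_re <- ewinf + (ews - ewinf) / den
  ew_im <- (ews - ewinf) * omega * tau / den
  beta_p <- 1.2748 - 0.519 * S - 0.152 * C
  beta_pp <- 1.33797 - 0.603 * S - 0.166 * C
  sigma_f <- 0.0467 + 0.2204 * rho_b - 0.411 * S + 0.6614 * C
  ep <- (1 + (rho_b / rho_s) * (eps_s^a - 1) + fw^beta_p * ew_re^a -
           fw)^(1 / a)
  ep <- 1.15 * ep - 0.68
  if (fw <= 0) {
    epp <- 0
  } else {
    ew_im_eff <- max(0, ew_im + sigma_f * (rho_s - rho_b) /
                       (omega * eps0 * rho_s * fw))
    epp <- (fw^beta_pp * ew_im_eff^a)^(1 / a)
  }
  list(eps_real = ep, eps_imag = epp,
       conductivity = 0.05563 * (f_hz / 1e9) * epp)
}

# straight two-way ray travel time to a flat reflector: depth d under a
# half-space of permittivity eps_r, source-receiver offset 2h, plus the
# source delay
oracle_ray_time <- function(depth, half_offset, eps_r, fc = 900e6) {
  v <- 2.99792458e8 / sqrt(eps_r)
  2 * sqrt(depth^2 + half_offset^2) / v + 1.5 / fc
}

# uniform 1% grid over the composition simplex
composition_grid <- function(step = 0.01) {
  g <- expand.grid(sand = seq(0, 1, step), silt = seq(0, 1, step))
  g <- g[g$sand + g$silt <= 1 + 1e-12, ]
  tibble::tibble(sand = g$sand, silt = g$silt,
                 clay = pmax(0, 1 - g$sand - g$silt))
}

# small network configuration exercising every block type
tiny_model_config <- function(input_size = 32) {
  pyvitenet_config(
    input_size = input_size,
    main_channels = c(enc = 16, feb1 = 16, feb2 = 16, vit = 16,
                      feb3 = 16, feb4 = 16),
    aux_channels = c(16, 16, 16, 16, 16),
    vit_heads = 2, vit_mlp_dim = 32, vit_blocks = 1,
    encoders_per_block = 1)
}

# deterministic synthetic (input, labels) samples that need no FDTD:
# a soft blob input with a sharp square permittivity label
toy_samples <- function(n, size = 32, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    i0 <- sample(seq(4, size - 12), 1)
    j0 <- sample(seq(4, size - 12), 1)
    perm <- matrix(0.1, size, size)
    perm[i0:(i0 + 8), j0:(j0 + 8)] <- 0.85
    edge <- matrix(0L, size, size)
    edge[i0:(i0 + 8), c(j0, j0 + 8)] <- 1L
    edge[c(i0, i0 + 8), j0:(j0 + 8)] <- 1L
    u <- seq_len(size)
    blob <- exp(-0.02 * outer((u - i0 - 4)^2, (u - j0 - 4)^2, "+") / 10)
    structure(list(input = blob + matrix(rnorm(size^2, sd = 0.05),
                                         size, size),
                   perm_label = perm, edge_label = edge,
                   meta = list(seed = seed + i)),
              class = "processed_sample")
  }))
}

# composite training loss of a model before any optimization step,
# evaluated with batch statistics like the training loop itself
initial_train_loss <- function(model, dataset, cfg, batch_size = 8) {
  tot <- 0
  idxs <- split(seq_along(dataset),
                ceiling(seq_along(dataset) / batch_size))
  for (idx in idxs) {
    b <- rootgpr:::.as_batch(dataset, idx)
    fw <- rootgpr:::.pyvitenet_forward(model, b$x, train = TRUE)
    ls <- composite_loss(fw$perm, b$perm, fw$edge, b$edge,
                         cfg$alpha, cfg$beta)
    tot <- tot + ls$value * length(idx)
  }
  for (l in model$layers) l$cache <- NULL
  tot / length(dataset)
}

# cached reduced-scale simulated dataset shared across expensive tests
sim_cache <- new.env()
reduced_dataset <- function(n, seed = 10) {
  key <- sprintf("ds_%d_%d", n, seed)
  if (is.null(sim_cache[[key]])) {
    rc <- reduced_sim_config()
    sim_cache[[key]] <- simulate_dataset(n, rc$config, rc$geometry,
                                         size = rc$size, seed = seed)
  }
  sim_cache[[key]]
}
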