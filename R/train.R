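#' Cosine-annealed learning rate
#'
#' Decays from `lr0` at the first epoch to 0 at the final epoch with no
#' warm restarts: `lr(e) = lr0 * (1 + cos(pi * (e - 1) / (E - 1))) / 2`.
#'
#' @param epoch 1-based epoch index.
#' @param total Total number of epochs.
#' @param lr0 Initial learning rate.
#' @return Learning rate for `epoch`.
#' @export
cosine_lr <- function(epoch, total, lr0 = 5e-4) {
  if (total <= 1) return(lr0)
  lr0 * (1 + cos(pi * (epoch - 1) / (total - 1))) / 2
}

# one AdamW step over all layers; decoupled weight decay is applied to
# weight matrices only (not biases / norm parameters)
.adamw_step <- function(layers, lr, weight_decay = 0.01, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8, t = 1) {
  for (l in layers) {
    if (is.null(l$opt_m)) {
      l$opt_m <- lapply(l$par, function(p) p * 0)
      l$opt_v <- lapply(l$par, function(p) p * 0)
    }
    for (k in seq_along(l$par)) {
      g <- l$grad[[k]]
      l$opt_m[[k]] <- beta1 * l$opt_m[[k]] + (1 - beta1) * g
      l$opt_v[[k]] <- beta2 * l$opt_v[[k]] + (1 - beta2) * g * g
      mhat <- l$opt_m[[k]] / (1 - beta1^t)
      vhat <- l$opt_v[[k]] / (1 - beta2^t)
      decay <- if (grepl("^(W|pos)", names(l$par)[k])) weight_decay else 0
      l$par[[k]] <- l$par[[k]] -
        lr * (mhat / (sqrt(vhat) + eps) + decay * l$par[[k]])
    }
  }
  invisible(NULL)
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: AdamW with decoupled
#' weight decay 0.01, initial learning rate 5e-4 annealed to zero by a
#' cosine schedule over the run, batch size 64, 150 epochs, loss weights
#' `alpha = 1`, `beta = 0.01`.
#'
#' @param epochs,batch_size,lr,weight_decay,alpha,beta,seed Scalars.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 150, batch_size = 64, lr = 5e-4,
                         weight_decay = 0.01, alpha = 1, beta = 0.01,
                         seed = 1L) {
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 weight_decay = weight_decay, alpha = alpha, beta = beta,
                 seed = seed),
            class = "train_config")
}

# stack dataset samples idx into network tensors
.as_batch <- function(dataset, idx) {
  s1 <- dataset[[idx[1]]]
  H <- nrow(s1$input); W <- ncol(s1$input); N <- length(idx)
  x <- array(0, c(H, W, 1, N))
  yp <- array(0, c(H, W, 1, N))
  ye <- array(0, c(H, W, 1, N))
  for (i in seq_along(idx)) {
    s <- dataset[[idx[i]]]
    x[, , 1, i] <- s$input
    yp[, , 1, i] <- s$perm_label
    ye[, , 1, i] <- s$edge_label
  }
  list(x = x, perm = yp, edge = ye)
}

#' Train an inversion model
#'
#' Mini-batch AdamW training with cosine learning-rate annealing, logging
#' per-epoch training (and optional validation) loss and retaining the
#' weights with the best validation loss (training loss when no
#' validation set is given).
#'
#' @param model A [build_pyvitenet()] model (modified in place).
#' @param train_set,val_set Lists of `processed_sample`s.
#' @param config A [train_config()].
#' @param verbose Print a line per epoch.
#' @return An object of class `rootgpr_fit`: list with the trained
#'   `model`, a `history` tibble (epoch, lr, train_loss, val_loss), the
#'   `best_weights` and the configs.
#' @export
train_model <- function(model, train_set, val_set = NULL,
                        config = train_config(), verbose = FALSE) {
  stopifnot(length(train_set) >= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  n <- length(train_set)
  bs <- min(config$batch_size, n)
  hist <- vector("list", config$epochs)
  best <- Inf
  best_w <- NULL
  step <- 0
  for (ep in seq_len(config$epochs)) {
    lr <- cosine_lr(ep, config$epochs, config$lr)
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      batch <- .as_batch(train_set, idx)
      fw <- .pyvitenet_forward(model, batch$x, train = TRUE)
      ls <- composite_loss(fw$perm, batch$perm, fw$edge, batch$edge,
                           config$alpha, config$beta, grad = TRUE)
      if (!is.finite(ls$value))
        stop(sprintf("non-finite loss at epoch %d (train): aborting", ep),
             call. = FALSE)
      nn_zero_grad(model$layers)
      .pyvitenet_backward(model, ls$dperm, ls$dedge)
      step <- step + 1
      .adamw_step(model$layers, lr, config$weight_decay, t = step)
      ep_loss <- ep_loss + ls$value
      nb <- nb + 1
    }
    train_loss <- ep_loss / nb
    invisible(gc(FALSE))
    val_loss <- NA_real_
    if (!is.null(val_set) && length(val_set)) {
      val_loss <- .dataset_loss(model, val_set, config)
      score <- val_loss
    } else score <- train_loss
    if (score < best) {
      best <- score
      best_w <- get_weights(model)
    }
    hist[[ep]] <- tibble::tibble(epoch = ep, lr = lr,
                                 train_loss = train_loss,
                                 val_loss = val_loss)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  train %.5f  val %s", ep, lr,
                      train_loss,
                      ifelse(is.na(val_loss), "-",
                             sprintf("%.5f", val_loss))))
  }
  structure(list(model = model, history = do.call(rbind, hist),
                 best_weights = best_w, best_score = best,
                 train_config = config, model_config = model$config),
            class = "rootgpr_fit")
}

.dataset_loss <- function(model, dataset, config, batch_size = 16) {
  tot <- 0; m <- 0
  for (start in seq(1, length(dataset), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, length(dataset))
    batch <- .as_batch(dataset, idx)
    fw <- .pyvitenet_forward(model, batch$x, train = FALSE)
    ls <- composite_loss(fw$perm, batch$perm, fw$edge, batch$edge,
                         config$alpha, config$beta)
    tot <- tot + ls$value * length(idx)
    m <- m + length(idx)
  }
  tot / m
}

#' Split a dataset into train / validation / test partitions
#'
#' Random, seed-deterministic, disjoint and exhaustive split at the
#' sample (scene) level; each scene's sample lands in exactly one
#' partition.
#'
#' @param dataset List of samples.
#' @param ratios Length-3 positive weights, normalized internally
#'   (default 8:1:1).
#' @param seed Integer seed.
#' @return List with `train`, `val`, `test` sub-lists.
#' @export
split_dataset <- function(dataset, ratios = c(8, 1, 1), seed = 1L) {
  stopifnot(length(ratios) == 3, all(ratios > 0), length(dataset) >= 1)
  ratios <- ratios / sum(ratios)
  n <- length(dataset)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  ord <- sample.int(n)
  n_train <- round(ratios[1] * n)
  n_val <- round(ratios[2] * n)
  n_test <- n - n_train - n_val
  list(train = dataset[ord[seq_len(n_train)]],
       val = dataset[ord[n_train + seq_len(n_val)]],
       test = dataset[ord[n_train + n_val + seq_len(n_test)]])
}

#' Evaluate a model on a dataset
#'
#' Runs the model in evaluation mode over the dataset and reports MSE,
#' MAE and global SSIM between predicted and true normalized permittivity
#' maps (see [image_metrics()] for the display scalings).
#'
#' @param model A `pyvitenet` model.
#' @param dataset List of `processed_sample`s (non-empty).
#' @param batch_size Forward-pass batch size.
#' @return One-row tibble of metrics, of class `rootgpr_eval`.
#' @export
evaluate_model <- function(model, dataset, batch_size = 16) {
  stopifnot(length(dataset) >= 1)
  H <- nrow(dataset[[1]]$input)
  preds <- array(0, c(H, H, length(dataset)))
  truth <- array(0, c(H, H, length(dataset)))
  for (start in seq(1, length(dataset), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, length(dataset))
    batch <- .as_batch(dataset, idx)
    fw <- .pyvitenet_forward(model, batch$x, train = FALSE)
    preds[, , idx] <- fw$perm[, , 1, ]
    truth[, , idx] <- batch$perm[, , 1, ]
  }
  out <- image_metrics(preds, truth)
  class(out) <- c("rootgpr_eval", class(out))
  out
}

#' Staged transfer-learning pipeline
#'
#' Trains the same architecture through a sequence of stages (e.g. broad
#' synthetic data, site-matched synthetic data, measured data), loading
#' each stage's starting weights from the previous stage's best
#' checkpoint.  Any number of stages >= 1 is allowed; skipping the
#' matched-synthetic stage is just a two-stage configuration.
#'
#' @param stages List of stages; each a list with `train` (sample list)
#'   and optionally `val` and `config` (a [train_config()]).
#' @param model_config A [pyvitenet_config()].
#' @param init_weights Optional starting weights for stage 1.
#' @param seed Seed for model initialization.
#' @param verbose Passed to [train_model()].
#' @return List of class `rootgpr_transfer` with per-stage fits and the
#'   final model.
#' @export
transfer_pipeline <- function(stages, model_config = pyvitenet_config(),
                              init_weights = NULL, seed = 1L,
                              verbose = FALSE) {
  stopifnot(length(stages) >= 1)
  model <- build_pyvitenet(model_config, seed = seed)
  if (!is.null(init_weights)) set_weights(model, init_weights)
  fits <- vector("list", length(stages))
  for (k in seq_along(stages)) {
    st <- stages[[k]]
    cfg <- st$config %||% train_config()
    fits[[k]] <- train_model(model, st$train, st$val, cfg,
                             verbose = verbose)
    set_weights(model, fits[[k]]$best_weights)
  }
  structure(list(fits = fits, model = model, model_config = model_config),
            class = "rootgpr_transfer")
}
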