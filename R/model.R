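#' Architecture configuration for the dual-branch inversion network
#'
#' The network maps a single-channel B-scan image to a permittivity map
#' (main branch) and a binary edge map (auxiliary branch).  Both branches
#' are encoder / feature-extractor / decoder chains: the auxiliary branch
#' uses five PyConvFEBs with output channels (64, 128, 128, 64, 32); the
#' main branch uses four PyConvFEBs and one ViTFEB in third position
#' (the only stage without an auxiliary skip).  The feature maps of
#' auxiliary stages 1, 2, 4 and 5 are channel-concatenated into main
#' stages 1, 2, 4 and 5 before those stages run.  The ViT settings are 16
#' attention heads, embedding width 256 and MLP width 512, with two
#' ViT blocks of two transformer encoder layers each.
#'
#' The widths of the two main stages after the ViTFEB are not pinned by
#' the printed architecture; the defaults (128, 96) are calibrated so the
#' total trainable parameter count is 18.9 million.
#'
#' @param input_size Square input size (must be divisible by 4).
#' @param main_channels Output widths of encoder, PyConvFEB1, PyConvFEB2,
#'   ViTFEB, PyConvFEB3, PyConvFEB4 on the main branch.
#' @param aux_channels Output widths of the five auxiliary PyConvFEBs.
#' @param vit_heads,vit_mlp_dim,vit_blocks,encoders_per_block ViT settings.
#' @param cbam_reduction Bottleneck ratio of the CBAM channel attention.
#' @param edge_branch Set `FALSE` for the main-branch-only ablation.
#' @return A list of class `pyvitenet_config`.
#' @export
pyvitenet_config <- function(input_size = 128,
                             main_channels = c(enc = 64, feb1 = 64,
                                               feb2 = 256, vit = 256,
                                               feb3 = 128, feb4 = 96),
                             aux_channels = c(64, 128, 128, 64, 32),
                             vit_heads = 16, vit_mlp_dim = 512,
                             vit_blocks = 2, encoders_per_block = 2,
                             cbam_reduction = 16, edge_branch = TRUE) {
  stopifnot(length(main_channels) == 6, length(aux_channels) == 5,
            input_size %% 4 == 0)
  if (main_channels[3] != main_channels[4])
    stop("config error: ViTFEB preserves its input width, so feb2 and vit must match",
         call. = FALSE)
  structure(list(input_size = as.integer(input_size),
                 main_channels = main_channels,
                 aux_channels = aux_channels,
                 vit_heads = vit_heads, vit_mlp_dim = vit_mlp_dim,
                 vit_blocks = vit_blocks,
                 encoders_per_block = encoders_per_block,
                 cbam_reduction = cbam_reduction,
                 edge_branch = isTRUE(edge_branch)),
            class = "pyvitenet_config")
}

#' Build the dual-branch inversion network
#'
#' Constructs the network described by a [pyvitenet_config()] with
#' randomly initialized weights (He initialization for convolutions).
#' Use `seed` for reproducible initialization.
#'
#' @param config A [pyvitenet_config()].
#' @param seed Optional seed for weight initialization.
#' @return An object of class `pyvitenet`.
#' @export
build_pyvitenet <- function(config = pyvitenet_config(), seed = NULL) {
  stopifnot(inherits(config, "pyvitenet_config"))
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  mc <- config$main_channels
  ac <- config$aux_channels
  r <- config$cbam_reduction
  m <- new.env(parent = emptyenv())
  m$config <- config
  if (config$edge_branch) {
    m$aux_enc <- nn_sequential(nn_conv2d(1L, ac[1], 3L),
                               nn_batchnorm2d(ac[1]), nn_relu())
    m$aux_feb <- list(
      nn_pyconvfeb(ac[1], ac[1], r),
      nn_pyconvfeb(ac[1], ac[2], r),
      nn_pyconvfeb(ac[2], ac[3], r),
      nn_pyconvfeb(ac[3], ac[4], r),
      nn_pyconvfeb(ac[4], ac[5], r))
    m$aux_dec <- nn_sequential(nn_conv2d(ac[5], 1L, 3L), nn_sigmoid())
    skip <- c(ac[1], ac[2], 0, ac[4], ac[5])
  } else {
    skip <- c(0, 0, 0, 0, 0)
  }
  m$main_enc <- nn_sequential(nn_conv2d(1L, mc[1], 3L),
                              nn_batchnorm2d(mc[1]), nn_relu())
  m$main_feb1 <- nn_pyconvfeb(mc[1] + skip[1], mc[2], r)
  m$main_feb2 <- nn_pyconvfeb(mc[2] + skip[2], mc[3], r)
  m$main_vit <- nn_vitfeb(mc[4], config$input_size, config$vit_heads,
                          config$vit_mlp_dim, config$vit_blocks,
                          config$encoders_per_block, r)
  m$main_feb3 <- nn_pyconvfeb(mc[4] + skip[4], mc[5], r)
  m$main_feb4 <- nn_pyconvfeb(mc[5] + skip[5], mc[6], r)
  m$main_dec <- nn_sequential(nn_conv2d(mc[6], 1L, 3L), nn_sigmoid())
  m$layers <- nn_collect(mget(grep("^(aux|main)_", ls(m), value = TRUE),
                              envir = m))
  class(m) <- "pyvitenet"
  m
}

.cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Forward pass of the inversion network
#'
#' @param model A [build_pyvitenet()] model.
#' @param x Input array `(H, W, 1, N)`, or a single `H x W` matrix.
#' @param train Logical; `TRUE` uses batch statistics in the batch-norm
#'   layers (training mode), `FALSE` the running statistics.
#' @return List with `perm` and `edge` arrays `(H, W, 1, N)` in `(0, 1)`
#'   (`edge` is `NULL` for an ablated model without the auxiliary branch).
#' @export
predict_pyvitenet <- function(model, x, train = FALSE) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1, 1))
  d <- dim(x)
  if (length(d) != 4 || d[1] != model$config$input_size ||
      d[2] != model$config$input_size || d[3] != 1)
    stop(sprintf("shape error: expected (%d, %d, 1, N) input",
                 model$config$input_size, model$config$input_size),
         call. = FALSE)
  if (!all(is.finite(x))) stop("input must be finite", call. = FALSE)
  fw <- .pyvitenet_forward(model, x, train)
  list(perm = fw$perm, edge = fw$edge)
}

.pyvitenet_forward <- function(m, x, train) {
  has_aux <- m$config$edge_branch
  if (has_aux) {
    a0 <- m$aux_enc$fwd(x, train)
    a1 <- m$aux_feb[[1]]$fwd(a0, train)
    a2 <- m$aux_feb[[2]]$fwd(a1, train)
    a3 <- m$aux_feb[[3]]$fwd(a2, train)
    a4 <- m$aux_feb[[4]]$fwd(a3, train)
    a5 <- m$aux_feb[[5]]$fwd(a4, train)
    edge <- m$aux_dec$fwd(a5, train)
  } else edge <- NULL
  m0 <- m$main_enc$fwd(x, train)
  m1 <- m$main_feb1$fwd(if (has_aux) .cat_ch(m0, a1) else m0, train)
  m2 <- m$main_feb2$fwd(if (has_aux) .cat_ch(m1, a2) else m1, train)
  m3 <- m$main_vit$fwd(m2, train)
  m4 <- m$main_feb3$fwd(if (has_aux) .cat_ch(m3, a4) else m3, train)
  m5 <- m$main_feb4$fwd(if (has_aux) .cat_ch(m4, a5) else m4, train)
  perm <- m$main_dec$fwd(m5, train)
  list(perm = perm, edge = edge)
}

# backward pass; dperm/dedge are gradients of the loss w.r.t. the two
# outputs.  Returns nothing; gradients accumulate in the layers.
.pyvitenet_backward <- function(m, dperm, dedge = NULL) {
  has_aux <- m$config$edge_branch
  mc <- m$config$main_channels
  ac <- m$config$aux_channels
  dm5 <- m$main_dec$bwd(dperm)
  dcat <- m$main_feb4$bwd(dm5)
  if (has_aux) {
    dm4 <- dcat[, , seq_len(mc[5]), , drop = FALSE]
    da5_main <- dcat[, , mc[5] + seq_len(ac[5]), , drop = FALSE]
  } else dm4 <- dcat
  dcat <- m$main_feb3$bwd(dm4)
  if (has_aux) {
    dm3 <- dcat[, , seq_len(mc[4]), , drop = FALSE]
    da4_main <- dcat[, , mc[4] + seq_len(ac[4]), , drop = FALSE]
  } else dm3 <- dcat
  dm2 <- m$main_vit$bwd(dm3)
  dcat <- m$main_feb2$bwd(dm2)
  if (has_aux) {
    dm1 <- dcat[, , seq_len(mc[2]), , drop = FALSE]
    da2_main <- dcat[, , mc[2] + seq_len(ac[2]), , drop = FALSE]
  } else dm1 <- dcat
  dcat <- m$main_feb1$bwd(dm1)
  if (has_aux) {
    dm0 <- dcat[, , seq_len(mc[1]), , drop = FALSE]
    da1_main <- dcat[, , mc[1] + seq_len(ac[1]), , drop = FALSE]
  } else dm0 <- dcat
  m$main_enc$bwd(dm0)
  if (has_aux) {
    da5 <- da5_main
    if (!is.null(dedge)) da5 <- da5 + m$aux_dec$bwd(dedge)
    da4 <- m$aux_feb[[5]]$bwd(da5) + da4_main
    da3 <- m$aux_feb[[4]]$bwd(da4)
    da2 <- m$aux_feb[[3]]$bwd(da3) + da2_main
    da1 <- m$aux_feb[[2]]$bwd(da2) + da1_main
    da0 <- m$aux_feb[[1]]$bwd(da1)
    m$aux_enc$bwd(da0)
  }
  invisible(NULL)
}

#' Count trainable parameters
#'
#' Total number of trainable scalars across both branches of the model.
#'
#' @param model A `pyvitenet` model.
#' @param millions If `TRUE`, return millions rounded to one decimal.
#' @return Numeric count.
#' @export
count_parameters <- function(model, millions = FALSE) {
  n <- nn_n_params(model$layers)
  if (millions) round(n / 1e6, 1) else n
}

#' Extract / restore model weights
#'
#' `get_weights()` returns all parameters (and batch-norm running
#' statistics) as a plain list; `set_weights()` writes such a list back
#' into a model of identical architecture.
#'
#' @param model A `pyvitenet` model.
#' @param w A list from `get_weights()`.
#' @return `get_weights()`: a list; `set_weights()`: the model, invisibly.
#' @export
get_weights <- function(model) {
  lapply(model$layers, function(l) {
    out <- list(par = l$par)
    if (!is.null(l$run_mean))
      out$running <- list(mean = l$run_mean, var = l$run_var)
    out
  })
}

#' @rdname get_weights
#' @export
set_weights <- function(model, w) {
  stopifnot(length(w) == length(model$layers))
  for (i in seq_along(w)) {
    l <- model$layers[[i]]
    stopifnot(identical(lapply(l$par, dim), lapply(w[[i]]$par, dim)))
    l$par <- w[[i]]$par
    if (!is.null(w[[i]]$running)) {
      l$run_mean <- w[[i]]$running$mean
      l$run_var <- w[[i]]$running$var
    }
  }
  invisible(model)
}

#' Save / load a training checkpoint
#'
#' Checkpoints store the architecture configuration as a fingerprint;
#' loading into a model with a different architecture is an error.
#'
#' @param model A `pyvitenet` model.
#' @param path File path (RDS format).
#' @param extra Optional list stored alongside the weights.
#' @return `load_checkpoint()` returns the model, invisibly.
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  saveRDS(list(config = model$config, weights = get_weights(model),
               extra = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(model, path) {
  ck <- readRDS(path)
  if (!identical(unclass(ck$config), unclass(model$config)))
    stop("architecture fingerprint mismatch between checkpoint and model",
         call. = FALSE)
  set_weights(model, ck$weights)
}

#' @export
print.pyvitenet <- function(x, ...) {
  cat(sprintf(
    "PyViTENet-style dual-branch inversion network\n  input %dx%d, edge branch: %s\n  trainable parameters: %s (%.1f M)\n",
    x$config$input_size, x$config$input_size,
    ifelse(x$config$edge_branch, "yes", "no"),
    format(count_parameters(x), big.mark = ","),
    count_parameters(x) / 1e6))
  invisible(x)
}
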