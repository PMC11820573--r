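# Composite blocks of the inversion network: sequential chains, the
# convolutional block attention module (CBAM), the pyramidal-convolution
# feature extraction block (PyConvFEB) and the vision-transformer feature
# extraction block (ViTFEB).

nn_sequential <- function(...) {
  b <- new.env(parent = emptyenv())
  b$type <- "sequential"
  b$layers <- list(...)
  b$fwd <- function(x, train = TRUE) {
    for (l in b$layers) x <- l$fwd(x, train)
    x
  }
  b$bwd <- function(dy) {
    for (l in rev(b$layers)) dy <- l$bwd(dy)
    dy
  }
  class(b) <- "nn_block"
  b
}

# flat list of parameterized layers inside any block/layer tree
nn_collect <- function(x) {
  if (inherits(x, "nn_layer")) return(if (length(x$par)) list(x) else list())
  if (inherits(x, "nn_block"))
    return(do.call(c, lapply(x$layers, nn_collect)))
  if (is.list(x)) return(do.call(c, lapply(x, nn_collect)))
  list()
}

# ---- CBAM ------------------------------------------------------------------
# channel attention from average- and max-pooled descriptors through a
# shared bottleneck MLP, then spatial attention from channel-wise
# average/max maps through a 7x7 convolution; sigmoid gates both.

nn_cbam <- function(C, reduction = 16, spatial_kernel = 7) {
  Cr <- max(1L, C %/% reduction)
  b <- new.env(parent = emptyenv())
  b$type <- "cbam"
  mlp <- nn_layer("cbam_mlp", list(
    W1 = array(rnorm(C * Cr, sd = sqrt(2 / C)), c(C, Cr)),
    b1 = array(0, Cr),
    W2 = array(rnorm(Cr * C, sd = sqrt(2 / Cr)), c(Cr, C)),
    b2 = array(0, C)))
  sp <- nn_conv2d(2L, 1L, spatial_kernel)
  b$layers <- list(mlp, sp)
  b$C <- C

  mlp_fwd <- function(A) {   # A: (C, N) pooled descriptor
    H1 <- pmax(crossprod(mlp$par$W1, A) + as.vector(mlp$par$b1), 0)
    list(out = crossprod(mlp$par$W2, H1) + as.vector(mlp$par$b2),
         H1 = H1, A = A)
  }
  mlp_bwd <- function(dout, cc) {
    mlp$grad$W2 <- mlp$grad$W2 + tcrossprod(cc$H1, dout)
    mlp$grad$b2 <- mlp$grad$b2 + rowSums(dout)
    dH1 <- (mlp$par$W2 %*% dout) * (cc$H1 > 0)
    mlp$grad$W1 <- mlp$grad$W1 + tcrossprod(cc$A, dH1)
    mlp$grad$b1 <- mlp$grad$b1 + rowSums(dH1)
    mlp$par$W1 %*% dH1    # dA (C, N)
  }

  b$fwd <- function(x, train = TRUE) {
    d <- dim(x)
    HW <- d[1] * d[2]
    xm <- x
    dim(xm) <- c(HW, d[3] * d[4])
    avg <- matrix(colMeans(xm), d[3], d[4])
    imax <- max.col(t(xm), ties.method = "first")
    mx <- matrix(xm[cbind(imax, seq_len(d[3] * d[4]))], d[3], d[4])
    f1 <- mlp_fwd(avg)
    f2 <- mlp_fwd(mx)
    s <- 1 / (1 + exp(-(f1$out + f2$out)))          # (C, N)
    y1 <- x * array(rep(as.vector(s), each = HW), d)
    # spatial attention on the channel-gated map
    y1m <- aperm(y1, c(1, 2, 4, 3))
    dim(y1m) <- c(HW * d[4], d[3])
    sav <- rowMeans(y1m)
    smi <- max.col(y1m, ties.method = "first")
    smx <- y1m[cbind(seq_len(HW * d[4]), smi)]
    pool <- array(0, c(d[1], d[2], 2, d[4]))
    pool[, , 1, ] <- array(sav, c(d[1], d[2], d[4]))
    pool[, , 2, ] <- array(smx, c(d[1], d[2], d[4]))
    smap_raw <- sp$fwd(pool, train)
    smap <- 1 / (1 + exp(-smap_raw))                # (H, W, 1, N)
    sm4 <- array(rep(aperm(smap, c(1, 2, 4, 3)), each = 1), c(d[1], d[2], d[4]))
    smB <- aperm(array(sm4, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    y <- y1 * smB
    if (train)
      b$cache <- list(x = x, d = d, avg_cc = f1, max_cc = f2, s = s,
                      imax = imax, y1 = y1, smi = smi, smap = smap,
                      smB = smB)
    y
  }
  b$bwd <- function(dy) {
    cc <- b$cache
    d <- cc$d
    HW <- d[1] * d[2]
    # spatial gate
    dy1 <- dy * cc$smB
    dsm <- dy * cc$y1
    dsm_hw <- aperm(dsm, c(1, 2, 4, 3))
    dim(dsm_hw) <- c(HW * d[4], d[3])
    dsmap <- rowSums(dsm_hw)                        # (H*W*N)
    dsmap <- array(dsmap, c(d[1], d[2], d[4]))
    dsmap4 <- array(0, c(d[1], d[2], 1, d[4]))
    dsmap4[, , 1, ] <- dsmap
    draw <- dsmap4 * cc$smap * (1 - cc$smap)
    dpool <- sp$bwd(draw)
    # pooled-map gradients back onto y1
    y1m_grad <- matrix(0, HW * d[4], d[3])
    dav <- as.vector(dpool[, , 1, ]) / d[3]
    y1m_grad <- y1m_grad + dav
    dmx <- as.vector(dpool[, , 2, ])
    y1m_grad[cbind(seq_len(HW * d[4]), cc$smi)] <-
      y1m_grad[cbind(seq_len(HW * d[4]), cc$smi)] + dmx
    dim(y1m_grad) <- c(d[1], d[2], d[4], d[3])
    dy1 <- dy1 + aperm(y1m_grad, c(1, 2, 4, 3))
    # channel gate
    sB <- array(rep(as.vector(cc$s), each = HW), d)
    dx <- dy1 * sB
    ds_full <- dy1 * cc$x
    dim(ds_full) <- c(HW, d[3] * d[4])
    ds <- matrix(colSums(ds_full), d[3], d[4])
    dpre <- ds * cc$s * (1 - cc$s)
    davg <- mlp_bwd(dpre, cc$avg_cc)
    dmax <- mlp_bwd(dpre, cc$max_cc)
    dxm <- matrix(0, HW, d[3] * d[4])
    dxm <- dxm + rep(as.vector(davg) / HW, each = HW)
    dxm[cbind(cc$imax, seq_len(d[3] * d[4]))] <-
      dxm[cbind(cc$imax, seq_len(d[3] * d[4]))] + as.vector(dmax)
    dim(dxm) <- d
    b$cache <- NULL
    dx + dxm
  }
  class(b) <- "nn_block"
  b
}

# residual wrapper: out = x + inner(x)
nn_residual <- function(inner) {
  b <- new.env(parent = emptyenv())
  b$type <- "residual"
  b$layers <- list(inner)
  b$fwd <- function(x, train = TRUE) x + inner$fwd(x, train)
  b$bwd <- function(dy) dy + inner$bwd(dy)
  class(b) <- "nn_block"
  b
}

# ---- PyConvFEB -------------------------------------------------------------
# three parallel grouped convolutions (3x3/g1, 5x5/g4, 7x7/g8), channel
# concatenation, 3x3 fuse convolution + BN + ReLU, CBAM residual

nn_pyconvfeb <- function(in_c, out_c, cbam_reduction = 16) {
  if (out_c %% 16 != 0 || in_c %% 8 != 0)
    stop("config error: PyConvFEB needs in_c %% 8 == 0 and out_c %% 16 == 0",
         call. = FALSE)
  half <- out_c %/% 2L
  b <- new.env(parent = emptyenv())
  b$type <- "pyconvfeb"
  b$in_c <- in_c; b$out_c <- out_c
  b3 <- nn_conv2d(in_c, half, 3L, groups = 1L)
  b5 <- nn_conv2d(in_c, half, 5L, groups = 4L)
  b7 <- nn_conv2d(in_c, half, 7L, groups = 8L)
  fuse <- nn_conv2d(3L * half, out_c, 3L)
  bn <- nn_batchnorm2d(out_c)
  act <- nn_relu()
  attn <- nn_residual(nn_cbam(out_c, cbam_reduction))
  b$layers <- list(b3, b5, b7, fuse, bn, act, attn)
  b$fwd <- function(x, train = TRUE) {
    y3 <- b3$fwd(x, train); y5 <- b5$fwd(x, train); y7 <- b7$fwd(x, train)
    d <- dim(y3)
    cat3 <- array(0, c(d[1], d[2], 3L * half, d[4]))
    cat3[, , 1:half, ] <- y3
    cat3[, , (half + 1):(2 * half), ] <- y5
    cat3[, , (2 * half + 1):(3 * half), ] <- y7
    z <- act$fwd(bn$fwd(fuse$fwd(cat3, train), train), train)
    attn$fwd(z, train)
  }
  b$bwd <- function(dy) {
    dz <- fuse$bwd(bn$bwd(act$bwd(attn$bwd(dy))))
    b3$bwd(dz[, , 1:half, , drop = FALSE]) +
      b5$bwd(dz[, , (half + 1):(2 * half), , drop = FALSE]) +
      b7$bwd(dz[, , (2 * half + 1):(3 * half), , drop = FALSE])
  }
  class(b) <- "nn_block"
  b
}

# ---- ViTFEB ----------------------------------------------------------------
# serial multi-scale convolutions downsample 4x; 1x1-patch tokens run
# through vit_blocks x encoders_per_block transformer encoder layers
# (pre-LN), the result is added back to the downsampled map, and two
# deconvolutions restore the input size; CBAM residual at the end.

nn_vitfeb <- function(C, input_size, heads = 16, mlp_dim = 512,
                      vit_blocks = 2, encoders_per_block = 2,
                      cbam_reduction = 16) {
  if (input_size %% 4 != 0)
    stop("config error: ViTFEB input size must be divisible by 4",
         call. = FALSE)
  hs <- input_size %/% 4L
  Tn <- hs * hs
  b <- new.env(parent = emptyenv())
  b$type <- "vitfeb"
  cbr <- function(k, stride = 1L)
    nn_sequential(nn_conv2d(C, C, k, stride = stride),
                  nn_batchnorm2d(C), nn_relu())
  down <- nn_sequential(cbr(7L, 2L), cbr(3L), cbr(3L),
                        cbr(5L, 2L), cbr(3L), cbr(3L), cbr(3L))
  embed <- nn_linear(C, C)
  pos <- nn_pos_embedding(Tn, C)
  enc_layer <- function() {
    ln1 <- nn_layernorm(C); at <- nn_mhsa(C, heads)
    ln2 <- nn_layernorm(C)
    ff <- nn_sequential(nn_linear(C, mlp_dim), nn_gelu(),
                        nn_linear(mlp_dim, C))
    nn_residual2(ln1, at, ln2, ff)
  }
  encoders <- lapply(seq_len(vit_blocks * encoders_per_block),
                     function(i) enc_layer())
  ln_final <- nn_layernorm(C)
  up <- nn_sequential(
    nn_deconv2d(C, C, 6L, 2L, 2L), nn_batchnorm2d(C), nn_relu(),
    cbr(3L), cbr(3L), cbr(3L),
    nn_deconv2d(C, C, 4L, 2L, 1L), nn_batchnorm2d(C), nn_relu())
  attn <- nn_residual(nn_cbam(C, cbam_reduction))
  b$layers <- list(down, embed, pos, encoders, ln_final, up, attn)
  b$C <- C; b$hs <- hs
  b$fwd <- function(x, train = TRUE) {
    stopifnot(dim(x)[3] == C)
    f <- down$fwd(x, train)              # (hs, hs, C, N)
    df <- dim(f)
    tok <- f
    dim(tok) <- c(Tn, C, df[4])          # 1x1 patches as tokens
    tok <- pos$fwd(embed$fwd(tok, train), train)
    for (e in encoders) tok <- e$fwd(tok, train)
    tok <- ln_final$fwd(tok, train)
    dim(tok) <- df
    g <- f + tok                          # transformer residual
    u <- up$fwd(g, train)
    attn$fwd(u, train)
  }
  b$bwd <- function(dy) {
    dg <- up$bwd(attn$bwd(dy))
    df <- dim(dg)
    dtok <- dg
    dim(dtok) <- c(Tn, C, df[4])
    dtok <- ln_final$bwd(dtok)
    for (e in rev(encoders)) dtok <- e$bwd(dtok)
    dtok <- embed$bwd(pos$bwd(dtok))
    dim(dtok) <- df
    down$bwd(dg + dtok)
  }
  class(b) <- "nn_block"
  b
}

# pre-LN transformer encoder layer: x + attn(ln1(x)), then + ff(ln2(.))
nn_residual2 <- function(ln1, at, ln2, ff) {
  b <- new.env(parent = emptyenv())
  b$type <- "encoder_layer"
  b$layers <- list(ln1, at, ln2, ff)
  b$fwd <- function(x, train = TRUE) {
    x <- x + at$fwd(ln1$fwd(x, train), train)
    x + ff$fwd(ln2$fwd(x, train), train)
  }
  b$bwd <- function(dy) {
    dy <- dy + ln2$bwd(ff$bwd(dy))
    dy + ln1$bwd(at$bwd(dy))
  }
  class(b) <- "nn_block"
  b
}
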