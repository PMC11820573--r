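# Minimal reverse-mode neural-network engine.
#
# A layer is an environment with:
#   par   named list of parameter arrays
#   grad  parallel list of accumulated gradients
#   fwd(x, train)  forward pass, caching what backward needs
#   bwd(dy)        backward pass; accumulates into grad, returns dx
# Tensors are R arrays with dim (H, W, C, N); token stacks are (T, D, N).
# Convolutions run through the C++ im2col/col2im kernels and BLAS.

nn_layer <- function(type, par = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$par <- par
  e$grad <- lapply(par, function(p) array(0, dim(p) %||% length(p)))
  e$cache <- NULL
  class(e) <- "nn_layer"
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nn_zero_grad <- function(layers) {
  for (l in layers)
    for (k in seq_along(l$grad)) l$grad[[k]][] <- 0
  invisible(NULL)
}

nn_n_params <- function(layers) sum(vapply(layers, function(l)
  sum(vapply(l$par, length, integer(1))), numeric(1)))

# ---- convolution -----------------------------------------------------------

nn_conv2d <- function(in_c, out_c, k, stride = 1L, pad = (k - 1L) %/% 2L,
                      groups = 1L) {
  if (in_c %% groups != 0 || out_c %% groups != 0)
    stop("config error: channels not divisible by groups", call. = FALSE)
  in_g <- in_c %/% groups
  out_g <- out_c %/% groups
  sdv <- sqrt(2 / (k * k * in_g))
  l <- nn_layer("conv2d", list(
    W = array(rnorm(k * k * in_g * out_c, sd = sdv),
              c(k * k * in_g, out_c)),
    b = array(0, out_c)))
  l$k <- k; l$stride <- stride; l$pad <- pad; l$groups <- groups
  l$in_c <- in_c; l$out_c <- out_c
  l$fwd <- function(x, train = TRUE) {
    d <- dim(x)
    stopifnot(d[3] == in_c)
    Ho <- (d[1] + 2 * l$pad - k) %/% l$stride + 1L
    Wo <- (d[2] + 2 * l$pad - k) %/% l$stride + 1L
    P <- Ho * Wo * d[4]
    Y <- matrix(0, P, out_c)
    for (g in seq_len(groups)) {
      ci <- ((g - 1) * in_g + 1):(g * in_g)
      co <- ((g - 1) * out_g + 1):(g * out_g)
      xg <- x[, , ci, , drop = FALSE]
      cols <- im2col_cpp(xg, d[1], d[2], in_g, d[4], k, l$stride, l$pad)
      Y[, co] <- cols %*% l$par$W[, co, drop = FALSE]
    }
    Y <- sweep(Y, 2, l$par$b, "+")
    # cache the input, not the patch matrices: backward re-extracts them,
    # trading a little compute for a large cut in peak memory
    if (train) l$cache <- list(x = x, dims = d, Ho = Ho, Wo = Wo)
    dim(Y) <- c(Ho, Wo, d[4], out_c)
    aperm(Y, c(1, 2, 4, 3))
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    d <- cc$dims
    dym <- aperm(dy, c(1, 2, 4, 3))
    dim(dym) <- c(cc$Ho * cc$Wo * d[4], out_c)
    l$grad$b <- l$grad$b + colSums(dym)
    dx <- array(0, d)
    for (g in seq_len(groups)) {
      ci <- ((g - 1) * in_g + 1):(g * in_g)
      co <- ((g - 1) * out_g + 1):(g * out_g)
      dyg <- dym[, co, drop = FALSE]
      xg <- cc$x[, , ci, , drop = FALSE]
      cols <- im2col_cpp(xg, d[1], d[2], in_g, d[4], k, l$stride, l$pad)
      l$grad$W[, co] <- l$grad$W[, co, drop = FALSE] +
        crossprod(cols, dyg)
      dcols <- tcrossprod(dyg, l$par$W[, co, drop = FALSE])
      dx[, , ci, ] <- col2im_cpp(dcols, d[1], d[2], in_g, d[4], k,
                                 l$stride, l$pad)
    }
    l$cache <- NULL
    dx
  }
  l
}

nn_deconv2d <- function(in_c, out_c, k, stride, pad) {
  sdv <- sqrt(2 / (k * k * in_c))
  l <- nn_layer("deconv2d", list(
    W = array(rnorm(k * k * out_c * in_c, sd = sdv),
              c(k * k * out_c, in_c)),
    b = array(0, out_c)))
  l$k <- k; l$stride <- stride; l$pad <- pad
  l$in_c <- in_c; l$out_c <- out_c
  l$fwd <- function(x, train = TRUE) {
    d <- dim(x)
    stopifnot(d[3] == in_c)
    Ho <- (d[1] - 1L) * l$stride + k - 2L * l$pad
    Wo <- (d[2] - 1L) * l$stride + k - 2L * l$pad
    xm <- aperm(x, c(1, 2, 4, 3))
    dim(xm) <- c(d[1] * d[2] * d[4], in_c)
    cols <- tcrossprod(xm, l$par$W)    # (P, k*k*out_c)
    y <- col2im_cpp(cols, Ho, Wo, out_c, d[4], k, l$stride, l$pad)
    y <- y + array(rep(rep(l$par$b, each = Ho * Wo), d[4]),
                   c(Ho, Wo, out_c, d[4]))
    if (train) l$cache <- list(xm = xm, dims = d, Ho = Ho, Wo = Wo)
    y
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    d <- cc$dims
    l$grad$b <- l$grad$b + apply(dy, 3, sum)
    dcols <- im2col_cpp(dy, cc$Ho, cc$Wo, out_c, d[4], k, l$stride, l$pad)
    l$grad$W <- l$grad$W + crossprod(dcols, cc$xm)
    dxm <- dcols %*% l$par$W
    dim(dxm) <- c(d[1], d[2], d[4], in_c)
    l$cache <- NULL
    aperm(dxm, c(1, 2, 4, 3))
  }
  l
}

# ---- normalization and activations ----------------------------------------

nn_batchnorm2d <- function(C, momentum = 0.1, eps = 1e-5) {
  l <- nn_layer("batchnorm2d", list(gamma = array(1, C),
                                    beta = array(0, C)))
  l$run_mean <- rep(0, C)
  l$run_var <- rep(1, C)
  l$C <- C
  l$fwd <- function(x, train = TRUE) {
    d <- dim(x)
    xp <- aperm(x, c(1, 2, 4, 3))
    dim(xp) <- c(d[1] * d[2] * d[4], d[3])
    if (train) {
      mu <- colMeans(xp)
      xc <- sweep(xp, 2, mu)
      v <- colMeans(xc * xc)
      l$run_mean <- (1 - momentum) * l$run_mean + momentum * mu
      l$run_var <- (1 - momentum) * l$run_var + momentum * v
    } else {
      mu <- l$run_mean
      v <- l$run_var
      xc <- sweep(xp, 2, mu)
    }
    ivar <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, ivar, "*")
    y <- sweep(sweep(xhat, 2, l$par$gamma, "*"), 2, l$par$beta, "+")
    if (train)
      l$cache <- list(xhat = xhat, ivar = ivar, dims = d, train = train)
    dim(y) <- c(d[1], d[2], d[4], d[3])
    aperm(y, c(1, 2, 4, 3))
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    d <- cc$dims
    dyp <- aperm(dy, c(1, 2, 4, 3))
    dim(dyp) <- c(d[1] * d[2] * d[4], d[3])
    l$grad$gamma <- l$grad$gamma + colSums(dyp * cc$xhat)
    l$grad$beta <- l$grad$beta + colSums(dyp)
    dxhat <- sweep(dyp, 2, l$par$gamma, "*")
    if (cc$train) {
      M <- nrow(dyp)
      t1 <- colSums(dxhat)
      t2 <- colSums(dxhat * cc$xhat)
      dxp <- sweep(dxhat, 2, t1 / M) -
        sweep(cc$xhat, 2, t2 / M, "*")
      dxp <- sweep(dxp, 2, cc$ivar, "*")
    } else {
      dxp <- sweep(dxhat, 2, cc$ivar, "*")
    }
    l$cache <- NULL
    dim(dxp) <- c(d[1], d[2], d[4], d[3])
    aperm(dxp, c(1, 2, 4, 3))
  }
  l
}

nn_relu <- function() {
  l <- nn_layer("relu")
  l$fwd <- function(x, train = TRUE) {
    m <- x > 0
    if (train) l$cache <- m
    x * m
  }
  l$bwd <- function(dy) {
    dx <- dy * l$cache
    l$cache <- NULL
    dx
  }
  l
}

nn_sigmoid <- function() {
  l <- nn_layer("sigmoid")
  l$fwd <- function(x, train = TRUE) {
    # clamp the logits: MSE on binary targets pushes them toward +/-Inf,
    # and exp() of very large magnitudes hits denormal arithmetic
    y <- 1 / (1 + exp(-pmin(pmax(x, -60), 60)))
    if (train) l$cache <- y
    y
  }
  l$bwd <- function(dy) {
    y <- l$cache
    l$cache <- NULL
    dy * y * (1 - y)
  }
  l
}

nn_gelu <- function() {
  l <- nn_layer("gelu")
  k0 <- sqrt(2 / pi)
  l$fwd <- function(x, train = TRUE) {
    inner <- k0 * (x + 0.044715 * x^3)
    th <- tanh(inner)
    if (train) l$cache <- list(x = x, th = th)
    0.5 * x * (1 + th)
  }
  l$bwd <- function(dy) {
    x <- l$cache$x; th <- l$cache$th
    l$cache <- NULL
    sech2 <- 1 - th^2
    d_inner <- k0 * (1 + 3 * 0.044715 * x^2)
    dy * (0.5 * (1 + th) + 0.5 * x * sech2 * d_inner)
  }
  l
}

# ---- token (transformer) layers -------------------------------------------
# token stacks are (T, D, N); matrix form is (T*N, D) via aperm(,c(1,3,2))

.tok2mat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1, 3, 2))
  dim(m) <- c(d[1] * d[3], d[2])
  m
}
.mat2tok <- function(m, d) {
  dim(m) <- c(d[1], d[3], d[2])
  aperm(m, c(1, 3, 2))
}

nn_linear <- function(in_d, out_d) {
  l <- nn_layer("linear", list(
    W = array(rnorm(in_d * out_d, sd = sqrt(2 / in_d)), c(in_d, out_d)),
    b = array(0, out_d)))
  l$fwd <- function(x, train = TRUE) {   # x: (T, D, N)
    d <- dim(x)
    m <- .tok2mat(x)
    y <- sweep(m %*% l$par$W, 2, l$par$b, "+")
    if (train) l$cache <- list(m = m, dims = d)
    .mat2tok(y, c(d[1], out_d, d[3]))
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    dm <- .tok2mat(dy)
    l$grad$W <- l$grad$W + crossprod(cc$m, dm)
    l$grad$b <- l$grad$b + colSums(dm)
    dx <- tcrossprod(dm, l$par$W)
    l$cache <- NULL
    .mat2tok(dx, cc$dims)
  }
  l
}

nn_layernorm <- function(D, eps = 1e-5) {
  l <- nn_layer("layernorm", list(gamma = array(1, D), beta = array(0, D)))
  l$fwd <- function(x, train = TRUE) {
    d <- dim(x)
    m <- .tok2mat(x)
    mu <- rowMeans(m)
    xc <- m - mu
    v <- rowMeans(xc * xc)
    ivar <- 1 / sqrt(v + eps)
    xhat <- xc * ivar
    y <- sweep(sweep(xhat, 2, l$par$gamma, "*"), 2, l$par$beta, "+")
    if (train) l$cache <- list(xhat = xhat, ivar = ivar, dims = d)
    .mat2tok(y, d)
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    dm <- .tok2mat(dy)
    l$grad$gamma <- l$grad$gamma + colSums(dm * cc$xhat)
    l$grad$beta <- l$grad$beta + colSums(dm)
    dxhat <- sweep(dm, 2, l$par$gamma, "*")
    Dn <- ncol(dm)
    t1 <- rowMeans(dxhat)
    t2 <- rowMeans(dxhat * cc$xhat)
    dx <- (dxhat - t1 - cc$xhat * t2) * cc$ivar
    l$cache <- NULL
    .mat2tok(dx, cc$dims)
  }
  l
}

nn_mhsa <- function(D, heads) {
  stopifnot(D %% heads == 0)
  dh <- D %/% heads
  l <- nn_layer("mhsa", list(
    Wqkv = array(rnorm(D * 3 * D, sd = sqrt(1 / D)), c(D, 3 * D)),
    bqkv = array(0, 3 * D),
    Wo = array(rnorm(D * D, sd = sqrt(1 / D)), c(D, D)),
    bo = array(0, D)))
  l$heads <- heads
  l$fwd <- function(x, train = TRUE) {   # (T, D, N)
    d <- dim(x)
    Tn <- d[1]; N <- d[3]
    y <- array(0, d)
    cache <- vector("list", N)
    for (n in seq_len(N)) {
      X <- x[, , n]
      QKV <- sweep(X %*% l$par$Wqkv, 2, l$par$bqkv, "+")
      O <- matrix(0, Tn, D)
      A_list <- vector("list", heads)
      for (h in seq_len(heads)) {
        iq <- ((h - 1) * dh + 1):(h * dh)
        Q <- QKV[, iq, drop = FALSE]
        K <- QKV[, D + iq, drop = FALSE]
        V <- QKV[, 2 * D + iq, drop = FALSE]
        S <- tcrossprod(Q, K) / sqrt(dh)
        S <- pmax(S - apply(S, 1, max), -60)   # denormal-safe softmax
        A <- exp(S)
        A <- A / rowSums(A)
        O[, iq] <- A %*% V
        A_list[[h]] <- A
      }
      y[, , n] <- sweep(O %*% l$par$Wo, 2, l$par$bo, "+")
      cache[[n]] <- list(X = X, QKV = QKV, A = A_list, O = O)
    }
    if (train) l$cache <- list(per_n = cache, dims = d)
    y
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    d <- cc$dims
    dx <- array(0, d)
    for (n in seq_len(d[3])) {
      cn <- cc$per_n[[n]]
      dyn <- dy[, , n]
      l$grad$Wo <- l$grad$Wo + crossprod(cn$O, dyn)
      l$grad$bo <- l$grad$bo + colSums(dyn)
      dO <- tcrossprod(dyn, l$par$Wo)
      dQKV <- matrix(0, d[1], 3 * D)
      for (h in seq_len(heads)) {
        iq <- ((h - 1) * dh + 1):(h * dh)
        Q <- cn$QKV[, iq, drop = FALSE]
        K <- cn$QKV[, D + iq, drop = FALSE]
        V <- cn$QKV[, 2 * D + iq, drop = FALSE]
        A <- cn$A[[h]]
        dOh <- dO[, iq, drop = FALSE]
        dA <- tcrossprod(dOh, V)
        dV <- crossprod(A, dOh)
        dS <- A * (dA - rowSums(dA * A))
        dS <- dS / sqrt(dh)
        dQKV[, iq] <- dS %*% K
        dQKV[, D + iq] <- crossprod(dS, Q)
        dQKV[, 2 * D + iq] <- dV
      }
      l$grad$Wqkv <- l$grad$Wqkv + crossprod(cn$X, dQKV)
      l$grad$bqkv <- l$grad$bqkv + colSums(dQKV)
      dx[, , n] <- tcrossprod(dQKV, l$par$Wqkv)
    }
    l$cache <- NULL
    dx
  }
  l
}

# learned additive positional embedding over a fixed token count
nn_pos_embedding <- function(Tn, D) {
  l <- nn_layer("pos_embedding",
                list(pos = array(rnorm(Tn * D, sd = 0.02), c(Tn, D))))
  l$fwd <- function(x, train = TRUE) {
    stopifnot(dim(x)[1] == Tn, dim(x)[2] == D)
    l$cache <- dim(x)[3]
    x + array(rep(as.vector(l$par$pos), dim(x)[3]), dim(x))
  }
  l$bwd <- function(dy) {
    N <- l$cache
    l$cache <- NULL
    g <- dy
    dim(g) <- c(Tn * D, N)
    l$grad$pos <- l$grad$pos + array(rowSums(g), c(Tn, D))
    dy
  }
  l
}
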