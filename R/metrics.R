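#' Composite training loss
#'
#' `alpha * MSE(perm) + beta * MSE(edge)`: batch-mean squared error on the
#' main permittivity output plus a down-weighted squared error on the edge
#' auxiliary output.  Defaults `alpha = 1`, `beta = 0.01` reflect the
#' difference in task difficulty; a near-unity `beta` lets the auxiliary
#' task dominate and hurts the main inversion.
#'
#' @param perm_pred,perm_label Arrays of identical shape.
#' @param edge_pred,edge_label Arrays of identical shape (may be `NULL`
#'   for an ablated model; then only the main term is used).
#' @param alpha,beta Non-negative task weights.
#' @param grad If `TRUE`, also return the gradients w.r.t. the two
#'   predictions.
#' @return List with `value` (scalar), `main`, `edge` components and,
#'   when `grad = TRUE`, `dperm` and `dedge`.
#' @export
composite_loss <- function(perm_pred, perm_label, edge_pred = NULL,
                           edge_label = NULL, alpha = 1, beta = 0.01,
                           grad = FALSE) {
  stopifnot(alpha >= 0, beta >= 0)
  if (!identical(unname(dim(perm_pred)) %||% length(perm_pred),
                 unname(dim(perm_label)) %||% length(perm_label)))
    stop("shape mismatch between prediction and label", call. = FALSE)
  rp <- perm_pred - perm_label
  main <- mean(rp^2)
  edge <- 0
  re <- NULL
  if (!is.null(edge_pred) && !is.null(edge_label) && beta > 0) {
    if (!identical(unname(dim(edge_pred)) %||% length(edge_pred),
                   unname(dim(edge_label)) %||% length(edge_label)))
      stop("shape mismatch between edge prediction and label",
           call. = FALSE)
    re <- edge_pred - edge_label
    edge <- mean(re^2)
  }
  out <- list(value = alpha * main + beta * edge, main = main, edge = edge)
  if (grad) {
    out$dperm <- 2 * alpha * rp / length(rp)
    out$dedge <- if (!is.null(re)) 2 * beta * re / length(re)
  }
  out
}

#' Global-statistics structural similarity (SSIM)
#'
#' SSIM computed from whole-image means, variances and covariance (no
#' sliding window), with stabilizing constants `c1 = 0.01`, `c2 = 0.03`,
#' averaged over the batch:
#' `(2 mu_y mu_yh + c1)(2 cov + c2) / ((mu_y^2 + mu_yh^2 + c1)(var_y + var_yh + c2))`.
#' Equals 1 exactly when the two stacks are identical.  An 11 x 11
#' Gaussian-windowed variant is available via `window`.
#'
#' @param y,yhat Matrices or `(H, W, N)` / `(H, W, 1, N)` arrays in
#'   `[0, 1]`.
#' @param c1,c2 Stabilizing constants.
#' @param window `NULL` (global statistics, the default) or an odd window
#'   size for the local variant.
#' @return Scalar batch-mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(y, yhat, c1 = 0.01, c2 = 0.03, window = NULL) {
  ys <- .as_image_stack(y)
  yh <- .as_image_stack(yhat)
  stopifnot(identical(dim(ys), dim(yh)), length(ys) > 0)
  N <- dim(ys)[3]
  vals <- vapply(seq_len(N), function(n) {
    a <- ys[, , n]; b <- yh[, , n]
    if (is.null(window)) {
      mu1 <- mean(a); mu2 <- mean(b)
      v1 <- mean((a - mu1)^2); v2 <- mean((b - mu2)^2)
      cov <- mean((a - mu1) * (b - mu2))
      ((2 * mu1 * mu2 + c1) * (2 * cov + c2)) /
        ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2))
    } else {
      .ssim_windowed(a, b, c1, c2, window)
    }
  }, numeric(1))
  mean(vals)
}

.as_image_stack <- function(x) {
  if (is.matrix(x)) return(array(x, c(dim(x), 1)))
  d <- dim(x)
  if (length(d) == 4) {
    stopifnot(d[3] == 1)
    return(array(x, c(d[1], d[2], d[4])))
  }
  stopifnot(length(d) == 3)
  x
}

.ssim_windowed <- function(a, b, c1, c2, window) {
  stopifnot(window %% 2 == 1)
  g <- exp(-0.5 * ((seq_len(window) - (window + 1) / 2) / 1.5)^2)
  g <- g / sum(g)
  K <- outer(g, g)
  f <- function(m) .conv2_valid(m, K)
  mu1 <- f(a); mu2 <- f(b)
  s1 <- f(a * a) - mu1^2; s2 <- f(b * b) - mu2^2
  s12 <- f(a * b) - mu1 * mu2
  mean(((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
         ((mu1^2 + mu2^2 + c1) * (s1 + s2 + c2)))
}

.conv2_valid <- function(m, K) {
  k <- nrow(K)
  H <- nrow(m) - k + 1; W <- ncol(m) - k + 1
  out <- matrix(0, H, W)
  for (i in seq_len(k))
    for (j in seq_len(k))
      out <- out + K[i, j] * m[i:(i + H - 1), j:(j + W - 1)]
  out
}

#' Image-regression evaluation metrics
#'
#' Batch-mean MSE, MAE and global SSIM between predicted and true
#' normalized permittivity maps, with the conventional display scalings
#' (`mse_1e4 = 1e4 * mse`, `mae_1e2 = 1e2 * mae`) added.
#'
#' @param pred,truth Matrices or image stacks (see [ssim()]).
#' @return One-row tibble with `mse`, `mae`, `ssim`, `mse_1e4`,
#'   `mae_1e2`, `n`.
#' @export
image_metrics <- function(pred, truth) {
  p <- .as_image_stack(pred)
  t <- .as_image_stack(truth)
  stopifnot(identical(dim(p), dim(t)))
  mse <- mean((p - t)^2)
  mae <- mean(abs(p - t))
  tibble::tibble(mse = mse, mae = mae, ssim = ssim(p, t),
                 mse_1e4 = 1e4 * mse, mae_1e2 = 1e2 * mae,
                 n = dim(p)[3])
}
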