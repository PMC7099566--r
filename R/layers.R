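# From-scratch neural-network layers: valid 2-D convolution (as
# cross-correlation), batch normalization, sigmoid, 2x2 average pooling, and
# a fully-connected softmax classifier, each with analytic backward passes.
#
# Activation layout throughout: a 4-D array (H, W, N, C) -- spatial dims
# first, batch third, channels last. The convolution inner loops live in
# src/conv.cpp (the one hot spot of training); everything else is vectorized
# R.

#' Valid 2-D convolution, forward pass
#'
#' Cross-correlation (no kernel flip, the learned-filter convention) of a
#' batch with a bank of kernels at stride 1 and no padding: a `H x W` input
#' and `KH x KW` kernels give `(H-KH+1) x (W-KW+1)` feature maps, one per
#' kernel, with a per-kernel bias added.
#'
#' @param x Input batch, array `(H, W, N, C)`.
#' @param kernels Kernel bank, array `(KH, KW, C, K)`.
#' @param bias Numeric vector of length `K`.
#' @return List with `out` (array `(OH, OW, N, K)`) and `cache` for
#'   [conv2d_backward()].
#' @export
conv2d_forward <- function(x, kernels, bias) {
  d <- dim(x); kd <- dim(kernels)
  stopifnot(length(d) == 4L, length(kd) == 4L)
  if (kd[3] != d[4]) stopf("kernel channels (%d) != input channels (%d)", kd[3], d[4])
  if (kd[1] > d[1] || kd[2] > d[2]) stopf("kernel larger than input")
  if (length(bias) != kd[4]) stopf("need one bias per kernel")
  OH <- d[1] - kd[1] + 1L; OW <- d[2] - kd[2] + 1L
  xcol <- im2col_cpp(x, d, kd[1], kd[2])
  out <- xcol %*% matrix(kernels, ncol = kd[4])
  out <- out + rep(bias, each = nrow(xcol))
  dim(out) <- c(OH, OW, d[3], kd[4])
  list(out = out, cache = list(xcol = xcol, x_dim = d, kernels = kernels))
}

#' Valid 2-D convolution, backward pass
#'
#' @param dout Upstream gradient, array `(OH, OW, N, K)`.
#' @param cache Cache from [conv2d_forward()].
#' @param need_dx Set `FALSE` for the first layer, whose input gradient is
#'   never used, to skip the most expensive accumulation.
#' @return List with `dx` (gradient w.r.t. the input, or `NULL`),
#'   `dkernels`, `dbias`.
#' @export
conv2d_backward <- function(dout, cache, need_dx = TRUE) {
  if (is.null(cache$xcol)) stopf("missing forward cache")
  kd <- dim(cache$kernels); d <- cache$x_dim
  dmat <- matrix(dout, ncol = kd[4])        # (OH*OW*N) x K, same row order
  dkernels <- array(crossprod(cache$xcol, dmat), kd)
  dbias <- colSums(dmat)
  dx <- if (need_dx)
    array(col2im_cpp(tcrossprod(dmat, matrix(cache$kernels, ncol = kd[4])),
                     d, kd[1], kd[2]), d)
  list(dx = dx, dkernels = dkernels, dbias = dbias)
}

#' Batch normalization, forward pass
#'
#' Standardizes every channel by mean and variance, then applies the learned
#' per-channel affine transform `gamma * xhat + beta` (the "two extra
#' parameters per activation"). In training mode the statistics are those of
#' the current mini-batch (biased variance, over all spatial positions and
#' samples of a channel) and running statistics are updated by an exponential
#' moving average; in inference mode the running statistics are used, so the
#' output of one sample never depends on its batch companions.
#'
#' @param x Array `(H, W, N, C)` (or a `N x C` matrix for dense layers).
#' @param gamma,beta Per-channel scale and shift, length `C`.
#' @param running_mean,running_var Running statistics, length `C`.
#' @param mode `"train"` or `"infer"`.
#' @param eps Variance floor, default `1e-5`.
#' @param momentum Running-average retention, default 0.9.
#' @return List with `out`, updated `running_mean`/`running_var`, and `cache`
#'   (train mode) for [batchnorm_backward()].
#' @export
batchnorm_forward <- function(x, gamma, beta, running_mean, running_var,
                              mode = c("train", "infer"), eps = 1e-5,
                              momentum = 0.9) {
  mode <- match.arg(mode)
  d <- dim(x)
  C <- d[length(d)]
  stopifnot(length(gamma) == C, length(beta) == C)
  n_batch <- if (length(d) == 4L) d[3] else d[1]
  if (mode == "train") {
    if (n_batch < 2L) stopf("batch normalization needs a batch of >= 2 in training mode")
    r <- bn_fwd_cpp(x, C, as.numeric(gamma), as.numeric(beta), eps)
    out <- r$out
    dim(out) <- d
    list(out = out,
         running_mean = momentum * running_mean + (1 - momentum) * r$mu,
         running_var = momentum * running_var + (1 - momentum) * r$var,
         cache = list(xhat = r$xhat, inv_sd = r$inv_sd, gamma = gamma, dim = d))
  } else {
    out <- bn_infer_cpp(x, C, as.numeric(running_mean), as.numeric(running_var),
                        as.numeric(gamma), as.numeric(beta), eps)
    dim(out) <- d
    list(out = out, running_mean = running_mean,
         running_var = running_var, cache = NULL)
  }
}

#' Batch normalization, backward pass
#'
#' @param dout Upstream gradient, same shape as the forward input.
#' @param cache Cache from a training-mode [batchnorm_forward()].
#' @return List with `dx`, `dgamma`, `dbeta`.
#' @export
batchnorm_backward <- function(dout, cache) {
  if (is.null(cache)) stopf("missing forward cache (was forward run in train mode?)")
  d <- cache$dim
  C <- d[length(d)]
  # dx = inv_sd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  r <- bn_bwd_cpp(dout, cache$xhat, cache$inv_sd, as.numeric(cache$gamma))
  dx <- r$dx
  dim(dx) <- d
  list(dx = dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

#' Numerically stable logistic sigmoid
#'
#' `1 / (1 + exp(-x))` elementwise, computed without overflow for large
#' `|x|` (saturates cleanly to 0 and 1).
#'
#' @param x Numeric array.
#' @return Values in `(0, 1)`, same shape as `x`.
#' @export
sigmoid <- function(x) {
  # IEEE-safe: exp(-x) overflows to Inf for very negative x and 1/(1+Inf)
  # is exactly 0; underflow to 0 gives exactly 1.
  out <- sigmoid_cpp(x)
  attributes(out) <- attributes(x)
  out
}

#' Sigmoid backward pass
#' @param dout Upstream gradient.
#' @param out The forward output `sigmoid(x)`.
#' @return Gradient w.r.t. `x`: `dout * out * (1 - out)`.
#' @export
sigmoid_backward <- function(dout, out) {
  dx <- sigmoid_bwd_cpp(dout, out)
  attributes(dx) <- attributes(dout)
  dx
}

#' 2x2 average pooling, forward pass
#'
#' Non-overlapping 2x2 windows, each replaced by the mean of its four
#' entries; spatial dimensions must be even and are halved.
#'
#' @param x Array `(H, W, N, C)` with even `H`, `W`.
#' @return Array `(H/2, W/2, N, C)`.
#' @export
avgpool_forward <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stopf("average pooling requires even spatial dimensions, got %dx%d", d[1], d[2])
  out <- pool_fwd_cpp(x, d)
  dim(out) <- c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4])
  out
}

#' 2x2 average pooling, backward pass
#' @param dout Upstream gradient, array `(H/2, W/2, N, C)`.
#' @return Gradient w.r.t. the input: each input cell of a window receives a
#'   quarter of the window's upstream gradient.
#' @export
avgpool_backward <- function(dout) {
  d <- dim(dout)
  dx <- pool_bwd_cpp(dout, d)
  dim(dx) <- c(2L * d[1], 2L * d[2], d[3], d[4])
  dx
}

#' Fully-connected layer with softmax output
#'
#' Affine map of flattened features to two class logits followed by a
#' shift-invariant softmax. Output column 1 is the malignant probability,
#' column 2 benign, matching the one-hot convention (1,0) = malignant.
#'
#' @param features `N x F` matrix.
#' @param weights `F x 2` matrix.
#' @param bias Length-2 vector.
#' @return List with `probs` (`N x 2`, rows sum to 1), `logits`, and `cache`.
#' @export
fc_softmax_forward <- function(features, weights, bias) {
  if (ncol(features) != nrow(weights))
    stopf("feature length %d does not match weight rows %d",
          ncol(features), nrow(weights))
  logits <- sweep(features %*% weights, 2L, bias, `+`)
  shifted <- logits - apply(logits, 1L, max)
  e <- exp(shifted)
  probs <- e / rowSums(e)
  list(probs = probs, logits = logits,
       cache = list(features = features, weights = weights))
}

#' Fully-connected layer backward pass
#' @param dlogits Gradient w.r.t. the logits, `N x 2`.
#' @param cache Cache from [fc_softmax_forward()].
#' @return List with `dfeatures`, `dweights`, `dbias`.
#' @export
fc_backward <- function(dlogits, cache) {
  if (is.null(cache$features)) stopf("missing forward cache")
  list(dfeatures = dlogits %*% t(cache$weights),
       dweights = crossprod(cache$features, dlogits),
       dbias = colSums(dlogits))
}

#' Softmax cross-entropy loss and logit gradient
#'
#' Mean negative log-probability of the true class, with the probability
#' clamped at `eps` so a confidently wrong prediction yields a finite loss.
#' The gradient w.r.t. the logits is `(probs - one_hot) / N`.
#'
#' @param probs `N x 2` softmax outputs (rows sum to 1).
#' @param one_hot `N x 2` one-hot true labels.
#' @param eps Probability clamp, default `1e-12`.
#' @return List with `loss` (scalar) and `dlogits`.
#' @export
cross_entropy_loss <- function(probs, one_hot, eps = 1e-12) {
  stopifnot(all(dim(probs) == dim(one_hot)))
  p_true <- rowSums(probs * one_hot)
  list(loss = -mean(log(pmax(p_true, eps))),
       dlogits = (probs - one_hot) / nrow(probs))
}
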