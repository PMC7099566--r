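# The full network: two convolution -> batch-norm -> sigmoid -> average-pool
# blocks followed by a fully-connected softmax classifier.
#
# Shape chain (asserted at construction):
#   32x32x1 -> conv 6@5x5 -> 28x28x6 -> pool -> 14x14x6
#           -> conv 12@5x5 -> 10x10x12 -> pool -> 5x5x12 = 300 -> 2

NET_INPUT <- 32L
NET_SHAPE_CHAIN <- c(32L, 28L, 14L, 10L, 5L)
NET_FEATURES <- 300L

#' Initialize network parameters
#'
#' Kernels and fully-connected weights are drawn from a uniform distribution
#' scaled by fan-in, `U(-sqrt(3/fan_in), +sqrt(3/fan_in))` (unit-variance
#' preactivations, keeping the sigmoids out of saturation at the start);
#' biases start at 0, batch-norm at the identity (gamma 1, beta 0, running
#' mean 0, running variance 1). Deterministic for a given seed. The layer
#' shape chain 32 -> 28 -> 14 -> 10 -> 5 -> 300 -> 2 is asserted here.
#'
#' @param seed Integer seed.
#' @return A `network_params` list: `conv1`, `bn1`, `conv2`, `bn2`, `fc`.
#' @export
init_params <- function(seed = 1L) {
  stopifnot((NET_INPUT - 5L + 1L) == 28L, 28L %/% 2L == 14L,
            (14L - 5L + 1L) == 10L, 10L %/% 2L == 5L,
            5L * 5L * 12L == NET_FEATURES)
  unif <- function(n, fan_in) stats::runif(n, -sqrt(3 / fan_in), sqrt(3 / fan_in))
  with_seed(seed, {
    p <- list(
      conv1 = list(W = array(unif(5 * 5 * 1 * 6, 5 * 5 * 1), c(5L, 5L, 1L, 6L)),
                   b = numeric(6L)),
      bn1 = list(gamma = rep(1, 6L), beta = numeric(6L),
                 running_mean = numeric(6L), running_var = rep(1, 6L)),
      conv2 = list(W = array(unif(5 * 5 * 6 * 12, 5 * 5 * 6), c(5L, 5L, 6L, 12L)),
                   b = numeric(12L)),
      bn2 = list(gamma = rep(1, 12L), beta = numeric(12L),
                 running_mean = numeric(12L), running_var = rep(1, 12L)),
      fc = list(W = matrix(unif(NET_FEATURES * 2L, NET_FEATURES),
                           NET_FEATURES, 2L),
                b = numeric(2L))
    )
    class(p) <- "network_params"
    p
  })
}

# Flatten (5, 5, N, 12) activations to an N x 300 feature matrix; the
# inverse is unflatten_features. Feature order (h, w, channel) is an internal
# convention, consistent between the two.
flatten_features <- function(x) {
  d <- dim(x)
  t(matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = d[3]))
}

unflatten_features <- function(f, d) {
  aperm(array(t(f), c(d[1], d[2], d[4], d[3])), c(1L, 2L, 4L, 3L))
}

#' Full network forward pass
#'
#' @param params A `network_params` object.
#' @param images Batch of inputs: array `(32, 32, N)` or `(32, 32, N, 1)`.
#' @param mode `"train"` (batch statistics, cache kept, running statistics
#'   returned updated) or `"infer"` (running statistics, no cache; the output
#'   for one image is independent of its batch companions).
#' @return List with `probs` (`N x 2`, column 1 = malignant), `params`
#'   (running statistics updated in train mode), and `cache` (train mode).
#' @export
net_forward <- function(params, images, mode = c("train", "infer")) {
  mode <- match.arg(mode)
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  d <- dim(images)
  if (d[1] != NET_INPUT || d[2] != NET_INPUT || d[4] != 1L)
    stopf("expected %dx%dx N x1 input, got %s", NET_INPUT, NET_INPUT,
          paste(d, collapse = "x"))
  c1 <- conv2d_forward(images, params$conv1$W, params$conv1$b)
  b1 <- batchnorm_forward(c1$out, params$bn1$gamma, params$bn1$beta,
                          params$bn1$running_mean, params$bn1$running_var, mode)
  s1 <- sigmoid(b1$out)
  p1 <- avgpool_forward(s1)
  c2 <- conv2d_forward(p1, params$conv2$W, params$conv2$b)
  b2 <- batchnorm_forward(c2$out, params$bn2$gamma, params$bn2$beta,
                          params$bn2$running_mean, params$bn2$running_var, mode)
  s2 <- sigmoid(b2$out)
  p2 <- avgpool_forward(s2)
  feats <- flatten_features(p2)
  fc <- fc_softmax_forward(feats, params$fc$W, params$fc$b)
  params$bn1$running_mean <- b1$running_mean
  params$bn1$running_var <- b1$running_var
  params$bn2$running_mean <- b2$running_mean
  params$bn2$running_var <- b2$running_var
  cache <- if (mode == "train")
    list(c1 = c1$cache, b1 = b1$cache, s1 = s1, c2 = c2$cache, b2 = b2$cache,
         s2 = s2, p2_dim = dim(p2), fc = fc$cache)
  list(probs = fc$probs, params = params, cache = cache)
}

#' Full network backward pass
#'
#' @param dlogits Gradient of the loss w.r.t. the two output logits (`N x 2`,
#'   e.g. from [cross_entropy_loss()]).
#' @param cache Cache from a training-mode [net_forward()].
#' @return Gradients with the same structure as `network_params` (batch-norm
#'   running statistics excluded; they are not learned by gradient).
#' @export
net_backward <- function(dlogits, cache) {
  if (is.null(cache)) stopf("missing forward cache (run net_forward in train mode)")
  fcb <- fc_backward(dlogits, cache$fc)
  g <- avgpool_backward(unflatten_features(fcb$dfeatures, cache$p2_dim))
  g <- sigmoid_backward(g, cache$s2)
  b2 <- batchnorm_backward(g, cache$b2)
  c2 <- conv2d_backward(b2$dx, cache$c2)
  g <- avgpool_backward(c2$dx)
  g <- sigmoid_backward(g, cache$s1)
  b1 <- batchnorm_backward(g, cache$b1)
  c1 <- conv2d_backward(b1$dx, cache$c1, need_dx = FALSE)
  list(conv1 = list(W = c1$dkernels, b = c1$dbias),
       bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
       conv2 = list(W = c2$dkernels, b = c2$dbias),
       bn2 = list(gamma = b2$dgamma, beta = b2$dbeta),
       fc = list(W = fcb$dweights, b = fcb$dbias))
}

# One-hot encoding: column 1 = malignant (1,0), column 2 = benign (0,1).
one_hot_labels <- function(labels) {
  labels <- as.character(labels)
  cbind(malignant = as.numeric(labels == "malignant"),
        benign = as.numeric(labels == "benign"))
}
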