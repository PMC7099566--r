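test_that("convolution output shapes follow valid-convolution arithmetic", {
  x <- array(0, c(32, 32, 3, 1))
  K <- array(0, c(5, 5, 1, 6))
  out <- conv2d_forward(x, K, rep(2.5, 6))$out
  expect_identical(dim(out), c(28L, 28L, 3L, 6L))
  # all-zero kernels with bias b give a constant-b map
  expect_true(all(out == 2.5))
  expect_error(conv2d_forward(x, array(0, c(5, 5, 2, 6)), numeric(6)),
               "channels")
  expect_error(conv2d_forward(array(0, c(3, 3, 1, 1)), K, numeric(6)),
               "larger")
})

test_that("convolution forward matches a four-nested-loop brute-force oracle", {
  set.seed(10)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  K <- array(rnorm(5 * 5 * 2 * 4), c(5, 5, 2, 4))
  b <- rnorm(4)
  out <- conv2d_forward(x, K, b)$out
  oracle <- array(NA_real_, c(4, 4, 3, 4))
  for (n in 1:3) for (k in 1:4) for (i in 1:4) for (j in 1:4) {
    s <- b[k]
    for (c in 1:2) for (p in 1:5) for (q in 1:5)
      s <- s + x[i + p - 1, j + q - 1, n, c] * K[p, q, c, k]
    oracle[i, j, n, k] <- s
  }
  expect_lt(max(abs(out - oracle)), 1e-10)
})

test_that("convolution backward matches central-difference gradients", {
  set.seed(11)
  x <- array(rnorm(7 * 6 * 2 * 2), c(7, 6, 2, 2))
  K <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  fwd <- conv2d_forward(x, K, b)
  dout <- array(rnorm(length(fwd$out)), dim(fwd$out))
  g <- conv2d_backward(dout, fwd$cache)
  obj_x <- function(xx) sum(conv2d_forward(xx, K, b)$out * dout)
  obj_k <- function(kk) sum(conv2d_forward(x, kk, b)$out * dout)
  obj_b <- function(bb) sum(conv2d_forward(x, K, bb)$out * dout)
  expect_lt(max(grad_rel_err(g$dx, numeric_grad(obj_x, x))), 1e-5)
  expect_lt(max(grad_rel_err(g$dkernels, numeric_grad(obj_k, K))), 1e-5)
  expect_lt(max(grad_rel_err(g$dbias, numeric_grad(obj_b, b))), 1e-5)
  expect_error(conv2d_backward(dout, list()), "cache")
})

test_that("batch normalization standardizes in train mode and is affine-correct", {
  set.seed(12)
  x <- array(rnorm(6 * 6 * 5 * 3, mean = 4, sd = 2), c(6, 6, 5, 3))
  f <- batchnorm_forward(x, gamma = rep(1, 3), beta = rep(0, 3),
                         running_mean = numeric(3), running_var = rep(1, 3),
                         mode = "train")
  m <- matrix(f$out, ncol = 3)
  expect_lt(max(abs(colMeans(m))), 1e-12)
  # biased variance ~ 1 up to the eps effect
  expect_lt(max(abs(colMeans(m^2) - 1)), 1e-3)
  # gamma 2, beta 3 on the same input: mean 3, variance ~ 4
  f2 <- batchnorm_forward(x, gamma = rep(2, 3), beta = rep(3, 3),
                          running_mean = numeric(3), running_var = rep(1, 3),
                          mode = "train")
  m2 <- matrix(f2$out, ncol = 3)
  expect_lt(max(abs(colMeans(m2) - 3)), 1e-12)
  expect_lt(max(abs(colMeans(sweep(m2, 2, colMeans(m2))^2) - 4)), 4e-3)
  # two-pass statistics oracle
  mu_o <- apply(x, 4, mean)
  var_o <- apply(x, 4, function(ch) mean((ch - mean(ch))^2))
  xhat_o <- array(NA_real_, dim(x))
  for (c in 1:3) xhat_o[, , , c] <- (x[, , , c] - mu_o[c]) / sqrt(var_o[c] + 1e-5)
  expect_lt(max(abs(f$out - xhat_o)), 1e-10)
  # running statistics move toward the batch statistics
  expect_equal(f$running_mean, 0.9 * 0 + 0.1 * mu_o, tolerance = 1e-12)
  expect_equal(f$running_var, 0.9 * 1 + 0.1 * var_o, tolerance = 1e-12)
})

test_that("batch normalization rejects singleton batches and honours inference mode", {
  x1 <- array(rnorm(4 * 4 * 1 * 2), c(4, 4, 1, 2))
  expect_error(batchnorm_forward(x1, rep(1, 2), rep(0, 2), numeric(2),
                                 rep(1, 2), mode = "train"), "batch")
  # inference mode uses the provided running stats, ignoring batch makeup
  rm_ <- c(1, -2); rv_ <- c(4, 9)
  f <- batchnorm_forward(x1, rep(1, 2), rep(0, 2), rm_, rv_, mode = "infer")
  expected <- array(NA_real_, dim(x1))
  for (c in 1:2) expected[, , , c] <- (x1[, , , c] - rm_[c]) / sqrt(rv_[c] + 1e-5)
  expect_equal(f$out, expected, tolerance = 1e-12)
})

test_that("batch normalization backward matches central differences", {
  set.seed(13)
  x <- array(rnorm(3 * 3 * 4 * 2), c(3, 3, 4, 2))
  gamma <- rnorm(2, 1, 0.2); beta <- rnorm(2)
  fwd <- batchnorm_forward(x, gamma, beta, numeric(2), rep(1, 2), "train")
  dout <- array(rnorm(length(fwd$out)), dim(fwd$out))
  g <- batchnorm_backward(dout, fwd$cache)
  obj <- function(xx, gg = gamma, bb = beta)
    sum(batchnorm_forward(xx, gg, bb, numeric(2), rep(1, 2), "train")$out * dout)
  expect_lt(max(grad_rel_err(g$dx, numeric_grad(obj, x))), 1e-5)
  expect_lt(max(grad_rel_err(g$dgamma,
    numeric_grad(function(gg) obj(x, gg = gg), gamma))), 1e-5)
  expect_lt(max(grad_rel_err(g$dbeta,
    numeric_grad(function(bb) obj(x, bb = bb), beta))), 1e-5)
  expect_error(batchnorm_backward(dout, NULL), "cache")
})

test_that("sigmoid satisfies its symmetry, saturation and derivative contracts", {
  expect_equal(sigmoid(0), 0.5)
  x <- rnorm(50)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, 50), tolerance = 1e-12)
  # extreme inputs saturate without overflow/NaN
  expect_identical(sigmoid(500), 1)
  expect_equal(sigmoid(-500), 0, tolerance = 1e-200)
  expect_identical(sigmoid(-800), 0)   # beyond exp overflow: 1/(1+Inf)
  expect_equal(sigmoid_backward(1, sigmoid(0)), 0.25)
  # derivative against central differences
  num <- numeric_grad(function(z) sigmoid(z), 0.3)
  expect_lt(abs(sigmoid_backward(1, sigmoid(0.3)) - num), 1e-8)
})

test_that("average pooling means 2x2 windows and distributes gradient evenly", {
  x <- array(0, c(2, 2, 1, 1)); x[, , 1, 1] <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(as.vector(avgpool_forward(x)), 2.5)
  cmap <- array(7, c(28, 28, 2, 3))
  pooled <- avgpool_forward(cmap)
  expect_identical(dim(pooled), c(14L, 14L, 2L, 3L))
  expect_true(all(pooled == 7))
  expect_error(avgpool_forward(array(0, c(5, 4, 1, 1))), "even")
  g <- avgpool_backward(array(2, c(2, 2, 1, 1)))
  expect_true(all(g == 0.5))  # each input cell receives g/4
  # adjoint check: <pool(x), y> == <x, pool_backward(y)>
  set.seed(14)
  x <- array(rnorm(8 * 6 * 2 * 2), c(8, 6, 2, 2))
  y <- array(rnorm(4 * 3 * 2 * 2), c(4, 3, 2, 2))
  expect_equal(sum(avgpool_forward(x) * y), sum(x * avgpool_backward(y)),
               tolerance = 1e-12)
})

test_that("softmax layer is correct, shift-invariant and matches an exp-normalize oracle", {
  f0 <- fc_softmax_forward(matrix(0, 3, 300), matrix(0, 300, 2), c(0, 0))
  expect_equal(f0$probs, matrix(0.5, 3, 2), ignore_attr = TRUE)
  set.seed(15)
  feats <- matrix(rnorm(4 * 300), 4, 300)
  W <- matrix(rnorm(600, sd = 0.1), 300, 2); b <- rnorm(2)
  f <- fc_softmax_forward(feats, W, b)
  expect_equal(rowSums(f$probs), rep(1, 4), tolerance = 1e-12)
  oracle <- t(apply(feats %*% W + rep(b, each = 4), 1,
                    function(l) exp(l) / sum(exp(l))))
  expect_lt(max(abs(f$probs - oracle)), 1e-12)
  # shifting both logits leaves probabilities unchanged
  f_shift <- fc_softmax_forward(feats, W, b + 13.7)
  expect_equal(f_shift$probs, f$probs, tolerance = 1e-9)
  expect_error(fc_softmax_forward(matrix(0, 3, 10), W, b), "match")
})

test_that("cross-entropy loss and logit gradient are correct", {
  perfect <- cross_entropy_loss(matrix(c(1, 0), 1), matrix(c(1, 0), 1))
  expect_equal(perfect$loss, 0)
  uniform <- cross_entropy_loss(matrix(0.5, 3, 2),
                                cbind(c(1, 0, 1), c(0, 1, 0)))
  expect_equal(uniform$loss, log(2))
  # gradient vs central differences through softmax + loss
  set.seed(16)
  logits <- matrix(rnorm(8), 4, 2)
  onehot <- cbind(c(1, 0, 0, 1), c(0, 1, 1, 0))
  loss_of <- function(l) {
    l <- matrix(l, 4, 2)
    p <- exp(l) / rowSums(exp(l))
    cross_entropy_loss(p, onehot)$loss
  }
  p <- exp(logits) / rowSums(exp(logits))
  ana <- cross_entropy_loss(p, onehot)$dlogits
  num <- numeric_grad(loss_of, as.vector(logits))
  expect_lt(max(grad_rel_err(as.vector(ana), num)), 1e-6)
})

test_that("parameter initialization is seeded, fan-in bounded, with identity batch norm", {
  p1 <- init_params(42); p2 <- init_params(42); p3 <- init_params(43)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  expect_true(all(p1$bn1$gamma == 1) && all(p1$bn2$gamma == 1))
  expect_true(all(p1$bn1$beta == 0) && all(p1$conv1$b == 0))
  expect_true(all(abs(p1$conv1$W) <= sqrt(3 / 25)))
  expect_true(all(abs(p1$conv2$W) <= sqrt(3 / 150)))
  expect_true(all(abs(p1$fc$W) <= sqrt(3 / 300)))
})

test_that("the architecture realizes the 32-28-14-10-5-300-2 shape chain", {
  p <- init_params(1)
  expect_identical(dim(p$conv1$W), c(5L, 5L, 1L, 6L))
  expect_identical(dim(p$conv2$W), c(5L, 5L, 6L, 12L))
  expect_identical(dim(p$fc$W), c(300L, 2L))
  imgs <- array(runif(32 * 32 * 3), c(32, 32, 3))
  fwd <- net_forward(p, imgs, mode = "infer")
  expect_identical(dim(fwd$probs), c(3L, 2L))
  expect_equal(rowSums(fwd$probs), rep(1, 3), tolerance = 1e-12)
  expect_error(net_forward(p, array(0, c(16, 16, 3)), mode = "infer"),
               "32x32")
})

test_that("full-network backpropagation matches numerical gradients on a small batch", {
  set.seed(17)
  imgs <- array(runif(32 * 32 * 4), c(32, 32, 4))
  onehot <- dotcad:::one_hot_labels(c("malignant", "benign", "malignant", "benign"))
  p <- init_params(7)
  fwd <- net_forward(p, imgs, mode = "train")
  grads <- net_backward(cross_entropy_loss(fwd$probs, onehot)$dlogits, fwd$cache)
  loss_at <- function(pp)
    cross_entropy_loss(net_forward(pp, imgs, mode = "train")$probs, onehot)$loss
  worst <- 0
  for (layer in names(grads)) for (leaf in names(grads[[layer]])) {
    arr <- p[[layer]][[leaf]]
    idx <- sample(length(arr), min(10L, length(arr)))
    num <- numeric_grad(function(v) {
      pp <- p; pp[[layer]][[leaf]] <- v; loss_at(pp)
    }, arr, eps = 1e-5, idx = idx)
    worst <- max(worst, grad_rel_err(grads[[layer]][[leaf]][idx], num))
  }
  expect_lt(worst, 1e-4)
})

test_that("inference output is independent of batch composition", {
  set.seed(18)
  p <- init_params(3)
  imgs <- array(runif(32 * 32 * 5), c(32, 32, 5))
  solo <- predict_network(p, imgs[, , 2, drop = FALSE])
  batch <- predict_network(p, imgs)
  # equal up to BLAS summation order (kernel choice varies with batch size)
  expect_equal(solo$score, batch$score[2], tolerance = 1e-12)
})
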