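# Mini-batch SGD-with-momentum training with early stopping on a monitored
# misclassification rate (MCR), restoring the best-epoch weights.

#' Training configuration
#'
#' Defaults follow the published recipe: learning rate 0.3, mini-batch size
#' 83, at most 500 epochs, classical momentum 0.9, and early stopping after
#' 100 epochs without improvement of the monitored MCR. The patience must
#' span the large noise excursions of a per-epoch MCR measured on a few
#' hundred images under this high learning rate: a short patience stops at
#' early fluctuation minima long before the documented convergence horizon
#' of roughly 200 epochs.
#'
#' @param learning_rate Positive SGD step size.
#' @param batch_size Images per mini-batch (>= 2; batch normalization needs
#'   at least two samples).
#' @param max_epochs Epoch cap (>= 1).
#' @param momentum Velocity retention coefficient in `[0, 1)`.
#' @param patience Epochs without monitored-MCR improvement before stopping.
#' @param seed Seed for parameter initialization and epoch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.3, batch_size = 83L,
                         max_epochs = 500L, momentum = 0.9,
                         patience = 100L, seed = 1L) {
  if (!(learning_rate > 0)) stopf("learning_rate must be positive")
  if (!(is_count(batch_size) && batch_size >= 2L))
    stopf("batch_size must be an integer >= 2")
  if (!(is_count(max_epochs) && max_epochs >= 1L))
    stopf("max_epochs must be an integer >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 momentum = momentum, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Map a function over every numeric leaf of a nested parameter list,
# preserving structure. Used for SGD updates and velocity initialization.
map_leaves <- function(f, a, b = NULL, c = NULL) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a))
      out[[nm]] <- map_leaves(f, a[[nm]],
                              if (!is.null(b)) b[[nm]],
                              if (!is.null(c)) c[[nm]])
    out
  } else if (is.null(b)) f(a) else f(a, b, c)
}

#' One SGD-with-momentum update
#'
#' Classical momentum for every parameter array:
#' `v <- momentum * v - learning_rate * g; p <- p + v`.
#' Applied only to learnable leaves (`grads` carries no entries for
#' batch-norm running statistics, which are left untouched).
#'
#' @param params `network_params`.
#' @param grads Gradients with the structure returned by [net_backward()].
#' @param velocity Velocity state with the structure of `grads` (use
#'   [zero_velocity()] to start).
#' @param learning_rate,momentum Scalars.
#' @return List with updated `params` and `velocity`.
#' @export
sgd_momentum_step <- function(params, grads, velocity, learning_rate,
                              momentum) {
  velocity <- map_leaves(function(v, g, ...) {
    if (!all(dim(v) %||% length(v) == (dim(g) %||% length(g))))
      stopf("velocity/gradient shape mismatch")
    momentum * v - learning_rate * g
  }, velocity, grads)
  for (layer in names(velocity))
    for (leaf in names(velocity[[layer]]))
      params[[layer]][[leaf]] <- params[[layer]][[leaf]] +
        velocity[[layer]][[leaf]]
  list(params = params, velocity = velocity)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Zero-initialized velocity matching a gradient structure
#' @param params `network_params`.
#' @return Nested list of zero arrays over the learnable leaves.
#' @export
zero_velocity <- function(params) {
  list(conv1 = list(W = array(0, dim(params$conv1$W)), b = numeric(length(params$conv1$b))),
       bn1 = list(gamma = numeric(length(params$bn1$gamma)), beta = numeric(length(params$bn1$beta))),
       conv2 = list(W = array(0, dim(params$conv2$W)), b = numeric(length(params$conv2$b))),
       bn2 = list(gamma = numeric(length(params$bn2$gamma)), beta = numeric(length(params$bn2$beta))),
       fc = list(W = array(0, dim(params$fc$W)), b = numeric(length(params$fc$b))))
}

#' Train the network with early stopping on a monitored MCR
#'
#' Each epoch the training set is reshuffled (seeded), consumed in
#' mini-batches (a final short batch is kept when it has at least two images,
#' otherwise dropped), and the misclassification rate on `monitor_set` is
#' evaluated in inference mode. Training stops at `max_epochs` or once
#' `patience` epochs pass without a strict improvement of the monitored MCR;
#' the returned parameters are those of the best epoch (ties: earliest).
#' Monitoring the test set mirrors the published protocol but is leaky --
#' pass a held-out validation split for honest model selection.
#'
#' @param params Initial `network_params` (e.g. [init_params()]).
#' @param train_set,monitor_set Non-empty `slice_dataset`s.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress every 25 epochs.
#' @return List with `params` (best epoch), `history` (data frame: `epoch`,
#'   `loss`, `train_mcr`, `monitor_mcr`), `best_epoch`, `stopped_early`.
#' @export
train_network <- function(params, train_set, monitor_set,
                          config = train_config(), verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (n_images(train_set) == 0L || n_images(monitor_set) == 0L)
    stopf("training and monitor sets must be non-empty")
  n <- n_images(train_set)
  one_hot <- one_hot_labels(train_set$meta$label)
  truth_train <- as.character(train_set$meta$label)
  truth_mon <- as.character(monitor_set$meta$label)
  velocity <- zero_velocity(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        train_mcr = numeric(0), monitor_mcr = numeric(0))
  best_mcr <- Inf; best_epoch <- 0L; best_params <- params
  stopped_early <- FALSE

  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, config$batch_size)
      epoch_loss <- 0; n_seen <- 0L; n_wrong <- 0L
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        if (length(idx) < 2L) next   # drop a singleton tail batch
        fwd <- net_forward(params, train_set$images[, , idx, drop = FALSE],
                           mode = "train")
        params <- fwd$params
        ce <- cross_entropy_loss(fwd$probs, one_hot[idx, , drop = FALSE])
        grads <- net_backward(ce$dlogits, fwd$cache)
        upd <- sgd_momentum_step(params, grads, velocity,
                                 config$learning_rate, config$momentum)
        params <- upd$params; velocity <- upd$velocity
        pred <- ifelse(fwd$probs[, 1L] > 0.5, "malignant", "benign")
        n_wrong <- n_wrong + sum(pred != truth_train[idx])
        n_seen <- n_seen + length(idx)
        epoch_loss <- epoch_loss + ce$loss * length(idx)
      }
      mon <- predict_network(params, monitor_set)
      mon_mcr <- mean(mon$label != truth_mon)
      history[epoch, ] <- list(epoch, epoch_loss / n_seen,
                               n_wrong / n_seen, mon_mcr)
      if (mon_mcr < best_mcr) {
        best_mcr <- mon_mcr; best_epoch <- epoch; best_params <- params
      }
      if (verbose && epoch %% 25L == 0L)
        message(sprintf("epoch %4d  loss %.4f  train MCR %.3f  monitor MCR %.3f",
                        epoch, epoch_loss / n_seen, n_wrong / n_seen, mon_mcr))
      if (epoch - best_epoch >= config$patience) {
        stopped_early <- TRUE
        break
      }
    }
  })
  list(params = best_params, history = history, best_epoch = best_epoch,
       stopped_early = stopped_early)
}

#' Inference-mode prediction
#'
#' Forward pass using batch-norm running statistics, processed in chunks, so
#' a score depends only on the parameters and the image. The malignant-class
#' softmax probability is the score; the hard label is the argmax with ties
#' (score exactly 0.5) resolved to benign.
#'
#' @param params Trained `network_params`.
#' @param images A `slice_dataset` or a `(32, 32, N)` array.
#' @param chunk Images per forward pass (memory control).
#' @return Data frame with `score` (malignant probability) and `label`.
#' @export
predict_network <- function(params, images, chunk = 512L) {
  if (inherits(images, "slice_dataset")) images <- images$images
  if (length(dim(images)) == 2L) dim(images) <- c(dim(images), 1L)
  n <- dim(images)[3]
  scores <- numeric(n)
  for (s in seq(1L, n, chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    fwd <- net_forward(params, images[, , idx, drop = FALSE], mode = "infer")
    scores[idx] <- fwd$probs[, 1L]
  }
  data.frame(score = scores,
             label = ifelse(scores > 0.5, "malignant", "benign"))
}
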