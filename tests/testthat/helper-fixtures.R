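# Shared fixtures: all test data is generated in code at run time.

# A small, fast phantom configuration for module tests (the full-size grid
# is exercised in the acceptance suite).
small_phantom_config <- function(psf_sigma_mm = 4, ...) {
  phantom_config(grid_shape = c(25L, 25L, 14L), tumor_z_range = c(4L, 11L),
                 psf_sigma_mm = psf_sigma_mm, ...)
}

# Linearly separable toy image set: malignant images carry a bright central
# square on a dim noisy background, benign ones a dark center on a brighter
# surround. Values already in [0, 1].
make_toy_dataset <- function(n_per_class = 20L, seed = 1L) {
  n <- 2L * n_per_class
  images <- array(0, c(32L, 32L, n))
  labels <- rep(c("benign", "malignant"), each = n_per_class)
  ctr <- 9:24
  dotcad:::with_seed(seed, {
    for (i in seq_len(n)) {
      img <- matrix(stats::runif(32 * 32, 0, 0.15), 32L, 32L)
      if (labels[i] == "malignant") img[ctr, ctr] <- img[ctr, ctr] + 0.8
      else img <- img + 0.4
      images[, , i] <- pmin(img, 1)
    }
  })
  dotcad:::new_slice_dataset(images,
    data.frame(patient_id = sprintf("T%03d", seq_len(n)), label = labels,
               z_index = 1L))
}

# Dataset of blank images with prescribed class counts, for split/count
# checks where pixel content is irrelevant.
make_count_dataset <- function(n_benign, n_malignant) {
  n <- n_benign + n_malignant
  dotcad:::new_slice_dataset(array(0, c(32L, 32L, n)),
    data.frame(patient_id = sprintf("C%04d", seq_len(n)),
               label = rep(c("benign", "malignant"), c(n_benign, n_malignant)),
               z_index = rep(1L, n)))
}

# Relative error with an absolute floor: gradients that are analytically
# (near-)zero -- e.g. convolution biases, which batch normalization cancels
# exactly -- are compared on an absolute scale instead of amplifying
# round-off noise.
grad_rel_err <- function(analytic, numeric, floor = 1e-6) {
  abs(analytic - numeric) / pmax(abs(analytic), abs(numeric), floor)
}

# Central-difference gradient of scalar-valued f at x, elementwise.
numeric_grad <- function(f, x, eps = 1e-6, idx = seq_along(x)) {
  g <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[j] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# O(n^2) Mann-Whitney AUC oracle: pairwise comparisons with half credit for
# ties, independent of the threshold-sweep implementation.
mann_whitney_auc <- function(scores, truth) {
  pos <- scores[truth == "malignant"]
  neg <- scores[truth == "benign"]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
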