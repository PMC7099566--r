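#' @keywords internal
#' @useDynLib dotcad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Derive child seeds from a parent seed, all < 2^31, deterministically.
derive_seeds <- function(seed, n) {
  if (n == 0L) return(integer(0))
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L &&
  is.finite(x) && x >= 0 && x == as.integer(x)

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

#' Classification labels used throughout the package
#'
#' Volumes and slice images carry a two-level label, `"benign"` or
#' `"malignant"`. Malignant is the positive class in every metric.
#'
#' @return Character vector of the two valid labels.
#' @export
dot_labels <- function() c("benign", "malignant")

check_label <- function(label) {
  if (!(is.character(label) && length(label) == 1L && label %in% dot_labels()))
    stopf("label must be one of %s", paste(shQuote(dot_labels()), collapse = ", "))
  label
}

# 1-D Gaussian convolution matrix with row-normalized (convex) weights, so
# smoothing can never push values outside the input range.
gauss_band_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  taps <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (d in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- taps[d + r + 1L]
  }
  K / rowSums(K)
}

# Separable 3-D Gaussian blur, sigma in voxels (scalar or length-3).
gaussian_blur_3d <- function(arr, sigma) {
  sigma <- rep_len(sigma, 3L)
  d <- dim(arr)
  stopifnot(length(d) == 3L)
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    K <- gauss_band_matrix(d[ax], sigma[ax])
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(arr, perm), nrow = d[ax])
    m <- K %*% m
    arr <- aperm(array(m, d[perm]), order(perm))
  }
  arr
}
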