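# Preprocessing: 3-D volumes -> normalized 32x32 slice dataset, stratified
# train/test split, minority-class flip augmentation.

#' Extract axial slices from a volume
#'
#' Returns the `z_lo..z_hi` (inclusive, 1-based) axial planes of a volume in
#' ascending z order, each carrying the volume's label and patient id.
#'
#' @param volume A `dot_volume`.
#' @param z_lo,z_hi Inclusive axial index range.
#' @return A list of slices; each is a list with `pixels` (2-D matrix),
#'   `label`, `patient_id`, `z_index`.
#' @export
slice_volume <- function(volume, z_lo = 6L, z_hi = 25L) {
  stopifnot(inherits(volume, "dot_volume"))
  depth <- dim(volume$voxels)[3]
  if (!(is_count(z_lo) && is_count(z_hi) && z_lo >= 1L && z_lo <= z_hi &&
        z_hi <= depth))
    stopf("need 1 <= z_lo <= z_hi <= %d", depth)
  lapply(seq(z_lo, z_hi), function(z) {
    list(pixels = volume$voxels[, , z],
         label = volume$label,
         patient_id = volume$patient_id,
         z_index = as.integer(z))
  })
}

#' Bilinear image resize
#'
#' Corner-aligned bilinear interpolation: output corner pixels sample the
#' input corners exactly, and every output value is a convex combination of
#' its four nearest input neighbours, so the output range is bounded by the
#' input range. Resizing to the input's own shape is the identity.
#'
#' @param img Numeric matrix.
#' @param out_h,out_w Positive output dimensions.
#' @return `out_h` x `out_w` numeric matrix.
#' @export
resize_bilinear <- function(img, out_h = 32L, out_w = 32L) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (!(is_count(out_h) && is_count(out_w) && out_h >= 1L && out_w >= 1L))
    stopf("output dimensions must be positive integers")
  src_coord <- function(n_out, n_in) {
    if (n_out == 1L) rep((n_in + 1) / 2, 1L)
    else 1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  }
  ry <- src_coord(out_h, nrow(img)); rx <- src_coord(out_w, ncol(img))
  y0 <- pmin(floor(ry), nrow(img) - 1L); y0 <- pmax(y0, 1L)
  x0 <- pmin(floor(rx), ncol(img) - 1L); x0 <- pmax(x0, 1L)
  if (nrow(img) == 1L) y0 <- rep(1L, out_h)
  if (ncol(img) == 1L) x0 <- rep(1L, out_w)
  wy <- ry - y0; wx <- rx - x0
  y1 <- pmin(y0 + 1L, nrow(img)); x1 <- pmin(x0 + 1L, ncol(img))
  Wy0 <- matrix(1 - wy, out_h, out_w); Wy1 <- matrix(wy, out_h, out_w)
  Wx0 <- matrix(1 - wx, out_h, out_w, byrow = TRUE)
  Wx1 <- matrix(wx, out_h, out_w, byrow = TRUE)
  Wy0 * Wx0 * img[y0, x0, drop = FALSE] + Wy0 * Wx1 * img[y0, x1, drop = FALSE] +
    Wy1 * Wx0 * img[y1, x0, drop = FALSE] + Wy1 * Wx1 * img[y1, x1, drop = FALSE]
}

#' Min-max normalization to [0, 1]
#'
#' `(x - min) / (max - min)` elementwise; a constant image maps to all zeros
#' by convention (the degenerate range carries no information).
#'
#' @param img Numeric matrix with finite entries.
#' @return Matrix with values in `[0, 1]`.
#' @export
normalize_minmax <- function(img) {
  if (!all(is.finite(img))) stopf("image contains non-finite values")
  lo <- min(img); hi <- max(img)
  if (hi == lo) return(array(0, dim(img)))
  (img - lo) / (hi - lo)
}

new_slice_dataset <- function(images, meta) {
  stopifnot(length(dim(images)) == 3L, nrow(meta) == dim(images)[3])
  meta$label <- factor(meta$label, levels = dot_labels())
  rownames(meta) <- NULL
  structure(list(images = images, meta = meta), class = "slice_dataset")
}

#' @export
print.slice_dataset <- function(x, ...) {
  n <- dim(x$images)[3]
  cat(sprintf("<slice_dataset> %d images %dx%d (%s)\n", n,
              dim(x$images)[1], dim(x$images)[2],
              paste(sprintf("%s %d", levels(x$meta$label),
                            tabulate(x$meta$label, 2L)), collapse = ", ")))
  invisible(x)
}

#' Number of images in a slice dataset
#' @param dataset A `slice_dataset`.
#' @return Integer count.
#' @export
n_images <- function(dataset) dim(dataset$images)[3]

# Subset a slice_dataset by image index.
subset_dataset <- function(dataset, idx) {
  new_slice_dataset(dataset$images[, , idx, drop = FALSE],
                    dataset$meta[idx, , drop = FALSE])
}

# Row-bind two slice_datasets.
bind_datasets <- function(a, b) {
  d <- dim(a$images)
  images <- array(c(a$images, b$images),
                  c(d[1], d[2], d[3] + dim(b$images)[3]))
  new_slice_dataset(images, rbind(a$meta, b$meta))
}

#' Build the 2-D slice dataset from labelled volumes
#'
#' Slices every volume over the axial range, resizes each plane to
#' `out_size` x `out_size` with bilinear interpolation, and min-max
#' normalizes it to `[0, 1]`. With the defaults, 63 volumes yield
#' 63 x 20 = 1260 images.
#'
#' @param volumes Non-empty list of `dot_volume` objects.
#' @param z_lo,z_hi Inclusive axial slicing range.
#' @param out_size Output image side length.
#' @return A `slice_dataset`: `images` is a `out_size x out_size x N` array,
#'   `meta` a data frame with `patient_id`, `label`, `z_index`.
#' @export
build_dataset <- function(volumes, z_lo = 6L, z_hi = 25L, out_size = 32L) {
  if (length(volumes) == 0L) stopf("volumes must be a non-empty list")
  per <- z_hi - z_lo + 1L
  n <- length(volumes) * per
  images <- array(NA_real_, c(out_size, out_size, n))
  pid <- character(n); lab <- character(n); zi <- integer(n)
  k <- 0L
  for (v in volumes) {
    for (s in slice_volume(v, z_lo, z_hi)) {
      k <- k + 1L
      images[, , k] <- normalize_minmax(resize_bilinear(s$pixels, out_size, out_size))
      pid[k] <- s$patient_id; lab[k] <- s$label; zi[k] <- s$z_index
    }
  }
  new_slice_dataset(images, data.frame(patient_id = pid, label = lab,
                                       z_index = zi))
}

#' Stratified train/test split
#'
#' Within each class, images are shuffled with the given seed and the first
#' `round(fraction_train * n_class)` (half away from zero) go to the training
#' set. Per-class counts are therefore deterministic regardless of seed: 860
#' benign + 400 malignant at fraction 0.75 always give 645/300 train and
#' 215/100 test. With `by = "patient"` whole patients are assigned to one
#' partition instead (no slice of a patient leaks across the split), at the
#' cost of per-image counts that are only approximately the target fraction.
#'
#' @param dataset A `slice_dataset`.
#' @param fraction_train Training proportion, strictly between 0 and 1.
#' @param seed Integer seed controlling membership (not counts).
#' @param by `"image"` (default, reproduces the published counts) or
#'   `"patient"`.
#' @return A `dataset_split`: list with `train`, `test` (slice datasets),
#'   `seed`, `fraction_train`, `by`.
#' @export
stratified_split <- function(dataset, fraction_train = 0.75, seed = 1L,
                             by = c("image", "patient")) {
  by <- match.arg(by)
  if (!(is.numeric(fraction_train) && length(fraction_train) == 1L &&
        fraction_train > 0 && fraction_train < 1))
    stopf("fraction_train must lie strictly between 0 and 1")
  train_idx <- with_seed(seed, {
    idx <- integer(0)
    for (lv in dot_labels()) {
      if (by == "image") {
        cls <- which(dataset$meta$label == lv)
        if (length(cls) == 0L) next
        cls <- sample(cls)
        idx <- c(idx, cls[seq_len(round_half_up(fraction_train * length(cls)))])
      } else {
        pats <- unique(dataset$meta$patient_id[dataset$meta$label == lv])
        if (length(pats) == 0L) next
        pats <- sample(pats)
        keep <- pats[seq_len(round_half_up(fraction_train * length(pats)))]
        idx <- c(idx, which(dataset$meta$patient_id %in% keep))
      }
    }
    sort(idx)
  })
  structure(list(train = subset_dataset(dataset, train_idx),
                 test = subset_dataset(dataset, setdiff(seq_len(n_images(dataset)),
                                                        train_idx)),
                 seed = seed, fraction_train = fraction_train, by = by),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> by %s, fraction %.2f\n  train: ", x$by,
              x$fraction_train))
  print(x$train); cat("  test:  "); print(x$test)
  invisible(x)
}

#' Mirror an image left-right
#' @param img Numeric matrix.
#' @return The horizontally flipped matrix.
#' @export
flip_horizontal <- function(img) img[, rev(seq_len(ncol(img))), drop = FALSE]

#' Double a minority class in the training set by horizontal flipping
#'
#' Every training image of `target_class` is duplicated as its left-right
#' mirror and appended; the test set is untouched. With the published counts
#' (645 benign / 300 malignant train) this yields the 1245-image augmented
#' training set (645 / 600).
#'
#' @param split A `dataset_split`.
#' @param target_class Class to double (default `"malignant"`).
#' @return A new `dataset_split` with the augmented training set.
#' @export
augment_flip_minority <- function(split, target_class = "malignant") {
  check_label(target_class)
  idx <- which(split$train$meta$label == target_class)
  if (length(idx) == 0L) {
    warning(sprintf("no '%s' images in training set; augmentation is a no-op",
                    target_class), call. = FALSE)
    return(split)
  }
  extra <- subset_dataset(split$train, idx)
  for (i in seq_len(dim(extra$images)[3]))
    extra$images[, , i] <- flip_horizontal(extra$images[, , i])
  split$train <- bind_datasets(split$train, extra)
  split
}
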