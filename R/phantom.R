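# Synthetic DOT breast phantom generator.
#
# The clinical cohort the classifier was designed for is private, so the
# package ships a generative stand-in: a z-tapered elliptical breast support
# filled with a correlated-noise absorption background, one inclusion per
# volume (a smooth ellipsoid for benign masses, a union of overlapping
# ellipsoidal lobules for malignant ones), and a global Gaussian point-spread
# blur emulating the diffuse millimetre-scale resolution of optical
# tomography. Absorption is in arbitrary units: only relative contrast
# survives the per-image normalization applied downstream.

#' Configuration for the synthetic DOT phantom generator
#'
#' @param grid_shape Integer triple, voxel grid dimensions. Default
#'   `c(91, 91, 31)`, the native DOT reconstruction grid.
#' @param voxel_pitch_mm Edge length of a voxel in millimetres. Default 2.0,
#'   so the 91-voxel transverse extent spans about 18 cm.
#' @param background_mu Baseline absorption, arbitrary units.
#' @param background_noise_sigma Correlation length (voxels) of the smoothed
#'   background heterogeneity field.
#' @param background_noise_amp Fractional amplitude of background
#'   heterogeneity (standard deviation relative to `background_mu`).
#' @param tumor_z_range Inclusive 1-based axial index range within which the
#'   inclusion center is placed. Default `c(6, 25)`, where clinical tumors
#'   concentrate.
#' @param contrast_benign,contrast_malignant Multiplicative absorption
#'   contrast range (min, max) for each class. The defaults (1.3--1.8 versus
#'   2.0--3.0) are disjoint, giving a separable but non-trivial cohort.
#' @param lobulation_count Number of overlapping ellipsoids forming a
#'   malignant mass (benign masses are single smooth ellipsoids).
#' @param psf_sigma_mm Gaussian blur in millimetres applied to the whole
#'   field, emulating the diffuse point-spread of optical tomography; a
#'   scalar or per-axis (x, y, z) triple. The default `c(6, 6, 12)` reflects
#'   DOT's anisotropic resolution: of order 5--10 mm transversely and
#'   substantially poorer in depth, which smears a lesion across most axial
#'   planes -- the property that makes whole-volume slice labelling
#'   informative.
#' @param tumor_semiaxes_cm List with elements `a`, `b`, `c`, each a (min,
#'   max) range in centimetres for the inclusion semi-axes along x, y, z.
#'   Defaults reproduce example tumor extents of roughly 3.0 x 1.3 x 1.3 cm.
#' @param seed Optional default seed used when `generate_phantom()` is called
#'   without one.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(91L, 91L, 31L),
                           voxel_pitch_mm = 2.0,
                           background_mu = 1.0,
                           background_noise_sigma = 3.0,
                           background_noise_amp = 0.05,
                           tumor_z_range = c(6L, 25L),
                           contrast_benign = c(1.3, 1.8),
                           contrast_malignant = c(2.0, 3.0),
                           lobulation_count = 4L,
                           psf_sigma_mm = c(6.0, 6.0, 12.0),
                           tumor_semiaxes_cm = list(a = c(1.0, 1.6),
                                                    b = c(0.5, 0.8),
                                                    c = c(0.5, 0.8)),
                           seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 3L))
    stopf("grid_shape must be three integers >= 3")
  tumor_z_range <- as.integer(tumor_z_range)
  if (length(tumor_z_range) != 2L || tumor_z_range[1] > tumor_z_range[2] ||
      tumor_z_range[1] < 1L || tumor_z_range[2] > grid_shape[3])
    stopf("tumor_z_range must lie within [1, %d]", grid_shape[3])
  for (rng in list(contrast_benign, contrast_malignant)) {
    if (length(rng) != 2L || any(rng <= 0) || rng[1] > rng[2])
      stopf("contrast ranges must be positive (min, max) pairs")
  }
  if (!all(c("a", "b", "c") %in% names(tumor_semiaxes_cm)))
    stopf("tumor_semiaxes_cm must have elements a, b, c")
  cfg <- list(grid_shape = grid_shape,
              voxel_pitch_mm = voxel_pitch_mm,
              background_mu = background_mu,
              background_noise_sigma = background_noise_sigma,
              background_noise_amp = background_noise_amp,
              tumor_z_range = tumor_z_range,
              contrast_benign = contrast_benign,
              contrast_malignant = contrast_malignant,
              lobulation_count = as.integer(lobulation_count),
              psf_sigma_mm = psf_sigma_mm,
              tumor_semiaxes_cm = tumor_semiaxes_cm,
              seed = seed)
  class(cfg) <- "phantom_config"
  cfg
}

runif1 <- function(range) stats::runif(1L, range[1], range[2])

# Breast support: ellipse in (x, y) whose radii shrink with depth z, like a
# pendant breast narrowing away from the chest wall. Returns a logical array.
breast_support_mask <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  rx <- 0.46 * nx; ry <- 0.46 * ny
  taper <- sqrt(1 - 0.8 * ((seq_len(nz) - 1) / (nz - 1))^2)
  x2 <- ((seq_len(nx) - cx) / rx)^2
  y2 <- ((seq_len(ny) - cy) / ry)^2
  plane <- outer(x2, y2, `+`)                      # (x, y) squared radius
  outer(plane, taper^2, `<=`)                      # nx x ny x nz logical
}

# Squared normalized distance to an axis-aligned ellipsoid; <= 1 is inside.
ellipsoid_field <- function(grid_shape, center, semiaxes_vox) {
  dx2 <- ((seq_len(grid_shape[1]) - center[1]) / semiaxes_vox[1])^2
  dy2 <- ((seq_len(grid_shape[2]) - center[2]) / semiaxes_vox[2])^2
  dz2 <- ((seq_len(grid_shape[3]) - center[3]) / semiaxes_vox[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

#' Generate one synthetic DOT breast volume
#'
#' Draws a breast-shaped absorption volume containing exactly one inclusion
#' of the requested class. Benign inclusions are single smooth ellipsoids
#' with contrast drawn from `config$contrast_benign`; malignant inclusions
#' are unions of `config$lobulation_count` overlapping ellipsoidal lobules
#' with contrast from `config$contrast_malignant`. The whole field is blurred
#' with a Gaussian point-spread function and masked to the breast support
#' (voxels outside the support are exactly zero).
#'
#' @param label `"benign"` or `"malignant"`.
#' @param config A [phantom_config()].
#' @param seed Integer seed; the output is bit-reproducible given
#'   `(label, config, seed)`.
#' @param patient_id Identifier stored on the volume.
#' @return An object of class `dot_volume`: a list with `voxels` (3-D array,
#'   non-negative), `label`, `patient_id`, `tumor_extent_cm` (full axis
#'   lengths of the primary inclusion, metadata), and `voxel_pitch_mm`.
#' @export
generate_phantom <- function(label, config = phantom_config(),
                             seed = config$seed, patient_id = "P000") {
  check_label(label)
  stopifnot(inherits(config, "phantom_config"))
  if (is.null(seed)) stopf("a seed is required (pass `seed` or set it in the config)")
  with_seed(seed, {
    gs <- config$grid_shape
    pitch <- config$voxel_pitch_mm
    support <- breast_support_mask(gs)

    noise <- array(stats::rnorm(prod(gs)), gs)
    noise <- gaussian_blur_3d(noise, config$background_noise_sigma)
    noise <- (noise - mean(noise)) / stats::sd(noise)
    vol <- config$background_mu * (1 + config$background_noise_amp * noise)

    # Inclusion geometry: semi-axes sampled in cm, converted to voxels.
    ax <- config$tumor_semiaxes_cm
    semi_cm <- c(runif1(ax$a), runif1(ax$b), runif1(ax$c))
    semi_vox <- pmax(semi_cm * 10 / pitch, 0.5)
    zc <- sample(seq(config$tumor_z_range[1], config$tumor_z_range[2]), 1L)
    taper <- sqrt(1 - 0.8 * ((zc - 1) / (gs[3] - 1))^2)
    cx <- (gs[1] + 1) / 2 + runif1(c(-1, 1)) * 0.25 * gs[1] * taper
    cy <- (gs[2] + 1) / 2 + runif1(c(-1, 1)) * 0.25 * gs[2] * taper
    center <- c(cx, cy, zc)

    contrast_range <- if (label == "malignant") config$contrast_malignant
                      else config$contrast_benign
    contrast <- runif1(contrast_range)

    inside <- ellipsoid_field(gs, center, semi_vox) <= 1
    if (label == "malignant" && config$lobulation_count > 1L) {
      for (i in seq_len(config$lobulation_count - 1L)) {
        off <- stats::runif(3L, -0.6, 0.6) * semi_vox
        scale <- stats::runif(1L, 0.5, 0.8)
        inside <- inside |
          (ellipsoid_field(gs, center + off, scale * semi_vox) <= 1)
      }
    }
    vol <- vol * (1 + (contrast - 1) * inside)

    vol <- gaussian_blur_3d(vol, config$psf_sigma_mm / pitch)
    vol[!support] <- 0
    vol[vol < 0] <- 0

    structure(list(voxels = vol,
                   label = label,
                   patient_id = patient_id,
                   tumor_extent_cm = 2 * semi_cm,
                   voxel_pitch_mm = pitch),
              class = "dot_volume")
  })
}

#' @export
print.dot_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<dot_volume> %s  %s  %dx%dx%d voxels  tumor extent %.1f x %.1f x %.1f cm\n",
              x$patient_id, x$label, d[1], d[2], d[3],
              x$tumor_extent_cm[1], x$tumor_extent_cm[2], x$tumor_extent_cm[3]))
  invisible(x)
}

#' Generate a labelled cohort of synthetic volumes
#'
#' Produces `n_benign + n_malignant` volumes with unique patient identifiers.
#' Per-volume seeds are derived deterministically from `seed`, so the whole
#' cohort is reproducible and individual volumes can be regenerated from the
#' manifest alone.
#'
#' @param n_benign,n_malignant Non-negative volume counts per class.
#' @param config A [phantom_config()].
#' @param seed Cohort-level integer seed.
#' @return A list of `dot_volume` objects (benign first), each with a
#'   `seed` attribute recording its per-volume seed.
#' @export
generate_cohort <- function(n_benign, n_malignant, config = phantom_config(),
                            seed = 1L) {
  if (!is_count(n_benign) || !is_count(n_malignant))
    stopf("n_benign and n_malignant must be non-negative integers")
  n <- as.integer(n_benign + n_malignant)
  labels <- rep(dot_labels(), c(n_benign, n_malignant))
  seeds <- derive_seeds(seed, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    v <- generate_phantom(labels[i], config, seed = seeds[i],
                          patient_id = sprintf("P%03d", i))
    attr(v, "seed") <- seeds[i]
    out[[i]] <- v
  }
  out
}
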