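# Minimal NIfTI-1 reader/writer for 3-D volumes. Hand-rolled because no
# NIfTI package is available in the target R stack; covers the single-file
# (.nii / .nii.gz) little-endian layout with float/integer datatypes, which
# is all this package ever produces or consumes. Voxel data are stored as
# float64 so write -> read round trips are lossless.

NIFTI_HDR_SIZE <- 348L
NIFTI_VOX_OFFSET <- 352
NIFTI_DTYPES <- list(`2` = list(what = "integer", size = 1L, signed = FALSE),
                     `4` = list(what = "integer", size = 2L, signed = TRUE),
                     `8` = list(what = "integer", size = 4L, signed = TRUE),
                     `16` = list(what = "double", size = 4L, signed = TRUE),
                     `64` = list(what = "double", size = 8L, signed = TRUE))

open_conn <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a volume as a NIfTI-1 file
#'
#' Single-file NIfTI-1, float64, little-endian; `.gz` suffixes are
#' compressed. Only voxel data, shape and voxel pitch go in the header --
#' label and patient id live in the cohort manifest, not the file.
#'
#' @param volume A `dot_volume`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "dot_volume"))
  d <- dim(volume$voxels)
  con <- open_conn(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wc <- function(n) writeBin(raw(n), con)
  wi(NIFTI_HDR_SIZE, 4L)                      # sizeof_hdr
  wc(36L)                                     # data_type..dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2L)            # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2L)                  # intent_p*, intent_code
  wi(64L, 2L); wi(64L, 2L); wi(0L, 2L)        # datatype, bitpix, slice_start
  wf(c(1, rep(volume$voxel_pitch_mm %||% 1, 3L), 0, 0, 0, 0))  # pixdim[8]
  wf(NIFTI_VOX_OFFSET)                        # vox_offset
  wf(1); wf(0)                                # scl_slope, scl_inter
  wi(0L, 2L); wc(2L)                          # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                           # cal_max..toffset
  wi(c(0L, 0L), 4L)                           # glmax, glmin
  wc(80L + 24L)                               # descrip, aux_file
  wi(c(0L, 0L), 2L)                           # qform_code, sform_code
  wf(rep(0, 6L))                              # quatern, qoffset
  wf(rep(0, 12L))                             # srow_x/y/z
  wc(16L)                                     # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con) # magic
  wc(4L)                                      # extension flag
  writeBin(as.numeric(volume$voxels), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a 3-D NIfTI-1 volume
#'
#' Accepts little-endian single-file NIfTI-1 with a float or integer
#' datatype; anything that is not exactly 3-dimensional is rejected with a
#' shape report.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param label,patient_id Metadata to attach (carried by the manifest, not
#'   the NIfTI header).
#' @return A `dot_volume`.
#' @export
read_volume <- function(path, label = "benign", patient_id = "P000") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  con <- open_conn(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", NIFTI_HDR_SIZE)
  if (length(hdr) < NIFTI_HDR_SIZE) stopf("truncated NIfTI header in %s", path)
  ri <- function(off, size, n = 1L)
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L,
            endian = "little")
  if (ri(0L, 4L) != NIFTI_HDR_SIZE)
    stopf("%s is not a little-endian NIfTI-1 file", path)
  dims <- ri(40L, 2L, 8L)
  if (dims[1] != 3L)
    stopf("expected a 3-D volume, got %d-D with extents %s", dims[1],
          paste(dims[2:(dims[1] + 1L)], collapse = "x"))
  d <- dims[2:4]
  dtype <- NIFTI_DTYPES[[as.character(ri(70L, 2L))]]
  if (is.null(dtype)) stopf("unsupported NIfTI datatype %d", ri(70L, 2L))
  pixdim <- rf(76L, 8L)
  vox_offset <- rf(108L)
  readBin(con, "raw", as.integer(vox_offset) - NIFTI_HDR_SIZE)
  vox <- readBin(con, dtype$what, n = prod(d), size = dtype$size,
                 signed = dtype$signed, endian = "little")
  scl <- rf(112L)
  if (is.finite(scl) && scl != 0 && scl != 1) vox <- vox * scl + rf(116L)
  structure(list(voxels = array(as.numeric(vox), d),
                 label = label, patient_id = patient_id,
                 tumor_extent_cm = c(NA_real_, NA_real_, NA_real_),
                 voxel_pitch_mm = pixdim[2]),
            class = "dot_volume")
}

#' Write a cohort to disk with its manifest
#'
#' One NIfTI file per volume plus `manifest.csv` with columns
#' `patient_id,label,path,seed` (`path` relative to the manifest).
#'
#' @param volumes List of `dot_volume`s.
#' @param dir Output directory (created if needed).
#' @param write_volumes If `FALSE`, only the manifest is written and the
#'   `path` column is empty (volumes can be regenerated from their seeds).
#' @return Path of the manifest, invisibly.
#' @export
save_cohort <- function(volumes, dir, write_volumes = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(volumes, function(v) {
    fn <- if (write_volumes) paste0(v$patient_id, ".nii.gz") else NA_character_
    if (write_volumes) write_volume(v, file.path(dir, fn))
    data.frame(patient_id = v$patient_id, label = v$label, path = fn,
               seed = attr(v, "seed") %||% NA_integer_)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Load a cohort from a manifest
#'
#' @param manifest_path `manifest.csv` written by [save_cohort()].
#' @return List of `dot_volume`s with labels and patient ids from the
#'   manifest. A row whose file is missing raises an error naming the
#'   patient id.
#' @export
load_cohort <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    p <- file.path(base, manifest$path[i])
    if (is.na(manifest$path[i]) || !file.exists(p))
      stopf("volume file for patient %s is missing (%s)",
            manifest$patient_id[i], manifest$path[i])
    read_volume(p, label = manifest$label[i],
                patient_id = manifest$patient_id[i])
  })
}
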