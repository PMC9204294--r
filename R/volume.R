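#' Construct a volume object
#'
#' A thin container for a 3D intensity array with its voxel-to-world
#' affine, as read from an MNI-registered NIfTI file.
#'
#' @param data 3D numeric array of voxel intensities.
#' @param affine 4x4 voxel-to-world transform; defaults to identity.
#' @return An object of class `recnn_volume` with fields `data`,
#'   `affine` and `shape`.
#' @export
as_volume <- function(data, affine = diag(4)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)), " dims")
  if (any(dim(data) < 1L)) stop("volume axes must be strictly positive")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix")
  structure(list(data = data, affine = affine, shape = dim(data)),
            class = "recnn_volume")
}

#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [as_volume()] object.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  as_volume(array(as.numeric(img), dim = dim(img)), RNifti::xform(img))
}

#' Write a volume to NIfTI
#'
#' @param vol A `recnn_volume` (or plain 3D array).
#' @param path Destination `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vol <- .coerce_volume(vol)
  img <- RNifti::asNifti(vol$data)
  RNifti::writeNifti(img, path)
  invisible(path)
}

.coerce_volume <- function(vol) {
  if (inherits(vol, "recnn_volume")) vol else as_volume(vol)
}

#' Intensity normalization with outlier clipping
#'
#' Standardizes all voxel intensities of a volume to zero mean and unit
#' (sample) standard deviation, then clips outliers to
#' `[clip_lo, clip_hi]`.  The default asymmetric range \[-1, 2.5\] keeps
#' bright tissue while flooring background; it only makes sense on
#' standardized intensities, which is why clipping follows the z-score.
#' Statistics are computed per volume over all voxels, so no cohort pass
#' is needed.
#'
#' @param vol A `recnn_volume` or 3D array.
#' @param clip_lo,clip_hi Clip bounds, `clip_lo < clip_hi`.
#' @return A `recnn_volume` with standardized, clipped intensities.
#' @export
normalize_and_clip <- function(vol, clip_lo = -1, clip_hi = 2.5) {
  vol <- .coerce_volume(vol)
  if (!(clip_lo < clip_hi)) stop("clip_lo must be < clip_hi")
  x <- vol$data
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("constant-intensity volume: standard deviation is zero, cannot standardize")
  z <- (x - mean(x)) / s
  z[z < clip_lo] <- clip_lo
  z[z > clip_hi] <- clip_hi
  as_volume(z, vol$affine)
}

#' Crop a patch out of a volume
#'
#' Extracts the half-open box `[corner, corner + size)` in 0-based voxel
#' coordinates, the convention used for the \[80, 100, 80\] hippocampal
#' patch on the MNI152 grid.
#'
#' @param vol A `recnn_volume` or 3D array.
#' @param corner Integer triple, 0-based voxel index of the low corner.
#' @param size Integer triple, patch extent per axis.
#' @return An object of class `recnn_patch` with fields `data`, `origin`
#'   (the corner) and `shape`.
#' @export
crop_patch <- function(vol, corner, size) {
  vol <- .coerce_volume(vol)
  corner <- as.integer(corner); size <- as.integer(size)
  stopifnot(length(corner) == 3L, length(size) == 3L)
  if (any(corner < 0L)) stop("corner must be nonnegative")
  if (any(size < 1L)) stop("size must be positive")
  hi <- corner + size
  bad <- which(hi > vol$shape)
  if (length(bad))
    stop("crop exceeds volume bounds on axis ", paste(bad, collapse = ", "),
         " (need ", paste(hi, collapse = "x"), ", have ",
         paste(vol$shape, collapse = "x"), ")")
  data <- vol$data[(corner[1] + 1L):hi[1],
                   (corner[2] + 1L):hi[2],
                   (corner[3] + 1L):hi[3], drop = FALSE]
  structure(list(data = data, origin = corner, shape = dim(data)),
            class = "recnn_patch")
}

#' Bundle a patch, metric vector and label into a sample record
#'
#' @param patch A `recnn_patch` (or 3D array, taken as a whole patch).
#' @param morph Numeric vector of morphological metrics (e.g. GM, WM,
#'   CSF volumes), possibly length 0.
#' @param label 0 for NC, 1 for AD.
#' @param subject_id Identifier string.
#' @return An object of class `recnn_sample`.
#' @export
sample_record <- function(patch, morph, label, subject_id) {
  if (!inherits(patch, "recnn_patch")) {
    arr <- as.array(patch)
    patch <- structure(list(data = arr, origin = c(0L, 0L, 0L),
                            shape = dim(arr)), class = "recnn_patch")
  }
  label <- as.integer(label)
  if (!label %in% c(0L, 1L)) stop("label must be 0 (NC) or 1 (AD)")
  structure(list(patch = patch, morph = as.numeric(morph), label = label,
                 subject_id = as.character(subject_id)),
            class = "recnn_sample")
}

#' Load a cohort of NIfTI volumes with labels and metrics
#'
#' Reads a CSV/TSV table with columns `subject_id`, `label` and one
#' column per morphological metric, locates `<subject_id>.nii` /
#' `.nii.gz` under `image_dir`, and applies the preprocessing chain
#' (per-volume standardization, clipping, patch cropping) to each
#' volume.  Rows whose image is missing or whose label is not 0/1 are
#' collected in a rejects table instead of failing the whole load.
#'
#' @param image_dir Directory containing one NIfTI per subject.
#' @param table_path Path to the label/metric table (comma or tab
#'   separated, with header).
#' @param crop_corner,crop_size 0-based corner and extent of the patch;
#'   `NULL` (default) keeps the whole volume.
#' @param clip Length-2 clip range applied after standardization, or
#'   `NULL` to skip normalization entirely.
#' @return A list with `samples` (list of [sample_record()]s, in table
#'   row order) and `rejects` (data frame with `subject_id`, `reason`).
#' @export
load_cohort <- function(image_dir, table_path, crop_corner = NULL,
                        crop_size = NULL, clip = c(-1, 2.5)) {
  if (!file.exists(table_path)) stop("no such table: ", table_path)
  sep <- if (grepl("\\.tsv$", table_path)) "\t" else ","
  tab <- utils::read.delim(table_path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("subject_id", "label")
  if (!all(need %in% names(tab)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab) == 0L) stop("empty cohort table")
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject_id in table: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]), collapse = ", "))
  metric_cols <- setdiff(names(tab), need)

  samples <- list()
  rejects <- data.frame(subject_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (r in seq_len(nrow(tab))) {
    sid <- as.character(tab$subject_id[r])
    lab <- suppressWarnings(as.integer(tab$label[r]))
    if (is.na(lab) || !lab %in% c(0L, 1L)) {
      rejects <- rbind(rejects, data.frame(subject_id = sid,
                                           reason = "malformed label"))
      next
    }
    path <- file.path(image_dir, paste0(sid, ".nii"))
    if (!file.exists(path)) path <- paste0(path, ".gz")
    if (!file.exists(path)) {
      rejects <- rbind(rejects, data.frame(subject_id = sid,
                                           reason = "missing image"))
      next
    }
    vol <- read_volume(path)
    if (!is.null(clip)) vol <- normalize_and_clip(vol, clip[1], clip[2])
    patch <- if (is.null(crop_corner)) {
      crop_patch(vol, c(0L, 0L, 0L), vol$shape)
    } else {
      crop_patch(vol, crop_corner, crop_size)
    }
    morph <- as.numeric(tab[r, metric_cols, drop = TRUE])
    samples[[length(samples) + 1L]] <- sample_record(patch, morph, lab, sid)
  }
  list(samples = samples, rejects = rejects, metric_cols = metric_cols)
}
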