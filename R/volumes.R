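#' CT volume in Hounsfield units
#'
#' Constructs a CT volume object. Voxels are stored as a 3-D array with
#' dimensions (row, col, slice); slice 1 is the most superior slice and
#' slices run superior to inferior. Values outside the 12-bit CT range
#' \[-1024, 3071\] are clipped with a warning.
#'
#' @param voxels 3-D numeric array (row, col, slice) of Hounsfield units.
#' @param slice_thickness_mm Positive slice thickness in mm.
#' @param pixel_spacing_mm Length-2 positive numeric, in-plane (row, col)
#'   spacing in mm.
#' @return An object of class `ct_volume`.
#' @examples
#' ct <- ct_volume(array(-1000, c(32, 32, 4)))
#' dim(ct$voxels)
#' @export
ct_volume <- function(voxels, slice_thickness_mm = 3.75,
                      pixel_spacing_mm = c(0.98, 0.98)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  d <- dim(voxels)
  if (d[3] < 1L || d[1] < 16L || d[2] < 16L) {
    stop("CT grid must be at least 16 x 16 in-plane with >= 1 slice",
         call. = FALSE)
  }
  stopifnot(slice_thickness_mm > 0, length(pixel_spacing_mm) == 2L,
            all(pixel_spacing_mm > 0))
  rng <- range(voxels)
  if (rng[1] < HU_MIN || rng[2] > HU_MAX) {
    warning("HU values outside [", HU_MIN, ", ", HU_MAX, "] clipped",
            call. = FALSE)
    voxels[] <- pmin(pmax(voxels, HU_MIN), HU_MAX)
  }
  structure(
    list(voxels = voxels,
         slice_thickness_mm = slice_thickness_mm,
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         slice_order = "superior_to_inferior"),
    class = "ct_volume")
}

HU_MIN <- -1024
HU_MAX <- 3071

#' PET activity volume
#'
#' Constructs a PET volume of nonnegative activity values on the same
#' (row, col, slice) convention as [ct_volume()]. Values are raw activity;
#' SUV conversion is not required because model inputs are max-normalized.
#'
#' @param voxels 3-D nonnegative numeric array (row, col, slice).
#' @inheritParams ct_volume
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(voxels, slice_thickness_mm = 3.75,
                       pixel_spacing_mm = c(3.9, 3.9)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (min(voxels) < 0) {
    stop("PET activity values must be nonnegative (unit error)", call. = FALSE)
  }
  stopifnot(slice_thickness_mm > 0, length(pixel_spacing_mm) == 2L,
            all(pixel_spacing_mm > 0))
  structure(
    list(voxels = voxels,
         slice_thickness_mm = slice_thickness_mm,
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         slice_order = "superior_to_inferior"),
    class = "pet_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d (row x col x slice), HU [%g, %g]\n",
              d[1], d[2], d[3], min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<pet_volume> %d x %d x %d (row x col x slice), max %g\n",
              d[1], d[2], d[3], max(x$voxels)))
  invisible(x)
}

#' Apply scanner rescale to stored voxel values
#'
#' Converts stored integer voxel values to physical units via the linear
#' rescale `value * slope + intercept`, as encoded in DICOM
#' RescaleSlope/RescaleIntercept or NIfTI scl_slope/scl_inter metadata.
#'
#' @param stored Numeric array or vector of stored values.
#' @param slope,intercept Rescale parameters; both must be finite and
#'   `slope` non-zero.
#' @return Rescaled values, same shape as `stored`.
#' @examples
#' apply_rescale(1000, slope = 1, intercept = -1024)  # -24 HU
#' @export
apply_rescale <- function(stored, slope, intercept) {
  if (!is.finite(slope) || !is.finite(intercept) || slope == 0) {
    stop("missing or invalid rescale metadata (unit error)", call. = FALSE)
  }
  stored * slope + intercept
}

read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  a <- as.numeric(as.array(img))  # drop image attributes, keep values
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3L) {
    stop("expected a 3-D volume in ", path, " (format error)", call. = FALSE)
  }
  dim(a) <- d
  list(voxels = a, pixdim = RNifti::pixdim(img))
}

#' Read a CT volume from a NIfTI file
#'
#' Reads a `.nii` / `.nii.gz` volume and returns a [ct_volume()]. The NIfTI
#' scl_slope/scl_inter rescale is applied by the reader, so the returned
#' voxels are Hounsfield units. The third array axis is taken as the slice
#' axis with index 1 most superior.
#'
#' @param path Path to a NIfTI file.
#' @return A `ct_volume`.
#' @seealso [write_volume_nifti()], [read_pet_volume()]
#' @export
read_ct_volume <- function(path) {
  v <- read_nifti_array(path)
  sp <- if (length(v$pixdim) >= 3) abs(v$pixdim[1:3]) else c(1, 1, 1)
  sp[sp == 0] <- 1
  ct_volume(v$voxels, slice_thickness_mm = sp[3], pixel_spacing_mm = sp[1:2])
}

#' Read a PET volume from a NIfTI file
#'
#' @inheritParams read_ct_volume
#' @return A `pet_volume`; negative post-rescale values raise a unit error.
#' @export
read_pet_volume <- function(path) {
  v <- read_nifti_array(path)
  sp <- if (length(v$pixdim) >= 3) abs(v$pixdim[1:3]) else c(1, 1, 1)
  sp[sp == 0] <- 1
  pet_volume(v$voxels, slice_thickness_mm = sp[3], pixel_spacing_mm = sp[1:2])
}

#' Write a volume to NIfTI
#'
#' Serializes a `ct_volume` or `pet_volume` to a NIfTI file. CT volumes with
#' integral HU are stored as int16 (lossless for the 12-bit CT range); other
#' data are stored as float64 so read-back is voxel-exact.
#'
#' @param vol A `ct_volume` or `pet_volume`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  stopifnot(inherits(vol, c("ct_volume", "pet_volume")))
  a <- vol$voxels
  dtype <- if (all(a == round(a)) && min(a) >= -32768 && max(a) <= 32767)
    "int16" else "double"
  attr(a, "pixdim") <- c(vol$pixel_spacing_mm, vol$slice_thickness_mm)
  attr(a, "pixunits") <- c("mm", "s")
  RNifti::writeNifti(RNifti::asNifti(a, datatype = dtype), path)
  invisible(path)
}

#' Pair a CT and a PET volume into one study
#'
#' Bundles co-registered CT and PET volumes for one case. The physical
#' extents (grid size times spacing, per axis) must agree within
#' `extent_tol`; PET slices are resampled onto the CT slice grid when counts
#' differ (nearest-neighbour duplication or linear interpolation along the
#' slice axis). CT voxels are never altered.
#'
#' @param ct A `ct_volume`.
#' @param pet A `pet_volume`; in-plane grid must be the CT grid downscaled by
#'   an integer factor (512 -> 128 gives the scanner default of 4).
#' @param case_id Character case identifier.
#' @param label One of `"benign"`, `"malignant"`, `"unknown"`.
#' @param extent_tol Relative tolerance on per-axis physical extent, default
#'   0.05.
#' @param slice_resample `"nearest"` or `"linear"`.
#' @return An object of class `study_pair`.
#' @export
pair_study <- function(ct, pet, case_id = "case", label = "unknown",
                       extent_tol = 0.05, slice_resample = c("nearest", "linear")) {
  stopifnot(inherits(ct, "ct_volume"), inherits(pet, "pet_volume"))
  slice_resample <- match.arg(slice_resample)
  label <- match.arg(label, c("benign", "malignant", "unknown"))
  dct <- dim(ct$voxels); dpet <- dim(pet$voxels)
  if (dct[1] %% dpet[1] != 0L || dct[2] %% dpet[2] != 0L) {
    stop("PET in-plane grid must divide the CT grid by an integer factor",
         call. = FALSE)
  }
  ext_ct <- c(dct[1:2] * ct$pixel_spacing_mm, dct[3] * ct$slice_thickness_mm)
  ext_pet <- c(dpet[1:2] * pet$pixel_spacing_mm, dpet[3] * pet$slice_thickness_mm)
  rel <- abs(ext_ct - ext_pet) / ext_ct
  if (any(rel > extent_tol)) {
    stop(sprintf(
      "CT and PET physical extents differ by up to %.1f%% (alignment error)",
      100 * max(rel)), call. = FALSE)
  }
  if (dpet[3] != dct[3]) {
    pet_vox <- resample_slices(pet$voxels, dct[3], slice_resample)
    pet <- pet_volume(pet_vox,
                      slice_thickness_mm = ct$slice_thickness_mm,
                      pixel_spacing_mm = pet$pixel_spacing_mm)
  }
  structure(list(case_id = as.character(case_id), ct = ct, pet = pet,
                 label = label),
            class = "study_pair")
}

# Resample the slice axis of a (row, col, slice) array to n_out slices.
resample_slices <- function(a, n_out, method = c("nearest", "linear")) {
  method <- match.arg(method)
  n_in <- dim(a)[3]
  if (n_in == n_out) return(a)
  # map output slice centres onto input slice coordinates (align extents)
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  if (method == "nearest") {
    idx <- pmin(pmax(round(pos), 1L), n_in)
    return(a[, , idx, drop = FALSE])
  }
  lo <- pmin(pmax(floor(pos), 1L), n_in)
  hi <- pmin(lo + 1L, n_in)
  w <- pos - lo
  out <- array(0, c(dim(a)[1:2], n_out))
  for (i in seq_len(n_out)) {
    out[, , i] <- (1 - w[i]) * a[, , lo[i]] + w[i] * a[, , hi[i]]
  }
  out
}

#' @export
print.study_pair <- function(x, ...) {
  cat(sprintf("<study_pair> %s [%s]\n", x$case_id, x$label))
  print(x$ct); print(x$pet)
  invisible(x)
}
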