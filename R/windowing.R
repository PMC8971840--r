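#' CT display window specification
#'
#' A window is the standard radiology display mapping: Hounsfield units are
#' clipped to \[level - width/2, level + width/2\] and scaled linearly to
#' \[0, 1\]. The two windows used throughout the pipeline are the mediastinal
#' window (WL 40 / WW 400), which renders lung air black and drives the
#' localizer's air binarization, and the lung window (WL -400 / WW 1500)
#' used to normalize CT model inputs.
#'
#' @param level_hu Window level (centre) in HU.
#' @param width_hu Window width in HU; must be positive.
#' @return An object of class `window_spec`.
#' @examples
#' window_bounds(window_mediastinal())  # -160, 240
#' @export
window_spec <- function(level_hu, width_hu) {
  stopifnot(is.numeric(level_hu), length(level_hu) == 1L,
            is.numeric(width_hu), length(width_hu) == 1L)
  if (width_hu <= 0) stop("window width must be positive", call. = FALSE)
  structure(list(level_hu = level_hu, width_hu = width_hu),
            class = "window_spec")
}

#' @rdname window_spec
#' @export
window_mediastinal <- function() window_spec(40, 400)

#' @rdname window_spec
#' @export
window_lung <- function() window_spec(-400, 1500)

#' Clip bounds of a display window
#'
#' @param spec A [window_spec()].
#' @return Named numeric vector `c(lower_hu, upper_hu)` =
#'   `level +/- width/2`.
#' @export
window_bounds <- function(spec) {
  stopifnot(inherits(spec, "window_spec"))
  c(lower_hu = spec$level_hu - spec$width_hu / 2,
    upper_hu = spec$level_hu + spec$width_hu / 2)
}

#' Window-normalize a CT volume to \[0, 1\]
#'
#' Applies the linear display-window transform
#' `clip((hu - lower) / (upper - lower), 0, 1)`. HU at or below the lower
#' bound map to 0 ("entirely black"), at or above the upper bound to 1
#' ("entirely white").
#'
#' @param volume Numeric array (any shape) of HU, or a `ct_volume`.
#' @param spec A [window_spec()].
#' @return Numeric array of the same shape with values in \[0, 1\].
#' @export
apply_window <- function(volume, spec) {
  if (inherits(volume, "ct_volume")) volume <- volume$voxels
  b <- window_bounds(spec)
  out <- (volume - b[["lower_hu"]]) / (b[["upper_hu"]] - b[["lower_hu"]])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Max-normalize a PET volume to \[0, 1\]
#'
#' Divides the whole volume by its maximum value, so the hottest voxel maps
#' to 1; this makes the model input invariant to global activity scaling.
#' By default the maximum is taken over the full 3-D volume; `per_slice =
#' TRUE` normalizes each trans-axial slice by its own maximum instead.
#' An all-zero volume is returned unchanged with a warning.
#'
#' @param pet Nonnegative numeric array, or a `pet_volume`.
#' @param per_slice Normalize each slice separately (default `FALSE`).
#' @return Numeric array of the same shape with values in \[0, 1\].
#' @export
normalize_pet <- function(pet, per_slice = FALSE) {
  if (inherits(pet, "pet_volume")) pet <- pet$voxels
  if (min(pet) < 0) stop("PET values must be nonnegative", call. = FALSE)
  if (per_slice && length(dim(pet)) == 3L) {
    mx <- apply(pet, 3, max)
    z <- mx == 0
    if (any(z)) warning("all-zero PET slice(s) left unnormalized", call. = FALSE)
    mx[z] <- 1
    return(sweep(pet, 3, mx, "/"))
  }
  mx <- max(pet)
  if (mx == 0) {
    warning("all-zero PET volume left unnormalized", call. = FALSE)
    return(pet)
  }
  pet / mx
}
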