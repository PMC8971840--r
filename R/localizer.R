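#' Parameters of the automated lung-field localizer
#'
#' The localizer finds, on mediastinal-windowed CT slices viewed superior to
#' inferior, the first trans-axial slice where intrathoracic air exceeds a
#' fraction of the body cross-section ("lung apex"), then extracts aligned
#' CT/PET sub-volumes centred on the body centroid of that slice.
#'
#' @param air_fraction_threshold Air-to-body-area ratio that marks the lung
#'   apex; default 0.05.
#' @param band_fraction Fraction of the body area that the central column
#'   band must enclose; default 0.33.
#' @param crop_width_px Side of the square CT crop; default 256.
#' @param num_slices Number of consecutive slices captured inferior of the
#'   apex; default 96.
#' @param pet_crop_px Side of the square PET crop; default 64.
#' @param min_body_area_fraction Smallest admissible body-contour area as a
#'   fraction of the image area; default 0.10.
#' @param edge_margin_fraction Body centroids closer than this fraction of
#'   the image side to any border are rejected; default 0.10.
#' @param air_threshold_hu HU at or below which a voxel counts as air; the
#'   default -160 is the lower clip bound of the mediastinal window
#'   (WL 40 / WW 400).
#' @param band_interpretation `"enclosed_body_area"` (default: grow the band
#'   until it encloses `band_fraction` of the body area) or `"band_area"`
#'   (grow until the band's own area reaches `band_fraction` of the body
#'   area).
#' @return An object of class `localizer_params`.
#' @export
localizer_params <- function(air_fraction_threshold = 0.05,
                             band_fraction = 0.33,
                             crop_width_px = 256L,
                             num_slices = 96L,
                             pet_crop_px = 64L,
                             min_body_area_fraction = 0.10,
                             edge_margin_fraction = 0.10,
                             air_threshold_hu = -160,
                             band_interpretation = c("enclosed_body_area",
                                                     "band_area")) {
  stopifnot(air_fraction_threshold > 0, air_fraction_threshold < 1,
            band_fraction > 0, band_fraction < 1,
            min_body_area_fraction > 0, min_body_area_fraction < 1,
            edge_margin_fraction > 0, edge_margin_fraction < 1,
            crop_width_px >= 4, num_slices >= 1, pet_crop_px >= 1)
  structure(list(air_fraction_threshold = air_fraction_threshold,
                 band_fraction = band_fraction,
                 crop_width_px = as.integer(crop_width_px),
                 num_slices = as.integer(num_slices),
                 pet_crop_px = as.integer(pet_crop_px),
                 min_body_area_fraction = min_body_area_fraction,
                 edge_margin_fraction = edge_margin_fraction,
                 air_threshold_hu = air_threshold_hu,
                 band_interpretation = match.arg(band_interpretation)),
            class = "localizer_params")
}

#' Binarize a CT slice into air and tissue
#'
#' Under the mediastinal window the tracheal lumen and lung parenchyma
#' render black; a voxel is "air" when its HU is at or below the window's
#' lower clip bound.
#'
#' @param slice_hu Numeric matrix (row, col) of HU.
#' @param threshold_hu Air threshold; default -160.
#' @return Logical matrix, `TRUE` where air.
#' @export
binarize_air <- function(slice_hu, threshold_hu = -160) {
  stopifnot(is.matrix(slice_hu))
  slice_hu <= threshold_hu
}

#' Find connected foreground regions and their outer contours
#'
#' Labels the 8-connected foreground components of a binary mask and
#' returns, per component, its outer boundary polygon, pixel-count area and
#' centroid. Holes enclosed in a component are not returned as separate
#' outer contours.
#'
#' @param mask Logical matrix.
#' @return List of `contour_region` objects (empty list for an empty mask),
#'   each with elements `boundary` (n x 2 matrix of row/col vertices),
#'   `area_px`, `centroid` (row, col) and `pixels` (m x 2 matrix).
#' @export
find_contours <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask & !is.na(mask)
  if (!any(mask)) return(list())
  lab <- label_components8(mask)
  n <- max(lab)
  oc <- EBImage::ocontour(lab)
  idx <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[lab > 0L]
  lapply(seq_len(n), function(i) {
    px <- idx[labs == i, , drop = FALSE]
    bnd <- oc[[i]] + 1L  # ocontour is 0-based
    colnames(bnd) <- c("row", "col")
    colnames(px) <- c("row", "col")
    structure(list(boundary = bnd,
                   area_px = nrow(px),
                   centroid = c(row = mean(px[, 1]), col = mean(px[, 2])),
                   pixels = px),
              class = "contour_region")
  })
}

#' @export
print.contour_region <- function(x, ...) {
  cat(sprintf("<contour_region> area %d px, centroid (%.1f, %.1f)\n",
              x$area_px, x$centroid[1], x$centroid[2]))
  invisible(x)
}

body_not_found <- function(msg) {
  stop(structure(class = c("petlung_body_not_found", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Select the main body contour among candidate regions
#'
#' A region is admissible when its area is at least
#' `min_body_area_fraction` of the image area and its centroid lies at least
#' `edge_margin_fraction` of the image side away from every border (regions
#' hugging an edge are scanner-table artifacts or cropping remnants, not the
#' torso). Among admissible regions the largest wins; exact area ties go to
#' the most central centroid.
#'
#' @param regions List of `contour_region` from [find_contours()], computed
#'   on the hole-filled tissue (non-air) mask of a slice.
#' @param image_shape Integer vector `c(nrow, ncol)`.
#' @param params A [localizer_params()].
#' @return The selected `contour_region`; errors with condition class
#'   `petlung_body_not_found` when no region qualifies.
#' @export
select_body_contour <- function(regions, image_shape,
                                params = localizer_params()) {
  if (length(regions) == 0L) body_not_found("no contour regions on slice")
  nr <- image_shape[1]; nc <- image_shape[2]
  min_area <- params$min_body_area_fraction * nr * nc
  mr <- params$edge_margin_fraction * nr
  mc <- params$edge_margin_fraction * nc
  ok <- vapply(regions, function(r) {
    r$area_px >= min_area &&
      r$centroid[1] >= mr && r$centroid[1] <= nr - mr &&
      r$centroid[2] >= mc && r$centroid[2] <= nc - mc
  }, logical(1))
  if (!any(ok)) body_not_found("no admissible body contour on slice")
  cand <- regions[ok]
  areas <- vapply(cand, function(r) r$area_px, numeric(1))
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    ctr <- c((nr + 1) / 2, (nc + 1) / 2)
    d <- vapply(cand[best], function(r) sum((r$centroid - ctr)^2), numeric(1))
    best <- best[which.min(d)]
  }
  cand[[best[1]]]
}

# Grow a symmetric column interval around `centre_col` until `need` body
# pixels (or band area) are enclosed. `col_counts` is the per-column body
# pixel count.
grow_band <- function(col_counts, centre_col, need, mode, nrow_img) {
  nc <- length(col_counts)
  lo <- hi <- centre_col
  enclosed <- col_counts[centre_col]
  repeat {
    got <- if (mode == "enclosed_body_area") enclosed
           else (hi - lo + 1L) * nrow_img
    if (got >= need || (lo == 1L && hi == nc)) break
    if (lo > 1L) { lo <- lo - 1L; enclosed <- enclosed + col_counts[lo] }
    if (hi < nc) { hi <- hi + 1L; enclosed <- enclosed + col_counts[hi] }
  }
  c(lo = lo, hi = hi)
}

#' Central calculation band of a slice
#'
#' Starting from the image centre column and extending symmetrically left
#' and right, returns the narrowest column interval enclosing at least
#' `band_fraction` of the body area. Only air inside this band counts
#' toward the apex rule, which shields the ratio from hollow artifacts near
#' the body margin on poor-quality slices.
#'
#' @param body A `contour_region` for the body.
#' @param image_shape `c(nrow, ncol)`.
#' @param band_fraction Target fraction; default 0.33.
#' @param band_interpretation See [localizer_params()].
#' @return Integer vector `c(lo, hi)` of column bounds (inclusive).
#' @export
central_band <- function(body, image_shape, band_fraction = 0.33,
                         band_interpretation = "enclosed_body_area") {
  if (body$area_px <= 0) stop("body area is zero", call. = FALSE)
  nc <- image_shape[2]
  cc <- as.integer(round((nc + 1) / 2))
  counts <- tabulate(body$pixels[, "col"], nbins = nc)
  need <- band_fraction * body$area_px
  grow_band(counts, cc, need, band_interpretation, image_shape[1])
}

#' Air fraction of a slice inside the body and central band
#'
#' @param slice_hu HU matrix for the slice.
#' @param body Body `contour_region` of the same slice.
#' @param band Column interval `c(lo, hi)` from [central_band()].
#' @param threshold_hu Air threshold (default -160).
#' @return Air pixels inside body-and-band divided by the body area, in
#'   \[0, 1\].
#' @export
air_fraction <- function(slice_hu, body, band, threshold_hu = -160) {
  px <- body$pixels
  in_band <- px[, "col"] >= band[1] & px[, "col"] <= band[2]
  if (!any(in_band)) return(0)
  sel <- px[in_band, , drop = FALSE]
  air <- slice_hu[cbind(sel[, "row"], sel[, "col"])] <= threshold_hu
  sum(air) / body$area_px
}

# Body contour of one slice: binarize air, invert to tissue, fill enclosed
# holes (lungs, trachea) so the body is a single solid region, then select.
slice_body <- function(slice_hu, params) {
  tissue <- !binarize_air(slice_hu, params$air_threshold_hu)
  filled <- EBImage::fillHull(tissue * 1L) > 0
  select_body_contour(find_contours(filled), dim(slice_hu), params)
}

#' Per-slice air-fraction profile of a CT volume
#'
#' Diagnostic companion of [detect_lung_apex()]: runs the body-contour,
#' band and air-fraction chain on every slice.
#'
#' @param ct A `ct_volume`.
#' @param params A [localizer_params()].
#' @return A tibble with columns `slice`, `body_found`, `body_area_px`,
#'   `air_fraction`.
#' @export
air_fraction_profile <- function(ct, params = localizer_params()) {
  stopifnot(inherits(ct, "ct_volume"))
  n <- dim(ct$voxels)[3]
  rows <- lapply(seq_len(n), function(s) {
    sl <- ct$voxels[, , s]
    body <- tryCatch(slice_body(sl, params),
                     petlung_body_not_found = function(e) NULL)
    if (is.null(body)) {
      return(tibble::tibble(slice = s, body_found = FALSE,
                            body_area_px = NA_integer_,
                            air_fraction = NA_real_))
    }
    band <- central_band(body, dim(sl), params$band_fraction,
                         params$band_interpretation)
    tibble::tibble(slice = s, body_found = TRUE,
                   body_area_px = body$area_px,
                   air_fraction = air_fraction(sl, body, band,
                                               params$air_threshold_hu))
  })
  dplyr::bind_rows(rows)
}

apex_not_found <- function(msg) {
  stop(structure(class = c("petlung_apex_not_found", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Detect the lung apex slice
#'
#' Scans slices superior to inferior and returns the first slice whose
#' air fraction (air inside the body's central band, relative to the body
#' area) reaches `air_fraction_threshold`. Slices without an admissible
#' body contour are skipped.
#'
#' @inheritParams air_fraction_profile
#' @return Integer slice index (1 = most superior); errors with condition
#'   class `petlung_apex_not_found` when no slice reaches the threshold.
#' @export
detect_lung_apex <- function(ct, params = localizer_params()) {
  stopifnot(inherits(ct, "ct_volume"))
  n <- dim(ct$voxels)[3]
  for (s in seq_len(n)) {
    sl <- ct$voxels[, , s]
    body <- tryCatch(slice_body(sl, params),
                     petlung_body_not_found = function(e) NULL)
    if (is.null(body)) next
    band <- central_band(body, dim(sl), params$band_fraction,
                         params$band_interpretation)
    af <- air_fraction(sl, body, band, params$air_threshold_hu)
    if (af >= params$air_fraction_threshold) return(s)
  }
  apex_not_found("no slice reached the air-fraction threshold")
}

# Clamp a crop window [start, start+width-1] into [1, n]; returns start.
clamp_window <- function(start, width, n) {
  if (width > n) stop("crop width exceeds grid size", call. = FALSE)
  min(max(start, 1L), n - width + 1L)
}

#' Extract aligned CT/PET lung sub-volumes
#'
#' Runs apex detection, then crops `crop_width_px` square windows centred
#' on the body centroid of the apex slice over `num_slices` consecutive
#' slices starting at the apex. The PET crop covers the same physical
#' window at `pet_crop_px` resolution (native crop when the window aligns
#' with the PET grid, per-slice bilinear resampling otherwise). Slices past
#' the inferior end are padded with air (HU -1000 / activity 0); windows
#' that would exit the grid are shifted inward. Both events are recorded in
#' the result's provenance.
#'
#' @param study A `study_pair`.
#' @param params A [localizer_params()].
#' @return An object of class `lung_crop_result` with elements `ct_crop`
#'   (crop x crop x num_slices HU array), `pet_crop`
#'   (pet x pet x num_slices), `apex_slice`, `crop_origin` (row, col of the
#'   crop's first pixel), `body_centroid`, `n_padded_slices`,
#'   `shifted_px` and `params`.
#' @export
extract_lung_volume <- function(study, params = localizer_params()) {
  stopifnot(inherits(study, "study_pair"))
  ct <- study$ct$voxels
  pet <- study$pet$voxels
  dct <- dim(ct)
  apex <- detect_lung_apex(study$ct, params)
  body <- slice_body(ct[, , apex], params)
  cw <- params$crop_width_px
  want <- as.integer(round(body$centroid) - cw %/% 2L + 1L)
  r0 <- clamp_window(want[1], cw, dct[1])
  c0 <- clamp_window(want[2], cw, dct[2])
  shifted <- c(row = r0 - want[1], col = c0 - want[2])

  slices <- apex:(apex + params$num_slices - 1L)
  have <- slices[slices <= dct[3]]
  n_pad <- params$num_slices - length(have)

  ct_crop <- array(-1000, c(cw, cw, params$num_slices))
  ct_crop[, , seq_along(have)] <-
    ct[r0:(r0 + cw - 1L), c0:(c0 + cw - 1L), have, drop = FALSE]

  f <- dct[1] / dim(pet)[1]  # integer in-plane downscale factor
  pw <- params$pet_crop_px
  pet_crop <- array(0, c(pw, pw, params$num_slices))
  # physical window in PET pixel coordinates (0-based continuous)
  pr0 <- (r0 - 1) / f; pc0 <- (c0 - 1) / f
  native <- cw / f
  aligned <- isTRUE(all.equal(pr0, round(pr0))) &&
    isTRUE(all.equal(pc0, round(pc0))) && native == pw
  for (i in seq_along(have)) {
    sl <- pet[, , have[i]]
    if (aligned) {
      pet_crop[, , i] <- sl[(round(pr0) + 1):(round(pr0) + pw),
                            (round(pc0) + 1):(round(pc0) + pw)]
    } else {
      rr <- floor(pr0):min(ceiling(pr0 + native), nrow(sl) - 1)
      cc <- floor(pc0):min(ceiling(pc0 + native), ncol(sl) - 1)
      sub <- sl[rr + 1, cc + 1, drop = FALSE]
      pet_crop[, , i] <- as.matrix(EBImage::resize(sub, w = pw, h = pw,
                                                   filter = "bilinear"))
    }
  }

  structure(list(ct_crop = ct_crop, pet_crop = pet_crop,
                 apex_slice = apex,
                 crop_origin = c(row = r0, col = c0),
                 body_centroid = body$centroid,
                 n_padded_slices = n_pad,
                 shifted_px = shifted,
                 params = params),
            class = "lung_crop_result")
}

#' @export
print.lung_crop_result <- function(x, ...) {
  cat(sprintf(paste0("<lung_crop_result> apex slice %d, origin (%d, %d), ",
                     "CT %s, PET %s, %d padded slice(s)\n"),
              x$apex_slice, x$crop_origin[1], x$crop_origin[2],
              paste(dim(x$ct_crop), collapse = "x"),
              paste(dim(x$pet_crop), collapse = "x"),
              x$n_padded_slices))
  invisible(x)
}
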