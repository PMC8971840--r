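#' Nodule annotation table
#'
#' Builds (or validates) the expert-annotation table used by the manual
#' preprocessing route: one row per nodule with the representative slice
#' (the slice of maximum nodule diameter), the in-plane centre in CT
#' pixels, and the pathology label. When a case carries several
#' annotations, [crop_manual()] uses the first and notes the rest.
#'
#' @param case_id Character vector.
#' @param slice Integer representative slice (1 = most superior).
#' @param row,col Nodule centre in CT pixels.
#' @param label `"benign"` or `"malignant"`.
#' @return A tibble with class-checked columns.
#' @export
nodule_annotations <- function(case_id, slice, row, col, label) {
  stopifnot(all(label %in% c("benign", "malignant")))
  tibble::tibble(case_id = as.character(case_id),
                 slice = as.integer(slice),
                 row = as.numeric(row), col = as.numeric(col),
                 label = as.character(label))
}

#' Read nodule annotations from CSV
#'
#' Expects columns `case_id, slice, row, col, label`.
#'
#' @param path CSV path.
#' @return Annotation tibble as from [nodule_annotations()].
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "slice", "row", "col", "label")
  if (!all(need %in% names(df))) {
    stop("annotation file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  nodule_annotations(df$case_id, df$slice, df$row, df$col, df$label)
}

#' Fixed-size crop around an annotated nodule
#'
#' The expert-annotation alternative to the automated localizer: 16
#' consecutive slices centred on the representative slice (8 above, 7
#' below, plus the slice itself; shifted inward at volume ends), a
#' `crop_px` square CT window centred on the annotated point, and the PET
#' crop over the same physical window resized per slice to the CT crop
#' size by bilinear interpolation.
#'
#' @param study A `study_pair`.
#' @param ann One annotation row (tibble or list with `slice`, `row`,
#'   `col`); for a multi-row table the first row matching the study's
#'   `case_id` is used and extra rows are reported in a message.
#' @param crop_px In-plane CT crop side; default 64.
#' @param n_slices Slice count; default 16.
#' @return An object of class `manual_crop_result` with `ct_crop` and
#'   `pet_crop_resized`, both `crop_px x crop_px x n_slices`, plus
#'   provenance (`slice_range`, `crop_origin`, `shifted_px`).
#' @export
crop_manual <- function(study, ann, crop_px = 64L, n_slices = 16L) {
  stopifnot(inherits(study, "study_pair"))
  if (is.data.frame(ann)) {
    if ("case_id" %in% names(ann)) {
      ann <- ann[ann$case_id == study$case_id, , drop = FALSE]
    }
    if (nrow(ann) == 0L) stop("no annotation for case ", study$case_id,
                              call. = FALSE)
    if (nrow(ann) > 1L) {
      message("case ", study$case_id, ": using first of ", nrow(ann),
              " annotations")
    }
    ann <- as.list(ann[1L, ])
  }
  ct <- study$ct$voxels; pet <- study$pet$voxels
  dct <- dim(ct)
  rep_slice <- as.integer(ann$slice)
  if (rep_slice < 1L || rep_slice > dct[3] ||
      ann$row < 1 || ann$row > dct[1] || ann$col < 1 || ann$col > dct[2]) {
    stop("annotation lies outside the volume", call. = FALSE)
  }
  # 16 consecutive slices centred on the representative slice: 8 above,
  # the slice itself, 7 below; shifted inward at the ends.
  s0 <- clamp_window(rep_slice - n_slices %/% 2L, n_slices, dct[3])
  want <- as.integer(round(c(ann$row, ann$col)) - crop_px %/% 2L + 1L)
  r0 <- clamp_window(want[1], crop_px, dct[1])
  c0 <- clamp_window(want[2], crop_px, dct[2])
  slices <- s0:(s0 + n_slices - 1L)

  ct_crop <- ct[r0:(r0 + crop_px - 1L), c0:(c0 + crop_px - 1L), slices,
                drop = FALSE]

  f <- dct[1] / dim(pet)[1]
  native <- crop_px / f
  pr0 <- (r0 - 1) / f; pc0 <- (c0 - 1) / f
  pet_crop <- array(0, c(crop_px, crop_px, n_slices))
  aligned <- isTRUE(all.equal(pr0, round(pr0))) &&
    isTRUE(all.equal(pc0, round(pc0)))
  for (i in seq_len(n_slices)) {
    sl <- pet[, , slices[i]]
    if (aligned) {
      sub <- sl[(round(pr0) + 1):(round(pr0) + native),
                (round(pc0) + 1):(round(pc0) + native), drop = FALSE]
    } else {
      rr <- floor(pr0):min(ceiling(pr0 + native), nrow(sl) - 1)
      cc <- floor(pc0):min(ceiling(pc0 + native), ncol(sl) - 1)
      sub <- sl[rr + 1, cc + 1, drop = FALSE]
    }
    pet_crop[, , i] <- as.matrix(EBImage::resize(sub, w = crop_px,
                                                 h = crop_px,
                                                 filter = "bilinear"))
  }

  structure(list(ct_crop = ct_crop, pet_crop_resized = pet_crop,
                 slice_range = c(first = s0, last = s0 + n_slices - 1L),
                 crop_origin = c(row = r0, col = c0),
                 shifted_px = c(row = r0 - want[1], col = c0 - want[2],
                                slice = s0 - (rep_slice - n_slices %/% 2L))),
            class = "manual_crop_result")
}

#' @export
print.manual_crop_result <- function(x, ...) {
  cat(sprintf("<manual_crop_result> slices %d..%d, origin (%d, %d), CT %s\n",
              x$slice_range[1], x$slice_range[2],
              x$crop_origin[1], x$crop_origin[2],
              paste(dim(x$ct_crop), collapse = "x")))
  invisible(x)
}
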