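#' Parametric synthetic thorax phantom specification
#'
#' Describes a synthetic PET-CT thorax: an elliptical soft-tissue body
#' cross-section (default 40 HU) in a dark background (-1000 HU), a
#' tracheal air column above the lung apex, bilateral air-density lung
#' ellipses (-850 HU, below the -160 HU mediastinal air threshold, so the
#' localizer's binarization treats parenchyma as air) that start at
#' `apex_slice` at a reduced scale and ramp to full size inferiorly, and
#' optional spherical nodules with their own HU and PET uptake. PET is
#' rendered on an in-plane grid downscaled by `pet_factor` with uniform
#' background uptake inside the body and per-slice Gaussian smoothing.
#'
#' All in-plane sizes scale with the grid, so the same fractional geometry
#' yields a full 512 x 512 phantom or a fast low-resolution profile (see
#' [phantom_profile()]).
#'
#' @param n_slices,n_rows,n_cols Grid size; default 120 x 512 x 512.
#' @param apex_slice First slice (1-based, superior) carrying lung tissue.
#' @param body_center `(row, col)` of the body ellipse; default grid centre.
#' @param body_semi_axes `(row, col)` semi-axes in px; default
#'   `(0.28 n_rows, 0.36 n_cols)`.
#' @param tissue_hu,background_hu,lung_hu Tissue/background/lung densities.
#' @param trachea_radius_px Tracheal air-column radius; default
#'   `0.022 n_cols`.
#' @param lung_scale0 Lung linear scale at the apex slice (default 0.6);
#'   the scale ramps linearly to 1 over `lung_ramp_slices` slices.
#' @param lung_ramp_slices Ramp length; default 15.
#' @param lung_semi_axes_frac Full-size lung semi-axes as fractions of the
#'   body semi-axes, default `(0.55, 0.30)`.
#' @param lung_medial_gap_frac Gap between the body's midline and each
#'   lung's medial edge, as a fraction of the body column semi-axis
#'   (default 0.08) — keeps the medial lung inside the localizer's central
#'   band at every scale.
#' @param nodules `NULL` or a data frame with columns
#'   `slice, row, col, diameter_px, hu, pet_uptake` (CT pixel
#'   coordinates); every nodule must lie inside a lung.
#' @param pet_factor Integer in-plane CT-to-PET downscale; default 4
#'   (512 -> 128).
#' @param pet_background Background uptake inside the body; default 0.5.
#' @param heart_uptake Uptake of an optional mediastinal/cardiac blood-pool
#'   structure sitting on the midline between the lungs from the apex
#'   downward (0, the default, omits it). When present and hotter than any
#'   nodule it anchors the PET max-normalization, so nodule conspicuity is
#'   read relative to the mediastinum (as in clinical SUV-ratio reading);
#'   this is the configuration used by the heatmap-localization
#'   experiments.
#' @param heart_semi_axes_frac Cardiac ellipse semi-axes as fractions of
#'   the body semi-axes; default `(0.15, 0.06)` (row, col).
#' @param pet_smooth_sigma Per-slice Gaussian sigma in PET px; default 1.
#' @param noise_sigma_hu CT Gaussian noise sigma; default 10.
#' @param seed Integer RNG seed; default 1.
#' @param label Case label recorded in the truth (`"benign"`,
#'   `"malignant"`, `"unknown"`).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 120L, n_rows = 512L, n_cols = 512L,
                         apex_slice = 15L,
                         body_center = NULL,
                         body_semi_axes = NULL,
                         tissue_hu = 40, background_hu = -1000,
                         lung_hu = -850,
                         trachea_radius_px = NULL,
                         lung_scale0 = 0.6, lung_ramp_slices = 15L,
                         lung_semi_axes_frac = c(0.55, 0.30),
                         lung_medial_gap_frac = 0.08,
                         nodules = NULL,
                         pet_factor = 4L, pet_background = 0.5,
                         heart_uptake = 0, heart_semi_axes_frac = c(0.15, 0.06),
                         pet_smooth_sigma = 1, noise_sigma_hu = 10,
                         seed = 1L, label = "unknown") {
  if (is.null(body_center)) body_center <- c((n_rows + 1) / 2, (n_cols + 1) / 2)
  if (is.null(body_semi_axes)) body_semi_axes <- c(0.28 * n_rows, 0.36 * n_cols)
  if (is.null(trachea_radius_px)) trachea_radius_px <- 0.022 * n_cols
  stopifnot(apex_slice >= 1L, apex_slice < n_slices,
            all(body_semi_axes > 0), trachea_radius_px > 0,
            lung_scale0 > 0, lung_scale0 <= 1,
            n_rows %% pet_factor == 0L, n_cols %% pet_factor == 0L,
            noise_sigma_hu >= 0)
  spec <- structure(
    list(n_slices = as.integer(n_slices), n_rows = as.integer(n_rows),
         n_cols = as.integer(n_cols), apex_slice = as.integer(apex_slice),
         body_center = body_center, body_semi_axes = body_semi_axes,
         tissue_hu = tissue_hu, background_hu = background_hu,
         lung_hu = lung_hu, trachea_radius_px = trachea_radius_px,
         lung_scale0 = lung_scale0,
         lung_ramp_slices = as.integer(lung_ramp_slices),
         lung_semi_axes_frac = lung_semi_axes_frac,
         lung_medial_gap_frac = lung_medial_gap_frac,
         nodules = nodules,
         pet_factor = as.integer(pet_factor),
         pet_background = pet_background,
         heart_uptake = heart_uptake,
         heart_semi_axes_frac = heart_semi_axes_frac,
         pet_smooth_sigma = pet_smooth_sigma,
         noise_sigma_hu = noise_sigma_hu,
         seed = as.integer(seed),
         label = match.arg(label, c("benign", "malignant", "unknown"))),
    class = "phantom_spec")
  if (!is.null(nodules)) {
    for (i in seq_len(nrow(nodules))) {
      nd <- nodules[i, ]
      if (!nodule_inside_lung(spec, nd)) {
        stop("nodule ", i, " lies outside the lung regions (spec error)",
             call. = FALSE)
      }
    }
  }
  spec
}

#' Reduced-resolution phantom profile
#'
#' Scales the default phantom geometry down for fast desk-scale runs
#' (grid 44 x 64 x 64) together with matching localizer parameters
#' (crop 32, 32 slices, PET crop 8). Everything downstream — windows,
#' localizer rules, classifier — is resolution-agnostic, so the fast
#' profile exercises the identical code paths.
#'
#' @param ... Overrides forwarded to [phantom_spec()].
#' @return List with elements `spec_args` (defaults for
#'   [phantom_spec()]) and `params` (a [localizer_params()]).
#' @export
phantom_profile <- function(...) {
  spec_args <- utils::modifyList(
    list(n_slices = 44L, n_rows = 64L, n_cols = 64L, apex_slice = 7L,
         lung_ramp_slices = 8L),
    list(...))
  list(spec_args = spec_args,
       params = localizer_params(crop_width_px = 32L, num_slices = 32L,
                                 pet_crop_px = 8L))
}

# Lung geometry at one slice: scale factor and per-lung (centre, semi-axes).
lung_geometry <- function(spec, slice) {
  if (slice < spec$apex_slice) return(NULL)
  ramp <- (slice - spec$apex_slice) / max(spec$lung_ramp_slices, 1L)
  s <- spec$lung_scale0 + (1 - spec$lung_scale0) * min(1, ramp)
  ax <- s * spec$lung_semi_axes_frac * spec$body_semi_axes
  gap <- spec$lung_medial_gap_frac * spec$body_semi_axes[2]
  off <- gap + ax[2]  # medial edge stays `gap` from the midline
  list(scale = s,
       centers = rbind(c(spec$body_center[1], spec$body_center[2] - off),
                       c(spec$body_center[1], spec$body_center[2] + off)),
       semi_axes = ax)
}

nodule_inside_lung <- function(spec, nd) {
  g <- lung_geometry(spec, nd$slice)
  if (is.null(g)) return(FALSE)
  for (i in 1:2) {
    d <- (nd$row - g$centers[i, 1])^2 / g$semi_axes[1]^2 +
         (nd$col - g$centers[i, 2])^2 / g$semi_axes[2]^2
    if (d <= 1) return(TRUE)
  }
  FALSE
}

ellipse_mask <- function(nr, nc, center, semi) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((r - center[1]) / semi[1])^2 + ((c - center[2]) / semi[2])^2 <= 1
}

disk_mask <- function(nr, nc, center, radius) {
  if (radius <= 0) return(matrix(FALSE, nr, nc))
  ellipse_mask(nr, nc, center, c(radius, radius))
}

# Clean (noiseless) per-slice masks; shared by the renderer and the truth.
phantom_slice_masks <- function(spec, slice) {
  nr <- spec$n_rows; nc <- spec$n_cols
  body <- ellipse_mask(nr, nc, spec$body_center, spec$body_semi_axes)
  air <- matrix(FALSE, nr, nc)
  lungs <- matrix(FALSE, nr, nc)
  if (slice < spec$apex_slice) {
    air <- disk_mask(nr, nc, spec$body_center, spec$trachea_radius_px) & body
  } else {
    g <- lung_geometry(spec, slice)
    lungs <- (ellipse_mask(nr, nc, g$centers[1, ], g$semi_axes) |
              ellipse_mask(nr, nc, g$centers[2, ], g$semi_axes)) & body
    air <- lungs
  }
  list(body = body, air = air, lungs = lungs)
}

# In-plane radius of a sphere of diameter d centred at slice s0, at slice s
# (slices treated as unit-spaced voxel layers).
sphere_slice_radius <- function(diameter, dz) {
  r <- diameter / 2
  if (abs(dz) > r) return(0)
  sqrt(r^2 - dz^2)
}

# The apex slice the 5% rule should find, computed on clean geometry:
# first slice where painted air inside the body's central band reaches the
# threshold fraction of the body area.
rule_apex_from_geometry <- function(spec, params = localizer_params()) {
  for (s in seq_len(spec$n_slices)) {
    m <- phantom_slice_masks(spec, s)
    area <- sum(m$body)
    if (area == 0) next
    counts <- tabulate(col(m$body)[m$body], nbins = spec$n_cols)
    cc <- as.integer(round((spec$n_cols + 1) / 2))
    band <- grow_band(counts, cc, params$band_fraction * area,
                      params$band_interpretation, spec$n_rows)
    in_band <- m$air & (col(m$air) >= band[1]) & (col(m$air) <= band[2])
    if (sum(in_band) / area >= params$air_fraction_threshold) return(s)
  }
  NA_integer_
}

#' Generate a synthetic thorax PET-CT study
#'
#' Renders the CT by painting background, body ellipse, tracheal column,
#' lung ellipses and nodule spheres, then adding Gaussian HU noise; the PET
#' carries uniform background uptake inside the body plus nodule uptake
#' spheres, smoothed per slice. Fully reproducible from `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `study` (a `study_pair`) and `truth` (class
#'   `phantom_truth`: the geometric apex, the apex the 5% rule should
#'   find on clean geometry, per-slice body centroid, the nodule table and
#'   the label).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nr <- spec$n_rows; nc <- spec$n_cols; ns <- spec$n_slices
  f <- spec$pet_factor
  pr <- nr %/% f; pc <- nc %/% f
  ct <- array(spec$background_hu, c(nr, nc, ns))
  pet <- array(0, c(pr, pc, ns))
  nodules <- spec$nodules
  for (s in seq_len(ns)) {
    m <- phantom_slice_masks(spec, s)
    sl <- matrix(spec$background_hu, nr, nc)
    sl[m$body] <- spec$tissue_hu
    if (s < spec$apex_slice) {
      sl[m$air] <- spec$background_hu
    } else {
      sl[m$lungs] <- spec$lung_hu
    }
    psl <- matrix(0, pr, pc)
    body_pet <- ellipse_mask(pr, pc, (spec$body_center - 0.5) / f + 0.5,
                             spec$body_semi_axes / f)
    psl[body_pet] <- spec$pet_background
    if (spec$heart_uptake > 0 && s >= spec$apex_slice) {
      heart <- ellipse_mask(pr, pc, (spec$body_center - 0.5) / f + 0.5,
                            pmax(spec$heart_semi_axes_frac *
                                   spec$body_semi_axes / f, 0.75))
      psl[heart] <- spec$heart_uptake
    }
    if (!is.null(nodules)) {
      for (i in seq_len(nrow(nodules))) {
        nd <- nodules[i, ]
        rad <- sphere_slice_radius(nd$diameter_px, s - nd$slice)
        if (rad > 0) {
          dm <- disk_mask(nr, nc, c(nd$row, nd$col), rad)
          sl[dm] <- nd$hu
          # PET partial-volume floor: a nodule smaller than a PET pixel
          # still produces (at least) a one-pixel uptake blob, as the
          # scanner PSF would
          pdm <- disk_mask(pr, pc, (c(nd$row, nd$col) - 0.5) / f + 0.5,
                           max(rad / f, 0.75))
          psl[pdm] <- nd$pet_uptake
        }
      }
    }
    ct[, , s] <- sl
    if (spec$pet_smooth_sigma > 0) {
      psl <- as.matrix(EBImage::gblur(psl, sigma = spec$pet_smooth_sigma))
      psl[psl < 0] <- 0
    }
    pet[, , s] <- psl
  }
  if (spec$noise_sigma_hu > 0) {
    ct <- ct + array(stats::rnorm(length(ct), 0, spec$noise_sigma_hu), dim(ct))
    ct[] <- pmin(pmax(ct, -1024), 3071)
  }
  study <- pair_study(
    ct_volume(ct, slice_thickness_mm = 3.75,
              pixel_spacing_mm = c(500 / nr, 500 / nc)),
    pet_volume(pet, slice_thickness_mm = 3.75,
               pixel_spacing_mm = c(500 / pr, 500 / pc)),
    case_id = sprintf("phantom_%08d", spec$seed),
    label = spec$label)
  truth <- structure(
    list(apex_slice = spec$apex_slice,
         rule_apex_slice = rule_apex_from_geometry(spec),
         body_center = spec$body_center,
         body_semi_axes = spec$body_semi_axes,
         nodules = nodules,
         spec = spec,
         label = spec$label),
    class = "phantom_truth")
  list(study = study, truth = truth)
}

#' Voxelized nodule mask in model-input coordinates
#'
#' Maps a phantom's nodule spheres through a crop's provenance (origin,
#' apex) and a model-input downscale into a logical mask with dimensions
#' `(slice, row, col)` matching [prepare_model_input()].
#'
#' @param truth A `phantom_truth`.
#' @param crop A `lung_crop_result`.
#' @param input_shape Model-input spatial shape `(slice, row, col)`.
#' @return Logical array of dimension `input_shape`; a voxel is inside when
#'   its centre lies within the sphere dilated by half a voxel (i.e. voxels
#'   intersected by the sphere count as nodule at coarse grids).
#' @export
nodule_mask_model <- function(truth, crop, input_shape = c(16L, 16L, 16L)) {
  p <- crop$params
  scale <- input_shape / c(p$num_slices, p$crop_width_px, p$crop_width_px)
  mask <- array(FALSE, input_shape)
  nd <- truth$nodules
  if (is.null(nd) || nrow(nd) == 0L) return(mask)
  d <- seq_len(input_shape[1]); h <- seq_len(input_shape[2])
  w <- seq_len(input_shape[3])
  # voxel centres in crop coordinates
  zc <- (d - 0.5) / scale[1]; rc <- (h - 0.5) / scale[2]
  cc <- (w - 0.5) / scale[3]
  for (i in seq_len(nrow(nd))) {
    ctr <- c(nd$slice[i] - (crop$apex_slice - 1),
             nd$row[i] - (crop$crop_origin["row"] - 1),
             nd$col[i] - (crop$crop_origin["col"] - 1))
    r <- nd$diameter_px[i] / 2 + 0.5 / min(scale)
    dist2 <- outer(outer((zc - ctr[1])^2, (rc - ctr[2])^2, "+"),
                   (cc - ctr[3])^2, "+")
    mask <- mask | (dist2 <= r^2)
  }
  mask
}

#' Generate a labeled phantom cohort
#'
#' Emulates a surgical-pathology cohort: `n_cases` phantoms with a fixed
#' malignant fraction (default 79/112, the class balance of the emulated
#' cohort), one nodule per case. Malignant cases draw larger nodules and
#' higher FDG uptake than benign ones (diameters N(30, 8) vs N(20, 6) px at
#' the 512 reference grid, scaled with the grid; uptake N(6, 1) vs
#' N(2, 0.8), truncated positive), so the classification task is separable
#' by construction. Per-case seeds derive deterministically from `seed`.
#'
#' @param n_cases Number of cases (>= 2).
#' @param malignant_fraction Fraction of malignant cases, in (0, 1).
#' @param profile `"fast"` (default; 44 x 64 x 64 grid) or `"full"`
#'   (120 x 512 x 512).
#' @param noise_sigma_hu CT noise; default 10.
#' @param diameter_params,uptake_params Class-conditional draws as
#'   `list(malignant = c(mean, sd), benign = c(mean, sd))`; diameters are
#'   in px at the 512 reference grid and scale with the grid. Overriding
#'   them changes which trait separates the classes — e.g. matched uptake
#'   with distinct diameters confines the class evidence to the nodule
#'   itself, the design used for heatmap-localization experiments.
#' @param spec_overrides Named list of [phantom_spec()] fields forced onto
#'   every case (e.g. `list(pet_background = 0)` for the
#'   heatmap-localization design).
#' @param seed Master seed.
#' @return List with `cohort` — a tibble (`case_id`, `label`, `study`,
#'   `truth` list-columns) — and `params`, the matching
#'   [localizer_params()].
#' @export
generate_cohort <- function(n_cases = 112L, malignant_fraction = 79 / 112,
                            profile = c("fast", "full"),
                            noise_sigma_hu = 10,
                            diameter_params = list(malignant = c(30, 8),
                                                   benign = c(20, 6)),
                            uptake_params = list(malignant = c(6, 1),
                                                 benign = c(2, 0.8)),
                            spec_overrides = list(),
                            seed = 7L) {
  profile <- match.arg(profile)
  stopifnot(n_cases >= 2, malignant_fraction > 0, malignant_fraction < 1)
  n_mal <- as.integer(round(n_cases * malignant_fraction))
  n_ben <- n_cases - n_mal
  if (n_mal < 1L || n_ben < 1L) {
    stop("infeasible malignant fraction for n = ", n_cases, call. = FALSE)
  }
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max, n_cases)
  labels <- c(rep("malignant", n_mal), rep("benign", n_ben))
  rows <- lapply(seq_len(n_cases), function(i) {
    set.seed(case_seeds[i])
    lab <- labels[i]
    base <- if (profile == "fast") phantom_profile()$spec_args
            else list(n_slices = 120L, n_rows = 512L, n_cols = 512L,
                      apex_slice = 15L, lung_ramp_slices = 15L)
    grid_scale <- base$n_cols / 512
    apex <- base$apex_slice + sample.int(7L, 1) - 4L  # jitter +/- 3
    dp <- diameter_params[[lab]]
    up <- uptake_params[[lab]]
    dia <- max(stats::rnorm(1, dp[1], dp[2]), 8) * grid_scale
    upt <- max(stats::rnorm(1, up[1], up[2]), 0.2)
    body_jit <- stats::runif(2, 0.9, 1.1)
    spec0 <- phantom_spec(n_slices = base$n_slices, n_rows = base$n_rows,
                          n_cols = base$n_cols, apex_slice = apex,
                          lung_ramp_slices = base$lung_ramp_slices,
                          body_semi_axes = c(0.28 * base$n_rows * body_jit[1],
                                             0.36 * base$n_cols * body_jit[2]),
                          noise_sigma_hu = noise_sigma_hu,
                          seed = case_seeds[i] %% .Machine$integer.max,
                          label = lab)
    # place the nodule inside a fully grown lung, midway down the volume
    nd_slice <- apex + spec0$lung_ramp_slices +
      sample.int(max(spec0$n_slices - apex - spec0$lung_ramp_slices - 6L, 1L), 1)
    g <- lung_geometry(spec0, nd_slice)
    side <- sample(1:2, 1)
    ctr <- g$centers[side, ] +
      stats::runif(2, -0.25, 0.25) * g$semi_axes
    dia <- min(dia, 1.2 * min(g$semi_axes))  # keep the sphere inside the lung
    nod <- data.frame(slice = nd_slice, row = ctr[1], col = ctr[2],
                      diameter_px = dia, hu = 20, pet_uptake = upt)
    spec_args <- utils::modifyList(
      list(n_slices = spec0$n_slices, n_rows = spec0$n_rows,
           n_cols = spec0$n_cols, apex_slice = apex,
           lung_ramp_slices = spec0$lung_ramp_slices,
           body_semi_axes = spec0$body_semi_axes,
           noise_sigma_hu = noise_sigma_hu,
           nodules = nod,
           seed = spec0$seed, label = lab),
      spec_overrides)
    spec <- do.call(phantom_spec, spec_args)
    ph <- generate_phantom(spec)
    ph$study$case_id <- sprintf("case_%03d", i)
    tibble::tibble(case_id = ph$study$case_id, label = lab,
                   study = list(ph$study), truth = list(ph$truth))
  })
  cohort <- dplyr::bind_rows(rows)
  # deterministic shuffle so folds are not label-ordered
  cohort <- cohort[sample.int(n_cases), ]
  params <- if (profile == "fast") phantom_profile()$params
            else localizer_params()
  list(cohort = cohort, params = params)
}
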