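test_that("air binarization thresholds at the mediastinal lower bound", {
  expect_true(all(binarize_air(matrix(-1000, 8, 8))))
  expect_false(any(binarize_air(matrix(40, 8, 8))))
  expect_true(binarize_air(matrix(-160), -160)[1, 1])  # <= convention
})

test_that("phantom air mask is recovered by binarization", {
  ph <- fast_phantom(seed = 5)
  s <- ph$truth$apex_slice + 10L
  masks <- petlung:::phantom_slice_masks(ph$spec, s)
  got <- binarize_air(ph$study$ct$voxels[, , s], -160)
  # air inside the body = lungs; outside = background (also <= -160)
  expect_identical(got & masks$body, masks$lungs)
})

test_that("contours report analytic areas and centroids", {
  m <- matrix(FALSE, 64, 64)
  m <- petlung:::ellipse_mask(64, 64, c(32, 32), c(20, 12))
  regs <- find_contours(m)
  expect_length(regs, 1)
  expect_lt(abs(regs[[1]]$area_px - pi * 20 * 12) / (pi * 20 * 12), 0.02)
  expect_equal(unname(regs[[1]]$centroid), c(32, 32), tolerance = 0.01)

  two <- matrix(FALSE, 32, 32)
  two[3:7, 3:7] <- TRUE      # 25 px
  two[20:29, 20:25] <- TRUE  # 60 px
  regs2 <- find_contours(two)
  expect_length(regs2, 2)
  expect_setequal(vapply(regs2, function(r) r$area_px, numeric(1)), c(25, 60))

  expect_identical(find_contours(matrix(FALSE, 8, 8)), list())
})

test_that("enclosed holes are not returned as outer contours", {
  ring <- petlung:::ellipse_mask(64, 64, c(32, 32), c(24, 24)) &
    !petlung:::ellipse_mask(64, 64, c(32, 32), c(10, 10))
  regs <- find_contours(ring)
  expect_length(regs, 1)  # one component; the hole is background
})

test_that("body selection rejects small and edge-biased regions", {
  img <- matrix(FALSE, 100, 100)
  body <- petlung:::ellipse_mask(100, 100, c(50, 50), c(35, 28))  # ~31% area
  blob <- matrix(FALSE, 100, 100); blob[1:10, 1:10] <- TRUE       # 1% corner
  regs <- find_contours(body | blob)
  sel <- select_body_contour(regs, c(100, 100))
  expect_equal(unname(sel$centroid), c(50, 50), tolerance = 0.5)

  # all regions hug the border: body-not-found
  edge <- matrix(FALSE, 100, 100); edge[1:15, ] <- TRUE
  expect_error(select_body_contour(find_contours(edge), c(100, 100)),
               class = "petlung_body_not_found")
})

test_that("a scanner-table strip along the bottom edge is not the body", {
  img_body <- petlung:::ellipse_mask(128, 128, c(60, 64), c(40, 45))
  table_strip <- matrix(FALSE, 128, 128)
  table_strip[120:126, 10:118] <- TRUE
  sel <- select_body_contour(find_contours(img_body | table_strip),
                             c(128, 128))
  expect_equal(unname(sel$centroid)[1], 60, tolerance = 1)
})

test_that("central band encloses the requested body-area fraction", {
  # body filling the full width uniformly: band width ~ fraction * width
  full <- matrix(TRUE, 40, 100)
  reg <- find_contours(full)[[1]]
  band <- central_band(reg, c(40, 100), band_fraction = 0.33)
  expect_lt(abs((band[2] - band[1] + 1) - 33), 2.5)

  # fraction -> 1: band spans the body's column extent
  band_all <- central_band(reg, c(40, 100), band_fraction = 0.999)
  expect_equal(unname(band_all), c(1, 100))

  # brute-force column sweep: enclosed area within one column of target
  ph <- fast_phantom(seed = 2)
  s <- ph$truth$apex_slice + 6L
  body <- petlung:::slice_body(ph$study$ct$voxels[, , s], ph$params)
  b <- central_band(body, c(64, 64), 0.33)
  cols <- body$pixels[, "col"]
  enclosed <- sum(cols >= b[1] & cols <= b[2])
  max_col <- max(tabulate(cols))
  expect_gte(enclosed, 0.33 * body$area_px)
  expect_lt(enclosed - 2 * max_col, 0.33 * body$area_px)
})

test_that("air fraction counts only air inside body and band", {
  sl <- matrix(40, 60, 60)
  body <- find_contours(matrix(TRUE, 60, 60))[[1]]
  band <- c(20L, 40L)
  expect_equal(air_fraction(sl, body, band), 0)
  # air strictly outside the band contributes nothing
  sl2 <- sl; sl2[, 1:10] <- -1000
  expect_equal(air_fraction(sl2, body, band), 0)
  # a known air block inside the band: exact pixel ratio
  sl3 <- sl; sl3[11:30, 21:38] <- -1000  # 20x18 = 360 px of 3600
  expect_equal(air_fraction(sl3, body, band), 0.1)
})

test_that("apex detection triggers at the air-fraction threshold", {
  ph <- fast_phantom(seed = 4)
  expect_identical(detect_lung_apex(ph$study$ct, ph$params),
                   ph$truth$rule_apex_slice)

  # an all-tissue volume has no apex
  solid <- ct_volume(array(40, c(64, 64, 6)))
  expect_error(detect_lung_apex(solid, ph$params),
               class = "petlung_apex_not_found")
})

test_that("air fractions just below threshold never trigger the apex", {
  # all-tissue 64x64 body with an air block inside the central band on
  # every slice: 4.9% of the body area at threshold 5% -> not found;
  # 5.5% -> found on the first slice
  make_vol <- function(frac) {
    body_px <- 64 * 64
    n_air <- round(frac * body_px)
    h <- 20; w <- ceiling(n_air / h)
    sl <- matrix(40, 64, 64)
    sl[23:(23 + h - 1), 28:(28 + w - 1)] <- -1000
    extra <- h * w - n_air
    if (extra > 0) sl[23:(23 + extra - 1), 28 + w - 1] <- 40
    ct_volume(array(rep(sl, 3), c(64, 64, 3)))
  }
  params <- localizer_params(min_body_area_fraction = 0.5,
                             crop_width_px = 32L, num_slices = 2L,
                             pet_crop_px = 8L)
  expect_error(detect_lung_apex(make_vol(0.049), params),
               class = "petlung_apex_not_found")
  expect_identical(detect_lung_apex(make_vol(0.055), params), 1L)
})

test_that("extracted crops have the configured shapes and provenance", {
  ph <- fast_phantom(seed = 6, nodule = TRUE)
  crop <- extract_lung_volume(ph$study, ph$params)
  expect_identical(dim(crop$ct_crop), c(32L, 32L, 32L))
  expect_identical(dim(crop$pet_crop), c(8L, 8L, 32L))
  expect_identical(crop$apex_slice, ph$truth$rule_apex_slice)
  expect_identical(crop$n_padded_slices,
                   max(0L, 32L - (44L - crop$apex_slice + 1L)))
})

test_that("short volumes are padded inferiorly with air", {
  ph <- fast_phantom(seed = 7, n_slices = 20L)
  crop <- extract_lung_volume(ph$study, ph$params)
  n_have <- 20L - crop$apex_slice + 1L
  expect_identical(crop$n_padded_slices, 32L - n_have)
  expect_true(all(crop$ct_crop[, , (n_have + 1):32] == -1000))
  expect_true(all(crop$pet_crop[, , (n_have + 1):32] == 0))
})

test_that("nodule voxels appear at predicted crop-relative indices", {
  ph <- fast_phantom(seed = 8, nodule = TRUE)
  crop <- extract_lung_volume(ph$study, ph$params)
  nd <- ph$truth$nodules[1, ]
  r <- nd$row - (crop$crop_origin["row"] - 1L)
  c <- nd$col - (crop$crop_origin["col"] - 1L)
  s <- nd$slice - (crop$apex_slice - 1L)
  expect_equal(unname(crop$ct_crop[r, c, s]), nd$hu)
})

test_that("localization is deterministic and translation-equivariant", {
  ph1 <- fast_phantom(seed = 9, nodule = TRUE, noise_sigma_hu = 10)
  c1 <- extract_lung_volume(ph1$study, ph1$params)
  c2 <- extract_lung_volume(ph1$study, ph1$params)
  expect_identical(c1, c2)

  # shift the body by (4, -4) px (a multiple of the PET factor)
  d <- c(4, -4)
  pp <- phantom_profile(seed = 9, noise_sigma_hu = 0)
  spec0 <- do.call(phantom_spec, pp$spec_args)
  shifted_args <- pp$spec_args
  shifted_args$body_center <- spec0$body_center + d
  spec1 <- do.call(phantom_spec, shifted_args)
  a <- extract_lung_volume(generate_phantom(spec0)$study, pp$params)
  b <- extract_lung_volume(generate_phantom(spec1)$study, pp$params)
  expect_identical(unname(b$crop_origin - a$crop_origin), as.integer(d))
  expect_equal(b$ct_crop, a$ct_crop)
  expect_equal(b$pet_crop, a$pet_crop)
})
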