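test_that("phantom generation is reproducible from the seed", {
  a <- fast_phantom(seed = 12, noise_sigma_hu = 10, nodule = TRUE)
  b <- fast_phantom(seed = 12, noise_sigma_hu = 10, nodule = TRUE)
  expect_identical(a$study$ct$voxels, b$study$ct$voxels)
  expect_identical(a$study$pet$voxels, b$study$pet$voxels)
})

test_that("noiseless air fraction equals the analytic pixel ratio", {
  ph <- fast_phantom(seed = 13)
  s <- ph$truth$apex_slice + 9L
  masks <- petlung:::phantom_slice_masks(ph$spec, s)
  body <- petlung:::slice_body(ph$study$ct$voxels[, , s], ph$params)
  band <- central_band(body, c(64, 64), 0.33)
  got <- air_fraction(ph$study$ct$voxels[, , s], body, band)
  in_band <- masks$air & col(masks$air) >= band[1] & col(masks$air) <= band[2]
  expect_equal(got, sum(in_band) / sum(masks$body))
})

test_that("the hottest PET voxel lies inside the nodule", {
  ph <- fast_phantom(seed = 14, nodule = TRUE)
  nd <- ph$truth$nodules[1, ]
  idx <- which(ph$study$pet$voxels == max(ph$study$pet$voxels),
               arr.ind = TRUE)[1, ]
  f <- ph$spec$pet_factor
  ctr_pet <- (c(nd$row, nd$col) - 0.5) / f + 0.5
  d <- sqrt((idx[1] - ctr_pet[1])^2 + (idx[2] - ctr_pet[2])^2)
  expect_lte(d, nd$diameter_px / 2 / f + 1)
  # within the sphere's slice extent (per-slice smoothing can move the
  # peak between slices of a small nodule)
  expect_lte(abs(unname(idx[3]) - nd$slice), floor(nd$diameter_px / 2))
})

test_that("nodules outside the lungs are rejected", {
  pp <- phantom_profile(nodules = data.frame(slice = 30, row = 32, col = 32,
                                             diameter_px = 4, hu = 20,
                                             pet_uptake = 5))
  expect_error(do.call(phantom_spec, pp$spec_args), "outside the lung")
  # a nodule above the apex has no lung to live in
  pp2 <- phantom_profile(nodules = data.frame(slice = 2, row = 32, col = 22,
                                              diameter_px = 4, hu = 20,
                                              pet_uptake = 5))
  expect_error(do.call(phantom_spec, pp2$spec_args), "outside the lung")
})

test_that("cohort class counts follow the malignant fraction", {
  gen <- generate_cohort(n_cases = 112, malignant_fraction = 79 / 112,
                         seed = 21)
  expect_identical(sum(gen$cohort$label == "malignant"), 79L)
  expect_identical(sum(gen$cohort$label == "benign"), 33L)

  gen2 <- generate_cohort(n_cases = 10, malignant_fraction = 0.5, seed = 22)
  expect_identical(as.integer(table(gen2$cohort$label)), c(5L, 5L))

  expect_error(generate_cohort(n_cases = 5, malignant_fraction = 0.01),
               "infeasible")
})

test_that("different master seeds move the nodules but not the counts", {
  g1 <- generate_cohort(n_cases = 8, malignant_fraction = 0.5, seed = 1)
  g2 <- generate_cohort(n_cases = 8, malignant_fraction = 0.5, seed = 2)
  expect_identical(table(g1$cohort$label), table(g2$cohort$label))
  n1 <- dplyr::bind_rows(lapply(g1$cohort$truth, function(t) t$nodules))
  n2 <- dplyr::bind_rows(lapply(g2$cohort$truth, function(t) t$nodules))
  expect_false(isTRUE(all.equal(n1$row, n2$row)))
})

test_that("class-conditional uptake distributions separate the cohort", {
  gen <- generate_cohort(n_cases = 112, seed = 23)
  upt <- vapply(gen$cohort$truth, function(t) t$nodules$pet_uptake[1],
                numeric(1))
  ht <- stats::t.test(upt[gen$cohort$label == "malignant"],
                      upt[gen$cohort$label == "benign"])
  expect_lt(ht$p.value, 0.01)
})

test_that("generated phantoms satisfy the localizer preconditions", {
  gen <- generate_cohort(n_cases = 6, malignant_fraction = 0.5,
                         noise_sigma_hu = 15, seed = 24)
  for (i in seq_len(6)) {
    ap <- detect_lung_apex(gen$cohort$study[[i]]$ct, gen$params)
    expect_lte(abs(ap - gen$cohort$truth[[i]]$rule_apex_slice), 1)
  }
})
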