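test_that("the top branch retains the input spatial shape at every stage", {
  set.seed(1)
  m <- build_hrnet3d(c(2, 8, 8, 8), n_branches = 3, base_channels = 2,
                     blocks_per_stage = 1)
  sh <- feature_shapes(m)
  top <- sh[!is.na(sh$d) & sh$branch == 0, ]
  expect_gt(nrow(top), 5)
  expect_true(all(top$d == 8 & top$h == 8 & top$w == 8))
  # lower branches live at halved resolutions
  b1 <- sh[!is.na(sh$d) & sh$branch == 1 & sh$role %in%
             c("stage_out", "fusion_out"), ]
  expect_true(all(b1$d == 4))
  b2 <- sh[!is.na(sh$d) & sh$branch == 2 & sh$role %in%
             c("stage_out", "fusion_out"), ]
  expect_true(all(b2$d == 2))
})

test_that("a single-branch model degenerates to a plain CNN", {
  set.seed(1)
  m <- build_hrnet3d(c(2, 6, 6, 6), n_branches = 1, base_channels = 2)
  ops <- vapply(m$nodes, function(n) n$op, character(1))
  expect_false(any(ops == "upsample"))
  strides <- vapply(m$nodes, function(n) {
    if (n$op == "conv") n$stride else 1L
  }, integer(1))
  expect_true(all(strides == 1L))
})

test_that("invalid input shapes are refused at build time", {
  expect_error(build_hrnet3d(c(2, 6, 6, 6), n_branches = 3), "divisible")
  expect_error(build_resnet3d(c(2, 6, 6, 6), n_stages = 3), "divisible")
})

test_that("model construction is deterministic given the seed", {
  set.seed(7); m1 <- build_hrnet3d(c(2, 8, 8, 8), base_channels = 2)
  set.seed(7); m2 <- build_hrnet3d(c(2, 8, 8, 8), base_channels = 2)
  expect_identical(n_parameters(m1), n_parameters(m2))
  expect_identical(m1$nodes, m2$nodes)
})

test_that("the residual baseline strictly downsamples across stages", {
  set.seed(1)
  m <- build_resnet3d(c(2, 16, 16, 16), base_channels = 2, n_stages = 3)
  sh <- feature_shapes(m)
  down <- sh[sh$role %in% "downsample", ]
  expect_identical(down$d, c(8L, 4L, 2L))
  expect_true(all(diff(down$d) < 0))
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(11)
  model <- build_hrnet3d(c(2, 4, 4, 4), n_branches = 2, base_channels = 2,
                         blocks_per_stage = 1)
  x <- array(stats::rnorm(2 * 4 * 4 * 4 * 3), c(2, 4, 4, 4, 3))
  y <- c(0L, 1L, 1L)
  cache <- petlung:::nn_forward(model, x)
  sm <- petlung:::softmax_ce(cache[[model$output]], y)
  grads <- petlung:::nn_backward(model, cache, sm$dlogits)
  eps <- 1e-5
  rel_errs <- numeric(0)
  for (id in names(grads)) {
    for (pn in names(grads[[id]])) {
      P <- model$nodes[[id]]$params[[pn]]
      k <- which.max(abs(grads[[id]][[pn]]))
      mp <- model; mp$nodes[[id]]$params[[pn]][k] <- P[k] + eps
      mm <- model; mm$nodes[[id]]$params[[pn]][k] <- P[k] - eps
      lp <- petlung:::softmax_ce(
        petlung:::nn_forward(mp, x)[[model$output]], y)$loss
      lm <- petlung:::softmax_ce(
        petlung:::nn_forward(mm, x)[[model$output]], y)$loss
      num <- (lp - lm) / (2 * eps)
      ana <- grads[[id]][[pn]][k]
      rel_errs <- c(rel_errs, abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
    }
  }
  # the finite-difference probe occasionally straddles a rectifier kink,
  # inflating isolated entries; a backprop defect would corrupt most of
  # them, so assert the error distribution rather than every entry
  expect_lt(median(rel_errs), 1e-7)
  expect_gte(mean(rel_errs < 1e-5), 0.9)
  expect_lt(max(rel_errs), 0.05)
})

test_that("multiscale fusion resamples linearly between branches", {
  # nearest upsampling repeats blocks exactly
  x <- array(seq_len(2 * 2 * 2 * 2), c(1, 2, 2, 2, 2))
  nd <- list(op = "upsample", factor = 2L)
  y <- petlung:::node_forward(nd, list(x))
  expect_identical(dim(y), c(1L, 4L, 4L, 4L, 2L))
  expect_equal(y[1, 1, 1, 1, 1], y[1, 2, 2, 2, 1])
  expect_equal(y[1, 3, 1, 1, 1], x[1, 2, 1, 1, 1])
  # fusion is additive: with one branch zeroed, the sum equals the other
  a <- array(stats::rnorm(8), c(1, 2, 2, 2, 1))
  expect_equal(petlung:::node_forward(list(op = "add"), list(a, a * 0)), a)
})

test_that("training separates a mean-shifted toy problem", {
  set.seed(5)
  n <- 16
  x <- array(stats::rnorm(2 * 4 * 4 * 4 * n, 0, 0.3), c(2, 4, 4, 4, n))
  y <- rep(0:1, each = n / 2)
  x[, , , , y == 1] <- x[, , , , y == 1] + 0.8
  m <- build_hrnet3d(c(2, 4, 4, 4), n_branches = 2, base_channels = 2,
                     blocks_per_stage = 1)
  fit <- fit_classifier(m, x, y, epochs = 15, batch_size = 8, lr = 5e-3)
  expect_equal(fit$history$train_acc[nrow(fit$history)], 1)
  p <- predict_proba(fit$model, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean(p[y == 1]), mean(p[y == 0]))
})

test_that("cross-validation partitions cases once and stratifies", {
  set.seed(9)
  n <- 40
  x <- array(stats::rnorm(1 * 4 * 4 * 4 * n), c(1, 4, 4, 4, n))
  y <- rep(c(0L, 1L), times = c(12, 28))
  ids <- sprintf("c%02d", seq_len(n))
  preds <- train_cv(x, y, ids,
                    function() build_resnet3d(c(1, 4, 4, 4),
                                              base_channels = 2,
                                              n_stages = 1),
                    folds = 5, seed = 3, epochs = 1, batch_size = 8)
  expect_setequal(preds$case_id, ids)
  expect_identical(nrow(preds), as.integer(n))
  expect_true(all(table(preds$fold) %in% c(8L)))
  # too few cases in a class to stratify across folds
  expect_error(
    train_cv(x, c(rep(0L, 37), rep(1L, 3)), ids,
             function() build_resnet3d(c(1, 4, 4, 4), base_channels = 2,
                                       n_stages = 1),
             folds = 5, seed = 3, epochs = 1),
    "at least")
})

test_that("cross-validated runs are reproducible", {
  set.seed(2)
  n <- 12
  x <- array(stats::rnorm(1 * 4 * 4 * 4 * n), c(1, 4, 4, 4, n))
  y <- rep(0:1, 6)
  ids <- as.character(seq_len(n))
  fac <- function() build_resnet3d(c(1, 4, 4, 4), base_channels = 2,
                                   n_stages = 1)
  p1 <- train_cv(x, y, ids, fac, folds = 2, seed = 8, epochs = 2)
  p2 <- train_cv(x, y, ids, fac, folds = 2, seed = 8, epochs = 2)
  expect_identical(p1, p2)
})

test_that("heatmaps have the input shape, unit range, and flag degeneracy", {
  set.seed(4)
  m <- build_hrnet3d(c(2, 8, 8, 8), n_branches = 2, base_channels = 2,
                     blocks_per_stage = 1)
  x <- array(stats::runif(2 * 8 * 8 * 8), c(2, 8, 8, 8))
  h <- compute_heatmap(m, x)
  expect_identical(dim(h), c(8L, 8L, 8L))
  expect_true(all(h >= 0 & h <= 1))
  expect_true(any(h == 0) && any(h == 1))
  # resnet heatmaps are upsampled from the last stage resolution
  mr <- build_resnet3d(c(2, 8, 8, 8), base_channels = 2, n_stages = 2)
  hr <- compute_heatmap(mr, x)
  expect_identical(dim(hr), c(8L, 8L, 8L))
  # a constant feature map warns and returns zeros
  mz <- m
  for (id in names(mz$nodes)) {
    if (!is.null(mz$nodes[[id]]$params)) {
      mz$nodes[[id]]$params$W[] <- 0
      mz$nodes[[id]]$params$b[] <- 0
    }
  }
  expect_warning(hz <- compute_heatmap(mz, x), "constant")
  expect_true(all(hz == 0))
})

test_that("model inputs are windowed, normalized and stacked as channels", {
  ph <- fast_phantom(seed = 15, nodule = TRUE)
  crop <- extract_lung_volume(ph$study, ph$params)
  x <- prepare_model_input(crop, input_shape = c(16, 16, 16))
  expect_identical(dim(x), c(2L, 16L, 16L, 16L))
  expect_true(all(x >= 0 & x <= 1))
  xct <- prepare_model_input(crop, input_shape = c(16, 16, 16),
                             channels = "ct")
  expect_identical(dim(xct), c(1L, 16L, 16L, 16L))
  expect_equal(xct[1, , , ], x[1, , , ])
})
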