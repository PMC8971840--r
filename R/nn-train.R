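# Training utilities: model-input assembly, Adam fitting, stratified k-fold
# cross-validation, and class-activation heatmaps.

# Integer-factor 3-D resize: axes needing enlargement are nearest-repeated,
# axes needing reduction are mean-pooled. Non-integer factors are refused —
# the pipeline's shapes are chosen so they never occur.
resize_3d <- function(a, out_shape) {
  d <- dim(a)
  out_shape <- as.integer(out_shape)
  up <- pmax(out_shape %/% d, 1L)
  if (any(up > 1L)) {
    bad <- up > 1L & (out_shape %% d != 0L)
    if (any(bad)) stop("non-integer upsample factor", call. = FALSE)
    a <- a[rep(seq_len(d[1]), each = up[1]),
           rep(seq_len(d[2]), each = up[2]),
           rep(seq_len(d[3]), each = up[3]), drop = FALSE]
    d <- dim(a)
  }
  f <- d %/% out_shape
  if (any(d %% out_shape != 0L)) stop("non-integer downsample factor",
                                      call. = FALSE)
  if (all(f == 1L)) return(a)
  dim(a) <- c(f[1], out_shape[1], f[2], out_shape[2], f[3], out_shape[3])
  a <- aperm(a, c(2, 4, 6, 1, 3, 5))
  dim(a) <- c(prod(out_shape), prod(f))
  a <- rowMeans(a)
  dim(a) <- out_shape
  a
}

#' Assemble the model-input tensor from a crop
#'
#' Normalizes the CT crop with the lung window (WL -400 / WW 1500), the
#' PET crop by its volume maximum, brings both to a common
#' `(slice, row, col)` grid (`input_shape`) and stacks them as channels:
#' CT = channel 1, PET = channel 2 (early fusion). `channels = "ct"`
#' produces the CT-only input used for the PET-CT-vs-CT contrast.
#'
#' @param crop A `lung_crop_result` or `manual_crop_result`.
#' @param input_shape Target spatial shape `(slice, row, col)`; default
#'   `c(16, 16, 16)`.
#' @param channels `"petct"` (default) or `"ct"`.
#' @return Numeric array `(channels, slice, row, col)` with values in
#'   \[0, 1\].
#' @export
prepare_model_input <- function(crop, input_shape = c(16L, 16L, 16L),
                                channels = c("petct", "ct")) {
  channels <- match.arg(channels)
  pet <- if (!is.null(crop$pet_crop)) crop$pet_crop else crop$pet_crop_resized
  ct_n <- apply_window(crop$ct_crop, window_lung())
  ct_n <- resize_3d(aperm(ct_n, c(3, 1, 2)), input_shape)
  if (channels == "ct") {
    x <- array(0, c(1L, input_shape))
    x[1, , , ] <- ct_n
    return(x)
  }
  pet_n <- suppressWarnings(normalize_pet(pet))
  pet_n <- resize_3d(aperm(pet_n, c(3, 1, 2)), input_shape)
  x <- array(0, c(2L, input_shape))
  x[1, , , ] <- ct_n
  x[2, , , ] <- pet_n
  x
}

annotation_from_truth <- function(truth, case_id) {
  nd <- truth$nodules
  if (is.null(nd) || nrow(nd) == 0L) {
    stop("phantom truth carries no nodule to annotate", call. = FALSE)
  }
  nodule_annotations(case_id, nd$slice[1], nd$row[1], nd$col[1],
                     if (truth$label == "unknown") "benign" else truth$label)
}

#' Preprocess a phantom cohort into a training tensor
#'
#' Runs either the automated localizer ([extract_lung_volume()]) or the
#' manual-annotation crop ([crop_manual()], annotated from the phantom
#' truth) on every study, then stacks the per-case model inputs.
#'
#' @param cohort Tibble from [generate_cohort()] (columns `case_id`,
#'   `label`, `study`, `truth`).
#' @param params [localizer_params()] for the automated mode.
#' @param mode `"automated"` or `"manual"`.
#' @param input_shape Spatial model-input shape.
#' @param channels `"petct"` or `"ct"`.
#' @param manual_crop_px,manual_n_slices Manual-mode crop geometry.
#' @return List with `x` (array `(C, D, H, W, N)`), `y` (integer 0/1,
#'   1 = malignant), `case_ids`, and `crops` (list of crop results).
#' @export
prepare_cohort_inputs <- function(cohort, params = localizer_params(),
                                  mode = c("automated", "manual"),
                                  input_shape = c(16L, 16L, 16L),
                                  channels = "petct",
                                  manual_crop_px = 64L,
                                  manual_n_slices = 16L) {
  mode <- match.arg(mode)
  crops <- purrr::map2(cohort$study, cohort$truth, function(st, tr) {
    if (mode == "automated") {
      extract_lung_volume(st, params)
    } else {
      crop_manual(st, annotation_from_truth(tr, st$case_id),
                  crop_px = manual_crop_px, n_slices = manual_n_slices)
    }
  })
  xs <- purrr::map(crops, prepare_model_input, input_shape = input_shape,
                   channels = channels)
  nch <- dim(xs[[1]])[1]
  x <- array(0, c(nch, input_shape, length(xs)))
  for (i in seq_along(xs)) x[, , , , i] <- xs[[i]]
  list(x = x,
       y = as.integer(cohort$label == "malignant"),
       case_ids = cohort$case_id,
       crops = crops)
}

#' Fit a classifier by Adam on softmax cross-entropy
#'
#' Mini-batch training with the Adam optimizer. Weight initialization and
#' batch shuffling use the current RNG state; seed before calling for a
#' reproducible run.
#'
#' @param model An `nn_model`.
#' @param x Input tensor `(C, D, H, W, N)`.
#' @param y Integer labels (0 = benign, 1 = malignant).
#' @param epochs,batch_size,lr Optimization schedule.
#' @param class_weights `NULL`, a length-2 numeric (benign, malignant), or
#'   `"balanced"` for inverse-frequency weights.
#' @param weight_decay Decoupled L2 shrinkage applied with each Adam step
#'   (default 0); non-zero values concentrate class-activation heatmaps on
#'   discriminative channels.
#' @param lr_schedule `"constant"` (default) or `"cosine"` — cosine decay
#'   anneals the step size to near zero over the run, which stabilizes the
#'   late phase of small-batch training.
#' @return List with the trained `model` and `history` (per-epoch mean
#'   loss and training accuracy).
#' @export
fit_classifier <- function(model, x, y, epochs = 12L, batch_size = 14L,
                           lr = 2e-3, class_weights = NULL,
                           weight_decay = 0,
                           lr_schedule = c("constant", "cosine")) {
  lr_schedule <- match.arg(lr_schedule)
  n <- dim(x)[5]
  stopifnot(length(y) == n, all(y %in% 0:1))
  if (identical(class_weights, "balanced")) {
    tab <- tabulate(y + 1L, 2L)
    class_weights <- n / (2 * pmax(tab, 1L))
  }
  state <- adam_init(model)
  history <- tibble::tibble(epoch = integer(0), loss = numeric(0),
                            train_acc = numeric(0))
  for (ep in seq_len(epochs)) {
    lr_ep <- if (lr_schedule == "cosine") {
      lr * 0.5 * (1 + cos(pi * (ep - 1) / epochs))
    } else lr
    ord <- sample.int(n)
    losses <- numeric(0)
    correct <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- x[, , , , idx, drop = FALSE]
      yb <- y[idx]
      cache <- nn_forward(model, xb)
      sm <- softmax_ce(cache[[model$output]], yb, class_weights)
      losses <- c(losses, sm$loss)
      correct <- correct + sum((sm$p[2, ] > 0.5) == (yb == 1L))
      grads <- nn_backward(model, cache, sm$dlogits)
      upd <- adam_step(model, grads, state, lr = lr_ep,
                       weight_decay = weight_decay)
      model <- upd$model
      state <- upd$state
    }
    history <- dplyr::bind_rows(history,
      tibble::tibble(epoch = ep, loss = mean(losses),
                     train_acc = correct / n))
  }
  list(model = model, history = history)
}

#' Malignancy scores for a batch of inputs
#'
#' @param model Trained `nn_model`.
#' @param x Input tensor `(C, D, H, W, N)`.
#' @param batch_size Forward-pass batch size.
#' @return Numeric vector of P(malignant) in \[0, 1\].
#' @export
predict_proba <- function(model, x, batch_size = 16L) {
  n <- dim(x)[5]
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    cache <- nn_forward(model, x[, , , , idx, drop = FALSE])
    logits <- cache[[model$output]]
    m <- apply(logits, 2, max)
    e <- exp(sweep(logits, 2, m))
    out[idx] <- e[2, ] / colSums(e)
  }
  out
}

# Stratified fold assignment: classes are shuffled separately and dealt
# round-robin with a continuing counter, so fold sizes differ by at most
# one overall and per class.
stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  counter <- 0L
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((counter + seq_along(idx) - 1L) %% folds) + 1L
    counter <- counter + length(idx)
  }
  fold
}

#' Stratified k-fold cross-validated training
#'
#' Splits cases into `folds` label-stratified folds by a seeded shuffle,
#' trains one model per fold on the remaining folds and scores the held-out
#' cases, so every case is predicted exactly once by a model that never saw
#' it.
#'
#' @param x Input tensor `(C, D, H, W, N)`.
#' @param y Integer labels (0/1).
#' @param case_ids Character case identifiers.
#' @param model_factory Zero-argument function returning a fresh
#'   `nn_model`.
#' @param folds Number of folds; default 5.
#' @param seed Seed for fold assignment, initialization and shuffling.
#' @inheritParams fit_classifier
#' @return Tibble `(case_id, label, score, fold)` covering every case once.
#' @export
train_cv <- function(x, y, case_ids, model_factory, folds = 5L, seed = 1L,
                     epochs = 12L, batch_size = 14L, lr = 2e-3,
                     class_weights = NULL, weight_decay = 0) {
  n <- dim(x)[5]
  stopifnot(length(y) == n, length(case_ids) == n, folds >= 2L)
  if (min(tabulate(y + 1L, 2L)) < folds) {
    stop("need at least `folds` cases per class", call. = FALSE)
  }
  set.seed(seed)
  fold <- stratified_folds(y, folds)
  out <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    if (length(unique(y[tr])) < 2L) {
      stop("a class is absent from fold ", f, "'s training split",
           call. = FALSE)
    }
    set.seed((seed %% 1000003L) * 1009L + f)  # stays within integer range
    model <- model_factory()
    fitted <- fit_classifier(model, x[, , , , tr, drop = FALSE], y[tr],
                             epochs = epochs, batch_size = batch_size,
                             lr = lr, class_weights = class_weights,
                             weight_decay = weight_decay)
    sc <- predict_proba(fitted$model, x[, , , , te, drop = FALSE])
    out[[f]] <- tibble::tibble(case_id = case_ids[te], label = y[te],
                               score = sc, fold = f)
  }
  dplyr::bind_rows(out)
}

#' Class-activation heatmap for one input
#'
#' Aggregates the channels of the model's last high-resolution feature map
#' with the malignant-class weights of the linear head (a class-activation
#' map: with global average pooling the head is linear in the per-voxel
#' features), min-max normalizes to \[0, 1\], and nearest-upsamples to the
#' input spatial shape.
#'
#' @param model Trained `nn_model`.
#' @param x Single input, array `(C, D, H, W)`.
#' @return Numeric array of the input's spatial shape with values in
#'   \[0, 1\]; a degenerate constant feature map returns all zeros with a
#'   warning.
#' @export
compute_heatmap <- function(model, x) {
  d <- dim(x)
  if (length(d) == 4L) dim(x) <- c(d, 1L)
  cache <- nn_forward(model, x)
  feat <- cache[[model$meta$heatmap_node]]
  fd <- dim(feat)
  w <- model$nodes[[model$meta$logits_node]]$params$W[2L, ]
  h <- as.numeric(crossprod(matrix(feat, fd[1]), w))
  dim(h) <- fd[2:4]
  rng <- range(h)
  if (rng[2] - rng[1] < 1e-12) {
    warning("constant feature map; returning a zero heatmap", call. = FALSE)
    h[] <- 0
  } else {
    h <- (h - rng[1]) / (rng[2] - rng[1])
  }
  target <- dim(x)[2:4]
  if (!all(dim(h) == target)) h <- resize_3d(h, target)
  h
}
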