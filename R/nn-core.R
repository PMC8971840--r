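# Minimal 3D convolutional network engine.
#
# Feature tensors are 5-D arrays with dim (C, D, H, W, N): channels fastest,
# then depth (slices), height (rows), width (cols), batch. Convolution is
# im2col (compiled) + BLAS matrix multiply; gradients are exact and checked
# against numerical differentiation in the test suite. A network is a DAG of
# nodes added in topological order; backward walks it in reverse. This keeps
# the whole engine small, deterministic and CPU-friendly.

conv_out_len <- function(n, k, stride, pad) (n + 2 * pad - k) %/% stride + 1L

LEAKY_SLOPE <- 0.05

new_nn_builder <- function(input_shape) {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$shapes <- list(input = as.integer(input_shape))  # (C, D, H, W)
  env$counter <- 0L
  env
}

nn_add <- function(b, op, inputs, id = NULL, branch = NA_integer_,
                   role = NA_character_, ...) {
  b$counter <- b$counter + 1L
  if (is.null(id)) id <- sprintf("%s_%03d", op, b$counter)
  attrs <- list(...)
  node <- c(list(id = id, op = op, inputs = inputs, branch = branch,
                 role = role), attrs)
  in_shape <- b$shapes[[inputs[1]]]
  out_shape <- switch(op,
    conv = {
      k <- attrs$k; s <- attrs$stride; p <- attrs$pad
      c(attrs$c_out, conv_out_len(in_shape[2], k, s, p),
        conv_out_len(in_shape[3], k, s, p), conv_out_len(in_shape[4], k, s, p))
    },
    relu = in_shape,
    add = in_shape,
    upsample = c(in_shape[1], in_shape[2:4] * attrs$factor),
    gap = c(in_shape[1]),
    dense = c(attrs$c_out),
    stop("unknown op ", op))
  if (op == "add") {
    for (i in inputs) {
      if (!identical(b$shapes[[i]], in_shape)) {
        stop("add inputs have incompatible shapes", call. = FALSE)
      }
    }
  }
  # parameter init (He for conv/dense)
  if (op == "conv") {
    fan_in <- in_shape[1] * attrs$k^3
    node$params <- list(
      W = matrix(stats::rnorm(attrs$c_out * fan_in, 0, sqrt(2 / fan_in)),
                 attrs$c_out, fan_in),
      b = stats::rnorm(attrs$c_out, 0, 0.01))
    node$c_in <- in_shape[1]
  } else if (op == "dense") {
    # small-scale head init keeps the softmax well away from saturation
    fan_in <- in_shape[1]
    node$params <- list(
      W = matrix(stats::rnorm(attrs$c_out * fan_in, 0, 0.01),
                 attrs$c_out, fan_in),
      b = stats::rnorm(attrs$c_out, 0, 0.01))
  }
  b$shapes[[id]] <- as.integer(out_shape)
  b$nodes[[id]] <- node
  id
}

nn_finalize <- function(b, output, meta = list()) {
  structure(list(nodes = b$nodes, output = output,
                 input_shape = b$shapes$input, shapes = b$shapes,
                 meta = meta),
            class = "nn_model")
}

#' Number of trainable parameters of a model
#' @param model An `nn_model` built by [build_hrnet3d()] or
#'   [build_resnet3d()].
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$nodes, function(nd) {
    if (is.null(nd$params)) 0L else sum(vapply(nd$params, length, integer(1)))
  }, integer(1)))
}

node_forward <- function(nd, ins, cache_extra = FALSE) {
  switch(nd$op,
    conv = {
      x <- ins[[1]]
      d <- dim(x)
      col <- im2col3d(x, d, nd$k, nd$stride, nd$pad)
      y <- nd$params$W %*% col + nd$params$b
      do <- conv_out_len(d[2], nd$k, nd$stride, nd$pad)
      ho <- conv_out_len(d[3], nd$k, nd$stride, nd$pad)
      wo <- conv_out_len(d[4], nd$k, nd$stride, nd$pad)
      dim(y) <- c(nd$c_out, do, ho, wo, d[5])
      y
    },
    relu = {
      # leaky rectifier: a small negative slope keeps every unit trainable
      y <- ins[[1]]
      neg <- y < 0
      y[neg] <- LEAKY_SLOPE * y[neg]
      y
    },
    add = Reduce(`+`, ins),
    upsample = {
      x <- ins[[1]]
      d <- dim(x)
      f <- nd$factor
      x[, rep(seq_len(d[2]), each = f), rep(seq_len(d[3]), each = f),
        rep(seq_len(d[4]), each = f), , drop = FALSE]
    },
    gap = {
      x <- ins[[1]]
      d <- dim(x)
      s <- prod(d[2:4])
      m <- aperm(array(x, c(d[1], s, d[5])), c(2, 1, 3))
      dim(m) <- c(s, d[1] * d[5])
      out <- colMeans(m)
      dim(out) <- c(d[1], d[5])
      out
    },
    dense = nd$params$W %*% ins[[1]] + nd$params$b)
}

nn_forward <- function(model, x, keep = NULL) {
  cache <- list(input = x)
  for (nd in model$nodes) {
    ins <- lapply(nd$inputs, function(i) cache[[i]])
    cache[[nd$id]] <- node_forward(nd, ins)
  }
  cache
}

# Backward pass: returns list(grads = named list(node id -> list(W, b)),
# using recomputation of im2col from cached activations.
nn_backward <- function(model, cache, dout) {
  dacc <- list()
  dacc[[model$output]] <- dout
  grads <- list()
  for (nd in rev(model$nodes)) {
    dy <- dacc[[nd$id]]
    if (is.null(dy)) next
    dacc[[nd$id]] <- NULL
    switch(nd$op,
      conv = {
        x <- cache[[nd$inputs[1]]]
        d <- dim(x)
        col <- im2col3d(x, d, nd$k, nd$stride, nd$pad)
        dym <- matrix(dy, nrow = nd$c_out)
        grads[[nd$id]] <- list(W = tcrossprod(dym, col), b = rowSums(dym))
        dcol <- crossprod(nd$params$W, dym)
        dx <- col2im3d(dcol, d, nd$k, nd$stride, nd$pad)
        dacc[[nd$inputs[1]]] <- acc_grad(dacc[[nd$inputs[1]]], dx)
      },
      relu = {
        y <- cache[[nd$id]]
        dx <- dy * ifelse(y > 0, 1, LEAKY_SLOPE)
        dacc[[nd$inputs[1]]] <- acc_grad(dacc[[nd$inputs[1]]], dx)
      },
      add = {
        for (i in nd$inputs) dacc[[i]] <- acc_grad(dacc[[i]], dy)
      },
      upsample = {
        f <- nd$factor
        d <- dim(dy)  # upsampled dims
        do <- d[2] %/% f; ho <- d[3] %/% f; wo <- d[4] %/% f
        g <- dy
        dim(g) <- c(d[1], f, do, f, ho, f, wo, d[5])
        g <- aperm(g, c(1, 3, 5, 7, 8, 2, 4, 6))
        dim(g) <- c(d[1] * do * ho * wo * d[5], f^3)
        dx <- rowSums(g)
        dim(dx) <- c(d[1], do, ho, wo, d[5])
        dacc[[nd$inputs[1]]] <- acc_grad(dacc[[nd$inputs[1]]], dx)
      },
      gap = {
        x <- cache[[nd$inputs[1]]]
        d <- dim(x)
        s <- prod(d[2:4])
        # spread dy/(spatial size) uniformly over the spatial positions
        dx <- aperm(array(dy / s, c(d[1], d[5], s)), c(1, 3, 2))
        dim(dx) <- d
        dacc[[nd$inputs[1]]] <- acc_grad(dacc[[nd$inputs[1]]], dx)
      },
      dense = {
        x <- cache[[nd$inputs[1]]]
        grads[[nd$id]] <- list(W = tcrossprod(dy, x), b = rowSums(dy))
        dx <- crossprod(nd$params$W, dy)
        dacc[[nd$inputs[1]]] <- acc_grad(dacc[[nd$inputs[1]]], dx)
      })
  }
  grads
}

acc_grad <- function(cur, g) if (is.null(cur)) g else cur + g

# Softmax cross-entropy on logits (2 x N); y in {0, 1}, 1 = malignant.
# Optional per-class weights. Returns loss and dlogits.
softmax_ce <- function(logits, y, class_weights = NULL) {
  n <- ncol(logits)
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  p <- sweep(e, 2, colSums(e), "/")
  w <- if (is.null(class_weights)) rep(1, n) else class_weights[y + 1L]
  idx <- cbind(y + 1L, seq_len(n))
  loss <- sum(w * (-log(pmax(p[idx], 1e-12)))) / sum(w)
  onehot <- matrix(0, 2, n)
  onehot[idx] <- 1
  dlogits <- sweep(p - onehot, 2, w, "*") / sum(w)
  list(loss = loss, p = p, dlogits = dlogits)
}

adam_init <- function(model) {
  st <- list(t = 0L, m = list(), v = list())
  for (nd in model$nodes) {
    if (!is.null(nd$params)) {
      st$m[[nd$id]] <- lapply(nd$params, function(p) p * 0)
      st$v[[nd$id]] <- lapply(nd$params, function(p) p * 0)
    }
  }
  st
}

adam_step <- function(model, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (id in names(grads)) {
    for (pn in names(grads[[id]])) {
      g <- grads[[id]][[pn]]
      state$m[[id]][[pn]] <- beta1 * state$m[[id]][[pn]] + (1 - beta1) * g
      state$v[[id]][[pn]] <- beta2 * state$v[[id]][[pn]] + (1 - beta2) * g^2
      mhat <- state$m[[id]][[pn]] / bc1
      vhat <- state$v[[id]][[pn]] / bc2
      p_old <- model$nodes[[id]]$params[[pn]]
      # decoupled weight decay (AdamW): shrinks non-discriminative weights
      model$nodes[[id]]$params[[pn]] <-
        p_old - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * p_old)
    }
  }
  list(model = model, state = state)
}

#' Per-node output shapes of a model
#'
#' Analytic (no forward pass) spatial shapes for every node, used by the
#' architecture-contract checks: the top branch of the high-resolution
#' network must retain the input spatial shape at every stage, and the
#' residual baseline must strictly downsample across stages.
#'
#' @param model An `nn_model`.
#' @return Tibble with `id`, `op`, `branch`, `role` and the output shape
#'   columns `c`, `d`, `h`, `w` (`NA` for non-spatial nodes).
#' @export
feature_shapes <- function(model) {
  rows <- lapply(model$nodes, function(nd) {
    sh <- model$shapes[[nd$id]]
    tibble::tibble(id = nd$id, op = nd$op, branch = nd$branch,
                   role = nd$role,
                   c = sh[1],
                   d = if (length(sh) >= 4) sh[2] else NA_integer_,
                   h = if (length(sh) >= 4) sh[3] else NA_integer_,
                   w = if (length(sh) >= 4) sh[4] else NA_integer_)
  })
  dplyr::bind_rows(rows)
}
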