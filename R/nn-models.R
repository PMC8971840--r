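# Architecture builders. Both models consume tensors of shape
# (C, D, H, W, N) built by prepare_model_input(): channel 1 = lung-windowed
# CT, channel 2 = max-normalized PET upsampled to the CT grid.

res_block <- function(b, x, ch, branch) {
  c1 <- nn_add(b, "conv", x, branch = branch, c_out = ch, k = 3L,
               stride = 1L, pad = 1L)
  r1 <- nn_add(b, "relu", c1, branch = branch)
  c2 <- nn_add(b, "conv", r1, branch = branch, c_out = ch, k = 3L,
               stride = 1L, pad = 1L)
  a <- nn_add(b, "add", c(c2, x), branch = branch)
  nn_add(b, "relu", a, branch = branch, role = "block_out")
}

#' Build the 3D high-resolution multi-branch classifier
#'
#' A high-resolution representation-learning network: the top branch keeps
#' the full input resolution through every stage (no stride, no pooling),
#' while lower branches at 1/2, 1/4, ... resolution are spawned by strided
#' convolutions and exchanged with the others at the end of each stage by
#' multiscale fusion — every branch receives the sum of all branches'
#' feature maps, downsampled by strided convolution or channel-projected
#' and nearest-upsampled to its own resolution. The classification head is
#' a 1x1x1 convolution on the fused top branch, global average pooling,
#' and a linear layer to 2 classes, which makes class-activation heatmaps
#' at full input resolution immediate.
#'
#' Layer weights are initialized from the current RNG state; seed before
#' building for reproducible models.
#'
#' @param input_shape `(channels, depth, height, width)` of the input
#'   tensor, e.g. `c(2, 16, 16, 16)`; the spatial dimensions must be
#'   divisible by `2^(n_branches - 1)`.
#' @param n_branches Number of resolution branches; default 3.
#' @param base_channels Channels of the top branch; branch i holds
#'   `base_channels * 2^i`. Default 8.
#' @param blocks_per_stage Residual blocks per branch and stage; default 2.
#' @return An `nn_model`.
#' @export
build_hrnet3d <- function(input_shape = c(2L, 16L, 16L, 16L),
                          n_branches = 3L, base_channels = 8L,
                          blocks_per_stage = 2L) {
  input_shape <- as.integer(input_shape)
  div <- 2L^(n_branches - 1L)
  if (any(input_shape[2:4] %% div != 0L)) {
    stop("input spatial shape must be divisible by 2^(n_branches - 1)",
         call. = FALSE)
  }
  b <- new_nn_builder(input_shape)
  ch <- base_channels * 2L^(seq_len(n_branches) - 1L)
  stem <- nn_add(b, "conv", "input", branch = 0L, role = "stem",
                 c_out = ch[1], k = 3L, stride = 1L, pad = 1L)
  cur <- list(nn_add(b, "relu", stem, branch = 0L, role = "stage_out"))
  for (stage in seq_len(n_branches)) {
    if (stage > 1L) {
      # spawn the next lower-resolution branch from the current lowest
      tr <- nn_add(b, "conv", cur[[stage - 1L]], branch = stage - 1L,
                   role = "transition", c_out = ch[stage], k = 3L,
                   stride = 2L, pad = 1L)
      cur[[stage]] <- nn_add(b, "relu", tr, branch = stage - 1L)
    }
    nb <- length(cur)
    for (br in seq_len(nb)) {
      for (blk in seq_len(blocks_per_stage)) {
        cur[[br]] <- res_block(b, cur[[br]], ch[br], branch = br - 1L)
      }
    }
    if (nb > 1L) cur <- fuse_branches(b, cur, ch[seq_len(nb)])
    for (br in seq_len(nb)) {
      b$nodes[[cur[[br]]]]$role <- "stage_out"
    }
  }
  head_ch <- ch[1] * 2L
  hc <- nn_add(b, "conv", cur[[1]], branch = 0L, role = "head_conv",
               c_out = head_ch, k = 1L, stride = 1L, pad = 0L)
  hr <- nn_add(b, "relu", hc, branch = 0L, role = "heatmap_feature")
  g <- nn_add(b, "gap", hr, branch = 0L)
  out <- nn_add(b, "dense", g, branch = 0L, role = "logits", c_out = 2L)
  nn_finalize(b, out, meta = list(arch = "hrnet3d",
                                  n_branches = n_branches,
                                  base_channels = base_channels,
                                  blocks_per_stage = blocks_per_stage,
                                  heatmap_node = hr, logits_node = out))
}

# Multiscale fusion: each branch j receives the sum of every branch i
# resampled to j's resolution. i < j (higher res -> lower): a chain of
# stride-2 convolutions, the last mapping to j's channel count. i > j
# (lower -> higher): a 1x1x1 channel projection followed by nearest
# upsampling. The identity carries i == j. A ReLU follows the sum.
fuse_branches <- function(b, branches, ch) {
  nb <- length(branches)
  out <- vector("list", nb)
  for (j in seq_len(nb)) {
    terms <- character(0)
    for (i in seq_len(nb)) {
      if (i == j) {
        terms <- c(terms, branches[[i]])
      } else if (i < j) {
        x <- branches[[i]]
        for (step in seq_len(j - i)) {
          # branch tag tracks the node's own resolution (divisor 2^branch)
          cout <- if (step == j - i) ch[j] else ch[i]
          x <- nn_add(b, "conv", x, branch = i - 1L + step,
                      role = "fuse_down", c_out = cout, k = 3L,
                      stride = 2L, pad = 1L)
          if (step < j - i) x <- nn_add(b, "relu", x, branch = i - 1L + step)
        }
        terms <- c(terms, x)
      } else {
        x <- nn_add(b, "conv", branches[[i]], branch = i - 1L,
                    role = "fuse_up_proj", c_out = ch[j], k = 1L,
                    stride = 1L, pad = 0L)
        x <- nn_add(b, "upsample", x, branch = j - 1L, role = "fuse_up",
                    factor = 2L^(i - j))
        terms <- c(terms, x)
      }
    }
    s <- nn_add(b, "add", terms, branch = j - 1L, role = "fusion_sum")
    out[[j]] <- nn_add(b, "relu", s, branch = j - 1L, role = "fusion_out")
  }
  out
}

#' Build the 3D residual baseline classifier
#'
#' A conventional residual network: a stem convolution followed by stages
#' that each halve the spatial resolution with a stride-2 convolution and
#' double the channel count, with residual blocks in between — the
#' "continuously reduce the feature-map size" design the high-resolution
#' network is compared against. Head: global average pooling and a linear
#' layer to 2 classes.
#'
#' @param input_shape `(channels, depth, height, width)`; spatial
#'   dimensions must be divisible by `2^n_stages`.
#' @param base_channels Stem channels; default 8.
#' @param n_stages Number of downsampling stages; default 3.
#' @param blocks_per_stage Residual blocks per stage; default 1.
#' @return An `nn_model`.
#' @export
build_resnet3d <- function(input_shape = c(2L, 16L, 16L, 16L),
                           base_channels = 8L, n_stages = 3L,
                           blocks_per_stage = 1L) {
  input_shape <- as.integer(input_shape)
  if (any(input_shape[2:4] %% 2L^n_stages != 0L)) {
    stop("input spatial shape must be divisible by 2^n_stages", call. = FALSE)
  }
  b <- new_nn_builder(input_shape)
  stem <- nn_add(b, "conv", "input", branch = 0L, role = "stem",
                 c_out = base_channels, k = 3L, stride = 1L, pad = 1L)
  x <- nn_add(b, "relu", stem, branch = 0L, role = "stage_out")
  ch <- base_channels
  for (stage in seq_len(n_stages)) {
    ch <- ch * 2L
    d <- nn_add(b, "conv", x, branch = stage, role = "downsample",
                c_out = ch, k = 3L, stride = 2L, pad = 1L)
    x <- nn_add(b, "relu", d, branch = stage)
    for (blk in seq_len(blocks_per_stage)) {
      x <- res_block(b, x, ch, branch = stage)
    }
    b$nodes[[x]]$role <- "stage_out"
  }
  b$nodes[[x]]$role <- "heatmap_feature"
  g <- nn_add(b, "gap", x, branch = n_stages)
  out <- nn_add(b, "dense", g, branch = n_stages, role = "logits", c_out = 2L)
  nn_finalize(b, out, meta = list(arch = "resnet3d",
                                  base_channels = base_channels,
                                  n_stages = n_stages,
                                  blocks_per_stage = blocks_per_stage,
                                  heatmap_node = x, logits_node = out))
}
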