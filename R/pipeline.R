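#' Configuration of an end-to-end experiment
#'
#' Bundles every knob of a phantom-cohort experiment: cohort generation,
#' localization mode(s), architectures, training schedule and the seed
#' cascade. The default arm grid crosses both architectures with both
#' preprocessing modes (the four comparison arms); `include_ct_contrast`
#' adds CT-only automated arms for the PET-CT-versus-CT contrast.
#'
#' @param n_cases,malignant_fraction,profile,noise_sigma_hu Cohort
#'   settings; see [generate_cohort()].
#' @param arms `NULL` for the default four arms, or a data frame with
#'   columns `arch` (`"hrnet"`/`"resnet"`), `mode`
#'   (`"automated"`/`"manual"`) and optionally `channels`.
#' @param include_ct_contrast Add `hrnet`/`resnet` automated CT-only arms.
#' @param annotations Source of manual-mode annotations; `"truth"`
#'   (phantom ground truth) or an annotation tibble. `NULL` with a manual
#'   arm is a configuration error.
#' @param folds,epochs,batch_size,lr,class_weights Training schedule.
#' @param input_shape Model-input spatial shape.
#' @param base_channels,n_branches Architecture sizing.
#' @param seed Master seed; all stage seeds derive from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_cases = 112L, malignant_fraction = 79 / 112,
                       profile = "fast", noise_sigma_hu = 10,
                       arms = NULL, include_ct_contrast = FALSE,
                       annotations = "truth",
                       folds = 5L, epochs = 12L, batch_size = 14L,
                       lr = 2e-3, class_weights = NULL,
                       input_shape = c(16L, 16L, 16L),
                       base_channels = 8L, n_branches = 3L,
                       seed = 1L) {
  if (is.null(arms)) {
    arms <- expand.grid(arch = c("hrnet", "resnet"),
                        mode = c("automated", "manual"),
                        stringsAsFactors = FALSE)
  }
  arms <- tibble::as_tibble(arms)
  if (!"channels" %in% names(arms)) arms$channels <- "petct"
  if (include_ct_contrast) {
    arms <- dplyr::bind_rows(arms,
      tibble::tibble(arch = c("hrnet", "resnet"),
                     mode = "automated", channels = "ct"))
  }
  stopifnot(all(arms$arch %in% c("hrnet", "resnet")),
            all(arms$mode %in% c("automated", "manual")),
            all(arms$channels %in% c("petct", "ct")))
  if (any(arms$mode == "manual") && is.null(annotations)) {
    stop("manual mode requires annotations (config error)", call. = FALSE)
  }
  structure(list(n_cases = n_cases, malignant_fraction = malignant_fraction,
                 profile = profile, noise_sigma_hu = noise_sigma_hu,
                 arms = arms, annotations = annotations,
                 folds = folds, epochs = epochs, batch_size = batch_size,
                 lr = lr, class_weights = class_weights,
                 input_shape = as.integer(input_shape),
                 base_channels = base_channels, n_branches = n_branches,
                 seed = as.integer(seed)),
            class = "run_config")
}

arm_id <- function(arch, mode, channels) {
  paste0(arch, "-", mode, ifelse(channels == "ct", "-ct", ""))
}

#' Run a full phantom-cohort experiment
#'
#' Generates a labeled phantom cohort, preprocesses it through every
#' localization mode the configured arms need, trains each arm with
#' stratified k-fold cross-validation, and reports per-arm AUCs with
#' confidence intervals plus all pairwise DeLong comparisons (the four
#' default arms yield six pairwise tests). The whole run is reproducible
#' from the master seed, and the report embeds the configuration hash.
#'
#' @param config A [run_config()].
#' @return Object of class `experiment_report`: `arms` (tibble with AUC and
#'   CI per arm), `comparisons` (pairwise DeLong p-values), `predictions`
#'   (named list of prediction tibbles), `config`, `config_hash`.
#' @export
run_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max %/% 2L, 4L)

  gen <- generate_cohort(n_cases = config$n_cases,
                         malignant_fraction = config$malignant_fraction,
                         profile = config$profile,
                         noise_sigma_hu = config$noise_sigma_hu,
                         seed = stage_seeds[1])
  cohort <- gen$cohort

  need <- unique(config$arms[, c("mode", "channels")])
  inputs <- list()
  for (i in seq_len(nrow(need))) {
    key <- paste(need$mode[i], need$channels[i], sep = "_")
    inputs[[key]] <- prepare_cohort_inputs(
      cohort, params = gen$params, mode = need$mode[i],
      input_shape = config$input_shape, channels = need$channels[i])
  }

  preds <- list()
  arm_rows <- list()
  for (i in seq_len(nrow(config$arms))) {
    spec_i <- config$arms[i, ]
    id <- arm_id(spec_i$arch, spec_i$mode, spec_i$channels)
    inp <- inputs[[paste(spec_i$mode, spec_i$channels, sep = "_")]]
    nch <- dim(inp$x)[1]
    factory <- if (spec_i$arch == "hrnet") {
      function() build_hrnet3d(c(nch, config$input_shape),
                               n_branches = config$n_branches,
                               base_channels = config$base_channels)
    } else {
      function() build_resnet3d(c(nch, config$input_shape),
                                base_channels = config$base_channels)
    }
    p <- train_cv(inp$x, inp$y, inp$case_ids, factory,
                  folds = config$folds,
                  seed = (stage_seeds[2] + i) %% .Machine$integer.max,
                  epochs = config$epochs, batch_size = config$batch_size,
                  lr = config$lr, class_weights = config$class_weights)
    preds[[id]] <- p
    r <- roc_auc(p)
    arm_info <- tibble::tibble(arm = id, arch = spec_i$arch,
                               mode = spec_i$mode, channels = spec_i$channels)
    arm_rows[[id]] <- dplyr::bind_cols(
      arm_info, tidy(r)[, c("auc", "ci_low", "ci_high")])
  }
  arms_tbl <- dplyr::bind_rows(arm_rows)

  ids <- names(preds)
  comp_rows <- list()
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in (i + 1L):length(ids)) {
        dt <- delong_test(preds[[ids[i]]], preds[[ids[j]]])
        comp_rows[[length(comp_rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(arm_a = ids[i], arm_b = ids[j]), tidy(dt))
      }
    }
  }
  comparisons <- dplyr::bind_rows(comp_rows)

  report <- list(arms = arms_tbl, comparisons = comparisons,
                 predictions = preds, config = config,
                 config_hash = rlang::hash(unclass(config)),
                 seed = config$seed)
  class(report) <- "experiment_report"
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> seed", x$seed, "config", x$config_hash, "\n")
  print(x$arms)
  if (nrow(x$comparisons)) {
    cat("pairwise DeLong comparisons:\n")
    print(x$comparisons[, c("arm_a", "arm_b", "auc_a", "auc_b", "p_value")])
  }
  invisible(x)
}

#' Write an experiment report to JSON
#'
#' @param report An `experiment_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "experiment_report"))
  out <- list(seed = report$seed,
              config_hash = report$config_hash,
              arms = report$arms,
              comparisons = report$comparisons,
              predictions = lapply(report$predictions, as.data.frame))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
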