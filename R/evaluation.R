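#' Validate a prediction set
#'
#' A prediction set is a tibble with one row per case: `case_id`
#' (unique), `label` (0 = benign, 1 = malignant; `"benign"`/`"malignant"`
#' strings are accepted and recoded) and `score` (malignancy score in
#' \[0, 1\]).
#'
#' @param preds Data frame with columns `case_id`, `label`, `score` (a
#'   missing `case_id` column is filled with row numbers).
#' @param require_both_classes Error unless both classes are present
#'   (default `TRUE`; ROC operations need both).
#' @return The validated tibble with `label` as integer 0/1.
#' @export
as_prediction_set <- function(preds, require_both_classes = TRUE) {
  stopifnot(is.data.frame(preds), all(c("label", "score") %in% names(preds)))
  preds <- tibble::as_tibble(preds)
  if (!"case_id" %in% names(preds)) {
    preds$case_id <- as.character(seq_len(nrow(preds)))
  }
  if (is.character(preds$label) || is.factor(preds$label)) {
    preds$label <- as.integer(as.character(preds$label) == "malignant")
  }
  stopifnot(all(preds$label %in% 0:1))
  if (anyDuplicated(preds$case_id)) {
    stop("case_ids must be unique", call. = FALSE)
  }
  if (require_both_classes && length(unique(preds$label)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  preds
}

# Mann-Whitney AUC via midranks; ties count 0.5. Exact (rational) arithmetic
# in doubles: identical to all-pairs counting.
auc_mann_whitney <- function(label, score) {
  pos <- score[label == 1L]
  neg <- score[label == 0L]
  r <- rank(c(pos, neg), ties.method = "average")
  np <- length(pos); nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# DeLong structural components: V10[i] = mean_j psi(x_i, y_j) over negatives,
# V01[j] = mean_i psi(x_i, y_j) over positives, psi = 1/0.5/0.
delong_components <- function(label, score) {
  pos <- score[label == 1L]
  neg <- score[label == 0L]
  psi <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
}

#' ROC area under the curve with a DeLong confidence interval
#'
#' AUC is the Mann-Whitney U statistic (probability that a malignant case
#' scores above a benign one, ties counted one half); the confidence
#' interval uses the DeLong variance estimator of the AUC of correlated
#' ROC data.
#'
#' @param preds A prediction set (see [as_prediction_set()]).
#' @param conf_level Confidence level; default 0.95.
#' @return Object of class `roc_result`: `auc`, `ci_low`, `ci_high`, `se`,
#'   `n_pos`, `n_neg`, plus the predictions for plotting.
#' @export
roc_auc <- function(preds, conf_level = 0.95) {
  preds <- as_prediction_set(preds)
  cmp <- delong_components(preds$label, preds$score)
  np <- length(cmp$v10); nn <- length(cmp$v01)
  var_auc <- if (np > 1L && nn > 1L) {
    stats::var(cmp$v10) / np + stats::var(cmp$v01) / nn
  } else NA_real_
  se <- sqrt(var_auc)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(auc = cmp$auc,
                 ci_low = max(0, cmp$auc - z * se),
                 ci_high = min(1, cmp$auc + z * se),
                 se = se, conf_level = conf_level,
                 n_pos = np, n_neg = nn, preds = preds),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%d%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
                 se = x$se, conf_level = x$conf_level,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
glance.roc_result <- function(x, ...) tidy(x)

#' ROC curve points
#'
#' @param preds A prediction set.
#' @return Tibble `(threshold, fpr, tpr)` stepping through every distinct
#'   score.
#' @export
roc_points <- function(preds) {
  preds <- as_prediction_set(preds)
  th <- c(Inf, sort(unique(preds$score), decreasing = TRUE), -Inf)
  rows <- lapply(th, function(t) {
    pred_pos <- preds$score >= t
    tibble::tibble(threshold = t,
                   fpr = sum(pred_pos & preds$label == 0L) /
                     sum(preds$label == 0L),
                   tpr = sum(pred_pos & preds$label == 1L) /
                     sum(preds$label == 1L))
  })
  dplyr::bind_rows(rows)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.roc_result <- function(object, ...) {
  pts <- roc_points(object$preds)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC %.3f (%d%% CI %.3f-%.3f)",
                                  object$auc, round(100 * object$conf_level),
                                  object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal()
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' @param tp,fn,tn,fp Confusion-matrix counts (positive class =
#'   malignant).
#' @return Tibble with `sensitivity` = TP/(TP+FN), `specificity` =
#'   TN/(TN+FP), `accuracy` = (TP+TN)/N and the counts.
#' @export
metrics_from_confusion <- function(tp, fn, tn, fp) {
  n <- tp + fn + tn + fp
  tibble::tibble(sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / n,
                 tp = tp, fn = fn, tn = tn, fp = fp, n = n)
}

#' Threshold metrics of a prediction set
#'
#' Cases scoring at or above `threshold` are called malignant.
#'
#' @param preds A prediction set.
#' @param threshold Decision threshold; default 0.5. `"youden"` picks the
#'   threshold maximizing sensitivity + specificity - 1.
#' @return Tibble as from [metrics_from_confusion()], plus the threshold.
#' @export
threshold_metrics <- function(preds, threshold = 0.5) {
  preds <- as_prediction_set(preds, require_both_classes = FALSE)
  if (identical(threshold, "youden")) {
    pts <- roc_points(preds)
    threshold <- pts$threshold[which.max(pts$tpr - pts$fpr)]
  }
  pred_pos <- preds$score >= threshold
  m <- metrics_from_confusion(tp = sum(pred_pos & preds$label == 1L),
                              fn = sum(!pred_pos & preds$label == 1L),
                              tn = sum(!pred_pos & preds$label == 0L),
                              fp = sum(pred_pos & preds$label == 0L))
  m$threshold <- threshold
  m
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two models scored on the same cases, accounting
#' for the correlation induced by the shared cases via the covariance of
#' the DeLong structural components.
#'
#' @param preds_a,preds_b Prediction sets over identical `case_id`s and
#'   labels.
#' @return Object of class `delong_comparison` with `auc_a`, `auc_b`,
#'   `auc_diff`, `z`, `p_value`.
#' @export
delong_test <- function(preds_a, preds_b) {
  a <- as_prediction_set(preds_a)
  b <- as_prediction_set(preds_b)
  b <- b[match(a$case_id, b$case_id), ]
  if (anyNA(b$case_id) || nrow(a) != nrow(b)) {
    stop("prediction sets must cover the same case_ids (pairing error)",
         call. = FALSE)
  }
  if (!all(a$label == b$label)) {
    stop("labels disagree between prediction sets (pairing error)",
         call. = FALSE)
  }
  ca <- delong_components(a$label, a$score)
  cb <- delong_components(b$label, b$score)
  np <- length(ca$v10); nn <- length(ca$v01)
  var_a <- stats::var(ca$v10) / np + stats::var(ca$v01) / nn
  var_b <- stats::var(cb$v10) / np + stats::var(cb$v01) / nn
  cov_ab <- stats::cov(ca$v10, cb$v10) / np + stats::cov(ca$v01, cb$v01) / nn
  delta <- ca$auc - cb$auc
  var_d <- var_a + var_b - 2 * cov_ab
  if (var_d <= .Machine$double.eps) {
    z <- if (abs(delta) < 1e-12) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(var_d)
  }
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(auc_a = ca$auc, auc_b = cb$auc, auc_diff = delta,
                 z = z, p_value = p, n = nrow(a)),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("<delong_comparison> AUC %.3f vs %.3f, z = %.3f, p = %.4f\n",
              x$auc_a, x$auc_b, x$z, x$p_value))
  invisible(x)
}

#' @export
tidy.delong_comparison <- function(x, ...) {
  tibble::tibble(auc_a = x$auc_a, auc_b = x$auc_b, auc_diff = x$auc_diff,
                 statistic = x$z, p_value = x$p_value, n = x$n)
}

#' Pooled-variance Student's t-test from summary statistics
#'
#' Reconstructs the two-sample Student's t-test from published group
#' summaries (n, mean, SD), as needed to check cohort tables that print
#' mean +/- SD per group.
#'
#' @param n1,mean1,sd1,n2,mean2,sd2 Group summaries; both `n` >= 2, SDs
#'   nonnegative.
#' @return Tibble `(statistic, df, p_value, mean_diff)`; `df = n1+n2-2`.
#'   A zero pooled variance yields p = 1 for equal means and p = 0
#'   otherwise.
#' @export
ttest_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  delta <- mean1 - mean2
  if (sp2 <= 0) {
    p <- if (delta == 0) 1 else 0
    t <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    t <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  tibble::tibble(statistic = t, df = df, p_value = p, mean_diff = delta)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction (df = 1), the form used for cohort
#' contingency rows.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return Tibble `(statistic, df, p_value)`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi-square undefined for a zero marginal", call. = FALSE)
  }
  ht <- stats::chisq.test(table, correct = FALSE)
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0),
            all(table == round(table)))
  stats::fisher.test(table)$p.value
}
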