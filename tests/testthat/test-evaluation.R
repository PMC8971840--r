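test_that("AUC handles separation, ties, and the hand-counted example", {
  perfect <- tibble::tibble(label = c(1, 1, 0, 0),
                            score = c(0.9, 0.8, 0.2, 0.1))
  expect_equal(roc_auc(perfect)$auc, 1)
  ties <- tibble::tibble(label = c(1, 1, 0, 0), score = rep(0.5, 4))
  expect_equal(roc_auc(ties)$auc, 0.5)
  # pos {0.9, 0.8, 0.4}, neg {0.7, 0.3}: 5 concordant of 6 pairs
  ex <- tibble::tibble(label = c(1, 1, 1, 0, 0),
                       score = c(0.9, 0.8, 0.4, 0.7, 0.3))
  expect_equal(roc_auc(ex)$auc, auc_brute_force(ex$label, ex$score))
  expect_equal(roc_auc(ex)$auc, 5 / 6)
  expect_error(roc_auc(tibble::tibble(label = c(1, 1), score = c(0.5, 0.6))),
               "both classes")
})

test_that("rank AUC equals the all-pairs oracle on random instances", {
  for (seed in 1:30) {
    p <- random_prediction_set(n = sample(6:60, 1), seed = seed)
    expect_identical(roc_auc(p)$auc, auc_brute_force(p$label, p$score))
  }
})

test_that("flipping all labels maps AUC to its complement", {
  for (seed in 31:40) {
    p <- random_prediction_set(30, seed)
    q <- p; q$label <- 1L - q$label
    expect_equal(roc_auc(q)$auc, 1 - roc_auc(p)$auc)
  }
})

test_that("the DeLong interval brackets the AUC", {
  p <- random_prediction_set(80, 99)
  r <- roc_auc(p)
  expect_lte(r$ci_low, r$auc)
  expect_gte(r$ci_high, r$auc)
  td <- tidy(r)
  expect_identical(td$auc, r$auc)
  expect_identical(td$n_pos + td$n_neg, 80L)
})

test_that("DeLong AUC and CI agree with an independent implementation", {
  skip_if_not_installed("pROC")
  p <- random_prediction_set(70, 123)
  r <- roc_auc(p)
  pr <- pROC::roc(p$label, p$score, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(c(r$ci_low, r$auc, r$ci_high), ci, tolerance = 1e-6)
})

test_that("threshold metrics recover printed cohort values", {
  m <- metrics_from_confusion(tp = 71, fn = 8, tn = 18, fp = 15)
  expect_equal(round(m$sensitivity, 3), 0.899)
  expect_equal(round(m$specificity, 3), 0.545)
  expect_equal(round(m$accuracy, 3), 0.795)
})

test_that("extreme thresholds saturate sensitivity and specificity", {
  p <- random_prediction_set(50, 7)
  expect_equal(threshold_metrics(p, threshold = 0)$sensitivity, 1)
  expect_equal(threshold_metrics(p, threshold = 1.01)$specificity, 1)
  # accuracy identity: acc = (sens * n_pos + spec * n_neg) / n
  m <- threshold_metrics(p, threshold = 0.4)
  n_pos <- sum(p$label); n_neg <- sum(1 - p$label)
  expect_equal(m$accuracy,
               (m$sensitivity * n_pos + m$specificity * n_neg) / 50)
})

test_that("the Youden threshold maximizes sensitivity + specificity", {
  p <- random_prediction_set(60, 17)
  m <- threshold_metrics(p, threshold = "youden")
  j <- m$sensitivity + m$specificity - 1
  for (t in seq(0, 1, by = 0.05)) {
    mt <- threshold_metrics(p, threshold = t)
    expect_lte(mt$sensitivity + mt$specificity - 1, j + 1e-12)
  }
})

test_that("comparing a model against itself yields p = 1", {
  p <- random_prediction_set(40, 3)
  d <- delong_test(p, p)
  expect_equal(d$auc_diff, 0)
  expect_equal(d$p_value, 1)
})

test_that("the paired DeLong test matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  n <- 60
  lab <- c(rep(1L, 35), rep(0L, 25))
  base <- stats::rnorm(n)
  pa <- tibble::tibble(case_id = as.character(1:n), label = lab,
                       score = stats::plogis(base + 0.8 * lab))
  pb <- tibble::tibble(case_id = as.character(1:n), label = lab,
                       score = stats::plogis(base + 0.5 * lab +
                                               stats::rnorm(n, 0, 0.4)))
  d <- delong_test(pa, pb)
  ra <- pROC::roc(lab, pa$score, quiet = TRUE, direction = "<")
  rb <- pROC::roc(lab, pb$score, quiet = TRUE, direction = "<")
  pt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(d$p_value, pt$p.value, tolerance = 1e-6)
  expect_equal(d$auc_a - d$auc_b, unname(diff(-pt$estimate)),
               tolerance = 1e-9)
})

test_that("pairing errors are caught before any statistics", {
  p <- random_prediction_set(20, 5)
  q <- p; q$case_id[3] <- "zz"
  expect_error(delong_test(p, q), "pairing")
  r <- p; r$label <- rev(r$label)
  if (!all(r$label == p$label)) expect_error(delong_test(p, r), "pairing")
})

test_that("DeLong p-values are uniform under the null of equal AUCs", {
  set.seed(77)
  n <- 100
  lab <- rep(0:1, each = n / 2)
  ids <- as.character(1:n)
  ps <- replicate(1000, {
    a <- tibble::tibble(case_id = ids, label = lab,
                        score = stats::rnorm(n))
    b <- tibble::tibble(case_id = ids, label = lab,
                        score = stats::rnorm(n))
    delong_test(a, b)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("summary-statistic t-tests reproduce pooled Student results", {
  # identical groups: no evidence
  eq <- ttest_from_summary(10, 5, 1, 10, 5, 1)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # oracle: pooled t from raw data equals the summary computation
  set.seed(8)
  x <- stats::rnorm(14, 1, 2); y <- stats::rnorm(19, 0.2, 2)
  ht <- stats::t.test(x, y, var.equal = TRUE)
  mine <- ttest_from_summary(length(x), mean(x), stats::sd(x),
                             length(y), mean(y), stats::sd(y))
  expect_equal(mine$statistic, unname(ht$statistic))
  expect_equal(mine$p_value, ht$p.value)
  # degenerate zero variance
  expect_equal(ttest_from_summary(5, 1, 0, 5, 2, 0)$p_value, 0)
  expect_equal(ttest_from_summary(5, 1, 0, 5, 1, 0)$p_value, 1)
})

test_that("chi-square and Fisher behave on balanced and degenerate tables", {
  bal <- matrix(c(10, 10, 10, 10), 2)
  cs <- chi_square_2x2(bal)
  expect_equal(cs$statistic, 0)
  expect_equal(cs$p_value, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")
  # Fisher is still defined there
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 5, 5), 2)), 1)
})

test_that("Fisher exact matches hypergeometric enumeration", {
  set.seed(10)
  for (i in 1:25) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab), fisher_enum_oracle(tab),
                 tolerance = 1e-10)
  }
})
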