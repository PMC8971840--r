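# Shared fixtures: fast-profile phantoms built in code.

fast_phantom <- function(seed = 1L, noise_sigma_hu = 0, nodule = FALSE, ...) {
  nod <- if (nodule) {
    data.frame(slice = 30, row = 32, col = 22, diameter_px = 6,
               hu = 20, pet_uptake = 6)
  } else NULL
  pp <- phantom_profile(seed = seed, noise_sigma_hu = noise_sigma_hu,
                        nodules = nod, ...)
  spec <- do.call(phantom_spec, pp$spec_args)
  c(generate_phantom(spec), list(params = pp$params, spec = spec))
}

# Brute-force all-pairs AUC oracle (ties count one half).
auc_brute_force <- function(label, score) {
  pos <- score[label == 1L]
  neg <- score[label == 0L]
  tot <- 0
  for (x in pos) for (y in neg) {
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Exact two-sided Fisher oracle by hypergeometric enumeration over all
# tables with the observed margins (sum of probabilities <= observed).
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  ks <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(ks, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

random_prediction_set <- function(n, seed) {
  set.seed(seed)
  label <- c(0L, 1L, sample(0:1, n - 2L, replace = TRUE))
  score <- round(stats::runif(n), 2)  # rounding induces ties
  tibble::tibble(case_id = as.character(seq_len(n)), label = label,
                 score = score)
}
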