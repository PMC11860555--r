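# Shared fixtures and independent oracles.

# Brute-force AMPD oracle: materialises the full local-maxima scalogram with
# the same RNG convention as the implementation (one uniform draw per entry,
# row-major), picks lambda by literal row-sum argmin, and reads peaks off the
# zero-variance columns of the truncated matrix.
ampd_bruteforce <- function(x, seed = 42, detrend = TRUE) {
  if (detrend) {
    n <- length(x)
    tt <- seq_len(n)
    b <- stats::cov(tt, x) / stats::var(tt)
    x <- x - (mean(x) - b * mean(tt)) - b * tt
  }
  n <- length(x)
  L <- ceiling(n / 2) - 1
  set.seed(seed)
  M <- matrix(0, L, n)
  for (k in seq_len(L)) {
    u <- runif(n)
    is_max <- rep(FALSE, n)
    if (n - 2 * k >= 1) {
      mid <- (k + 1):(n - k)
      is_max[mid] <- (x[mid] > x[mid - k]) & (x[mid] > x[mid + k])
    }
    M[k, ] <- ifelse(is_max, 0, 1 + u)
  }
  lambda <- which.min(rowSums(M))
  Mt <- M[seq_len(lambda), , drop = FALSE]
  if (lambda >= 2) {
    which(apply(Mt, 2, stats::sd) == 0)
  } else {
    which(Mt[1, ] == 0)
  }
}

# Synthetic feature tables with a controllable informative feature.
make_feature_df <- function(n = 400, p = 6, shift = 6, informative = "f1",
                            seed = 1, shuffle_labels = FALSE) {
  withr::with_seed(seed, {
    y <- rep(0:1, length.out = n)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    if (!shuffle_labels) X[, informative] <- X[, informative] + shift * y
    df <- data.frame(X)
    df$label <- y
    df[sample(n), ]
  })
}

# Small two-condition session reused across feature/dataset tests.
make_small_session <- function(seed = 5, label_noise = 0,
                               dur_each = 120) {
  prof <- subject_profile(baseline_hr = 70, sdnn = 0.05, resp_rate = 14,
                          ie_ratio = 0.8)
  plan <- list(condition_interval(0, dur_each, "relaxation"),
               condition_interval(dur_each, 2 * dur_each, "cold_pressor"))
  generate_session(prof, plan, seed = seed, label_noise = label_noise)
}
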