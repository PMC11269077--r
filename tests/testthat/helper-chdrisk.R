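# Shared helpers for the chdrisk test suite.

# A tiny valid procedure-outcome table.
tiny_tab <- function() {
  tibble::tibble(
    procedure = c("alpha", "bravo", "charlie", "delta", "echo"),
    cases = c(500L, 120L, 40L, 10L, 2000L),
    deaths = c(5L, 6L, 0L, 4L, 30L))
}

# Exhaustive minimal case-weighted within-category SSE over all contiguous
# partitions of `rates` into K categories (independent oracle for the DP).
enumerate_partition_oracle <- function(rates, weights, K) {
  J <- length(rates)
  if (K == 1L) {
    return(list(score = homogeneity_score(rates, weights), boundaries = integer(0)))
  }
  combos <- utils::combn(J - 1L, K - 1L)
  best <- Inf
  best_b <- NULL
  for (i in seq_len(ncol(combos))) {
    b <- combos[, i]
    s <- homogeneity_score(rates, weights, boundaries = b)
    if (s < best) {
      best <- s
      best_b <- b
    }
  }
  list(score = best, boundaries = best_b)
}

# Feature matrix with a planted signal: 3 informative gaussian features and
# `n_noise` pure-noise features, logistic outcome.
planted_feature_matrix <- function(seed, n = 8000L, n_noise = 7L) {
  set.seed(seed)
  p <- 3L + n_noise
  x <- matrix(rnorm(n * p), ncol = p,
              dimnames = list(NULL, c(paste0("informative", 1:3),
                                      paste0("noise", seq_len(n_noise)))))
  beta <- c(1.5, 1.0, 0.8, rep(0, n_noise))
  y <- rbinom(n, 1, plogis(-2.5 + drop(x %*% beta)))
  structure(list(x = x, y = y, split = NULL, schema = list()),
            class = "chd_feature_matrix")
}

# Mean of the logit-normal rate distribution by quadrature (independent of
# the package's own logit_normal_mu helper).
logit_normal_mean <- function(mu, tau) {
  z <- seq(-8, 8, length.out = 2001)
  w <- stats::dnorm(z)
  sum(w * stats::plogis(mu + tau * z)) / sum(w)
}

hyper_estimate <- function(fit, what) {
  fit$hyper$estimate[fit$hyper$parameter == what]
}
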