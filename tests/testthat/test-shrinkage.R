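test_that("conditional posterior matches a dense brute-force grid oracle", {
  mu <- -3; tau <- 1
  cases <- c(10, 250, 4)
  deaths <- c(2, 10, 3)
  got <- chdrisk:::conditional_rate_posterior(deaths, cases, mu, tau)
  # independent oracle: plain Riemann sum on a very wide, very fine b grid
  b <- seq(-12, 12, length.out = 48001)
  for (j in seq_along(cases)) {
    lw <- deaths[j] * (mu + b) - cases[j] * log1p(exp(mu + b)) -
      b^2 / (2 * tau^2)
    w <- exp(lw - max(lw)); w <- w / sum(w)
    p <- plogis(mu + b)
    expect_equal(got$posterior_mean[j], sum(w * p), tolerance = 1e-6)
    cw <- cumsum(w)
    expect_lt(abs(got$credible_low[j] - p[which(cw >= 0.025)[1]]), 1e-3)
    expect_lt(abs(got$credible_high[j] - p[which(cw >= 0.975)[1]]), 1e-3)
  }
})

test_that("empirical-Bayes hyperparameters agree with glmer on simulated data", {
  skip_if_not_installed("lme4")
  set.seed(42)
  J <- 80
  mu_true <- -3.5; tau_true <- 0.8
  n <- as.integer(round(exp(runif(J, log(50), log(2000)))))
  p <- plogis(mu_true + tau_true * rnorm(J))
  d <- rbinom(J, n, p)
  tab <- tibble::tibble(procedure = paste0("p", 1:J), cases = n, deaths = d)
  fit <- fit_procedure_shrinkage(tab, method = "eb", seed = 1)

  gl <- lme4::glmer(cbind(d, n - d) ~ 1 + (1 | g),
                    data = data.frame(d = d, n = n, g = factor(1:J)),
                    family = stats::binomial())
  mu_gl <- unname(lme4::fixef(gl)[1])
  tau_gl <- sqrt(unname(lme4::VarCorr(gl)$g[1]))
  expect_equal(hyper_estimate(fit, "mu"), mu_gl, tolerance = 0.05)
  expect_equal(hyper_estimate(fit, "tau"), tau_gl, tolerance = 0.1)
})

test_that("MCMC fit is reproducible and shaped as documented", {
  tab <- tiny_tab()
  refit <- function(seed) {
    suppressWarnings(fit_procedure_shrinkage(
      tab, method = "mcmc", chains = 2L, iter = 1500L, warmup = 750L,
      on_nonconvergence = "warn", seed = seed))
  }
  f1 <- refit(7)
  f2 <- refit(7)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$hyper, f2$hyper)
  est <- f1$estimates
  expect_equal(est$procedure, tab$procedure)
  expect_equal(est$n_draws, rep(2L * 750L, nrow(tab)))
  expect_true(all(est$credible_low <= est$posterior_mean))
  expect_true(all(est$posterior_mean <= est$credible_high))
  expect_true(all(est$posterior_mean > 0 & est$posterior_mean < 1))
  # a different seed gives different (but close) draws
  f3 <- refit(8)
  expect_false(identical(f1$estimates$posterior_mean,
                         f3$estimates$posterior_mean))
})

test_that("MCMC and empirical-Bayes estimates agree on the reference table", {
  tab <- apply_inclusion_rules(chd_table2())
  mc <- fit_procedure_shrinkage(tab, method = "mcmc", seed = 2)
  eb <- fit_procedure_shrinkage(tab, method = "eb", seed = 2)
  expect_gt(cor(qlogis(mc$estimates$posterior_mean),
                qlogis(eb$estimates$posterior_mean)), 0.99)
  # plug-in EB and full MCMC differ most on extreme low-volume rows
  expect_lt(median(abs(mc$estimates$posterior_mean -
                         eb$estimates$posterior_mean)), 0.005)
  expect_lt(max(abs(mc$estimates$posterior_mean -
                      eb$estimates$posterior_mean)), 0.15)
  expect_equal(hyper_estimate(mc, "mu"), hyper_estimate(eb, "mu"),
               tolerance = 0.15)
})

test_that("shrinkage pulls extreme rates toward the population", {
  tab <- tiny_tab()
  fit <- fit_procedure_shrinkage(tab, method = "eb", seed = 1)
  est <- fit$estimates
  # zero observed deaths still yields a positive estimate
  expect_gt(est$posterior_mean[est$procedure == "charlie"], 0)
  # the extreme low-volume rate (4/10) is pulled down a lot
  expect_lt(est$posterior_mean[est$procedure == "delta"], 0.4)
  # the high-volume procedure barely moves
  echo <- est[est$procedure == "echo", ]
  expect_lt(abs(echo$posterior_mean - echo$raw_rate), 0.002)
  # lower volume at the same raw rate shrinks more toward a low anchor
  tab2 <- tibble::tibble(procedure = c("small", "large", "mid", "anchor"),
                         cases = c(10L, 1000L, 100L, 10000L),
                         deaths = c(2L, 200L, 20L, 200L))
  fit2 <- fit_procedure_shrinkage(tab2, method = "eb", seed = 1)
  est2 <- fit2$estimates
  move <- abs(est2$posterior_mean - est2$raw_rate)
  expect_gt(move[est2$procedure == "small"], move[est2$procedure == "mid"])
  expect_gt(move[est2$procedure == "mid"], move[est2$procedure == "large"])
  same_raw <- est2$procedure != "anchor"
  expect_true(all(est2$posterior_mean[same_raw] < 0.2))
  expect_true(all(est2$posterior_mean[same_raw] > 0.02))
})

test_that("the convergence gate signals a typed condition", {
  tab <- tiny_tab()
  expect_error(
    fit_procedure_shrinkage(tab, method = "mcmc", chains = 2L, iter = 1000L,
                            warmup = 500L, rhat_max = 1.000001, seed = 3),
    class = "chd_nonconvergence")
  expect_warning(
    fit_procedure_shrinkage(tab, method = "mcmc", chains = 2L, iter = 1000L,
                            warmup = 500L, rhat_max = 1.000001,
                            on_nonconvergence = "warn", seed = 3),
    "split-Rhat")
})

test_that("the reference-table MCMC fit passes its own convergence gate", {
  tab <- apply_inclusion_rules(chd_table2())
  fit <- fit_procedure_shrinkage(tab, method = "mcmc", seed = 1)
  expect_lte(max(fit$diagnostics$rhat, na.rm = TRUE), 1.01)
})

test_that("input contracts of the shrinkage fit are enforced", {
  expect_error(fit_procedure_shrinkage(tiny_tab()[1, ]), "at least 2")
  bad <- tibble::tibble(procedure = c("a", "b"), cases = c(0L, 10L),
                        deaths = c(0L, 1L))
  expect_error(fit_procedure_shrinkage(bad), "at least 1 case")
})

test_that("posterior predictive tail probabilities are calibrated", {
  set.seed(11)
  J <- 60
  n <- as.integer(round(exp(runif(J, log(30), log(3000)))))
  mu <- qlogis(0.03); tau <- 0.6
  p <- plogis(mu + tau * rnorm(J))
  d <- rbinom(J, n, p)
  tab <- tibble::tibble(procedure = paste0("p", 1:J), cases = n, deaths = d)
  fit <- fit_procedure_shrinkage(tab, method = "eb", seed = 1)
  ppc <- posterior_predictive_check(fit)
  expect_equal(ppc$procedure, tab$procedure)
  expect_true(all(ppc$tail_prob >= 0 & ppc$tail_prob <= 1))
  # zero observed deaths means replicates are always >= observed
  expect_true(all(ppc$tail_prob[tab$deaths == 0] == 1))
  # no procedure generated by the model itself should look like an outlier
  expect_gt(min(ppc$tail_prob), 0.001)
  # a planted 10x death count is flagged
  tab_out <- tab
  j <- which(n > 500)[1]
  tab_out$deaths[j] <- as.integer(min(n[j], 10L * max(d[j], 3L)))
  ppc_out <- posterior_predictive_check(fit, tab = tab_out)
  expect_lt(ppc_out$tail_prob[j], 0.01)
  # unchanged rows keep their tail probabilities
  expect_equal(ppc_out$tail_prob[-j], ppc$tail_prob[-j])
})

test_that("mcmc and eb posterior predictive checks agree", {
  tab <- tiny_tab()
  mc <- suppressWarnings(fit_procedure_shrinkage(
    tab, method = "mcmc", chains = 2L, iter = 3000L, warmup = 1000L,
    on_nonconvergence = "warn", seed = 5))
  eb <- fit_procedure_shrinkage(tab, method = "eb", seed = 5)
  expect_equal(posterior_predictive_check(mc)$tail_prob,
               posterior_predictive_check(eb)$tail_prob, tolerance = 0.08)
})

test_that("tidy, glance and autoplot methods work for shrinkage fits", {
  fit <- fit_procedure_shrinkage(tiny_tab(), method = "eb", seed = 1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("procedure", "posterior_mean", "credible_low",
                    "credible_high") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("mu", "tau") %in% names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "random-effects")
})
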