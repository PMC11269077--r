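#' Fit the Bayesian binomial random-effects (shrinkage) model
#'
#' Per-procedure in-hospital mortality is modelled as
#' \deqn{d_j \sim \mathrm{Binomial}(n_j, p_j), \qquad
#'       \mathrm{logit}(p_j) = \mu + b_j, \qquad b_j \sim N(0, \tau^2),}
#' with weakly informative priors \eqn{\mu \sim N(0, 5^2)} and
#' \eqn{\tau \sim \mathrm{HalfNormal}(1)} on the logit scale. The posterior
#' mean of \eqn{p_j} is the "model-based" mortality estimate: raw rates of
#' low-volume procedures are shrunk toward the population rate, which
#' stabilises the ordering used by the stratification stage.
#'
#' Two inference routes are provided. `method = "mcmc"` (default) runs an
#' adaptive Metropolis-within-Gibbs sampler over \eqn{(\mu, \tau, b)} with a
#' translation move along the \eqn{\mu}-versus-\eqn{b} ridge, several chains,
#' and a split-\eqn{\widehat{R}} convergence gate. `method = "eb"` is a
#' deterministic empirical-Bayes route: the random effects are integrated out
#' by adaptive Gaussian quadrature, \eqn{(\mu, \tau)} maximise the marginal
#' likelihood, and per-procedure posteriors are conditional on the plug-in
#' hyperparameters.
#'
#' @param tab Procedure-outcome tibble (`procedure`, `cases`, `deaths`) that
#'   already passed [apply_inclusion_rules()]; at least 2 procedures.
#' @param method `"mcmc"` for full posterior sampling, `"eb"` for the
#'   deterministic empirical-Bayes route.
#' @param chains,iter,warmup MCMC chain count and per-chain total/warmup
#'   iterations (post-warmup draws per chain are `iter - warmup`).
#' @param prior_mu Length-2 numeric: mean and sd of the normal prior on
#'   \eqn{\mu}.
#' @param prior_tau_scale Scale of the half-normal prior on \eqn{\tau}.
#' @param rhat_max Convergence gate: maximum allowed split-\eqn{\widehat{R}}
#'   for \eqn{\mu} and \eqn{\tau}.
#' @param on_nonconvergence `"error"` (default) or `"warn"` when the gate is
#'   exceeded.
#' @param seed Integer seed for the sampler.
#' @return An object of class `chd_shrinkage_fit`: a list with `estimates`
#'   (tibble: `procedure`, `cases`, `deaths`, `raw_rate`, `posterior_mean`,
#'   `credible_low`, `credible_high`, `n_draws`), `hyper` (tibble summarising
#'   \eqn{\mu} and \eqn{\tau}), `diagnostics`, `draws` (for `"mcmc"`), and the
#'   input data.
#' @examples
#' fit <- chd_table2() |>
#'   apply_inclusion_rules() |>
#'   fit_procedure_shrinkage(method = "eb", seed = 1)
#' dplyr::filter(tidy(fit), procedure == "Norwood operation")
#' @export
fit_procedure_shrinkage <- function(tab,
                                    method = c("mcmc", "eb"),
                                    chains = 4L,
                                    iter = 4000L,
                                    warmup = 2000L,
                                    prior_mu = c(0, 5),
                                    prior_tau_scale = 1,
                                    rhat_max = 1.01,
                                    on_nonconvergence = c("error", "warn"),
                                    seed = 1L) {
  method <- match.arg(method)
  on_nonconvergence <- match.arg(on_nonconvergence)
  tab <- validate_procedure_table(tab)
  if (nrow(tab) < 2L) abort("need at least 2 procedures to fit the model")
  d <- as.numeric(tab$deaths)
  n <- as.numeric(tab$cases)
  if (any(n < 1)) abort("every procedure needs at least 1 case")

  if (method == "mcmc") {
    fit <- shrinkage_mcmc(d, n, chains = chains, iter = iter,
                          warmup = warmup, prior_mu = prior_mu,
                          prior_tau_scale = prior_tau_scale, seed = seed)
    max_rhat <- max(fit$diagnostics$rhat, na.rm = TRUE)
    if (is.finite(max_rhat) && max_rhat > rhat_max) {
      msg <- paste0("MCMC did not converge: max split-Rhat = ",
                    format(round(max_rhat, 4)), " > ", rhat_max)
      if (on_nonconvergence == "error") {
        cnd <- rlang::error_cnd("chd_nonconvergence", message = msg,
                                diagnostics = fit$diagnostics)
        rlang::cnd_signal(cnd)
      } else {
        warn(msg)
      }
    }
  } else {
    fit <- shrinkage_eb(d, n, prior_mu = prior_mu,
                        prior_tau_scale = prior_tau_scale)
  }

  est <- fit$estimates
  est$procedure <- tab$procedure
  est$cases <- tab$cases
  est$deaths <- tab$deaths
  est$raw_rate <- d / n
  est <- est |> relocate("procedure", "cases", "deaths", "raw_rate")

  structure(
    list(estimates = est, hyper = fit$hyper, diagnostics = fit$diagnostics,
         draws = fit$draws, method = method, data = tab,
         prior = list(mu = prior_mu, tau_scale = prior_tau_scale)),
    class = "chd_shrinkage_fit")
}

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

shrinkage_mcmc <- function(d, n, chains, iter, warmup, prior_mu,
                           prior_tau_scale, seed) {
  J <- length(d)
  n_keep <- iter - warmup
  if (n_keep < 1L) abort("iter must exceed warmup")
  set.seed(seed)

  loglik <- function(eta) d * eta - n * log1pexp(eta)

  mu_draws <- matrix(NA_real_, n_keep, chains)
  tau_draws <- matrix(NA_real_, n_keep, chains)
  p_draws <- matrix(NA_real_, chains * n_keep, J)

  pooled <- (sum(d) + 0.5) / (sum(n) + 1)
  for (ch in seq_len(chains)) {
    mu <- qlogis(pooled) + rnorm(1, 0, 0.3)
    b <- 0.5 * (qlogis((d + 0.5) / (n + 1)) - qlogis(pooled)) +
      rnorm(J, 0, 0.1)
    ltau <- log(max(sd(b), 0.2)) + rnorm(1, 0, 0.2)
    s_b <- rep(0.5, J); s_mu <- 0.2; s_ltau <- 0.3; s_shift <- 0.2
    s_scale <- 0.2

    for (t in seq_len(iter)) {
      tau2 <- exp(2 * ltau)
      # random effects: independent random-walk proposals, vectorised
      b_prop <- b + rnorm(J, 0, s_b)
      ll_cur <- loglik(mu + b) - b^2 / (2 * tau2)
      ll_prop <- loglik(mu + b_prop) - b_prop^2 / (2 * tau2)
      acc_b <- log(runif(J)) < (ll_prop - ll_cur)
      b[acc_b] <- b_prop[acc_b]

      # population mean: random walk
      mu_prop <- mu + rnorm(1, 0, s_mu)
      lp_cur <- sum(loglik(mu + b)) -
        (mu - prior_mu[1])^2 / (2 * prior_mu[2]^2)
      lp_prop <- sum(loglik(mu_prop + b)) -
        (mu_prop - prior_mu[1])^2 / (2 * prior_mu[2]^2)
      acc_mu <- log(runif(1)) < (lp_prop - lp_cur)
      if (acc_mu) mu <- mu_prop

      # translation along the mu-vs-b ridge: likelihood-invariant
      delta <- rnorm(1, 0, s_shift)
      mu_s <- mu + delta; b_s <- b - delta
      lr <- (-sum(b_s^2) / (2 * tau2) -
               (mu_s - prior_mu[1])^2 / (2 * prior_mu[2]^2)) -
        (-sum(b^2) / (2 * tau2) -
           (mu - prior_mu[1])^2 / (2 * prior_mu[2]^2))
      acc_sh <- log(runif(1)) < lr
      if (acc_sh) { mu <- mu_s; b <- b_s }

      # log tau: random walk (half-normal prior, log-scale Jacobian)
      ltau_prop <- ltau + rnorm(1, 0, s_ltau)
      lt_post <- function(lt) {
        -J * lt - sum(b^2) / (2 * exp(2 * lt)) -
          exp(2 * lt) / (2 * prior_tau_scale^2) + lt
      }
      acc_lt <- log(runif(1)) < (lt_post(ltau_prop) - lt_post(ltau))
      if (acc_lt) ltau <- ltau_prop

      # joint rescale of (tau, b): decouples tau from the current spread
      # of the random effects (the main source of slow tau mixing)
      dsc <- rnorm(1, 0, s_scale)
      b_r <- b * exp(dsc); ltau_r <- ltau + dsc
      # the Gaussian exponent and normalisation of b are invariant under
      # this map and its +J*dsc Jacobian cancels the -J*dsc shift, so only
      # the likelihood, the tau prior, and the log-scale Jacobian remain
      lr2 <- (sum(loglik(mu + b_r)) -
                exp(2 * ltau_r) / (2 * prior_tau_scale^2) + ltau_r) -
        (sum(loglik(mu + b)) -
           exp(2 * ltau) / (2 * prior_tau_scale^2) + ltau)
      acc_sc <- log(runif(1)) < lr2
      if (acc_sc) { b <- b_r; ltau <- ltau_r }

      if (t <= warmup) {
        g <- (t + 10)^-0.6
        s_b <- s_b * exp(g * ((acc_b) - 0.44))
        s_mu <- s_mu * exp(g * (acc_mu - 0.44))
        s_shift <- s_shift * exp(g * (acc_sh - 0.44))
        s_ltau <- s_ltau * exp(g * (acc_lt - 0.44))
        s_scale <- s_scale * exp(g * (acc_sc - 0.44))
      } else {
        k <- t - warmup
        mu_draws[k, ch] <- mu
        tau_draws[k, ch] <- exp(ltau)
        p_draws[(ch - 1L) * n_keep + k, ] <- plogis(mu + b)
      }
    }
  }

  est <- tibble(
    posterior_mean = colMeans(p_draws),
    credible_low = apply(p_draws, 2, quantile, 0.025, names = FALSE),
    credible_high = apply(p_draws, 2, quantile, 0.975, names = FALSE),
    n_draws = nrow(p_draws))
  hyper <- tibble(
    parameter = c("mu", "tau"),
    estimate = c(mean(mu_draws), mean(tau_draws)),
    credible_low = c(quantile(mu_draws, 0.025, names = FALSE),
                     quantile(tau_draws, 0.025, names = FALSE)),
    credible_high = c(quantile(mu_draws, 0.975, names = FALSE),
                      quantile(tau_draws, 0.975, names = FALSE)),
    rhat = c(split_rhat(mu_draws), split_rhat(tau_draws)))
  diagnostics <- tibble(parameter = hyper$parameter, rhat = hyper$rhat,
                        n_draws = chains * n_keep)
  list(estimates = est, hyper = hyper, diagnostics = diagnostics,
       draws = list(mu = as.vector(mu_draws), tau = as.vector(tau_draws),
                    p = p_draws))
}

# split-Rhat from an (iterations x chains) matrix
split_rhat <- function(x) {
  m <- ncol(x); half <- floor(nrow(x) / 2)
  segs <- do.call(cbind, lapply(seq_len(m), function(j) {
    cbind(x[seq_len(half), j], x[half + seq_len(half), j])
  }))
  n_it <- nrow(segs)
  w <- mean(apply(segs, 2, var))
  bvar <- n_it * var(colMeans(segs))
  sqrt(((n_it - 1) / n_it * w + bvar / n_it) / w)
}

# Conditional posterior of p = plogis(mu + b) for one procedure given
# hyperparameters, by adaptive quadrature: the integrand is centred at its
# Laplace mode so that very concentrated posteriors (large n) stay resolved.
conditional_rate_posterior <- function(deaths, cases, mu, tau,
                                       n_grid = 241L, half_width = 8) {
  J <- length(deaths)
  stopifnot(length(cases) == J)
  b_hat <- numeric(J)
  for (i in 1:40) {
    p <- plogis(mu + b_hat)
    g1 <- deaths - cases * p - b_hat / tau^2
    g2 <- -cases * p * (1 - p) - 1 / tau^2
    b_hat <- b_hat - g1 / g2
  }
  p_hat <- plogis(mu + b_hat)
  s_hat <- 1 / sqrt(cases * p_hat * (1 - p_hat) + 1 / tau^2)
  z <- seq(-half_width, half_width, length.out = n_grid)
  out <- matrix(NA_real_, J, 3L)
  for (j in seq_len(J)) {
    b <- b_hat[j] + s_hat[j] * z
    lw <- deaths[j] * (mu + b) - cases[j] * log1pexp(mu + b) -
      b^2 / (2 * tau^2)
    w <- exp(lw - max(lw)); w <- w / sum(w)
    p <- plogis(mu + b)
    cw <- cumsum(w)
    out[j, ] <- c(sum(w * p),
                  p[which(cw >= 0.025)[1]],
                  p[which(cw >= 0.975)[1]])
  }
  tibble(posterior_mean = out[, 1], credible_low = out[, 2],
         credible_high = out[, 3])
}

# marginal log-likelihood of (mu, tau) with b integrated out by adaptive
# quadrature, plus the (improper-friendly) priors so EB is a MAP-type fit
shrinkage_marginal_ll <- function(mu, tau, d, n, n_grid = 81L) {
  J <- length(d)
  b_hat <- numeric(J)
  for (i in 1:40) {
    p <- plogis(mu + b_hat)
    g1 <- d - n * p - b_hat / tau^2
    g2 <- -n * p * (1 - p) - 1 / tau^2
    b_hat <- b_hat - g1 / g2
  }
  p_hat <- plogis(mu + b_hat)
  s_hat <- 1 / sqrt(n * p_hat * (1 - p_hat) + 1 / tau^2)
  z <- seq(-8, 8, length.out = n_grid)
  dz <- z[2] - z[1]
  total <- 0
  for (j in seq_len(J)) {
    b <- b_hat[j] + s_hat[j] * z
    lw <- d[j] * (mu + b) - n[j] * log1pexp(mu + b) -
      b^2 / (2 * tau^2) - log(tau) - 0.5 * log(2 * pi)
    m <- max(lw)
    total <- total + m + log(sum(exp(lw - m)) * s_hat[j] * dz)
  }
  total
}

shrinkage_eb <- function(d, n, prior_mu, prior_tau_scale) {
  obj <- function(par) {
    mu <- par[1]; tau <- exp(par[2])
    -(shrinkage_marginal_ll(mu, tau, d, n) +
        dnorm(mu, prior_mu[1], prior_mu[2], log = TRUE) +
        dnorm(tau, 0, prior_tau_scale, log = TRUE) + par[2])
  }
  start <- c(qlogis((sum(d) + 0.5) / (sum(n) + 1)), log(0.8))
  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  mu_hat <- opt$par[1]; tau_hat <- exp(opt$par[2])
  est <- conditional_rate_posterior(d, n, mu_hat, tau_hat)
  est$n_draws <- 0L
  hyper <- tibble(parameter = c("mu", "tau"),
                  estimate = c(mu_hat, tau_hat),
                  credible_low = NA_real_, credible_high = NA_real_,
                  rhat = NA_real_)
  diagnostics <- tibble(parameter = hyper$parameter, rhat = NA_real_,
                        n_draws = 0L, convergence = opt$convergence)
  list(estimates = est, hyper = hyper, diagnostics = diagnostics,
       draws = NULL)
}

#' Posterior predictive tail probabilities per procedure
#'
#' For each procedure, the posterior predictive probability that replicated
#' deaths are at least the observed count,
#' \eqn{\Pr(d^{rep}_j \ge d_j \mid \mathrm{data})}, computed exactly from the
#' binomial survival function averaged over the posterior of \eqn{p_j} (no
#' extra Monte-Carlo noise on top of the posterior draws). Small values flag
#' procedures whose observed mortality is higher than the model can explain.
#'
#' @param fit A `chd_shrinkage_fit`.
#' @param tab Optional replacement procedure table with the same procedures
#'   (e.g. with perturbed death counts); defaults to the fitted data.
#' @param seed Unused for the exact computation; accepted for interface
#'   stability.
#' @return A tibble with `procedure`, `deaths`, `cases`, `tail_prob`.
#' @export
posterior_predictive_check <- function(fit, tab = NULL, seed = NULL) {
  stopifnot(inherits(fit, "chd_shrinkage_fit"))
  tab <- if (is.null(tab)) fit$data else validate_procedure_table(tab)
  if (nrow(tab) != nrow(fit$data)) {
    abort("replacement table must match the fitted procedures")
  }
  d <- tab$deaths; n <- tab$cases
  J <- length(d)
  tail_prob <- numeric(J)
  if (fit$method == "mcmc") {
    p <- fit$draws$p
    for (j in seq_len(J)) {
      tail_prob[j] <- mean(pbinom(d[j] - 1L, n[j], p[, j],
                                  lower.tail = FALSE))
    }
  } else {
    mu <- fit$hyper$estimate[fit$hyper$parameter == "mu"]
    tau <- fit$hyper$estimate[fit$hyper$parameter == "tau"]
    for (j in seq_len(J)) {
      # grid posterior of b for the fitted counts, evaluated against the
      # (possibly replaced) observed count
      b_hat <- 0
      for (i in 1:40) {
        pp <- plogis(mu + b_hat)
        g1 <- fit$data$deaths[j] - fit$data$cases[j] * pp - b_hat / tau^2
        g2 <- -fit$data$cases[j] * pp * (1 - pp) - 1 / tau^2
        b_hat <- b_hat - g1 / g2
      }
      p_hat <- plogis(mu + b_hat)
      s_hat <- 1 / sqrt(fit$data$cases[j] * p_hat * (1 - p_hat) + 1 / tau^2)
      b <- b_hat + s_hat * seq(-8, 8, length.out = 241L)
      lw <- fit$data$deaths[j] * (mu + b) -
        fit$data$cases[j] * log1pexp(mu + b) - b^2 / (2 * tau^2)
      w <- exp(lw - max(lw)); w <- w / sum(w)
      tail_prob[j] <- sum(w * pbinom(d[j] - 1L, n[j], plogis(mu + b),
                                     lower.tail = FALSE))
    }
  }
  tibble(procedure = tab$procedure, deaths = d, cases = n,
         tail_prob = tail_prob)
}

#' @export
print.chd_shrinkage_fit <- function(x, ...) {
  cat("Bayesian binomial random-effects fit (", x$method, ")\n", sep = "")
  cat("  procedures:", nrow(x$estimates), "\n")
  mu <- x$hyper$estimate[x$hyper$parameter == "mu"]
  tau <- x$hyper$estimate[x$hyper$parameter == "tau"]
  cat("  population rate:", sprintf("%.2f%%", 100 * plogis(mu)),
      " tau:", sprintf("%.3f", tau), "\n")
  if (x$method == "mcmc") {
    cat("  max split-Rhat:", sprintf("%.4f", max(x$diagnostics$rhat)), "\n")
  }
  invisible(x)
}

#' @rdname fit_procedure_shrinkage
#' @param x A `chd_shrinkage_fit`.
#' @param ... Unused.
#' @method tidy chd_shrinkage_fit
#' @export
tidy.chd_shrinkage_fit <- function(x, ...) x$estimates

#' @rdname fit_procedure_shrinkage
#' @method glance chd_shrinkage_fit
#' @export
glance.chd_shrinkage_fit <- function(x, ...) {
  mu <- x$hyper$estimate[x$hyper$parameter == "mu"]
  tau <- x$hyper$estimate[x$hyper$parameter == "tau"]
  tibble(n_procedures = nrow(x$estimates),
         mu = mu, tau = tau, population_rate = plogis(mu),
         method = x$method,
         max_rhat = suppressWarnings(max(x$diagnostics$rhat)))
}

#' Shrinkage plot: raw versus model-based mortality
#'
#' @param object A `chd_shrinkage_fit`.
#' @param ... Unused.
#' @return A ggplot: raw rate against posterior mean, point size by case
#'   count, with the identity line; the vertical gap visualises shrinkage.
#' @method autoplot chd_shrinkage_fit
#' @export
autoplot.chd_shrinkage_fit <- function(object, ...) {
  ggplot(object$estimates,
         aes(x = .data$raw_rate, y = .data$posterior_mean,
             size = .data$cases)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.6) +
    scale_size_continuous(trans = "log10") +
    labs(x = "Unadjusted mortality", y = "Model-based mortality",
         size = "Cases") +
    theme_minimal()
}
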