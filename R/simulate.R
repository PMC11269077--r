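#' Default preoperative covariate specification
#'
#' The ten strongest predictors of in-hospital death in this setting, typed
#' as in a congenital-heart-surgery registry: the pulse-oxygen-saturation
#' category (at or below 90 percent versus above), the procedure risk
#' category (carried by the procedure assignment rather than listed here),
#' age in days, preoperative mechanical ventilation, atrial and ventricular
#' shunt directions, pulmonary insufficiency severity, left atrial dimension
#' against its critical value, history of cardiac surgery, and the number of
#' cardiac defects. Marginal level frequencies follow the registry's
#' published cohort description; log-odds effects are ordered so that the
#' pulse-oxygen category dominates, mirroring the published importance
#' ranking.
#'
#' Each element gives `type` (`"binary"`, `"categorical"` or `"lognormal"`),
#' the marginal (`prob`, `probs` + `levels`, or `meanlog`/`sdlog`), a
#' per-level or per-unit log-odds effect `beta`, and an MCAR `missing`
#' fraction.
#'
#' @return A named list of covariate specifications.
#' @export
default_covariate_spec <- function() {
  list(
    spo2_low = list(type = "binary", prob = 0.262, beta = 2.0,
                    missing = 0.05),
    age_days = list(type = "lognormal", meanlog = log(316), sdlog = 1.4,
                    beta = -0.35, missing = 0),
    preop_mech_vent = list(type = "binary", prob = 0.089, beta = 1.5,
                           missing = 0),
    atrial_shunt = list(type = "categorical",
                        levels = c("none", "left_to_right", "right_to_left",
                                   "two_way"),
                        probs = c(0.3648, 0.4405, 0.0400, 0.1547),
                        beta = c(0, 0.2, 0.9, 1.0), missing = 0.03),
    pulm_insufficiency = list(type = "categorical",
                              levels = c("negative", "slight", "mild",
                                         "mild_moderate", "moderate",
                                         "moderate_severe", "severe"),
                              probs = c(0.1545, 0.5608, 0.2677, 0.0058,
                                        0.0104, 0.0004, 0.0004),
                              beta = c(0.8, 0, 0.2, 0.4, 0.6, 0.8, 1.0),
                              missing = 0.05),
    ventricular_shunt = list(type = "categorical",
                             levels = c("none", "left_to_right",
                                        "right_to_left", "two_way"),
                             probs = c(0.2727, 0.3529, 0.0021, 0.3723),
                             beta = c(0, -0.8, 0.5, 0.9), missing = 0.03),
    left_atrial_dim = list(type = "categorical",
                           levels = c("below_critical", "normal",
                                      "above_critical"),
                           probs = c(0.1247, 0.2171, 0.6582),
                           beta = c(0.9, 0.4, 0), missing = 0.08),
    prior_cardiac_surgery = list(type = "categorical",
                                 levels = c("0", "1", "2"),
                                 probs = c(0.895, 0.098, 0.007),
                                 beta = c(0, 1.2, 2.0), missing = 0),
    n_defects = list(type = "categorical",
                     levels = as.character(0:8),
                     probs = c(0.360, 0.236, 0.216, 0.094, 0.059, 0.027,
                               0.007, 0.0007, 0.0003),
                     beta = 0.25 * (0:8), missing = 0)
  )
}

#' Specification of a synthetic surgical registry
#'
#' Collects every knob of the synthetic-data generator: the number of
#' procedures and patients, the logit-scale hyperparameters of procedure
#' mortality heterogeneity, the heavy-tailed case-volume law, the covariate
#' marginals and effects, and the target overall death rate. The defaults
#' emulate the reference cohort: 102 procedures, 24,685 patients, an overall
#' in-hospital mortality of 2.4 percent, case volumes spanning 3 to about
#' 8,000, and between-procedure heterogeneity `tau = 0.9` on the logit
#' scale. `mu = NULL` (the default) calibrates the population intercept by
#' quadrature so that the mean of the logit-normal rate distribution equals
#' `target_rate`.
#'
#' @param n_procedures Number of procedures.
#' @param n_patients Number of patients (at least `n_procedures`).
#' @param mu Logit-scale population mean; `NULL` to calibrate from
#'   `target_rate`.
#' @param tau Logit-scale between-procedure standard deviation (>= 0).
#' @param target_rate Overall death rate used to calibrate `mu` when `mu` is
#'   `NULL`, and to calibrate the patient-level intercept.
#' @param volume_range Case-count span of the discretised log-uniform volume
#'   law (truncated below at 3).
#' @param covariate_spec Covariate specification, see
#'   [default_covariate_spec()].
#' @param seed Integer seed.
#' @return A list of class `chd_registry_spec`.
#' @export
registry_spec <- function(n_procedures = 102L,
                          n_patients = 24685L,
                          mu = NULL,
                          tau = 0.9,
                          target_rate = 0.024,
                          volume_range = c(3, 8000),
                          covariate_spec = default_covariate_spec(),
                          seed = 1L) {
  if (n_patients < n_procedures) abort("need n_patients >= n_procedures")
  if (tau < 0) abort("tau must be non-negative")
  for (nm in names(covariate_spec)) {
    cv <- covariate_spec[[nm]]
    if (identical(cv$type, "categorical")) {
      if (abs(sum(cv$probs) - 1) > 1e-6) {
        abort(paste0("level probabilities of ", nm, " must sum to 1"))
      }
      if (length(cv$probs) != length(cv$levels) ||
          length(cv$beta) != length(cv$levels)) {
        abort(paste0("levels/probs/beta length mismatch in ", nm))
      }
    }
    if (!is.null(cv$missing) && (cv$missing < 0 || cv$missing > 0.95)) {
      abort(paste0("missingness of ", nm, " must be in [0, 0.95]"))
    }
  }
  if (is.null(mu)) mu <- logit_normal_mu(target_rate, tau)
  structure(list(n_procedures = as.integer(n_procedures),
                 n_patients = as.integer(n_patients),
                 mu = mu, tau = tau, target_rate = target_rate,
                 volume_range = volume_range,
                 covariate_spec = covariate_spec, seed = as.integer(seed)),
            class = "chd_registry_spec")
}

#' Logit-scale location matching a target logit-normal mean
#'
#' Solves \eqn{E[\mathrm{logit}^{-1}(\mu + \tau Z)] = m} for \eqn{\mu} by
#' Gauss–Hermite quadrature and root finding, so that simulated procedure
#' mortality rates average to the intended overall rate.
#'
#' @param target_mean Intended mean rate in (0, 1).
#' @param tau Logit-scale standard deviation.
#' @return The calibrated `mu`.
#' @export
logit_normal_mu <- function(target_mean, tau) {
  if (tau == 0) return(qlogis(target_mean))
  z <- seq(-8, 8, length.out = 801)
  w <- dnorm(z); w <- w / sum(w)
  f <- function(mu) sum(w * plogis(mu + tau * z)) - target_mean
  uniroot(f, lower = qlogis(target_mean) - 4 * tau,
          upper = qlogis(target_mean) + 1, tol = 1e-10)$root
}

#' Simulate a procedure-outcome table
#'
#' True rates are drawn from the logit-normal law
#' \eqn{\mathrm{logit}(p_j) = \mu + \tau Z_j}; case counts from a discretised
#' log-uniform law truncated below at 3 (reproducing the heavy-tailed 3-to-
#' thousands volume span of real registries); deaths as
#' \eqn{d_j \sim \mathrm{Binomial}(n_j, p_j)}.
#'
#' @param spec A [registry_spec()].
#' @return A procedure-outcome tibble with the additional column `true_rate`
#'   (kept separate from the modelling columns so recovery tests can compare
#'   estimates against truth).
#' @examples
#' sim <- simulate_procedure_outcomes(registry_spec(n_procedures = 20,
#'                                                  n_patients = 2000,
#'                                                  seed = 7))
#' sum(sim$deaths) / sum(sim$cases)
#' @export
simulate_procedure_outcomes <- function(spec) {
  stopifnot(inherits(spec, "chd_registry_spec"))
  set.seed(spec$seed)
  J <- spec$n_procedures
  p <- plogis(spec$mu + spec$tau * rnorm(J))
  lo <- log(spec$volume_range[1]); hi <- log(spec$volume_range[2])
  n <- pmax(3L, as.integer(round(exp(runif(J, lo, hi)))))
  d <- rbinom(J, n, p)
  tibble(procedure = sprintf("procedure_%03d", seq_len(J)),
         cases = n, deaths = as.integer(d), true_rate = p)
}

sample_covariate <- function(cv, n) {
  switch(cv$type,
         binary = as.integer(runif(n) < cv$prob),
         categorical = factor(sample(cv$levels, n, replace = TRUE,
                                     prob = cv$probs), levels = cv$levels),
         lognormal = pmax(1, round(rlnorm(n, cv$meanlog, cv$sdlog))),
         abort(paste0("unknown covariate type: ", cv$type)))
}

covariate_effect <- function(cv, x) {
  switch(cv$type,
         binary = cv$beta * x,
         categorical = cv$beta[as.integer(x)],
         # continuous effects act on the standardised log scale
         lognormal = cv$beta * (log(x) - cv$meanlog) / cv$sdlog)
}

#' Simulate a patient-level registry
#'
#' Each patient is assigned a procedure with probability proportional to its
#' case volume; covariates are drawn independently from their marginals; the
#' in-hospital death outcome follows a logistic model
#' \deqn{\Pr(\mathrm{death}) = \mathrm{logit}^{-1}\!\big(\beta_0 +
#'   \textstyle\sum_c \beta_c x_c + b_{proc}\big),}
#' where \eqn{b_{proc}} is the procedure's logit-scale random effect (from
#' `procedures$true_rate`). The intercept \eqn{\beta_0} is calibrated by root
#' finding so the expected death fraction equals `spec$target_rate`.
#' Missingness is applied per covariate, completely at random, after the
#' outcome is generated; the outcome itself is never missing.
#'
#' @param spec A [registry_spec()].
#' @param procedures Optional procedure table with `procedure`, `cases` and
#'   `true_rate`; defaults to [simulate_procedure_outcomes()] under the same
#'   spec.
#' @param strat Optional `chd_stratification` used to fill `risk_category`.
#' @return A patient tibble: `patient_id`, covariates, `procedure`,
#'   `risk_category` (if `strat` given), `died_in_hospital`.
#' @export
simulate_patients <- function(spec, procedures = NULL, strat = NULL) {
  stopifnot(inherits(spec, "chd_registry_spec"))
  if (is.null(procedures)) procedures <- simulate_procedure_outcomes(spec)
  stopifnot(all(c("procedure", "cases", "true_rate") %in% names(procedures)))
  set.seed(spec$seed + 1L)
  N <- spec$n_patients
  idx <- sample.int(nrow(procedures), N, replace = TRUE,
                    prob = procedures$cases)
  b_proc <- qlogis(procedures$true_rate[idx]) - spec$mu

  covs <- lapply(spec$covariate_spec, sample_covariate, n = N)
  eta <- b_proc
  for (nm in names(covs)) {
    eta <- eta + covariate_effect(spec$covariate_spec[[nm]], covs[[nm]])
  }
  # centre the covariate contribution, then calibrate the intercept so the
  # expected death fraction matches the target rate
  f <- function(b0) mean(plogis(b0 + eta)) - spec$target_rate
  b0 <- uniroot(f, lower = spec$mu - 15, upper = spec$mu + 15,
                tol = 1e-10)$root
  died <- as.integer(runif(N) < plogis(b0 + eta))

  for (nm in names(covs)) {
    m <- spec$covariate_spec[[nm]]$missing %||% 0
    if (m > 0) covs[[nm]][runif(N) < m] <- NA
  }

  out <- tibble(patient_id = sprintf("pt_%06d", seq_len(N)), !!!covs,
                procedure = procedures$procedure[idx])
  if (!is.null(strat)) out <- assign_categories(out, strat)
  out$died_in_hospital <- died
  out
}
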