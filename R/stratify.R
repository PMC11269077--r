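#' Within-category homogeneity score of a partition
#'
#' The homogeneity criterion is the case-weighted within-category sum of
#' squares of the (model-based) mortality rates,
#' \deqn{H = \sum_k \sum_{j \in k} w_j (r_j - \bar r_k)^2,}
#' with \eqn{\bar r_k} the weight-averaged rate of category \eqn{k}. Lower is
#' more homogeneous; maximising homogeneity means minimising this score.
#'
#' @param rates Per-procedure mortality rates, sorted ascending.
#' @param weights Positive case counts, same length as `rates`.
#' @param boundaries Integer vector of cut positions: a cut at position `i`
#'   ends a category after the `i`-th procedure. `K - 1` cuts define `K`
#'   contiguous categories; `integer(0)` means a single category.
#' @return The non-negative homogeneity score.
#' @examples
#' homogeneity_score(c(0.01, 0.02, 0.30, 0.31), rep(1, 4), boundaries = 2)
#' @export
homogeneity_score <- function(rates, weights, boundaries = integer(0)) {
  check_segmentation_input(rates, weights)
  J <- length(rates)
  boundaries <- sort(as.integer(boundaries))
  if (length(boundaries) > 0 &&
      (min(boundaries) < 1L || max(boundaries) >= J ||
       anyDuplicated(boundaries))) {
    abort("boundaries must be distinct cut positions in 1..(J-1)")
  }
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, J)
  sum(vapply(seq_along(starts), function(k) {
    idx <- starts[k]:ends[k]
    wbar <- sum(weights[idx] * rates[idx]) / sum(weights[idx])
    sum(weights[idx] * (rates[idx] - wbar)^2)
  }, numeric(1)))
}

check_segmentation_input <- function(rates, weights) {
  if (length(rates) != length(weights)) abort("rates/weights length mismatch")
  if (is.unsorted(rates)) abort("rates must be sorted ascending")
  if (any(weights <= 0)) abort("weights must be positive")
  invisible(TRUE)
}

# weighted SSE of the segment a..b from prefix sums, vectorised over a
segment_cost <- function(cw, cwr, cwr2, a, b) {
  w <- cw[b + 1L] - cw[a]
  s <- cwr[b + 1L] - cwr[a]
  q <- cwr2[b + 1L] - cwr2[a]
  pmax(q - s^2 / w, 0)
}

#' Optimal contiguous partition into K categories
#'
#' Exact dynamic programming over the rate-ordered procedure list: among all
#' \eqn{\binom{J-1}{K-1}} contiguous partitions it returns one minimising the
#' case-weighted within-category sum of squares ([homogeneity_score()]).
#' Costs are evaluated in O(1) from prefix sums; the scan is
#' \eqn{O(K J^2)} and fully deterministic (ties broken toward the earliest
#' cut).
#'
#' @inheritParams homogeneity_score
#' @param K Number of categories, `1 <= K <= length(rates)`.
#' @return A list with `boundaries` (length `K - 1`), `K`, and `homogeneity`.
#' @export
optimal_partition <- function(rates, weights, K) {
  check_segmentation_input(rates, weights)
  J <- length(rates)
  K <- as.integer(K)
  if (K < 1L || K > J) abort("K must be between 1 and the number of procedures")
  cw <- c(0, cumsum(weights))
  cwr <- c(0, cumsum(weights * rates))
  cwr2 <- c(0, cumsum(weights * rates^2))

  # cost[k, j]: minimal score of the first j procedures in k categories
  cost <- matrix(Inf, K, J)
  back <- matrix(0L, K, J)
  cost[1L, ] <- segment_cost(cw, cwr, cwr2, 1L, seq_len(J))
  if (K > 1L) {
    for (k in 2:K) {
      for (j in k:J) {
        a <- k:j  # start index of the last category
        cand <- cost[k - 1L, a - 1L] + segment_cost(cw, cwr, cwr2, a, j)
        best <- which.min(cand)
        cost[k, j] <- cand[best]
        back[k, j] <- a[best] - 1L
      }
    }
  }
  boundaries <- integer(0)
  j <- J
  if (K > 1L) {
    for (k in K:2) {
      j <- back[k, j]
      boundaries <- c(j, boundaries)
    }
  }
  list(boundaries = boundaries, K = K, homogeneity = cost[K, J])
}

#' Bayesian information criterion of a category partition
#'
#' Each category is assigned its pooled death rate
#' \eqn{\hat p_k = \sum_{j \in k} d_j / \sum_{j \in k} n_j}; the BIC is
#' \deqn{-2 \sum_j \log \mathrm{Binomial}(d_j \mid n_j, \hat p_{k(j)})
#'       + K \log\left(\sum_j n_j\right),}
#' trading within-category fit against the number of category rate
#' parameters.
#'
#' @param cases,deaths Per-procedure counts, in the same (rate-sorted) order
#'   used for the partition.
#' @param boundaries Cut positions as in [homogeneity_score()].
#' @return The BIC value.
#' @export
partition_bic <- function(cases, deaths, boundaries = integer(0)) {
  J <- length(cases)
  stopifnot(length(deaths) == J)
  boundaries <- sort(as.integer(boundaries))
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, J)
  K <- length(starts)
  ll <- 0
  for (k in seq_len(K)) {
    idx <- starts[k]:ends[k]
    n_k <- sum(cases[idx])
    if (n_k == 0) abort("category with zero total cases")
    p_k <- sum(deaths[idx]) / n_k
    ll <- ll + sum(dbinom(deaths[idx], cases[idx], p_k, log = TRUE))
  }
  -2 * ll + K * log(sum(cases))
}

#' Stratify procedures into risk categories
#'
#' Orders procedures by their model-based (shrunk) mortality, runs
#' [optimal_partition()] for each candidate number of categories, scores each
#' partition with [partition_bic()] on the observed counts, and returns the
#' stratification whose BIC is minimal (ties broken toward fewer categories).
#' Equal posterior means are ordered by descending case count, then by
#' procedure name.
#'
#' @param tab Procedure-outcome tibble (after inclusion rules).
#' @param estimates Either a `chd_shrinkage_fit` or its [tidy()] tibble with
#'   `procedure` and `posterior_mean`.
#' @param k_range Candidate numbers of categories, default `2:20`.
#' @return An object of class `chd_stratification`: list with `K`,
#'   `boundaries`, `categories` (tibble: `procedure`, rates, `risk_category`),
#'   `category_summary` (per-category pooled death rates and totals),
#'   `homogeneity`, `bic`, and `trace` (tibble of K, homogeneity, BIC).
#' @examples
#' \donttest{
#' tab <- apply_inclusion_rules(chd_table2())
#' fit <- fit_procedure_shrinkage(tab, method = "eb", seed = 1)
#' strat <- select_num_categories(tab, fit)
#' strat$K
#' }
#' @export
select_num_categories <- function(tab, estimates, k_range = 2:20) {
  tab <- validate_procedure_table(tab)
  est <- if (inherits(estimates, "chd_shrinkage_fit")) {
    estimates$estimates
  } else {
    as_tibble(estimates)
  }
  stopifnot(all(c("procedure", "posterior_mean") %in% names(est)))
  missing_est <- setdiff(tab$procedure, est$procedure)
  if (length(missing_est) > 0) {
    abort(paste0("no estimate for: ", paste(missing_est, collapse = "; ")))
  }
  dat <- tab |>
    left_join(select(est, "procedure", "posterior_mean"), by = "procedure") |>
    arrange(.data$posterior_mean, desc(.data$cases), .data$procedure)
  J <- nrow(dat)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > J) {
    warn(paste0("k_range truncated to at most ", J, " categories"))
    k_range <- k_range[k_range <= J]
  }
  if (length(k_range) == 0L) abort("empty k_range")

  parts <- lapply(k_range, function(K) {
    optimal_partition(dat$posterior_mean, dat$cases, K)
  })
  trace <- tibble(
    K = k_range,
    homogeneity = map_dbl(parts, "homogeneity"),
    bic = map_dbl(parts, function(p) {
      partition_bic(dat$cases, dat$deaths, p$boundaries)
    }))
  best <- which(trace$bic == min(trace$bic))[1L]
  chosen <- parts[[best]]
  build_stratification(dat, chosen, trace)
}

build_stratification <- function(dat, part, trace = NULL) {
  J <- nrow(dat)
  starts <- c(1L, part$boundaries + 1L)
  ends <- c(part$boundaries, J)
  cat_id <- rep(seq_along(starts), times = ends - starts + 1L)
  dat$risk_category <- cat_id
  summary <- dat |>
    group_by(risk_category = .data$risk_category) |>
    summarise(n_procedures = dplyr::n(),
              mean_model_rate = stats::weighted.mean(.data$posterior_mean,
                                                     .data$cases),
              cases = sum(.data$cases),
              deaths = sum(.data$deaths),
              .groups = "drop") |>
    mutate(pooled_rate = .data$deaths / .data$cases) |>
    relocate("risk_category", "n_procedures", "cases", "deaths",
             "pooled_rate", "mean_model_rate")
  structure(
    list(K = part$K, boundaries = part$boundaries,
         categories = dat, category_summary = summary,
         homogeneity = part$homogeneity,
         bic = if (is.null(trace)) {
           partition_bic(dat$cases, dat$deaths, part$boundaries)
         } else {
           trace$bic[trace$K == part$K]
         },
         trace = trace),
    class = "chd_stratification")
}

#' Stratify at a fixed number of categories
#'
#' Convenience wrapper around [optimal_partition()] returning a full
#' `chd_stratification` for a single, fixed `K`.
#'
#' @inheritParams select_num_categories
#' @param K Number of categories.
#' @return A `chd_stratification` (with a single-row trace).
#' @export
stratify_at_k <- function(tab, estimates, K) {
  s <- select_num_categories(tab, estimates, k_range = K)
  s
}

#' Assign risk categories to patients
#'
#' @param patients Patient tibble with a `procedure` column.
#' @param strat A `chd_stratification`.
#' @return `patients` with an ordinal `risk_category` column filled from the
#'   stratification. Unknown procedures raise an error naming them.
#' @export
assign_categories <- function(patients, strat) {
  stopifnot(inherits(strat, "chd_stratification"))
  patients <- as_tibble(patients)
  if (nrow(patients) == 0L) {
    patients$risk_category <- integer(0)
    return(patients)
  }
  stopifnot("procedure" %in% names(patients))
  lookup <- setNames(strat$categories$risk_category,
                     strat$categories$procedure)
  unknown <- setdiff(unique(patients$procedure), names(lookup))
  if (length(unknown) > 0) {
    abort(paste0("procedures without a risk category: ",
                 paste(unknown, collapse = "; ")))
  }
  patients$risk_category <- unname(lookup[patients$procedure])
  patients
}

#' @export
print.chd_stratification <- function(x, ...) {
  cat("Risk stratification:", x$K, "categories,",
      nrow(x$categories), "procedures\n")
  cat("  homogeneity:", format(signif(x$homogeneity, 4)),
      " BIC:", format(round(x$bic, 1)), "\n")
  print(x$category_summary)
  invisible(x)
}

#' @rdname select_num_categories
#' @param x A `chd_stratification`.
#' @param ... Unused.
#' @method tidy chd_stratification
#' @export
tidy.chd_stratification <- function(x, ...) {
  select(x$categories, "procedure", "cases", "deaths", "posterior_mean",
         "risk_category")
}

#' @rdname select_num_categories
#' @method glance chd_stratification
#' @export
glance.chd_stratification <- function(x, ...) {
  tibble(K = x$K, homogeneity = x$homogeneity, bic = x$bic,
         n_procedures = nrow(x$categories))
}

#' Plot the K-versus-BIC trace of a stratification
#'
#' @param object A `chd_stratification` produced by
#'   [select_num_categories()].
#' @param ... Unused.
#' @return A ggplot of BIC against the number of categories, with the
#'   selected K marked.
#' @method autoplot chd_stratification
#' @export
autoplot.chd_stratification <- function(object, ...) {
  if (is.null(object$trace)) abort("no K-vs-BIC trace recorded")
  ggplot(object$trace, aes(x = .data$K, y = .data$bic)) +
    geom_line() + geom_point() +
    geom_point(data = dplyr::filter(object$trace, .data$K == object$K),
               colour = "red", size = 3) +
    labs(x = "Number of categories", y = "BIC") +
    theme_minimal()
}
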