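check_binary_labels <- function(labels) {
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    abort("labels must be 0/1 with no missing values")
  }
  if (length(unique(labels)) < 2L) abort("both outcome classes must be present")
  labels
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive case receives a higher
#' score than a randomly chosen negative case, with ties counted one half
#' (the Mann–Whitney rank formulation).
#'
#' @param scores Numeric scores, higher meaning more likely positive.
#' @param labels Binary 0/1 outcomes.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
auc <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  if (length(scores) != length(labels)) abort("scores/labels length mismatch")
  if (anyNA(scores)) abort("scores must not be missing")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-index optimal threshold
#'
#' Scans every distinct observed score (plus `+Inf`) as a candidate cut, with
#' the rule "score >= threshold is called positive", and returns the cut
#' maximising the Youden index \eqn{J = } sensitivity + specificity \eqn{-
#' 1}. Ties are broken toward the lowest threshold.
#'
#' @inheritParams auc
#' @return A tibble with `threshold`, `sensitivity`, `specificity`,
#'   `youden`.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  cuts <- c(sort(unique(scores)), Inf)
  stats <- vapply(cuts, function(th) {
    pos <- scores >= th
    c(sens = sum(pos & labels == 1L) / n1,
      spec = sum(!pos & labels == 0L) / n0)
  }, numeric(2))
  j <- stats["sens", ] + stats["spec", ] - 1
  best <- which(j == max(j))[1L]
  tibble(threshold = cuts[best],
         sensitivity = unname(stats["sens", best]),
         specificity = unname(stats["spec", best]),
         youden = unname(j[best]))
}

#' Bootstrap percentile confidence interval for the AUC
#'
#' Patients (score-label rows) are resampled with replacement `n_boot`
#' times; the 2.5 and 97.5 percentiles of the resampled AUCs form the 95
#' percent interval. Resamples containing a single outcome class cannot be
#' scored and are skipped (and counted); more than half degenerate resamples
#' is an error.
#'
#' @inheritParams auc
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param stratified Resample within outcome classes, preserving class
#'   counts (default off: plain row resampling).
#' @return A tibble with `ci_low`, `ci_high`, `n_boot`, `n_degenerate`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 1000L, seed = 1L,
                             stratified = FALSE) {
  labels <- check_binary_labels(labels)
  set.seed(seed)
  n <- length(labels)
  idx1 <- which(labels == 1L); idx0 <- which(labels == 0L)
  vals <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    take <- if (stratified) {
      c(sample(idx1, length(idx1), replace = TRUE),
        sample(idx0, length(idx0), replace = TRUE))
    } else {
      sample.int(n, n, replace = TRUE)
    }
    lb <- labels[take]
    if (length(unique(lb)) < 2L) next
    vals[b] <- auc(scores[take], lb)
  }
  n_bad <- sum(is.na(vals))
  if (n_bad > n_boot / 2) abort("more than half of bootstrap resamples degenerate")
  if (n_bad > 0) {
    inform(paste0("skipped ", n_bad, " single-class bootstrap resample(s)"))
  }
  vals <- vals[!is.na(vals)]
  tibble(ci_low = quantile(vals, 0.025, names = FALSE),
         ci_high = quantile(vals, 0.975, names = FALSE),
         n_boot = as.integer(n_boot), n_degenerate = as.integer(n_bad))
}

#' Evaluate a scorer against binary outcomes
#'
#' Combines [auc()], [bootstrap_auc_ci()] and [youden_threshold()] into the
#' standard discrimination summary: AUC with a bootstrap 95 percent
#' interval, and sensitivity/specificity at the Youden-optimal threshold.
#'
#' @inheritParams bootstrap_auc_ci
#' @param name Label for the scorer (e.g. the model name).
#' @return An object of class `chd_eval`: a one-row tibble with `model`,
#'   `auc`, `ci_low`, `ci_high`, `threshold`, `sensitivity`, `specificity`,
#'   `youden`, `n`, `n_boot`; scores and labels kept as attributes for
#'   plotting.
#' @export
evaluate_scores <- function(scores, labels, name = "model",
                            n_boot = 1000L, seed = 1L, stratified = FALSE) {
  labels <- check_binary_labels(labels)
  ci <- bootstrap_auc_ci(scores, labels, n_boot = n_boot, seed = seed,
                         stratified = stratified)
  yj <- youden_threshold(scores, labels)
  out <- tibble(model = name, auc = auc(scores, labels),
                ci_low = ci$ci_low, ci_high = ci$ci_high,
                threshold = yj$threshold, sensitivity = yj$sensitivity,
                specificity = yj$specificity, youden = yj$youden,
                n = length(labels), n_boot = ci$n_boot)
  attr(out, "scores") <- scores
  attr(out, "labels") <- labels
  class(out) <- c("chd_eval", class(out))
  out
}

#' Evaluate an ordinal risk score
#'
#' Treats an ordinal category (e.g. a 1-5 risk stratification) as the score;
#' patients within a category are tied and counted one half in the AUC, as
#' for any other scorer.
#'
#' @param categories Ordinal (integer or ordered factor) per-patient
#'   categories.
#' @inheritParams evaluate_scores
#' @return A `chd_eval`, see [evaluate_scores()].
#' @export
evaluate_ordinal_score <- function(categories, labels, name = "ordinal",
                                   n_boot = 1000L, seed = 1L,
                                   stratified = FALSE) {
  evaluate_scores(as.numeric(categories), labels, name = name,
                  n_boot = n_boot, seed = seed, stratified = stratified)
}

roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lb <- labels[ord]
  tibble(fpr = c(0, cumsum(lb == 0) / sum(lb == 0)),
         tpr = c(0, cumsum(lb == 1) / sum(lb == 1)))
}

#' ROC curve of an evaluation
#'
#' @param object A `chd_eval` from [evaluate_scores()].
#' @param ... Further `chd_eval` objects to overlay.
#' @return A ggplot of the ROC curve(s) with the chance diagonal.
#' @method autoplot chd_eval
#' @export
autoplot.chd_eval <- function(object, ...) {
  evals <- c(list(object), Filter(function(e) inherits(e, "chd_eval"),
                                  list(...)))
  pts <- purrr::map(evals, function(e) {
    roc_points(attr(e, "scores"), attr(e, "labels")) |>
      mutate(model = e$model[[1]])
  }) |> list_rbind()
  ggplot(pts, aes(x = .data$fpr, y = .data$tpr, colour = .data$model)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_path() +
    coord_equal() +
    labs(x = "1 - specificity", y = "Sensitivity", colour = NULL) +
    theme_minimal()
}
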