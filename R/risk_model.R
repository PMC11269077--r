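#' Build the model feature matrix from a patient table
#'
#' Encodes patient covariates for the boosted-tree classifier. Ordered
#' clinical ladders (ordered factors, or factors whose levels are all
#' numeric strings such as defect counts) become integer codes; unordered
#' factors are one-hot encoded; binary/numeric columns pass through. Missing
#' values stay `NA` — the booster routes them with its native
#' missing-branch rule. The outcome and identifier columns are never
#' features.
#'
#' @param patients Patient tibble with a binary `died_in_hospital` column.
#' @param outcome Name of the outcome column.
#' @param exclude Columns never used as features.
#' @param ordinal Extra column names to force to ordinal integer coding.
#' @return An object of class `chd_feature_matrix`: list with `x` (numeric
#'   matrix, `NA` for missing), `y` (integer outcomes), `split` (train/test
#'   labels if present), and `schema` (per-source-column encoding).
#' @export
build_feature_matrix <- function(patients,
                                 outcome = "died_in_hospital",
                                 exclude = c("patient_id", "procedure"),
                                 ordinal = c("pulm_insufficiency",
                                             "left_atrial_dim")) {
  patients <- as_tibble(patients)
  stopifnot(outcome %in% names(patients))
  y <- check_binary_labels(patients[[outcome]])
  split <- patients[["split"]]
  feats <- patients[setdiff(names(patients),
                            c(outcome, exclude, "split"))]
  schema <- list()
  cols <- list()
  for (nm in names(feats)) {
    v <- feats[[nm]]
    if (is.factor(v) || is.character(v)) {
      if (is.character(v)) v <- factor(v)
      numeric_levels <- !anyNA(suppressWarnings(as.numeric(levels(v))))
      if (is.ordered(v) || numeric_levels || nm %in% ordinal) {
        cols[[nm]] <- as.numeric(v)
        schema[[nm]] <- list(encoding = "ordinal", levels = levels(v))
      } else {
        for (lv in levels(v)) {
          cols[[paste0(nm, "=", lv)]] <- as.numeric(v == lv)
        }
        schema[[nm]] <- list(encoding = "one_hot", levels = levels(v))
      }
    } else {
      cols[[nm]] <- as.numeric(v)
      schema[[nm]] <- list(encoding = "numeric")
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- NULL
  structure(list(x = x, y = y, split = split, schema = schema),
            class = "chd_feature_matrix")
}

#' @export
print.chd_feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$x), "patients x", ncol(x$x), "features\n")
  if (!is.null(x$split)) print(table(x$split))
  invisible(x)
}

#' Drop features with excessive missingness
#'
#' Removes every feature whose missing fraction is strictly greater than
#' `threshold` (a feature missing in exactly the threshold fraction is
#' kept).
#'
#' @param fm A `chd_feature_matrix`.
#' @param threshold Maximum tolerated missing fraction (default 0.30).
#' @return The pruned `chd_feature_matrix`; dropped and kept feature names
#'   are recorded in its `report` element.
#' @export
drop_sparse_features <- function(fm, threshold = 0.30) {
  stopifnot(inherits(fm, "chd_feature_matrix"))
  frac <- colMeans(is.na(fm$x))
  drop <- frac > threshold
  if (all(drop)) abort("all features exceed the missingness threshold")
  if (any(drop)) {
    inform(paste0("dropped ", sum(drop), " feature(s) with > ",
                  round(100 * threshold), "% missing: ",
                  paste(names(frac)[drop], collapse = ", ")))
  }
  fm$x <- fm$x[, !drop, drop = FALSE]
  fm$report <- tibble(feature = names(frac), missing_fraction = unname(frac),
                      dropped = unname(drop))
  fm
}

#' Split patients into training and testing sets
#'
#' @param patients Patient tibble with the outcome column.
#' @param ratio Training fraction (default 0.75, the 7.5:2.5 split).
#' @param stratified Preserve outcome prevalence across the split (default
#'   `TRUE`).
#' @param seed Integer seed.
#' @param outcome Outcome column name.
#' @return `patients` with a `split` column of `"train"`/`"test"`.
#' @export
split_train_test <- function(patients, ratio = 0.75, stratified = TRUE,
                             seed = 1L, outcome = "died_in_hospital") {
  patients <- as_tibble(patients)
  n <- nrow(patients)
  if (n < 4L) abort("need at least 4 patients to split")
  set.seed(seed)
  split <- character(n)
  if (stratified) {
    y <- check_binary_labels(patients[[outcome]])
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      n_tr <- round(ratio * length(idx))
      tr <- sample(idx, n_tr)
      split[tr] <- "train"
      split[setdiff(idx, tr)] <- "test"
    }
    for (s in c("train", "test")) {
      if (length(unique(y[split == s])) < 2L) {
        abort(paste0("outcome class missing from the ", s, " split"))
      }
    }
  } else {
    tr <- sample.int(n, round(ratio * n))
    split[tr] <- "train"
    split[-tr] <- "test"
  }
  patients$split <- split
  patients
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_booster <- function(x, y, settings) {
  dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  params <- list(objective = "binary:logistic",
                 max_depth = settings$max_depth %||% 4L,
                 eta = settings$eta %||% 0.1,
                 scale_pos_weight = settings$scale_pos_weight %||% 1,
                 nthread = 1)
  xgboost::xgb.train(params = params, data = dm,
                     nrounds = settings$nrounds %||% 100L, verbose = 0)
}

cv_auc <- function(x, y, settings, cv_folds, seed) {
  fold <- stratified_folds(y, cv_folds, seed)
  aucs <- vapply(seq_len(cv_folds), function(f) {
    tr <- fold != f
    m <- fit_booster(x[tr, , drop = FALSE], y[tr], settings)
    p <- predict(m, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE],
                                         nthread = 1))
    auc(p, y[!tr])
  }, numeric(1))
  mean(aucs)
}

gain_importance <- function(model, feature_names) {
  imp <- xgboost::xgb.importance(model = model)
  gain <- setNames(rep(0, length(feature_names)), feature_names)
  gain[imp$Feature] <- imp$Gain
  gain
}

#' Recursive feature elimination by boosted-tree importance
#'
#' Starting from all features, repeatedly: record the cross-validated AUC of
#' the current subset, fit the booster on the full training data, and drop
#' the feature with the smallest gain importance (unused features count as
#' zero gain; ties drop the later column). The selected subset is the one
#' with the highest recorded validation AUC; ties go to the smaller subset.
#'
#' @param fm A `chd_feature_matrix` (training rows only, or with a `split`
#'   column, in which case only the training rows are used).
#' @param settings Booster settings used during elimination (list with
#'   `nrounds`, `max_depth`, `eta`, `scale_pos_weight`).
#' @param cv_folds Stratified cross-validation folds for the per-subset AUC.
#' @param min_features Stop eliminating at this subset size.
#' @param seed Integer seed.
#' @return An object of class `chd_rfe`: list with `trace` (tibble of subset
#'   size, features, cv_auc), `elimination_order`, and `selected` feature
#'   names.
#' @export
rfe_select <- function(fm, settings = list(nrounds = 60L, max_depth = 3L,
                                           eta = 0.3),
                       cv_folds = 5L, min_features = 1L, seed = 1L) {
  stopifnot(inherits(fm, "chd_feature_matrix"))
  xy <- training_rows(fm)
  x <- xy$x; y <- xy$y
  if (ncol(x) < 2L) abort("need at least 2 features for elimination")
  if (length(unique(y)) < 2L) abort("outcome has a single class")

  current <- colnames(x)
  eliminated <- character(0)
  sizes <- integer(0); aucs <- numeric(0); feat_sets <- list()
  step <- 0L
  while (length(current) >= max(1L, min_features)) {
    step <- step + 1L
    xs <- x[, current, drop = FALSE]
    sizes <- c(sizes, length(current))
    feat_sets[[step]] <- current
    aucs <- c(aucs, cv_auc(xs, y, settings, cv_folds, seed + step))
    if (length(current) == max(1L, min_features)) break
    m <- fit_booster(xs, y, settings)
    gain <- gain_importance(m, current)
    worst <- names(gain)[max(which(gain == min(gain)))]
    eliminated <- c(eliminated, worst)
    current <- setdiff(current, worst)
  }
  trace <- tibble(n_features = sizes, features = feat_sets, cv_auc = aucs)
  best_auc <- max(trace$cv_auc)
  best <- trace |> dplyr::filter(.data$cv_auc == best_auc) |>
    slice_min(.data$n_features, n = 1, with_ties = FALSE)
  structure(list(trace = trace, elimination_order = eliminated,
                 selected = best$features[[1]],
                 best_cv_auc = best_auc),
            class = "chd_rfe")
}

#' @export
print.chd_rfe <- function(x, ...) {
  cat("Recursive feature elimination:",
      length(x$selected), "feature(s) selected, CV AUC",
      sprintf("%.3f", x$best_cv_auc), "\n")
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

training_rows <- function(fm) {
  if (!is.null(fm$split)) {
    keep <- fm$split == "train"
    list(x = fm$x[keep, , drop = FALSE], y = fm$y[keep])
  } else {
    list(x = fm$x, y = fm$y)
  }
}

#' Default hyperparameter lattice for the grid search
#'
#' Tree count, depth, learning rate, and the positive-class weight (the
#' class-imbalance knob of the booster); the training prevalence of deaths
#' is low, so the weight axis matters.
#'
#' @return A data frame, one row per candidate setting.
#' @export
default_param_grid <- function() {
  expand.grid(nrounds = c(60L, 150L), max_depth = c(3L, 5L),
              eta = c(0.1, 0.3), scale_pos_weight = c(1, 5),
              KEEP.OUT.ATTRS = FALSE)
}

#' Grid-search the booster hyperparameters and fit the final model
#'
#' Every lattice point is scored by stratified cross-validated AUC on the
#' training rows only; the best setting (ties: first row) is refit on the
#' full training set.
#'
#' @param fm A `chd_feature_matrix`.
#' @param grid Data frame of candidate settings, see [default_param_grid()].
#' @param cv_folds Stratified cross-validation folds.
#' @param features Optional feature subset (e.g. from [rfe_select()]).
#' @param seed Integer seed.
#' @return An object of class `chd_risk_model`: list with the fitted
#'   `booster`, `settings`, `feature_names`, normalised gain `importance`,
#'   `grid_results`, and the training prevalence.
#' @export
grid_search_fit <- function(fm, grid = default_param_grid(), cv_folds = 5L,
                            features = NULL, seed = 1L) {
  stopifnot(inherits(fm, "chd_feature_matrix"))
  if (nrow(grid) == 0L) abort("empty hyperparameter grid")
  xy <- training_rows(fm)
  x <- xy$x; y <- xy$y
  if (!is.null(features)) {
    missing_f <- setdiff(features, colnames(x))
    if (length(missing_f) > 0) {
      abort(paste0("unknown feature(s): ", paste(missing_f, collapse = ", ")))
    }
    x <- x[, features, drop = FALSE]
  }
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    cv_auc(x, y, as.list(grid[i, ]), cv_folds, seed)
  }, numeric(1))
  best <- which.max(scores)
  settings <- as.list(grid[best, ])
  booster <- fit_booster(x, y, settings)
  gain <- gain_importance(booster, colnames(x))
  structure(
    list(booster = booster, settings = settings,
         feature_names = colnames(x),
         importance = tibble(feature = names(gain),
                             weight = unname(gain / max(sum(gain), 1e-12))) |>
           arrange(desc(.data$weight)),
         grid_results = as_tibble(grid) |> mutate(cv_auc = scores),
         train_prevalence = mean(y)),
    class = "chd_risk_model")
}

#' Predict in-hospital death probabilities
#'
#' @param model A `chd_risk_model`.
#' @param newdata A `chd_feature_matrix` (or a bare numeric matrix) whose
#'   columns cover the model's training schema.
#' @return Numeric vector of per-patient probabilities in `[0, 1]`.
#' @export
predict_risk <- function(model, newdata) {
  stopifnot(inherits(model, "chd_risk_model"))
  x <- if (inherits(newdata, "chd_feature_matrix")) newdata$x else newdata
  missing_f <- setdiff(model$feature_names, colnames(x))
  if (length(missing_f) > 0) {
    abort(paste0("newdata lacks feature(s): ",
                 paste(missing_f, collapse = ", ")))
  }
  x <- x[, model$feature_names, drop = FALSE]
  predict(model$booster, xgboost::xgb.DMatrix(x, nthread = 1))
}

#' @export
print.chd_risk_model <- function(x, ...) {
  cat("Boosted mortality classifier:", length(x$feature_names),
      "features\n")
  cat("  settings:", paste(names(x$settings), unlist(x$settings),
                           sep = "=", collapse = ", "), "\n")
  print(head(x$importance, 10))
  invisible(x)
}

#' @rdname grid_search_fit
#' @param x A `chd_risk_model`.
#' @param ... Unused.
#' @method tidy chd_risk_model
#' @export
tidy.chd_risk_model <- function(x, ...) x$importance

#' @rdname grid_search_fit
#' @method glance chd_risk_model
#' @export
glance.chd_risk_model <- function(x, ...) {
  tibble(n_features = length(x$feature_names),
         train_prevalence = x$train_prevalence,
         best_cv_auc = max(x$grid_results$cv_auc),
         !!!x$settings)
}

#' Feature-importance plot
#'
#' @param object A `chd_risk_model`.
#' @param top_n Number of features shown.
#' @param ... Unused.
#' @return A ggplot of normalised gain importances (weights sum to 1).
#' @method autoplot chd_risk_model
#' @export
autoplot.chd_risk_model <- function(object, top_n = 10, ...) {
  imp <- head(object$importance, top_n)
  ggplot(imp, aes(x = .data$weight,
                  y = stats::reorder(.data$feature, .data$weight))) +
    geom_col() +
    labs(x = "Weight coefficient (normalised gain)", y = NULL) +
    theme_minimal()
}
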