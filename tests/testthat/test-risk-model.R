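make_patients <- function(n = 400, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    patient_id = sprintf("p%04d", 1:n),
    procedure = sample(c("a", "b"), n, replace = TRUE),
    age_days = rlnorm(n, log(300), 1),
    spo2_low = rbinom(n, 1, 0.3),
    shunt = factor(sample(c("none", "left", "right"), n, replace = TRUE)),
    severity = factor(sample(c("mild", "moderate", "severe"), n,
                             replace = TRUE),
                      levels = c("mild", "moderate", "severe"),
                      ordered = TRUE),
    n_defects = factor(sample(as.character(0:3), n, replace = TRUE),
                       levels = as.character(0:3)),
    died_in_hospital = rbinom(n, 1, 0.15))
}

test_that("feature matrix encodes ordinal, one-hot and numeric columns", {
  pts <- make_patients()
  pts$spo2_low[1:5] <- NA
  fm <- build_feature_matrix(pts)
  expect_s3_class(fm, "chd_feature_matrix")
  cn <- colnames(fm$x)
  # unordered factor: one-hot; ordered and numeric-levelled factors: ordinal
  expect_true(all(c("shunt=none", "shunt=left", "shunt=right") %in% cn))
  expect_true(all(c("severity", "n_defects") %in% cn))
  expect_false(any(grepl("^severity=", cn)))
  # excluded columns never become features
  expect_false(any(grepl("patient_id|procedure|died_in_hospital", cn)))
  # missing values survive encoding
  expect_equal(sum(is.na(fm$x[, "spo2_low"])), 5L)
  # ordinal codes follow the level order, one-hot is 0/1
  expect_equal(sort(unique(fm$x[, "severity"])), 1:3)
  expect_equal(sort(unique(fm$x[, "n_defects"])), 1:4)
  expect_true(all(fm$x[, "shunt=none"] %in% 0:1))
  expect_equal(fm$y, pts$died_in_hospital)
  expect_output(print(fm), "features")
})

test_that("drop_sparse_features uses a strict threshold", {
  pts <- make_patients(n = 200)
  pts$mostly_missing <- NA_real_
  pts$mostly_missing[1:20] <- 1          # 90% missing: dropped
  pts$exactly_thirty <- 1
  pts$exactly_thirty[1:60] <- NA         # exactly 30%: kept
  fm <- build_feature_matrix(pts)
  expect_message(pruned <- drop_sparse_features(fm), "mostly_missing")
  expect_false("mostly_missing" %in% colnames(pruned$x))
  expect_true("exactly_thirty" %in% colnames(pruned$x))
  rep <- pruned$report
  expect_equal(rep$dropped[rep$feature == "mostly_missing"], TRUE)
  expect_equal(rep$missing_fraction[rep$feature == "exactly_thirty"], 0.30)
  all_na <- build_feature_matrix(
    tibble::tibble(x1 = NA_real_, x2 = NA_real_,
                   died_in_hospital = rep(0:1, 5)))
  expect_error(drop_sparse_features(all_na), "all features")
})

test_that("train/test split is stratified, sized and reproducible", {
  pts <- make_patients(n = 1000, seed = 3)
  sp <- split_train_test(pts, ratio = 0.75, seed = 42)
  expect_lte(abs(sum(sp$split == "train") - 750), 1)
  expect_equal(sum(sp$split == "test"), 1000 - sum(sp$split == "train"))
  prev_tr <- mean(sp$died_in_hospital[sp$split == "train"])
  prev_te <- mean(sp$died_in_hospital[sp$split == "test"])
  expect_lt(abs(prev_tr - prev_te), 0.005)
  expect_identical(sp$split, split_train_test(pts, seed = 42)$split)
  expect_false(identical(sp$split, split_train_test(pts, seed = 43)$split))
  expect_error(split_train_test(pts[1:3, ]), "at least 4")
})

test_that("the cohort-scale 3:1 split lands within per-class rounding", {
  set.seed(10)
  pts <- tibble::tibble(patient_id = as.character(1:24685),
                        died_in_hospital = c(rep(1L, 591),
                                             rep(0L, 24685 - 591)))
  sp <- split_train_test(pts, ratio = 0.75, seed = 1)
  expect_lte(abs(sum(sp$split == "train") - 0.75 * 24685), 1)
  expect_equal(sum(sp$died_in_hospital == 1 & sp$split == "train"),
               round(0.75 * 591))
})

test_that("grid search fits, predicts deterministically and reports", {
  pts <- make_patients(n = 600, seed = 5)
  # make the outcome depend on the features so AUC is informative
  pts$died_in_hospital <- rbinom(600, 1,
                                 plogis(-2.5 + 1.5 * pts$spo2_low +
                                          0.6 * as.numeric(pts$severity)))
  pts <- split_train_test(pts, seed = 2)
  fm <- build_feature_matrix(pts)
  grid <- data.frame(nrounds = c(20L, 40L), max_depth = 2L, eta = 0.3,
                     scale_pos_weight = 1)
  m1 <- grid_search_fit(fm, grid = grid, cv_folds = 3, seed = 9)
  m2 <- grid_search_fit(fm, grid = grid, cv_folds = 3, seed = 9)
  expect_s3_class(m1, "chd_risk_model")
  expect_equal(nrow(m1$grid_results), 2L)
  expect_true(all(is.finite(m1$grid_results$cv_auc)))
  expect_equal(m1$settings$nrounds,
               m1$grid_results$nrounds[which.max(m1$grid_results$cv_auc)])
  p1 <- predict_risk(m1, fm)
  expect_identical(p1, predict_risk(m2, fm))
  expect_true(all(p1 >= 0 & p1 <= 1))
  # importance weights are a normalised distribution
  expect_equal(sum(m1$importance$weight), 1, tolerance = 1e-6)
  expect_true(all(m1$importance$weight >= 0))
  # informative features dominate the importances
  top2 <- m1$importance$feature[1:2]
  expect_true("spo2_low" %in% top2 || "severity" %in% top2)
  # tidy/glance/print/autoplot
  expect_identical(tidy(m1), m1$importance)
  expect_equal(glance(m1)$n_features, length(m1$feature_names))
  expect_s3_class(autoplot(m1), "ggplot")
  expect_output(print(m1), "classifier")
  expect_error(grid_search_fit(fm, grid = grid[0, ]), "empty")
})

test_that("predictions are roughly calibrated in the large", {
  pts <- make_patients(n = 2000, seed = 6)
  pts$died_in_hospital <- rbinom(2000, 1, plogis(-3 + 1.2 * pts$spo2_low))
  fm <- build_feature_matrix(pts)
  grid <- data.frame(nrounds = 40L, max_depth = 2L, eta = 0.2,
                     scale_pos_weight = 1)
  m <- grid_search_fit(fm, grid = grid, cv_folds = 3, seed = 1)
  expect_equal(mean(predict_risk(m, fm)), mean(fm$y), tolerance = 0.02)
  expect_equal(m$train_prevalence, mean(fm$y))
})

test_that("predict_risk enforces the feature schema", {
  fm <- planted_feature_matrix(1, n = 500, n_noise = 2)
  grid <- data.frame(nrounds = 10L, max_depth = 2L, eta = 0.3,
                     scale_pos_weight = 1)
  m <- grid_search_fit(fm, grid = grid, cv_folds = 2, seed = 1)
  bad <- fm$x[, 1:3]
  expect_error(predict_risk(m, bad), "lacks feature")
  # extra columns and reordered columns are fine
  shuffled <- fm$x[, rev(colnames(fm$x))]
  expect_equal(predict_risk(m, shuffled), predict_risk(m, fm))
  expect_error(grid_search_fit(fm, grid = grid, features = "nope"),
               "unknown feature")
})

test_that("RFE keeps signal, sheds noise, and records its trace", {
  fm <- planted_feature_matrix(4, n = 4000, n_noise = 5)
  r <- rfe_select(fm, settings = list(nrounds = 40L, max_depth = 3L,
                                      eta = 0.3),
                  cv_folds = 3, seed = 4)
  expect_s3_class(r, "chd_rfe")
  expect_true(all(c("informative1", "informative2", "informative3") %in%
                    r$selected))
  expect_equal(nrow(r$trace), 8L)          # 8 subsets scanned down to size 1
  expect_equal(r$trace$n_features, 8:1)
  expect_equal(length(r$elimination_order), 7L)
  expect_equal(r$best_cv_auc, max(r$trace$cv_auc))
  # selected set is one of the scanned subsets with the best AUC
  expect_true(any(sapply(r$trace$features, identical, r$selected)))
  expect_output(print(r), "selected")
})

test_that("RFE on pure noise finds nothing better than chance", {
  set.seed(13)
  n <- 2000
  x <- matrix(rnorm(n * 6), ncol = 6,
              dimnames = list(NULL, paste0("noise", 1:6)))
  y <- rbinom(n, 1, 0.2)
  fm <- structure(list(x = x, y = y, split = NULL, schema = list()),
                  class = "chd_feature_matrix")
  r <- rfe_select(fm, settings = list(nrounds = 30L, max_depth = 2L,
                                      eta = 0.3),
                  cv_folds = 3, seed = 13)
  expect_lt(r$best_cv_auc, 0.57)
  expect_gt(r$best_cv_auc, 0.43)
})

test_that("RFE respects the split column and input contracts", {
  fm <- planted_feature_matrix(2, n = 1000, n_noise = 2)
  fm$split <- rep(c("train", "test"), length.out = 1000)
  r <- rfe_select(fm, settings = list(nrounds = 20L, max_depth = 2L,
                                      eta = 0.3),
                  cv_folds = 2, seed = 1)
  expect_s3_class(r, "chd_rfe")
  one <- structure(list(x = fm$x[, 1, drop = FALSE], y = fm$y,
                        split = NULL, schema = list()),
                   class = "chd_feature_matrix")
  expect_error(rfe_select(one), "at least 2 features")
})

test_that("a reasonable setting beats a crippled one in the grid search", {
  fm <- planted_feature_matrix(6, n = 3000, n_noise = 3)
  grid <- data.frame(nrounds = c(1L, 80L), max_depth = c(1L, 3L),
                     eta = c(0.01, 0.3), scale_pos_weight = 1)
  m <- grid_search_fit(fm, grid = grid, cv_folds = 3, seed = 2)
  expect_gt(m$grid_results$cv_auc[2], m$grid_results$cv_auc[1])
  expect_equal(m$settings$nrounds, 80L)
})
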