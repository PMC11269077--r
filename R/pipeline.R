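#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end run — registry simulation (or a
#' procedure-table path), shrinkage inference, category search range,
#' train/test split, elimination and grid-search settings, and bootstrap
#' settings — with an explicit seed for every stochastic stage.
#'
#' @param procedures_path Optional path to a procedure-outcome CSV; `NULL`
#'   simulates procedures from `registry`.
#' @param registry A [registry_spec()] for synthetic patients (and
#'   procedures when no path is given).
#' @param shrinkage List: `method`, `chains`, `iter`, `warmup`, `seed`.
#' @param k_range Candidate numbers of risk categories.
#' @param split List: `ratio`, `stratified`, `seed`.
#' @param rfe `NULL` to skip elimination, or a list with `settings`,
#'   `cv_folds`, `seed`.
#' @param grid Data frame of booster settings for [grid_search_fit()].
#' @param cv_folds Cross-validation folds for the grid search.
#' @param train_seed Seed of the grid search.
#' @param bootstrap List: `n_boot`, `seed`.
#' @return A list of class `chd_pipeline_config`.
#' @export
pipeline_config <- function(procedures_path = NULL,
                            registry = registry_spec(),
                            shrinkage = list(method = "mcmc", chains = 4L,
                                             iter = 4000L, warmup = 2000L,
                                             seed = 1L),
                            k_range = 2:20,
                            split = list(ratio = 0.75, stratified = TRUE,
                                         seed = 2L),
                            rfe = NULL,
                            grid = default_param_grid(),
                            cv_folds = 5L,
                            train_seed = 3L,
                            bootstrap = list(n_boot = 1000L, seed = 4L)) {
  cfg <- list(procedures_path = procedures_path, registry = registry,
              shrinkage = shrinkage, k_range = k_range, split = split,
              rfe = rfe, grid = grid, cv_folds = cv_folds,
              train_seed = train_seed, bootstrap = bootstrap)
  validate_pipeline_config(cfg)
  structure(cfg, class = "chd_pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  needed <- list(c("shrinkage", "seed"), c("split", "seed"),
                 c("bootstrap", "seed"))
  for (path in needed) {
    v <- cfg[[path[1]]][[path[2]]]
    if (is.null(v) || !is.numeric(v)) {
      abort(paste0("config: ", paste(path, collapse = "$"),
                   " must be an explicit integer seed"))
    }
  }
  if (!is.null(cfg$rfe) && is.null(cfg$rfe$seed)) {
    abort("config: rfe$seed must be an explicit integer seed")
  }
  if (is.null(cfg$train_seed)) abort("config: train_seed must be set")
  if (!inherits(cfg$registry, "chd_registry_spec")) {
    abort("config: registry must be a registry_spec()")
  }
  invisible(cfg)
}

write_stage_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — procedures (load or simulate), shrinkage
#' fit, risk stratification, patient simulation and category assignment,
#' train/test split, optional feature elimination, grid-search fit, and
#' evaluation of both the fitted classifier and the ordinal risk-category
#' scorer on the held-out test set. Every stage's output is written under
#' `out_dir` and hashed (MD5) into a manifest; rerunning with the same
#' configuration reproduces the hashes of all deterministic stages.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return A list with the in-memory stage results (`procedures`, `fit`,
#'   `strat`, `patients`, `model`, `rfe`, `evaluation`) and the `manifest`
#'   tibble (file, stage, md5).
#' @export
run_pipeline <- function(config, out_dir = tempfile("chdrisk_run_")) {
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(path, stage) {
    hash <- unname(tools::md5sum(path))
    manifest[[length(manifest) + 1L]] <<-
      tibble(file = basename(path), stage = stage, md5 = hash)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  procedures <- stage("procedures", {
    if (is.null(config$procedures_path)) {
      simulate_procedure_outcomes(config$registry)
    } else {
      load_procedure_table(config$procedures_path)
    }
  })
  procedures <- apply_inclusion_rules(procedures)
  pf <- file.path(out_dir, "procedures.csv")
  readr::write_csv(procedures, pf, progress = FALSE); note(pf, "procedures")

  fit <- stage("shrinkage", {
    sh <- config$shrinkage
    fit_procedure_shrinkage(
      procedures, method = sh$method %||% "mcmc",
      chains = sh$chains %||% 4L, iter = sh$iter %||% 4000L,
      warmup = sh$warmup %||% 2000L, seed = sh$seed)
  })
  ef <- file.path(out_dir, "estimates.json")
  write_stage_json(list(hyper = fit$hyper, estimates = fit$estimates,
                        diagnostics = fit$diagnostics), ef)
  note(ef, "shrinkage")

  strat <- stage("stratify", {
    select_num_categories(procedures, fit, k_range = config$k_range)
  })
  sf <- file.path(out_dir, "strat.json")
  write_stage_json(list(K = strat$K, boundaries = strat$boundaries,
                        homogeneity = strat$homogeneity, bic = strat$bic,
                        trace = strat$trace,
                        categories = select(strat$categories, "procedure",
                                            "risk_category")), sf)
  note(sf, "stratify")

  patients <- stage("patients", {
    simulate_patients(config$registry, procedures = procedures,
                      strat = strat) |>
      split_train_test(ratio = config$split$ratio %||% 0.75,
                       stratified = config$split$stratified %||% TRUE,
                       seed = config$split$seed)
  })
  ptf <- file.path(out_dir, "patients.csv")
  readr::write_csv(patients, ptf, progress = FALSE); note(ptf, "patients")

  fm <- build_feature_matrix(patients) |> drop_sparse_features()
  rfe <- NULL
  features <- NULL
  if (!is.null(config$rfe)) {
    rfe <- stage("rfe", {
      rfe_select(fm, settings = config$rfe$settings %||%
                   list(nrounds = 60L, max_depth = 3L, eta = 0.3),
                 cv_folds = config$rfe$cv_folds %||% 5L,
                 seed = config$rfe$seed)
    })
    features <- rfe$selected
    rf <- file.path(out_dir, "rfe.json")
    write_stage_json(list(selected = rfe$selected,
                          elimination_order = rfe$elimination_order,
                          trace = select(rfe$trace, "n_features", "cv_auc")),
                     rf)
    note(rf, "rfe")
  }

  model <- stage("train", {
    grid_search_fit(fm, grid = config$grid, cv_folds = config$cv_folds,
                    features = features, seed = config$train_seed)
  })
  mf <- file.path(out_dir, "model.json")
  write_stage_json(list(settings = model$settings,
                        features = model$feature_names,
                        importance = model$importance,
                        grid_results = model$grid_results), mf)
  note(mf, "train")

  evaluation <- stage("evaluate", {
    test <- fm$split == "test"
    scores <- predict_risk(model, fm$x[test, , drop = FALSE])
    bind_rows(
      evaluate_scores(scores, fm$y[test], name = "boosted model",
                      n_boot = config$bootstrap$n_boot %||% 1000L,
                      seed = config$bootstrap$seed),
      evaluate_ordinal_score(patients$risk_category[test], fm$y[test],
                             name = "risk categories",
                             n_boot = config$bootstrap$n_boot %||% 1000L,
                             seed = config$bootstrap$seed))
  })
  evf <- file.path(out_dir, "eval.json")
  write_stage_json(evaluation, evf); note(evf, "evaluate")

  manifest <- list_rbind(manifest)
  wf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, wf, auto_unbox = TRUE, dataframe = "rows",
                       pretty = TRUE)

  list(procedures = procedures, fit = fit, strat = strat,
       patients = patients, rfe = rfe, model = model,
       evaluation = evaluation, manifest = manifest, out_dir = out_dir)
}
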