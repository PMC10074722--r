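# End-to-end pipeline: featurize -> balance -> select -> cross-validate /
# train, with every stage artifact materialized to the run directory so each
# stage is independently re-runnable and every seed is recorded.

#' Pipeline configuration
#'
#' Serializable (JSON) bundle of all stage parameters. Unknown keys in a
#' config file are rejected.
#'
#' @param input path to a traditional-stage CSV/TSV table, or `NULL` to
#'   simulate one with `sim`.
#' @param outdir run directory for artifacts.
#' @param seed global seed; stage seeds are derived from it.
#' @param folds CV folds.
#' @param repeats CV repeats for the final model evaluation.
#' @param balance balancing method (`"smote"`, `"random"`, `"none"`).
#' @param balance_before_cv if `TRUE`, balance the whole table once before
#'   cross-validation (the leakage-prone reading of the protocol) instead of
#'   inside training folds (the default, leakage-safe).
#' @param smote_k SMOTE neighbour count.
#' @param select if `FALSE`, skip feature selection and model all 175
#'   columns.
#' @param classifier [classifier_config()] for the final model.
#' @param selection_classifier [classifier_config()] for the SFS wrapper.
#' @param sim [simulation_config()] used when `input` is `NULL`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, outdir = tempfile("hotwave_run_"),
                            seed = 1L, folds = 10L, repeats = 1L,
                            balance = "smote", balance_before_cv = FALSE,
                            smote_k = 5L, select = TRUE,
                            classifier = classifier_config(seed = seed),
                            selection_classifier = classifier_config(
                              n_estimators = 200L, num_leaves = 8L,
                              max_depth = 5L, seed = seed),
                            sim = simulation_config(seed = seed)) {
  structure(
    list(input = input, outdir = outdir, seed = as.integer(seed),
         folds = as.integer(folds), repeats = as.integer(repeats),
         balance = balance, balance_before_cv = isTRUE(balance_before_cv),
         smote_k = as.integer(smote_k), select = isTRUE(select),
         classifier = classifier, selection_classifier = selection_classifier,
         sim = sim),
    class = "pipeline_config"
  )
}

.config_to_list <- function(cfg) {
  l <- unclass(cfg)
  l$classifier <- unclass(l$classifier)
  l$selection_classifier <- unclass(l$selection_classifier)
  for (k in c("classifier", "selection_classifier")) {
    if (is.list(l[[k]]$backend)) l[[k]]$backend <- "plugin"
  }
  l$sim <- unclass(l$sim)
  l
}

#' Write a pipeline config to JSON
#'
#' @param cfg a [pipeline_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(.config_to_list(cfg), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a pipeline config from JSON
#'
#' @param path JSON file written by [write_pipeline_config()] (or by hand).
#' @return a [pipeline_config()]. Unknown keys raise an error.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- raw[setdiff(names(raw), c("classifier", "selection_classifier", "sim"))]
  if (!is.null(raw$classifier)) {
    args$classifier <- do.call(classifier_config, as.list(raw$classifier))
  }
  if (!is.null(raw$selection_classifier)) {
    args$selection_classifier <-
      do.call(classifier_config, as.list(raw$selection_classifier))
  }
  if (!is.null(raw$sim)) args$sim <- do.call(simulation_config, as.list(raw$sim))
  do.call(pipeline_config, args)
}

.log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full pipeline
#'
#' Executes featurize, balance, feature selection (mRMR ranking + sequential
#' forward selection), final cross-validated evaluation and a final model fit
#' on all rows, writing each stage artifact and a reproducibility manifest to
#' the run directory: `full175.csv`, `balanced.csv`, `selection.json`,
#' `model_meta.json`, `metrics.json`, `manifest.json`, `run.log`.
#'
#' @param cfg a [pipeline_config()].
#' @return list with elements `outdir`, `selection`, `cv`, `model`,
#'   invisibly.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(cfg$outdir, "run.log"), "w")
  on.exit(close(logcon))
  stage <- "input"
  run <- function(stage_name, expr) {
    stage <<- stage_name
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage_name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  tab <- run("input", {
    if (is.null(cfg$input)) {
      .log_line(logcon, "simulating input table (seed ", cfg$sim$seed, ")")
      simulate_table(cfg$sim)
    } else {
      .log_line(logcon, "reading ", cfg$input)
      read_feature_table(cfg$input, stage = "traditional")
    }
  })

  full <- run("featurize", featurize_table(tab))
  write_feature_table(full, file.path(cfg$outdir, "full175.csv"))
  .log_line(logcon, "featurized: ", nrow(full$features), " rows x ",
            ncol(full$features), " columns")

  balanced <- run("balance", {
    if (cfg$balance == "none") full
    else .balance_table(full, cfg$balance, seed = 114L, k = cfg$smote_k)
  })
  write_feature_table(balanced, file.path(cfg$outdir, "balanced.csv"))
  .log_line(logcon, "balanced (", cfg$balance, "): ",
            sum(balanced$labels == 1), " pos / ",
            sum(balanced$labels == 0), " neg")

  # leakage-safe default: select and evaluate on the raw table with in-fold
  # balancing; the pre-balanced table is used only under balance_before_cv
  work <- if (cfg$balance_before_cv) balanced else full
  fold_balance <- if (cfg$balance_before_cv) "none" else cfg$balance

  sel <- run("select", {
    if (!cfg$select) {
      NULL
    } else {
      ranked <- mrmr_rank(work)
      sfs_select(ranked, work, folds = cfg$folds,
                 config = cfg$selection_classifier, seed = cfg$seed,
                 balance = fold_balance, smote_k = cfg$smote_k)
    }
  })
  if (!is.null(sel)) {
    jsonlite::write_json(
      list(ranked = sel$ranked, chosen = sel$chosen,
           cv_scores = as.list(sel$cv_scores), best_size = sel$best_size),
      file.path(cfg$outdir, "selection.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    .log_line(logcon, "selected ", sel$best_size, " features (CV AUC ",
              sprintf("%.3f", sel$best_score), ")")
  }

  chosen <- if (is.null(sel)) names(work$features) else sel$chosen
  modelled <- feature_table(work$features[chosen], labels = work$labels,
                            stage = "selected")

  cv <- run("cross_validate",
            cross_validate(modelled, folds = cfg$folds, repeats = cfg$repeats,
                           seed = cfg$seed, balance = fold_balance,
                           config = cfg$classifier, smote_k = cfg$smote_k))
  jsonlite::write_json(
    list(mean = as.list(cv$mean),
         per_repeat = apply(cv$per_repeat, 1L, as.list)),
    file.path(cfg$outdir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  .log_line(logcon, "CV metrics: ",
            paste(names(cv$mean), sprintf("%.3f", cv$mean), sep = "=",
                  collapse = " "))

  model <- run("train", {
    fit_tab <- .balance_table(modelled, fold_balance, seed = 114L,
                              k = cfg$smote_k)
    train_classifier(fit_tab$features, fit_tab$labels, cfg$classifier)
  })
  jsonlite::write_json(
    list(backend = if (is.list(model$backend)) "plugin" else model$backend,
         features = model$feature_names,
         config = unclass(cfg$classifier)[c("max_depth", "num_leaves",
                                            "n_estimators", "learning_rate",
                                            "min_data_in_leaf", "seed")]),
    file.path(cfg$outdir, "model_meta.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  write_pipeline_config(cfg, file.path(cfg$outdir, "manifest.json"))
  .log_line(logcon, "done; artifacts in ", cfg$outdir)
  invisible(list(outdir = cfg$outdir, selection = sel, cv = cv, model = model))
}
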