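# Experiment orchestration: synthetic data -> preprocessing -> feature
# bank -> SC selection -> base classifiers -> CCV adjustment -> metrics
# and curves, for each classifier with and without the CCV weights.

#' Experiment configuration
#'
#' @param seed Master seed; train set, test set and every classifier draw
#'   derived sub-seeds from it.
#' @param n_train_per_class,n_test_per_class Patches per class in the
#'   training and test sets.
#' @param classifiers Subset of `c("elm", "svm", "rf")`.
#' @param features A [feature_config()].
#' @param normal,abnormal Class generator presets
#'   (see [default_class_params()]).
#' @param rho_max,delta1,delta2 SC selection parameters ([sc_fit()]).
#' @param elm_L,elm_activation,svm_cost,rf_ntree Classifier parameters.
#' @param ccv_interval Curve sampling interval for the CCV statistic.
#' @param radius_cv,mean_jitter Patch-to-patch variation
#'   (see [generate_dataset()]).
#' @param verbose Log per-stage progress and timing to stderr.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L, n_train_per_class = 200L,
                              n_test_per_class = 100L,
                              classifiers = c("elm", "svm", "rf"),
                              features = feature_config(),
                              normal = default_class_params("normal"),
                              abnormal = default_class_params("abnormal"),
                              rho_max = 0.95, delta1 = NULL, delta2 = 0.05,
                              elm_L = 100L, elm_activation = "sigmoid",
                              svm_cost = 1, rf_ntree = 100L,
                              ccv_interval = 2L, radius_cv = 0.08,
                              mean_jitter = 8, verbose = FALSE) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  structure(as.list(environment()), class = "experiment_config")
}

stage_log <- function(verbose, t0, fmt, ...) {
  if (verbose) {
    message(sprintf("[%6.1fs] ", as.numeric(Sys.time()) - t0),
            sprintf(fmt, ...))
  }
}

#' Run a full classification experiment
#'
#' Generates (or accepts) labelled patch sets, extracts the feature bank,
#' fits the SC selection model on the training set, trains each configured
#' classifier, computes the CCV model from the training contours, and
#' evaluates every classifier with and without the CCV adjustment.
#'
#' @param config An [experiment_config()].
#' @param train,test Optional pre-built `patch_set`s; generated from the
#'   config presets when `NULL`.
#' @return Object of class `ccv_experiment`: list with `metrics` (one row
#'   per classifier x variant), `per_sample` (per-sample predictions,
#'   weights and labels), `curves`, `sc_model`, `ccv_model` and the
#'   `config`.
#' @export
#' @examples
#' cfg <- experiment_config(seed = 1, n_train_per_class = 8,
#'                          n_test_per_class = 4,
#'                          features = feature_config(groups = c("intensity",
#'                                                               "morphology")),
#'                          classifiers = "rf")
#' \donttest{run_experiment(cfg)}
run_experiment <- function(config = experiment_config(), train = NULL,
                           test = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- as.numeric(Sys.time())
  v <- config$verbose
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (is.null(train)) {
    train <- run_stage("generate-train", generate_dataset(
      config$n_train_per_class, normal = config$normal,
      abnormal = config$abnormal, seed = derive_seed(config$seed, 1L),
      radius_cv = config$radius_cv, mean_jitter = config$mean_jitter))
  }
  if (is.null(test)) {
    test <- run_stage("generate-test", generate_dataset(
      config$n_test_per_class, normal = config$normal,
      abnormal = config$abnormal, seed = derive_seed(config$seed, 2L),
      radius_cv = config$radius_cv, mean_jitter = config$mean_jitter))
  }
  test <- lapply(test, function(p) { p$id <- paste0("test_", p$id); p })
  class(test) <- "patch_set"
  y_train <- patch_labels(train)
  y_test <- patch_labels(test)
  stage_log(v, t0, "generated %d train / %d test patches",
            length(train), length(test))

  fs_train <- run_stage("features-train", extract_all(train, config$features))
  fs_test <- run_stage("features-test", extract_all(test, config$features))
  stage_log(v, t0, "extracted %d features", nrow(fs_train$values))

  sc <- run_stage("sc-selection", sc_fit(
    fs_train, y_train, rho_max = config$rho_max, delta1 = config$delta1,
    delta2 = config$delta2))
  x_train <- t(sc_transform(sc, fs_train)$values)
  x_test <- t(sc_transform(sc, fs_test)$values)
  stage_log(v, t0, "SC selection kept %d / %d features", sc$k, sc$m)

  ccv_train <- run_stage("ccv-train", vapply(train, function(p) {
    ccv_of_mask(p$mask, interval = config$ccv_interval)
  }, integer(1)))
  ccv_test <- run_stage("ccv-test", vapply(test, function(p) {
    ccv_of_mask(p$mask, interval = config$ccv_interval)
  }, integer(1)))
  cmodel <- run_stage("ccv-model", fit_ccv_model(ccv_train, y_train))
  stage_log(v, t0, "CCV model: m1 = %.2f, m2 = %.2f", cmodel$m1, cmodel$m2)

  params <- list(elm = list(L = config$elm_L,
                            activation = config$elm_activation),
                 svm = list(cost = config$svm_cost),
                 rf = list(ntree = config$rf_ntree))
  metrics <- list()
  per_sample <- list()
  curves <- list()
  for (clf in config$classifiers) {
    fit <- run_stage(paste0("train-", clf), train_classifier(
      clf, x_train, y_train, params = params[[clf]],
      seed = derive_seed(config$seed, 10L + match(clf, c("elm", "svm", "rf")))))
    preds <- run_stage(paste0("predict-", clf),
                       initial_predictions(fit, x_test, ids = patch_ids(test)))
    adj <- run_stage(paste0("adjust-", clf),
                     adjust_predictions(preds, ccv_test, cmodel))
    adj$truth <- y_test
    adj$classifier <- clf
    per_sample[[clf]] <- adj
    base_m <- compute_metrics(confusion_counts(y_test, adj$initial_label))
    ccv_m <- compute_metrics(confusion_counts(y_test, adj$final_label))
    base_c <- classification_curves(adj$p_abnormal, y_test)
    ccv_c <- classification_curves(adj$p_abnormal_adj, y_test)
    metrics[[paste0(clf, "_base")]] <-
      data.frame(classifier = clf, variant = "base", t(base_m),
                 auc_roc = base_c$auc_roc, auc_pr = base_c$auc_pr)
    metrics[[paste0(clf, "_ccv")]] <-
      data.frame(classifier = clf, variant = "ccv", t(ccv_m),
                 auc_roc = ccv_c$auc_roc, auc_pr = ccv_c$auc_pr)
    curves[[clf]] <- list(base = base_c, ccv = ccv_c)
    stage_log(v, t0, "%s: ACC %.3f -> %.3f", clf,
              base_m["ACC"], ccv_m["ACC"])
  }
  structure(list(metrics = do.call(rbind, c(metrics, make.row.names = FALSE)),
                 per_sample = do.call(rbind, c(per_sample,
                                               make.row.names = FALSE)),
                 curves = curves, sc_model = sc, ccv_model = cmodel,
                 config = config),
            class = "ccv_experiment")
}

#' @export
print.ccv_experiment <- function(x, ...) {
  cat("CCV classification experiment\n")
  cat(sprintf("  SC selection: %d -> %d features; CCV model m1 = %.2f, m2 = %.2f\n",
              x$sc_model$m, x$sc_model$k, x$ccv_model$m1, x$ccv_model$m2))
  print(x$metrics, digits = 4)
  invisible(x)
}

#' Write an experiment report to disk
#'
#' `metrics.json` (metrics table plus the selection and CCV model
#' summaries), `metrics.csv`, `per_sample.csv` (id, ccv, initial label and
#' probability, omega, adjusted probability, final label) and one
#' `curve_<classifier>_<variant>_<type>.csv` per curve.
#'
#' @param experiment A `ccv_experiment`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(experiment, dir) {
  stopifnot(inherits(experiment, "ccv_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(metrics = experiment$metrics,
         sc = list(m = experiment$sc_model$m, m1 = experiment$sc_model$m1,
                   k = experiment$sc_model$k,
                   delta1 = experiment$sc_model$delta1,
                   delta2 = experiment$sc_model$delta2),
         ccv = list(m1 = experiment$ccv_model$m1,
                    m2 = experiment$ccv_model$m2)),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  utils::write.csv(experiment$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(experiment$per_sample, file.path(dir, "per_sample.csv"),
                   row.names = FALSE)
  for (clf in names(experiment$curves)) {
    for (variant in c("base", "ccv")) {
      cd <- experiment$curves[[clf]][[variant]]
      utils::write.csv(cd$roc,
                       file.path(dir, sprintf("curve_%s_%s_roc.csv", clf,
                                              variant)), row.names = FALSE)
      utils::write.csv(cd$pr,
                       file.path(dir, sprintf("curve_%s_%s_pr.csv", clf,
                                              variant)), row.names = FALSE)
    }
  }
  invisible(dir)
}
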