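#' Specify a cross-validated classification experiment
#'
#' Describes one run of the tissue classifier: the class split, the feature
#' set (the base milestones `ttfp_s`, `time_ratio`, `ds10` are always
#' included; longer downslopes are added cumulatively up to
#' `downslope_horizon_added_s`), the missing-data policy, the fold scheme
#' and the candidate classifiers.
#'
#' @param split_mode `"two_way"` (cancer vs not cancer) or `"three_way"`
#'   (cancer vs benign vs healthy).
#' @param downslope_horizon_added_s Longest downslope horizon included
#'   (one of 10, 50, 100, 200, 300, 400; 10 means base features only).
#' @param include_upslope,include_kurtosis Include the upslope / kurtosis
#'   milestones.
#' @param imputation_mode `"imputed"`: within each fold, missing training
#'   cells are KNN-imputed from the training rows only and missing test
#'   cells are filled by exponential-tail fits to each test trace;
#'   `"complete_only"`: rows with missing cells among the used features are
#'   dropped.
#' @param n_folds Number of cross-validation folds (default 5, i.e. an
#'   80:20 split per fold, no holdout).
#' @param grouping `"roi_level"` (stratified by class over ROIs) or
#'   `"patient_level"` (all of a patient's ROIs share a fold, guarding
#'   against within-patient leakage).
#' @param candidates Candidate classifiers tuned by inner cross-validation:
#'   any of `"bagged_knn"` (bootstrap ensemble of K-nearest-neighbour
#'   learners), `"logistic"`, `"random_forest"`.
#' @param knn_k_grid Neighbour counts tried for the bagged-KNN ensemble.
#' @param bag_size Number of bootstrap learners in the ensemble.
#' @param n_trees Trees in the random forest candidate.
#' @param inner_folds Folds of the inner model-selection loop.
#' @param knn_impute_k `k` for within-fold KNN imputation.
#' @param seed Integer seed controlling folds and classifier randomness.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(split_mode = c("two_way", "three_way"),
                            downslope_horizon_added_s = 400,
                            include_upslope = TRUE,
                            include_kurtosis = TRUE,
                            imputation_mode = c("imputed", "complete_only"),
                            n_folds = 5,
                            grouping = c("roi_level", "patient_level"),
                            candidates = c("bagged_knn", "logistic",
                                           "random_forest"),
                            knn_k_grid = c(3, 5, 7),
                            bag_size = 25,
                            n_trees = 200,
                            inner_folds = 3,
                            knn_impute_k = 5,
                            seed = 1) {
  structure(
    list(split_mode = match.arg(split_mode),
         downslope_horizon_added_s = downslope_horizon_added_s,
         include_upslope = include_upslope,
         include_kurtosis = include_kurtosis,
         imputation_mode = match.arg(imputation_mode),
         n_folds = n_folds,
         grouping = match.arg(grouping),
         candidates = match.arg(candidates, several.ok = TRUE),
         knn_k_grid = knn_k_grid, bag_size = bag_size, n_trees = n_trees,
         inner_folds = inner_folds, knn_impute_k = knn_impute_k,
         seed = as.integer(seed)),
    class = "experiment_spec"
  )
}

features_for_spec <- function(spec) {
  feats <- c("ttfp_s", "time_ratio", "ds10")
  if (spec$include_upslope) feats <- c(feats, "upslope")
  if (spec$include_kurtosis) feats <- c(feats, "kurtosis")
  extra <- c(50, 100, 200, 300, 400)
  extra <- extra[extra <= spec$downslope_horizon_added_s]
  if (length(extra) > 0) feats <- c(feats, paste0("ds", extra))
  feats
}

split_labels <- function(class, split_mode) {
  if (split_mode == "two_way")
    factor(ifelse(class == "cancer", "cancer", "not_cancer"),
           levels = c("not_cancer", "cancer"))
  else
    factor(class, levels = intersect(c("healthy", "benign", "cancer"),
                                     unique(class)))
}

# ---- AUC ------------------------------------------------------------------

auc_binary <- function(y, score, neg, pos) {
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                 levels = c(neg, pos), direction = "<",
                                 quiet = TRUE)))
}

# macro-averaged one-vs-rest AUC for >2 classes, standard binary AUC for 2
auc_score <- function(y, probs) {
  lv <- levels(y)
  if (length(lv) == 2) {
    auc_binary(y, probs[, lv[2]], lv[1], lv[2])
  } else {
    mean(vapply(lv, function(cls) {
      yy <- factor(ifelse(y == cls, "pos", "neg"), levels = c("neg", "pos"))
      auc_binary(yy, probs[, cls], "neg", "pos")
    }, numeric(1)))
  }
}

# ---- candidate classifiers ------------------------------------------------

candidate_grid <- function(spec) {
  grid <- list()
  for (cand in spec$candidates) {
    if (cand == "bagged_knn") {
      for (k in spec$knn_k_grid)
        grid[[length(grid) + 1]] <- list(name = "bagged_knn", k = k)
    } else {
      grid[[length(grid) + 1]] <- list(name = cand)
    }
  }
  grid
}

fit_model <- function(hyper, X, y, spec) {
  lv <- levels(y)
  model <- switch(hyper$name,
    bagged_knn = {
      n <- nrow(X)
      bags <- lapply(seq_len(spec$bag_size), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        # a bag must contain every class for knn3 probabilities to align
        for (cls in lv)
          if (!any(y[idx] == cls)) idx <- c(idx, which(y == cls)[1])
        caret::knn3(as.matrix(X[idx, , drop = FALSE]), droplevels(y[idx]),
                    k = min(hyper$k, length(idx)))
      })
      list(bags = bags)
    },
    logistic = {
      df <- X; df$.y <- y
      if (length(lv) == 2)
        suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      else
        nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 300)
    },
    random_forest = randomForest::randomForest(
      x = as.matrix(X), y = y, ntree = spec$n_trees),
    stop("unknown classifier: ", hyper$name)
  )
  structure(list(hyper = hyper, model = model, levels = lv),
            class = "icg_classifier")
}

predict_probs <- function(fit, X) {
  lv <- fit$levels
  out <- switch(fit$hyper$name,
    bagged_knn = {
      acc <- matrix(0, nrow(X), length(lv), dimnames = list(NULL, lv))
      for (m in fit$model$bags) {
        p <- stats::predict(m, as.matrix(X), type = "prob")
        acc[, colnames(p)] <- acc[, colnames(p)] + p
      }
      acc / length(fit$model$bags)
    },
    logistic = {
      if (length(lv) == 2) {
        p <- stats::predict(fit$model, newdata = X, type = "response")
        matrix(c(1 - p, p), ncol = 2, dimnames = list(NULL, lv))
      } else {
        p <- stats::predict(fit$model, newdata = X, type = "probs")
        if (is.null(dim(p))) p <- matrix(p, ncol = length(lv),
                                         dimnames = list(NULL, lv))
        p[, lv, drop = FALSE]
      }
    },
    random_forest = stats::predict(fit$model, as.matrix(X),
                                   type = "prob")[, lv, drop = FALSE]
  )
  out
}

select_model <- function(X, y, spec) {
  grid <- candidate_grid(spec)
  if (length(grid) == 1)
    return(list(best = grid[[1]], inner_auc = NA_real_))
  k_inner <- min(spec$inner_folds, min(table(y)))
  if (k_inner < 2) return(list(best = grid[[1]], inner_auc = NA_real_))
  folds <- caret::createFolds(y, k = k_inner)
  scores <- vapply(grid, function(hyper) {
    mean(vapply(folds, function(test_idx) {
      fit <- fit_model(hyper, X[-test_idx, , drop = FALSE], y[-test_idx],
                       spec)
      probs <- predict_probs(fit, X[test_idx, , drop = FALSE])
      yy <- y[test_idx]
      if (length(unique(yy)) < 2) return(NA_real_)
      auc_score(droplevels_probs(yy, probs)$y,
                droplevels_probs(yy, probs)$probs)
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  list(best = grid[[which.max(scores)]], inner_auc = max(scores))
}

droplevels_probs <- function(y, probs) {
  y2 <- droplevels(y)
  list(y = y2, probs = probs[, levels(y2), drop = FALSE])
}

# ---- fold fitting (training data only; no test argument by design) -------

#' Fit one cross-validation fold from training rows only
#'
#' Everything learned in a fold — KNN imputations, feature standardization,
#' model selection and the final classifier — is a function of the training
#' rows alone; test rows are not an argument, which is the structural
#' no-leakage guarantee.
#'
#' @param train_table Training-fold slice of the feature table.
#' @param spec An [experiment_spec()].
#' @return An object of class `icg_fold_fit` with the imputed training
#'   table, standardization parameters, the selected classifier and fit.
#' @export
fit_fold <- function(train_table, spec) {
  feats <- features_for_spec(spec)
  missing_feats <- setdiff(feats, names(train_table))
  if (length(missing_feats) > 0)
    stop("feature table lacks column(s): ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  n_imputed <- 0L
  if (spec$imputation_mode == "imputed") {
    if (anyNA(train_table[feats])) {
      imp <- knn_impute_train(train_table, k = spec$knn_impute_k,
                              feature_cols = feats)
      train_table <- imp$table
      n_imputed <- nrow(imp$log)
    }
  } else {
    train_table <- train_table[stats::complete.cases(train_table[feats]), ,
                               drop = FALSE]
  }
  y <- split_labels(train_table$class, spec$split_mode)
  if (length(unique(y)) < 2)
    stop("training fold contains fewer than 2 classes (stratification error)",
         call. = FALSE)
  X <- train_table[feats]
  center <- vapply(X, mean, numeric(1))
  scale <- vapply(X, stats::sd, numeric(1))
  scale[!is.finite(scale) | scale == 0] <- 1
  Xs <- as.data.frame(scale(X, center = center, scale = scale))
  sel <- select_model(Xs, y, spec)
  fit <- fit_model(sel$best, Xs, y, spec)
  structure(
    list(imputed_table = train_table, features = feats,
         center = center, scale = scale, classifier = sel$best,
         inner_auc = sel$inner_auc, fit = fit, n_imputed_cells = n_imputed,
         spec = spec),
    class = "icg_fold_fit"
  )
}

# impute missing cells of test rows one trace at a time (exponential tail
# fit on the trace's own data; never uses other rows)
impute_test_rows <- function(test_table, feats, normalized) {
  ds_feats <- grep("^ds[0-9]+$", feats, value = TRUE)
  n_imputed <- 0L
  for (r in seq_len(nrow(test_table))) {
    miss <- ds_feats[vapply(ds_feats, function(cl) is.na(test_table[r, cl]),
                            logical(1))]
    if (length(miss) == 0) next
    id <- test_table$trace_id[r]
    if (is.null(normalized[[id]]))
      stop(sprintf("trace %s needed for test-time imputation but not supplied",
                   id), call. = FALSE)
    test_table[r, ] <- exp_impute_test(normalized[[id]], test_table[r, ],
                                       horizons_to_fill =
                                         as.integer(sub("^ds", "", miss)))
    n_imputed <- n_imputed + length(miss)
  }
  attr(test_table, "n_imputed") <- n_imputed
  test_table
}

#' Predict fold test rows from a fitted fold
#'
#' @param fold_fit An `icg_fold_fit` from [fit_fold()].
#' @param test_table Test-fold slice of the feature table.
#' @param normalized Named list of smoothed, normalized traces (by
#'   `trace_id`), needed when test rows have missing downslopes under the
#'   `"imputed"` policy.
#' @return A list with `y` (true labels), `probs` (class probability
#'   matrix), `n_imputed_cells`.
#' @export
predict_fold <- function(fold_fit, test_table, normalized = NULL) {
  spec <- fold_fit$spec
  feats <- fold_fit$features
  n_imputed <- 0L
  if (spec$imputation_mode == "imputed") {
    test_table <- impute_test_rows(test_table, feats, normalized)
    n_imputed <- attr(test_table, "n_imputed")
  } else {
    test_table <- test_table[stats::complete.cases(test_table[feats]), ,
                             drop = FALSE]
  }
  y <- split_labels(test_table$class, spec$split_mode)
  Xs <- as.data.frame(scale(test_table[feats], center = fold_fit$center,
                            scale = fold_fit$scale))
  probs <- predict_probs(fold_fit$fit, Xs)
  list(y = y, probs = probs, n_imputed_cells = n_imputed,
       trace_id = test_table$trace_id)
}

make_folds <- function(feature_table, spec) {
  y <- split_labels(feature_table$class, spec$split_mode)
  if (length(unique(feature_table$class)) < 2 || length(unique(y)) < 2)
    stop("need at least 2 classes for classification", call. = FALSE)
  if (spec$grouping == "roi_level") {
    if (min(table(y)) < spec$n_folds)
      stop("a class has fewer rows than folds (stratification error)",
           call. = FALSE)
    caret::createFolds(y, k = spec$n_folds)
  } else {
    pts <- unique(feature_table$patient_id)
    pt_class <- vapply(pts, function(p) {
      cls <- feature_table$class[feature_table$patient_id == p]
      if (any(cls == "cancer")) "cancer" else if (any(cls == "benign"))
        "benign" else "healthy"
    }, character(1))
    ord <- pts[order(pt_class, sample.int(length(pts)))]
    fold_of_pt <- stats::setNames(rep(seq_len(spec$n_folds),
                                      length.out = length(ord)), ord)
    lapply(seq_len(spec$n_folds), function(f)
      which(fold_of_pt[feature_table$patient_id] == f))
  }
}

#' Cross-validated tissue classification
#'
#' Runs stratified k-fold cross-validation of the tissue classifier on a
#' milestone feature table. Within every fold, missing-data handling and
#' model fitting see training rows only ([fit_fold()]); test rows with
#' missing downslopes are completed by exponential-tail fits to their own
#' traces ([exp_impute_test()]). Candidate classifiers are selected by
#' inner cross-validation on the training rows. Two-way performance is
#' standard binary AUC-ROC; three-way is macro-averaged one-vs-rest.
#'
#' @param feature_table Feature table from [build_feature_table()].
#' @param spec An [experiment_spec()].
#' @param traces Optional list of raw [fluorescence_trace()] (or a named
#'   list of already-normalized traces via `normalized`), required when
#'   test rows need imputation.
#' @param normalized Optional named list of preprocessed traces keyed by
#'   `trace_id`; computed from `traces` when absent.
#' @param return_details Also return per-fold fits and predictions.
#' @return An object of class `classification_report`: `per_fold_auc`,
#'   `mean_auc`, `classifier_chosen`, `n_rois`, `n_imputed_cells`, `spec`,
#'   and (optionally) `details`.
#' @export
run_cv <- function(feature_table, spec, traces = NULL, normalized = NULL,
                   return_details = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  set.seed(spec$seed)
  feats <- features_for_spec(spec)
  if (spec$imputation_mode == "imputed" && is.null(normalized) &&
      !is.null(traces))
    normalized <- prepare_normalized(traces)
  folds <- make_folds(feature_table, spec)

  per_fold_auc <- numeric(length(folds))
  chosen <- character(length(folds))
  n_imputed <- 0L
  details <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    fold_fit <- fit_fold(feature_table[-test_idx, , drop = FALSE], spec)
    pred <- predict_fold(fold_fit, feature_table[test_idx, , drop = FALSE],
                         normalized)
    dp <- droplevels_probs(pred$y, pred$probs)
    if (length(levels(dp$y)) < 2)
      stop("test fold contains a single class (stratification error)",
           call. = FALSE)
    per_fold_auc[f] <- auc_score(dp$y, dp$probs)
    chosen[f] <- paste0(fold_fit$classifier$name,
                        if (!is.null(fold_fit$classifier$k))
                          paste0("(k=", fold_fit$classifier$k, ")") else "")
    n_imputed <- n_imputed + fold_fit$n_imputed_cells + pred$n_imputed_cells
    if (return_details)
      details[[f]] <- list(fit = fold_fit, prediction = pred,
                           test_idx = test_idx)
  }
  structure(
    list(spec = spec,
         per_fold_auc = per_fold_auc,
         mean_auc = mean(per_fold_auc),
         classifier_chosen = names(sort(table(chosen), decreasing = TRUE))[1],
         per_fold_classifier = chosen,
         n_rois = nrow(feature_table),
         n_imputed_cells = n_imputed,
         details = if (return_details) details else NULL),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s, horizon %d s, %s\n",
              x$spec$split_mode, x$spec$downslope_horizon_added_s,
              x$spec$imputation_mode))
  cat(sprintf("  mean AUC-ROC %.3f (folds: %s)  classifier %s  n=%d  imputed cells %d\n",
              x$mean_auc, paste(sprintf("%.3f", x$per_fold_auc),
                                collapse = ", "),
              x$classifier_chosen, x$n_rois, x$n_imputed_cells))
  invisible(x)
}

#' Prepare smoothed, normalized traces keyed by trace id
#'
#' @param traces List of raw [fluorescence_trace()].
#' @param window_s,polyorder Smoothing parameters.
#' @return Named list of `normalized_trace` objects.
#' @export
prepare_normalized <- function(traces, window_s = 11, polyorder = 3) {
  out <- lapply(traces, preprocess_trace, window_s = window_s,
                polyorder = polyorder)
  stats::setNames(out, vapply(traces, `[[`, character(1), "trace_id"))
}

#' Incremental-downslope feature experiment
#'
#' Re-runs cross-validated classification while cumulatively extending the
#' downslope horizon (50, 100, 200, 300, 400 s added to the base features),
#' under each missing-data policy, to measure the benefit of longer
#' fluorescence tracking on classification performance.
#'
#' @param feature_table Feature table from [build_feature_table()].
#' @param split_mode `"two_way"` or `"three_way"`.
#' @param horizons_s Downslope horizons to add, in seconds.
#' @param imputation_modes Policies to evaluate.
#' @param traces,normalized Traces for test-time imputation, see
#'   [run_cv()].
#' @param seed Seed shared by all runs.
#' @param ... Further arguments to [experiment_spec()].
#' @return A data frame (one row per horizon x policy) with `mean_auc`,
#'   per-fold AUCs collapsed to a string, `n_rois`, `n_imputed_cells`, and
#'   the full reports in attribute `"reports"`.
#' @export
incremental_feature_experiment <- function(feature_table,
                                           split_mode = "two_way",
                                           horizons_s = c(50, 100, 200, 300,
                                                          400),
                                           imputation_modes = c("complete_only",
                                                                "imputed"),
                                           traces = NULL, normalized = NULL,
                                           seed = 1, ...) {
  if (is.null(normalized) && !is.null(traces))
    normalized <- prepare_normalized(traces)
  rows <- list(); reports <- list()
  for (h in horizons_s) for (mode in imputation_modes) {
    spec <- experiment_spec(split_mode = split_mode,
                            downslope_horizon_added_s = h,
                            imputation_mode = mode, seed = seed, ...)
    rep <- run_cv(feature_table, spec, normalized = normalized)
    key <- sprintf("%ds_%s", h, mode)
    reports[[key]] <- rep
    rows[[key]] <- data.frame(
      horizon_s = h, imputation_mode = mode, split_mode = split_mode,
      mean_auc = rep$mean_auc,
      fold_aucs = paste(sprintf("%.3f", rep$per_fold_auc), collapse = ";"),
      classifier = rep$classifier_chosen,
      n_rois = rep$n_rois, n_imputed_cells = rep$n_imputed_cells,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' Truncation-and-impute inference simulation
#'
#' Simulates the extreme inference scenario in which every ROI is tracked
#' for only `keep_post_peak_s` seconds beyond its peak: all downslope
#' milestones beyond that horizon are removed and refilled by
#' exponential-tail fits to each trace's truncated tail, and the
#' cross-validated classification is re-run on the fully imputed table for
#' comparison with the full-data run.
#'
#' @param feature_table Feature table from [build_feature_table()].
#' @param traces Raw traces (or pass `normalized`).
#' @param spec An [experiment_spec()]; both arms use its folds and seed.
#' @param keep_post_peak_s Post-peak seconds of data retained.
#' @param normalized Optional preprocessed traces keyed by id.
#' @return A list of class `truncation_report` with `full` and `truncated`
#'   [run_cv()] reports and `keep_post_peak_s`.
#' @export
truncation_inference_simulation <- function(feature_table, traces = NULL,
                                            spec = experiment_spec(),
                                            keep_post_peak_s = 10,
                                            normalized = NULL) {
  if (is.null(normalized)) {
    if (is.null(traces))
      stop("supply traces or normalized traces", call. = FALSE)
    normalized <- prepare_normalized(traces)
  }
  full <- run_cv(feature_table, spec, normalized = normalized)

  feats <- features_for_spec(spec)
  ds_feats <- grep("^ds[0-9]+$", names(feature_table), value = TRUE)
  horizons <- as.integer(sub("^ds", "", ds_feats))
  beyond <- ds_feats[horizons > keep_post_peak_s]

  trunc_table <- feature_table
  if (length(beyond) > 0) {
    for (r in seq_len(nrow(trunc_table))) {
      id <- trunc_table$trace_id[r]
      nt <- normalized[[id]]
      if (is.null(nt))
        stop(sprintf("trace %s not found among supplied traces", id),
             call. = FALSE)
      peak <- detect_first_peak(nt)
      nt_short <- truncate_trace(nt, peak$time_s + keep_post_peak_s)
      for (col in beyond) trunc_table[r, col] <- NA_real_
      trunc_table[r, ] <- exp_impute_test(
        nt_short, trunc_table[r, ],
        horizons_to_fill = as.integer(sub("^ds", "", beyond)))
      for (col in beyond) {
        prov <- paste0(col, "_provenance")
        if (prov %in% names(trunc_table)) trunc_table[r, prov] <- "imputed"
      }
    }
  }
  spec_trunc <- spec
  spec_trunc$imputation_mode <- "complete_only"  # nothing left missing
  truncated <- run_cv(trunc_table, spec_trunc, normalized = normalized)
  structure(list(full = full, truncated = truncated,
                 keep_post_peak_s = keep_post_peak_s),
            class = "truncation_report")
}

#' @export
print.truncation_report <- function(x, ...) {
  cat(sprintf("<truncation_report> keep %g s post-peak\n", x$keep_post_peak_s))
  cat(sprintf("  full-data mean AUC %.3f  truncated+imputed mean AUC %.3f  (drop %.3f)\n",
              x$full$mean_auc, x$truncated$mean_auc,
              x$full$mean_auc - x$truncated$mean_auc))
  invisible(x)
}
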