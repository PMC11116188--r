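# "Fine tree" classification: a single CART decision tree (Gini impurity,
# at most `max_splits` internal splits) with stratified 5-fold
# cross-validation, plus the confusion-matrix metric suite.

tree_control <- function() {
  # engine defaults for minsplit/minbucket; fine cp so the split budget is
  # set by cost-complexity pruning (below), not by the growing phase
  rpart::rpart.control(minsplit = 20L, minbucket = 7L, cp = 0.001, xval = 5L,
                       maxcompete = 0L, maxsurrogate = 0L, usesurrogate = 0L,
                       maxdepth = 30L)
}

# grow a CART tree, then apply cost-complexity pruning: the smallest subtree
# whose internal cross-validation error is within one standard error of the
# minimum (the classic 1-SE rule), further capped at `max_splits` internal
# nodes. The internal xval folds are seeded, so fits are deterministic.
fit_cart <- function(dat, feature_cols, max_splits, seed = 1L) {
  form <- stats::as.formula(paste("label ~", paste(feature_cols, collapse = " + ")))
  fit <- withr::with_seed(seed,
    rpart::rpart(form, data = dat, method = "class",
                 parms = list(split = "gini"), control = tree_control()))
  cpt <- fit$cptable
  ok <- cpt[cpt[, "nsplit"] <= max_splits, , drop = FALSE]
  if ("xerror" %in% colnames(ok)) {
    imin <- which.min(ok[, "xerror"])
    thr <- ok[imin, "xerror"] + ok[imin, "xstd"]
    sel <- which(ok[, "xerror"] <= thr)[1]
  } else {
    sel <- nrow(ok)
  }
  rpart::prune(fit, cp = ok[sel, "CP"] * 1.000001)
}

n_internal_splits <- function(fit) sum(fit$frame$var != "<leaf>")

# deterministic argmax over class-probability columns: ties go to the lower
# class id (columns are ordered by class id)
prob_to_class <- function(prob, classes) {
  classes[max.col(prob, ties.method = "first")]
}

#' Train a fine decision tree with stratified cross-validation
#'
#' Fits a CART classification tree (Gini impurity) capped at `max_splits`
#' internal splits on the full table, and reports the mean accuracy over
#' `cv_folds` stratified cross-validation folds (each fold's model trained on
#' the remaining folds). Deterministic given `seed`.
#'
#' @param features A labelled `cyto_features` table (see
#'   [build_feature_table()]); rows with `NA` labels are dropped.
#' @param max_splits Maximum number of internal decision nodes.
#' @param cv_folds Number of stratified folds.
#' @param seed Seed controlling fold assignment.
#'
#' @return Object of class `cyto_tree`: the fitted tree, `cv_acc`,
#'   `feature_cols`, `classes`, `max_splits`, `seed` and a
#'   `training_fingerprint` hash of the training table.
#' @export
train_fine_tree <- function(features, max_splits = 100L, cv_folds = 5L,
                            seed = 1L) {
  feature_cols <- attr(features, "feature_cols") %||%
    setdiff(names(features), c("label", "run_id", "event_id", "time_s"))
  dat <- as_tibble(features)[, c(feature_cols, "label")]
  dat <- dat[!is.na(dat$label), ]
  if (!nrow(dat)) abort("no labelled rows to train on.")
  classes <- sort(unique(dat$label))
  if (length(classes) < 2L) abort("training table has a single class.")
  counts <- table(dat$label)
  if (any(counts < cv_folds)) {
    abort(sprintf("every class needs >= %d members for %d-fold CV.",
                  cv_folds, cv_folds))
  }
  dat$label <- factor(dat$label, levels = classes)

  fold <- integer(nrow(dat))
  withr::with_seed(seed, {
    for (cl in classes) {
      idx <- which(dat$label == cl)
      fold[idx] <- sample(rep(seq_len(cv_folds), length.out = length(idx)))
    }
  })
  fit_seeds <- derive_seeds(seed, cv_folds + 1L)
  fold_acc <- vapply(seq_len(cv_folds), function(k) {
    tr <- dat[fold != k, ]; ho <- dat[fold == k, ]
    fit_k <- fit_cart(tr, feature_cols, max_splits, seed = fit_seeds[k])
    prob <- predict(fit_k, ho, type = "prob")
    mean(prob_to_class(prob, as.integer(colnames(prob))) == as.integer(as.character(ho$label)))
  }, numeric(1))

  fit <- fit_cart(dat, feature_cols, max_splits,
                  seed = fit_seeds[cv_folds + 1L])
  structure(list(fit = fit, cv_acc = mean(fold_acc), fold_acc = fold_acc,
                 feature_cols = feature_cols, classes = classes,
                 max_splits = max_splits, cv_folds = cv_folds, seed = seed,
                 n_train = nrow(dat),
                 training_fingerprint = rlang::hash(dat)),
            class = "cyto_tree")
}

#' @export
print.cyto_tree <- function(x, ...) {
  cat(sprintf("<cyto_tree>: %d splits (cap %d), classes %s, n = %d, CV accuracy %.3f\n",
              n_internal_splits(x$fit), x$max_splits,
              paste(x$classes, collapse = "/"), x$n_train, x$cv_acc))
  invisible(x)
}

#' Predict classes and class probabilities
#'
#' @param object A `cyto_tree`.
#' @param newdata Table containing the training feature columns.
#' @param ... Unused.
#' @return Tibble with `pred_class` (integer) and one `prob_<class>` column
#'   per training class (leaf class frequencies, summing to 1). Ties in leaf
#'   probabilities resolve to the lower class id.
#' @export
predict.cyto_tree <- function(object, newdata, ...) {
  missing_f <- setdiff(object$feature_cols, names(newdata))
  if (length(missing_f)) {
    abort(sprintf("newdata lacks feature columns: %s",
                  paste(missing_f, collapse = ", ")))
  }
  prob <- predict(object$fit, as.data.frame(newdata), type = "prob")
  cls <- as.integer(colnames(prob))
  out <- as_tibble(prob, .name_repair = ~ paste0("prob_", cls))
  out$pred_class <- prob_to_class(prob, cls)
  dplyr::relocate(out, "pred_class")
}

#' Confusion matrix and metric suite
#'
#' Counts the K x K confusion matrix (rows = truth, columns = prediction,
#' class order fixed) and derives the per-class one-vs-rest metric suite:
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, fallout `FP/(TN+FP)` and false-negative rate `FN/(TP+FN)`,
#' plus the overall multiclass accuracy (trace over total).
#'
#' @param truth Integer vector of true class ids.
#' @param predicted Integer vector of predicted class ids (same length).
#' @param classes Class id order of the matrix; defaults to the sorted union.
#' @return Object of class `cyto_eval` with `confusion` (integer matrix),
#'   `metrics` (per-class tibble), `accuracy` and `n`. Supports [tidy()] and
#'   [glance()].
#' @export
evaluate_predictions <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted)) abort("length mismatch.")
  if (!length(truth)) abort("empty input.")
  classes <- classes %||% sort(unique(c(truth, predicted)))
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(truth = classes, predicted = classes))
  total <- sum(cm)
  metrics <- purrr::map_dfr(seq_along(classes), function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    tibble(class_id = classes[k], tp = tp, tn = tn, fp = fp, fn = fn,
           acc = (tp + tn) / total,
           tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           tnr = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
           fpr = if (tn + fp > 0) fp / (tn + fp) else NA_real_,
           fnr = if (tp + fn > 0) fn / (tp + fn) else NA_real_)
  })
  structure(list(confusion = cm, metrics = metrics,
                 accuracy = sum(diag(cm)) / total, n = total),
            class = "cyto_eval")
}

#' @export
print.cyto_eval <- function(x, ...) {
  cat(sprintf("<cyto_eval>: accuracy %.3f on %d events\n", x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

# extract + fuse one synthetic run into labelled multimodal rows
pipeline_fuse_run <- function(run, tolerance_s = 0.05, prominence_k = 5) {
  oe <- extract_optical_events(run)
  ee <- detect_peaks(normalize_trace(run$trace), prominence_k = prominence_k)
  fuse_events(oe, ee, truth = run$truth, tolerance_s = tolerance_s,
              run_id = run$run_id)
}

#' Modality comparison experiment
#'
#' Trains and evaluates the fine-tree classifier on electrical-only,
#' optical-only and multimodal feature sets, at a single representative
#' frequency and with all frequencies combined, using pooled training runs
#' and genuinely independent test runs (different seeds, hence different
#' run-level gain drift). Each run goes through the full extraction and
#' fusion pipeline before classification.
#'
#' @param train_runs,test_runs Lists of `cyto_run` objects with distinct
#'   `run_id`s across the two groups.
#' @param single_frequency_hz The representative single frequency.
#' @param tolerance_s Event-matching tolerance.
#' @param max_splits,cv_folds,seed Passed to [train_fine_tree()].
#'
#' @return Tibble of class `cyto_experiment`: one row per mode x frequency
#'   set with train/CV/test accuracies, event counts, and the train and test
#'   `cyto_eval` reports in list-columns.
#' @export
run_comparison_experiment <- function(train_runs, test_runs,
                                      single_frequency_hz = 500e3,
                                      tolerance_s = 0.05,
                                      max_splits = 100L, cv_folds = 5L,
                                      seed = 1L) {
  ids_tr <- vapply(train_runs, function(r) r$run_id, "")
  ids_te <- vapply(test_runs, function(r) r$run_id, "")
  if (length(intersect(ids_tr, ids_te))) {
    abort("train and test runs share run_ids.")
  }
  train_ev <- dplyr::bind_rows(purrr::map(train_runs, pipeline_fuse_run,
                                          tolerance_s = tolerance_s))
  test_ev <- dplyr::bind_rows(purrr::map(test_runs, pipeline_fuse_run,
                                         tolerance_s = tolerance_s))
  all_freqs <- as.numeric(sub("pi_([0-9.]+)kHz", "\\1",
                              grep("^pi_", names(train_ev), value = TRUE))) * 1e3
  grid <- tidyr::expand_grid(
    mode = c("electrical", "optical", "multimodal"),
    frequency_set = c("single", "all"))
  rows <- purrr::pmap(grid, function(mode, frequency_set) {
    freqs <- if (frequency_set == "single") single_frequency_hz else all_freqs
    tr_tab <- build_feature_table(train_ev, mode = mode, frequencies_hz = freqs)
    te_tab <- build_feature_table(test_ev, mode = mode, frequencies_hz = freqs)
    tr_tab <- tr_tab[!is.na(tr_tab$label), ]
    te_tab <- te_tab[!is.na(te_tab$label), ]
    model <- train_fine_tree(tr_tab, max_splits = max_splits,
                             cv_folds = cv_folds, seed = seed)
    ev_train <- evaluate_predictions(tr_tab$label,
                                     predict(model, tr_tab)$pred_class,
                                     classes = model$classes)
    ev_test <- evaluate_predictions(te_tab$label,
                                    predict(model, te_tab)$pred_class,
                                    classes = model$classes)
    tibble(mode = mode, frequency_set = frequency_set,
           n_train = nrow(tr_tab), n_test = nrow(te_tab),
           train_acc = ev_train$accuracy, cv_acc = model$cv_acc,
           test_acc = ev_test$accuracy,
           model = list(model), eval_train = list(ev_train),
           eval_test = list(ev_test))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "manifest") <- list(
    train_run_ids = ids_tr, test_run_ids = ids_te,
    single_frequency_hz = single_frequency_hz, tolerance_s = tolerance_s,
    max_splits = max_splits, cv_folds = cv_folds, seed = seed)
  structure(out, class = c("cyto_experiment", class(tibble())))
}

#' Generate runs and execute the modality comparison end to end
#'
#' Convenience wrapper that simulates independent training and test runs
#' (test size about one third of training, different per-run seeds so the
#' test runs carry their own gain drift) and calls
#' [run_comparison_experiment()]. Fully reproducible from `seed`.
#'
#' @param seed Master seed for run generation, fold assignment and training.
#' @param n_train_per_class Events per class in each training run.
#' @param n_test_per_class Events per class in the test run.
#' @param n_train_runs Number of training runs pooled.
#' @param config,classes,params Shared acquisition configuration, class table
#'   and simulation parameters (per-run seeds are overridden internally).
#' @param ... Passed on to [run_comparison_experiment()].
#' @return A `cyto_experiment` tibble.
#' @export
run_modality_experiment <- function(seed = 1L,
                                    n_train_per_class = 30L,
                                    n_test_per_class = 20L,
                                    n_train_runs = 2L,
                                    config = acquisition_config(),
                                    classes = class_specs(),
                                    params = sim_params(),
                                    ...) {
  seeds <- derive_seeds(seed, n_train_runs + 1L)
  make <- function(run_seed, n_per, id) {
    p <- params
    p$seed <- run_seed
    p$n_events_per_class <- as.integer(n_per)
    generate_run(config, classes, p, run_id = id)
  }
  train_runs <- purrr::map(seq_len(n_train_runs), function(i) {
    make(seeds[i], n_train_per_class, sprintf("train-%d", i))
  })
  test_runs <- list(make(seeds[n_train_runs + 1L], n_test_per_class, "test-1"))
  run_comparison_experiment(train_runs, test_runs, seed = seed, ...)
}
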