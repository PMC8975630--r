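#' Configuration of the hybrid fusion pipeline
#'
#' Collects the tunable parameters of the end-to-end classifier: the base
#' classifier applied to each level-1 branch, its hyperparameters, the
#' feature-extraction settings of the three modalities, and the smoothing
#' of the level-2 weighted naive Bayes.
#'
#' @param base_classifier `"RF"` (random forest), `"SVM"` (RBF
#'   support-vector machine) or `"KNN"` (K-nearest neighbors).
#' @param rf_ntree trees for RF (default 500).
#' @param svm_cost soft-margin cost for SVM (default 1).
#' @param knn_k neighbors for KNN (default 5).
#' @param gaze_K number of areas of interest (default 8; the study grid is
#'   8, 12, 16, 20).
#' @param gaze_n_init K-means restarts per fit (default 10).
#' @param expr_window frames per expression window (default 40).
#' @param eeg_mode `"fixed12"` (the fixed 12-feature panel) or
#'   `"screened"` (t-test screening refit on each training fold).
#' @param eeg_epoch_s,eeg_amp_thresh epoching length (s) and artifact
#'   threshold (amplitude units) of the EEG pathway.
#' @param alpha screening threshold for `eeg_mode = "screened"`.
#' @param smoothing Laplace smoothing of the level-2 [wnb()] (default 1).
#' @param seed integer seed governing every stochastic step (K-means
#'   restarts, RF bootstrap); fixed seed gives an identical report.
#' @return An object of class `"fusion_config"`.
#' @export
fusion_config <- function(base_classifier = c("RF", "SVM", "KNN"),
                          rf_ntree = 500L, svm_cost = 1, knn_k = 5L,
                          gaze_K = 8L, gaze_n_init = 10L,
                          expr_window = 40L,
                          eeg_mode = c("fixed12", "screened"),
                          eeg_epoch_s = 2, eeg_amp_thresh = 100,
                          alpha = 0.05, smoothing = 1, seed = 1L) {
  base_classifier <- match.arg(base_classifier)
  eeg_mode <- match.arg(eeg_mode)
  check_that(is_count(rf_ntree), "rf_ntree", "must be a positive integer")
  check_that(svm_cost > 0, "svm_cost", "must be positive")
  check_that(is_count(knn_k), "knn_k", "must be a positive integer")
  check_that(is_count(gaze_K), "gaze_K", "must be a positive integer")
  check_that(is_count(expr_window), "expr_window",
             "must be a positive integer")
  structure(list(base_classifier = base_classifier, rf_ntree = rf_ntree,
                 svm_cost = svm_cost, knn_k = knn_k, gaze_K = gaze_K,
                 gaze_n_init = gaze_n_init, expr_window = expr_window,
                 eeg_mode = eeg_mode, eeg_epoch_s = eeg_epoch_s,
                 eeg_amp_thresh = eeg_amp_thresh, alpha = alpha,
                 smoothing = smoothing, seed = seed),
            class = "fusion_config")
}

#' @export
print.fusion_config <- function(x, ...) {
  cat(sprintf("Fusion config: %s base classifier, K = %d AOIs, %d-frame windows, EEG mode %s, seed %d\n",
              x$base_classifier, x$gaze_K, x$expr_window, x$eeg_mode,
              x$seed))
  invisible(x)
}

# z-score columns by training statistics (zero-variance columns untouched)
standardize_by_train <- function(x, train_idx) {
  xt <- x[train_idx, , drop = FALSE]
  n <- nrow(xt)
  mu <- colMeans(xt)
  sdv <- sqrt(pmax(colSums(xt * xt) - n * mu * mu, 0) / (n - 1))
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  t((t(x) - mu) / sdv)
}

# Train the configured base classifier on train rows, predict for test rows.
# Features are standardized with training-fold statistics.
base_classify <- function(x, y, train_idx, test_idx, config, seed) {
  xs <- standardize_by_train(x, train_idx)
  xtr <- xs[train_idx, , drop = FALSE]
  xte <- xs[test_idx, , drop = FALSE]
  ytr <- droplevels(factor(y[train_idx], levels = levels(factor(y))))
  if (nlevels(ytr) < 2L)
    stop("training fold contains a single class", call. = FALSE)
  pred <- switch(config$base_classifier,
    RF = with_seed(seed, {
      fit <- randomForest::randomForest(x = xtr, y = ytr,
                                        ntree = config$rf_ntree)
      stats::predict(fit, xte)
    }),
    SVM = {
      fit <- e1071::svm(x = xtr, y = ytr, kernel = "radial",
                        cost = config$svm_cost, scale = FALSE)
      stats::predict(fit, xte)
    },
    KNN = with_seed(seed, {
      class::knn(train = xtr, test = xte, cl = ytr, k = config$knn_k)
    }))
  factor(as.character(pred), levels = levels(factor(y)))
}

# Subdecisions for training rows by an inner leave-one-out (each training
# subject predicted by a classifier fit on the other training subjects)
# plus subdecisions for the test rows from the full-training-fold fit.
inner_loo_subdecisions <- function(x, y, train_idx, test_idx, config, seed) {
  d_train <- factor(rep(NA_character_, length(train_idx)),
                    levels = levels(factor(y)))
  for (j in seq_along(train_idx)) {
    d_train[j] <- base_classify(x, y, train_idx[-j], train_idx[j],
                                config, child_seed(seed, j))
  }
  d_test <- base_classify(x, y, train_idx, test_idx, config,
                          child_seed(seed, 0L))
  list(train = d_train, test = d_test)
}

#' Level-1 branch classification
#'
#' `level1_behavioral` concatenates the facial-expression and eye-fixation
#' feature blocks into one behavioral feature vector per subject and trains
#' the configured base classifier; `level1_physiological` does the same on
#' the EEG feature block alone. Both return categorical subdecisions
#' (ASD/TD) for the requested subjects. When `train` is given, the
#' classifier is fit on those subjects only and the rest are predicted
#' out-of-sample; by default it is fit (and evaluated) on all subjects.
#'
#' @param expr_feat,gaze_feat,eeg_feat numeric feature matrices with one
#'   row per subject (aligned row names).
#' @param labels named diagnosis labels (`"ASD"`/`"TD"`).
#' @param config a [fusion_config()].
#' @param train subject names (or indices) to train on; default all.
#' @return Factor of subdecisions, one per subject (named).
#' @export
level1_behavioral <- function(expr_feat, gaze_feat, labels,
                              config = fusion_config(), train = NULL) {
  if (!identical(rownames(expr_feat), rownames(gaze_feat))) {
    off <- union(setdiff(rownames(expr_feat), rownames(gaze_feat)),
                 setdiff(rownames(gaze_feat), rownames(expr_feat)))
    stop("expression and gaze features are misaligned; offending subject(s): ",
         paste(if (length(off)) off else "(row order differs)",
               collapse = ", "), call. = FALSE)
  }
  level1_branch(cbind(expr_feat, gaze_feat), labels, config, train)
}

#' @rdname level1_behavioral
#' @export
level1_physiological <- function(eeg_feat, labels,
                                 config = fusion_config(), train = NULL) {
  level1_branch(eeg_feat, labels, config, train)
}

level1_branch <- function(x, labels, config, train) {
  stopifnot(!is.null(rownames(x)))
  off <- setdiff(rownames(x), names(labels))
  if (length(off))
    stop("no label for subject(s): ", paste(off, collapse = ", "),
         call. = FALSE)
  y <- factor(labels[rownames(x)], levels = intersect(CLASSES, labels))
  idx <- seq_len(nrow(x))
  train_idx <- if (is.null(train)) idx else
    if (is.numeric(train)) as.integer(train) else match(train, rownames(x))
  pred <- base_classify(x, y, train_idx, idx, config,
                        child_seed(config$seed, 1L))
  stats::setNames(pred, rownames(x))
}

#' Level-2 decision fusion by weighted naive Bayes
#'
#' Fuses the physiological and behavioral subdecisions into a final
#' decision: a two-attribute decision table is built from the training
#' subdecisions and labels, a [wnb()] model is fit on it, and the final
#' class of each queried subject is the weighted-posterior argmax over its
#' subdecision pair.
#'
#' @param d1,d2 factors of physiological and behavioral subdecisions for
#'   the training subjects.
#' @param labels true classes of the training subjects.
#' @param query_d1,query_d2 subdecisions of the subjects to classify
#'   (default: the training subjects themselves).
#' @param smoothing Laplace smoothing for the [wnb()] fit.
#' @return List with `decisions` (factor of fused classes for the queried
#'   subjects) and `model` (the fitted `"wnb"`).
#' @export
level2_fuse <- function(d1, d2, labels, query_d1 = d1, query_d2 = d2,
                        smoothing = 1) {
  stopifnot(length(d1) == length(labels), length(d2) == length(labels))
  table <- data.frame(d1 = as.character(d1), d2 = as.character(d2))
  model <- wnb(table, labels, smoothing = smoothing)
  query <- data.frame(d1 = as.character(query_d1),
                      d2 = as.character(query_d2))
  list(decisions = predict(model, query), model = model)
}

#' Column-normalized confusion matrix and confusion-graph edges
#'
#' Builds the 2x2 confusion matrix in percent of the *target* class:
#' element (i, j) is the percentage of samples of true class j predicted
#' as class i, so every column sums to 100. The off-diagonal entries are
#' the confusion-graph edge weights (percentage of one class predicted as
#' the other).
#'
#' @param predictions predicted classes.
#' @param labels true classes, aligned with `predictions`.
#' @return An object of class `"confusion_report"`: list with `matrix`
#'   (2x2 percent, columns = target class), `counts` (raw 2x2 table),
#'   `accuracy` (percent correct), and `edges` (named vector of
#'   off-diagonal percentages, e.g. `"ASD->TD"`).
#' @export
confusion_report <- function(predictions, labels) {
  if (length(predictions) == 0L)
    stop("no predictions supplied", call. = FALSE)
  stopifnot(length(predictions) == length(labels))
  lev <- intersect(CLASSES, unique(c(as.character(labels),
                                     as.character(predictions))))
  pred <- factor(as.character(predictions), levels = lev)
  truth <- factor(as.character(labels), levels = lev)
  counts <- table(predicted = pred, target = truth)
  pct <- sweep(counts, 2, pmax(colSums(counts), 1L), "/") * 100
  edges <- c()
  for (j in lev) for (i in setdiff(lev, j))
    edges[paste0(j, "->", i)] <- pct[i, j]
  structure(list(matrix = unclass(pct), counts = unclass(counts),
                 accuracy = 100 * mean(pred == truth), edges = edges),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("Accuracy: %.2f%%\n", x$accuracy))
  cat("Confusion matrix (% of target class; columns sum to 100):\n")
  print(round(x$matrix, 2))
  invisible(x)
}

#' Confusion-graph edge table across modalities
#'
#' Combines several [confusion_report()]s (one per modality or fusion
#' variant) into a long table of directed misclassification edges, the
#' tabular form of the confusion graph used to compare the complementary
#' strengths of modalities.
#'
#' @param reports named list of `"confusion_report"` objects.
#' @return data.frame with columns `modality`, `from`, `to`, `percent`.
#' @export
confusion_graph <- function(reports) {
  stopifnot(is.list(reports), length(reports) >= 1L,
            !is.null(names(reports)))
  do.call(rbind, lapply(names(reports), function(nm) {
    e <- reports[[nm]]$edges
    data.frame(modality = nm,
               from = sub("->.*$", "", names(e)),
               to = sub("^.*->", "", names(e)),
               percent = as.numeric(e))
  }))
}

#' Leave-one-out evaluation of the fusion pipeline
#'
#' Runs n-fold leave-one-out cross-validation of the configured pipeline
#' on a synthetic (or assembled) cohort. In every fold the held-out
#' subject is excluded from *all* fitting: the AOI K-means is refit on the
#' training subjects' pooled fixations (the held-out subject is projected
#' onto the trained centers), EEG screening (in `"screened"` mode) is
#' refit on training subjects, base classifiers are trained on the
#' training fold, and — for the hybrid pipeline — the level-2 weighted
#' naive Bayes is fit on a decision table whose training subdecisions come
#' from an inner leave-one-out over the training fold (avoiding the
#' optimistic resubstitution subdecisions that would make the learned
#' weights degenerate).
#'
#' @param cohort a [generate_cohort()] cohort (or a list with the same
#'   structure).
#' @param config a [fusion_config()].
#' @param modality `"hybrid"` (the full two-level pipeline) or a single
#'   branch: `"eeg"` (physiological), `"behavioral"` (expression + gaze
#'   feature fusion), `"gaze"`, `"expression"`.
#' @return An object of class `"fusion_eval"`: list with `predictions`
#'   (data.frame: subject, truth, predicted and, for hybrid, the branch
#'   subdecisions d1, d2), `accuracy` (percent), `confusion`
#'   (a [confusion_report()]), `branch_accuracy` (hybrid only), `modality`,
#'   `config`.
#' @export
fusion_loocv <- function(cohort, config = fusion_config(),
                         modality = c("hybrid", "eeg", "behavioral",
                                      "gaze", "expression")) {
  modality <- match.arg(modality)
  labels <- cohort_labels(cohort)
  n <- length(labels)
  if (n < 2L) stop("need at least two subjects", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  y <- factor(labels, levels = intersect(CLASSES, labels))
  ids <- names(labels)

  fixations <- cohort_fixations(cohort)
  spec <- cohort$spec
  need_expr <- modality %in% c("hybrid", "behavioral", "expression")
  need_gaze <- modality %in% c("hybrid", "behavioral", "gaze")
  need_eeg <- modality %in% c("hybrid", "eeg")
  expr_feat <- if (need_expr)
    expr_features(cohort_expressions(cohort), target = spec$target_label,
                  window = config$expr_window)
  powers <- if (need_eeg)
    lapply(cohort_eeg(cohort), region_band_features,
           epoch_s = config$eeg_epoch_s,
           amp_thresh = config$eeg_amp_thresh)

  pred <- factor(rep(NA_character_, n), levels = levels(y))
  d1_all <- d2_all <- pred
  for (i in seq_len(n)) {
    train_idx <- setdiff(seq_len(n), i)
    fold_seed <- child_seed(config$seed, i)
    gaze_feat <- if (need_gaze)
      gaze_features(fixations, K = config$gaze_K,
                    seed = child_seed(fold_seed, 1L),
                    train = ids[train_idx])$features
    eeg_feat <- if (need_eeg) {
      if (config$eeg_mode == "screened")
        eeg_features(powers, mode = "screened",
                     labels = stats::setNames(labels, ids)[train_idx],
                     train = ids[train_idx],
                     alpha = config$alpha)$features
      else eeg_features(powers, mode = "fixed12")$features
    }
    if (modality == "hybrid") {
      behav <- cbind(expr_feat, gaze_feat)
      b1 <- inner_loo_subdecisions(eeg_feat, y, train_idx, i, config,
                                   child_seed(fold_seed, 2L))
      b2 <- inner_loo_subdecisions(behav, y, train_idx, i, config,
                                   child_seed(fold_seed, 3L))
      fused <- level2_fuse(b1$train, b2$train, y[train_idx],
                           query_d1 = b1$test, query_d2 = b2$test,
                           smoothing = config$smoothing)
      pred[i] <- fused$decisions
      d1_all[i] <- b1$test
      d2_all[i] <- b2$test
    } else {
      x <- switch(modality,
                  eeg = eeg_feat,
                  behavioral = cbind(expr_feat, gaze_feat),
                  gaze = gaze_feat,
                  expression = expr_feat)
      pred[i] <- base_classify(x, y, train_idx, i, config,
                               child_seed(fold_seed, 2L))
    }
  }

  predictions <- data.frame(subject = ids, truth = as.character(y),
                            predicted = as.character(pred))
  out <- list(predictions = predictions,
              accuracy = 100 * mean(pred == y),
              confusion = confusion_report(pred, y),
              modality = modality, config = config)
  if (modality == "hybrid") {
    predictions$d1 <- as.character(d1_all)
    predictions$d2 <- as.character(d2_all)
    out$predictions <- predictions
    out$branch_accuracy <- c(physiological = 100 * mean(d1_all == y),
                             behavioral = 100 * mean(d2_all == y))
  }
  structure(out, class = "fusion_eval")
}

#' @export
print.fusion_eval <- function(x, ...) {
  cat(sprintf("Leave-one-out evaluation (%s, %s base classifier)\n",
              x$modality, x$config$base_classifier))
  cat(sprintf("  %d held-out predictions; accuracy %.2f%%\n",
              nrow(x$predictions), x$accuracy))
  if (!is.null(x$branch_accuracy))
    cat(sprintf("  branch accuracies: physiological %.2f%%, behavioral %.2f%%\n",
                x$branch_accuracy[["physiological"]],
                x$branch_accuracy[["behavioral"]]))
  print(x$confusion)
  invisible(x)
}

#' @export
summary.fusion_eval <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.fusion_eval <- function(x, ...) {
  m <- x$confusion$matrix
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ]),
                  col = grDevices::hcl.colors(32, "Blues", rev = TRUE),
                  axes = FALSE, xlab = "Target class", ylab = "Predicted class",
                  main = sprintf("%s: %.2f%%", x$modality, x$accuracy), ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m))
  graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    graphics::text(j, nrow(m) - i + 1, sprintf("%.1f%%", m[i, j]))
  invisible(x)
}
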