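CLASSIFIERS <- c("decision_tree", "bagged_trees", "fine_knn", "linear_svm",
                 "linear_discriminant", "kernel_naive_bayes")

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Seizure is the positive class: sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, accuracy `(TP+TN)/(TP+TN+FP+FN)`. A metric whose class is
#' absent from the counts is `NA` (flagged with a warning).
#'
#' @param counts a list/one-row data frame with `TP`, `TN`, `FP`, `FN`, or
#'   the `TP` value when the four counts are given positionally.
#' @param TN,FP,FN counts when given positionally.
#' @return A one-row tibble with `sensitivity`, `specificity`, `accuracy`.
#' @export
#' @examples
#' compute_metrics(list(TP = 90, TN = 95, FP = 5, FN = 10))
compute_metrics <- function(counts, TN = NULL, FP = NULL, FN = NULL) {
  if (is.numeric(counts) && length(counts) == 1L && !is.null(TN)) {
    counts <- list(TP = counts, TN = TN, FP = FP, FN = FN)
  }
  cc <- lapply(counts[c("TP", "TN", "FP", "FN")], as.numeric)
  if (any(vapply(cc, function(v) length(v) != 1 || is.na(v) || v < 0, TRUE))) {
    abort("Confusion counts TP, TN, FP, FN must be nonnegative scalars.")
  }
  sens <- if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else NA_real_
  spec <- if (cc$TN + cc$FP > 0) cc$TN / (cc$TN + cc$FP) else NA_real_
  total <- cc$TP + cc$TN + cc$FP + cc$FN
  acc <- if (total > 0) (cc$TP + cc$TN) / total else NA_real_
  if (is.na(sens) || is.na(spec)) {
    warn("compute_metrics: one class is empty; its metric is NA.")
  }
  tibble(sensitivity = sens, specificity = spec, accuracy = acc)
}

confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  tibble(
    TP = sum(truth == 1 & pred == 1), TN = sum(truth == 0 & pred == 0),
    FP = sum(truth == 0 & pred == 1), FN = sum(truth == 1 & pred == 0)
  )
}

feature_matrix <- function(table) {
  fcols <- grep("^f_\\d+$", names(table), value = TRUE)
  as.matrix(table[, fcols, drop = FALSE])
}

# ---- classifier registry ----------------------------------------------------

fit_classifier <- function(name, X, y, seed) {
  y <- factor(y, levels = c(0, 1))
  withr::with_seed(seed, switch(
    name,
    decision_tree = {
      df <- data.frame(X, .label = y)
      rpart::rpart(.label ~ ., data = df, method = "class")
    },
    bagged_trees = randomForest::randomForest(
      x = X, y = y, mtry = ncol(X), ntree = 100
    ),
    fine_knn = list(X = X, y = y),
    linear_svm = e1071::svm(
      x = X, y = y, kernel = "linear", cost = 1, type = "C-classification"
    ),
    linear_discriminant = {
      keep <- apply(X, 2, function(v) stats::sd(v) > 1e-12)
      list(keep = keep, fit = MASS::lda(X[, keep, drop = FALSE], grouping = y))
    },
    kernel_naive_bayes = fit_kernel_nb(X, y),
    abort(paste0("Unknown classifier: ", name, ". Choose one of: ",
                 paste(CLASSIFIERS, collapse = ", ")))
  ))
}

predict_classifier <- function(name, fit, X) {
  pred <- switch(
    name,
    decision_tree = {
      cls <- stats::predict(fit, newdata = data.frame(X), type = "class")
      as.integer(as.character(cls))
    },
    bagged_trees = as.integer(as.character(stats::predict(fit, X))),
    fine_knn = as.integer(as.character(
      class::knn(fit$X, X, fit$y, k = 1)
    )),
    linear_svm = as.integer(as.character(stats::predict(fit, X))),
    linear_discriminant = as.integer(as.character(
      stats::predict(fit$fit, X[, fit$keep, drop = FALSE])$class
    )),
    kernel_naive_bayes = predict_kernel_nb(fit, X)
  )
  pred
}

# Gaussian-kernel-density naive Bayes: per class and feature, the class-
# conditional density is a KDE over the training values (Silverman
# bandwidth); prediction maximizes log prior + summed log densities.
fit_kernel_nb <- function(X, y) {
  classes <- levels(y)
  models <- lapply(classes, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    lapply(seq_len(ncol(X)), function(j) {
      v <- Xc[, j]
      bw <- stats::bw.nrd0(v)
      if (!is.finite(bw) || bw <= 0) bw <- max(stats::sd(v), 1e-6)
      list(x = v, bw = bw)
    })
  })
  names(models) <- classes
  list(models = models, prior = table(y) / length(y), classes = classes)
}

predict_kernel_nb <- function(fit, X) {
  logpost <- vapply(fit$classes, function(cl) {
    ll <- log(as.numeric(fit$prior[cl]))
    for (j in seq_len(ncol(X))) {
      kd <- fit$models[[cl]][[j]]
      # mean of N(x; x_i, bw) over training points, evaluated per query row
      dens <- vapply(X[, j], function(q) {
        mean(stats::dnorm(q, mean = kd$x, sd = kd$bw))
      }, numeric(1))
      ll <- ll + log(pmax(dens, 1e-300))
    }
    ll
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) logpost <- matrix(logpost, nrow = 1)
  as.integer(fit$classes[max.col(logpost, ties.method = "first")])
}

# ---- cross-validation -------------------------------------------------------

#' k-fold cross-validation of an epoch classifier
#'
#' Rows are shuffled with the given seed and split into `k` equal folds;
#' each fold is held out once, the classifier is trained on the rest, and
#' the report averages the per-fold sensitivity, specificity and accuracy.
#' Fold assignment depends only on the seed and the row count, so a rerun
#' with the same seed is identical.
#'
#' Note that with half-overlapping epochs, adjacent rows share samples, so
#' epoch-level shuffling lets near-duplicates cross the train/test boundary;
#' `group_by` (e.g. `"recording_id"`) switches to leakage-safe grouped folds.
#'
#' @param table feature table from [extract_features()].
#' @param classifier one of `decision_tree`, `bagged_trees`, `fine_knn`,
#'   `linear_svm`, `linear_discriminant`, `kernel_naive_bayes`.
#' @param k number of folds (default 10).
#' @param seed RNG seed controlling the shuffle and any classifier
#'   randomness.
#' @param group_by optional column name; folds then partition groups, not
#'   rows.
#' @return A `cv_report`: list with `classifier`, `k`, `seed`, per-fold
#'   tibble `folds`, and a one-row `summary` tibble of mean metrics.
#' @export
cross_validate <- function(table, classifier = "decision_tree", k = 10,
                           seed = 20240316, group_by = NULL) {
  classifier <- match.arg(classifier, CLASSIFIERS)
  if (!all(table$label %in% c(0L, 1L))) abort("Labels must be 0/1.")
  if (length(unique(table$label)) < 2L) {
    abort("Cross-validation needs both classes present.")
  }
  n <- nrow(table)
  if (n < k) abort("Fewer rows than folds.")

  if (is.null(group_by)) {
    fold_of <- withr::with_seed(seed, {
      perm <- sample.int(n)
      fold <- integer(n)
      fold[perm] <- rep(seq_len(k), length.out = n)
      fold
    })
  } else {
    groups <- table[[group_by]]
    ug <- unique(groups)
    if (length(ug) < k) abort("Fewer groups than folds.")
    gfold <- withr::with_seed(seed, {
      perm <- sample(length(ug))
      gf <- integer(length(ug)); gf[perm] <- rep(seq_len(k), length.out = length(ug))
      gf
    })
    fold_of <- gfold[match(groups, ug)]
  }

  X <- feature_matrix(table)
  y <- table$label
  folds <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- fold_of != f
    fit <- fit_classifier(classifier, X[tr, , drop = FALSE], y[tr],
                          seed = seed + f)
    pred <- predict_classifier(classifier, fit, X[!tr, , drop = FALSE])
    cc <- confusion_counts(y[!tr], pred)
    dplyr::bind_cols(tibble(fold = f), cc,
                     suppressWarnings(compute_metrics(cc)))
  })
  summary <- tibble(
    classifier = classifier, k = k, seed = seed,
    sensitivity = mean(folds$sensitivity, na.rm = TRUE),
    specificity = mean(folds$specificity, na.rm = TRUE),
    accuracy = mean(folds$accuracy, na.rm = TRUE)
  )
  structure(
    list(classifier = classifier, k = k, seed = seed, folds = folds,
         summary = summary),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %s, %d-fold (seed %d)\n  sensitivity %.3f | specificity %.3f | accuracy %.3f\n",
    x$classifier, x$k, x$seed,
    x$summary$sensitivity, x$summary$specificity, x$summary$accuracy
  ))
  invisible(x)
}

#' @describeIn cross_validate per-fold confusion counts and metrics.
#' @param x a `cv_report`.
#' @param ... unused.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$folds

#' @describeIn cross_validate one-row summary of mean metrics.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) x$summary

#' Train a final classifier on a full feature table
#'
#' @inheritParams cross_validate
#' @return A `seizure_classifier`: the fitted model plus the feature width,
#'   order and a hash of the training configuration. Use
#'   [save_classifier()] / [load_classifier()] for persistence and
#'   `predict()` for 0/1 epoch predictions.
#' @export
train_final <- function(table, classifier = "decision_tree", seed = 20240316) {
  classifier <- match.arg(classifier, CLASSIFIERS)
  if (length(unique(table$label)) < 2L) abort("Training needs both classes.")
  X <- feature_matrix(table)
  fit <- fit_classifier(classifier, X, table$label, seed = seed)
  structure(
    list(
      classifier = classifier, fit = fit, m = unique(table$m),
      n_features = ncol(X), seed = seed,
      config_hash = rlang::hash(list(classifier, unique(table$m), ncol(X), seed))
    ),
    class = "seizure_classifier"
  )
}

#' @export
predict.seizure_classifier <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) feature_matrix(newdata) else as.matrix(newdata)
  if (ncol(X) != object$n_features) {
    abort(sprintf("Feature width %d does not match the trained width %d.",
                  ncol(X), object$n_features))
  }
  predict_classifier(object$classifier, object$fit, X)
}

#' @rdname train_final
#' @param object a `seizure_classifier`.
#' @param path file path for the persisted model.
#' @export
save_classifier <- function(object, path) {
  stopifnot(inherits(object, "seizure_classifier"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname train_final
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "seizure_classifier")) abort("Not a persisted classifier.")
  obj
}

#' @export
print.seizure_classifier <- function(x, ...) {
  cat(sprintf("<seizure_classifier> %s | order %s | %d features | config %s\n",
              x$classifier, paste(x$m, collapse = ","), x$n_features,
              substr(x$config_hash, 1, 8)))
  invisible(x)
}
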