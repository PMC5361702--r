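#' Recursive feature elimination for biomarker selection
#'
#' Outer loop over candidate subset sizes (largest first): features are
#' ranked by the estimator's importance on the full training data
#' (random forest: mean decrease in node impurity; linear-kernel SVM:
#' absolute hyperplane weight), the lowest-ranked features are eliminated
#' down to each candidate size, and each size is scored by seeded
#' stratified k-fold cross-validated ROC AUC. The best size is the maximum
#' mean score, ties resolved toward the smaller subset; the final model is
#' refit on all training samples with the selected features.
#'
#' @param pt A complete [peak_table()].
#' @param meta [sample_meta()] with exactly two experimental classes (QCs
#'   are excluded automatically).
#' @param estimator `"rf"` (random forest, 500 trees) or `"svm"` (linear
#'   kernel).
#' @param cv_folds Cross-validation folds. Default 5.
#' @param sizes Candidate subset sizes; default halves the feature count
#'   down to 1 (p, p/2, p/4, ..., 1).
#' @param seed Integer seed controlling fold splits and forests.
#' @return An `rfe_result`: `profile` (tibble size/cv_auc), `selected_features`,
#'   `best_size`, `estimator`, and the refitted `model`.
#' @export
rfe_select <- function(pt, meta, estimator = c("rf", "svm"), cv_folds = 5,
                       sizes = NULL, seed = 1L) {
  estimator <- match.arg(estimator)
  d <- xy_for_groups(pt, meta)
  x <- d$x
  y <- factor(ifelse(d$y > 0, d$case, d$control),
              levels = c(d$control, d$case))
  p <- ncol(x)
  if (is.null(sizes)) {
    sizes <- p
    while (sizes[length(sizes)] > 1) {
      sizes <- c(sizes, max(1, floor(sizes[length(sizes)] / 2)))
    }
  }
  sizes <- sort(unique(as.integer(sizes)), decreasing = TRUE)
  if (any(sizes < 1) || any(sizes > p)) {
    stop("`sizes` must lie in [1, feature count]", call. = FALSE)
  }
  if (min(table(y)) < cv_folds) {
    stop("a cross-validation fold would miss a class; use fewer folds",
         call. = FALSE)
  }
  # Elimination schedule from the full-data ranking (computed once per
  # size from the surviving feature set, per standard backward RFE).
  surviving <- colnames(x)
  ranked_sets <- list()
  for (s in sizes) {
    if (length(surviving) > s) {
      imp <- feature_importance(x[, surviving, drop = FALSE], y, estimator,
                                seed)
      surviving <- names(sort(imp, decreasing = TRUE))[seq_len(s)]
    }
    ranked_sets[[as.character(s)]] <- surviving
  }
  fold <- stratified_folds(as.character(y), cv_folds, seed)
  profile <- purrr::map_dfr(sizes, function(s) {
    feats <- ranked_sets[[as.character(s)]]
    aucs <- vapply(seq_len(cv_folds), function(f) {
      tr <- fold != f; te <- fold == f
      sc <- fit_and_score(x[tr, feats, drop = FALSE], y[tr],
                          x[te, feats, drop = FALSE], estimator, seed)
      univariate_auc(sc[y[te] == levels(y)[2]], sc[y[te] == levels(y)[1]])
    }, numeric(1))
    tibble::tibble(size = s, cv_auc = mean(aucs))
  })
  best <- profile$size[profile$cv_auc >= max(profile$cv_auc) - 1e-12]
  best_size <- min(best)  # ties toward the smaller subset
  feats <- ranked_sets[[as.character(best_size)]]
  set.seed(seed)
  model <- fit_estimator(x[, feats, drop = FALSE], y, estimator)
  structure(list(profile = dplyr::arrange(profile, .data$size),
                 selected_features = feats, best_size = best_size,
                 estimator = estimator, model = model,
                 classes = levels(y), case = d$case, control = d$control),
            class = "rfe_result")
}

feature_importance <- function(x, y, estimator, seed) {
  set.seed(seed)
  if (estimator == "rf") {
    fit <- randomForest::randomForest(x = x, y = y, ntree = 500,
                                      importance = FALSE)
    imp <- fit$importance[, "MeanDecreaseGini"]
  } else {
    fit <- e1071::svm(x = x, y = y, kernel = "linear", scale = TRUE)
    w <- t(fit$coefs) %*% fit$SV
    imp <- stats::setNames(abs(as.numeric(w)), colnames(fit$SV))
    imp <- imp[colnames(x)]
  }
  imp
}

fit_estimator <- function(x, y, estimator) {
  if (estimator == "rf") {
    randomForest::randomForest(x = x, y = y, ntree = 500)
  } else {
    e1071::svm(x = x, y = y, kernel = "linear", probability = TRUE,
               scale = TRUE)
  }
}

# Fit on (xtr, ytr), return a case-class score for each row of xte.
fit_and_score <- function(xtr, ytr, xte, estimator, seed) {
  set.seed(seed)
  fit <- fit_estimator(xtr, ytr, estimator)
  case_level <- levels(ytr)[2]
  if (estimator == "rf") {
    stats::predict(fit, xte, type = "prob")[, case_level]
  } else {
    pr <- stats::predict(fit, xte, probability = TRUE)
    attr(pr, "probabilities")[, case_level]
  }
}

#' @export
print.rfe_result <- function(x, ...) {
  cat("<rfe_result> ", x$estimator, ": best size ", x$best_size,
      " (CV AUC ", round(max(x$profile$cv_auc), 3), ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.rfe_result <- function(x, ...) x$profile

#' @export
glance.rfe_result <- function(x, ...) {
  tibble::tibble(estimator = x$estimator, best_size = x$best_size,
                 best_cv_auc = max(x$profile$cv_auc),
                 n_sizes_tried = nrow(x$profile))
}

#' Held-out evaluation of a feature panel
#'
#' Fits the estimator on a training split with the given features and
#' scores the held-out samples, returning the ROC curve (one point per
#' score threshold, from (0,0) to (1,1)) and the pair-counting AUROC.
#'
#' @param pt A complete [peak_table()].
#' @param meta [sample_meta()] with two experimental classes.
#' @param features Feature ids to use.
#' @param estimator `"rf"` or `"svm"`.
#' @param train_frac Fraction of each class assigned to training when
#'   explicit lists are not given. Default 0.5.
#' @param train_samples,test_samples Optional explicit sample-id lists
#'   (override `train_frac`), e.g. to mirror a published split.
#' @param seed Seed for the random split and the estimator.
#' @return An `evaluation_result`: `roc` (tibble fpr/tpr), `auroc`,
#'   `scores` (per test sample), `train_samples`, `test_samples`.
#' @export
evaluate_model <- function(pt, meta, features, estimator = c("rf", "svm"),
                           train_frac = 0.5, train_samples = NULL,
                           test_samples = NULL, seed = 1L) {
  estimator <- match.arg(estimator)
  miss <- setdiff(features, feature_ids(pt))
  if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  d <- xy_for_groups(pt, meta)
  x <- d$x[, features, drop = FALSE]
  y <- factor(ifelse(d$y > 0, d$case, d$control),
              levels = c(d$control, d$case))
  ids <- rownames(x)
  if (is.null(train_samples)) {
    set.seed(seed)
    tr_idx <- unlist(lapply(levels(y), function(g) {
      cand <- which(y == g)
      sample(cand, max(1, round(train_frac * length(cand))))
    }))
    train_samples <- ids[sort(tr_idx)]
    test_samples <- setdiff(ids, train_samples)
  } else if (is.null(test_samples)) {
    test_samples <- setdiff(ids, train_samples)
  }
  tr <- ids %in% train_samples
  te <- ids %in% test_samples
  if (length(unique(y[te])) < 2) {
    stop("test split contains a single class", call. = FALSE)
  }
  if (length(unique(y[tr])) < 2) {
    stop("training split contains a single class", call. = FALSE)
  }
  sc <- fit_and_score(x[tr, , drop = FALSE], y[tr], x[te, , drop = FALSE],
                      estimator, seed)
  is_case <- y[te] == d$case
  structure(list(
    roc = roc_points(sc, is_case),
    auroc = univariate_auc(sc[is_case], sc[!is_case]),
    scores = tibble::tibble(sample = ids[te], score = as.numeric(sc),
                            group = as.character(y[te])),
    train_samples = ids[tr], test_samples = ids[te],
    estimator = estimator, features = features
  ), class = "evaluation_result")
}

# ROC curve by threshold sweep; ties handled by grouping equal scores.
roc_points <- function(scores, is_case) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; pos <- is_case[ord]
  uniq <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(pos)[uniq]; fp <- cumsum(!pos)[uniq]
  tibble::tibble(fpr = c(0, fp / sum(!is_case), 1),
                 tpr = c(0, tp / sum(is_case), 1))
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result> ", x$estimator, " on ", length(x$features),
      " feature(s): AUROC = ", round(x$auroc, 3), " (",
      length(x$test_samples), " test samples)\n", sep = "")
  invisible(x)
}

#' @export
tidy.evaluation_result <- function(x, ...) x$roc

#' @export
glance.evaluation_result <- function(x, ...) {
  tibble::tibble(estimator = x$estimator, n_features = length(x$features),
                 n_train = length(x$train_samples),
                 n_test = length(x$test_samples), auroc = x$auroc)
}
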