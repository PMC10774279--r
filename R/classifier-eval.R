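#' Configuration for classifier training and evaluation
#'
#' @param penalty_grid candidate soft-margin penalties `C` for the grid
#'   search (default `10^(-3:3)`).
#' @param n_folds folds `K` for stratified cross-validation (default 8).
#' @param positive_class group label treated as positive (the bipolar-like
#'   class; sensitivity is computed on it). Default `"BD"`.
#' @param rng_seed seed for fold assignment and permutation draws.
#' @param n_permutations label permutations for the significance test
#'   (default 1000).
#' @param permutation_scheme `"label"` permutes labels (default);
#'   `"resample"` bootstrap-resamples subjects and permutes their labels.
#' @param refit_selection_per_fold re-run feature selection inside every CV
#'   training split (leakage-free, default `TRUE`); `FALSE` reproduces the
#'   optimistic variant where one selection feeds all folds.
#' @return A `classifier_config`.
#' @export
classifier_config <- function(penalty_grid = 10^(-3:3), n_folds = 8L,
                              positive_class = "BD", rng_seed = 1L,
                              n_permutations = 1000L,
                              permutation_scheme = c("label", "resample"),
                              refit_selection_per_fold = TRUE) {
  if (length(penalty_grid) == 0L || any(penalty_grid <= 0))
    stop("penalty_grid must be non-empty and positive")
  if (n_folds < 2L) stop("n_folds must be >= 2")
  structure(list(penalty_grid = sort(penalty_grid),
                 n_folds = as.integer(n_folds),
                 positive_class = positive_class,
                 rng_seed = as.integer(rng_seed),
                 n_permutations = as.integer(n_permutations),
                 permutation_scheme = match.arg(permutation_scheme),
                 refit_selection_per_fold = isTRUE(refit_selection_per_fold)),
            class = "classifier_config")
}

# binary factor with the positive class as the FIRST level, which makes
# libsvm's decision values positive for the positive class
.binary_factor <- function(labels, positive_class) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (!positive_class %in% lev)
    stop("positive class '", positive_class, "' absent from labels")
  if (length(lev) != 2L) stop("labels must contain exactly 2 classes")
  factor(labels, levels = c(positive_class, setdiff(lev, positive_class)))
}

#' Fit a linear soft-margin classifier
#'
#' Linear-kernel support vector machine (hinge loss with penalty `C`),
#' without feature rescaling. The decision score `w'x + b` is positive for
#' the positive class.
#'
#' @param values samples x features matrix.
#' @param labels binary labels.
#' @param C soft-margin penalty (> 0).
#' @param positive_class label of the positive class.
#' @return A `linear_margin` model: `weights`, `bias`, `positive_class`,
#'   `negative_class`.
#' @export
fit_linear_margin <- function(values, labels, C = 1,
                              positive_class = labels[[1]]) {
  if (C <= 0) stop("C must be positive")
  yf <- .binary_factor(labels, positive_class)
  fit <- e1071::svm(x = values, y = yf, kernel = "linear", cost = C,
                    scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm orients the decision function toward whichever class appears
  # first in the data; flip so positive scores always mean positive class
  if (fit$labels[1] != 1L) {
    w <- -w
    b <- -b
  }
  structure(list(weights = w, bias = b,
                 positive_class = levels(yf)[1],
                 negative_class = levels(yf)[2]),
            class = "linear_margin")
}

#' Decision scores of a linear margin model
#'
#' @param model a `linear_margin`.
#' @param values samples x features matrix.
#' @return Numeric vector of signed scores (positive -> positive class).
#' @export
decision_scores <- function(model, values) {
  if (ncol(values) != length(model$weights))
    stop("feature count (", ncol(values), ") does not match model (",
         length(model$weights), ")")
  drop(values %*% model$weights) + model$bias
}

#' @export
predict.linear_margin <- function(object, newdata, ...) {
  s <- decision_scores(object, newdata)
  ifelse(s > 0, object$positive_class, object$negative_class)
}

#' Stratified fold assignment
#'
#' Shuffles within class and deals round-robin, so fold class proportions
#' match the sample as closely as integer arithmetic allows (e.g. 50+48
#' subjects in 8 folds gives six folds of 12 and two of 13).
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param rng_seed seed for the within-class shuffle.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
make_stratified_folds <- function(labels, k, rng_seed = 1L) {
  labels <- factor(labels)
  if (min(table(labels)) < k)
    stop("every class must have at least k = ", k, " members")
  folds <- integer(length(labels))
  withr_seed(rng_seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Confusion-matrix metrics
#'
#' Sensitivity is the true-positive rate on the positive (bipolar-like)
#' class, specificity the true-negative rate.
#'
#' @param predictions predicted labels.
#' @param labels true binary labels.
#' @param positive_class label of the positive class.
#' @return List `accuracy, sensitivity, specificity`.
#' @export
confusion_metrics <- function(predictions, labels, positive_class) {
  pos <- labels == positive_class
  if (!any(pos) || all(pos))
    stop("labels must contain both positive and negative cases")
  pred_pos <- predictions == positive_class
  tp <- sum(pos & pred_pos); fn <- sum(pos & !pred_pos)
  tn <- sum(!pos & !pred_pos); fp <- sum(!pos & pred_pos)
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp))
}

#' ROC curve and area under it
#'
#' Threshold sweep over the unique decision scores (ties grouped), yielding a
#' monotone curve from (0,0) to (1,1); the area is the trapezoidal integral,
#' which equals the pairwise estimate `P(score_pos > score_neg) + P(tie)/2`.
#'
#' @param scores numeric decision scores (higher -> more positive).
#' @param labels true binary labels.
#' @param positive_class label of the positive class.
#' @return List with `roc_points` (data.frame `fpr, tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive_class) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  pos <- labels == positive_class
  if (!any(pos) || all(pos))
    stop("labels must contain both positive and negative cases")
  np <- sum(pos); nn <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # cumulative counts at each distinct threshold
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, cumsum(p)[last_of_tie] / np)
  fpr <- c(0, cumsum(!p)[last_of_tie] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Choose the penalty by cross-validated grid search
#'
#' Returns the grid value maximizing mean stratified K-fold accuracy on the
#' supplied (training) data; ties go to the smallest `C`.
#'
#' @param values samples x features matrix (typically already restricted to
#'   the selected features).
#' @param labels binary labels.
#' @param config a [classifier_config()].
#' @return The chosen `C`.
#' @export
grid_search_penalty <- function(values, labels, config = classifier_config()) {
  k <- min(config$n_folds, min(table(labels)))
  folds <- make_stratified_folds(labels, k, config$rng_seed)
  acc <- vapply(config$penalty_grid, function(C) {
    mean(vapply(seq_len(k), function(f) {
      tr <- folds != f
      m <- fit_linear_margin(values[tr, , drop = FALSE], labels[tr], C,
                             config$positive_class)
      mean(predict(m, values[!tr, , drop = FALSE]) == labels[!tr])
    }, numeric(1)))
  }, numeric(1))
  config$penalty_grid[which.max(acc)]  # which.max takes the first (smallest C)
}

#' Stratified K-fold cross-validated evaluation
#'
#' For each fold, the selection hook (feature selection) runs on the training
#' split alone, a linear margin classifier is fit on the selected features,
#' and the held-out split is scored. Reports per-fold and mean accuracy,
#' sensitivity and specificity, plus one ROC pooled over the held-out
#' decision scores. When the hook signals an empty selection the fold falls
#' back to predicting the training majority class (score 0).
#'
#' @param values samples x features matrix.
#' @param labels binary labels.
#' @param config a [classifier_config()].
#' @param selection_hook `NULL` (use all features) or
#'   `function(values, labels) -> integer feature indices`.
#' @param C soft-margin penalty used in every fold (default 1; see
#'   [grid_search_penalty()]).
#' @return An `eval_report`: `per_fold` data.frame, `mean_accuracy`,
#'   `mean_sensitivity`, `mean_specificity`, `roc_points`, `auc`,
#'   `chosen_C`, `folds`.
#' @export
stratified_kfold_eval <- function(values, labels, config = classifier_config(),
                                  selection_hook = NULL, C = 1) {
  labels <- as.character(labels)
  folds <- make_stratified_folds(labels, config$n_folds, config$rng_seed)
  scores <- numeric(length(labels))
  preds <- character(length(labels))
  per_fold <- vector("list", config$n_folds)
  for (f in seq_len(config$n_folds)) {
    tr <- folds != f
    xtr <- values[tr, , drop = FALSE]; ytr <- labels[tr]
    xte <- values[!tr, , drop = FALSE]; yte <- labels[!tr]
    mask <- seq_len(ncol(values))
    ok <- TRUE
    if (!is.null(selection_hook)) {
      mask <- tryCatch(selection_hook(xtr, ytr),
                       limbicscreen_empty_selection = function(e) integer(0))
      if (length(mask) == 0L) ok <- FALSE
    }
    if (ok) {
      m <- fit_linear_margin(xtr[, mask, drop = FALSE], ytr, C,
                             config$positive_class)
      sc <- decision_scores(m, xte[, mask, drop = FALSE])
      pd <- ifelse(sc > 0, m$positive_class, m$negative_class)
    } else {
      maj <- names(which.max(table(ytr)))
      sc <- rep(0, length(yte))
      pd <- rep(maj, length(yte))
    }
    scores[!tr] <- sc
    preds[!tr] <- pd
    per_fold[[f]] <- as.data.frame(confusion_metrics(pd, yte,
                                                     config$positive_class))
  }
  per_fold <- do.call(rbind, per_fold)
  roc <- roc_auc(scores, labels, config$positive_class)
  structure(list(per_fold = per_fold,
                 mean_accuracy = mean(per_fold$accuracy),
                 mean_sensitivity = mean(per_fold$sensitivity),
                 mean_specificity = mean(per_fold$specificity),
                 roc_points = roc$roc_points, auc = roc$auc,
                 chosen_C = C, folds = folds,
                 predictions = preds, scores = scores),
            class = "eval_report")
}

#' Evaluate a frozen classifier on an independent test sample
#'
#' No refitting and no reselection: the model and its feature mask come from
#' training, and the test features must be vectorized on the same registry.
#'
#' @param classifier a `trained_classifier` from [train_classifier()].
#' @param values test subjects x voxels matrix (full registry width).
#' @param labels test labels.
#' @param registry the test set's voxel registry; must match training.
#' @param positive_class test label counted as positive (default: the
#'   model's own positive class). A positive decision score predicts this
#'   class, so a classifier trained on known bipolar cases can be scored on
#'   a converted-bipolar test group.
#' @return An `eval_report` (single "fold" = the whole test set).
#' @export
holdout_test <- function(classifier, values, labels, registry,
                         positive_class = classifier$model$positive_class) {
  if (!identical(registry$region, classifier$registry_regions) ||
      ncol(values) != length(classifier$registry_regions))
    stop("feature-space mismatch: test registry differs from training")
  labels <- as.character(labels)
  neg <- setdiff(unique(labels), positive_class)
  if (!positive_class %in% labels || length(neg) != 1L)
    stop("test labels must contain the positive class and one other class")
  x <- values[, classifier$mask, drop = FALSE]
  sc <- decision_scores(classifier$model, x)
  pd <- ifelse(sc > 0, positive_class, neg)
  cm <- confusion_metrics(pd, labels, positive_class)
  roc <- roc_auc(sc, labels, positive_class)
  structure(list(per_fold = as.data.frame(cm),
                 mean_accuracy = cm$accuracy,
                 mean_sensitivity = cm$sensitivity,
                 mean_specificity = cm$specificity,
                 roc_points = roc$roc_points, auc = roc$auc,
                 chosen_C = classifier$chosen_C, folds = NULL,
                 predictions = pd, scores = sc),
            class = "eval_report")
}

#' Train the final classifier on the full training sample
#'
#' Runs feature selection on the whole training set, chooses the penalty by
#' cross-validated grid search on the selected features, and fits the final
#' linear margin model; the feature mask and registry are frozen into the
#' returned object for leak-free holdout testing.
#'
#' @param values training subjects x voxels matrix.
#' @param labels training labels.
#' @param registry a [voxel_registry()].
#' @param sel_config a [selection_config()].
#' @param config a [classifier_config()].
#' @param region_names optional id -> name map for the region table.
#' @return A `trained_classifier`: `model`, `mask`, `selection` (region
#'   table), `chosen_C`, `registry_regions`.
#' @export
train_classifier <- function(values, labels, registry,
                             sel_config = selection_config(),
                             config = classifier_config(),
                             region_names = NULL) {
  sel <- select_features(values, labels, registry, sel_config, region_names)
  xsel <- values[, sel$mask, drop = FALSE]
  chosen_C <- grid_search_penalty(xsel, labels, config)
  model <- fit_linear_margin(xsel, labels, chosen_C, config$positive_class)
  structure(list(model = model, mask = sel$mask, selection = sel$table,
                 importance = sel$importance, chosen_C = chosen_C,
                 registry_regions = registry$region),
            class = "trained_classifier")
}

#' Permutation significance of the cross-validated accuracy
#'
#' Recomputes the full pipeline (feature selection + fit, via
#' `pipeline_hook`) under label permutations and reports
#' `p = (1 + #{null accuracy >= observed}) / (n_permutations + 1)`.
#'
#' @param values samples x features matrix.
#' @param labels binary labels.
#' @param config a [classifier_config()] (supplies `n_permutations`,
#'   `permutation_scheme`, `rng_seed`).
#' @param pipeline_hook `function(values, labels) -> mean CV accuracy`; must
#'   itself be leakage-free.
#' @return List with `p_value`, `observed`, and `null_accuracies`.
#' @export
permutation_significance <- function(values, labels, config,
                                     pipeline_hook) {
  stopifnot(config$n_permutations >= 1L)
  observed <- pipeline_hook(values, labels)
  null_acc <- withr_seed(config$rng_seed + 1L, {
    vapply(seq_len(config$n_permutations), function(b) {
      if (config$permutation_scheme == "label") {
        pipeline_hook(values, sample(labels))
      } else {
        idx <- sample(length(labels), replace = TRUE)
        # keep both classes represented
        while (length(unique(labels[idx])) < 2L)
          idx <- sample(length(labels), replace = TRUE)
        pipeline_hook(values[idx, , drop = FALSE], sample(labels[idx]))
      }
    }, numeric(1))
  })
  list(p_value = (1 + sum(null_acc >= observed)) / (config$n_permutations + 1),
       observed = observed, null_accuracies = null_acc)
}
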