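#' Radial basis function kernel
#'
#' `k(x, y) = exp(-g * ||x - y||^2)` with squared Euclidean distance: the
#' kernel used to lift the 16-dimensional factor vectors into a space
#' where the two effectiveness classes are linearly separable.
#'
#' @param x,y numeric vectors of equal length (finite).
#' @param g kernel width parameter (`>= 0`).
#' @return kernel value in `(0, 1]`.
#' @export
rbf_kernel <- function(x, y, g) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)) || !is.finite(g) || g < 0)
    stop("inputs must be finite and `g` >= 0")
  exp(-g * sum((x - y)^2))
}

#' Split the former cohort into training and testing sets
#'
#' Training projects are those completed in `train_years` (default
#' 2006-2009), testing projects those completed in `test_years` (default
#' 2010); the split is disjoint and exhaustive over the former cohort.
#'
#' @param projects data.frame with a `completion_year` column.
#' @param train_years,test_years completion-year ranges.
#' @return list with data.frames `train` and `test`.
#' @export
split_cohorts <- function(projects, train_years = 2006:2009,
                          test_years = 2010) {
  train <- projects[projects$completion_year %in% train_years, , drop = FALSE]
  test <- projects[projects$completion_year %in% test_years, , drop = FALSE]
  if (nrow(train) == 0) stop("empty training partition")
  if (nrow(test) == 0) stop("empty testing partition")
  list(train = train, test = test)
}

#' Fit / apply per-feature [0, 1] scaling
#'
#' Min-max scaling parameters are learned on training data only and then
#' applied unchanged to any evaluation set (no test leakage). A feature
#' with zero range on the training data carries no information for the
#' classifier and is dropped with a warning.
#'
#' @param x numeric matrix or data.frame of features (training data).
#' @return for `scale_fit`, an object of class `fc_scaler` with elements
#'   `offset`, `scale`, `keep`; for `scale_apply`, the scaled matrix
#'   restricted to the retained features.
#' @export
scale_fit <- function(x) {
  x <- as.matrix(x)
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  rng <- hi - lo
  keep <- rng > 0
  if (!all(keep))
    warning("dropping zero-variance feature(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
  structure(list(offset = lo, scale = ifelse(keep, rng, 1), keep = keep),
            class = "fc_scaler")
}

#' @rdname scale_fit
#' @param scaler an `fc_scaler` from `scale_fit`.
#' @export
scale_apply <- function(scaler, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$offset), 2, scaler$scale, "/")[, scaler$keep,
                                                          drop = FALSE]
}

# Stratified k-fold assignment: within each class, shuffled indices are
# dealt round-robin so fold class balance matches the data.
stratified_folds <- function(y, k, seed = 1L) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# Cross-validated overall accuracy of a C-SVC with RBF kernel at (C, g).
cv_accuracy <- function(x, y, C, g, fold) {
  correct <- 0L
  for (f in sort(unique(fold))) {
    tr <- fold != f
    m <- e1071::svm(x[tr, , drop = FALSE], y[tr], type = "C-classification",
                    kernel = "radial", cost = C, gamma = g, scale = FALSE)
    pred <- stats::predict(m, x[!tr, , drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' Coarse-then-fine grid search for the C-SVC parameters
#'
#' Tunes the penalty `C` and kernel width `g` by stratified k-fold
#' cross-validated overall accuracy. A coarse pass scans powers of two
#' over `[2^-8, 2^8]` at step `2^2`; fine passes then rescan a +/- 2
#' octave neighborhood of the incumbent optimum at step `2^0.25`,
#' repeating (re-centered) until the optimum improves by less than
#' `improve_tol` (0.1 accuracy percentage points), i.e. until the accuracy
#' is high and stable. Ties are broken toward the smallest `C`, then the
#' smallest `g`. Features are expected pre-scaled (see [scale_fit()]).
#'
#' For large training sets the cross-validation within the search runs on
#' a stratified subsample of `cv_subsample` projects (the quadratic-
#' programming cost of the underlying solver grows quadratically in n, and
#' parameter selection stabilizes well below the full cohort size); the
#' final model is always fitted on the full training set.
#'
#' @param x numeric feature matrix (scaled).
#' @param y factor or vector of +1/-1 labels (both classes present).
#' @param folds number of cross-validation folds.
#' @param seed RNG seed for fold assignment and subsampling; fixed seed
#'   gives a fully deterministic search.
#' @param coarse_exp,coarse_step coarse-phase exponent range (base 2) and
#'   step.
#' @param fine_span,fine_step fine-phase half-width and step, in octaves.
#' @param cv_subsample cap on the number of projects used inside the
#'   cross-validation (`Inf` to disable).
#' @param max_fine_rounds upper bound on fine re-centering rounds.
#' @param improve_tol stop when a fine round improves accuracy by less
#'   than this (proportion; 0.001 = 0.1 percentage points).
#' @return object of class `fc_grid_search`: list with `grid` (data.frame
#'   of phase, C, g, cv_accuracy), `chosen_c`, `chosen_g`, `cv_accuracy`,
#'   `phase` of the chosen cell.
#' @export
grid_search <- function(x, y, folds = 5, seed = 1L,
                        coarse_exp = c(-8, 8), coarse_step = 2,
                        fine_span = 2, fine_step = 0.25,
                        cv_subsample = 800, max_fine_rounds = 3,
                        improve_tol = 0.001) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) stop("training labels contain a single class")
  if (nrow(x) < 2 * folds) stop("need at least ", 2 * folds, " training examples")

  sub <- seq_len(nrow(x))
  if (nrow(x) > cv_subsample) {
    sub <- with_seed(seed + 1L, {
      unlist(lapply(levels(y), function(cl) {
        idx <- which(y == cl)
        sample(idx, round(length(idx) * cv_subsample / nrow(x)))
      }))
    })
  }
  xs <- x[sub, , drop = FALSE]
  ys <- droplevels(y[sub])
  fold <- stratified_folds(ys, folds, seed = seed)

  # memoize cells across phases and rounds: fine neighborhoods overlap the
  # coarse lattice and each other
  memo <- new.env(parent = emptyenv())
  eval_grid <- function(cexp, gexp, phase) {
    cells <- expand.grid(ce = cexp, ge = gexp)
    acc <- mapply(function(ce, ge) {
      key <- sprintf("%.6f|%.6f", ce, ge)
      if (is.null(memo[[key]]))
        memo[[key]] <- cv_accuracy(xs, ys, 2^ce, 2^ge, fold)
      memo[[key]]
    }, cells$ce, cells$ge)
    data.frame(phase = phase, C = 2^cells$ce, g = 2^cells$ge,
               cv_accuracy = acc)
  }
  pick_best <- function(grid) {
    best <- max(grid$cv_accuracy)
    cand <- grid[grid$cv_accuracy >= best - 1e-12, , drop = FALSE]
    cand[order(cand$C, cand$g), , drop = FALSE][1, ]
  }

  exps <- seq(coarse_exp[1], coarse_exp[2], by = coarse_step)
  grid <- eval_grid(exps, exps, "coarse")
  best <- pick_best(grid)
  for (round in seq_len(max_fine_rounds)) {
    ce0 <- log2(best$C); ge0 <- log2(best$g)
    fine <- eval_grid(seq(ce0 - fine_span, ce0 + fine_span, by = fine_step),
                      seq(ge0 - fine_span, ge0 + fine_span, by = fine_step),
                      "fine")
    grid <- rbind(grid, fine)
    new_best <- pick_best(grid)
    improved <- new_best$cv_accuracy - best$cv_accuracy
    best <- new_best
    if (improved < improve_tol) break
  }
  structure(list(grid = grid, chosen_c = best$C, chosen_g = best$g,
                 cv_accuracy = best$cv_accuracy, phase = best$phase),
            class = "fc_grid_search")
}

#' @export
print.fc_grid_search <- function(x, ...) {
  cat(sprintf("<fc_grid_search> %d cells; chosen C = %g, g = %g (%s), CV accuracy %.4f\n",
              nrow(x$grid), x$chosen_c, x$chosen_g, x$phase, x$cv_accuracy))
  invisible(x)
}

#' Train a C-SVC and evaluate it on the held-out cohort
#'
#' Fits a soft-margin C-SVC with RBF kernel at the given `(C, g)` on the
#' training features (min-max scaled with training-set parameters only)
#' and reports overall accuracy on the held-out test set.
#'
#' @param train_x,train_y training features (16 factors) and +1/-1 labels.
#' @param test_x,test_y held-out features and labels.
#' @param C penalty parameter.
#' @param g RBF kernel width.
#' @param indicator optional name of the indicator being modelled.
#' @return object of class `fc_classifier`: the fitted model, the scaler,
#'   `C`, `g`, `train_accuracy` and `test_accuracy`.
#' @export
train_and_evaluate <- function(train_x, train_y, test_x, test_y, C, g,
                               indicator = NA_character_) {
  stopifnot(C > 0, g > 0)
  train_y <- factor(train_y, levels = c(-1, 1))
  test_y <- factor(test_y, levels = c(-1, 1))
  if (nlevels(droplevels(train_y)) < 2)
    stop("training labels contain a single class")
  scaler <- scale_fit(train_x)
  xs <- scale_apply(scaler, train_x)
  model <- e1071::svm(xs, train_y, type = "C-classification",
                      kernel = "radial", cost = C, gamma = g, scale = FALSE)
  acc <- function(x, y) {
    pred <- stats::predict(model, scale_apply(scaler, x))
    mean(pred == y)
  }
  structure(list(indicator = indicator, model = model, scaler = scaler,
                 C = C, g = g,
                 train_accuracy = acc(train_x, train_y),
                 test_accuracy = acc(test_x, test_y)),
            class = "fc_classifier")
}

#' @export
print.fc_classifier <- function(x, ...) {
  cat(sprintf("<fc_classifier> %s: C = %g, g = %g, train acc %.4f, test acc %.4f\n",
              x$indicator, x$C, x$g, x$train_accuracy, x$test_accuracy))
  invisible(x)
}

#' Predict effectiveness of later projects
#'
#' Applies a trained classifier to the prediction cohort. Projects with
#' missing features are skipped (with a message) rather than imputed.
#'
#' @param classifier an `fc_classifier` from [train_and_evaluate()].
#' @param later data.frame of later projects containing the feature
#'   columns used in training and a `project_id` column.
#' @param feature_cols names of the feature columns.
#' @return list with `predictions` (data.frame `project_id`, `label` in
#'   {+1, -1}) and `rate` (fraction predicted effective), or empty output
#'   for an empty prediction set.
#' @export
predict_later <- function(classifier, later,
                          feature_cols = names(classifier$scaler$offset)) {
  stopifnot(inherits(classifier, "fc_classifier"))
  if (nrow(later) == 0)
    return(list(predictions = data.frame(project_id = character(0),
                                         label = integer(0)),
                rate = NA_real_))
  x <- as.matrix(later[, feature_cols, drop = FALSE])
  complete <- stats::complete.cases(x) & apply(is.finite(x), 1, all)
  if (!all(complete))
    message(sum(!complete), " project(s) skipped: missing features")
  x <- x[complete, , drop = FALSE]
  pred <- stats::predict(classifier$model, scale_apply(classifier$scaler, x))
  labels <- as.integer(as.character(pred))
  list(predictions = data.frame(project_id = later$project_id[complete],
                                label = labels),
       rate = mean(labels == 1L))
}

#' Published optimal SVM parameter presets
#'
#' The `(C, g)` pairs reported as optimal for the four indicators in the
#' reference national study, for users replaying comparable real data.
#' They are presets, not defaults: synthetic cohorts are tuned by
#' [grid_search()].
#'
#' @return data.frame with columns `indicator`, `C`, `g`.
#' @export
svm_parameter_presets <- function() {
  data.frame(indicator = c("pl", "pv", "pp", "mi"),
             C = c(0.9, 0.07, 9.5, 2.0),
             g = c(3.0, 1.0, 4.5, 0.7))
}

#' Tune, train and predict for all four indicators
#'
#' End-to-end prediction stage: for each indicator, split the former
#' cohort into 2006-2009 training and 2010 testing sets, grid-search
#' `(C, g)`, fit the final classifier on the training set, evaluate on the
#' test set, and predict the later cohort.
#'
#' @param projects cohort project table (with `completion_year`, `period`
#'   and the sixteen factor columns).
#' @param indicators per-project indicator table with `project_id` and the
#'   four `effective_*` flags (typically from [evaluate_cohort_series()]).
#' @param feature_cols feature column names (default the sixteen factors).
#' @param seed RNG seed for the grid search.
#' @param ... further arguments passed to [grid_search()].
#' @return list with `models` (per-indicator `fc_classifier`), `searches`
#'   (per-indicator `fc_grid_search`), `summary` (data.frame of chosen
#'   parameters and accuracies), `predictions` (later-project labels per
#'   indicator) and `later_rates` (named vector of predicted effectiveness
#'   rates, percent).
#' @export
fit_effectiveness_models <- function(projects, indicators,
                                     feature_cols = factor_names(),
                                     seed = 1L, ...) {
  former <- projects[projects$period == "former", , drop = FALSE]
  later <- projects[projects$period == "later", , drop = FALSE]
  former <- merge(former, indicators, by = "project_id")
  parts <- split_cohorts(former)
  models <- searches <- predictions <- list()
  summary_rows <- list()
  rates <- c()
  for (ind in c("pl", "pv", "pp", "mi")) {
    flag <- paste0("effective_", ind)
    lab <- function(d) ifelse(d[[flag]], 1L, -1L)
    scaler <- scale_fit(parts$train[, feature_cols])
    gs <- grid_search(scale_apply(scaler, parts$train[, feature_cols]),
                      lab(parts$train), seed = seed, ...)
    clf <- train_and_evaluate(parts$train[, feature_cols], lab(parts$train),
                              parts$test[, feature_cols], lab(parts$test),
                              C = gs$chosen_c, g = gs$chosen_g,
                              indicator = ind)
    pr <- predict_later(clf, later, feature_cols)
    models[[ind]] <- clf
    searches[[ind]] <- gs
    predictions[[ind]] <- pr$predictions
    rates[ind] <- 100 * pr$rate
    summary_rows[[ind]] <- data.frame(
      indicator = ind, C = gs$chosen_c, g = gs$chosen_g,
      cv_accuracy = gs$cv_accuracy, train_accuracy = clf$train_accuracy,
      test_accuracy = clf$test_accuracy,
      later_rate = round_half_up(100 * pr$rate, 2))
  }
  list(models = models, searches = searches,
       summary = do.call(rbind, summary_rows),
       predictions = predictions, later_rates = rates)
}
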