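# Uniform fit/score interface over the five classifier families. Every
# fitter takes a numeric feature matrix and a 0/1 label vector and returns
# an object `score_classifier()` maps to positive-class probabilities.

CLASSIFIER_SPECS <- c("rf", "knn", "nb", "svm_rbf", "adaboost")

#' Fit a classifier of a given family
#'
#' Families: `rf` (probability random forest, `ntree` from config), `knn`
#' (k-nearest neighbours, k = 5), `nb` (Gaussian naive Bayes), `svm_rbf`
#' (RBF-kernel SVM with Platt probabilities), `adaboost` (discrete
#' AdaBoost.M1 over depth-1 decision stumps, 50 rounds).
#'
#' @param x numeric feature matrix (rows = pairs).
#' @param y 0/1 labels (1 = combination).
#' @param spec one of `r toString(CLASSIFIER_SPECS)`.
#' @param config a [run_config()] (tree counts).
#' @param seed integer seed for the stochastic fitters.
#' @return classifier object for [score_classifier()].
#' @export
fit_classifier <- function(x, y, spec, config = run_config(), seed = 1L) {
  if (!spec %in% CLASSIFIER_SPECS)
    format_error("unknown classifier_spec '%s' (expected one of %s)",
                 spec, paste(CLASSIFIER_SPECS, collapse = ", "))
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    degenerate_input_error("training set has a single class")
  model <- switch(spec,
    rf = ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                        num.trees = config$rf_ntree, probability = TRUE,
                        seed = seed, num.threads = 1),
    knn = list(x = x, y = y, k = 5L),
    nb = e1071::naiveBayes(x, factor(y, levels = c(0, 1))),
    svm_rbf = {
      set.seed(seed)
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                 probability = TRUE)
    },
    adaboost = fit_adaboost(x, y, rounds = 50L, seed = seed))
  structure(list(spec = spec, model = model, features = colnames(x)),
            class = "pair_classifier")
}

#' Positive-class scores from a fitted classifier
#'
#' @param clf a [fit_classifier()] object.
#' @param x feature matrix with at least the training features.
#' @return numeric vector of positive-class probabilities in `[0, 1]`.
#' @export
score_classifier <- function(clf, x) {
  x <- as.matrix(x)
  if (!is.null(clf$features)) {
    missing <- setdiff(clf$features, colnames(x))
    if (length(missing))
      format_error("missing feature(s) at prediction time: %s",
                   paste(missing, collapse = ", "))
    x <- x[, clf$features, drop = FALSE]
  }
  switch(clf$spec,
    rf = predict(clf$model, data = x, num.threads = 1)$predictions[, "1"],
    knn = {
      pr <- class::knn(clf$model$x, x, factor(clf$model$y), k = clf$model$k,
                       prob = TRUE)
      p_win <- attr(pr, "prob")
      ifelse(pr == "1", p_win, 1 - p_win)
    },
    nb = predict(clf$model, x, type = "raw")[, "1"],
    svm_rbf = attr(predict(clf$model, x, probability = TRUE),
                   "probabilities")[, "1"],
    adaboost = score_adaboost(clf$model, x))
}

# Discrete AdaBoost.M1 with rpart stumps; labels in {-1, +1} internally.
fit_adaboost <- function(x, y, rounds = 50L, seed = 1L) {
  set.seed(seed)
  yy <- ifelse(y == 1, 1, -1)
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- data.frame(x, check.names = FALSE)
  stumps <- vector("list", rounds)
  alphas <- numeric(rounds)
  used <- 0L
  for (m in seq_len(rounds)) {
    fit <- rpart::rpart(y ~ ., data = cbind(df, y = factor(yy)), weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2, xval = 0))
    pred <- ifelse(predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != yy))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    used <- used + 1L
    stumps[[used]] <- fit
    alphas[used] <- alpha
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    if (err < 1e-9) break  # perfect stump; further rounds add nothing
  }
  list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)])
}

score_adaboost <- function(model, x) {
  df <- data.frame(x, check.names = FALSE)
  f <- rep(0, nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- ifelse(predict(model$stumps[[m]], df, type = "class") == "1", 1, -1)
    f <- f + model$alphas[m] * pred
  }
  1 / (1 + exp(-2 * f))  # logistic link on the additive margin
}
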