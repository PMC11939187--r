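# Internal classifier registry: uniform fit / predict-probability surface
# over the eight benchmarked models. X is samples x features (numeric),
# y a factor with levels c("healthy", "cancer"); probabilities are always
# P(cancer).

.modelNames <- c("knn", "svm", "gaussian_nb", "decision_tree",
                 "random_forest", "xgboost", "adaboost", "lgbm")

.scaleSensitive <- c("knn", "svm")

.standardize <- function(X, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(X, 2, center, "-"), 2, scale, "/")
}

.fitClassifier <- function(modelName, X, y, seed = 1) {
  if (!modelName %in% .modelNames)
    stop("unknown model '", modelName, "'; valid models: ",
         paste(.modelNames, collapse = ", "))
  y <- factor(y, levels = c("healthy", "cancer"))
  X <- as.matrix(X)
  colnames(X) <- paste0("F", seq_len(ncol(X)))
  set.seed(seed)
  prep <- NULL
  if (modelName %in% .scaleSensitive) {
    prep <- list(center = colMeans(X), scale = apply(X, 2, stats::sd))
    X <- .standardize(X, prep$center, prep$scale)
  }
  fit <- switch(modelName,
    knn = list(trainX = X, trainY = y, k = 5),
    svm = e1071::svm(x = X, y = y, kernel = "radial", probability = TRUE,
                     scale = FALSE),
    gaussian_nb = e1071::naiveBayes(x = as.data.frame(X), y = y),
    decision_tree = rpart::rpart(y ~ ., data = data.frame(y = y, X),
                                 method = "class"),
    random_forest = randomForest::randomForest(x = X, y = y, ntree = 500),
    xgboost = xgboost::xgboost(
      X, y, objective = "binary:logistic", nrounds = 100,
      learning_rate = 0.3, max_depth = 6, nthreads = 1,
      seed = seed %% .Machine$integer.max, verbosity = 0),
    adaboost = .fitAdaboost(X, y, nRounds = 50),
    lgbm = xgboost::xgboost(
      X, y, objective = "binary:logistic", nrounds = 100,
      learning_rate = 0.1, tree_method = "hist",
      grow_policy = "lossguide", max_leaves = 31, max_depth = 0,
      nthreads = 1, seed = seed %% .Machine$integer.max, verbosity = 0))
  structure(list(model = fit, name = modelName, prep = prep,
                 nFeatures = ncol(X)), class = "maldiDxClassifier")
}

.predictProb <- function(fit, X) {
  X <- as.matrix(X)
  colnames(X) <- paste0("F", seq_len(ncol(X)))
  if (!is.null(fit$prep)) X <- .standardize(X, fit$prep$center, fit$prep$scale)
  m <- fit$model
  switch(fit$name,
    knn = {
      pr <- class::knn(m$trainX, X, m$trainY, k = m$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "cancer", win, 1 - win)
    },
    svm = {
      p <- stats::predict(m, X, probability = TRUE)
      attr(p, "probabilities")[, "cancer"]
    },
    gaussian_nb = stats::predict(m, as.data.frame(X), type = "raw")[, "cancer"],
    decision_tree = stats::predict(m, data.frame(X), type = "prob")[, "cancer"],
    random_forest = stats::predict(m, X, type = "prob")[, "cancer"],
    xgboost = stats::predict(m, X),
    adaboost = .predictAdaboost(m, X),
    lgbm = stats::predict(m, X))
}

# Discrete AdaBoost (SAMME) over depth-1 rpart stumps; the ensemble
# margin is mapped to a probability through the logistic link.
.fitAdaboost <- function(X, y, nRounds = 50) {
  n <- nrow(X)
  df <- data.frame(y = y, X)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(nRounds)) {
    st <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                       control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                      minsplit = 2, xval = 0))
    pred <- stats::predict(st, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- st
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  list(stumps = stumps, alphas = alphas)
}

.predictAdaboost <- function(fit, X) {
  df <- data.frame(X)
  score <- rep(0, nrow(df))
  for (m in seq_along(fit$stumps)) {
    pred <- stats::predict(fit$stumps[[m]], df, type = "class")
    score <- score + fit$alphas[m] * ifelse(pred == "cancer", 1, -1)
  }
  1 / (1 + exp(-score))
}

# Impurity (Gini/gain) importances for tree-based fits; NULL for models
# without an importance attribute.
.rawImportances <- function(fit) {
  m <- fit$model
  d <- fit$nFeatures
  sc <- switch(fit$name,
    decision_tree = {
      vi <- m$variable.importance
      out <- stats::setNames(rep(0, d), paste0("F", seq_len(d)))
      out[names(vi)] <- vi
      out
    },
    random_forest = stats::setNames(m$importance[, "MeanDecreaseGini"],
                                    rownames(m$importance)),
    xgboost = ,
    lgbm = {
      imp <- xgboost::xgb.importance(model = m)
      out <- stats::setNames(rep(0, d), paste0("F", seq_len(d)))
      out[imp$Feature] <- imp$Gain
      out
    },
    NULL)
  if (is.null(sc)) return(NULL)
  sc[paste0("F", seq_len(d))]
}
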