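#' Train a single classifier
#'
#' Fits one of the eight supported classifiers on a feature matrix (used
#' directly by the attribution and intersection tools; cross-validated
#' evaluation lives in \code{\link{crossvalEvaluate}}).
#'
#' @param fm a \linkS4class{PeptideFeatureMatrix}, or a samples x features
#'   numeric matrix.
#' @param modelName one of \code{supportedModels()}.
#' @param labels group labels (ignored when \code{fm} carries them).
#' @param seed RNG seed.
#' @return A fitted classifier object (class \code{maldiDxClassifier}).
#' @export
trainClassifier <- function(fm, modelName, labels = NULL, seed = 1) {
  if (is(fm, "PeptideFeatureMatrix")) {
    X <- featureValues(fm)
    labels <- sampleGroups(fm)
  } else X <- as.matrix(fm)
  .fitClassifier(modelName, X, labels, seed = seed)
}

#' Predicted cancer probability
#'
#' @param fit a classifier from \code{\link{trainClassifier}}.
#' @param X samples x features matrix on the training feature space.
#' @return Numeric vector of P(cancer).
#' @export
predictProbability <- function(fit, X) .predictProb(fit, X)

#' Impurity (Gini) feature importances
#'
#' Normalised impurity-decrease importances from tree-based models
#' (\code{decision_tree}, \code{random_forest}, \code{xgboost},
#' \code{lgbm}), with descending 1-based ranks (ties broken by feature
#' order, i.e. ascending m/z).
#'
#' @param fit a fitted classifier from \code{\link{trainClassifier}}.
#' @param featureNames optional feature names (default \code{F1..Fd}).
#' @return An importance ranking: data.frame with columns \code{feature},
#'   \code{score} (>= 0, summing to 1) and \code{rank}; attribute
#'   \code{method = "gini"}.
#' @export
modelImportances <- function(fit, featureNames = NULL) {
  sc <- .rawImportances(fit)
  if (is.null(sc))
    stop("model '", fit$name, "' has no impurity importances; supported: ",
         "decision_tree, random_forest, xgboost, lgbm")
  if (!is.null(featureNames)) names(sc) <- featureNames
  if (sum(sc) > 0) sc <- sc / sum(sc)
  out <- data.frame(feature = names(sc), score = unname(sc),
                    rank = rank(-sc, ties.method = "first"))
  rownames(out) <- NULL
  attr(out, "method") <- "gini"
  out
}

# ---- kernel SHAP ----------------------------------------------------------

# Value of coalition S for instance x: model output averaged over the
# background with the features in S pinned to x.
.coalitionValues <- function(predictFun, x, background, Z, chunkRows = 6e4) {
  nB <- nrow(background)
  m <- nrow(Z)
  vals <- numeric(m)
  perChunk <- max(1L, floor(chunkRows / nB))
  for (start in seq(1, m, by = perChunk)) {
    idx <- start:min(m, start + perChunk - 1)
    M <- background[rep(seq_len(nB), length(idx)), , drop = FALSE]
    for (q in seq_along(idx)) {
      s <- which(Z[idx[q], ] == 1)
      rows <- (q - 1) * nB + seq_len(nB)
      M[rows, s] <- matrix(x[s], nrow = nB, ncol = length(s), byrow = TRUE)
    }
    p <- predictFun(M)
    vals[idx] <- colMeans(matrix(p, nrow = nB))
  }
  vals
}

#' Kernel SHAP attributions
#'
#' Model-agnostic Shapley value estimation: coalition values are model
#' outputs averaged over a background sample with the coalition's
#' features pinned to the explained instance, and Shapley values are
#' recovered by Shapley-kernel-weighted least squares over coalitions.
#' When the coalition budget covers full enumeration (all \eqn{2^d - 2}
#' proper coalitions, always the case for small feature counts) the
#' result is the exact Shapley value of the interventional value
#' function; otherwise coalitions are sampled with size frequencies
#' proportional to the Shapley kernel. Local accuracy (base value +
#' contributions = model output) holds by construction.
#'
#' @param fit a fitted classifier from \code{\link{trainClassifier}}, or
#'   a function mapping a samples x features matrix to probabilities.
#' @param background background data matrix (the convention is up to 200
#'   rows drawn from the training set).
#' @param X instances to explain (samples x features matrix).
#' @param nsamples coalition budget; default \code{2^min(d, 11)} capped
#'   at 2048.
#' @param seed RNG seed for coalition sampling.
#' @return List with \code{values} (instances x features matrix of
#'   contributions), \code{baseValue} (mean background output),
#'   \code{prediction} (per-instance model outputs), and \code{ranking}
#'   (global importance: mean |contribution| per feature, with ranks;
#'   attribute \code{method = "shap"}).
#' @export
shapAttributions <- function(fit, background, X, nsamples = NULL, seed = 1) {
  predictFun <- if (is.function(fit)) fit else function(M) .predictProb(fit, M)
  background <- as.matrix(background)
  X <- as.matrix(X)
  d <- ncol(X)
  if (ncol(background) != d) stop("background and X must share features")
  if (is.null(nsamples)) nsamples <- min(2^min(d, 11), 2048)
  set.seed(seed)

  f0 <- mean(predictFun(background))
  fx <- predictFun(X)
  phi <- matrix(0, nrow = nrow(X), ncol = d,
                dimnames = list(rownames(X), colnames(X)))
  if (d == 1) {
    phi[, 1] <- fx - f0
  } else {
    full <- (2^d - 2) <= nsamples
    if (full) {
      sizes <- unlist(lapply(1:(d - 1), function(s)
        utils::combn(d, s, simplify = FALSE)), recursive = FALSE)
      Z <- do.call(rbind, lapply(sizes, function(s) {
        z <- numeric(d); z[s] <- 1; z
      }))
      s <- rowSums(Z)
      w <- (d - 1) / (choose(d, s) * s * (d - s))
    } else {
      pSize <- (d - 1) / ((1:(d - 1)) * (d - (1:(d - 1))))
      sz <- sample(1:(d - 1), nsamples, replace = TRUE,
                   prob = pSize / sum(pSize))
      Z <- t(vapply(sz, function(s) {
        z <- numeric(d); z[sample.int(d, s)] <- 1; z
      }, numeric(d)))
      w <- rep(1, nsamples)   # size frequencies already follow the kernel
    }
    A <- Z[, -d, drop = FALSE] - Z[, d]
    AtW <- t(A * w)
    G <- AtW %*% A
    for (i in seq_len(nrow(X))) {
      v <- .coalitionValues(predictFun, X[i, ], background, Z)
      yv <- v - f0 - Z[, d] * (fx[i] - f0)
      head <- as.numeric(solve(G, AtW %*% yv))
      phi[i, ] <- c(head, fx[i] - f0 - sum(head))
    }
  }
  g <- colMeans(abs(phi))
  ranking <- data.frame(
    feature = if (is.null(colnames(X))) paste0("F", 1:d) else colnames(X),
    score = unname(g), rank = rank(-g, ties.method = "first"))
  attr(ranking, "method") <- "shap"
  list(values = phi, baseValue = f0, prediction = fx, ranking = ranking)
}

# ---- LIME-style local surrogates ------------------------------------------

# weighted ridge regression with unpenalised intercept
.ridgeFit <- function(A, y, w, lambda) {
  A1 <- cbind(1, A)
  P <- diag(c(0, rep(lambda, ncol(A))))
  beta <- solve(t(A1 * w) %*% A1 + P, t(A1 * w) %*% y)
  beta[-1]
}

#' LIME-style global feature rankings
#'
#' For each explained instance, samples perturbed points from the
#' training distribution (Gaussian per feature, standardised
#' representation), weights them by an exponential kernel on Euclidean
#' distance to the instance (width \code{0.75 * sqrt(d)}), fits a ridge
#' surrogate to the model's probabilities, and keeps the
#' \code{nFeaturesKept} largest-magnitude surrogate weights. Instance
#' explanations are aggregated into a global ranking: the signed score is
#' the mean signed weight, the rank follows mean |weight|.
#'
#' @param fit fitted classifier or probability function (as in
#'   \code{\link{shapAttributions}}).
#' @param X training data matrix (samples x features); its columns must
#'   not all be constant.
#' @param explainIdx indices of instances to explain (default: all).
#' @param nPerturb perturbations per instance.
#' @param nFeaturesKept sparse surrogate size per instance.
#' @param lambda ridge penalty.
#' @param seed RNG seed.
#' @return An importance ranking data.frame (\code{feature},
#'   \code{score} = mean signed weight, \code{absScore}, \code{rank});
#'   attribute \code{method = "lime"}.
#' @export
limeRankings <- function(fit, X, explainIdx = seq_len(nrow(X)),
                         nPerturb = 5000, nFeaturesKept = 10, lambda = 1,
                         seed = 1) {
  predictFun <- if (is.function(fit)) fit else function(M) .predictProb(fit, M)
  X <- as.matrix(X)
  d <- ncol(X)
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  if (all(sg == 0)) stop("feature set has zero variance; nothing to perturb")
  sg[sg == 0] <- 1
  kw <- 0.75 * sqrt(d)
  set.seed(seed)
  W <- matrix(0, nrow = length(explainIdx), ncol = d)
  for (q in seq_along(explainIdx)) {
    x <- X[explainIdx[q], ]
    Zs <- matrix(stats::rnorm(nPerturb * d), nrow = nPerturb)
    raw <- sweep(sweep(Zs, 2, sg, "*"), 2, mu, "+")
    raw[1, ] <- x                              # the instance itself
    zStd <- sweep(sweep(raw, 2, mu, "-"), 2, sg, "/")
    xStd <- (x - mu) / sg
    dist <- sqrt(rowSums(sweep(zStd, 2, xStd, "-")^2))
    wts <- sqrt(exp(-dist^2 / kw^2))
    beta <- .ridgeFit(zStd, predictFun(raw), wts, lambda)
    keep <- order(-abs(beta))[seq_len(min(nFeaturesKept, d))]
    W[q, keep] <- beta[keep]
  }
  signed <- colMeans(W)
  absW <- colMeans(abs(W))
  out <- data.frame(
    feature = if (is.null(colnames(X))) paste0("F", 1:d) else colnames(X),
    score = signed, absScore = absW, rank = rank(-absW, ties.method = "first"))
  attr(out, "method") <- "lime"
  out
}

# ---- consensus -------------------------------------------------------------

#' Majority-voting consensus feature selection
#'
#' Combines three importance rankings (impurity, SHAP, LIME): every
#' feature appearing in the top-k of at least two methods is selected
#' (majority voting); remaining slots are filled by ascending average
#' rank across the three methods. Ties break by the canonical feature
#' order (ascending m/z). The result is invariant to the order in which
#' the rankings are supplied.
#'
#' @param rankings list of 3 importance ranking data.frames over the same
#'   feature set (columns \code{feature}, \code{rank}).
#' @param k consensus size.
#' @return List with \code{selected} (character, length k), \code{votes}
#'   (named counts in 0..3), \code{fillRank} (named average ranks) and
#'   \code{table} (per-feature summary).
#' @export
consensusTopK <- function(rankings, k = 20) {
  if (length(rankings) != 3) stop("exactly three rankings are expected")
  feats <- rankings[[1]]$feature
  for (r in rankings[-1])
    if (!setequal(r$feature, feats)) stop("rankings cover different feature sets")
  rk <- vapply(rankings, function(r) r$rank[match(feats, r$feature)],
               numeric(length(feats)))
  votes <- rowSums(rk <= k)
  avgRank <- rowMeans(rk)
  k <- min(k, length(feats))
  # majority features first (by average rank), then fill by average rank
  maj <- which(votes >= 2)
  maj <- maj[order(avgRank[maj], maj)]
  rest <- setdiff(seq_along(feats), maj)
  rest <- rest[order(avgRank[rest], rest)]
  selIdx <- c(maj, rest)[seq_len(k)]
  tab <- data.frame(feature = feats, votes = votes, avgRank = avgRank,
                    selected = seq_along(feats) %in% selIdx)
  list(selected = feats[sort(selIdx)],
       votes = stats::setNames(votes, feats),
       fillRank = stats::setNames(avgRank, feats),
       table = tab)
}

#' Cross-validated cross-model top-importance intersection
#'
#' The stringent stability selection that isolates the handful of peaks
#' every tree ensemble agrees on: each model exposing impurity
#' importances (decision tree, random forest, leaf-wise boosting,
#' XGBoost) is refit on the training portion of each stratified
#' cross-validation fold; a feature enters a model's stable set only if
#' it ranks in the positive top-m on every fold, and the final selection
#' is the intersection of the models' stable sets. Fold resampling is
#' what removes features whose apparent importance is a quirk of the full
#' data set rather than reproducible signal.
#'
#' @param fm a \linkS4class{PeptideFeatureMatrix} (or matrix with
#'   \code{labels}).
#' @param models models to intersect (must expose importances).
#' @param topM per-model, per-fold list length.
#' @param nFolds stratified folds per model (1 = fit once on all data).
#' @param labels group labels when \code{fm} is a bare matrix.
#' @param seed RNG seed.
#' @return Character vector of features in every model's every-fold top-m
#'   (possibly empty, with a warning).
#' @export
importanceIntersection <- function(fm, models = c("decision_tree",
                                                  "random_forest",
                                                  "lgbm", "xgboost"),
                                   topM = 10, nFolds = 5, labels = NULL,
                                   seed = 1) {
  if (is(fm, "PeptideFeatureMatrix")) {
    X <- featureValues(fm); labels <- sampleGroups(fm)
    featureNames <- sprintf("mz_%.2f", featureMz(fm))
  } else {
    X <- as.matrix(fm)
    featureNames <- colnames(X)
    if (is.null(featureNames)) featureNames <- paste0("F", seq_len(ncol(X)))
  }
  y <- factor(labels, levels = c("healthy", "cancer"))
  fold <- if (nFolds > 1) .stratifiedFolds(y, nFolds, seed) else
    rep(0L, length(y))
  topOf <- function(m, rows) {
    imp <- modelImportances(
      .fitClassifier(m, X[rows, , drop = FALSE], y[rows], seed = seed),
      featureNames)
    # zero-importance features never count as top-ranked
    imp$feature[imp$rank <= topM & imp$score > 0]
  }
  tops <- lapply(models, function(m) {
    if (nFolds <= 1) return(topOf(m, rep(TRUE, length(y))))
    Reduce(intersect,
           lapply(sort(unique(fold)), function(f) topOf(m, fold != f)))
  })
  out <- Reduce(intersect, tops)
  if (!length(out)) warning("the models' cross-validated top-", topM,
                            " importance lists share no feature")
  out
}
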