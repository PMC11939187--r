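#' Stratified train/test split
#'
#' Splits samples into train and test sets preserving the class
#' proportions: within each class, \code{round(testFrac * n)} samples are
#' drawn for the test set. Deterministic for a fixed seed; the two index
#' sets are disjoint and exhaustive.
#'
#' @param fm a \linkS4class{PeptideFeatureMatrix} (or a vector of group
#'   labels).
#' @param testFrac fraction of each class assigned to the test set.
#' @param seed RNG seed.
#' @return A list with integer index vectors \code{train} and \code{test}.
#' @export
stratifiedSplit <- function(fm, testFrac = 0.2, seed = 1) {
  g <- if (is(fm, "PeptideFeatureMatrix")) sampleGroups(fm) else fm
  if (length(unique(g)) < 2) stop("both classes must be present")
  if (any(table(g) < 2)) stop("each class needs >= 2 samples")
  set.seed(seed)
  test <- integer(0)
  for (cl in unique(g)) {
    idx <- which(g == cl)
    nTest <- round(testFrac * length(idx))
    if (nTest > 0) test <- c(test, sample(idx, nTest))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(g), test), test = test)
}

# Stratified k-fold assignment: within each class, shuffled samples are
# dealt to folds round-robin.
.stratifiedFolds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# AUC of P(positive) scores by trapezoidal integration of the ROC curve
# (ties handled by pROC).
.aucOf <- function(labels, scores, positive = "cancer") {
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(setdiff(c("healthy", "cancer"), positive),
                            positive),
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy (TP+TN)/N, precision TP/(TP+FP), recall TP/(TP+FN) and the F1
#' score (harmonic mean of precision and recall). A zero denominator
#' yields 0 with a warning.
#'
#' @param confusion named numeric vector with elements TP, FP, TN, FN
#'   (non-negative, total > 0).
#' @return Named numeric vector: accuracy, precision, recall, f1.
#' @examples
#' computeMetrics(c(TP = 3, FP = 1, TN = 5, FN = 1))
#' @export
computeMetrics <- function(confusion) {
  need <- c("TP", "FP", "TN", "FN")
  if (!all(need %in% names(confusion))) stop("confusion must name TP, FP, TN, FN")
  cm <- confusion[need]
  if (any(cm < 0)) stop("confusion counts must be non-negative")
  if (sum(cm) == 0) stop("confusion matrix is all zero")
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as 0")
      return(0)
    }
    num / den
  }
  acc <- (cm["TP"] + cm["TN"]) / sum(cm)
  prec <- safe(cm["TP"], cm["TP"] + cm["FP"], "precision")
  rec <- safe(cm["TP"], cm["TP"] + cm["FN"], "recall")
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(accuracy = unname(acc), precision = unname(prec),
    recall = unname(rec), f1 = unname(f1))
}

#' Cross-validated classifier evaluation
#'
#' Stratified k-fold cross-validation of one of the eight supported
#' classifiers (\code{knn}, \code{svm}, \code{gaussian_nb},
#' \code{decision_tree}, \code{random_forest}, \code{xgboost},
#' \code{adaboost}, \code{lgbm}). Out-of-fold class probabilities give
#' per-fold one-vs-rest ROC AUCs for both classes (equal in the binary
#' case), their mean ± SD and the macro mean, plus the pooled confusion
#' matrix at the 0.5 probability operating point and the derived
#' accuracy/precision/recall/F1. Feature standardisation (train-fitted)
#' is applied for the scale-sensitive models (knn, svm).
#'
#' @param fm an imputed, replicate-collapsed
#'   \linkS4class{PeptideFeatureMatrix}.
#' @param modelName one of the eight model identifiers.
#' @param k number of folds.
#' @param seed RNG seed (controls folds and any stochastic training).
#' @return A \linkS4class{CVEvaluation}.
#' @examples
#' \donttest{
#' coh <- generateCohort(cohortConfig(nCancer = 15, nHealthy = 15,
#'                                    replicates = 1, nPeaks = 12,
#'                                    mzMax = 4000, seed = 2))
#' ps <- lapply(coh$spectra, function(s) detectPeaks(preprocessSpectrum(s)))
#' fm <- imputeMissing(greedyAlign(ps))
#' crossvalEvaluate(fm, "svm", k = 5, seed = 1)
#' }
#' @export
crossvalEvaluate <- function(fm, modelName, k = 5, seed = 1) {
  if (!modelName %in% .modelNames)
    stop("unknown model '", modelName, "'; valid models: ",
         paste(.modelNames, collapse = ", "))
  X <- featureValues(fm)
  y <- factor(sampleGroups(fm), levels = c("healthy", "cancer"))
  if (anyNA(X)) stop("impute missing values before evaluation")
  if (any(table(y) < k)) stop("each class needs at least k samples")
  fold <- .stratifiedFolds(y, k, seed)
  aucs <- matrix(NA_real_, nrow = k, ncol = 2,
                 dimnames = list(NULL, c("healthy", "cancer")))
  prob <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- .fitClassifier(modelName, X[tr, , drop = FALSE], y[tr],
                          seed = seed + f)
    p <- .predictProb(fit, X[!tr, , drop = FALSE])
    prob[!tr] <- p
    aCancer <- .aucOf(y[!tr], p, positive = "cancer")
    aHealthy <- .aucOf(y[!tr], 1 - p, positive = "healthy")
    aucs[f, ] <- c(aHealthy, aCancer)
  }
  meanAuc <- colMeans(aucs)
  sdAuc <- apply(aucs, 2, stats::sd)
  pred <- prob >= 0.5
  confusion <- c(TP = sum(pred & y == "cancer"),
                 FP = sum(pred & y == "healthy"),
                 TN = sum(!pred & y == "healthy"),
                 FN = sum(!pred & y == "cancer"))
  roc <- pROC::roc(response = y, predictor = prob,
                   levels = c("healthy", "cancer"), direction = "<",
                   quiet = TRUE)
  new("CVEvaluation", modelName = modelName, aucPerFold = aucs,
      meanAuc = meanAuc, sdAuc = sdAuc, macroAuc = mean(meanAuc),
      confusion = confusion, metrics = computeMetrics(confusion),
      rocPoints = data.frame(fpr = 1 - roc$specificities,
                             tpr = roc$sensitivities))
}

#' Benchmark several classifiers
#'
#' Runs \code{\link{crossvalEvaluate}} for each requested model under the
#' same folds.
#'
#' @param fm an imputed \linkS4class{PeptideFeatureMatrix}.
#' @param models character vector of model names (default: all eight).
#' @param k,seed as in \code{\link{crossvalEvaluate}}.
#' @return Named list of \linkS4class{CVEvaluation} objects.
#' @export
benchmarkModels <- function(fm, models = .modelNames, k = 5, seed = 1) {
  stats::setNames(lapply(models, function(m)
    crossvalEvaluate(fm, m, k = k, seed = seed)), models)
}

#' Names of the supported classifiers
#' @return Character vector of the eight model identifiers.
#' @export
supportedModels <- function() .modelNames
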