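#' ROC of a single feature with expression-direction orientation
#'
#' Scores are oriented so that higher means more cancer-like: if the
#' cancer group mean exceeds the healthy mean the raw values are used
#' ("highly expressed" indicator), otherwise the values are negated
#' ("lowly expressed"). The AUC is computed on the oriented scores, so it
#' is always >= 0.5 up to sampling noise.
#'
#' @param values numeric indicator values, one per sample.
#' @param labels group labels ("healthy"/"cancer"), both present.
#' @param direction force \code{"high"}/\code{"low"} instead of
#'   orienting by group means.
#' @return List with \code{auc}, \code{direction}, \code{oriented}
#'   (oriented scores) and \code{roc} (data.frame fpr, tpr). Constant
#'   values yield AUC 0.5 with a warning.
#' @examples
#' singleFeatureROC(c(1, 2, 3, 10, 11, 12),
#'                  rep(c("healthy", "cancer"), each = 3))
#' @export
singleFeatureROC <- function(values, labels, direction = NULL) {
  labels <- factor(labels, levels = c("healthy", "cancer"))
  if (any(is.na(labels)) || length(unique(labels)) < 2)
    stop("both classes must be present")
  if (stats::sd(values) == 0) {
    warning("constant indicator; AUC is degenerate (0.5)")
    return(list(auc = 0.5, direction = "high", oriented = values,
                roc = data.frame(fpr = c(0, 1), tpr = c(0, 1))))
  }
  if (is.null(direction))
    direction <- if (mean(values[labels == "cancer"]) >
                     mean(values[labels == "healthy"])) "high" else "low"
  oriented <- if (direction == "high") values else -values
  r <- pROC::roc(response = labels, predictor = oriented,
                 levels = c("healthy", "cancer"), direction = "<",
                 quiet = TRUE)
  list(auc = as.numeric(pROC::auc(r)), direction = direction,
       oriented = oriented,
       roc = data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities))
}

#' Youden-index threshold optimisation
#'
#' Evaluates 100 equally spaced thresholds over the score range; at each
#' threshold (positive call: score >= threshold) the confusion matrix
#' gives sensitivity, specificity and the Youden index J = SEN + SPEC - 1.
#' The optimal operating point is the J-maximising threshold (lowest
#' threshold on ties).
#'
#' @param values indicator scores (oriented so higher = more cancer-like;
#'   use \code{\link{singleFeatureROC}}'s \code{oriented} output, or set
#'   \code{orient = TRUE} to orient by group means first).
#' @param labels group labels, both classes present.
#' @param nThresholds grid size.
#' @param orient orient values by group means before thresholding.
#' @return List with \code{thresholds}, \code{sen}, \code{spec},
#'   \code{youden}, \code{optimalThreshold}, \code{optimalJ}.
#' @export
youdenOptimize <- function(values, labels, nThresholds = 100,
                           orient = FALSE) {
  labels <- factor(labels, levels = c("healthy", "cancer"))
  if (any(is.na(labels)) || length(unique(labels)) < 2)
    stop("both classes must be present")
  if (orient &&
      mean(values[labels == "cancer"]) < mean(values[labels == "healthy"]))
    values <- -values
  thr <- seq(min(values), max(values), length.out = nThresholds)
  nPos <- sum(labels == "cancer")
  nNeg <- sum(labels == "healthy")
  sen <- vapply(thr, function(t)
    sum(values >= t & labels == "cancer") / nPos, numeric(1))
  spec <- vapply(thr, function(t)
    sum(values < t & labels == "healthy") / nNeg, numeric(1))
  j <- sen + spec - 1
  best <- which.max(j)            # which.max returns the first (lowest) tie
  list(thresholds = thr, sen = sen, spec = spec, youden = j,
       optimalThreshold = thr[best], optimalJ = j[best])
}

#' Net benefit of a diagnostic rule
#'
#' The decision-analytic net benefit at probability threshold t:
#' \deqn{NB = TP/N - (FP/N) \cdot t/(1-t).}
#'
#' @param tp,fp true/false positive counts.
#' @param nTotal total evaluated samples.
#' @param t decision threshold, strictly inside (0, 1).
#' @return Net benefit (dimensionless).
#' @examples
#' netBenefit(30, 10, 100, 0.2)   # 0.275
#' @export
netBenefit <- function(tp, fp, nTotal, t) {
  if (any(t <= 0 | t >= 1)) stop("'t' must lie strictly in (0, 1)")
  if (nTotal <= 0) stop("'nTotal' must be positive")
  tp / nTotal - (fp / nTotal) * t / (1 - t)
}

#' Treat-all net benefit
#'
#' Net benefit of classifying every sample positive. Two variants are
#' provided. \code{"as_printed"} uses (TP + TN) as the denominator with
#' counts from the classify-everyone-positive rule (TP = all positives,
#' TN = 0, FP = all negatives), i.e.
#' \eqn{TP/(TP+TN) - FP/(TP+TN) \cdot t/(1-t)}; this is the default for
#' fidelity to the reporting convention it reproduces, although with
#' TN = 0 the denominator reduces to the positive count.
#' \code{"standard"} is the textbook decision-curve form
#' \eqn{\pi - (1-\pi) \cdot t/(1-t)} with prevalence \eqn{\pi}, which
#' crosses zero at t = prevalence.
#'
#' @param nPos,nNeg positive/negative class counts.
#' @param t decision threshold in (0, 1).
#' @param variant \code{"as_printed"} or \code{"standard"}.
#' @return Net benefit of the treat-all strategy.
#' @export
treatAllBenefit <- function(nPos, nNeg, t, variant = c("as_printed",
                                                       "standard")) {
  variant <- match.arg(variant)
  if (any(t <= 0 | t >= 1)) stop("'t' must lie strictly in (0, 1)")
  if (variant == "as_printed") {
    tp <- nPos; tn <- 0; fp <- nNeg
    if (tp + tn == 0) stop("zero denominator: no positive samples")
    tp / (tp + tn) - fp / (tp + tn) * t / (1 - t)
  } else {
    prev <- nPos / (nPos + nNeg)
    prev - (1 - prev) * t / (1 - t)
  }
}

# composite Simpson integration on a uniform grid; a trailing trapezoid
# handles an odd interval count
.simpsonArea <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  h <- x[2] - x[1]
  nInt <- n - 1
  area <- 0
  useInt <- if (nInt %% 2 == 0) nInt else nInt - 1
  if (useInt >= 2) {
    idx <- seq(1, useInt - 1, by = 2)
    area <- sum(h / 3 * (y[idx] + 4 * y[idx + 1] + y[idx + 2]))
  }
  if (nInt %% 2 == 1) area <- area + h * (y[n - 1] + y[n]) / 2
  area
}

#' Cross-validated decision-curve analysis of a classifier
#'
#' Stratified k-fold cross-validation produces out-of-fold probabilities;
#' at each threshold t of the grid, a sample is called positive when its
#' probability >= t, and each fold's net benefit is computed with
#' \code{\link{netBenefit}} on that fold's validation samples. The curve
#' reports the fold mean with a normal-approximation 95\% CI
#' (mean ± 1.96 SD / sqrt(k)), the treat-all and treat-none references,
#' and the Simpson-integrated area of the region where the model's net
#' benefit is positive.
#'
#' @param fm an imputed \linkS4class{PeptideFeatureMatrix}.
#' @param modelName one of \code{supportedModels()}.
#' @param k folds.
#' @param thresholds threshold grid strictly inside (0, 1).
#' @param treatAllVariant passed to \code{\link{treatAllBenefit}}.
#' @param seed RNG seed.
#' @return A \code{DCACurve}: list with \code{thresholds}, \code{nbModel}
#'   (mean), \code{ciLow}, \code{ciHigh}, \code{nbAll}, \code{nbNone}
#'   (zeros) and \code{benefitArea}.
#' @export
dcaCrossval <- function(fm, modelName, k = 5,
                        thresholds = seq(0.01, 0.99, length.out = 99),
                        treatAllVariant = "as_printed", seed = 1) {
  X <- featureValues(fm)
  y <- factor(sampleGroups(fm), levels = c("healthy", "cancer"))
  if (anyNA(X)) stop("impute missing values before evaluation")
  fold <- .stratifiedFolds(y, k, seed)
  nbFold <- matrix(NA_real_, nrow = k, ncol = length(thresholds))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- .fitClassifier(modelName, X[tr, , drop = FALSE], y[tr],
                          seed = seed + f)
    p <- .predictProb(fit, X[!tr, , drop = FALSE])
    yv <- y[!tr]
    nV <- length(yv)
    nbFold[f, ] <- vapply(seq_along(thresholds), function(ti) {
      pos <- p >= thresholds[ti]
      netBenefit(sum(pos & yv == "cancer"), sum(pos & yv == "healthy"),
                 nV, thresholds[ti])
    }, numeric(1))
  }
  nbModel <- colMeans(nbFold)
  se <- apply(nbFold, 2, stats::sd) / sqrt(k)
  nbAll <- treatAllBenefit(sum(y == "cancer"), sum(y == "healthy"),
                           thresholds, variant = treatAllVariant)
  structure(list(thresholds = thresholds, nbModel = nbModel,
                 ciLow = nbModel - 1.96 * se, ciHigh = nbModel + 1.96 * se,
                 nbAll = nbAll, nbNone = rep(0, length(thresholds)),
                 benefitArea = .simpsonArea(thresholds, pmax(nbModel, 0)),
                 model = modelName),
            class = "DCACurve")
}

#' Decision-curve analysis of a single indicator
#'
#' Maps the probability-threshold axis onto the indicator's value range
#' through its empirical quantiles: at grid point t the value cutoff is
#' the t-quantile (direction \code{"high"}: positive when value >=
#' cutoff) or the (1-t)-quantile (direction \code{"low"}: positive when
#' value <= cutoff), so larger t always means a stricter rule. Net
#' benefit follows \code{\link{netBenefit}} at each t.
#'
#' @param values indicator values.
#' @param labels group labels.
#' @param direction \code{"high"} (cancer-elevated indicator) or
#'   \code{"low"}.
#' @param thresholds probability-threshold grid in (0, 1).
#' @param treatAllVariant passed to \code{\link{treatAllBenefit}}.
#' @return A \code{DCACurve} list (without CI bands; single split).
#' @export
singleFeatureDCA <- function(values, labels, direction = c("high", "low"),
                             thresholds = seq(0.01, 0.99, length.out = 99),
                             treatAllVariant = "as_printed") {
  direction <- match.arg(direction)
  labels <- factor(labels, levels = c("healthy", "cancer"))
  n <- length(values)
  nb <- vapply(thresholds, function(t) {
    if (direction == "high") {
      cut <- stats::quantile(values, t, names = FALSE)
      pos <- values >= cut
    } else {
      cut <- stats::quantile(values, 1 - t, names = FALSE)
      pos <- values <= cut
    }
    netBenefit(sum(pos & labels == "cancer"), sum(pos & labels == "healthy"),
               n, t)
  }, numeric(1))
  nbAll <- treatAllBenefit(sum(labels == "cancer"), sum(labels == "healthy"),
                           thresholds, variant = treatAllVariant)
  structure(list(thresholds = thresholds, nbModel = nb, ciLow = nb,
                 ciHigh = nb, nbAll = nbAll,
                 nbNone = rep(0, length(thresholds)),
                 benefitArea = .simpsonArea(thresholds, pmax(nb, 0)),
                 model = paste0("single-feature (", direction, ")")),
            class = "DCACurve")
}

#' Plot a decision curve
#'
#' @param x a \code{DCACurve}.
#' @param ... passed to \code{plot}.
#' @return Invisibly, \code{x}.
#' @export
plotDCA <- function(x, ...) {
  graphics::plot(x$thresholds, x$nbModel, type = "l", lwd = 2,
                 col = "firebrick", xlab = "threshold probability",
                 ylab = "net benefit",
                 ylim = range(c(x$ciLow, x$ciHigh, x$nbAll, 0)), ...)
  graphics::polygon(c(x$thresholds, rev(x$thresholds)),
                    c(x$ciLow, rev(x$ciHigh)),
                    col = grDevices::adjustcolor("firebrick", 0.2),
                    border = NA)
  graphics::lines(x$thresholds, x$nbAll, col = "grey40", lty = 2)
  graphics::abline(h = 0, col = "grey40", lty = 3)
  invisible(x)
}
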