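#' Bisecting K-means clustering
#'
#' Divisive clustering: starting from one cluster holding all samples,
#' the cluster with the largest within-cluster sum of squared distances
#' is repeatedly split by 2-means (10 restarts, seeded) until k clusters
#' remain.
#'
#' @param fm a \linkS4class{PeptideFeatureMatrix} or samples x features
#'   matrix.
#' @param k number of clusters (1 <= k <= n).
#' @param seed RNG seed.
#' @param nstart restarts per 2-means split.
#' @param standardize z-score the features first (recommended for
#'   relative-area matrices, whose raw scale is far below the usual
#'   distance thresholds).
#' @return Integer cluster assignments of length n.
#' @export
bisectingKmeans <- function(fm, k = 2, seed = 1, nstart = 10,
                            standardize = FALSE) {
  X <- if (is(fm, "PeptideFeatureMatrix")) featureValues(fm) else as.matrix(fm)
  if (standardize) X <- .zscore(X)
  n <- nrow(X)
  if (k < 1) stop("'k' must be >= 1")
  if (k > n) stop("'k' exceeds the number of samples")
  set.seed(seed)
  sse <- function(idx) {
    if (length(idx) < 2) return(0)
    sub <- X[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub), "-")^2)
  }
  splittable <- function(idx)
    length(idx) >= 2 && nrow(unique(X[idx, , drop = FALSE])) >= 2
  clusters <- list(seq_len(n))
  while (length(clusters) < k) {
    scores <- vapply(clusters, sse, numeric(1))
    ok <- vapply(clusters, splittable, logical(1))
    if (!any(ok)) stop("no cluster can be split further (duplicate points)")
    target <- which(ok)[which.max(scores[ok])]
    idx <- clusters[[target]]
    km <- stats::kmeans(X[idx, , drop = FALSE], centers = 2,
                        nstart = nstart)
    clusters[[target]] <- idx[km$cluster == 1]
    clusters[[length(clusters) + 1]] <- idx[km$cluster == 2]
  }
  out <- integer(n)
  for (ci in seq_along(clusters)) out[clusters[[ci]]] <- ci
  out
}

# z-score columns, guarding constant features
.zscore <- function(X) {
  s <- apply(X, 2, stats::sd)
  s[s == 0] <- 1
  scale(X, center = TRUE, scale = s)
}

# ---- BIRCH -----------------------------------------------------------------
# Clustering-feature tree. A CF is the triple (n, linear sum, sum of
# squared norms); CFs are additive, and the entry radius is
# sqrt(SS/n - ||LS/n||^2).

.cfNew <- function(x) list(n = 1, ls = x, ss = sum(x^2))
.cfMerge <- function(a, b) list(n = a$n + b$n, ls = a$ls + b$ls,
                                ss = a$ss + b$ss)
.cfRadius <- function(cf) {
  c2 <- sum((cf$ls / cf$n)^2)
  sqrt(max(cf$ss / cf$n - c2, 0))
}
.cfCentroid <- function(cf) cf$ls / cf$n

# split an over-full node: seed with the farthest entry pair, assign the
# rest to the nearer seed; returns a list of two nodes
.birchSplit <- function(node) {
  cents <- t(vapply(node$entries, function(e) .cfCentroid(e$cf),
                    numeric(length(node$entries[[1]]$cf$ls))))
  D <- as.matrix(stats::dist(cents))
  far <- which(D == max(D), arr.ind = TRUE)[1, ]
  g1 <- far[1]; g2 <- far[2]
  asg <- apply(D[, c(g1, g2), drop = FALSE], 1, which.min)
  mk <- function(sel) list(leaf = node$leaf, entries = node$entries[sel])
  list(mk(asg == 1), mk(asg == 2))
}

.nodeCf <- function(node) Reduce(.cfMerge, lapply(node$entries, `[[`, "cf"))

# insert point x (index idx) into the subtree; returns either list(node)
# or list(nodeA, nodeB) after a split
.birchInsert <- function(node, x, idx, threshold, B) {
  if (node$leaf) {
    if (length(node$entries)) {
      d <- vapply(node$entries,
                  function(e) sqrt(sum((.cfCentroid(e$cf) - x)^2)),
                  numeric(1))
      j <- which.min(d)
      cand <- .cfMerge(node$entries[[j]]$cf, .cfNew(x))
      if (.cfRadius(cand) <= threshold) {
        node$entries[[j]]$cf <- cand
        node$entries[[j]]$points <- c(node$entries[[j]]$points, idx)
        return(list(node))
      }
    }
    node$entries[[length(node$entries) + 1]] <-
      list(cf = .cfNew(x), points = idx)
  } else {
    d <- vapply(node$entries,
                function(e) sqrt(sum((.cfCentroid(e$cf) - x)^2)),
                numeric(1))
    j <- which.min(d)
    res <- .birchInsert(node$entries[[j]]$child, x, idx, threshold, B)
    if (length(res) == 1) {
      node$entries[[j]]$child <- res[[1]]
      node$entries[[j]]$cf <- .nodeCf(res[[1]])
    } else {
      node$entries[[j]] <- list(cf = .nodeCf(res[[1]]), child = res[[1]])
      node$entries[[length(node$entries) + 1]] <-
        list(cf = .nodeCf(res[[2]]), child = res[[2]])
    }
  }
  if (length(node$entries) > B) .birchSplit(node) else list(node)
}

.birchLeafEntries <- function(node) {
  if (node$leaf) return(node$entries)
  do.call(c, lapply(node$entries, function(e) .birchLeafEntries(e$child)))
}

#' BIRCH clustering
#'
#' Builds a clustering-feature (CF) tree by inserting each sample into
#' its nearest leaf entry — absorbing it when the entry's radius stays
#' within \code{threshold}, opening a new entry otherwise, and splitting
#' nodes whose fan-out exceeds \code{branchingFactor} — then clusters the
#' leaf-entry centroids into \code{k} groups by Ward agglomeration.
#' Every sample inherits its leaf entry's global cluster.
#'
#' @param fm a \linkS4class{PeptideFeatureMatrix} or samples x features
#'   matrix.
#' @param threshold maximum leaf-entry radius (> 0).
#' @param branchingFactor maximum entries per node (> 1).
#' @param k number of global clusters.
#' @param standardize z-score the features first (recommended for
#'   relative-area matrices; the 0.5 radius threshold presumes
#'   roughly unit-scale features).
#' @return Integer cluster assignments of length n.
#' @export
birchCluster <- function(fm, threshold = 0.5, branchingFactor = 50, k = 2,
                         standardize = FALSE) {
  X <- if (is(fm, "PeptideFeatureMatrix")) featureValues(fm) else as.matrix(fm)
  if (standardize) X <- .zscore(X)
  if (threshold <= 0) stop("'threshold' must be > 0")
  if (branchingFactor < 2) stop("'branchingFactor' must be >= 2")
  n <- nrow(X)
  if (k > n) stop("'k' exceeds the number of samples")
  root <- list(leaf = TRUE, entries = list())
  for (i in seq_len(n)) {
    res <- .birchInsert(root, X[i, ], i, threshold, branchingFactor)
    root <- if (length(res) == 1) res[[1]] else
      list(leaf = FALSE,
           entries = lapply(res, function(nd)
             list(cf = .nodeCf(nd), child = nd)))
  }
  entries <- .birchLeafEntries(root)
  cents <- t(vapply(entries, function(e) .cfCentroid(e$cf),
                    numeric(ncol(X))))
  kk <- min(k, nrow(cents))
  entCl <- if (nrow(cents) == 1) 1L else
    stats::cutree(stats::hclust(stats::dist(cents), method = "ward.D2"), kk)
  out <- integer(n)
  for (e in seq_along(entries)) out[entries[[e]]$points] <- entCl[e]
  out
}

# ---- concordance -----------------------------------------------------------

# expected mutual information under the permutation (hypergeometric) model
.expectedMI <- function(a, b, N) {
  emi <- 0
  for (ai in a) for (bj in b) {
    lo <- max(1, ai + bj - N)
    hi <- min(ai, bj)
    if (lo > hi) next
    for (nij in lo:hi) {
      term <- nij / N * log(N * nij / (ai * bj))
      lp <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(N - ai + 1) +
        lgamma(N - bj + 1) - lgamma(N + 1) - lgamma(nij + 1) -
        lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
        lgamma(N - ai - bj + nij + 1)
      emi <- emi + term * exp(lp)
    }
  }
  emi
}

#' Concordance between a clustering and reference labels
#'
#' Rand index (fraction of sample pairs on which the two partitions
#' agree), adjusted Rand index, and adjusted mutual information under the
#' permutation model,
#' \eqn{AMI = (MI - E[MI]) / (\mathrm{mean}(H(U), H(V)) - E[MI])}.
#' All three are invariant to cluster relabelling; identical partitions
#' score 1.
#'
#' @param assignments cluster ids.
#' @param labels reference labels, same length.
#' @return Named numeric: \code{rand}, \code{ari}, \code{ami}.
#' @examples
#' clusteringConcordance(c(1, 1, 2, 2), c("a", "a", "b", "b"))
#' @export
clusteringConcordance <- function(assignments, labels) {
  if (length(assignments) != length(labels))
    stop("'assignments' and 'labels' differ in length")
  N <- length(labels)
  tab <- table(assignments, labels)
  a <- rowSums(tab)
  b <- colSums(tab)
  sumNij2 <- sum(choose(tab, 2))
  sumA2 <- sum(choose(a, 2))
  sumB2 <- sum(choose(b, 2))
  nPairs <- choose(N, 2)
  rand <- (nPairs + 2 * sumNij2 - sumA2 - sumB2) / nPairs
  expIdx <- sumA2 * sumB2 / nPairs
  maxIdx <- (sumA2 + sumB2) / 2
  ari <- if (maxIdx == expIdx) 1 else (sumNij2 - expIdx) / (maxIdx - expIdx)
  p <- tab / N
  mi <- sum(ifelse(p > 0, p * log(p / (a[row(tab)] / N * b[col(tab)] / N)), 0))
  hU <- -sum(ifelse(a > 0, a / N * log(a / N), 0))
  hV <- -sum(ifelse(b > 0, b / N * log(b / N), 0))
  emi <- .expectedMI(a, b, N)
  den <- (hU + hV) / 2 - emi
  ami <- if (abs(den) < 1e-12) 1 else (mi - emi) / den
  c(rand = rand, ari = ari, ami = unname(ami))
}

#' Low-dimensional embeddings for visualisation
#'
#' Seeded 2-D/3-D embeddings of the sample space: PCA (orthonormal,
#' variance-ordered components), kernel PCA with an RBF kernel (bandwidth
#' from the median-heuristic \code{\link[kernlab]{sigest}} range), t-SNE
#' and UMAP.
#'
#' @param fm a \linkS4class{PeptideFeatureMatrix} or samples x features
#'   matrix.
#' @param method one of \code{"pca"}, \code{"kpca"}, \code{"tsne"},
#'   \code{"umap"}.
#' @param dims output dimensionality (2 or 3), < number of features.
#' @param seed RNG seed.
#' @return n x dims coordinate matrix.
#' @export
embedSamples <- function(fm, method = c("pca", "kpca", "tsne", "umap"),
                         dims = 2, seed = 1) {
  method <- match.arg(method)
  X <- if (is(fm, "PeptideFeatureMatrix")) featureValues(fm) else as.matrix(fm)
  if (dims >= ncol(X)) stop("'dims' must be < the number of features")
  n <- nrow(X)
  set.seed(seed)
  coords <- switch(method,
    pca = stats::prcomp(X, center = TRUE)$x[, seq_len(dims), drop = FALSE],
    kpca = {
      sig <- mean(kernlab::sigest(X, scaled = FALSE)[c(1, 3)])
      kp <- kernlab::kpca(X, kernel = "rbfdot",
                          kpar = list(sigma = sig), features = dims)
      kernlab::rotated(kp)[, seq_len(dims), drop = FALSE]
    },
    tsne = Rtsne::Rtsne(X, dims = dims,
                        perplexity = min(30, floor((n - 1) / 3)),
                        check_duplicates = FALSE)$Y,
    umap = uwot::umap(X, n_components = dims,
                      n_neighbors = min(15, n - 1), n_threads = 1,
                      n_sgd_threads = 0))
  rownames(coords) <- rownames(X)
  coords
}
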