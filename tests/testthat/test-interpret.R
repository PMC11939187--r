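test_that("impurity importances rank a planted signal first, normalise, and reject unsupported models", {
  set.seed(2)
  n <- 60; d <- 8
  X <- matrix(rnorm(n * d), n, d)
  y <- rep(c("healthy", "cancer"), each = n / 2)
  X[y == "cancer", 4] <- X[y == "cancer", 4] + 5
  fit <- trainClassifier(X, "random_forest", labels = y, seed = 1)
  imp <- modelImportances(fit, paste0("f", 1:d))
  expect_equal(imp$feature[imp$rank == 1], "f4")
  expect_equal(sum(imp$score), 1, tolerance = 1e-9)
  expect_true(all(imp$score >= 0))
  expect_setequal(imp$rank, 1:d)
  imp2 <- modelImportances(trainClassifier(X, "random_forest",
                                           labels = y, seed = 1),
                           paste0("f", 1:d))
  expect_identical(imp, imp2)
  expect_error(modelImportances(trainClassifier(X, "knn", labels = y)),
               "decision_tree")
})

test_that("kernel SHAP satisfies local accuracy and recovers linear-model attributions exactly", {
  set.seed(3)
  d <- 6
  bg <- matrix(rnorm(40 * d), 40, d)
  beta <- c(2, -1, 0.5, 0, 3, -2)
  linFun <- function(M) 0.2 + as.numeric(M %*% beta)
  X <- matrix(rnorm(4 * d), 4, d)
  sh <- shapAttributions(linFun, bg, X)      # budget covers full enumeration
  # additivity on every explained instance
  expect_equal(unname(rowSums(sh$values) + sh$baseValue),
               unname(sh$prediction), tolerance = 1e-6)
  # closed form: phi_j = beta_j (x_j - mean background_j)
  expected <- sweep(X, 2, colMeans(bg), "-") %*% diag(beta)
  expect_equal(unname(sh$values), unname(expected), tolerance = 1e-6)
})

test_that("kernel SHAP splits contributions symmetrically across duplicated features", {
  set.seed(5)
  bg <- matrix(rnorm(30 * 4), 30, 4)
  bg[, 2] <- bg[, 1]                       # identical pair
  f <- function(M) as.numeric(1 / (1 + exp(-(M[, 1] + M[, 2] + 0.3 * M[, 3]))))
  x <- matrix(c(1.2, 1.2, -0.4, 0.7), 1, 4)
  sh <- shapAttributions(f, bg, x)
  expect_equal(sh$values[1, 1], sh$values[1, 2], tolerance = 1e-8)
})

test_that("sampled-coalition SHAP stays close to the exact values", {
  set.seed(13)
  d <- 12                                   # 2^12 - 2 > default budget
  bg <- matrix(rnorm(25 * d), 25, d)
  beta <- rnorm(d)
  f <- function(M) as.numeric(M %*% beta)
  x <- matrix(rnorm(d), 1, d)
  sh <- shapAttributions(f, bg, x, nsamples = 2000, seed = 2)
  expected <- as.numeric(beta * (x - colMeans(bg)))
  expect_equal(unname(rowSums(sh$values) + sh$baseValue),
               unname(sh$prediction), tolerance = 1e-6)
  expect_lt(max(abs(sh$values[1, ] - expected)), 0.15)
})

test_that("LIME surrogates ignore irrelevant features, match linear signs, and are seeded", {
  set.seed(6)
  n <- 80; d <- 5
  X <- matrix(rnorm(n * d), n, d)
  beta <- c(3, -2, 1.5, 0, 0)
  f <- function(M) as.numeric(1 / (1 + exp(-(M %*% beta))))
  r <- limeRankings(f, X, explainIdx = 1:10, nPerturb = 800, seed = 4)
  expect_lt(r$absScore[4], 0.02)
  expect_lt(r$absScore[5], 0.02)
  expect_gt(r$score[1], 0)
  expect_lt(r$score[2], 0)
  expect_gt(r$score[3], 0)
  expect_equal(which(r$rank <= 3), 1:3)
  r2 <- limeRankings(f, X, explainIdx = 1:10, nPerturb = 800, seed = 4)
  expect_identical(r, r2)
  expect_error(limeRankings(f, matrix(1, 10, 3)), "zero variance")
})

test_that("consensus majority voting matches the enumeration oracle and is order-invariant", {
  mk <- function(ranks) data.frame(feature = paste0("f", 1:6), rank = ranks)
  # identical rankings: consensus = common top-k
  same <- mk(c(1, 2, 3, 4, 5, 6))
  cons <- consensusTopK(list(same, same, same), k = 3)
  expect_setequal(cons$selected, c("f1", "f2", "f3"))

  # a feature in the top-k of exactly two methods is selected
  a <- mk(c(1, 2, 3, 4, 5, 6))
  b <- mk(c(1, 2, 6, 3, 4, 5))
  c3 <- mk(c(6, 1, 2, 3, 4, 5))
  cons2 <- consensusTopK(list(a, b, c3), k = 3)
  expect_true("f2" %in% cons2$selected)    # top-3 in all three
  expect_equal(unname(cons2$votes["f2"]), 3)

  # enumeration oracle: majority set, then fill by average rank
  oracle <- function(rks, k) {
    votes <- rowSums(sapply(rks, function(r) r$rank <= k))
    avg <- rowMeans(sapply(rks, `[[`, "rank"))
    maj <- which(votes >= 2)
    maj <- maj[order(avg[maj], maj)]
    rest <- setdiff(order(avg, seq_along(avg)), maj)
    sort(paste0("f", c(maj, rest)[seq_len(k)]))
  }
  set.seed(8)
  for (i in 1:10) {
    rks <- list(mk(sample(6)), mk(sample(6)), mk(sample(6)))
    got <- consensusTopK(rks, k = 3)
    expect_setequal(got$selected, oracle(rks, 3))
    # invariance to the order of the three rankings
    got2 <- consensusTopK(rks[c(3, 1, 2)], k = 3)
    expect_setequal(got$selected, got2$selected)
  }
  expect_error(consensusTopK(list(a, b), k = 3), "three")
  expect_error(consensusTopK(list(a, b, mk(1:6)[c(1, 3, 2, 4, 5, 6), ]), 3),
               NA)  # same set, different order is fine
  bad <- data.frame(feature = paste0("g", 1:6), rank = 1:6)
  expect_error(consensusTopK(list(a, b, bad), 3), "different feature sets")
})

test_that("cross-model importance intersection recovers planted dominant features", {
  set.seed(10)
  n <- 120; d <- 15
  X <- matrix(abs(rnorm(n * d, 5, 1)), n, d)
  colnames(X) <- paste0("f", 1:d)
  y <- rep(c("healthy", "cancer"), each = n / 2)
  # three complementary dominant features: each elevated in one cancer
  # subtype, so every tree model must use all three
  sub <- rep_len(1:3, n / 2)
  for (j in 1:3)
    X[which(y == "cancer")[sub == j], j] <-
      X[which(y == "cancer")[sub == j], j] + 8
  got <- importanceIntersection(X, topM = 10, labels = y, seed = 2)
  expect_setequal(got, c("f1", "f2", "f3"))

  # all models agree on a single dominant feature
  X2 <- matrix(abs(rnorm(n * 4, 5, 1)), n, 4)
  colnames(X2) <- paste0("f", 1:4)
  X2[y == "cancer", 2] <- X2[y == "cancer", 2] + 10
  expect_true("f2" %in% importanceIntersection(X2, topM = 1, labels = y))

  # pure-noise data: the stable sets share nothing
  X3 <- matrix(abs(rnorm(n * 20, 5, 1)), n, 20)
  colnames(X3) <- paste0("f", 1:20)
  expect_warning(none <- importanceIntersection(X3, topM = 1, labels = y,
                                                seed = 3),
                 "share no feature")
  expect_length(none, 0)
})

test_that("all three attribution methods surface a 3-feature planted signal", {
  set.seed(12)
  n <- 60; d <- 10
  X <- matrix(rnorm(n * d), n, d)
  colnames(X) <- paste0("f", 1:d)
  y <- rep(c("healthy", "cancer"), each = n / 2)
  X[y == "cancer", 1:3] <- X[y == "cancer", 1:3] + 4
  fit <- trainClassifier(X, "random_forest", labels = y, seed = 3)
  gini <- modelImportances(fit, colnames(X))
  bg <- X[sample(n, 40), ]
  sh <- shapAttributions(fit, bg, X[c(1, 2, n - 1, n), ], seed = 3)
  lm1 <- limeRankings(fit, X, explainIdx = seq(1, n, by = 6),
                      nPerturb = 600, seed = 3)
  for (r in list(gini, sh$ranking, lm1))
    expect_true(all(c("f1", "f2", "f3") %in% r$feature[r$rank <= 5]))
})
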