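test_that("repeated 5-fold CV yields folds x repeats validation scores", {
  pl <- plantedTurnoverModel(targetR2 = 0.7, missingness = c(),
                             blockMissing = 0, seed = 3)
  ds <- generateRegressionDataset(120, pl)
  res <- trainCV(ds$features, ds$y, modelSpec("elastic_net", folds = 5,
                                              repeats = 5, seed = 1))
  expect_equal(nrow(res$cv$scores), 25)
  expect_true(all(res$cv$scores$r2 <= 1))
  res3 <- trainCV(ds$features, ds$y, modelSpec("elastic_net", folds = 4,
                                               repeats = 2, seed = 1))
  expect_equal(nrow(res3$cv$scores), 8)
})

test_that("a noiseless linear signal is learned almost perfectly", {
  set.seed(5)
  X <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  y <- 2 * X$a - 1 * X$b
  res <- trainCV(X, y, modelSpec("elastic_net", seed = 2))
  expect_gte(res$cv$summary$medianR2, 0.99)
})

test_that("CV is exactly reproducible given the seed", {
  pl <- plantedTurnoverModel(targetR2 = 0.6, missingness = c(),
                             blockMissing = 0, seed = 8)
  ds <- generateRegressionDataset(80, pl)
  r1 <- trainCV(ds$features, ds$y, modelSpec("random_forest",
                                             repeats = 1, ntree = 50,
                                             seed = 7))
  r2 <- trainCV(ds$features, ds$y, modelSpec("random_forest",
                                             repeats = 1, ntree = 50,
                                             seed = 7))
  expect_identical(r1$cv$scores, r2$cv$scores)
  p1 <- predictTurnover(r1$fit, ds$features)
  p2 <- predictTurnover(r2$fit, ds$features)
  expect_identical(p1, p2)
})

test_that("degenerate inputs raise errors", {
  X <- data.frame(a = rnorm(30))
  expect_error(trainCV(X, rep(1, 30), modelSpec("linear")), "constant")
  expect_error(trainCV(X[1:6, , drop = FALSE], rnorm(6),
                       modelSpec("linear", folds = 5)), "too few")
})

test_that("null response gives no cross-validated signal", {
  ## guards against leakage through the imputation path: y is permuted,
  ## so median CV R^2 must be ~0 or below
  pl <- plantedTurnoverModel(targetR2 = 0.7, seed = 9)
  ds <- generateRegressionDataset(150, pl)
  set.seed(10)
  ynull <- sample(ds$y)
  imp <- imputeFeatures(ds$features, "all", seed = 2)
  res <- trainCV(imp, ynull, modelSpec("elastic_net", seed = 3))
  expect_lte(res$cv$summary$medianR2, 0.05)
})

test_that("the default ensemble has 12 tagged members", {
  pl <- plantedTurnoverModel(targetR2 = 0.75, seed = 5)
  ds <- generateRegressionDataset(120, pl)
  ens <- buildEnsemble(ds$features, ds$y, repeats = 1, budget = 4,
                       ntree = 60, seed = 1)
  expect_equal(length(ensembleMembers(ens)), 12)
  tags <- vapply(ensembleMembers(ens), function(m)
    paste(m$algorithm, m$strategy), "")
  expect_equal(length(unique(tags)), 12)
  expect_equal(sort(unique(vapply(ensembleMembers(ens), `[[`, "",
                                  "algorithm"))),
               c("elastic_net", "neural_net", "random_forest"))
})

test_that("the ensemble mean stays inside the member range", {
  pl <- plantedTurnoverModel(targetR2 = 0.75, seed = 6)
  ds <- generateRegressionDataset(60, pl, applyMissingness = FALSE)
  ens <- buildEnsemble(ds$features, ds$y, repeats = 1, budget = 2,
                       ntree = 40, seed = 2)
  ## fully observed rows: every member predicts; mean in [min, max]
  preds <- vapply(ensembleMembers(ens), function(m)
    predictTurnover(m$fit, ds$features[1:5, ]), numeric(5))
  out <- predictEnsemble(ens, ds$features[1:5, ], logScale = TRUE)
  expect_true(all(out >= apply(preds, 1, min) - 1e-9))
  expect_true(all(out <= apply(preds, 1, max) + 1e-9))
})

test_that("rows a member cannot predict fall back to its median", {
  pl <- plantedTurnoverModel(targetR2 = 0.75, missingness = c(),
                             blockMissing = 0, seed = 6)
  ds <- generateRegressionDataset(60, pl)
  ens <- buildEnsemble(ds$features, ds$y, repeats = 1, budget = 2,
                       ntree = 40, seed = 2,
                       strategies = "none")
  rows <- ds$features[1:4, ]
  rows$flux_feature[1:2] <- NA   # incomplete rows for every member
  out <- predictEnsemble(ens, rows, logScale = TRUE)
  fallbacks <- vapply(ensembleMembers(ens), `[[`, 0, "fallback")
  expect_equal(unname(out[1]), mean(fallbacks))
  expect_equal(unname(out[2]), mean(fallbacks))
  ## complete rows differ from the pure-fallback value
  expect_false(isTRUE(all.equal(unname(out[3]), mean(fallbacks))))
})

test_that("fully observed data makes the four strategies agree", {
  pl <- plantedTurnoverModel(targetR2 = 0.8, missingness = c(),
                             blockMissing = 0, seed = 12)
  ds <- generateRegressionDataset(70, pl)
  ens <- buildEnsemble(ds$features, ds$y, repeats = 1, budget = 2,
                       ntree = 40, seed = 3,
                       algorithms = "elastic_net")
  preds <- vapply(ensembleMembers(ens), function(m)
    predictTurnover(m$fit, ds$features[1:8, ]), numeric(8))
  ## imputation is a no-op on complete data: all four members identical
  expect_lt(max(apply(preds, 1, function(r) diff(range(r)))), 1e-9)
})

test_that("planted population R^2 is recovered by elastic-net CV", {
  r2s <- numeric(6)
  for (s in seq_along(r2s)) {
    pl <- plantedTurnoverModel(targetR2 = 0.7, missingness = c(),
                               blockMissing = 0, seed = 100 + s)
    ds <- generateRegressionDataset(300, pl)
    res <- trainCV(ds$features, ds$y,
                   modelSpec("elastic_net", repeats = 2, seed = s))
    r2s[s] <- res$cv$summary$medianR2
  }
  expect_lt(abs(median(r2s) - 0.7), 0.1)
})

test_that("the linear and PLS comparison algorithms train and predict", {
  pl <- plantedTurnoverModel(targetR2 = 0.8, missingness = c(),
                             blockMissing = 0, seed = 44)
  ds <- generateRegressionDataset(100, pl)
  rl <- trainCV(ds$features, ds$y, modelSpec("linear", repeats = 1,
                                             seed = 1))
  expect_gt(rl$cv$summary$medianR2, 0.5)
  rp <- trainCV(ds$features, ds$y, modelSpec("pls", repeats = 1,
                                             seed = 1))
  expect_gt(rp$cv$summary$medianR2, 0.5)
  expect_equal(length(predictTurnover(rp$fit, ds$features[1:5, ])), 5)
  ## held-out test split reports an R^2 of its own
  rt <- trainCV(ds$features, ds$y, modelSpec("elastic_net", repeats = 1,
                                             seed = 2),
                testFraction = 0.2)
  expect_true(is.finite(rt$cv$testR2))
})
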