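test_that("default mtry is the floor square root of the feature count", {
  expect_equal(defaultMtry(3039), 55)
  expect_equal(defaultMtry(1), 1)
  expect_equal(defaultMtry(49), 7)
  expect_equal(defaultMtry(48), 6)
  expect_error(defaultMtry(0), "positive")
})

test_that("the model grid is 7 mtry values x 3 runs = 21 configurations", {
  g <- buildModelGrid(3039, base_seed = 1)
  expect_equal(nrow(g), 21)
  expect_equal(sort(unique(g$mtry)), 52:58)
  expect_equal(unname(table(g$mtry)), rep(3L, 7), ignore_attr = TRUE)
  expect_equal(anyDuplicated(g$seed), 0L)
  # repeat runs of the same mtry use distinct seeds
  expect_equal(length(unique(g$seed[g$mtry == 55])), 3)
})

test_that("mtry clipping deduplicates with a warning", {
  expect_warning(g <- buildModelGrid(4, base_seed = 1), "collide")
  expect_equal(sort(unique(g$mtry)), 1:4)
  expect_equal(nrow(g), 12)
  g1 <- buildModelGrid(100, offsets = 0, n_runs = 1)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$mtry, 10)
})

test_that("Cohen's kappa matches hand-computed confusion matrices", {
  expect_equal(cohenKappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  # confusion [[2,1],[1,2]]: p_o = 2/3, p_e = 1/2 -> kappa = 1/3
  y_true <- c("a", "a", "a", "b", "b", "b")
  y_pred <- c("a", "a", "b", "a", "b", "b")
  expect_equal(cohenKappa(y_true, y_pred), 1 / 3)
  # invariance under bijective relabeling of both vectors
  map <- c(a = "Q", b = "Z")
  expect_equal(cohenKappa(map[y_true], map[y_pred]), 1 / 3)
  expect_warning(k <- cohenKappa(c("a", "a"), c("a", "a")), "convention")
  expect_equal(k, 1)
  expect_error(cohenKappa(character(0), character(0)), "empty")
  expect_error(cohenKappa("a", c("a", "b")), "length")
})

test_that("kappa agrees with the caret implementation on random labelings", {
  skip_if_not_installed("caret")
  set.seed(17)
  for (i in 1:5) {
    t_ <- factor(sample(letters[1:3], 40, replace = TRUE),
                 levels = letters[1:3])
    p_ <- factor(sample(letters[1:3], 40, replace = TRUE),
                 levels = letters[1:3])
    ref <- unname(caret::confusionMatrix(p_, t_)$overall["Kappa"])
    expect_equal(cohenKappa(t_, p_), ref, tolerance = 1e-10)
  }
})

test_that("kappa bands use strict >0.8 and <0.6 boundaries", {
  expect_equal(as.character(kappaBand(0.88)), "almost_perfect")
  expect_equal(as.character(kappaBand(0.82)), "almost_perfect")
  expect_equal(as.character(kappaBand(0.71)), "moderate")
  expect_equal(as.character(kappaBand(0.8)), "moderate")
  expect_equal(as.character(kappaBand(0.6)), "moderate")
  expect_equal(as.character(kappaBand(0.59)), "poor")
  expect_equal(as.character(kappaBand(-0.2)), "poor")
  expect_true(kappaBand(0.9) > kappaBand(0.7))
  expect_error(kappaBand(NA_real_), "finite")
})

test_that("OOB training separates strongly structured classes", {
  tab <- generateDataset(tinySpec(seed = 6))
  rel <- toRelativeAbundance(tab)
  fit <- trainRfOob(rel, mtry = defaultMtry(nrow(tab)), n_trees = 500,
                    seed = 3)
  expect_lt(fit$oob_error, 0.05)
  expect_gt(fit$kappa, 0.8)
  expect_equal(fit$accuracy, 1 - fit$oob_error)
  refit <- trainRfOob(rel, mtry = defaultMtry(nrow(tab)), n_trees = 500,
                      seed = 3)
  expect_identical(fit$oob_error, refit$oob_error)
  expect_identical(fit$kappa, refit$kappa)
})

test_that("permuted labels drive kappa to the chance level", {
  tab <- generateDataset(hardBoundarySpec(seed = 8))
  y <- classLabels(tab)
  kappas <- vapply(1:20, function(s) {
    perm <- y[ampliDepth:::.withSeed(s, sample(length(y)))]
    rel <- toRelativeAbundance(AsvExperiment(asvCounts(tab),
                                             labels = perm))
    trainRfOob(rel, mtry = 16, n_trees = 200, seed = s)$kappa
  }, numeric(1))
  expect_lt(abs(median(kappas)), 0.15)
  expect_lt(mean(abs(kappas) >= 0.5), 0.2)
})

test_that("samples without an OOB tree are excluded with a warning", {
  tab <- generateDataset(tinySpec(seed = 10))
  rel <- toRelativeAbundance(tab)
  expect_warning(fit <- trainRfOob(rel, mtry = 5, n_trees = 1, seed = 2),
                 "out-of-bag")
  expect_lt(fit$n_scored, ncol(tab))
})

test_that("degenerate labels are rejected", {
  tab <- generateDataset(tinySpec(seed = 1))
  one <- AsvExperiment(asvCounts(tab), labels = rep("x", ncol(tab)))
  expect_error(trainRfOob(toRelativeAbundance(one), mtry = 5),
               "two classes")
})

test_that("level evaluation yields one record per grid configuration", {
  tab <- generateDataset(tinySpec(seed = 12))
  grid <- buildModelGrid(nrow(tab), base_seed = 7)
  res <- evaluateLevel(tab, grid, n_trees = 150, depth = 500)
  expect_s4_class(res, "ModelGridResult")
  expect_equal(nrow(gridRecords(res)), 21)
  expect_true(all(gridRecords(res)$kappa <= 1))
  expect_equal(as.character(kappaBand(medianKappa(res))),
               "almost_perfect")
  res2 <- evaluateLevel(tab, grid, n_trees = 150, depth = 500)
  expect_identical(gridRecords(res), gridRecords(res2))
  b <- bestModel(res)
  expect_equal(b$kappa, max(gridRecords(res)$kappa))
})

test_that("the minimum-depth walk enforces contiguity from the deepest level", {
  ladder <- c(15177, 12500, 10000, 7500, 5000, 2500, 1000)
  # bands AP AP AP AP AP M M with an AP benchmark -> min depth 5000
  traj <- c(0.9, 0.9, 0.85, 0.88, 0.83, 0.7, 0.65)
  res <- lapply(seq_along(ladder),
                function(i) fakeGrid(rep(traj[i], 3), depth = ladder[i]))
  dec <- minDepthForTarget(fakeGrid(rep(0.9, 3)), res)
  expect_equal(minDepth(dec), 5000)
  expect_equal(dec@benchmarkBand, "almost_perfect")

  # every level AP -> the ladder floor wins
  all_ap <- lapply(seq_along(ladder),
                   function(i) fakeGrid(rep(0.95, 3), depth = ladder[i]))
  expect_equal(minDepth(minDepthForTarget(fakeGrid(rep(0.9, 3)), all_ap)),
               1000)

  # moderate benchmark: levels above the benchmark band also pass,
  # and a poor level breaks the run even if shallower levels recover
  traj2 <- c(0.85, 0.7, 0.65, 0.61, 0.3, 0.7, 0.2)
  res2 <- lapply(seq_along(ladder),
                 function(i) fakeGrid(rep(traj2[i], 3), depth = ladder[i]))
  dec2 <- minDepthForTarget(fakeGrid(rep(0.7, 3)), res2)
  expect_equal(dec2@benchmarkBand, "moderate")
  expect_equal(minDepth(dec2), 7500)

  # deepest level failing -> benchmark not reached
  dec3 <- minDepthForTarget(fakeGrid(rep(0.9, 3)),
                            list(fakeGrid(rep(0.5, 3), depth = 5000)))
  expect_false(dec3@reached)
  expect_true(is.na(minDepth(dec3)))

  expect_error(minDepthForTarget(fakeGrid(0.9), list()), "empty")
  expect_error(minDepthForTarget(
    fakeGrid(0.9),
    list(fakeGrid(0.9, depth = 100), fakeGrid(0.9, depth = 500))),
    "decreasing")
})

test_that("gate choice switches between median and best-model banding", {
  ladder <- c(1000, 500)
  res <- list(fakeGrid(c(0.9, 0.5, 0.5), depth = 1000),
              fakeGrid(c(0.5, 0.5, 0.5), depth = 500))
  full <- fakeGrid(c(0.9, 0.85, 0.88))
  by_median <- minDepthForTarget(full, res, gate = "median")
  expect_false(by_median@reached)           # median 0.5 at 1000 is poor
  by_best <- minDepthForTarget(full, res, gate = "best")
  expect_equal(minDepth(by_best), 1000)     # best model at 1000 is AP
})

test_that("kappa is 1 exactly when the OOB confusion matrix is diagonal", {
  y <- factor(rep(c("a", "b", "c"), each = 4))
  expect_identical(cohenKappa(y, y), 1)
  y2 <- y; y2[1] <- "b"
  expect_lt(cohenKappa(y, y2), 1)
})

test_that("a full sweep on separable data meets its benchmark at the ladder floor", {
  tab <- generateDataset(tinySpec(seed = 20))
  ladder <- new("DepthLadder", levels = c(500L, 200L, 50L),
                includesFull = TRUE)
  sw <- depthSweep(tab, ladder = ladder, n_trees = 150, offsets = -1:1,
                   n_runs = 2, seed = 77)
  expect_s4_class(sw$decision, "DepthDecision")
  expect_equal(nrow(gridRecords(sw$full)), 6)
  expect_equal(sw$decision@benchmarkBand, "almost_perfect")
  expect_equal(minDepth(sw$decision), 50)
  sw2 <- depthSweep(tab, ladder = ladder, n_trees = 150, offsets = -1:1,
                    n_runs = 2, seed = 77)
  expect_identical(levelSummary(sw$decision), levelSummary(sw2$decision))
})
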