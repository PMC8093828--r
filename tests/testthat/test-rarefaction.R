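test_that("ladder starts at the shallowest sample and carries the fixed tail", {
  tail12 <- c(12500, 10000, 7500, 5000, 2500, 1000, 500, 400, 300, 200,
              100, 50)
  tab <- toyTable(rbind(c(15177, 16000, 20000)), labels = c("a", "b", "a"))
  expect_equal(ladderLevels(buildLadder(tab)), c(15177, tail12))

  deep <- toyTable(rbind(c(31000, 40000)), labels = c("a", "b"))
  expect_equal(ladderLevels(buildLadder(deep, cap = 15000)),
               c(15000, tail12))

  # a dataset only modestly deeper than the cap keeps its own minimum
  modest <- toyTable(rbind(c(16501, 18000)), labels = c("a", "b"))
  expect_equal(ladderLevels(buildLadder(modest))[1], 16501)

  exact <- toyTable(rbind(c(15000, 20000)), labels = c("a", "b"))
  lv <- ladderLevels(buildLadder(exact))
  expect_equal(lv, c(15000, tail12))
  expect_equal(anyDuplicated(lv), 0L)

  shallow <- toyTable(rbind(c(2011, 3000)), labels = c("a", "b"))
  expect_equal(ladderLevels(buildLadder(shallow)),
               c(2011, 1000, 500, 400, 300, 200, 100, 50))
  expect_error(buildLadder(toyTable(rbind(c(40, 100)),
                                    labels = c("a", "b"))),
               "smallest ladder level")
})

test_that("rarefied samples sum to depth and never exceed the originals", {
  counts <- c(10, 0, 5)
  expect_identical(rarefySample(counts, 15, seed = 1), c(10L, 0L, 5L))
  expect_identical(rarefySample(counts, sum(counts), seed = 1),
                   c(10L, 0L, 5L))
  for (s in 1:20) {
    x <- rarefySample(c(100, 3, 0, 57, 1), 40, seed = s)
    expect_equal(sum(x), 40)
    expect_true(all(x <= c(100, 3, 0, 57, 1)))
    expect_true(all(x >= 0))
  }
  expect_identical(rarefySample(counts, 8, seed = 7),
                   rarefySample(counts, 8, seed = 7))
  expect_error(rarefySample(c(5, 5), 11, seed = 1), "replacement")
  expect_equal(sum(rarefySample(c(5, 5), 0, seed = 1)), 0)
})

test_that("per-ASV draws match closed-form hypergeometric moments", {
  n <- 10000
  draws <- vapply(seq_len(n),
                  function(s) rarefySample(c(100, 100), 100, seed = s)[1],
                  integer(1))
  # mean 50, variance 100 * 0.5 * 0.5 * (100/199)
  v <- 100 * 0.5 * 0.5 * (100 / 199)
  expect_lt(abs(mean(draws) - 50), 3 * sqrt(v / n))
  expect_lt(abs(var(draws) - v), 4 * v * sqrt(2 / n))
})

test_that("sequential conditional draws match uniform subset draws", {
  counts <- c(40, 7, 0, 23, 2)
  depth <- 30
  n <- 2000
  mine <- rowMeans(vapply(seq_len(n), function(s)
    rarefySample(counts, depth, seed = s), integer(length(counts))))
  set.seed(4242)
  brute <- rowMeans(vapply(seq_len(n), function(s)
    bruteForceRarefy(counts, depth), integer(length(counts))))
  # both estimate depth * counts / total; compare within MC error
  expected <- depth * counts / sum(counts)
  expect_true(all(abs(mine - expected) < 0.3))
  expect_true(all(abs(mine - brute) < 0.45))
})

test_that("table rarefaction preserves structure and is reproducible", {
  tab <- generateDataset(tinySpec(seed = 2))
  r <- rarefyTable(tab, 200, seed = 5)
  expect_true(all(sampleDepths(r) == 200))
  expect_true(all(asvCounts(r) <= asvCounts(tab)))
  expect_identical(classLabels(r), classLabels(tab))
  expect_identical(rownames(r), rownames(tab))
  expect_identical(asvCounts(rarefyTable(tab, 200, seed = 5)),
                   asvCounts(r))
  expect_false(identical(asvCounts(rarefyTable(tab, 200, seed = 6)),
                         asvCounts(r)))
})

test_that("bias-corrected Chao1 matches hand-computed values", {
  # S_obs = 10, f1 = 4, f2 = 2 -> 10 + 4*3/(2*3) = 12
  expect_equal(chao1(c(rep(1, 4), rep(2, 2), rep(5, 4))), 12)
  expect_equal(chao1(c(1, 1, 1)), 6)           # 3 + 3*2/2
  expect_equal(chao1(c(3, 5, 2, 2)), 4)        # f1 = 0 -> S_obs
  expect_error(chao1(integer(0)), "empty")
  expect_error(chao1(c(1, -1)), "non-negative")
})

test_that("Chao1 agrees with the vegan estimator and bounds observed richness", {
  set.seed(31)
  for (i in 1:5) {
    x <- rpois(300, 0.8)
    if (sum(x > 0) == 0) next
    expect_gte(chao1(x), sum(x > 0))
    ref <- unname(vegan::estimateR(x)["S.chao1"])
    expect_equal(chao1(x), ref, tolerance = 1e-8)
  }
})

test_that("coverage fraction is the observed share of the Chao1 estimate", {
  expect_equal(coverageFraction(12, 12), 100)
  expect_equal(coverageFraction(12, 24), 50)
  expect_error(coverageFraction(10, 5), "below the observed")
  expect_error(coverageFraction(0, 5), "observed richness")
})

test_that("coverage against the full-table Chao1 is non-increasing along the ladder", {
  tab <- generateDataset(tinySpec(seed = 4))
  traj <- coverageTrajectory(tab, c(500, 300, 150, 50), seed = 1)
  expect_true(is.na(traj$depth[1]))                 # full model first
  expect_true(all(diff(traj$coverage_pct) <= 1e-9))
  expect_true(all(traj$coverage_pct <= 100))
  expect_equal(traj$coverage_pct[1],
               datasetCoverage(tab)$coverage_pct)   # same full-depth number
})

test_that("analytic rarefaction curve matches identities and oracles", {
  counts <- c(1, 1)
  expect_equal(rarefactionCurve(counts, 1)$expected_richness, 1.0)
  x <- c(10, 5, 2, 1, 0, 30)
  expect_equal(rarefactionCurve(x, sum(x))$expected_richness,
               sum(x > 0))
  # vegan::rarefy implements the same exact expectation
  probes <- c(1, 5, 10, 25, 48)
  mine <- rarefactionCurve(x, probes)$expected_richness
  ref <- as.numeric(vegan::rarefy(x, probes))
  expect_equal(mine, ref, tolerance = 1e-10)
  expect_error(rarefactionCurve(x, sum(x) + 1), "exceeds")
})

test_that("analytic curve matches Monte-Carlo within 3 standard errors", {
  counts <- c(20, 10, 5, 3, 1, 1, 60)
  for (d in c(5, 20, 60)) {
    rich <- vapply(1:800, function(s)
      sum(rarefySample(counts, d, seed = 1000 + s) > 0), integer(1))
    ana <- rarefactionCurve(counts, d)$expected_richness
    se <- sd(rich) / sqrt(length(rich))
    expect_lt(abs(mean(rich) - ana), 3 * max(se, 1e-6))
  }
})

test_that("expected richness is monotone and concave in depth", {
  counts <- c(50, 20, 8, 3, 1, 1, 1, 120)
  d <- seq(0, sum(counts), by = 8)
  e <- rarefactionCurve(counts, d)$expected_richness
  expect_true(all(diff(e) >= -1e-9))
  expect_true(all(diff(diff(e)) <= 1e-9))
})
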