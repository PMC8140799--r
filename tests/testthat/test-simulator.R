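test_that("offsets are uniform on (0, r - 2h) and require r > 2h", {
  cfg <- SimulationConfig()
  d <- sampleOffsets(cfg, seed = 4)
  expect_length(d, 50)
  expect_true(all(d > 0 & d < 3))
  expect_identical(sampleOffsets(cfg, seed = 4), d)
  expect_error(sampleOffsets(SimulationConfig(radiusUm = 5, heightUm = 3)),
               "r > 2h")
  big <- SimulationConfig(cellsPerSection = 1e5)
  expect_equal(mean(sampleOffsets(big, seed = 1)), 1.5, tolerance = 0.02)
})

test_that("per-nucleus volume fraction follows the segment-to-sphere ratio", {
  g <- SectionGeometry(9, 3)
  expect_equal(volumeFraction(0, g), 234 / 972)
  expect_equal(volumeFraction(10, g), 0)
  d <- seq(0, 12, by = 0.25)
  f <- volumeFraction(d, g)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("observed counts are Poisson thinned by the volume fraction", {
  x <- sampleObservedCounts(rep(4, 1e5), rep(0.4, 1e5), seed = 2)
  expect_equal(mean(x), 1.6, tolerance = 0.02)
  expect_equal(var(x), mean(x), tolerance = 0.05)
  expect_true(all(sampleObservedCounts(rep(3, 100), rep(0, 100)) == 0))
})

test_that("overlap merging sums counts, pairs once, and uses the circle union", {
  nuc <- data.frame(offset_um = c(1, 2, 1.5), volume_fraction = 0.2,
                    true_copies = c(4, 4, 4), true_control = 2,
                    observed = c(2L, 3L, 1L), observed_control = c(1L, 2L, 0L),
                    cells = 1L, merged = FALSE, projected_area_um2 = 100)
  g <- SectionGeometry(9, 3)
  out <- mergeOverlaps(nuc, 1, g, seed = 1)
  # first pair merges; the pair is removed from further pairing, and with
  # only one nucleus left no further merge can happen
  expect_equal(nrow(out), 2)
  expect_equal(out$observed[1], 5)
  expect_equal(out$observed_control[1], 3)
  expect_equal(out$cells[1], 2)
  expect_true(out$merged[1])
  expect_identical(mergeOverlaps(nuc, 0, g), nuc)
  # tangent circles: union is exactly two full circles
  expect_equal(sectionFISH:::.twoCircleUnion(9, 18), 2 * pi * 81)
  # coincident circles: union is one circle
  expect_equal(sectionFISH:::.twoCircleUnion(9, 0), pi * 81)
})

test_that("count error perturbs exactly round(|e| C) nuclei with a floor at zero", {
  counts <- rep(2L, 50)
  out <- applyCountError(counts, 0.2, seed = 6)
  expect_equal(sum(out - counts), 10)
  expect_true(all(out - counts >= 0))
  down <- applyCountError(counts, -0.2, seed = 6)
  expect_equal(sum(counts - down), 10)
  expect_identical(applyCountError(counts, 0), counts)
  expect_identical(applyCountError(rep(0L, 30), -1, seed = 1), rep(0L, 30))
})

test_that("simulated sections are reproducible and match the analytic mean", {
  cfg <- SimulationConfig(trueCopies = 6, controlCopies = 2,
                          cellsPerSection = 10000L)
  sec <- simulateSection(cfg, seed = 10)
  expect_identical(sectionNuclei(simulateSection(cfg, seed = 10)),
                   sectionNuclei(sec))
  # analytic E[V_frac] under d ~ Uniform(0, 3) from the quadrature oracle
  ev <- uniformOffsetOracle(9, 3, 3) / (4 / 3 * pi * 9^3)
  expect_equal(mean(sectionNuclei(sec)$observed), 6 * ev, tolerance = 0.03)
  expect_warning(simulateSection(SimulationConfig(trueCopies = 2,
                                                  controlCopies = 2)),
                 "distinct")
})

test_that("subclonal mixtures draw true copies from the ploidy mixture", {
  cfg <- SimulationConfig(cellsPerSection = 5000L,
                          subclones = data.frame(ploidy = c(2, 4),
                                                 fraction = c(0.5, 0.5)))
  sec <- simulateSection(cfg, seed = 3)
  expect_equal(mean(sectionNuclei(sec)$true_copies), 3, tolerance = 0.1)
  expect_setequal(unique(sectionNuclei(sec)$true_copies), c(2, 4))
})

test_that("benchmark grid has the right shape and reproduces itself", {
  res <- runGrid(eValues = 0, pValues = 0, nCtrlValues = 2, nValues = 4,
                 replicates = 10, seed = 11, chainLength = 1000)
  df <- benchmarkResults(res)
  expect_equal(nrow(df), 10 * 3)   # 10 replicates x 3 estimators
  expect_equal(sort(unique(df$replicate)), 1:10)
  res2 <- runGrid(eValues = 0, pValues = 0, nCtrlValues = 2, nValues = 4,
                  replicates = 10, seed = 11, chainLength = 1000)
  expect_identical(benchmarkResults(res2), df)
})

test_that("naive estimator underestimates at the analytic sampling rate", {
  res <- runGrid(eValues = 0, pValues = 0, nCtrlValues = 2, nValues = 8,
                 replicates = 10, seed = 12, chainLength = 1000)
  df <- benchmarkResults(res)
  naive <- df$estimate[df$estimator == "naive"]
  ev <- uniformOffsetOracle(9, 3, 3) / (4 / 3 * pi * 9^3)
  expect_equal(mean(naive), 8 * ev, tolerance = 0.1)
  expect_lt(mean(naive), 8 - 4)
})

test_that("volume-adjusted Poisson estimator recovers the true copy number", {
  # noiseless, non-overlapping sections: mean estimate within one copy of
  # truth for every copy number in the benchmark range
  res <- runGrid(eValues = 0, pValues = 0, nCtrlValues = 2, nValues = 1:10,
                 replicates = 10, seed = 13, chainLength = 2000)
  df <- benchmarkResults(res)
  ff <- df[df$estimator == "frenchfish_manual", ]
  means <- tapply(ff$estimate, ff$n, mean)
  expect_true(all(abs(means - as.numeric(names(means))) <= 1))
})

test_that("diploid-control baseline achieves near-zero error for small n", {
  res <- runGrid(eValues = 0, pValues = 0, nCtrlValues = 2, nValues = 2,
                 replicates = 10, seed = 14, chainLength = 1000)
  s <- summarizeBenchmark(res)
  expect_lt(s$mae[s$estimator == "control_adjusted"], 0.5)
})

test_that("subclonal sections track the ploidy-weighted average copy number", {
  g <- SectionGeometry(9, 3)
  for (fr in c(0.25, 0.5, 0.75)) {
    cfg <- SimulationConfig(subclones = data.frame(ploidy = c(2, 4),
                                                   fraction = c(fr, 1 - fr)))
    wavg <- 2 * fr + 4 * (1 - fr)
    ests <- vapply(1:10, function(s) {
      sec <- simulateSection(cfg, seed = 100 + s)
      sectionEstimates(sec, "frenchfish_manual", chainLength = 2000)
    }, 0)
    expect_equal(mean(ests), wavg, tolerance = 0.45)
  }
})

test_that("error and accuracy metrics follow their definitions", {
  expect_equal(mae(c(2, 2, 4), c(2, 3, 4)), 1 / 3)
  expect_equal(mae(c(1, 2), c(1, 2)), 0)
  expect_equal(accuracy(c(1, 2), c(1, 2)), 1)
  expect_equal(mae(rep(2.4, 10), 2), 0.4)
  expect_equal(accuracy(rep(2.4, 10), 2), 1)
  expect_error(mae(numeric(0), numeric(0)), "no estimates")
})
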