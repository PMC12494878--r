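test_that("field generation validates inputs and reports infeasible density", {
  expect_error(simulateField(simulationParams(nCells = 0)), "nCells")
  p <- simulationParams(fieldShape = c(48L, 48L), nCells = 40,
                        retryPerCell = 10)
  expect_error(simulateField(p), "density")
})

test_that("noiseless focus-free cells render exactly base + background", {
  p <- simulationParams(nCells = 3, noiseSd = 0, fociProb = 0,
                        backgroundLevel = 150, seed = 4)
  fld <- simulateField(p)
  tr <- truthTable(fld)
  for (i in tr$cell_id) {
    px <- greenChannel(fld)[labelMask(fld) == i]
    expect_true(all(px == tr$base_green[i] + 150))
    expect_true(all(redChannel(fld)[labelMask(fld) == i] ==
                      tr$base_red[i] + 150))
  }
  bg <- greenChannel(fld)[labelMask(fld) == 0]
  expect_true(all(bg == 150))
})

test_that("generators are bit-identical under identical params and seed", {
  p <- simulationParams(nCells = 5, seed = 11)
  f1 <- simulateField(p); f2 <- simulateField(p)
  expect_identical(greenChannel(f1), greenChannel(f2))
  expect_identical(redChannel(f1), redChannel(f2))
  expect_identical(truthTable(f1), truthTable(f2))
  pop1 <- simulateDissolutionPopulation(p, 200)
  pop2 <- simulateDissolutionPopulation(p, 200)
  expect_identical(pop1, pop2)
  g1 <- simulateGrowth(0.7, noiseSd = 0.02, seed = 5)
  g2 <- simulateGrowth(0.7, noiseSd = 0.02, seed = 5)
  expect_identical(g1, g2)
})

test_that("cell regions are pairwise disjoint and foci lie inside cells", {
  p <- simulationParams(nCells = 15, fociProb = 1, seed = 9)
  fld <- simulateField(p)
  m <- labelMask(fld)
  tr <- truthTable(fld)
  expect_setequal(setdiff(unique(as.vector(m)), 0L), tr$cell_id)
  for (i in tr$cell_id[tr$has_focus])
    expect_equal(m[tr$focus_r[i], tr$focus_c[i]], i)
})

test_that("a bright spot focus is recovered by puncta detection near truth", {
  p <- simulationParams(nCells = 1, focusPeakFold = 5, fociProb = 1,
                        noiseSd = 0, seed = 21)
  fld <- simulateField(p)
  bg <- estimateBackground(greenChannel(fld), labelMask(fld))
  calls <- detectPuncta(greenChannel(fld), labelMask(fld), bg)
  expect_equal(nrow(calls), 1)
  tr <- truthTable(fld)
  d <- sqrt((calls$centroid_r - tr$focus_r)^2 +
              (calls$centroid_c - tr$focus_c)^2)
  expect_lt(d, 2)
})

test_that("coloc pair generator places shared foci at identical pixels", {
  p <- simulationParams(nCells = 8, noiseSd = 0, seed = 3)
  fld <- simulateColocPair(p, sharedFraction = 1)
  tr <- truthTable(fld)
  expect_true(all(tr$focus_shared))
  expect_identical(tr$focus_r, tr$red_focus_r)
  expect_identical(tr$focus_c, tr$red_focus_c)
  fld0 <- simulateColocPair(simulationParams(nCells = 8, noiseSd = 0,
                                             seed = 3), sharedFraction = 0)
  tr0 <- truthTable(fld0)
  expect_true(all(!tr0$focus_shared))
  d <- sqrt((tr0$focus_r - tr0$red_focus_r)^2 +
              (tr0$focus_c - tr0$red_focus_c)^2)
  expect_true(all(d > 0))
})

test_that("aggregate-mode foci are ratio-independent within binomial bounds", {
  p <- simulationParams(dissolutionMode = "aggregate",
                        aggregateFociProb = 0.4, seed = 17)
  pop <- simulateDissolutionPopulation(p, 10000)
  dec <- cut(rank(pop$ratio_red_green, ties.method = "first"),
             breaks = 10, labels = FALSE)
  bound <- 3 * sqrt(0.4 * 0.6 / 1000)
  for (b in 1:10) {
    frac <- mean(pop$has_focus_true[dec == b])
    expect_lt(abs(frac - 0.4), bound + 0.02)
  }
})

test_that("aggregate-mode decile counts pass a chi-square independence test
           in at least 95% of seeds", {
  notSig <- 0
  nSeeds <- 40
  for (s in seq_len(nSeeds)) {
    p <- simulationParams(dissolutionMode = "aggregate", seed = s)
    pop <- simulateDissolutionPopulation(p, 10000)
    dec <- cut(rank(pop$ratio_red_green, ties.method = "first"),
               breaks = 10, labels = FALSE)
    tab <- table(dec, pop$has_focus_true)
    pval <- suppressWarnings(chisq.test(tab)$p.value)
    if (pval > 0.01) notSig <- notSig + 1
  }
  expect_gte(notSig / nSeeds, 0.95)
})

test_that("infinite dissolution steepness yields a step in focus probability", {
  p <- simulationParams(dissolutionMode = "agglomerate",
                        dissolutionSteepness = 1e9, seed = 2)
  pop <- simulateDissolutionPopulation(p, 2000)
  mid <- exp(mean(log(p$ratioBounds)))
  below <- pop$ratio_red_green < mid
  expect_true(all(pop$has_focus_true[below]))
  expect_true(all(!pop$has_focus_true[!below]))
})

test_that("growth generator hits its closed forms and validates input", {
  g <- simulateGrowth(rPerHour = 0.5, carryingCapacity = Inf, od0 = 0.01,
                      times = seq(0, 600, 30), noiseSd = 0)
  slope <- diff(log2(g$od)) / diff(g$time_min / 60)
  expect_equal(slope, rep(0.5, length(slope)))
  expect_error(simulateGrowth(0.5, od0 = 0), "od0")
  expect_error(simulateGrowth(0.5, carryingCapacity = -1), "capacity")
})

test_that("competition generator follows the selection recursion", {
  cs <- simulateCompetition(0, nCycles = 3, cellsCounted = Inf)
  expect_equal(cs$count_x, rep(0.5, 4))
  cs2 <- simulateCompetition(-0.0034, gPerCycle = 10, nCycles = 4,
                             cellsCounted = Inf)
  f <- attr(cs2, "f_true")
  w <- (1 - 0.0034)^10
  expect_equal(f[2], 0.5 * w / (0.5 * w + 0.5))
  expect_error(simulateCompetition(1.2), "s")
  cs0 <- simulateCompetition(0.01, nCycles = 0)
  expect_equal(nrow(cs0), 1)
  expect_equal(cs0$cycle, 0)
})

test_that("spectra generator oracle integral matches closed forms", {
  s0 <- simulateSpectra(perturbation = "none")
  expect_equal(s0$true_delta, 0)
  expect_identical(s0$wt$ellipticity, s0$mut$ellipticity)
  sOff <- simulateSpectra(perturbation = "offset", offset = 2,
                          offsetRange = c(200, 250))
  expect_equal(sOff$true_delta, 100, tolerance = 1e-3)
  expect_error(simulateSpectra(gridNm = c(200, 199, 201)), "increasing")
})

test_that("abundance generator respects null, missingness and subset checks", {
  expect_error(simulateAbundance(nProteins = 50, deProteins = 60),
               "subset")
  sim <- simulateAbundance(nProteins = 60, missingRate = 0, seed = 2)
  expect_true(all(SummarizedExperiment::assay(sim$experiment, "detected")))
  f <- filterAbundance(sim$experiment)
  rep <- S4Vectors::metadata(f)$filter_report
  expect_equal(rep$removed_detection, 0)
})
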