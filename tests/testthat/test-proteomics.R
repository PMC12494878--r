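mkExperiment <- function(intensity, pept = NULL, group = NULL) {
  if (is.null(pept)) pept <- rep(3L, nrow(intensity))
  if (is.null(group)) group <- rep(c("A", "B"), each = ncol(intensity) / 2)
  if (is.null(rownames(intensity)))
    rownames(intensity) <- sprintf("p%02d", seq_len(nrow(intensity)))
  AbundanceExperiment(intensity, pept, group)
}

test_that("filtering applies the peptide and detection rules inclusively", {
  int <- matrix(100, 3, 6)
  int[2, 1] <- NA            # detected 5/6 = 83% -> kept
  int[3, 1:2] <- NA          # detected 4/6 = 67% -> removed
  ae <- mkExperiment(int, pept = c(1L, 2L, 5L))
  f <- filterAbundance(ae)
  expect_identical(rownames(f), "p02")  # p01 fails peptides, p03 detection
  rep <- S4Vectors::metadata(f)$filter_report
  expect_equal(rep$removed_peptides, 1)
  expect_equal(rep$removed_detection, 1)
  int2 <- matrix(NA_real_, 2, 4)
  int2[, 1] <- 1
  expect_warning(filterAbundance(mkExperiment(int2)), "no proteins")
})

test_that("quantile normalization equalizes sample distributions", {
  int <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  ae <- mkExperiment(int, group = c("A", "B"))
  out <- SummarizedExperiment::assay(quantileNormalize(ae), "intensity")
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))
  # identical columns unchanged
  int2 <- cbind(a = c(5, 1, 9), b = c(5, 1, 9))
  out2 <- SummarizedExperiment::assay(
    quantileNormalize(mkExperiment(int2, group = c("A", "B"))), "intensity")
  expect_equal(unname(out2), unname(int2))
  # postcondition: sorted detected values identical across columns
  set.seed(4)
  int3 <- matrix(rlnorm(60, 10, 1), 10, 6)
  out3 <- SummarizedExperiment::assay(quantileNormalize(mkExperiment(int3)),
                                      "intensity")
  srt <- apply(out3, 2, sort)
  expect_true(all(abs(srt - srt[, 1]) < 1e-9))
  # single sample: identity
  one <- mkExperiment(matrix(c(3, 1, 4), 3, 1), group = "A")
  expect_equal(SummarizedExperiment::assay(quantileNormalize(one),
                                           "intensity"),
               SummarizedExperiment::assay(one, "intensity"))
})

test_that("imputation fills gaps by the documented conventions", {
  int <- matrix(c(10, NA, 12, 8, 9, 10), 2, 3, byrow = TRUE)
  ae <- mkExperiment(int, group = c("A", "A", "B"))
  half <- SummarizedExperiment::assay(imputeAbundance(ae, "half_min"),
                                      "intensity")
  expect_equal(unname(half[1, ]), c(10, 5, 12))
  expect_equal(S4Vectors::metadata(imputeAbundance(ae, "half_min"))$imputation,
               "half_min")
  # no missing entries: identity under either method
  full <- mkExperiment(matrix(1:12, 3, 4))
  expect_equal(SummarizedExperiment::assay(imputeAbundance(full, "knn"),
                                           "intensity"),
               SummarizedExperiment::assay(full, "intensity"))
  # on missing-at-random data knn beats half_min in RMSE against truth
  set.seed(10)
  truthM <- 2^(matrix(rnorm(400, 20, 2), 50, 8) +
                 matrix(rnorm(400, 0, 0.2), 50, 8))
  holes <- matrix(runif(400) < 0.1, 50, 8)
  obs <- truthM; obs[holes] <- NA
  ok <- rowSums(!is.na(obs)) > 0
  ae2 <- mkExperiment(obs[ok, ])
  rmse <- function(m) sqrt(mean((log2(m[holes[ok, ]]) -
                                   log2(truthM[ok, ][holes[ok, ]]))^2))
  knn <- SummarizedExperiment::assay(imputeAbundance(ae2, "knn"),
                                     "intensity")
  hm <- SummarizedExperiment::assay(imputeAbundance(ae2, "half_min"),
                                    "intensity")
  expect_lte(rmse(knn), rmse(hm))
})

test_that("differential testing flags separation and stays null on nulls", {
  int <- 2^rbind(p1 = c(1, 1, 1, 8, 8, 8))
  int <- rbind(int, p2 = rep(100, 6))
  ae <- mkExperiment(int)
  de <- differentialAbundance(ae)
  expect_equal(de$log2_fc[1], -7)
  expect_lt(de$p_value[1], 1e-4)
  expect_equal(de$p_value[2], 1)   # zero variance, equal means
  # identical groups: no hits
  set.seed(3)
  int2 <- matrix(rlnorm(300, 14, 0.3), 50, 6)
  de2 <- differentialAbundance(mkExperiment(int2))
  expect_length(callHits(de2), 0)
  expect_error(differentialAbundance(mkExperiment(int2[, 1:3],
                                                  group = c("A", "A", "B"))),
               "2 samples")
})

test_that("hit calling is strict at the fold cutoff and supports exclusivity", {
  res <- data.frame(protein = c("a", "b", "c"),
                    log2_fc = c(log2(1.68), log2(2), -log2(2)),
                    p_value = 0.001, adj_p = c(0.04, 0.04, 0.04))
  h <- callHits(res)
  expect_setequal(h, c("b", "c"))  # exactly 1.68-fold is not a hit
  resB <- data.frame(protein = c("a", "b", "c"),
                     log2_fc = c(0, log2(2), 0),
                     p_value = 0.5, adj_p = c(1, 0.01, 1))
  ex <- callHits(res, resB, exclusive = TRUE)
  expect_setequal(ex$only_A, "c")  # b is a hit in both contrasts
  expect_length(ex$only_B, 0)
  expect_error(callHits(res, exclusive = TRUE), "two result sets")
})

test_that("fold-2 spikes are fully recovered with bounded false positives", {
  sim <- simulateAbundance(nProteins = 800, deProteins = 1:10, fold = 2,
                           noiseSdLog2 = 0.1, nPerGroup = 6, seed = 5)
  ae <- imputeAbundance(filterAbundance(sim$experiment), method = "knn")
  de <- differentialAbundance(ae)
  hits <- callHits(de)
  kept <- intersect(sim$truth$de_proteins, de$protein)
  expect_true(all(kept %in% hits))
  expect_lte(length(setdiff(hits, kept)), 0.05 * (nrow(de) - length(kept)))
})

test_that("type-I error is controlled under the null", {
  fp <- vapply(1:25, function(s) {
    sim <- simulateAbundance(nProteins = 120, deProteins = integer(),
                             fold = 1, seed = 400 + s)
    de <- differentialAbundance(imputeAbundance(
      filterAbundance(sim$experiment), method = "knn"))
    mean(de$adj_p < 0.05)
  }, numeric(1))
  expect_lte(mean(fp), 0.05 + 3 * sqrt(0.05 * 0.95 / (25 * 100)))
})

test_that("resampling enrichment converges to the exact hypergeometric tail", {
  set.seed(60)
  for (i in 1:5) {
    N <- sample(15:25, 1); K <- sample(4:8, 1); n <- sample(3:6, 1)
    universe <- sprintf("u%02d", 1:N)
    ann <- data.frame(protein = universe[1:K], category = "cat")
    hits <- c(universe[1:2], universe[(K + 1):(K + n - 2)])  # k = 2
    m <- 20000
    res <- bootstrapEnrichment(hits, universe, ann, iterations = m,
                               seed = i)
    pTrue <- enrichmentTailOracle(N, K, n, 2)
    se <- sqrt(pTrue * (1 - pTrue) / m)
    expect_lt(abs(res$p_value - pTrue), 3 * se + 1 / m)
    expect_equal(res$K, K); expect_equal(res$n, n); expect_equal(res$k, 2)
  }
})

test_that("enrichment handles whole-universe categories and the p floor", {
  universe <- sprintf("u%02d", 1:12)
  annAll <- data.frame(protein = universe, category = "everything")
  res <- bootstrapEnrichment(universe[1:4], universe, annAll,
                             iterations = 2000, seed = 2)
  expect_equal(res$p_value, 1)
  # a category that can essentially never reach k by chance hits the floor
  ann1 <- data.frame(protein = universe[1:2], category = "tiny")
  big <- sprintf("x%03d", 1:300)
  resF <- bootstrapEnrichment(universe[1:2], c(universe, big), ann1,
                              iterations = 2000, seed = 3)
  expect_true(resF$at_floor)
  expect_equal(resF$p_value, 1 / 2000)
  expect_error(bootstrapEnrichment(c("zz"), universe, ann1), "subset")
  expect_warning(bootstrapEnrichment(universe[1:2], universe, ann1,
                                     iterations = 500, seed = 1),
                 "resolution")
})

test_that("BH adjustment matches the hand-computed step-up and is monotone", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
  set.seed(8)
  for (i in 1:10) {
    p <- runif(20)
    q <- bhAdjust(p)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # no order inversion
    expect_true(all(q >= p - 1e-12))
  }
})
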