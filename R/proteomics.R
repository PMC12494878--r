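#' Filter an abundance experiment on peptide support and detection
#'
#' Keeps proteins with at least \code{minUniquePeptides} unique peptides
#' that were detected in at least \code{minDetection} of the samples
#' (inclusive: 5/6 = 83\% passes an 80\% cut). A per-criterion removal
#' report is attached as the \code{"filter_report"} metadata entry. An
#' empty result is a warning, not an error.
#'
#' @param x an [AbundanceExperiment-class].
#' @param minUniquePeptides minimum unique peptides (default 2).
#' @param minDetection minimum detection fraction across samples
#'   (default 0.8).
#' @return the filtered \code{AbundanceExperiment}.
#' @export
filterAbundance <- function(x, minUniquePeptides = 2, minDetection = 0.8) {
  stopifnot(is(x, "AbundanceExperiment"))
  pepOK <- uniquePeptides(x) >= minUniquePeptides
  detOK <- detectionRate(x) >= minDetection
  keep <- pepOK & detOK
  if (!any(keep)) warning("no proteins survive the filter")
  out <- x[keep, ]
  S4Vectors::metadata(out)$filter_report <- list(
    n_in = nrow(x), n_out = sum(keep),
    removed_peptides = sum(!pepOK),
    removed_detection = sum(!detOK),
    removed_total = sum(!keep))
  out
}

#' Quantile-normalize sample intensity distributions
#'
#' Standard quantile normalization (rank, then mean of order statistics
#' across samples) on detected values; missing entries stay missing for
#' downstream imputation. Delegates to \code{limma::normalizeQuantiles}.
#' A single-sample table is returned unchanged.
#'
#' @param x an [AbundanceExperiment-class].
#' @return the normalized \code{AbundanceExperiment}.
#' @export
quantileNormalize <- function(x) {
  stopifnot(is(x, "AbundanceExperiment"))
  int <- SummarizedExperiment::assay(x, "intensity")
  if (any(colSums(!is.na(int)) == 0)) stop("a sample has no detected values")
  if (ncol(int) == 1) return(x)
  norm <- limma::normalizeQuantiles(int)
  dimnames(norm) <- dimnames(int)
  SummarizedExperiment::assay(x, "intensity") <- norm
  S4Vectors::metadata(x)$normalized <- "quantile"
  x
}

#' Impute missing intensities
#'
#' \code{half_min}: each missing entry is replaced by half the row minimum
#' of detected values (a left-censoring assumption suited to
#' missing-not-at-random dropout). \code{knn}: each missing entry is the
#' mean over the \code{k} rows most correlated with the target row
#' (pairwise-complete Pearson on log2 intensities) that are detected in
#' that sample. The method used is recorded in the metadata so outputs are
#' identifiable as method-variant.
#'
#' @param x an [AbundanceExperiment-class].
#' @param method "half_min" or "knn".
#' @param k neighbours for knn.
#' @return the imputed \code{AbundanceExperiment} (no remaining NAs).
#' @export
imputeAbundance <- function(x, method = c("half_min", "knn"), k = 5) {
  stopifnot(is(x, "AbundanceExperiment"))
  method <- match.arg(method)
  int <- SummarizedExperiment::assay(x, "intensity")
  if (any(rowSums(!is.na(int)) == 0))
    stop("fully missing row(s); filter the table before imputing")
  if (anyNA(int)) {
    if (method == "half_min") {
      rmin <- apply(int, 1, min, na.rm = TRUE)
      for (i in which(rowSums(is.na(int)) > 0))
        int[i, is.na(int[i, ])] <- rmin[i] / 2
    } else {
      lg <- log2(int)
      rmean <- rowMeans(lg, na.rm = TRUE)
      dev <- lg - rmean  # column deviations, level-free
      cc <- suppressWarnings(cor(t(lg), use = "pairwise.complete.obs"))
      diag(cc) <- -Inf
      cc[is.na(cc)] <- -Inf
      for (i in which(rowSums(is.na(int)) > 0)) {
        ord <- order(cc[i, ], decreasing = TRUE)
        for (j in which(is.na(int[i, ]))) {
          donors <- head(ord[!is.na(lg[ord, j])], k)
          # impute at the target row's own level, borrowing only the
          # donors' deviation in this sample
          int[i, j] <- if (length(donors))
            2^(rmean[i] + mean(dev[donors, j]))
          else 2^rmean[i]
        }
      }
    }
  }
  SummarizedExperiment::assay(x, "intensity") <- int
  S4Vectors::metadata(x)$imputation <- method
  x
}

#' Differential protein abundance between two groups
#'
#' Per protein: log2 fold change of group means on the log2 scale and a
#' two-sided Welch t-test on log2 intensities, with Benjamini-Hochberg
#' adjustment across all tested proteins. This is a plain Welch test, not
#' a moderated (empirical-Bayes) statistic; outputs carry a \code{method}
#' attribute saying so. Proteins with zero variance in both groups and
#' equal means get p = 1 by convention.
#'
#' @param x an imputed [AbundanceExperiment-class] (no NAs).
#' @param groupA,groupB group labels in \code{sampleGroups(x)}; the fold
#'   change is A relative to B.
#' @return data.frame with \code{protein}, \code{log2_fc}, \code{p_value},
#'   \code{adj_p}; attribute \code{method = "welch_t"}.
#' @export
differentialAbundance <- function(x, groupA = "A", groupB = "B") {
  stopifnot(is(x, "AbundanceExperiment"))
  g <- sampleGroups(x)
  ia <- which(g == groupA); ib <- which(g == groupB)
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs at least 2 samples")
  lg <- log2(SummarizedExperiment::assay(x, "intensity"))
  if (anyNA(lg)) stop("impute missing values before testing")
  pv <- numeric(nrow(lg)); fc <- numeric(nrow(lg))
  for (i in seq_len(nrow(lg))) {
    a <- lg[i, ia]; b <- lg[i, ib]
    fc[i] <- mean(a) - mean(b)
    if (sd(a) == 0 && sd(b) == 0) {
      pv[i] <- if (mean(a) == mean(b)) 1 else 0
    } else {
      pv[i] <- tryCatch(t.test(a, b)$p.value, error = function(e) 1)
    }
  }
  out <- data.frame(protein = rownames(lg) %||% as.character(seq_len(nrow(lg))),
                    log2_fc = fc, p_value = pv, adj_p = bhAdjust(pv))
  attr(out, "method") <- "welch_t"
  out
}

#' Call differential-abundance hits
#'
#' A protein is a hit when its fold change strictly exceeds
#' \code{fold}-fold in either direction (\code{|log2FC| > log2(fold)}; a
#' change of exactly \code{fold} is not a hit) and its BH-adjusted p-value
#' is below \code{alpha}. With \code{exclusive = TRUE}, two result sets
#' sharing a protein universe are compared and only hits seen in one
#' contrast and not the other are returned.
#'
#' @param resultsA data.frame from [differentialAbundance()].
#' @param resultsB optional second contrast (required when
#'   \code{exclusive = TRUE}).
#' @param fold linear fold-change threshold (default 1.68).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param exclusive return set differences instead of plain hit sets.
#' @return with \code{exclusive = FALSE}: character vector of hits in
#'   \code{resultsA} (and, if given, \code{hitsB} attribute); with
#'   \code{exclusive = TRUE}: list with \code{only_A} and \code{only_B}.
#' @export
callHits <- function(resultsA, resultsB = NULL, fold = 1.68, alpha = 0.05,
                     exclusive = FALSE) {
  hitSet <- function(res) {
    res$protein[abs(res$log2_fc) > log2(fold) & res$adj_p < alpha]
  }
  if (exclusive) {
    if (is.null(resultsB))
      stop("exclusive hit calling needs two result sets")
    if (!setequal(resultsA$protein, resultsB$protein))
      stop("exclusive hit calling requires a shared protein universe")
    a <- hitSet(resultsA); b <- hitSet(resultsB)
    return(list(only_A = setdiff(a, b), only_B = setdiff(b, a)))
  }
  out <- hitSet(resultsA)
  if (!is.null(resultsB)) attr(out, "hitsB") <- hitSet(resultsB)
  out
}

#' Resampling-based category over-representation test
#'
#' For a hit set of size n drawn from a universe of size N, resamples n
#' proteins without replacement from the universe \code{iterations} times
#' and, for every annotated category with at least one observed hit,
#' estimates the upper-tail p-value as the fraction of iterations in
#' which the resampled category count reached the observed count. All
#' categories are scored against the same joint draws per iteration (the
#' marginals equal the hypergeometric upper tail either way). An
#' estimated p of 0 is reported at the resolution floor 1/iterations,
#' flagged in \code{at_floor}; BH adjustment is applied across the tested
#' categories.
#'
#' @param hits character vector of hit proteins (subset of
#'   \code{universe}).
#' @param universe character vector of all scoreable proteins.
#' @param annotations data.frame with \code{protein} and \code{category}
#'   columns (a protein may appear in any number of categories).
#' @param iterations number of resampling iterations (default 1e6; below
#'   1000 triggers a resolution warning).
#' @param seed integer seed.
#' @return data.frame with \code{category}, \code{k} (observed hits in
#'   category), \code{n} (hit-set size), \code{K} (category size in
#'   universe), \code{N} (universe size), \code{p_value}, \code{adj_p},
#'   \code{at_floor}, \code{iterations}.
#' @export
bootstrapEnrichment <- function(hits, universe, annotations,
                                iterations = 1e6, seed = 1L) {
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  stopifnot(all(c("protein", "category") %in% names(annotations)))
  if (iterations < 1000)
    warning("fewer than 1000 iterations gives poor p-value resolution")
  universe <- unique(universe)
  hits <- unique(hits)
  N <- length(universe); n <- length(hits)
  if (n > N) stop("hit set larger than universe")
  ann <- annotations[annotations$protein %in% universe, , drop = FALSE]
  # membership matrix: universe x category
  cats <- sort(unique(ann$category))
  memb <- matrix(FALSE, N, length(cats), dimnames = list(universe, cats))
  memb[cbind(match(ann$protein, universe), match(ann$category, cats))] <- TRUE
  kObs <- colSums(memb[match(hits, universe), , drop = FALSE])
  test <- which(kObs >= 1)
  if (!length(test))
    return(data.frame(category = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      adj_p = numeric(), at_floor = logical(),
                      iterations = numeric()))
  membT <- memb[, test, drop = FALSE]
  kT <- kObs[test]
  m <- as.integer(iterations)
  hitsGE <- integer(length(test))
  withSeed(childSeed(seed, "enrichment"), {
    chunk <- 10000L
    done <- 0L
    while (done < m) {
      nIt <- min(chunk, m - done)
      # joint draws: one resample of n proteins serves every category
      draws <- vapply(seq_len(nIt),
                      function(i) sample.int(N, n, replace = FALSE),
                      integer(n))
      for (j in seq_along(test)) {
        v <- membT[, j]
        cnt <- colSums(matrix(v[draws], nrow = n))
        hitsGE[j] <- hitsGE[j] + sum(cnt >= kT[j])
      }
      done <- done + nIt
    }
  })
  p <- hitsGE / m
  floorFlag <- p == 0
  p[floorFlag] <- 1 / m
  out <- data.frame(category = cats[test], k = as.integer(kT), n = n,
                    K = as.integer(colSums(memb)[test]), N = N,
                    p_value = p, adj_p = bhAdjust(p),
                    at_floor = floorFlag, iterations = m)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment (sorted p-values scaled by M/rank, running
#' minimum from the largest down, clipped at 1), returned in input order.
#' Delegates to \code{stats::p.adjust(method = "BH")} after validating the
#' inputs.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as input.
#' @export
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
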