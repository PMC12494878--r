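#' Ratio-quantile bins of foci fractions (dissolution assay)
#'
#' Groups cells into \code{nBins} bins at the empirical quantiles of their
#' red/green (wild-type:mutant) intensity ratio — computed per construct,
#' i.e. on the records supplied — and reports the fraction of
#' foci-positive cells per bin with a 95% Wilson score confidence
#' interval. Foci positivity comes from [classifyFociCell()].
#'
#' @param records per-cell records with \code{ratio_red_green} and
#'   \code{ratio_max_median_green} columns.
#' @param nBins number of quantile bins (default 10).
#' @param params a [quantParams()] object.
#' @param conf confidence level for the interval.
#' @param ciMethod "wilson" (default) or "normal".
#' @return data.frame with one row per bin: \code{bin_index},
#'   \code{ratio_lo}, \code{ratio_hi}, \code{n_cells},
#'   \code{foci_fraction}, \code{ci_lo}, \code{ci_hi}.
#' @export
ratioBins <- function(records, nBins = 10, params = quantParams(),
                      conf = 0.95, ciMethod = "wilson") {
  ok <- is.finite(records$ratio_red_green)
  records <- records[ok, , drop = FALSE]
  n <- nrow(records)
  if (n < nBins)
    stop(sprintf(paste0("only %d cells with finite ratios for %d bins; ",
                        "use a smaller nBins"), n, nBins))
  edges <- quantile(records$ratio_red_green,
                    probs = seq(0, 1, length.out = nBins + 1), type = 7,
                    names = FALSE)
  # guard duplicate edges (heavily tied ratios)
  edges[1] <- edges[1] - 1e-9
  bin <- cut(records$ratio_red_green, breaks = unique(edges),
             labels = FALSE, include.lowest = TRUE)
  foci <- classifyFociCell(records, params)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    inb <- bin == b
    ci <- wilsonInterval(sum(foci[inb]), sum(inb), conf = conf,
                         method = ciMethod)
    data.frame(bin_index = b,
               ratio_lo = min(records$ratio_red_green[inb]),
               ratio_hi = max(records$ratio_red_green[inb]),
               n_cells = sum(inb),
               foci_fraction = ci[["fraction"]],
               ci_lo = ci[["lo"]], ci_hi = ci[["hi"]])
  }))
  rownames(out) <- NULL
  out
}

#' Classify a construct on the agglomerate-aggregate continuum
#'
#' The dissolution index is \code{1 - top/bottom}, where \code{bottom} and
#' \code{top} are the pooled foci fractions in the bottom and top terciles
#' of the ratio bins (low ratio = little wild-type subunit), clipped to
#' [-1, 1]. Full dissolution of foci at high wild-type levels gives index
#' 1 (agglomerate); a flat profile gives 0 (aggregate). Default label
#' cuts: agglomerate at index >= 0.8, aggregate at <= 0.2, else
#' intermediate. This quantitative rule is this package's formalization of
#' a call usually made by inspection; the cuts are configurable.
#'
#' @param bins output of [ratioBins()].
#' @param agglomerateMin,aggregateMax index cutoffs for the two labels.
#' @param minCellsPerTercile minimum pooled cells required in each tercile.
#' @return list with \code{label} ("agglomerate", "aggregate",
#'   "intermediate"), \code{dissolution_index}, \code{baseline_fraction}
#'   (bottom tercile), \code{top_fraction}, and \code{flagged} (TRUE when
#'   the bottom-tercile fraction is 0 and the index is undefined).
#' @export
dissolutionCall <- function(bins, agglomerateMin = 0.8, aggregateMax = 0.2,
                            minCellsPerTercile = 10) {
  nb <- nrow(bins)
  if (nb < 3) stop("need at least 3 bins")
  t1 <- bins[seq_len(floor(nb / 3)), , drop = FALSE]
  t3 <- bins[(nb - floor(nb / 3) + 1):nb, , drop = FALSE]
  if (sum(t1$n_cells) < minCellsPerTercile ||
      sum(t3$n_cells) < minCellsPerTercile)
    stop("need at least ", minCellsPerTercile, " cells in each tercile")
  bottom <- sum(t1$foci_fraction * t1$n_cells) / sum(t1$n_cells)
  top <- sum(t3$foci_fraction * t3$n_cells) / sum(t3$n_cells)
  if (bottom == 0) {
    return(list(label = "intermediate", dissolution_index = NA_real_,
                baseline_fraction = bottom, top_fraction = top,
                flagged = TRUE))
  }
  idx <- max(-1, min(1, 1 - top / bottom))
  label <- if (idx >= agglomerateMin) "agglomerate"
           else if (idx <= aggregateMax) "aggregate"
           else "intermediate"
  list(label = label, dissolution_index = idx,
       baseline_fraction = bottom, top_fraction = top, flagged = FALSE)
}

#' Intersection-over-union co-localization score for one cell
#'
#' For each channel the \code{ceiling(topFraction * area)} brightest pixels
#' inside the cell mask are selected (ties at the cutoff broken by
#' deterministic raster order: ascending row, then column); the score is
#' the Jaccard index |A∩B|/|A∪B| of the two pixel sets. The score is
#' rank-based, hence invariant under any strictly monotone intensity
#' transform of either channel. Cells sharing a focus across channels
#' typically score above 0.45; unrelated channels typically score below
#' 0.3 (reported as annotations, not used as filters).
#'
#' @param green,red intensity matrices.
#' @param cellMask logical matrix (or 0/1) selecting the cell's pixels.
#' @param topFraction fraction of brightest pixels per channel.
#' @return list with \code{score} in [0,1] (NA when a channel is constant
#'   inside the mask), \code{n_top_pixels}, and \code{status} ("ok" or
#'   "NA_no_signal").
#' @export
colocScore <- function(green, red, cellMask, topFraction = 0.10) {
  stopifnot(identical(dim(green), dim(red)),
            identical(dim(green), dim(cellMask)),
            topFraction > 0, topFraction < 1)
  sel <- which(cellMask > 0)
  if (!length(sel)) stop("cell mask is empty")
  g <- green[sel]; r <- red[sel]
  if (diff(range(g)) == 0 || diff(range(r)) == 0)
    return(list(score = NA_real_, n_top_pixels = NA_integer_,
                status = "NA_no_signal"))
  k <- ceiling(topFraction * length(sel))
  # raster (row-major) order for deterministic tie-breaks
  rows <- (sel - 1L) %% nrow(green) + 1L
  cols <- (sel - 1L) %/% nrow(green) + 1L
  topSet <- function(v) sel[order(-v, rows, cols)][seq_len(k)]
  A <- topSet(g); B <- topSet(r)
  list(score = length(intersect(A, B)) / length(union(A, B)),
       n_top_pixels = k, status = "ok")
}

#' Score co-localization for every cell of a field
#'
#' Applies [colocScore()] within each labelled cell of a
#' [FluorField-class].
#'
#' @param field a \code{FluorField}.
#' @param topFraction passed to [colocScore()].
#' @return data.frame with \code{cell_id}, \code{score},
#'   \code{n_top_pixels}, \code{status}.
#' @export
colocScoreField <- function(field, topFraction = 0.10) {
  stopifnot(is(field, "FluorField"))
  labs <- setdiff(sort(unique(as.vector(labelMask(field)))), 0L)
  do.call(rbind, lapply(labs, function(lb) {
    cs <- colocScore(greenChannel(field), redChannel(field),
                     labelMask(field) == lb, topFraction)
    data.frame(cell_id = lb, score = cs$score,
               n_top_pixels = cs$n_top_pixels, status = cs$status)
  }))
}

#' Strain-level co-localization summary
#'
#' Mean co-localization score over foci-positive cells of one
#' query-construct / library-marker pair. Pairs where no cell has usable
#' signal report \code{NA_no_signal}; pairs with fewer than
#' \code{minCellsPerStrain} usable foci-positive cells report
#' \code{NA_too_few_cells}.
#'
#' @param colocResults data.frame from [colocScoreField()] (or compatible:
#'   cell_id, score, status).
#' @param fociFlags logical vector parallel to \code{colocResults} rows,
#'   TRUE for foci-positive cells (e.g. from [classifyFociCell()]).
#' @param params a [quantParams()] object (uses \code{minCellsPerStrain}).
#' @return list with \code{mean_score}, \code{n_cells_used},
#'   \code{status} in \{"ok", "NA_too_few_cells", "NA_no_signal"\}.
#' @export
strainPairSummary <- function(colocResults, fociFlags,
                              params = quantParams()) {
  stopifnot(nrow(colocResults) == length(fociFlags))
  if (nrow(colocResults) == 0 || all(colocResults$status == "NA_no_signal"))
    return(list(mean_score = NA_real_, n_cells_used = 0L,
                status = "NA_no_signal"))
  usable <- fociFlags & colocResults$status == "ok" &
    !is.na(colocResults$score)
  if (sum(usable) < params$minCellsPerStrain)
    return(list(mean_score = NA_real_, n_cells_used = sum(usable),
                status = "NA_too_few_cells"))
  list(mean_score = mean(colocResults$score[usable]),
       n_cells_used = sum(usable), status = "ok")
}

#' Hierarchically cluster a constructs-by-markers score matrix
#'
#' Average-linkage agglomerative clustering on Euclidean distances
#' computed over pairwise-complete entries (as in \code{stats::dist});
#' pairs of rows (or columns) sharing no non-NA entry are assigned the
#' maximal finite distance observed. Leaf order is the deterministic
#' \code{stats::hclust} order.
#'
#' @param mat numeric matrix (constructs x markers), NAs allowed.
#' @return list with \code{row_order}, \code{col_order} (integer
#'   permutations), \code{row_tree}, \code{col_tree} (hclust objects).
#' @export
clusterMatrix <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) < 2 || ncol(mat) < 2)
    stop("need a matrix with at least 2 rows and 2 columns")
  if (all(is.na(mat))) stop("matrix is all NA")
  clusterOne <- function(m) {
    d <- as.matrix(stats::dist(m))  # pairwise-complete with rescaling
    if (all(!is.finite(d[upper.tri(d)])))
      stop("no pair of rows shares a non-NA entry")
    mx <- max(d[upper.tri(d)][is.finite(d[upper.tri(d)])])
    d[!is.finite(d)] <- mx
    stats::hclust(as.dist(d), method = "average")
  }
  rt <- clusterOne(mat)
  ct <- clusterOne(t(mat))
  list(row_order = rt$order, col_order = ct$order,
       row_tree = rt, col_tree = ct)
}
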