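#' Quantification parameters for puncta detection and classification
#'
#' Defaults follow the imaging workflow this package implements: a focus
#' pixel must be at least 2.5-fold above its cell's median intensity AND at
#' least 100 AU above the field background; only the largest connected
#' candidate region per cell is kept; regions with circularity above 0.4
#' pass the shape filter (discs pass, long filaments fail); a cell is
#' called foci-positive when its max/median green ratio strictly exceeds
#' 2.5; co-localization uses the top 10% brightest pixels; strain-level
#' co-localization summaries require at least 20 qualifying cells.
#'
#' @param fociFoldThreshold multiplicative intensity threshold relative to
#'   the cell median (pixel candidacy, inclusive: \code{>=}).
#' @param backgroundMarginAU additive threshold above the background
#'   estimate (AU, inclusive).
#' @param circularityMin circularity cut for \code{passed_circularity}.
#' @param fociRatioThreshold max/median ratio above which a cell is
#'   classified foci-positive (strict: \code{>}).
#' @param colocTopFraction fraction of brightest pixels per channel used by
#'   the co-localization score, in (0, 1).
#' @param minCellsPerStrain minimum foci-positive cells for a strain-level
#'   co-localization mean.
#' @param connectivity pixel connectivity for candidate components, 4 or 8.
#' @param minCellArea minimum region area (px) retained by segmentation.
#' @return validated list of class \code{"QuantParams"}.
#' @export
quantParams <- function(fociFoldThreshold = 2.5, backgroundMarginAU = 100,
                        circularityMin = 0.4, fociRatioThreshold = 2.5,
                        colocTopFraction = 0.10, minCellsPerStrain = 20,
                        connectivity = 8, minCellArea = 30) {
  stopifnot(fociFoldThreshold > 0, backgroundMarginAU > 0,
            circularityMin > 0, fociRatioThreshold > 0,
            colocTopFraction > 0, colocTopFraction < 1,
            minCellsPerStrain > 0, connectivity %in% c(4, 8),
            minCellArea >= 1)
  structure(list(fociFoldThreshold = fociFoldThreshold,
                 backgroundMarginAU = backgroundMarginAU,
                 circularityMin = circularityMin,
                 fociRatioThreshold = fociRatioThreshold,
                 colocTopFraction = colocTopFraction,
                 minCellsPerStrain = minCellsPerStrain,
                 connectivity = connectivity,
                 minCellArea = minCellArea),
            class = "QuantParams")
}

#' Segment cells from a single-channel image
#'
#' Global Otsu threshold, hole filling, connected-component labelling and a
#' minimum-area filter; labels are relabelled 1..K in raster order. A
#' user-supplied external label mask bypasses segmentation entirely and is
#' validated and returned unchanged.
#'
#' @param image 2-D numeric intensity matrix.
#' @param params a [quantParams()] object.
#' @param mask optional externally produced label mask (integer matrix,
#'   0 = background); returned as-is after validation.
#' @return integer label mask (0 = background).
#' @export
segmentCells <- function(image, params = quantParams(), mask = NULL) {
  if (!is.null(mask)) {
    if (!is.matrix(mask) || any(mask < 0) || any(mask != round(mask)))
      stop("external mask must be a matrix of non-negative integer labels")
    storage.mode(mask) <- "integer"
    return(mask)
  }
  if (!is.matrix(image)) stop("image must be a 2-D matrix")
  rng <- range(image)
  if (diff(rng) == 0) return(matrix(0L, nrow(image), ncol(image)))
  sc <- (image - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(sc), range = c(0, 1))
  bin <- sc > thr
  if (!any(bin)) return(matrix(0L, nrow(image), ncol(image)))
  bin <- EBImage::fillHull(EBImage::Image(bin * 1))
  lab <- labelComponents(as.matrix(bin) > 0, connectivity = 4)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= params$minCellArea)
  out <- matrix(0L, nrow(image), ncol(image))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

#' Estimate the field background intensity
#'
#' Median intensity of all background (label 0) pixels. "Background" is
#' defined per field; an even count of pixels uses the usual convention of
#' the mean of the two central order statistics.
#'
#' @param image 2-D intensity matrix.
#' @param mask label mask of identical dimensions.
#' @return background level (AU).
#' @export
estimateBackground <- function(image, mask) {
  stopifnot(identical(dim(image), dim(mask)))
  bg <- image[mask == 0]
  if (!length(bg)) stop("mask has no background pixels")
  median(bg)
}

#' Per-cell intensity statistics for both channels
#'
#' One record per nonzero label: area, median/mean/min/max and the nine
#' deciles (10th..90th percentile, linear interpolation, \code{quantile}
#' type 7) per channel, the red/green median ratio, and the max/median
#' green ratio used by the foci classifier. Cells whose green median is 0
#' get \code{Inf} ratios and are flagged.
#'
#' @param green,red intensity matrices (AU).
#' @param mask label mask of identical dimensions.
#' @return data.frame of per-cell records, one row per label present in
#'   the mask.
#' @export
cellStats <- function(green, red, mask) {
  if (!identical(dim(green), dim(red)) || !identical(dim(green), dim(mask)))
    stop("green, red and mask must have identical dimensions")
  inCell <- mask > 0
  labs <- mask[inCell]
  if (!length(labs)) return(data.frame())
  gs <- split(green[inCell], labs)
  rs <- split(red[inCell], labs)
  chanStats <- function(v, prefix) {
    dec <- quantile(v, probs = seq(0.1, 0.9, by = 0.1), type = 7,
                    names = FALSE)
    out <- c(median(v), mean(v), min(v), max(v), dec)
    names(out) <- paste0(prefix, c("median", "mean", "min", "max",
                                    paste0("p", seq(10, 90, 10))))
    out
  }
  rows <- lapply(seq_along(gs), function(i) {
    g <- chanStats(gs[[i]], "green_")
    r <- chanStats(rs[[i]], "red_")
    medG <- g[["green_median"]]
    data.frame(cell_id = as.integer(names(gs)[i]),
               area_px = length(gs[[i]]),
               as.list(g), as.list(r),
               ratio_red_green = if (medG > 0)
                 r[["red_median"]] / medG else Inf,
               ratio_max_median_green = if (medG > 0)
                 g[["green_max"]] / medG else Inf,
               ratio_flagged = medG <= 0)
  })
  out <- do.call(rbind, rows)
  out[order(out$cell_id), , drop = FALSE]
}

#' Detect the largest punctum or filament in each cell
#'
#' Per cell: (1) the cell's median intensity is computed; (2) candidate
#' pixels are those with intensity at least
#' \code{max(fociFoldThreshold * median, background + backgroundMarginAU)}
#' — both conditions must hold; (3) candidates are split into connected
#' components (connectivity from \code{params}); (4) only the largest
#' component is kept, ties broken deterministically by lowest minimum row,
#' then lowest minimum column; (5) circularity \eqn{4\pi A / P^2} is
#' computed with a weighted boundary-length estimator (regions of 1-2
#' pixels are assigned circularity 1.0 by convention). Cells with no
#' candidate pixel yield no call.
#'
#' @param image intensity matrix of the channel to analyse (AU).
#' @param mask label mask.
#' @param background field background estimate (AU), e.g. from
#'   [estimateBackground()]; must be finite.
#' @param params a [quantParams()] object.
#' @return data.frame with one row per detected focus: \code{cell_id},
#'   \code{area_px}, \code{centroid_r}, \code{centroid_c} (1-based),
#'   \code{mean_AU}, \code{peak_AU}, \code{circularity},
#'   \code{passed_circularity}, and a list-column \code{pixels} of 2-column
#'   (row, col) matrices.
#' @export
detectPuncta <- function(image, mask, background, params = quantParams()) {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask must have identical dimensions")
  if (!is.finite(background)) stop("background must be finite")
  labs <- setdiff(sort(unique(as.vector(mask))), 0L)
  calls <- list()
  for (lb in labs) {
    sel <- mask == lb
    vals <- image[sel]
    med <- median(vals)
    thr <- max(params$fociFoldThreshold * med,
               background + params$backgroundMarginAU)
    cand <- sel & image >= thr
    if (!any(cand)) next
    # work in the candidate bounding box to keep labelling cheap
    w <- which(cand, arr.ind = TRUE)
    r0 <- min(w[, 1]); r1 <- max(w[, 1])
    c0 <- min(w[, 2]); c1 <- max(w[, 2])
    sub <- cand[r0:r1, c0:c1, drop = FALSE]
    comp <- labelComponents(sub, connectivity = params$connectivity)
    sizes <- tabulate(comp[comp > 0])
    best <- which(sizes == max(sizes))
    if (length(best) > 1) {
      # lowest min-row, then lowest min-col, in absolute coordinates
      key <- vapply(best, function(b) {
        ww <- which(comp == b, arr.ind = TRUE)
        c(min(ww[, 1]), min(ww[, 2]))
      }, numeric(2))
      best <- best[order(key[1, ], key[2, ])[1]]
    }
    pix <- which(comp == best, arr.ind = TRUE)
    pix[, 1] <- pix[, 1] + r0 - 1L
    pix[, 2] <- pix[, 2] + c0 - 1L
    colnames(pix) <- c("row", "col")
    region <- matrix(FALSE, nrow(image), ncol(image))
    region[pix] <- TRUE
    circ <- regionCircularity(region[max(1, r0 - 1):min(nrow(image), r1 + 1),
                                     max(1, c0 - 1):min(ncol(image), c1 + 1),
                                     drop = FALSE])
    v <- image[pix]
    calls[[length(calls) + 1L]] <- data.frame(
      cell_id = lb, area_px = nrow(pix),
      centroid_r = mean(pix[, 1]), centroid_c = mean(pix[, 2]),
      mean_AU = mean(v), peak_AU = max(v),
      circularity = circ,
      passed_circularity = circ > params$circularityMin)
    calls[[length(calls)]]$pixels <- I(list(pix))
  }
  if (!length(calls))
    return(data.frame(cell_id = integer(), area_px = integer(),
                      centroid_r = numeric(), centroid_c = numeric(),
                      mean_AU = numeric(), peak_AU = numeric(),
                      circularity = numeric(),
                      passed_circularity = logical()))
  do.call(rbind, calls)
}

#' Classify cells as foci-positive from their max/median ratio
#'
#' A cell contains a punctum or filament when its max/median green ratio
#' strictly exceeds the threshold (default 2.5); a ratio of exactly 2.5 is
#' negative. Cells with zero median (infinite ratio) classify positive and
#' carry a flag.
#'
#' @param records data.frame of cell records with a
#'   \code{ratio_max_median_green} column (from [cellStats()] or the
#'   population generator).
#' @param params a [quantParams()] object.
#' @return logical vector, one element per record row.
#' @export
#' @examples
#' classifyFociCell(data.frame(ratio_max_median_green = c(2.5, 2.51)))
classifyFociCell <- function(records, params = quantParams()) {
  stopifnot("ratio_max_median_green" %in% names(records))
  r <- records$ratio_max_median_green
  flagged <- is.infinite(r)
  if (any(flagged))
    warning(sum(flagged), " cell(s) with zero median classified positive ",
            "(infinite ratio)")
  r > params$fociRatioThreshold
}
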