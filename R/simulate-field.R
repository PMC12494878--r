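#' Parameters for the synthetic microscopy and population generators
#'
#' Bundles and validates every knob of the synthetic-data module. Cells are
#' rendered as non-touching ellipses with log-normal base intensity (the
#' intensity distribution of real cells is not established; log-normal is an
#' assumption, flagged as such in the vignette). Foci are 2-D Gaussian spots
#' or anisotropic Gaussian ridges (filaments) whose peak is
#' \code{focusPeakFold} times the cell's base intensity.
#'
#' @param fieldShape integer length-2, field size in pixels (rows, cols).
#' @param nCells number of cells to place (>= 1 for [simulateField()]).
#' @param backgroundLevel background intensity (AU, >= 0).
#' @param noiseSd additive Gaussian read-noise SD (AU, >= 0).
#' @param ratioBounds length-2, bounds of the log-uniform red/green
#'   intensity-ratio distribution.
#' @param dissolutionMode one of "agglomerate", "aggregate", "intermediate":
#'   whether focus probability falls with the wild-type:mutant (red/green)
#'   ratio, is flat, or falls partially with dimmer foci.
#' @param dissolutionSteepness logistic slope (on log-ratio) of the
#'   dissolution response; larger = sharper switch.
#' @param aggregateFociProb constant focus probability in aggregate mode.
#' @param fociProb probability a cell carries a focus in [simulateField()].
#' @param focusKind "spot", "filament" or "mixed".
#' @param focusPeakFold peak intensity of a focus as a multiple of the cell
#'   base intensity (>= 1).
#' @param filamentAspect aspect ratio of filament ridges (>= 4 so that the
#'   circularity filter at 0.4 can be exercised on both sides).
#' @param cellAxesRange length-2, range of ellipse semi-axes in px.
#' @param baseIntensity median of the log-normal base green intensity (AU).
#' @param baseSdLog log-scale SD of the base intensity.
#' @param retryPerCell placement attempts allowed per cell before the
#'   generator reports that the requested density is infeasible.
#' @param seed integer global seed; each operation derives its own child
#'   seed via [childSeed()].
#' @return a validated list of class \code{"SimulationParams"}.
#' @export
#' @examples
#' p <- simulationParams(nCells = 4, seed = 7)
#' fld <- simulateField(p)
simulationParams <- function(fieldShape = c(192L, 192L),
                             nCells = 12,
                             backgroundLevel = 200,
                             noiseSd = 10,
                             ratioBounds = c(0.25, 4),
                             dissolutionMode = c("agglomerate", "aggregate",
                                                 "intermediate"),
                             dissolutionSteepness = 3,
                             aggregateFociProb = 0.4,
                             fociProb = 0.5,
                             focusKind = c("spot", "filament", "mixed"),
                             focusPeakFold = 5,
                             filamentAspect = 6,
                             cellAxesRange = c(5, 9),
                             baseIntensity = 1000,
                             baseSdLog = 0.3,
                             retryPerCell = 200,
                             seed = 1L) {
  dissolutionMode <- match.arg(dissolutionMode)
  focusKind <- match.arg(focusKind)
  stopifnot(length(fieldShape) == 2, all(fieldShape >= 16),
            backgroundLevel >= 0, noiseSd >= 0,
            length(ratioBounds) == 2, all(ratioBounds > 0),
            ratioBounds[1] < ratioBounds[2],
            dissolutionSteepness >= 0,
            aggregateFociProb >= 0, aggregateFociProb <= 1,
            fociProb >= 0, fociProb <= 1,
            focusPeakFold >= 1, filamentAspect >= 4,
            length(cellAxesRange) == 2, cellAxesRange[1] >= 2,
            cellAxesRange[1] <= cellAxesRange[2],
            baseIntensity > 0, baseSdLog >= 0, retryPerCell >= 1)
  structure(list(fieldShape = as.integer(fieldShape), nCells = nCells,
                 backgroundLevel = backgroundLevel, noiseSd = noiseSd,
                 ratioBounds = ratioBounds, dissolutionMode = dissolutionMode,
                 dissolutionSteepness = dissolutionSteepness,
                 aggregateFociProb = aggregateFociProb,
                 fociProb = fociProb, focusKind = focusKind,
                 focusPeakFold = focusPeakFold,
                 filamentAspect = filamentAspect,
                 cellAxesRange = cellAxesRange,
                 baseIntensity = baseIntensity, baseSdLog = baseSdLog,
                 retryPerCell = retryPerCell, seed = as.integer(seed)),
            class = "SimulationParams")
}

# pixel set of an ellipse: list(r=, c=) of 1-based coordinates inside field
ellipsePixels <- function(centre, axes, theta, shape) {
  a <- axes[1]; b <- axes[2]
  ext <- ceiling(max(a, b)) + 1L
  rs <- max(1L, floor(centre[1] - ext)):min(shape[1], ceiling(centre[1] + ext))
  cs <- max(1L, floor(centre[2] - ext)):min(shape[2], ceiling(centre[2] + ext))
  gr <- expand.grid(r = rs, c = cs)
  dr <- gr$r - centre[1]; dc <- gr$c - centre[2]
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  list(r = gr$r[keep], c = gr$c[keep])
}

# place nCells non-overlapping ellipses; returns geometry or errors with a
# message naming the density when the retry budget is exhausted
placeCells <- function(params) {
  shape <- params$fieldShape
  occupied <- matrix(FALSE, shape[1], shape[2])
  cells <- vector("list", params$nCells)
  for (i in seq_len(params$nCells)) {
    placed <- FALSE
    for (try in seq_len(params$retryPerCell)) {
      axes <- sort(runif(2, params$cellAxesRange[1], params$cellAxesRange[2]),
                   decreasing = TRUE)
      theta <- runif(1, 0, pi)
      margin <- ceiling(axes[1]) + 2L
      if (shape[1] <= 2 * margin || shape[2] <= 2 * margin)
        stop("field too small for the requested cell sizes")
      centre <- c(runif(1, margin + 1, shape[1] - margin),
                  runif(1, margin + 1, shape[2] - margin))
      # demand one pixel of clearance so labelled cells never touch
      px <- ellipsePixels(centre, axes + 1, theta, shape)
      if (!any(occupied[cbind(px$r, px$c)])) {
        core <- ellipsePixels(centre, axes, theta, shape)
        occupied[cbind(px$r, px$c)] <- TRUE
        cells[[i]] <- list(centre = centre, axes = axes, theta = theta,
                           pixels = core)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf(paste0(
        "could not place cell %d of %d after %d attempts: requested density",
        " (%d cells in a %dx%d field) is too high"),
        i, params$nCells, params$retryPerCell, params$nCells,
        shape[1], shape[2]))
  }
  cells
}

# additive focus profile over given cell pixels; peak = (fold-1) * base
focusProfile <- function(kind, centre, theta, px, base, fold, aspect) {
  dr <- px$r - centre[1]; dc <- px$c - centre[2]
  if (kind == "spot") {
    s <- 1.8
    g <- exp(-(dr^2 + dc^2) / (2 * s^2))
  } else {
    sMin <- 1.2; sMaj <- aspect * sMin
    u <- dr * cos(theta) + dc * sin(theta)
    v <- -dr * sin(theta) + dc * cos(theta)
    g <- exp(-(u^2 / (2 * sMaj^2) + v^2 / (2 * sMin^2)))
  }
  base * (fold - 1) * g
}

#' Simulate a two-channel fluorescence field with known ground truth
#'
#' Places \code{nCells} non-touching ellipses, assigns each a log-normal
#' base green intensity and a log-uniform red/green ratio, optionally adds a
#' Gaussian spot or filament focus with peak \code{focusPeakFold} times the
#' base intensity, then adds a flat background and Gaussian read noise.
#' With \code{noiseSd = 0} and no foci every cell pixel equals base
#' intensity + background exactly.
#'
#' @param params a [simulationParams()] object with \code{nCells >= 1}.
#' @param fociChannel channel(s) that receive foci: "green" (default) or
#'   "both" (same location, used by the co-localization generator).
#' @return a [FluorField-class]; the truth table has one row per cell with
#'   1-based centre coordinates, semi-axes, base intensities, focus
#'   presence/kind/peak-fold and 1-based focus coordinates.
#' @export
simulateField <- function(params, fociChannel = c("green", "both")) {
  stopifnot(inherits(params, "SimulationParams"))
  fociChannel <- match.arg(fociChannel)
  if (params$nCells < 1) stop("nCells must be >= 1")
  withSeed(childSeed(params$seed, "field"), {
    shape <- params$fieldShape
    cells <- placeCells(params)
    n <- length(cells)
    baseG <- rlnorm(n, log(params$baseIntensity), params$baseSdLog)
    ratio <- exp(runif(n, log(params$ratioBounds[1]),
                       log(params$ratioBounds[2])))
    baseR <- baseG * ratio
    hasFocus <- runif(n) < params$fociProb
    kinds <- ifelse(!hasFocus, "none",
                    switch(params$focusKind,
                           mixed = sample(c("spot", "filament"), n, TRUE),
                           params$focusKind))
    green <- matrix(0, shape[1], shape[2])
    red <- matrix(0, shape[1], shape[2])
    mask <- matrix(0L, shape[1], shape[2])
    truth <- data.frame(cell_id = seq_len(n),
                        center_r = NA_real_, center_c = NA_real_,
                        axis_major = NA_real_, axis_minor = NA_real_,
                        base_green = baseG, base_red = baseR,
                        ratio_red_green = ratio,
                        has_focus = hasFocus, focus_kind = kinds,
                        focus_peak_fold = ifelse(hasFocus,
                                                 params$focusPeakFold, NA),
                        focus_r = NA_real_, focus_c = NA_real_,
                        focus_shared = fociChannel == "both" & hasFocus)
    for (i in seq_len(n)) {
      cl <- cells[[i]]
      idx <- cbind(cl$pixels$r, cl$pixels$c)
      mask[idx] <- i
      green[idx] <- green[idx] + baseG[i]
      red[idx] <- red[idx] + baseR[i]
      truth$center_r[i] <- cl$centre[1]; truth$center_c[i] <- cl$centre[2]
      truth$axis_major[i] <- cl$axes[1]; truth$axis_minor[i] <- cl$axes[2]
      if (hasFocus[i]) {
        dr <- cl$pixels$r - cl$centre[1]; dc <- cl$pixels$c - cl$centre[2]
        if (kinds[i] == "filament") {
          # filaments span the cell: anchor at the cell centre
          j <- which.min(dr^2 + dc^2)
        } else {
          # spots are drawn from the inner half of the cell
          u <- dr * cos(cl$theta) + dc * sin(cl$theta)
          v <- -dr * sin(cl$theta) + dc * cos(cl$theta)
          inner <- which((u / cl$axes[1])^2 + (v / cl$axes[2])^2 <= 0.25)
          if (!length(inner)) inner <- seq_along(cl$pixels$r)
          j <- inner[sample.int(length(inner), 1)]
        }
        fc <- c(cl$pixels$r[j], cl$pixels$c[j])
        truth$focus_r[i] <- fc[1]; truth$focus_c[i] <- fc[2]
        prof <- focusProfile(kinds[i], fc, cl$theta, cl$pixels, baseG[i],
                             params$focusPeakFold, params$filamentAspect)
        green[idx] <- green[idx] + prof
        if (fociChannel == "both")
          red[idx] <- red[idx] + prof * ratio[i]
      }
    }
    green <- green + params$backgroundLevel
    red <- red + params$backgroundLevel
    if (params$noiseSd > 0) {
      green <- green + rnorm(length(green), 0, params$noiseSd)
      red <- red + rnorm(length(red), 0, params$noiseSd)
    }
    FluorField(green, red, mask, truth)
  })
}

#' Simulate a two-channel field with a stated fraction of shared foci
#'
#' Every cell carries one green focus; a fraction \code{sharedFraction} of
#' cells place the red focus at the identical pixel coordinates (shared),
#' the remainder place it independently at least \code{minSeparation} px
#' away (unshared). Used to exercise the intersection-over-union
#' co-localization score on both ends of its range.
#'
#' @param params a [simulationParams()] object.
#' @param sharedFraction fraction of cells whose foci are shared, in [0,1].
#' @param minSeparation minimum distance (px) between unshared foci.
#' @return a [FluorField-class]; truth gains columns \code{focus_shared},
#'   \code{red_focus_r}, \code{red_focus_c}.
#' @export
simulateColocPair <- function(params, sharedFraction = 0.5,
                              minSeparation = 6) {
  stopifnot(inherits(params, "SimulationParams"),
            sharedFraction >= 0, sharedFraction <= 1)
  withSeed(childSeed(params$seed, "coloc"), {
    shape <- params$fieldShape
    cells <- placeCells(params)
    n <- length(cells)
    baseG <- rlnorm(n, log(params$baseIntensity), params$baseSdLog)
    ratio <- exp(runif(n, log(params$ratioBounds[1]),
                       log(params$ratioBounds[2])))
    baseR <- baseG * ratio
    nShared <- round(sharedFraction * n)
    shared <- rep(FALSE, n)
    if (nShared > 0) shared[sample.int(n, nShared)] <- TRUE
    green <- matrix(0, shape[1], shape[2])
    red <- matrix(0, shape[1], shape[2])
    mask <- matrix(0L, shape[1], shape[2])
    truth <- data.frame(cell_id = seq_len(n), center_r = NA_real_,
                        center_c = NA_real_, base_green = baseG,
                        base_red = baseR, has_focus = TRUE,
                        focus_kind = "spot",
                        focus_peak_fold = params$focusPeakFold,
                        focus_r = NA_real_, focus_c = NA_real_,
                        red_focus_r = NA_real_, red_focus_c = NA_real_,
                        focus_shared = shared)
    for (i in seq_len(n)) {
      cl <- cells[[i]]
      idx <- cbind(cl$pixels$r, cl$pixels$c)
      mask[idx] <- i
      green[idx] <- green[idx] + baseG[i]
      red[idx] <- red[idx] + baseR[i]
      truth$center_r[i] <- cl$centre[1]; truth$center_c[i] <- cl$centre[2]
      j <- sample.int(length(cl$pixels$r), 1)
      gc <- c(cl$pixels$r[j], cl$pixels$c[j])
      if (shared[i]) {
        rc <- gc
      } else {
        d <- sqrt((cl$pixels$r - gc[1])^2 + (cl$pixels$c - gc[2])^2)
        far <- which(d >= min(minSeparation, max(d)))
        k <- far[sample.int(length(far), 1)]
        rc <- c(cl$pixels$r[k], cl$pixels$c[k])
      }
      truth$focus_r[i] <- gc[1]; truth$focus_c[i] <- gc[2]
      truth$red_focus_r[i] <- rc[1]; truth$red_focus_c[i] <- rc[2]
      green[idx] <- green[idx] +
        focusProfile("spot", gc, cl$theta, cl$pixels, baseG[i],
                     params$focusPeakFold, params$filamentAspect)
      red[idx] <- red[idx] +
        focusProfile("spot", rc, cl$theta, cl$pixels, baseR[i],
                     params$focusPeakFold, params$filamentAspect)
    }
    green <- green + params$backgroundLevel
    red <- red + params$backgroundLevel
    if (params$noiseSd > 0) {
      green <- green + rnorm(length(green), 0, params$noiseSd)
      red <- red + rnorm(length(red), 0, params$noiseSd)
    }
    FluorField(green, red, mask, truth)
  })
}
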