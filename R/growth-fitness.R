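#' Fit exponential growth and doubling time from an OD curve
#'
#' Slides every window of at least \code{minWindow} consecutive points
#' over \code{log2(od)} versus time and fits a linear model in each; among
#' windows whose R-squared reaches \code{r2Min}, the one with maximal
#' slope is chosen (ties to the earliest window). The doubling time is the
#' inverse slope (slope is in doublings per minute). Zero or negative OD
#' values are excluded with a warning. The area under the full curve is
#' also reported ([growthAUC()]).
#'
#' @param curve data.frame with \code{time_min} and \code{od} columns.
#' @param minWindow minimum number of points per fit window.
#' @param r2Min minimum R-squared a window must reach.
#' @return list with \code{doubling_time_min}, \code{rate_per_hour}
#'   (doublings/h), \code{window} (start/end indices into the used
#'   points), \code{r_squared}, \code{auc_od_h}.
#' @export
#' @examples
#' g <- simulateGrowth(60 / 90, carryingCapacity = Inf, od0 = 0.005,
#'                     times = seq(0, 360, 20), noiseSd = 0)
#' fitGrowth(g)$doubling_time_min
fitGrowth <- function(curve, minWindow = 5, r2Min = 0.99) {
  stopifnot(all(c("time_min", "od") %in% names(curve)))
  bad <- curve$od <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive OD value(s) excluded from fitting")
  }
  full <- curve
  curve <- curve[!bad, , drop = FALSE]
  n <- nrow(curve)
  if (n < max(4, minWindow)) stop("need at least ", max(4, minWindow),
                                  " positive-OD points")
  t <- curve$time_min
  y <- log2(curve$od)
  best <- NULL
  bestR2 <- -Inf
  for (i in seq_len(n - minWindow + 1)) {
    for (j in seq(i + minWindow - 1, n)) {
      tt <- t[i:j]; yy <- y[i:j]
      mt <- mean(tt); my <- mean(yy)
      sxx <- sum((tt - mt)^2)
      sxy <- sum((tt - mt) * (yy - my))
      syy <- sum((yy - my)^2)
      slope <- sxy / sxx
      r2 <- if (syy == 0) 1 else (sxy^2) / (sxx * syy)
      bestR2 <- max(bestR2, r2)
      if (r2 >= r2Min && slope > 0 &&
          (is.null(best) || slope > best$slope + 1e-15)) {
        best <- list(slope = slope, window = c(i, j), r2 = r2)
      }
    }
  }
  if (is.null(best))
    stop(sprintf("no window of >= %d points reached R^2 >= %g (best: %.4f)",
                 minWindow, r2Min, bestR2))
  list(doubling_time_min = 1 / best$slope,
       rate_per_hour = best$slope * 60,
       window = best$window,
       r_squared = best$r2,
       auc_od_h = growthAUC(full))
}

#' Area under a growth curve
#'
#' Trapezoidal integral of OD over time, reported in OD·h.
#'
#' @param curve data.frame with \code{time_min} and \code{od}.
#' @return numeric, OD·h.
#' @export
growthAUC <- function(curve) {
  stopifnot(all(c("time_min", "od") %in% names(curve)))
  if (nrow(curve) < 2) stop("need at least 2 points for the AUC")
  trapz(curve$time_min / 60, curve$od)
}

#' Generations implied by one serial-dilution regrowth cycle
#'
#' A culture diluted 1:\code{dilutionFactor} that regrows to the same
#' density doubles \code{log2(dilutionFactor)} times; 1:1000 gives 9.97,
#' i.e. about 10 generations per daily cycle.
#'
#' @param dilutionFactor dilution factor (> 1).
#' @return generations per cycle (unrounded; callers may round for
#'   reporting).
#' @export
#' @examples
#' generationsPerCycle(1000)
generationsPerCycle <- function(dilutionFactor) {
  if (any(dilutionFactor <= 1)) stop("dilution factor must exceed 1")
  log2(dilutionFactor)
}

#' Per-generation growth-rate difference from competition counts
#'
#' Converts checkpoint counts to mutant frequencies
#' \code{f = count_x / (count_x + count_y)} and regresses the log odds
#' \code{ln(f/(1-f))} on cumulative generations (cycle index times
#' \code{g_per_cycle}). The slope is \code{ln(1+s)}; the estimate returned
#' is \code{s = exp(slope) - 1}, the per-generation rate difference of
#' strain x over strain y. Checkpoints with f of exactly 0 or 1 are
#' excluded with a warning (a +0.5 Haldane correction is available).
#' Frequencies are scale-free: multiplying both counts at a checkpoint by
#' a constant changes nothing.
#'
#' @param series data.frame with \code{cycle}, \code{count_x},
#'   \code{count_y} (one replicate; see [selectiveAdvantage()] for
#'   aggregation), e.g. from [simulateCompetition()].
#' @param gPerCycle generations per cycle; defaults to the series'
#'   \code{g_per_cycle} attribute, else 10.
#' @param haldane use a +0.5 count correction instead of dropping f in
#'   \{0, 1\}.
#' @return list with \code{s} (per generation), \code{slope} (log-odds per
#'   generation), \code{frequencies} data.frame (cycle, generations, f).
#' @export
competitionRates <- function(series, gPerCycle = NULL, haldane = FALSE) {
  stopifnot(all(c("cycle", "count_x", "count_y") %in% names(series)))
  if (is.null(gPerCycle))
    gPerCycle <- attr(series, "g_per_cycle") %||% 10
  tot <- series$count_x + series$count_y
  if (any(tot < 1)) stop("each checkpoint needs at least one counted cell")
  cx <- series$count_x; cy <- series$count_y
  if (haldane) {
    cx <- cx + 0.5; cy <- cy + 0.5
  }
  f <- cx / (cx + cy)
  gen <- series$cycle * gPerCycle
  usable <- f > 0 & f < 1
  if (any(!usable) && !haldane)
    warning(sum(!usable), " checkpoint(s) with frequency 0 or 1 excluded")
  if (sum(usable) < 2)
    stop("fewer than 2 usable checkpoints; cannot estimate s")
  lo <- log(f[usable] / (1 - f[usable]))
  g <- gen[usable]
  slope <- sum((g - mean(g)) * (lo - mean(lo))) / sum((g - mean(g))^2)
  list(s = exp(slope) - 1, slope = slope,
       frequencies = data.frame(cycle = series$cycle, generations = gen,
                                f = f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Selective advantage of strain x over strain y
#'
#' \deqn{S_{x/y} = (r_x - r_y) / r_{ref}}
#' with r the growth rate in generations per unit time. When replicate
#' rate differences are supplied, the standard error is the sample SD over
#' replicates divided by sqrt(n). The reference rate defaults to the
#' competitor's (\code{r_y}), the usual wild-type normalizer.
#'
#' @param rX,rY growth rates of the two strains; vectors are treated as
#'   replicates (elementwise differences).
#' @param rRef reference rate (nonzero); default \code{mean(rY)}.
#' @return list with \code{S}, \code{se} (NA for a single replicate),
#'   \code{r_x}, \code{r_y}, \code{r_ref}, \code{n_replicates}.
#' @export
#' @examples
#' selectiveAdvantage(1.01, 1.00, 1.00)$S
selectiveAdvantage <- function(rX, rY, rRef = mean(rY)) {
  stopifnot(length(rX) == length(rY))
  if (rRef == 0) stop("reference rate must be nonzero")
  S <- (rX - rY) / rRef
  list(S = mean(S),
       se = if (length(S) > 1) sd(S) / sqrt(length(S)) else NA_real_,
       r_x = mean(rX), r_y = mean(rY), r_ref = rRef,
       n_replicates = length(S))
}
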