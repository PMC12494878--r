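#' Simulate a logistic growth curve read by optical density
#'
#' OD follows the logistic solution
#' \eqn{K / (1 + (K/OD_0 - 1) e^{-r \ln 2 \, t})} with \code{r} in
#' doublings per hour, optionally perturbed by multiplicative log-normal
#' noise. With \code{carryingCapacity = Inf} the curve is a pure
#' exponential and \code{log2(OD)} is exactly linear in time with slope
#' \code{r} doublings/h.
#'
#' @param rPerHour growth rate in doublings per hour.
#' @param carryingCapacity saturation OD (> 0; \code{Inf} allowed).
#' @param od0 inoculum OD (> 0).
#' @param times sampling times in minutes, strictly increasing.
#' @param noiseSd log-scale SD of multiplicative noise (0 = exact).
#' @param seed integer seed.
#' @param replicate replicate label attached to the output.
#' @return data.frame with columns \code{time_min}, \code{od},
#'   \code{replicate}.
#' @export
#' @examples
#' g <- simulateGrowth(rPerHour = 60 / 90, carryingCapacity = Inf,
#'                     od0 = 0.005, times = seq(0, 360, 20), noiseSd = 0)
simulateGrowth <- function(rPerHour, carryingCapacity = 5, od0 = 0.005,
                           times = seq(0, 1440, by = 40), noiseSd = 0,
                           seed = 1L, replicate = 1L) {
  if (od0 <= 0) stop("od0 must be positive")
  if (carryingCapacity <= 0) stop("carrying capacity must be positive")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  stopifnot(noiseSd >= 0, rPerHour >= 0)
  th <- times / 60
  mu <- rPerHour * log(2)  # continuous rate per hour
  od <- if (is.infinite(carryingCapacity)) {
    od0 * exp(mu * th)
  } else {
    carryingCapacity / (1 + (carryingCapacity / od0 - 1) * exp(-mu * th))
  }
  if (noiseSd > 0)
    od <- withSeed(childSeed(seed, "growth"),
                   od * rlnorm(length(od), 0, noiseSd))
  data.frame(time_min = times, od = od, replicate = replicate)
}

#' Simulate a two-strain serial-transfer competition
#'
#' The mutant frequency evolves deterministically between imaging
#' checkpoints as
#' \deqn{f' = f (1+s)^g / (f (1+s)^g + (1-f))}
#' where \code{s} is the per-generation selection coefficient and \code{g}
#' the generations per cycle; growth itself is treated as deterministic and
#' counting noise enters only at the imaging step, as a binomial draw of
#' \code{cellsCounted} cells. \code{cellsCounted = Inf} returns the exact
#' frequencies (as fractional counts summing to 1).
#'
#' @param sPerGeneration selection coefficient per generation, |s| < 1.
#' @param gPerCycle generations per cycle (about 10 for a 1:1000 daily
#'   dilution; see [generationsPerCycle()]).
#' @param nCycles number of growth cycles after the initial 1:1 mix.
#' @param cellsCounted cells classified per imaging checkpoint (>= 1 or
#'   \code{Inf}).
#' @param f0 initial mutant frequency.
#' @param seed integer seed.
#' @param replicate replicate label.
#' @return data.frame of class \code{"CompetitionSeries"} with columns
#'   \code{cycle}, \code{count_x} (mutant), \code{count_y} (reference),
#'   \code{replicate}, plus attributes \code{g_per_cycle}, \code{s_true},
#'   \code{f_true}.
#' @export
#' @examples
#' cs <- simulateCompetition(-0.0034, gPerCycle = 10, nCycles = 4,
#'                           cellsCounted = 1000, seed = 2)
simulateCompetition <- function(sPerGeneration, gPerCycle = 10, nCycles = 4,
                                cellsCounted = 1000, f0 = 0.5, seed = 1L,
                                replicate = 1L) {
  if (abs(sPerGeneration) >= 1) stop("|s| must be < 1")
  stopifnot(cellsCounted >= 1, f0 > 0, f0 < 1, nCycles >= 0, gPerCycle > 0)
  f <- numeric(nCycles + 1)
  f[1] <- f0
  w <- (1 + sPerGeneration)^gPerCycle
  for (i in seq_len(nCycles))
    f[i + 1] <- f[i] * w / (f[i] * w + (1 - f[i]))
  counts <- if (is.infinite(cellsCounted)) {
    cbind(x = f, y = 1 - f)
  } else {
    cx <- withSeed(childSeed(seed, "competition"),
                   rbinom(length(f), size = cellsCounted, prob = f))
    cbind(x = cx, y = cellsCounted - cx)
  }
  out <- data.frame(cycle = 0:nCycles, count_x = counts[, "x"],
                    count_y = counts[, "y"], replicate = replicate)
  attr(out, "g_per_cycle") <- gPerCycle
  attr(out, "s_true") <- sPerGeneration
  attr(out, "f_true") <- f
  class(out) <- c("CompetitionSeries", "data.frame")
  out
}

#' Simulate a label-free protein abundance experiment
#'
#' Log-normal intensities with a log2(\code{fold}) shift spiked into
#' \code{deProteins} in group B, missing-at-random dropout, unique-peptide
#' counts drawn so that a stated fraction of proteins fail the >= 2-peptide
#' filter, and random category annotations of stated sizes.
#'
#' @param nProteins number of proteins.
#' @param nPerGroup samples per group (two groups, A and B).
#' @param deProteins indices (or names) of differentially abundant
#'   proteins; must be a subset of the protein set.
#' @param fold linear fold change applied in group B (> 0; < 1 means down).
#' @param missingRate probability an entry is undetected, in [0, 1).
#' @param noiseSdLog2 per-entry SD on the log2 scale.
#' @param categories named integer vector of category sizes, or a number of
#'   categories (sizes drawn between 5 and nProteins/4).
#' @param peptideFailFraction fraction of proteins drawn with < 2 unique
#'   peptides.
#' @param seed integer seed.
#' @return list with elements \code{experiment}
#'   ([AbundanceExperiment-class]), \code{annotations} (data.frame protein,
#'   category) and \code{truth} (list: de_proteins, fold).
#' @export
simulateAbundance <- function(nProteins = 400, nPerGroup = 6,
                              deProteins = integer(), fold = 2,
                              missingRate = 0.05, noiseSdLog2 = 0.25,
                              categories = 8, peptideFailFraction = 0.1,
                              seed = 1L) {
  stopifnot(fold > 0, missingRate >= 0, missingRate < 1,
            nProteins >= 2, nPerGroup >= 2)
  prot <- sprintf("P%04d", seq_len(nProteins))
  if (is.character(deProteins)) {
    if (!all(deProteins %in% prot))
      stop("deProteins must be a subset of the protein set")
    deIdx <- match(deProteins, prot)
  } else {
    if (length(deProteins) && (any(deProteins < 1) ||
                               any(deProteins > nProteins)))
      stop("deProteins must be a subset of the protein set")
    deIdx <- as.integer(deProteins)
  }
  withSeed(childSeed(seed, "abundance"), {
    baseLog2 <- rnorm(nProteins, mean = 20, sd = 2)
    nS <- 2 * nPerGroup
    group <- rep(c("A", "B"), each = nPerGroup)
    log2int <- matrix(baseLog2, nProteins, nS) +
      matrix(rnorm(nProteins * nS, 0, noiseSdLog2), nProteins, nS)
    if (length(deIdx))
      log2int[deIdx, group == "B"] <-
        log2int[deIdx, group == "B"] + log2(fold)
    intensity <- 2^log2int
    detected <- matrix(runif(nProteins * nS) >= missingRate, nProteins, nS)
    intensity[!detected] <- NA
    pept <- ifelse(runif(nProteins) < peptideFailFraction, 1L,
                   1L + stats::rpois(nProteins, 6) + 1L)
    dimnames(intensity) <- list(prot, paste0(group, seq_len(nS)))
    ae <- AbundanceExperiment(intensity, pept, group, detected)
    if (length(categories) == 1 && is.numeric(categories) &&
        is.null(names(categories))) {
      nCat <- as.integer(categories)
      sizes <- pmax(5L, stats::rbinom(nCat, size = max(5L,
                    as.integer(nProteins / 4)), prob = 0.5))
      names(sizes) <- sprintf("GO%02d", seq_len(nCat))
    } else {
      sizes <- categories
    }
    ann <- do.call(rbind, lapply(names(sizes), function(cat) {
      data.frame(protein = sample(prot, min(sizes[[cat]], nProteins)),
                 category = cat)
    }))
    list(experiment = ae, annotations = ann,
         truth = list(de_proteins = prot[deIdx], fold = fold))
  })
}

#' Simulate wild-type and mutant circular-dichroism spectra
#'
#' Both spectra are smooth sums of Gaussians over the wavelength grid; the
#' mutant adds a perturbation (none, a constant offset over a window, or a
#' random smooth bump set). The true integrated absolute difference is
#' computed by dense trapezoidal quadrature on a grid at least 100-fold
#' finer, serving as the oracle for [deltaCD()].
#'
#' @param gridNm wavelength grid (nm), strictly increasing.
#' @param perturbation "none", "offset" or "random".
#' @param offset constant offset value (used when
#'   \code{perturbation = "offset"}).
#' @param offsetRange wavelength window of the constant offset.
#' @param seed integer seed (random perturbation).
#' @return list with \code{wt} and \code{mut} spectra (data.frames
#'   wavelength/ellipticity), and \code{true_delta} from dense quadrature.
#' @export
simulateSpectra <- function(gridNm = seq(200, 250, by = 1),
                            perturbation = c("none", "offset", "random"),
                            offset = 2, offsetRange = range(gridNm),
                            seed = 1L) {
  perturbation <- match.arg(perturbation)
  if (any(diff(gridNm) <= 0)) stop("wavelength grid must be strictly increasing")
  mix <- function(x, centres, widths, amps) {
    y <- numeric(length(x))
    for (i in seq_along(centres))
      y <- y + amps[i] * exp(-(x - centres[i])^2 / (2 * widths[i]^2))
    y
  }
  lo <- min(gridNm); hi <- max(gridNm)
  wtC <- c(lo + 0.25 * (hi - lo), lo + 0.65 * (hi - lo))
  wtW <- c(0.18, 0.22) * (hi - lo)
  wtA <- c(-12, 8)
  pert <- withSeed(childSeed(seed, "spectra"), {
    switch(perturbation,
      none = function(x) numeric(length(x)),
      offset = function(x) ifelse(x >= offsetRange[1] & x <= offsetRange[2],
                                  offset, 0),
      random = {
        # widths are kept broad relative to the grid so the sampled
        # spectra remain faithful to the underlying smooth curves
        pc <- runif(3, lo, hi); pw <- runif(3, 0.2, 0.3) * (hi - lo)
        # one coherent direction, as when a structural element is lost:
        # same-sign bumps keep the integrand away from cancellation
        pa <- sample(c(-1, 1), 1) * runif(3, 0.5, 6)
        function(x) mix(x, pc, pw, pa)
      })
  })
  wtF <- function(x) mix(x, wtC, wtW, wtA)
  mutF <- function(x) wtF(x) + pert(x)
  fine <- seq(lo, hi, length.out = max(200L, 101L * length(gridNm)))
  trueDelta <- trapz(fine, abs(wtF(fine) - mutF(fine)))
  list(wt = data.frame(wavelength = gridNm, ellipticity = wtF(gridNm)),
       mut = data.frame(wavelength = gridNm, ellipticity = mutF(gridNm)),
       true_delta = trueDelta)
}
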