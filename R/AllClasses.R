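#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Two-channel fluorescence field with label mask and ground truth
#'
#' Container for one simulated (or loaded) microscopy field: a green (YFP)
#' and a red (mScarlet-I / mCherry) intensity matrix in arbitrary units, an
#' integer label mask (0 = background, cell_id elsewhere), and a per-cell
#' ground-truth table when the field was simulated.
#'
#' @slot green numeric matrix, green-channel intensities (AU).
#' @slot red numeric matrix, red-channel intensities (AU), same dimensions.
#' @slot mask integer matrix of cell labels, same dimensions; 0 = background.
#' @slot truth data.frame of per-cell ground truth (may have zero rows for
#'   fields loaded from disk); when present it has one row per cell with at
#'   least a \code{cell_id} column.
#'
#' @seealso [simulateField()], [cellStats()], [detectPuncta()]
#' @export
setClass("FluorField",
  slots = c(green = "matrix", red = "matrix", mask = "matrix",
            truth = "data.frame"))

setValidity("FluorField", function(object) {
  msg <- character()
  if (!identical(dim(object@green), dim(object@red)))
    msg <- c(msg, "green and red channels must have identical dimensions")
  if (!identical(dim(object@green), dim(object@mask)))
    msg <- c(msg, "mask must match channel dimensions")
  if (any(object@mask < 0))
    msg <- c(msg, "mask labels must be non-negative")
  if (any(object@mask != round(object@mask)))
    msg <- c(msg, "mask labels must be integers")
  if (nrow(object@truth) > 0 && !"cell_id" %in% names(object@truth))
    msg <- c(msg, "truth table must contain a cell_id column")
  if (length(msg)) msg else TRUE
})

#' Construct a FluorField
#'
#' @param green,red numeric intensity matrices (AU), identical dimensions.
#' @param mask integer label matrix (0 background), identical dimensions.
#' @param truth optional per-cell ground-truth data.frame.
#' @return a [FluorField-class] object.
#' @export
FluorField <- function(green, red, mask, truth = data.frame()) {
  storage.mode(mask) <- "integer"
  new("FluorField", green = green, red = red, mask = mask, truth = truth)
}

#' @describeIn FluorField-class green-channel intensity matrix
#' @param x a \code{FluorField}.
#' @export
greenChannel <- function(x) { stopifnot(is(x, "FluorField")); x@green }

#' @describeIn FluorField-class red-channel intensity matrix
#' @export
redChannel <- function(x) { stopifnot(is(x, "FluorField")); x@red }

#' @describeIn FluorField-class integer label mask (0 = background)
#' @export
labelMask <- function(x) { stopifnot(is(x, "FluorField")); x@mask }

#' @describeIn FluorField-class per-cell ground-truth table
#' @export
truthTable <- function(x) { stopifnot(is(x, "FluorField")); x@truth }

setMethod("show", "FluorField", function(object) {
  d <- dim(object@green)
  ncell <- length(setdiff(unique(as.vector(object@mask)), 0L))
  cat(sprintf("FluorField: %d x %d px, %d cells, truth rows: %d\n",
              d[1], d[2], ncell, nrow(object@truth)))
})

#' Label-free protein abundance experiment
#'
#' A \linkS4class{SummarizedExperiment} holding a proteins-by-samples
#' intensity matrix (assay \code{"intensity"}, AU, NA where not detected),
#' a logical detection assay (\code{"detected"}), per-protein unique-peptide
#' counts in \code{rowData(x)$unique_peptides}, and the sample-to-group
#' mapping in \code{colData(x)$group}.
#'
#' @seealso [simulateAbundance()], [filterAbundance()],
#'   [differentialAbundance()]
#' @export
setClass("AbundanceExperiment", contains = "SummarizedExperiment")

setValidity("AbundanceExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("intensity", "detected") %in% an))
    msg <- c(msg, "assays 'intensity' and 'detected' are required")
  if (!"unique_peptides" %in% names(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain unique_peptides")
  if (!"group" %in% names(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain group")
  if ("intensity" %in% an) {
    int <- SummarizedExperiment::assay(object, "intensity")
    if (any(int < 0, na.rm = TRUE))
      msg <- c(msg, "detected intensities must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceExperiment
#'
#' @param intensity numeric proteins-by-samples matrix (AU); NA = not
#'   detected.
#' @param uniquePeptides integer vector, unique peptides per protein.
#' @param group character/factor of length \code{ncol(intensity)} mapping
#'   samples to groups.
#' @param detected optional logical matrix; defaults to
#'   \code{!is.na(intensity)}.
#' @return an [AbundanceExperiment-class].
#' @export
AbundanceExperiment <- function(intensity, uniquePeptides, group,
                                detected = !is.na(intensity)) {
  stopifnot(nrow(intensity) == length(uniquePeptides),
            ncol(intensity) == length(group))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity, detected = detected),
    rowData = S4Vectors::DataFrame(unique_peptides = as.integer(uniquePeptides)),
    colData = S4Vectors::DataFrame(group = as.character(group)))
  new("AbundanceExperiment", se)
}

#' @describeIn AbundanceExperiment-class unique-peptide counts per protein
#' @param x an \code{AbundanceExperiment}.
#' @export
uniquePeptides <- function(x) {
  stopifnot(is(x, "AbundanceExperiment"))
  SummarizedExperiment::rowData(x)$unique_peptides
}

#' @describeIn AbundanceExperiment-class sample-to-group mapping
#' @export
sampleGroups <- function(x) {
  stopifnot(is(x, "AbundanceExperiment"))
  SummarizedExperiment::colData(x)$group
}

#' @describeIn AbundanceExperiment-class fraction of samples in which each
#'   protein was detected
#' @export
detectionRate <- function(x) {
  stopifnot(is(x, "AbundanceExperiment"))
  rowMeans(SummarizedExperiment::assay(x, "detected"))
}

setMethod("show", "AbundanceExperiment", function(object) {
  cat(sprintf(
    "AbundanceExperiment: %d proteins x %d samples (groups: %s)\n",
    nrow(object), ncol(object),
    paste(unique(sampleGroups(object)), collapse = ", ")))
})
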