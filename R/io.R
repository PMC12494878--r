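#' Read and write 16-bit grayscale TIFF channels and label masks
#'
#' Intensities are stored as 16-bit grayscale TIFF, one file per channel,
#' scaled by \code{2^16 - 1}; values are clipped to [0, 65535] and rounded
#' on write, so integer AU round-trip exactly. Label masks use the same
#' encoding with 0 = background.
#'
#' @param image numeric matrix (AU, expected within [0, 65535]).
#' @param path file path.
#' @return \code{writeImageTIFF} returns \code{path} invisibly;
#'   \code{readImageTIFF} returns a numeric matrix in AU;
#'   \code{readMaskTIFF} returns an integer label matrix.
#' @name tiff-io
NULL

#' @rdname tiff-io
#' @export
writeImageTIFF <- function(image, path) {
  stopifnot(is.matrix(image))
  img <- pmin(pmax(round(image), 0), 65535) / 65535
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname tiff-io
#' @export
readImageTIFF <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  round(m * 65535)
}

#' @rdname tiff-io
#' @export
writeMaskTIFF <- function(image, path) writeImageTIFF(image, path)

#' @rdname tiff-io
#' @export
readMaskTIFF <- function(path) {
  m <- readImageTIFF(path)
  storage.mode(m) <- "integer"
  m
}

#' Write a FluorField to a directory
#'
#' Writes \code{green.tif}, \code{red.tif}, \code{mask.tif} and
#' \code{truth.csv} (when ground truth is present).
#'
#' @param field a [FluorField-class].
#' @param dir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
writeFieldData <- function(field, dir) {
  stopifnot(is(field, "FluorField"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(green = file.path(dir, "green.tif"),
             red = file.path(dir, "red.tif"),
             mask = file.path(dir, "mask.tif"))
  writeImageTIFF(greenChannel(field), paths["green"])
  writeImageTIFF(redChannel(field), paths["red"])
  writeMaskTIFF(labelMask(field), paths["mask"])
  if (nrow(truthTable(field)) > 0) {
    paths <- c(paths, truth = file.path(dir, "truth.csv"))
    write.csv(truthTable(field), paths["truth"], row.names = FALSE)
  }
  invisible(paths)
}
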