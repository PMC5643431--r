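## External interfaces: 8-bit PNG tiles, 0/255 single-channel mask PNGs,
## CSV/TSV tables, JSON transforms and selection results.

#' Read and write tiles and masks as PNG
#'
#' Tiles are 8-bit RGB PNGs; masks are single-channel PNGs with foreground
#' 255 and background 0.
#'
#' @param x H x W x 3 array in [0, 1] (tile) or logical matrix (mask).
#' @param path file path.
#' @return \code{readTilePNG()} an array, \code{readMaskPNG()} a logical
#'   matrix; the writers return \code{path} invisibly.
#' @export
writeTilePNG <- function(x, path) {
  png::writePNG(x, path)
  invisible(path)
}

#' @rdname writeTilePNG
#' @export
readTilePNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] > 3) img <- img[, , 1:3]
  img
}

#' @rdname writeTilePNG
#' @export
writeMaskPNG <- function(x, path) {
  png::writePNG(matrix(as.numeric(x), nrow(x), ncol(x)), path)
  invisible(path)
}

#' @rdname writeTilePNG
#' @export
readMaskPNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Write centroid/contour ground truth as CSV
#'
#' Columns \code{tile_id, class, row, col} with 0-based, row-major pixel
#' coordinates.
#'
#' @param tile a [GroundTruthTile-class].
#' @param tile_id identifier for the tile.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeCentroidCSV <- function(tile, tile_id, path) {
  rows <- rbind(
    if (nrow(tile@ecCentroids)) data.frame(class = "endothelial",
      row = tile@ecCentroids[, 1] - 1, col = tile@ecCentroids[, 2] - 1),
    if (nrow(tile@lymphCentroids)) data.frame(class = "lymphocyte",
      row = tile@lymphCentroids[, 1] - 1, col = tile@lymphCentroids[, 2] - 1),
    if (nrow(tile@cancerCentroids)) data.frame(class = "cancer",
      row = tile@cancerCentroids[, 1] - 1, col = tile@cancerCentroids[, 2] - 1))
  utils::write.csv(cbind(tile_id = tile_id, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write an affine transform or feature-selection result as JSON
#'
#' @param x an [AffineTransform-class] or \code{featureSelection}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeResultJSON <- function(x, path) {
  obj <- if (is(x, "AffineTransform"))
    list(matrix = x@m, converged = x@converged, metric = x@metric)
  else if (inherits(x, "featureSelection"))
    list(selected = x$selected, frequency = as.list(x$frequency),
         n_iter = x$n_iter, seed = x$seed, final_logrank_p = x$final_logrank_p)
  else stop("unsupported object")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-case vascular-feature profiles as TSV
#'
#' @param profiles cases x features matrix.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeProfilesTSV <- function(profiles, path) {
  df <- data.frame(case_id = rownames(profiles), profiles, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
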