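#' Standard stain bases
#'
#' Unit-norm optical-density stain vectors.  \code{hematoxylinEosinBasis()}
#' returns the standard literature H&E pair; \code{ihcBasis()} returns the
#' three-stain basis used to render pseudo-IHC tiles (hematoxylin, CD31
#' purple, DAB brown).
#'
#' @param i0 background intensity per RGB channel (default blank field 1).
#' @return A [StainBasis-class] object.
#' @export
hematoxylinEosinBasis <- function(i0 = c(1, 1, 1)) {
  v <- cbind(hematoxylin = c(0.650, 0.704, 0.286),
             eosin       = c(0.070, 0.990, 0.110))
  v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
  new("StainBasis", vectors = v, i0 = i0)
}

#' @rdname hematoxylinEosinBasis
#' @export
ihcBasis <- function(i0 = c(1, 1, 1)) {
  v <- cbind(hematoxylin = c(0.650, 0.704, 0.286),
             cd31_purple = c(0.360, 0.870, 0.310),
             dab         = c(0.268, 0.570, 0.776))
  v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
  new("StainBasis", vectors = v, i0 = i0)
}

#' Render stain density maps into an RGB image (Beer-Lambert mixing)
#'
#' The inverse of [unmixStains()]: per-pixel optical density is the linear
#' combination of the basis vectors weighted by the density maps, and
#' intensity is \code{I = I0 * 10^-OD}, optionally with additive Gaussian
#' intensity noise (clipped to [0, 1]).
#'
#' @param densities named list of density matrices, one per basis stain (in
#'   basis column order; missing stains allowed if named).
#' @param basis a [StainBasis-class].
#' @param noise_sd Gaussian intensity noise standard deviation (0 = none).
#' @return H x W x 3 array in [0, 1].
#' @export
renderStains <- function(densities, basis, noise_sd = 0) {
  stopifnot(length(densities) >= 1)
  nm <- names(densities)
  if (is.null(nm)) nm <- colnames(basis@vectors)[seq_along(densities)]
  d <- dim(densities[[1]])
  od <- matrix(0, prod(d), 3)
  for (i in seq_along(densities)) {
    v <- basis@vectors[, nm[i]]
    od <- od + as.vector(densities[[i]]) %o% v
  }
  img <- array(0, c(d, 3))
  for (ch in 1:3) {
    plane <- basis@i0[ch] * 10^(-od[, ch])
    if (noise_sd > 0) plane <- plane + rnorm(length(plane), 0, noise_sd)
    img[, , ch] <- matrix(pmin(pmax(plane, 0), 1), d[1], d[2])
  }
  img
}

#' Unmix RGB stains into absorbance channels
#'
#' Converts intensities to optical density \code{OD = -log10(I / I0)} and
#' projects every pixel onto the Moore-Penrose pseudo-inverse of the stain
#' matrix.  Negative projections are clipped to 0.  With
#' \code{normalize = TRUE} each channel is divided by its 99th-percentile
#' value and clipped to [0, 1].
#'
#' @param rgb H x W x 3 array in [0, 1].
#' @param basis a [StainBasis-class] with >= 2 stains.
#' @param normalize normalize channels to [0, 1] by the 99th percentile.
#' @return A [StainChannels-class] object with one channel per basis stain.
#' @examples
#' b <- hematoxylinEosinBasis()
#' img <- renderStains(list(hematoxylin = matrix(0.5, 8, 8),
#'                          eosin = matrix(0.2, 8, 8)), b)
#' ch <- unmixStains(img, b, normalize = FALSE)
#' channel(ch, "hematoxylin")[1, 1]  # ~0.5
#' @export
unmixStains <- function(rgb, basis, normalize = TRUE) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  validObject(basis)
  d <- dim(rgb)[1:2]
  eps <- 1e-6
  od <- sapply(1:3, function(ch)
    -log10(pmax(as.vector(rgb[, , ch]), eps) / basis@i0[ch]))
  pinv <- MASS::ginv(basis@vectors)          # k x 3
  dens <- od %*% t(pinv)                      # n x k
  dens[dens < 0] <- 0
  chans <- lapply(seq_len(ncol(dens)), function(j) {
    m <- matrix(dens[, j], d[1], d[2])
    if (normalize) {
      q <- quantile(m, 0.99, names = FALSE)
      if (q > 0) m <- pmin(m / q, 1)
    }
    m
  })
  names(chans) <- colnames(basis@vectors)
  new("StainChannels", channels = chans)
}
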