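## S4 containers for the imaging pipeline.  Images are numeric/logical R
## matrices (rows = image rows); RGB images are H x W x 3 arrays in [0, 1].

#' Stain basis for optical-density unmixing
#'
#' Holds 2 or 3 unit-norm stain vectors in optical-density RGB space plus the
#' per-channel background intensity I0.  Absorbance images are obtained by
#' projecting pixel optical densities onto the pseudo-inverse of this basis.
#'
#' @slot vectors 3 x k numeric matrix, one unit-norm stain vector per column.
#' @slot i0 numeric(3), background (blank-field) intensity per RGB channel.
#' @export
setClass("StainBasis", representation(vectors = "matrix", i0 = "numeric"))

setValidity("StainBasis", function(object) {
  v <- object@vectors
  if (nrow(v) != 3 || ncol(v) < 2) return("vectors must be 3 x k, k >= 2")
  nrm <- sqrt(colSums(v^2))
  if (any(abs(nrm - 1) > 1e-6)) return("stain vectors must be unit-norm")
  for (i in seq_len(ncol(v) - 1)) for (j in (i + 1):ncol(v)) {
    if (abs(sum(v[, i] * v[, j])) > 1 - 1e-6)
      return("stain vectors must be pairwise non-parallel")
  }
  if (length(object@i0) != 3 || any(object@i0 <= 0))
    return("i0 must be 3 positive intensities")
  TRUE
})

#' Named absorbance channels unmixed from an RGB tile
#'
#' @slot channels named list of non-negative numeric matrices, all of the same
#'   dimension (e.g. \code{hematoxylin}, \code{eosin}).
#' @export
setClass("StainChannels", representation(channels = "list"))

setValidity("StainChannels", function(object) {
  ch <- object@channels
  if (length(ch) == 0 || is.null(names(ch))) return("channels must be named")
  d <- dim(ch[[1]])
  for (m in ch) {
    if (!identical(dim(m), d)) return("channels must share dimensions")
    if (any(m < -1e-9, na.rm = TRUE)) return("absorbance must be >= 0")
  }
  TRUE
})

#' Synthetic ground-truth tile
#'
#' A rendered H&E/pseudo-IHC tile pair with exact ground truth: the vascular
#' area mask, nucleus centroids by class, and the rendered nucleus contours.
#'
#' @slot rgbHE,rgbIHC H x W x 3 arrays in [0, 1].
#' @slot vesselMask logical matrix, TRUE = vascular area.
#' @slot ecCentroids,lymphCentroids,cancerCentroids n x 2 matrices (row, col).
#' @slot nucleusContours list of \code{list(class=, coords=)} closed polygons.
#' @slot seed integer seed the tile was generated from.
#' @export
setClass("GroundTruthTile", representation(
  rgbHE = "array", rgbIHC = "array", vesselMask = "matrix",
  ecCentroids = "matrix", lymphCentroids = "matrix", cancerCentroids = "matrix",
  nucleusContours = "list", seed = "integer"))

setValidity("GroundTruthTile", function(object) {
  d <- dim(object@vesselMask)
  if (!identical(dim(object@rgbHE)[1:2], d)) return("image/mask size mismatch")
  if (!identical(dim(object@rgbIHC)[1:2], d)) return("image/mask size mismatch")
  if (nrow(object@ecCentroids) > 0) {
    dil <- cpp_edt(object@vesselMask)
    idx <- round(object@ecCentroids)
    dd <- dil[cbind(pmin(pmax(idx[, 1], 1), d[1]), pmin(pmax(idx[, 2], 1), d[2]))]
    if (any(dd > 10)) return("EC centroids must lie within 10 px of the vessel mask")
  }
  TRUE
})

#' Six-state Gaussian color model for IHC segmentation
#'
#' Hidden Markov model over pixel RGB values with three ink states (DAB,
#' CD31 purple, hematoxylin) and three background states (white, light blue,
#' light brown).  Decoding is per image row by the Viterbi algorithm.
#'
#' @slot stateNames character vector of state names.
#' @slot means k x 3 matrix of per-state RGB emission means.
#' @slot covs list of k positive-definite 3 x 3 covariance matrices.
#' @slot transition k x k row-stochastic transition matrix.
#' @slot initial length-k initial distribution.
#' @export
setClass("HMMColorModel", representation(
  stateNames = "character", means = "matrix", covs = "list",
  transition = "matrix", initial = "numeric"))

setValidity("HMMColorModel", function(object) {
  k <- length(object@stateNames)
  if (nrow(object@means) != k || length(object@covs) != k) return("state count mismatch")
  if (any(abs(rowSums(object@transition) - 1) > 1e-9))
    return("transition rows must sum to 1")
  if (abs(sum(object@initial) - 1) > 1e-9) return("initial must sum to 1")
  for (S in object@covs) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) return("covariances must be positive-definite")
  }
  TRUE
})

#' Binary masks of positive IHC staining
#'
#' @slot cd31 logical matrix, CD31-positive (endothelial) area.
#' @slot cd45 logical matrix, CD45-positive (lymphocyte) area.
#' @export
setClass("IHCLabelMask", representation(cd31 = "matrix", cd45 = "matrix"))

setValidity("IHCLabelMask", function(object) {
  if (!identical(dim(object@cd31), dim(object@cd45))) return("mask size mismatch")
  if (any(object@cd31 & object@cd45)) return("masks must be disjoint")
  TRUE
})

#' Affine transform mapping moving (row, col) to fixed (row, col)
#'
#' @slot m 2 x 3 matrix: linear part in columns 1:2, translation in column 3.
#' @slot converged logical flag from the registration optimizer.
#' @slot metric final mean-squared-error of the registration.
#' @export
setClass("AffineTransform",
         representation(m = "matrix", converged = "logical", metric = "numeric"))

setValidity("AffineTransform", function(object) {
  if (!identical(dim(object@m), c(2L, 3L))) return("m must be 2 x 3")
  if (abs(det(object@m[, 1:2])) < 1e-12) return("linear part is singular")
  TRUE
})

#' Vascular area mask (VAM)
#'
#' Binary image of predicted vascular/perivascular area, the output of the
#' pixel-wise vascular classifier after morphological clean-up.
#'
#' @slot mask logical matrix.
#' @slot tileId character tile identifier.
#' @export
setClass("VascularAreaMask", representation(mask = "matrix", tileId = "character"))

#' Vascular skeleton with branch points and arms
#'
#' One-pixel-wide thinning of a vascular area mask together with its branch
#' points (skeleton pixels with >= 3 neighbours, clustered) and arms (maximal
#' skeleton segments between branch points / endpoints) with axial
#' orientations in [0, 180).
#'
#' @slot skeleton logical matrix (1-px wide).
#' @slot branchPoints k x 2 matrix of (row, col) branch-cluster centroids.
#' @slot arms list of \code{list(pixels=, length=, orientation=)}.
#' @slot eulerComponents integer, number of connected skeleton components.
#' @export
setClass("VascularSkeleton", representation(
  skeleton = "matrix", branchPoints = "matrix", arms = "list",
  eulerComponents = "integer"))

setValidity("VascularSkeleton", function(object) {
  ok <- vapply(object@arms, function(a)
    is.finite(a$orientation) && a$orientation >= 0 && a$orientation < 180, TRUE)
  if (length(ok) && !all(ok)) return("arm orientations must be in [0, 180)")
  TRUE
})

#' Specification of a simulated cohort
#'
#' @slot nCases number of cases.
#' @slot tilesPerCase integer range (min, max) of tiles per case; the default
#'   3--74 mirrors the observed per-case tile counts (mean 25, sd 18).
#' @slot nGenes,nSignalGenes total genes and planted signal genes.
#' @slot plantedHazardRatio hazard ratio between the two phenotype groups.
#' @slot correlationStrength target Pearson correlation of signal genes with
#'   their vascular feature, in [0, 1].
#' @slot censoringRate expected fraction of censored cases, in [0, 1].
#' @slot seed integer seed.
#' @export
setClass("SyntheticCohortSpec", representation(
  nCases = "integer", tilesPerCase = "integer", nGenes = "integer",
  nSignalGenes = "integer", plantedHazardRatio = "numeric",
  correlationStrength = "numeric", censoringRate = "numeric", seed = "integer"))

setValidity("SyntheticCohortSpec", function(object) {
  if (object@nSignalGenes > object@nGenes) return("nSignalGenes must be <= nGenes")
  if (object@plantedHazardRatio <= 0) return("plantedHazardRatio must be > 0")
  if (object@correlationStrength < 0 || object@correlationStrength > 1)
    return("correlationStrength must be in [0, 1]")
  if (object@censoringRate < 0 || object@censoringRate > 1)
    return("censoringRate must be in [0, 1]")
  TRUE
})

#' Simulated cohort with expression assay, survival, and vascular profiles
#'
#' Extends \code{SummarizedExperiment}: the \code{rpkm} assay holds the
#' genes x cases expression matrix, \code{colData} the survival table
#' (\code{dfs_months}, \code{event}, \code{stage_high}, \code{grade_high}) and
#' the planted phenotype group, and the \code{vfProfiles} slot the cases x
#' features vascular-feature matrix.  Planted truth (signal genes/features)
#' is recorded in \code{metadata()}.
#'
#' @slot vfProfiles numeric matrix, cases x vascular features.
#' @export
setClass("VascularCohort", contains = "SummarizedExperiment",
         representation(vfProfiles = "matrix"))

setValidity("VascularCohort", function(object) {
  if (nrow(object@vfProfiles) != ncol(object))
    return("vfProfiles rows must match cases")
  TRUE
})
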