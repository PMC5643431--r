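#' @name accessors
#' @title Accessors for vasculomorph containers
#' @description Slot accessors for the S4 data containers: stain channels,
#'   ground-truth tiles, IHC masks, skeletons, and simulated cohorts.
#' @param x an object.
#' @param name channel name for \code{channel()}.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("channel", function(x, name) standardGeneric("channel"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("vesselMask", function(x) standardGeneric("vesselMask"))
#' @rdname accessors
#' @export
setGeneric("ecCentroids", function(x) standardGeneric("ecCentroids"))
#' @rdname accessors
#' @export
setGeneric("nucleusContours", function(x) standardGeneric("nucleusContours"))
#' @rdname accessors
#' @export
setGeneric("cd31Mask", function(x) standardGeneric("cd31Mask"))
#' @rdname accessors
#' @export
setGeneric("cd45Mask", function(x) standardGeneric("cd45Mask"))
#' @rdname accessors
#' @export
setGeneric("transformMatrix", function(x) standardGeneric("transformMatrix"))
#' @rdname accessors
#' @export
setGeneric("maskImage", function(x) standardGeneric("maskImage"))
#' @rdname accessors
#' @export
setGeneric("skeletonMask", function(x) standardGeneric("skeletonMask"))
#' @rdname accessors
#' @export
setGeneric("branchPoints", function(x) standardGeneric("branchPoints"))
#' @rdname accessors
#' @export
setGeneric("arms", function(x) standardGeneric("arms"))
#' @rdname accessors
#' @export
setGeneric("vfProfiles", function(x) standardGeneric("vfProfiles"))
#' @rdname accessors
#' @export
setGeneric("survivalTable", function(x) standardGeneric("survivalTable"))
#' @rdname accessors
#' @export
setGeneric("riskGroups", function(x) standardGeneric("riskGroups"))

#' @rdname accessors
setMethod("channel", "StainChannels", function(x, name) {
  if (!name %in% names(x@channels)) stop("no channel named '", name, "'")
  x@channels[[name]]
})
#' @rdname accessors
setMethod("channelNames", "StainChannels", function(x) names(x@channels))
#' @rdname accessors
setMethod("vesselMask", "GroundTruthTile", function(x) x@vesselMask)
#' @rdname accessors
setMethod("ecCentroids", "GroundTruthTile", function(x) x@ecCentroids)
#' @rdname accessors
setMethod("nucleusContours", "GroundTruthTile", function(x) x@nucleusContours)
#' @rdname accessors
setMethod("cd31Mask", "IHCLabelMask", function(x) x@cd31)
#' @rdname accessors
setMethod("cd45Mask", "IHCLabelMask", function(x) x@cd45)
#' @rdname accessors
setMethod("transformMatrix", "AffineTransform", function(x) x@m)
#' @rdname accessors
setMethod("maskImage", "VascularAreaMask", function(x) x@mask)
#' @rdname accessors
setMethod("skeletonMask", "VascularSkeleton", function(x) x@skeleton)
#' @rdname accessors
setMethod("branchPoints", "VascularSkeleton", function(x) x@branchPoints)
#' @rdname accessors
setMethod("arms", "VascularSkeleton", function(x) x@arms)
#' @rdname accessors
setMethod("vfProfiles", "VascularCohort", function(x) x@vfProfiles)
#' @rdname accessors
setMethod("survivalTable", "VascularCohort", function(x) {
  cd <- colData(x)
  data.frame(case_id = rownames(cd), dfs_months = cd$dfs_months,
             event = cd$event, stage_high = cd$stage_high,
             grade_high = cd$grade_high, row.names = NULL)
})
#' @rdname accessors
setMethod("riskGroups", "VascularCohort", function(x) colData(x)$true_group)

setMethod("show", "StainChannels", function(object) {
  d <- dim(object@channels[[1]])
  cat("StainChannels:", paste(names(object@channels), collapse = ", "),
      sprintf("(%d x %d)\n", d[1], d[2]))
})
setMethod("show", "GroundTruthTile", function(object) {
  d <- dim(object@vesselMask)
  cat(sprintf("GroundTruthTile %d x %d | vessel area %.1f%% | EC %d, lymph %d, cancer %d nuclei | seed %d\n",
              d[1], d[2], 100 * mean(object@vesselMask),
              nrow(object@ecCentroids), nrow(object@lymphCentroids),
              nrow(object@cancerCentroids), object@seed))
})
setMethod("show", "HMMColorModel", function(object) {
  cat("HMMColorModel with", length(object@stateNames), "states:",
      paste(object@stateNames, collapse = ", "), "\n")
})
setMethod("show", "IHCLabelMask", function(object) {
  cat(sprintf("IHCLabelMask: CD31 %.1f%%, CD45 %.1f%% positive\n",
              100 * mean(object@cd31), 100 * mean(object@cd45)))
})
setMethod("show", "AffineTransform", function(object) {
  cat("AffineTransform (moving -> fixed), converged =", object@converged,
      ", MSE =", signif(object@metric, 4), "\n")
  print(round(object@m, 4))
})
setMethod("show", "VascularAreaMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("VascularAreaMask '%s' %d x %d, %.1f%% vascular\n",
              object@tileId, d[1], d[2], 100 * mean(object@mask)))
})
setMethod("show", "VascularSkeleton", function(object) {
  cat(sprintf("VascularSkeleton: %d px, %d branch points, %d arms, %d components\n",
              sum(object@skeleton), nrow(object@branchPoints),
              length(object@arms), object@eulerComponents))
})
setMethod("show", "SyntheticCohortSpec", function(object) {
  cat(sprintf("SyntheticCohortSpec: %d cases, %d-%d tiles/case, %d genes (%d signal), HR %.2f, rho %.2f, censoring %.2f, seed %d\n",
              object@nCases, object@tilesPerCase[1], object@tilesPerCase[2],
              object@nGenes, object@nSignalGenes, object@plantedHazardRatio,
              object@correlationStrength, object@censoringRate, object@seed))
})
setMethod("show", "VascularCohort", function(object) {
  callNextMethod()
  cat(sprintf("vfProfiles: %d cases x %d vascular features\n",
              nrow(object@vfProfiles), ncol(object@vfProfiles)))
})
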