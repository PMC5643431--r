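#' Per-pixel 17-feature map for vascular-area classification
#'
#' Every pixel is described by 17 features: the distances to its 1st..5th
#' nearest endothelial-cell centroid (5), and the mean/SD/max/min of eosin
#' absorbance in square sliding windows of half-widths 5, 15 and 30 px (12),
#' with edge-replicated padding.  With fewer than 5 EC centroids the missing
#' distance features saturate at the tile diagonal.
#'
#' @param eosin numeric eosin absorbance matrix.
#' @param ec_centroids n x 2 matrix of (row, col) EC centroids.
#' @param stride feature-grid stride in px (1 = dense).
#' @param window_halfwidths window half-widths (3 values).
#' @return object of class \code{pixelFeatureMap}: list with \code{features}
#'   (pixels x 17 matrix in column-major grid order), \code{rows},
#'   \code{cols} (grid coordinates), \code{dim}, and \code{stride}.
#' @export
pixelFeatures <- function(eosin, ec_centroids, stride = 1L,
                          window_halfwidths = c(5L, 15L, 30L)) {
  if (length(eosin) == 0) stop("empty eosin image")
  stopifnot(length(window_halfwidths) == 3)
  nr <- nrow(eosin); nc <- ncol(eosin)
  rows <- seq(1L, nr, by = stride)
  cols <- seq(1L, nc, by = stride)
  grid <- cbind(rep(rows, times = length(cols)), rep(cols, each = length(rows)))
  cap <- sqrt(nr^2 + nc^2)
  k_av <- min(5L, nrow(ec_centroids))
  D <- matrix(cap, nrow(grid), 5)
  if (k_av > 0) {
    D[, seq_len(k_av)] <-
      FNN::knnx.dist(ec_centroids, grid, k = k_av)
  }
  wmats <- lapply(window_halfwidths, function(hw) cpp_window_stats(eosin, as.integer(hw)))
  idx <- cbind(grid[, 1], grid[, 2])
  W <- do.call(cbind, lapply(wmats, function(s)
    cbind(s$mean[idx], s$sd[idx], s$max[idx], s$min[idx])))
  feats <- cbind(D, W)
  colnames(feats) <- c(paste0("ec_dist_", 1:5),
                       as.vector(t(outer(paste0("eosin_w", window_halfwidths),
                                         c("mean", "sd", "max", "min"),
                                         paste, sep = "_"))))
  structure(list(features = feats, rows = rows, cols = cols,
                 dim = c(nr, nc), stride = as.integer(stride)),
            class = "pixelFeatureMap")
}

#' Train the pixel-wise vascular-area classifier
#'
#' A bootstrap-aggregated decision-tree ensemble (bagged CART, Gini
#' impurity, random feature subsets per split) trained on \code{n_samples}
#' pixels drawn stratified from CD31-positive and CD31-negative areas.
#'
#' @param feature_samples pixels x 17 feature matrix (or a
#'   \code{pixelFeatureMap}).
#' @param cd31_labels logical/0-1 vector: pixel lies in CD31-positive area.
#' @param n_samples total training pixels after stratified sampling
#'   (default 6000).
#' @param n_trees trees in the ensemble.
#' @param mtry features tried per split.
#' @param seed integer seed.
#' @return object of class \code{vamForest} with the ensemble and the
#'   out-of-bag vascular-probability estimates/accuracy.
#' @export
trainVamClassifier <- function(feature_samples, cd31_labels, n_samples = 6000L,
                               n_trees = 100L, mtry = 4L, seed = 1L) {
  if (inherits(feature_samples, "pixelFeatureMap"))
    feature_samples <- feature_samples$features
  X <- as.matrix(feature_samples)
  y <- as.integer(as.logical(cd31_labels))
  if (length(unique(y)) < 2) stop("both classes must be present in the sample")
  set.seed(as.integer(seed))
  per <- n_samples %/% 2L
  pick <- function(idx) idx[sample.int(length(idx), min(per, length(idx)))]
  sel <- c(pick(which(y == 1L)), pick(which(y == 0L)))
  X <- X[sel, , drop = FALSE]; y <- y[sel]
  fit <- cpp_forest_fit(X, y, as.integer(n_trees), as.integer(mtry), 5L, 25L)
  oob_p <- ifelse(fit$oob_n > 0, fit$oob_sum / pmax(fit$oob_n, 1L), NA_real_)
  structure(list(trees = fit$trees, n_trees = n_trees, mtry = mtry,
                 feature_names = colnames(feature_samples),
                 oob_prob = oob_p,
                 oob_accuracy = mean((oob_p > 0.5) == (y == 1L), na.rm = TRUE),
                 seed = as.integer(seed)),
            class = "vamForest")
}

#' Predict the vascular area mask
#'
#' Thresholds the per-pixel vascular probability, then cleans the mask by
#' morphological closing (disc, \code{closing_radius}) and removal of
#' components below \code{min_component} px.
#'
#' @param classifier a \code{vamForest}.
#' @param feature_map a \code{pixelFeatureMap} with stride 1.
#' @param threshold probability threshold (default 0.5).
#' @param closing_radius,min_component clean-up parameters.
#' @param tile_id identifier stored in the mask.
#' @return A [VascularAreaMask-class].
#' @export
predictVam <- function(classifier, feature_map, threshold = 0.5,
                       closing_radius = 3, min_component = 50L,
                       tile_id = "tile") {
  stopifnot(inherits(feature_map, "pixelFeatureMap"))
  p <- vamProbability(classifier, feature_map)
  mask <- p > threshold
  if (any(mask)) {
    mask <- morphClose(mask, closing_radius)
    mask <- removeSmallComponents(mask, min_component)
  }
  new("VascularAreaMask", mask = mask, tileId = tile_id)
}

#' @rdname predictVam
#' @return \code{vamProbability()}: the raw probability matrix on the
#'   feature grid (pre-threshold, pre-morphology).
#' @export
vamProbability <- function(classifier, feature_map) {
  stopifnot(inherits(feature_map, "pixelFeatureMap"))
  pv <- cpp_forest_predict(classifier$trees, feature_map$features)
  matrix(pv, length(feature_map$rows), length(feature_map$cols))
}

#' Post-process a VAM into skeleton, branch points, and arms
#'
#' Topology-preserving thinning to a 1-px skeleton; branch points are
#' skeleton pixels with >= 3 skeleton neighbours (8-connectivity), with
#' 8-connected runs of branch pixels clustered to a single point at their
#' centroid; arms are the connected skeleton segments that remain after
#' removing branch pixels, each with its pixel chain, length, and the axial
#' orientation (degrees in [0, 180)) of its principal axis.
#'
#' @param vam a [VascularAreaMask-class] or logical matrix.
#' @param min_spur branch-attached terminal arms shorter than this many
#'   pixels are pruned as thinning artifacts before the final analysis.
#' @return A [VascularSkeleton-class]; an empty mask yields an empty
#'   skeleton with 0 branch points and 0 arms.
#' @export
postprocessVam <- function(vam, min_spur = 4L) {
  mask <- if (is(vam, "VascularAreaMask")) vam@mask else vam
  storage.mode(mask) <- "logical"
  if (!any(mask))
    return(new("VascularSkeleton", skeleton = mask,
               branchPoints = matrix(numeric(0), 0, 2), arms = list(),
               eulerComponents = 0L))
  sk <- cpp_thin(mask)
  pass <- 0L
  repeat {
    pass <- pass + 1L
    ## branch pixels: >= 3 skeleton neighbours AND >= 3 distinct exiting
    ## directions (crossing number), which is robust to diagonal staircases
    branch_px <- sk & neighborCount8(sk) >= 3L & crossingNumber(sk) >= 3L
    arms <- traceArms(sk, branch_px)
    if (!any(branch_px) || min_spur <= 1 || pass > 3) break
    near_branch <- neighborCount8(branch_px) > 0L
    lab <- labelComponents(branch_px, 8L)
    adjClusters <- function(r, c) {
      rr <- pmin(pmax(r + c(-1, -1, -1, 0, 0, 1, 1, 1), 1), nrow(sk))
      cc <- pmin(pmax(c + c(-1, 0, 1, -1, 1, -1, 0, 1), 1), ncol(sk))
      unique(lab[cbind(rr, cc)][lab[cbind(rr, cc)] > 0])
    }
    spur <- vapply(arms, function(a) {
      if (a$length >= min_spur) return(FALSE)
      h <- a$pixels[1, ]; t <- a$pixels[a$length, ]
      if (!near_branch[h[1], h[2]]) return(FALSE)  # not junction-attached
      ## keep short arms that bridge two distinct junction clusters
      length(unique(c(adjClusters(h[1], h[2]), adjClusters(t[1], t[2])))) < 2
    }, TRUE)
    if (!any(spur)) break
    for (a in arms[spur]) sk[a$pixels] <- FALSE
  }
  bp_lab <- labelComponents(branch_px, 8L)
  bp <- matrix(numeric(0), 0, 2)
  if (max(bp_lab) > 0) {
    ind <- which(bp_lab > 0, arr.ind = TRUE)
    bp <- do.call(rbind, lapply(seq_len(max(bp_lab)), function(l)
      colMeans(ind[bp_lab[ind] == l, , drop = FALSE])))
  }
  new("VascularSkeleton", skeleton = sk, branchPoints = bp, arms = arms,
      eulerComponents = max(labelComponents(sk, 8L)))
}

## Arm extraction by chain walking: every non-branch skeleton pixel is
## claimed by exactly one arm, so total arm length + branch pixels =
## skeleton pixel count.  Walks start at branch-cluster neighbours, then
## endpoints, then leftover (cycle) pixels; at forks the walk prefers
## orthogonal, non-branch-adjacent continuations, which keeps diagonal
## staircases from jumping between arms around a removed junction.
traceArms <- function(sk, branch_px) {
  nr <- nrow(sk); nc <- ncol(sk)
  off <- cbind(dr = c(-1, 1, 0, 0, -1, -1, 1, 1),
               dc = c(0, 0, -1, 1, -1, 1, -1, 1))   # orthogonal first
  near_branch <- if (any(branch_px)) neighborCount8(branch_px) > 0L else
    matrix(FALSE, nr, nc)
  visited <- matrix(FALSE, nr, nc)
  arms <- list()
  walk <- function(r, c) {
    chain <- matrix(0L, 64L, 2L); n <- 0L
    repeat {
      visited[r, c] <<- TRUE
      n <- n + 1L
      if (n > nrow(chain)) chain <- rbind(chain, matrix(0L, nrow(chain), 2L))
      chain[n, ] <- c(r, c)
      rr <- r + off[, 1]; cc <- c + off[, 2]
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      ok[ok] <- sk[cbind(rr[ok], cc[ok])] & !branch_px[cbind(rr[ok], cc[ok])] &
        !visited[cbind(rr[ok], cc[ok])]
      if (!any(ok)) break
      cand <- which(ok)
      score <- (cand > 4) + 2 * near_branch[cbind(rr[cand], cc[cand])]
      pick <- cand[order(score)[1]]
      r <- rr[pick]; c <- cc[pick]
    }
    chain[seq_len(n), , drop = FALSE]
  }
  addArm <- function(px) {
    arms[[length(arms) + 1L]] <<- list(pixels = px, length = nrow(px),
                                       orientation = axialOrientation(px))
  }
  ## seeds next to branch clusters
  if (any(branch_px)) {
    bidx <- which(branch_px, arr.ind = TRUE)
    for (i in seq_len(nrow(bidx))) {
      rr <- bidx[i, 1] + off[, 1]; cc <- bidx[i, 2] + off[, 2]
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      ok[ok] <- sk[cbind(rr[ok], cc[ok])] & !branch_px[cbind(rr[ok], cc[ok])] &
        !visited[cbind(rr[ok], cc[ok])]
      for (j in which(ok)) {
        if (!visited[rr[j], cc[j]]) addArm(walk(rr[j], cc[j]))
      }
    }
  }
  ## endpoints of branch-free segments, then any leftover (cycles)
  rest <- sk & !branch_px & !visited
  if (any(rest)) {
    deg <- neighborCount8(sk & !branch_px)
    ends <- which(rest & deg <= 1L, arr.ind = TRUE)
    for (i in seq_len(nrow(ends)))
      if (!visited[ends[i, 1], ends[i, 2]]) addArm(walk(ends[i, 1], ends[i, 2]))
    left <- which(sk & !branch_px & !visited, arr.ind = TRUE)
    for (i in seq_len(nrow(left)))
      if (!visited[left[i, 1], left[i, 2]]) addArm(walk(left[i, 1], left[i, 2]))
  }
  arms
}

## principal-axis orientation of a pixel set, degrees in [0, 180).
## 0 = horizontal (along columns), 90 = vertical.
axialOrientation <- function(px) {
  if (nrow(px) < 2) return(0)
  dr <- px[, 1] - mean(px[, 1]); dc <- px[, 2] - mean(px[, 2])
  mu20 <- mean(dc^2); mu02 <- mean(dr^2); mu11 <- mean(dc * dr)
  if (mu20 == mu02 && mu11 == 0) return(0)
  ang <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  ang %% 180
}
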