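#' Euler-Poincare characteristic of a binary image
#'
#' Number of 8-connected foreground components minus number of 4-connected
#' holes (background components not touching the image border).
#'
#' @param mask logical matrix.
#' @return integer.
#' @export
eulerPoincare <- function(mask) {
  storage.mode(mask) <- "logical"
  if (!any(mask)) return(0L)
  comp <- max(labelComponents(mask, 8L))
  bg <- labelComponents(!mask, 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  holes <- length(setdiff(unique(bg[bg > 0L]), border))
  as.integer(comp - holes)
}

#' Box-counting fractal dimension
#'
#' Least-squares slope of \code{log N(s)} versus \code{log(1/s)}, where
#' \code{N(s)} counts boxes of side \code{s} (grid anchored at the image
#' origin) containing at least one foreground pixel.
#'
#' @param mask logical matrix.
#' @param box_sizes >= 3 box sides, dyadic \code{2,4,...,256} by default
#'   (sizes not smaller than both image dimensions are dropped).
#' @return the dimension estimate in [0, 2]; \code{NA} with a warning for an
#'   empty mask.
#' @export
boxCountingDimension <- function(mask, box_sizes = 2^(1:8)) {
  storage.mode(mask) <- "logical"
  if (!any(mask)) { warning("empty mask: fractal dimension undefined"); return(NA_real_) }
  box_sizes <- box_sizes[box_sizes <= min(dim(mask))]
  if (length(box_sizes) < 3) stop("need >= 3 usable box sizes")
  counts <- vapply(box_sizes, function(s) {
    ri <- (seq_len(nrow(mask)) - 1L) %/% s
    ci <- (seq_len(ncol(mask)) - 1L) %/% s
    occ <- rowsum(mask + 0L, ri) > 0L              # rows collapsed
    sum(rowsum(t(occ) + 0L, ci) > 0L)              # then columns
  }, 0)
  fit <- stats::lm.fit(cbind(1, log(1 / box_sizes)), log(counts))
  unname(fit$coefficients[2])
}

#' Sliding-box lacunarity
#'
#' \code{Lambda = E[M^2] / E[M]^2} over all positions of a \code{box_size}
#' square box, where \code{M} is the foreground mass in the box.  The
#' default stride 1 slides densely; grid-aligned gliding (stride =
#' \code{box_size}) is available for fixtures whose boxes tile the pattern
#' exactly.
#'
#' @param mask logical matrix.
#' @param box_size box side, smaller than both image dimensions
#'   (equality allowed when it tiles the image).
#' @param stride box step in px (default 1 = dense).
#' @return lacunarity >= 1; \code{NA} with a warning for an empty mask.
#' @export
slidingBoxLacunarity <- function(mask, box_size = 32L, stride = 1L) {
  storage.mode(mask) <- "logical"
  if (!any(mask)) { warning("empty mask: lacunarity undefined"); return(NA_real_) }
  nr <- nrow(mask); nc <- ncol(mask)
  b <- as.integer(box_size)
  if (b > nr || b > nc) stop("box_size must not exceed image dimensions")
  ## integral image for box masses
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1, -1] <- t(apply(apply(mask + 0, 2, cumsum), 1, cumsum))
  r0 <- seq(0L, nr - b, by = stride)
  c0 <- seq(0L, nc - b, by = stride)
  M <- S[r0 + b + 1L, c0 + b + 1L, drop = FALSE] - S[r0 + 1L, c0 + b + 1L, drop = FALSE] -
       S[r0 + b + 1L, c0 + 1L, drop = FALSE] + S[r0 + 1L, c0 + 1L, drop = FALSE]
  m1 <- mean(M)
  if (m1 == 0) return(NA_real_)
  mean(M^2) / m1^2
}

#' The fixed 22-name primary tile-feature roster
#'
#' Twenty-two binary-image features over the four object sets (EC nucleus
#' mask, branch-point mask, arm skeleton, VAM): density, lacunarity, and
#' box-counting fractal dimension for every set; mean nearest-neighbour
#' distance for ECs; arm count, mean arm length, and circular SD of axial
#' arm orientations; and area fraction, object count, mean object area,
#' mean solidity, mean eccentricity, mean extent, and the Euler-Poincare
#' characteristic for the VAM.
#'
#' @return character vector of 22 feature names.
#' @export
primaryFeatureRoster <- function() c(
  "ec_density", "ec_lacunarity", "ec_fractal_dim", "ec_mean_nn_dist",
  "bp_density", "bp_lacunarity", "bp_fractal_dim",
  "arm_density", "arm_lacunarity", "arm_fractal_dim",
  "arm_count", "arm_mean_length", "arm_orient_sd",
  "vam_area_fraction", "vam_lacunarity", "vam_fractal_dim",
  "vam_object_count", "vam_mean_object_area", "vam_mean_solidity",
  "vam_mean_eccentricity", "vam_mean_extent", "vam_euler")

## circular SD (degrees) of axial orientations: angles are doubled so the
## statistic respects the [0, 180) wrap-around of axial data.
circularSdAxial <- function(deg) {
  if (length(deg) == 0) return(NA_real_)
  th <- 2 * deg * pi / 180
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  if (R <= 0) return(180 / 2)
  sqrt(-2 * log(R)) * 180 / pi / 2
}

maskLacFd <- function(mask, lac_box) {
  if (!any(mask)) return(c(NA_real_, NA_real_))
  c(slidingBoxLacunarity(mask, min(lac_box, dim(mask))),
    boxCountingDimension(mask))
}

#' Compute the 22 primary features of one tile
#'
#' @param ec_mask logical matrix of EC nucleus pixels (or n x 2 centroid
#'   matrix, stamped as 2-px discs).
#' @param bp_mask logical matrix of branch-point pixels (or a
#'   [VascularSkeleton-class], from which branch points and arms are taken).
#' @param arm_records list of arm records (ignored when \code{bp_mask} is a
#'   skeleton); each needs \code{pixels}, \code{length}, \code{orientation}.
#' @param vam a [VascularAreaMask-class] or logical matrix.
#' @param lac_box lacunarity box size (default 32).
#' @return named numeric vector of length 22; features undefined on an
#'   empty tile are \code{NA} sentinels (flagged via \code{attr(, "flagged")}).
#' @export
tilePrimaryFeatures <- function(ec_mask, bp_mask, arm_records, vam,
                                lac_box = 32L) {
  vmask <- if (is(vam, "VascularAreaMask")) vam@mask else vam
  dims <- dim(vmask)
  if (is(bp_mask, "VascularSkeleton")) {
    sk <- bp_mask
    arm_records <- sk@arms
    bp <- matrix(FALSE, dims[1], dims[2])
    if (nrow(sk@branchPoints) > 0)
      bp[round(sk@branchPoints)] <- TRUE
    bp_mask <- bp
  }
  if (is.matrix(ec_mask) && ncol(ec_mask) == 2 && !is.logical(ec_mask)) {
    m <- matrix(FALSE, dims[1], dims[2])
    if (nrow(ec_mask) > 0) m <- stampDiscs(m, ec_mask, rep(2, nrow(ec_mask)))
    ec_centers <- ec_mask
    ec_mask <- m
  } else {
    cc <- labelComponents(ec_mask, 8L)
    ec_centers <- if (max(cc) > 0) {
      ind <- which(cc > 0, arr.ind = TRUE)
      do.call(rbind, lapply(seq_len(max(cc)), function(l)
        colMeans(ind[cc[ind] == l, , drop = FALSE])))
    } else matrix(numeric(0), 0, 2)
  }
  if (!identical(dim(ec_mask), dims) || !identical(dim(bp_mask), dims))
    stop("object masks must share the tile dimensions")

  arm_mask <- matrix(FALSE, dims[1], dims[2])
  for (a in arm_records) arm_mask[a$pixels] <- TRUE
  ors <- vapply(arm_records, `[[`, 0, "orientation")
  lens <- vapply(arm_records, `[[`, 0, "length")

  ec_nn <- if (nrow(ec_centers) >= 2)
    mean(FNN::knn.dist(ec_centers, k = 1)) else NA_real_

  vstats <- c(count = 0, area = NA_real_, solidity = NA_real_,
              ecc = NA_real_, extent = NA_real_)
  if (any(vmask)) {
    lab <- labelComponents(vmask, 8L)
    ind <- which(lab > 0, arr.ind = TRUE)
    per_obj <- vapply(seq_len(max(lab)), function(l) {
      px <- ind[lab[ind] == l, , drop = FALSE]
      a <- nrow(px)
      bb <- (diff(range(px[, 1])) + 1) * (diff(range(px[, 2])) + 1)
      if (a >= 3) {
        h <- px[chull(px[, 2], px[, 1]), , drop = FALSE]
        ha <- max(polygonArea(h), a)
        dr <- px[, 1] - mean(px[, 1]); dc <- px[, 2] - mean(px[, 2])
        C <- matrix(c(mean(dr^2), mean(dr * dc), mean(dr * dc), mean(dc^2)), 2, 2)
        ev <- sort(pmax(eigen(C, symmetric = TRUE, only.values = TRUE)$values, 0),
                   decreasing = TRUE)
        ecc <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0
      } else { ha <- a; ecc <- 0 }
      c(a, min(a / ha, 1), ecc, a / bb)
    }, numeric(4))
    vstats <- c(count = max(lab), area = mean(per_obj[1, ]),
                solidity = mean(per_obj[2, ]), ecc = mean(per_obj[3, ]),
                extent = mean(per_obj[4, ]))
  }

  out <- c(
    mean(ec_mask), maskLacFd(ec_mask, lac_box), ec_nn,
    mean(bp_mask), maskLacFd(bp_mask, lac_box),
    mean(arm_mask), maskLacFd(arm_mask, lac_box),
    length(arm_records),
    if (length(lens)) mean(lens) else NA_real_,
    circularSdAxial(ors),
    mean(vmask), maskLacFd(vmask, lac_box),
    vstats["count"], vstats["area"], vstats["solidity"], vstats["ecc"],
    vstats["extent"],
    eulerPoincare(vmask))
  names(out) <- primaryFeatureRoster()
  attr(out, "flagged") <- names(out)[is.na(out)]
  out
}

#' Aggregate tile features into the 88 per-case vascular features
#'
#' For each of the 22 primary features: sample mean, sample SD (n-1),
#' skewness (g1) and excess kurtosis (g2) across the case's tiles.
#' NA-sentinel tile values are excluded per feature (with count
#' bookkeeping); zero-variance features get NA skewness/kurtosis sentinels.
#'
#' @param tiles list of >= 3 primary feature vectors from
#'   [tilePrimaryFeatures()].
#' @param case_id case identifier attribute.
#' @return named numeric vector of length 88
#'   (\code{<feature>_<mean|sd|skewness|kurtosis>}), with attributes
#'   \code{case_id}, \code{n_tiles}, and per-feature \code{n_used}.
#' @export
aggregateCase <- function(tiles, case_id = "case") {
  if (length(tiles) < 3) stop("a case needs >= 3 tiles")
  M <- do.call(rbind, tiles)
  stopifnot(ncol(M) == 22)
  moments <- c("mean", "sd", "skewness", "kurtosis")
  out <- numeric(0)
  n_used <- integer(ncol(M))
  for (j in seq_len(ncol(M))) {
    v <- M[, j]; v <- v[is.finite(v)]
    n_used[j] <- length(v)
    if (length(v) == 0) { vals <- rep(NA_real_, 4) }
    else {
      m <- mean(v); s <- sd(v)
      if (length(v) < 2 || s == 0) vals <- c(m, if (length(v) < 2) NA else 0, NA, NA)
      else {
        z <- (v - m) / (s * sqrt((length(v) - 1) / length(v)))  # population sd for g1/g2
        vals <- c(m, s, mean(z^3), mean(z^4) - 3)
      }
    }
    out <- c(out, setNames(vals, paste(colnames(M)[j], moments, sep = "_")))
  }
  attr(out, "case_id") <- case_id
  attr(out, "n_tiles") <- length(tiles)
  attr(out, "n_used") <- setNames(n_used, colnames(M))
  out
}
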