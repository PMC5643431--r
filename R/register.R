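## Intensity-based affine co-registration on absorbance images.
## The spec'd landmark channel is hematoxylin absorbance from both tiles.

downsample2 <- function(img) {
  nr <- 2L * (nrow(img) %/% 2L); nc <- 2L * (ncol(img) %/% 2L)
  img <- img[seq_len(nr), seq_len(nc)]
  0.25 * (img[seq(1, nr, 2), seq(1, nc, 2)] + img[seq(2, nr, 2), seq(1, nc, 2)] +
          img[seq(1, nr, 2), seq(2, nc, 2)] + img[seq(2, nr, 2), seq(2, nc, 2)])
}

## params p = (tr, tc, theta, log_scale, a_shear, b_shear) about image center.
## Returns the 6-vector (a11,a12,a21,a22,tr,tc) consumed by cpp_warp_affine,
## mapping fixed (row, col) -> moving (row, col), 0-based.
paramsToWarp <- function(p, dims) {
  s <- exp(p[4])
  R <- matrix(c(cos(p[3]), -sin(p[3]), sin(p[3]), cos(p[3])), 2, 2, byrow = TRUE)
  Sh <- matrix(c(1, p[5], p[6], 1), 2, 2, byrow = TRUE)
  A <- s * R %*% Sh
  ctr <- (dims - 1) / 2
  t <- ctr + p[1:2] - A %*% ctr
  c(A[1, 1], A[1, 2], A[2, 1], A[2, 2], t[1], t[2])
}

warpMSE <- function(p, fixed, moving) {
  w <- cpp_warp_affine(moving, paramsToWarp(p, dim(fixed)))
  d <- (fixed - w)^2
  v <- d[is.finite(d)]
  if (length(v) < 0.25 * length(d)) return(1e6)   # insufficient overlap
  mean(v)
}

#' Register a moving image to a fixed image with an affine transform
#'
#' Multi-resolution (3-level pyramid) minimization of the mean-squared
#' intensity error with Nelder-Mead refinement, parameterized as translation,
#' rotation, log-scale and shears about the image center.  Intended inputs
#' are hematoxylin absorbance channels, which both H&E and IHC tiles share
#' as a landmark.
#'
#' @param fixed,moving numeric matrices of equal dimension.
#' @param max_iter optimizer iteration budget per pyramid level.
#' @param tol on convergence, the transform snaps to identity when within
#'   0.25 px RMS displacement of it.
#' @return An [AffineTransform-class] mapping moving (row, col) to fixed
#'   (row, col); \code{converged = FALSE} flags a poor final metric.
#' @export
registerAffine <- function(fixed, moving, max_iter = 300L, tol = 0.25) {
  if (!identical(dim(fixed), dim(moving))) stop("images must share dimensions")
  pyr_f <- list(fixed); pyr_m <- list(moving)
  for (l in 2:3) {
    pyr_f[[l]] <- downsample2(pyr_f[[l - 1]])
    pyr_m[[l]] <- downsample2(pyr_m[[l - 1]])
  }
  p <- rep(0, 6)
  for (l in 3:1) {
    f <- pyr_f[[l]]; m <- pyr_m[[l]]
    sc <- 2^(l - 1)
    p[1:2] <- p[1:2] / sc
    ## coarse translation sweep at the coarsest level stabilizes large shifts
    if (l == 3) {
      grid <- expand.grid(tr = seq(-8, 8, 2), tc = seq(-8, 8, 2))
      mse <- apply(grid, 1, function(g) warpMSE(c(g[1], g[2], p[3:6]), f, m))
      p[1:2] <- as.numeric(grid[which.min(mse), ])
    }
    opt <- optim(p, warpMSE, fixed = f, moving = m, method = "Nelder-Mead",
                 control = list(maxit = max_iter, reltol = 1e-10,
                                parscale = c(1, 1, 0.02, 0.02, 0.02, 0.02)))
    p <- opt$par
    p[1:2] <- p[1:2] * sc
  }
  metric <- warpMSE(p, fixed, moving)
  ## fixed -> moving warp, inverted to the spec'd moving -> fixed convention
  w <- paramsToWarp(p, dim(fixed))
  A <- matrix(w[1:4], 2, 2, byrow = TRUE)
  t <- w[5:6]
  Ainv <- solve(A)
  m23 <- cbind(Ainv, -Ainv %*% t)
  ## snap to identity for already-aligned inputs
  corners <- rbind(c(0, 0), c(nrow(fixed) - 1, 0), c(0, ncol(fixed) - 1),
                   c(nrow(fixed) - 1, ncol(fixed) - 1))
  disp <- sqrt(rowSums((t(m23[, 1:2] %*% t(corners)) +
                        rep(m23[, 3], each = 4) - corners)^2))
  if (max(disp) < tol) m23 <- cbind(diag(2), c(0, 0))
  baseline <- mean((fixed - mean(fixed))^2)
  new("AffineTransform", m = m23, converged = metric < 0.5 * baseline,
      metric = metric)
}

#' Apply an affine transform to an image or mask
#'
#' Resamples \code{img} (living in the moving frame) into the fixed frame of
#' the transform.  Logical masks are warped with bilinear interpolation and
#' re-thresholded at 0.5; out-of-frame pixels become \code{fill}.
#'
#' @param img numeric or logical matrix in the moving frame.
#' @param transform an [AffineTransform-class] (moving -> fixed).
#' @param fill value for unmapped pixels.
#' @return matrix in the fixed frame, same type as the input.
#' @export
applyTransform <- function(img, transform, fill = 0) {
  logical_in <- is.logical(img)
  A <- transform@m[, 1:2]; t <- transform@m[, 3]
  Ainv <- solve(A)                      # fixed -> moving resampling map
  par <- c(Ainv[1, 1], Ainv[1, 2], Ainv[2, 1], Ainv[2, 2], -Ainv %*% t)
  out <- cpp_warp_affine(img + 0, par)
  out[!is.finite(out)] <- fill
  if (logical_in) out > 0.5 else out
}

#' Transfer IHC class labels onto H&E nucleus contours
#'
#' Warps the CD31/CD45 masks into the H&E frame, dilates each by a disc of
#' \code{dilation_radius} pixels, and labels a nucleus \code{endothelial}
#' (CD31) or \code{lymphocyte} (CD45) when at least \code{overlap_frac} of
#' its interior pixels fall inside the warped, dilated mask; ties go to CD31
#' and unlabeled nuclei are \code{cancer}.
#'
#' @param ihc an [IHCLabelMask-class] in the IHC (moving) frame.
#' @param transform an [AffineTransform-class] mapping IHC to H&E.
#' @param nuclei list of nucleus contours (n x 2 (row, col) matrices, or
#'   \code{list(coords=)} records as produced by [segmentNuclei()]).
#' @param dilation_radius disc radius in px (default 5).
#' @param overlap_frac required interior overlap fraction in (0, 1],
#'   default 0.5.
#' @return character vector of class labels, one per nucleus (empty contours
#'   are skipped with a warning and labeled \code{NA}).
#' @export
transferLabels <- function(ihc, transform, nuclei, dilation_radius = 5,
                           overlap_frac = 0.5) {
  if (overlap_frac <= 0 || overlap_frac > 1) stop("overlap_frac must be in (0, 1]")
  cd31 <- dilateDisc(applyTransform(ihc@cd31, transform), dilation_radius)
  cd45 <- dilateDisc(applyTransform(ihc@cd45, transform), dilation_radius)
  dims <- dim(cd31)
  out <- character(length(nuclei))
  for (i in seq_along(nuclei)) {
    coords <- if (is.list(nuclei[[i]])) nuclei[[i]]$coords else nuclei[[i]]
    if (is.null(coords) || nrow(coords) < 3) {
      warning("nucleus ", i, " has a degenerate contour; skipped")
      out[i] <- NA_character_
      next
    }
    px <- polygonInterior(coords, dims)
    if (nrow(px) == 0) { out[i] <- "cancer"; next }
    f31 <- mean(cd31[px])
    f45 <- mean(cd45[px])
    out[i] <- if (f31 >= overlap_frac && f31 >= f45) "endothelial"
      else if (f45 >= overlap_frac) "lymphocyte" else "cancer"
  }
  out
}
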