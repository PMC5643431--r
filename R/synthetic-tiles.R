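#' Generate a synthetic branched vascular tile with paired ground truth
#'
#' Grows a branched tubular network by a biased random walk with Bernoulli
#' branching per step, places endothelial-cell (EC) nuclei along the vessel
#' walls, fills the non-vascular space with cancer nuclei (plus a few
#' lymphocytes), and renders the scene twice by Beer-Lambert stain mixing:
#' once as H&E (hematoxylin on nuclei, eosin on the vessel matrix) and once
#' as pseudo-IHC (hematoxylin on nuclei, CD31 purple ink on the vascular
#' area, DAB on lymphocytes).  The returned tile carries the exact vessel
#' mask, per-class nucleus centroids, and nucleus contours as rendered.
#'
#' @param width,height tile dimensions in pixels (>= 128; default 256).
#' @param n_seeds number of walk seed points (0 = avascular tile).
#' @param branch_prob per-step Bernoulli branching probability in [0, 1].
#' @param thickness_range (min, max) vessel diameter in px.
#' @param curvature_sd angular noise (radians) per step; 0 = straight growth.
#' @param n_cancer target number of cancer nuclei (non-touching).
#' @param n_lymph number of lymphocyte nuclei.
#' @param ec_spacing approximate spacing of EC nuclei along vessel walls (px).
#' @param noise_sd Gaussian intensity noise of the rendering.
#' @param seed integer seed; regeneration with identical arguments is
#'   bit-identical.
#' @return A [GroundTruthTile-class] object.
#' @examples
#' tile <- generateVesselNetwork(256, 256, n_seeds = 2, seed = 7)
#' tile
#' @export
generateVesselNetwork <- function(width = 256, height = 256, n_seeds = 3,
                                  branch_prob = 0.02,
                                  thickness_range = c(6, 12),
                                  curvature_sd = 0.12,
                                  n_cancer = 120, n_lymph = 6,
                                  ec_spacing = 14, noise_sd = 0.01,
                                  seed = 1L) {
  if (width <= 0 || height <= 0) stop("tile dimensions must be positive")
  if (width < 128 || height < 128) stop("tiles below 128 px are not supported")
  if (branch_prob < 0 || branch_prob > 1) stop("branch_prob must be in [0, 1]")
  set.seed(as.integer(seed))
  nr <- height; nc <- width
  mask <- matrix(FALSE, nr, nc)

  ## --- vessel growth: biased random walk with Bernoulli branching ---------
  ## every walker carries a finite step budget; children inherit a shrinking
  ## share, which keeps total vessel area in a histologically plausible range
  max_walkers <- 50L
  n_spawned <- 0L
  walkers <- list()
  if (n_seeds > 0) {
    for (i in seq_len(n_seeds)) {
      walkers[[i]] <- list(r = runif(1, 0.15 * nr, 0.85 * nr),
                           c = runif(1, 0.15 * nc, 0.85 * nc),
                           a = runif(1, 0, 2 * pi),
                           th = runif(1, thickness_range[1], thickness_range[2]),
                           budget = round(runif(1, 0.5, 1.2) * max(nr, nc)))
    }
    n_spawned <- n_seeds
  }
  pts <- vector("list", 5000L); np <- 0L
  while (length(walkers) > 0) {
    w <- walkers[[1]]; walkers[[1]] <- NULL
    repeat {
      w$budget <- w$budget - 1L
      if (w$budget <= 0L) break
      w$a <- w$a + rnorm(1, 0, curvature_sd)
      w$r <- w$r + sin(w$a); w$c <- w$c + cos(w$a)
      if (w$r < 2 || w$r > nr - 1 || w$c < 2 || w$c > nc - 1) break
      np <- np + 1L
      if (np > length(pts)) pts <- c(pts, vector("list", length(pts)))
      pts[[np]] <- c(w$r, w$c, w$th / 2)
      if (branch_prob > 0 && runif(1) < branch_prob &&
          n_spawned < max_walkers) {
        n_spawned <- n_spawned + 1L
        walkers[[length(walkers) + 1L]] <- list(
          r = w$r, c = w$c,
          a = w$a + sample(c(-1, 1), 1) * runif(1, pi / 6, pi / 3),
          th = runif(1, thickness_range[1], thickness_range[2]),
          budget = round(w$budget * runif(1, 0.5, 0.9)))
      }
    }
  }
  if (np > 0) {
    P <- do.call(rbind, pts[seq_len(np)])
    mask <- stampDiscs(mask, P[, 1:2, drop = FALSE], P[, 3])
  }

  ## --- EC nuclei along vessel walls ---------------------------------------
  ec <- matrix(numeric(0), 0, 2)
  if (any(mask)) {
    inner <- distanceTransform(!mask)           # distance to background
    wall <- mask & inner <= 2
    cand <- which(wall, arr.ind = TRUE)
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      p <- cand[i, ]
      if (nrow(ec) == 0 ||
          min((ec[, 1] - p[1])^2 + (ec[, 2] - p[2])^2) >= ec_spacing^2)
        ec <- rbind(ec, p)
    }
  }

  ## --- cancer + lymphocyte nuclei in non-vascular space -------------------
  keepout <- if (any(mask)) dilateDisc(mask, 6) else mask
  placeNuclei <- function(n, min_sep, rad_lim) {
    out <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(out) < n && tries < 40L * n) {
      tries <- tries + 1L
      p <- c(runif(1, rad_lim + 2, nr - rad_lim - 1),
             runif(1, rad_lim + 2, nc - rad_lim - 1))
      if (keepout[round(p[1]), round(p[2])]) next
      if (nrow(out) && min((out[, 1] - p[1])^2 + (out[, 2] - p[2])^2) < min_sep^2) next
      if (nrow(ec) && min((ec[, 1] - p[1])^2 + (ec[, 2] - p[2])^2) < min_sep^2) next
      out <- rbind(out, p)
    }
    out
  }
  cancer <- placeNuclei(n_cancer, min_sep = 15, rad_lim = 7)
  lymph <- placeNuclei(n_lymph, min_sep = 15, rad_lim = 4)

  ## --- nucleus geometry and contours --------------------------------------
  nuc_mask <- matrix(FALSE, nr, nc)
  lymph_ink <- matrix(FALSE, nr, nc)
  contours <- list()
  addNucleus <- function(ctr, a, b, theta, cls) {
    t <- seq(0, 2 * pi, length.out = 40L)[-40L]
    coords <- cbind(ctr[1] + a * cos(t) * sin(theta) + b * sin(t) * cos(theta),
                    ctr[2] + a * cos(t) * cos(theta) - b * sin(t) * sin(theta))
    contours[[length(contours) + 1L]] <<- list(class = cls, coords = coords)
    nuc_mask <<- stampEllipse(nuc_mask, ctr[1], ctr[2], a, b, theta)
    if (cls == "lymphocyte")
      lymph_ink <<- stampEllipse(lymph_ink, ctr[1], ctr[2], a + 2, b + 2, theta)
  }
  for (i in seq_len(nrow(ec)))
    addNucleus(ec[i, ], runif(1, 3.6, 4.6), runif(1, 1.8, 2.4),
               runif(1, 0, pi), "endothelial")
  for (i in seq_len(nrow(cancer)))
    addNucleus(cancer[i, ], runif(1, 5, 7), runif(1, 4, 5.5),
               runif(1, 0, pi), "cancer")
  for (i in seq_len(nrow(lymph)))
    addNucleus(lymph[i, ], runif(1, 2.6, 3.2), runif(1, 2.4, 2.8),
               runif(1, 0, pi), "lymphocyte")

  ## --- rendering -----------------------------------------------------------
  hema <- 0.75 * boxBlur(nuc_mask + 0, 1L) + 0.04
  eosin <- 0.55 * boxBlur(mask + 0, 2L) + 0.07
  rgb_he <- renderStains(list(hematoxylin = hema, eosin = eosin),
                         hematoxylinEosinBasis(), noise_sd = noise_sd)
  purple <- 0.7 * boxBlur(mask + 0, 1L) + 0.01
  dab <- 0.8 * boxBlur(lymph_ink + 0, 1L)
  rgb_ihc <- renderStains(list(hematoxylin = 0.6 * boxBlur(nuc_mask + 0, 1L) + 0.03,
                               cd31_purple = purple, dab = dab),
                          ihcBasis(), noise_sd = noise_sd)
  ## 8-bit quantization so tiles round-trip through PNG exactly
  rgb_he <- round(rgb_he * 255) / 255
  rgb_ihc <- round(rgb_ihc * 255) / 255

  emptyMat <- function(m) if (nrow(m)) m else matrix(numeric(0), 0, 2)
  new("GroundTruthTile", rgbHE = rgb_he, rgbIHC = rgb_ihc, vesselMask = mask,
      ecCentroids = emptyMat(ec), lymphCentroids = emptyMat(lymph),
      cancerCentroids = emptyMat(cancer), nucleusContours = contours,
      seed = as.integer(seed))
}
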