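## Shared fixtures, generated once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

## a branched vascular tile used by the stain/nuclei/vam tests
fixtureTile <- function() memo("tile", {
  generateVesselNetwork(256, 256, n_seeds = 3, branch_prob = 0.04, seed = 21)
})

fixtureChannels <- function() memo("channels", {
  unmixStains(fixtureTile()@rgbHE, hematoxylinEosinBasis())
})

fixtureFeatureMap <- function() memo("fmap", {
  pixelFeatures(channel(fixtureChannels(), "eosin"), ecCentroids(fixtureTile()))
})

## per-state RGB pixel samples drawn from a tile's pseudo-IHC rendering
fixtureIhcSamples <- function(tile, n = 200) {
  ihc <- tile@rgbIHC
  dims <- dim(tile@vesselMask)
  vm <- tile@vesselMask
  nucmask <- matrix(FALSE, dims[1], dims[2])
  lymphmask <- matrix(FALSE, dims[1], dims[2])
  for (ct in nucleusContours(tile)) {
    px <- vasculomorph:::polygonInterior(ct$coords, dims)
    nucmask[px] <- TRUE
    if (ct$class == "lymphocyte") lymphmask[px] <- TRUE
  }
  getpx <- function(sel) {
    idx <- which(sel)
    idx <- idx[seq_len(min(n, length(idx)))]
    cbind(ihc[, , 1][idx], ihc[, , 2][idx], ihc[, , 3][idx])
  }
  bg <- !vm & !nucmask
  list(dab = getpx(lymphmask & !vm),
       cd31_purple = getpx(vm & !nucmask),
       hematoxylin = getpx(nucmask & !vm & !lymphmask),
       white_bg = getpx(bg & ihc[, , 1] > 0.8),
       light_blue = getpx(bg & ihc[, , 1] <= 0.8 & ihc[, , 3] > ihc[, , 1]),
       light_brown = getpx(bg & ihc[, , 1] <= 0.8 & ihc[, , 3] <= ihc[, , 1]))
}

## filled disc as a logical matrix
discMask <- function(n, r0, c0, rad) {
  vasculomorph:::stampDiscs(matrix(FALSE, n, n), cbind(r0, c0), rad)
}

## rank-statistic AUC for a score vector against binary truth
rankAUC <- function(scores, truth) {
  r <- rank(scores)
  (sum(r[truth]) - sum(truth) * (sum(truth) + 1) / 2) /
    (sum(truth) * sum(!truth))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
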