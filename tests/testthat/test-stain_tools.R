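test_that("optical-density unmixing inverts Beer-Lambert rendering", {
  b <- hematoxylinEosinBasis()

  # pure-white image has zero absorbance everywhere
  ch <- unmixStains(array(1, c(16, 16, 3)), b, normalize = FALSE)
  expect_equal(max(abs(channel(ch, "hematoxylin"))), 0)
  expect_equal(max(abs(channel(ch, "eosin"))), 0)

  # a pixel colored exactly along stain vector 1 at OD 0.5
  img <- array(1, c(4, 4, 3))
  img[2, 2, ] <- 10^(-0.5 * b@vectors[, 1])
  ch <- unmixStains(img, b, normalize = FALSE)
  expect_equal(channel(ch, "hematoxylin")[2, 2], 0.5, tolerance = 1e-6)
  expect_equal(channel(ch, "eosin")[2, 2], 0, tolerance = 1e-8)

  # noise-free render-unmix round trip recovers densities up to scale
  set.seed(1)
  hd <- matrix(runif(64 * 64, 0, 0.8), 64, 64)
  ed <- matrix(runif(64 * 64, 0, 0.8), 64, 64)
  img <- renderStains(list(hematoxylin = hd, eosin = ed), b, noise_sd = 0)
  ch <- unmixStains(img, b, normalize = FALSE)
  expect_gt(cor(as.vector(channel(ch, "eosin")), as.vector(ed)), 0.999)
  expect_gt(cor(as.vector(channel(ch, "hematoxylin")), as.vector(hd)), 0.999)

  # degenerate basis refused
  v <- cbind(c(1, 0, 0), c(1, 0, 0))
  expect_error(new("StainBasis", vectors = v, i0 = c(1, 1, 1)) |> validObject())

  # on a rendered tile the recovered eosin channel tracks the true density
  tile <- fixtureTile()
  ed_true <- 0.55 * vasculomorph:::boxBlur(vesselMask(tile) + 0, 2L) + 0.07
  chn <- unmixStains(tile@rgbHE, b, normalize = FALSE)
  expect_gt(cor(as.vector(channel(chn, "eosin")), as.vector(ed_true)), 0.99)
})

test_that("color HMM training and Viterbi decoding recover known state structure", {
  set.seed(4)
  # six well-separated synthetic color clusters
  mus <- rbind(c(0.6, 0.35, 0.25), c(0.5, 0.2, 0.55), c(0.3, 0.27, 0.6),
               c(0.95, 0.95, 0.95), c(0.75, 0.8, 0.9), c(0.85, 0.75, 0.65))
  states <- vasculomorph:::ihcStateNames()
  samples <- lapply(seq_len(6), function(s)
    matrix(rnorm(3 * 60, mean = rep(mus[s, ], each = 60), sd = 0.015), 60, 3))
  names(samples) <- states
  model <- trainColorHMM(samples)
  expect_equal(rowSums(model@transition), rep(1, 6), tolerance = 1e-9)

  # decoding a sequence drawn from the generating states
  truth <- rep(sample(1:6, 40, replace = TRUE), each = 8)
  obs <- mus[truth, ] + rnorm(length(truth) * 3, 0, 0.015)
  path <- vasculomorph:::cpp_viterbi(vasculomorph:::hmmLogLik(obs, model),
                                     log(model@transition), log(model@initial))
  expect_gte(mean(path == truth), 0.99)

  # duplicated emissions are flagged
  dup <- samples; dup$light_brown <- dup$light_blue
  expect_warning(trainColorHMM(dup), "collision")

  # missing state refused
  expect_error(trainColorHMM(samples[-1]), "dab")
})

test_that("segmentIHC produces disjoint despeckled masks that match the ink", {
  tile <- fixtureTile()
  model <- memo("hmm_model", trainColorHMM(fixtureIhcSamples(tile)))

  # all-white image decodes to background only
  mw <- segmentIHC(array(1, c(40, 40, 3)), model)
  expect_equal(sum(cd31Mask(mw)), 0)
  expect_equal(sum(cd45Mask(mw)), 0)

  masks <- segmentIHC(tile@rgbIHC, model)
  expect_false(any(cd31Mask(masks) & cd45Mask(masks)))
  expect_gte(vasculomorph:::diceCoefficient(cd31Mask(masks), vesselMask(tile)), 0.8)

  # row independence: appending an all-background row leaves decoding unchanged
  sub <- tile@rgbIHC[1:40, 1:64, , drop = FALSE]
  padded <- array(1, c(41, 64, 3))
  padded[1:40, , ] <- sub
  m1 <- segmentIHC(sub, model, min_component = 1)
  m2 <- segmentIHC(padded, model, min_component = 1)
  expect_identical(cd31Mask(m1), cd31Mask(m2)[1:40, ])
})

test_that("affine registration recovers known warps to sub-pixel accuracy", {
  tile <- fixtureTile()
  h <- channel(fixtureChannels(), "hematoxylin")

  # identical images snap to the identity
  t1 <- registerAffine(h, h)
  expect_lt(max(abs(transformMatrix(t1) - cbind(diag(2), c(0, 0)))), 0.5)
  expect_true(t1@converged)

  # pure translation (7, -3)
  shift <- function(img, dr, dc) {
    out <- matrix(mean(img), nrow(img), ncol(img))
    rs <- max(1, 1 + dr):min(nrow(img), nrow(img) + dr)
    cs <- max(1, 1 + dc):min(ncol(img), ncol(img) + dc)
    out[rs, cs] <- img[rs - dr, cs - dc]
    out
  }
  t2 <- registerAffine(h, shift(h, 7, -3))
  expect_lt(max(abs(transformMatrix(t2)[, 3] - c(-7, 3))), 0.5)

  # 5-degree rotation about the image center
  th <- 5 * pi / 180
  mv <- vasculomorph:::cpp_warp_affine(
    h, vasculomorph:::paramsToWarp(c(0, 0, th, 0, 0, 0), dim(h)))
  mv[!is.finite(mv)] <- mean(h)
  t3 <- registerAffine(h, mv)
  A <- transformMatrix(t3)[, 1:2]
  expect_lt(abs(abs(atan2(A[2, 1], A[1, 1]) * 180 / pi) - 5), 0.5)

  # inverse consistency: forward then backward displacement stays below 1 px
  fwd <- t2
  bwd <- registerAffine(shift(h, 7, -3), h)
  compose <- function(a, b) {   # apply a then b on (row, col)
    A <- b@m[, 1:2] %*% a@m[, 1:2]
    t <- b@m[, 1:2] %*% a@m[, 3] + b@m[, 3]
    cbind(A, t)
  }
  m <- compose(fwd, bwd)
  corners <- rbind(c(0, 0), c(255, 0), c(0, 255), c(255, 255))
  disp <- sqrt(rowSums((t(m[, 1:2] %*% t(corners)) + rep(m[, 3], each = 4) -
                        corners)^2))
  expect_lt(max(disp), 1)

  expect_error(registerAffine(h, h[1:100, 1:100]), "dimensions")
})

test_that("label transfer imposes IHC classes at the 50% overlap rule", {
  dims <- c(120L, 120L)
  cd31 <- matrix(FALSE, dims[1], dims[2]); cd31[30:70, 30:70] <- TRUE
  cd45 <- matrix(FALSE, dims[1], dims[2]); cd45[90:110, 90:110] <- TRUE
  ihc <- new("IHCLabelMask", cd31 = cd31, cd45 = cd45)
  idt <- new("AffineTransform", m = cbind(diag(2), c(0, 0)),
             converged = TRUE, metric = 0)
  circle <- function(r0, c0, rad) {
    t <- seq(0, 2 * pi, length.out = 33)[-33]
    cbind(r0 + rad * sin(t), c0 + rad * cos(t))
  }
  # fully inside the dilated CD31 area -> endothelial
  # centered on the CD45 area -> lymphocyte; far away -> cancer
  nuclei <- list(circle(50, 50, 6), circle(100, 100, 6), circle(15, 110, 6))
  labs <- transferLabels(ihc, idt, nuclei, dilation_radius = 5)
  expect_identical(labs, c("endothelial", "lymphocyte", "cancer"))

  # below the 50% overlap threshold the nucleus stays cancer: the CD31
  # border after 5 px dilation is at row 75; this box has 4 of 10 interior
  # pixel rows inside it
  box <- cbind(c(71.5, 81.5, 81.5, 71.5), c(50, 50, 60, 60))
  labs2 <- transferLabels(ihc, idt, list(box), dilation_radius = 5)
  expect_identical(labs2, "cancer")

  # degenerate contour warned and NA
  expect_warning(l3 <- transferLabels(ihc, idt, list(cbind(1, 1))), "degenerate")
  expect_true(is.na(l3))

  # end-to-end on a synthetic tile: transferred labels match generator truth
  tile <- fixtureTile()
  vm <- vesselMask(tile)
  lymphink <- matrix(FALSE, 256, 256)
  for (ct in nucleusContours(tile)) if (ct$class == "lymphocyte")
    lymphink <- vasculomorph:::stampEllipse(
      lymphink, mean(ct$coords[, 1]), mean(ct$coords[, 2]), 6, 5, 0)
  ihc2 <- new("IHCLabelMask", cd31 = vm, cd45 = lymphink & !vm)
  labs4 <- transferLabels(ihc2, idt, nucleusContours(tile))
  truth <- vapply(nucleusContours(tile), `[[`, "", "class")
  expect_gte(mean(labs4 == truth, na.rm = TRUE), 0.95)
})
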