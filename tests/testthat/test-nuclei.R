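test_that("nucleus segmentation finds rendered nuclei and splits touching pairs", {
  # blank channel
  expect_length(segmentNuclei(matrix(0, 64, 64)), 0)

  # 50 rendered non-touching ellipses: all found, centroids within 2 px
  tile <- memo("nuc_tile", generateVesselNetwork(
    256, 256, n_seeds = 0, n_cancer = 50, n_lymph = 0, seed = 9,
    noise_sd = 0.005))
  h <- channel(unmixStains(tile@rgbHE, hematoxylinEosinBasis()), "hematoxylin")
  nuc <- segmentNuclei(h)
  expect_equal(length(nuc), 50)
  truth <- tile@cancerCentroids
  errs <- vapply(nuc, function(n)
    sqrt(min(colSums((t(truth) - n$centroid)^2))), 0)
  expect_lt(max(errs), 2)

  # two overlapping ellipses with distinct cores split by watershed
  mm <- vasculomorph:::stampEllipse(matrix(FALSE, 120, 120), 60, 45, 16, 11, 0)
  mm <- vasculomorph:::stampEllipse(mm, 60, 75, 16, 11, 0)
  img <- 0.7 * vasculomorph:::boxBlur(mm + 0, 1L) + 0.03
  expect_equal(length(segmentNuclei(img)), 2)
})

test_that("the 63-feature extraction matches analytic shapes and is translation-invariant", {
  expect_length(nuclearFeatureRoster(), 63)

  # perfect circle: eccentricity ~0, solidity ~1; constant interior:
  # zero intensity SD and unit GLCM energy
  t <- seq(0, 2 * pi, length.out = 60)[-60]
  circ <- cbind(50 + 20 * sin(t), 50 + 20 * cos(t))
  img <- matrix(0.5, 100, 100)
  f <- extractNuclearFeatures(list(contour = circ), img, img)
  expect_length(f, 63)
  expect_identical(names(f), nuclearFeatureRoster())
  expect_lt(f[["eccentricity"]], 0.1)
  expect_gt(f[["solidity"]], 0.97)
  expect_equal(f[["hema_sd"]], 0)
  expect_equal(f[["hema_glcm_energy_0"]], 1)
  expect_equal(f[["eosin_glcm_contrast_90"]], 0)

  # degenerate contour
  expect_error(extractNuclearFeatures(list(contour = cbind(1, 1)), img, img),
               "degenerate")

  # translation invariance: shift image and contour together
  set.seed(2)
  tex <- matrix(runif(100 * 100), 100, 100)
  blob <- cbind(30 + 9 * sin(t), 30 + 13 * cos(t))
  f1 <- extractNuclearFeatures(list(contour = blob), tex, tex)
  sh <- matrix(0, 100, 100); sh[31:100, 26:100] <- tex[1:70, 1:75]
  f2 <- extractNuclearFeatures(list(contour = blob + rep(c(30, 25), each = nrow(blob))),
                               sh, sh)
  expect_lt(max(abs(f1 - f2)), 1e-9)

  # every nucleus of a real synthetic tile yields exactly 63 finite features
  tile <- fixtureTile()
  h <- channel(fixtureChannels(), "hematoxylin")
  e <- channel(fixtureChannels(), "eosin")
  cts <- nucleusContours(tile)[seq(1, 40, by = 4)]
  F <- t(vapply(cts, function(ct)
    extractNuclearFeatures(list(contour = ct$coords), h, e), numeric(63)))
  expect_true(all(is.finite(F)))
})

test_that("the max-margin nucleus classifier trains, predicts and reproduces", {
  set.seed(5)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 4), 30, 2),
             matrix(rnorm(60, 8), 30, 2))
  y <- rep(c("endothelial", "lymphocyte", "cancer"), each = 30)

  clf <- trainNucleusClassifier(X, y, seed = 1)
  pr <- predictNucleusClass(clf, X)
  expect_equal(mean(pr$predicted_class == y), 1)           # separable blobs

  clf2 <- trainNucleusClassifier(X, y, seed = 1)
  expect_identical(predictNucleusClass(clf2, X)$predicted_class,
                   pr$predicted_class)                     # determinism

  expect_error(trainNucleusClassifier(X, rep("a", 90)), "classes")

  # label permutation drives cross-validated kappa to its null
  kappas <- vapply(1:6, function(s) {
    set.seed(100 + s)
    yp <- sample(y)
    cl <- trainNucleusClassifier(X, yp, cost_grid = 1,
                                 gamma_grid = 0.5, seed = s)
    idx <- seq(1, 90, by = 3)     # held-out-ish subset
    evaluateClassifier(predictNucleusClass(cl, X[idx, ])$predicted_class,
                       yp[idx])$cohen_kappa
  }, 0)
  expect_lt(abs(mean(kappas)), 2 * max(sd(kappas), 0.05))
})

test_that("classifier evaluation reproduces hand-computed agreement statistics", {
  # hand example: marginals give pe = 0.5, so kappa = 0 at agreement 0.5
  ev <- evaluateClassifier(c("a", "b", "a", "b"), c("a", "a", "b", "b"))
  expect_equal(ev$observed_agreement, 0.5)
  expect_equal(ev$cohen_kappa, 0)

  # perfect predictions
  y <- rep(c("a", "b", "c"), each = 5)
  ev2 <- evaluateClassifier(y, y,
                            scores = matrix(rnorm(45), 15, 3,
                                            dimnames = list(NULL, c("a", "b", "c"))))
  expect_equal(ev2$cohen_kappa, 1)
  expect_equal(ev2$observed_agreement, 1)

  # all-tied scores give AUC 0.5 by the midrank convention
  ev3 <- evaluateClassifier(y, y, scores = matrix(1, 15, 3,
                                                  dimnames = list(NULL, c("a", "b", "c"))))
  expect_equal(unname(ev3$auc_per_class["a"]), 0.5)

  expect_error(evaluateClassifier(c("a", "b"), c("a")), "mismatch")
  expect_error(evaluateClassifier(c("a", "a"), c("a", "a")), "2 classes")

  # property: kappa never exceeds observed agreement; kappa 1 iff diagonal
  set.seed(3)
  for (i in 1:25) {
    tr <- sample(c("a", "b", "c"), 30, replace = TRUE)
    pd <- sample(c("a", "b", "c"), 30, replace = TRUE)
    if (length(unique(tr)) < 2) next
    e <- evaluateClassifier(pd, tr)
    expect_lte(e$cohen_kappa, e$observed_agreement + 1e-12)
    if (e$cohen_kappa == 1) expect_true(all(pd == tr))
  }
})

test_that("EC-vs-rest discrimination reaches the reported operating floor on separated classes", {
  # synthetic 63-feature classes separated by >= 2 SD, 5-fold CV by hand
  set.seed(11)
  n <- c(endothelial = 60, lymphocyte = 30, cancer = 90)
  mus <- list(endothelial = rnorm(10, 2), lymphocyte = rnorm(10, -2),
              cancer = rnorm(10, 0))
  X <- do.call(rbind, lapply(names(n), function(cl)
    matrix(rnorm(n[cl] * 10, mean = rep(mus[[cl]], each = n[cl])), n[cl], 10)))
  y <- rep(names(n), n)
  folds <- integer(length(y))
  for (l in unique(y)) folds[y == l] <- sample(rep_len(1:5, sum(y == l)))
  scores <- numeric(length(y))
  for (f in 1:5) {
    cl <- trainNucleusClassifier(X[folds != f, ], y[folds != f],
                                 cost_grid = 10, gamma_grid = 0.1, seed = f)
    scores[folds == f] <- predictNucleusClass(cl, X[folds == f, ])$endothelial
  }
  expect_gte(rankAUC(scores, y == "endothelial"), 0.95)
})
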