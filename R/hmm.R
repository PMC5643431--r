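## Six-state Gaussian-emission HMM over pixel RGB values ("HMMseg").
## Observation sequences are image rows, decoded left to right.

ihcStateNames <- function()
  c("dab", "cd31_purple", "hematoxylin", "white_bg", "light_blue", "light_brown")

## log N(x; mu, Sigma) for an n x 3 matrix of observations
gaussLogLik <- function(x, mean, inv, logdet) {
  d <- sweep(x, 2, mean)
  -0.5 * (3 * log(2 * pi) + logdet + rowSums((d %*% inv) * d))
}

hmmLogLik <- function(x, model) {
  k <- length(model@stateNames)
  ll <- matrix(0, nrow(x), k)
  for (s in seq_len(k)) {
    S <- model@covs[[s]]
    ll[, s] <- gaussLogLik(x, model@means[s, ], solve(S),
                           determinant(S, logarithm = TRUE)$modulus)
  }
  ll
}

#' Train the six-state color HMM for IHC segmentation
#'
#' Emission means/covariances are estimated from labeled per-state RGB pixel
#' samples (covariances regularized by \code{pseudo_count * I}); the
#' transition matrix starts self-biased (0.9 on the diagonal) and is refined
#' by Viterbi (segmental) re-estimation on rows formed from the training
#' samples until the decoded labels stabilize, at most \code{max_iter}
#' sweeps.
#'
#' @param labeled_pixels named list of n x 3 RGB sample matrices, one entry
#'   per state in \code{ihcStateNames()} order, >= 20 samples each.
#' @param pseudo_count ridge added to each emission covariance.
#' @param max_iter maximum Viterbi-training sweeps.
#' @return An [HMMColorModel-class] object.
#' @export
trainColorHMM <- function(labeled_pixels, pseudo_count = 1e-4, max_iter = 20L) {
  states <- ihcStateNames()
  if (!all(states %in% names(labeled_pixels)))
    stop("labeled_pixels must contain samples for states: ",
         paste(setdiff(states, names(labeled_pixels)), collapse = ", "))
  labeled_pixels <- labeled_pixels[states]
  ns <- vapply(labeled_pixels, nrow, 0L)
  if (any(ns < 20L)) stop("each state needs >= 20 labeled pixels")
  k <- length(states)
  est <- function(blocks) {
    means <- t(vapply(blocks, colMeans, numeric(3)))
    covs <- lapply(blocks, function(m) cov(m) + diag(pseudo_count, 3))
    list(means = means, covs = covs)
  }
  e <- est(labeled_pixels)
  ## emission collision guard
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (sqrt(sum((e$means[i, ] - e$means[j, ])^2)) < 1e-3)
      warning("emission collision: states '", states[i], "' and '", states[j],
              "' have indistinguishable means")
  }
  trans <- matrix(0.1 / (k - 1), k, k); diag(trans) <- 0.9
  init <- rep(1 / k, k)
  model <- new("HMMColorModel", stateNames = states, means = e$means,
               covs = e$covs, transition = trans, initial = init)
  ## training rows: concatenated per-state blocks (a long segmental sequence)
  x <- do.call(rbind, labeled_pixels)
  prev <- rep.int(seq_len(k), ns)
  for (iter in seq_len(max_iter)) {
    path <- cpp_viterbi(hmmLogLik(x, model), log(model@transition), log(model@initial))
    ## re-estimate transitions from the decoded path (with +1 smoothing)
    tc <- matrix(1, k, k)
    from <- path[-length(path)]; to <- path[-1]
    for (s in seq_len(k)) {
      tab <- tabulate(to[from == s], nbins = k)
      tc[s, ] <- tc[s, ] + tab
    }
    model@transition <- tc / rowSums(tc)
    ## segmental re-estimation of emissions keeps states anchored to their
    ## labeled samples: only re-estimate when a state keeps >= 20 pixels
    for (s in seq_len(k)) {
      sel <- path == s
      if (sum(sel) >= 20L) {
        model@means[s, ] <- colMeans(x[sel, , drop = FALSE])
        model@covs[[s]] <- cov(x[sel, , drop = FALSE]) + diag(pseudo_count, 3)
      }
    }
    if (identical(path, prev)) break
    prev <- path
  }
  validObject(model)
  model
}

#' Segment an IHC tile into CD31/CD45 masks
#'
#' Decodes each image row independently with the Viterbi algorithm under the
#' trained color model; the CD31 mask collects \code{cd31_purple}-state
#' pixels and the CD45 mask \code{dab}-state pixels.  Both masks are
#' despeckled by removing 8-connected components below \code{min_component}
#' pixels.
#'
#' @param rgb H x W x 3 array in [0, 1].
#' @param model an [HMMColorModel-class].
#' @param min_component despeckle threshold in pixels (default 20).
#' @return An [IHCLabelMask-class] object.
#' @export
segmentIHC <- function(rgb, model, min_component = 20L) {
  stopifnot(length(dim(rgb)) == 3)
  nr <- dim(rgb)[1]; nc <- dim(rgb)[2]
  x <- cbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]), as.vector(rgb[, , 3]))
  ll <- hmmLogLik(x, model)          # row-major index: (r, c) -> r + (c-1)*nr
  lt <- log(model@transition); li <- log(model@initial)
  states <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) {
    idx <- r + (seq_len(nc) - 1L) * nr
    states[r, ] <- cpp_viterbi(ll[idx, , drop = FALSE], lt, li)
  }
  s31 <- match("cd31_purple", model@stateNames)
  s45 <- match("dab", model@stateNames)
  cd31 <- removeSmallComponents(states == s31, min_component)
  cd45 <- removeSmallComponents(states == s45, min_component)
  cd45 <- cd45 & !cd31    # CD31 precedence on overlap after despeckling
  new("IHCLabelMask", cd31 = cd31, cd45 = cd45)
}
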