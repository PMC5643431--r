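#' Segment nuclei from a hematoxylin absorbance channel
#'
#' Median-filters the channel, Otsu-thresholds it, fills holes, splits
#' touching nuclei by marker watershed on the distance transform, discards
#' components outside \code{[min_area, max_area]}, and traces each remaining
#' component's 8-connected boundary.
#'
#' @param hematoxylin numeric matrix (absorbance, higher = more stain).
#' @param median_radius median-filter radius in px (>= 1).
#' @param min_area,max_area component area bounds in px.
#' @return list of nucleus records \code{list(nucleus_id, contour, centroid,
#'   area)}; empty list for a blank channel.
#' @export
segmentNuclei <- function(hematoxylin, median_radius = 2L, min_area = 30,
                          max_area = 2500) {
  if (median_radius < 1) stop("median_radius must be >= 1")
  if (length(hematoxylin) == 0) return(list())
  sm <- cpp_median_filter(hematoxylin, as.integer(median_radius))
  thr <- otsuThreshold(sm)
  fg <- sm > thr
  if (!any(fg)) return(list())
  fg <- fillHoles(fg)
  ## watershed split: markers at regional maxima of the inner distance map
  d <- distanceTransform(!fg)
  dsm <- boxBlur(d, 2L)
  mx <- cpp_window_stats(dsm, 4L)$max
  markers <- fg & dsm >= mx - 1e-9 & d > 1.5
  markers <- labelComponents(markers, 8L)
  lab <- cpp_watershed(-d, markers, fg)
  out <- list()
  nid <- 0L
  for (l in seq_len(max(lab))) {
    px <- which(lab == l, arr.ind = TRUE)
    area <- nrow(px)
    if (area < min_area || area > max_area) next
    comp <- matrix(FALSE, nrow(fg), ncol(fg))
    comp[px] <- TRUE
    first <- px[order(px[, 2], px[, 1])[1], ]
    contour <- cpp_trace_boundary(comp, first[1], first[2])
    nid <- nid + 1L
    out[[nid]] <- list(nucleus_id = nid, contour = contour,
                       centroid = colMeans(px), area = area)
  }
  out
}

nuclearFeatureGroups <- function() {
  shape <- c("area", "perimeter", "circularity", "eccentricity", "major_axis",
             "minor_axis", "aspect_ratio", "solidity", "extent",
             "equiv_diameter", "convexity")
  stats <- c("mean", "sd", "skewness", "kurtosis", "min", "max", "q25",
             "median", "q75", "iqr")
  glcm <- as.vector(outer(c("contrast", "correlation", "energy", "homogeneity"),
                          c("0", "45", "90", "135"), paste, sep = "_"))
  list(shape = shape,
       intensity = c(paste0("hema_", stats), paste0("eosin_", stats)),
       texture = c(paste0("hema_glcm_", glcm), paste0("eosin_glcm_", glcm)))
}

#' The fixed 63-name nuclear feature roster
#'
#' Eleven shape descriptors, ten intensity statistics per stain channel, and
#' gray-level co-occurrence texture (contrast, correlation, energy,
#' homogeneity at 4 offsets) per channel: 11 + 20 + 32 = 63.  The roster is
#' versioned here; [extractNuclearFeatures()] always returns this order.
#' Coordinate-valued quantities (centroids) are deliberately excluded so all
#' features are translation-invariant.
#'
#' @return character vector of 63 feature names.
#' @export
nuclearFeatureRoster <- function() unlist(nuclearFeatureGroups(), use.names = FALSE)

glcmStats <- function(q, px, n_levels = 8L) {
  ## q: quantized level matrix (NA outside nucleus); offsets in (dr, dc)
  offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
                  `135` = c(-1L, -1L))
  nr <- nrow(q); nc <- ncol(q)
  out <- numeric(0)
  for (nm in names(offsets)) {
    o <- offsets[[nm]]
    r2 <- px[, 1] + o[1]; c2 <- px[, 2] + o[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    a <- q[px[ok, , drop = FALSE]]
    b <- q[cbind(r2[ok], c2[ok])]
    ok2 <- !is.na(a) & !is.na(b)
    a <- a[ok2]; b <- b[ok2]
    if (length(a) == 0) {
      out <- c(out, contrast = 0, correlation = 0, energy = 1, homogeneity = 1)
      next
    }
    ## symmetric, normalized co-occurrence
    tab <- matrix(0, n_levels, n_levels)
    for (i in seq_along(a)) {
      tab[a[i], b[i]] <- tab[a[i], b[i]] + 1
      tab[b[i], a[i]] <- tab[b[i], a[i]] + 1
    }
    p <- tab / sum(tab)
    lv <- seq_len(n_levels)
    pi_ <- rowSums(p)
    mu <- sum(lv * pi_)
    s2 <- sum((lv - mu)^2 * pi_)
    dif <- outer(lv, lv, "-")
    contrast <- sum(p * dif^2)
    energy <- sum(p^2)
    homogeneity <- sum(p / (1 + abs(dif)))
    correlation <- if (s2 > 0) sum(p * outer(lv - mu, lv - mu)) / s2 else 0
    out <- c(out, contrast = contrast, correlation = correlation,
             energy = energy, homogeneity = homogeneity)
  }
  out
}

#' Extract the 63 morphometric and texture features of one nucleus
#'
#' @param record a nucleus record from [segmentNuclei()] (needs
#'   \code{$contour}).
#' @param hematoxylin,eosin absorbance channels the nucleus was segmented
#'   from.
#' @return named numeric vector of length 63 (see [nuclearFeatureRoster()]).
#' @export
extractNuclearFeatures <- function(record, hematoxylin, eosin) {
  contour <- if (is.list(record)) record$contour else record
  if (is.null(contour) || nrow(contour) < 3) stop("degenerate nucleus contour")
  dims <- dim(hematoxylin)
  px <- polygonInterior(contour, dims)
  if (nrow(px) < 3) stop("degenerate nucleus interior")

  area <- nrow(px)
  perim <- polygonPerimeter(contour)
  hull <- contour[chull(contour[, 2], contour[, 1]), , drop = FALSE]
  hull_area <- max(polygonArea(hull), area)
  hull_perim <- polygonPerimeter(hull)
  ## second central moments of interior pixels
  mu <- colMeans(px)
  dr <- px[, 1] - mu[1]; dc <- px[, 2] - mu[2]
  C <- matrix(c(mean(dr^2), mean(dr * dc), mean(dr * dc), mean(dc^2)), 2, 2)
  ev <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  shape <- c(
    area = area,
    perimeter = perim,
    circularity = 4 * pi * area / perim^2,
    eccentricity = if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0,
    major_axis = major,
    minor_axis = minor,
    aspect_ratio = if (minor > 0) major / minor else 1,
    solidity = min(area / hull_area, 1),
    extent = area / ((diff(range(px[, 1])) + 1) * (diff(range(px[, 2])) + 1)),
    equiv_diameter = 2 * sqrt(area / pi),
    convexity = min(hull_perim / perim, 1))

  istats <- function(v) {
    s <- sd(v)
    m <- mean(v)
    z <- if (s > 0) (v - m) / s else rep(0, length(v))
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    c(mean = m, sd = s,
      skewness = if (s > 0) mean(z^3) else 0,
      kurtosis = if (s > 0) mean(z^4) - 3 else 0,   # excess kurtosis
      min = min(v), max = max(v), q25 = q[1], median = q[2], q75 = q[3],
      iqr = q[3] - q[1])
  }
  quantize <- function(img) {
    v <- img[px]
    r <- range(v)
    q <- matrix(NA_integer_, dims[1], dims[2])
    q[px] <- if (r[2] > r[1])
      pmin(1L + as.integer(8 * (v - r[1]) / (r[2] - r[1])), 8L) else 1L
    q
  }
  hv <- hematoxylin[px]; evv <- eosin[px]
  out <- c(shape, istats(hv), istats(evv),
           glcmStats(quantize(hematoxylin), px), glcmStats(quantize(eosin), px))
  names(out) <- nuclearFeatureRoster()
  out
}
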