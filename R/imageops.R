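## Internal binary-image helpers on logical/numeric matrices, backed by the
## compiled primitives in src/.

labelComponents <- function(mask, conn = 8L) {
  storage.mode(mask) <- "logical"
  cpp_label_components(mask, as.integer(conn))
}

#' Euclidean distance transform
#'
#' Exact Euclidean distance from every pixel to the nearest \code{TRUE} pixel
#' of \code{on}.  Pixels of \code{on} itself have distance 0.
#'
#' @param on logical matrix.
#' @return numeric matrix of distances (Inf-free; all-FALSE input yields a
#'   large finite sentinel distance).
#' @export
distanceTransform <- function(on) {
  storage.mode(on) <- "logical"
  cpp_edt(on)
}

dilateDisc <- function(mask, radius) {
  if (radius <= 0) return(mask)
  distanceTransform(mask) <= radius
}

erodeDisc <- function(mask, radius) {
  if (radius <= 0) return(mask)
  !(distanceTransform(!mask) <= radius)
}

morphClose <- function(mask, radius) erodeDisc(dilateDisc(mask, radius), radius)

removeSmallComponents <- function(mask, min_px, conn = 8L) {
  if (!any(mask)) return(mask)
  lab <- labelComponents(mask, conn)
  sz <- tabulate(lab[lab > 0L])
  keep <- which(sz >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

fillHoles <- function(mask) {
  bg <- labelComponents(!mask, 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0L]
  matrix(mask | (bg > 0L & !(bg %in% border)), nrow(mask), ncol(mask))
}

otsuThreshold <- function(img, n_bins = 256L) {
  v <- img[is.finite(img)]
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  h <- tabulate(pmin(pmax(findInterval(v, seq(r[1], r[2], length.out = n_bins + 1L),
                                       all.inside = TRUE), 1L), n_bins), n_bins)
  p <- h / sum(h)
  mids <- (seq_len(n_bins) - 0.5) / n_bins * (r[2] - r[1]) + r[1]
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

boxBlur <- function(img, radius = 1L) cpp_window_stats(img, as.integer(radius))$mean

## Stamp filled discs of the given radii at (row, col) centres into a mask.
stampDiscs <- function(mask, centers, radii) {
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]; rad <- radii[i]
    rr <- max(1, floor(r0 - rad)):min(nr, ceiling(r0 + rad))
    cc <- max(1, floor(c0 - rad)):min(nc, ceiling(c0 + rad))
    if (!length(rr) || !length(cc)) next
    d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
    mask[rr, cc] <- mask[rr, cc] | (d2 <= rad^2)
  }
  mask
}

## Stamp filled, rotated ellipses; returns the mask and per-ellipse pixel sets.
stampEllipse <- function(mask, r0, c0, a, b, theta) {
  nr <- nrow(mask); nc <- ncol(mask)
  ext <- max(a, b)
  rr <- max(1, floor(r0 - ext)):min(nr, ceiling(r0 + ext))
  cc <- max(1, floor(c0 - ext)):min(nc, ceiling(c0 + ext))
  dr <- outer(rr - r0, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - c0)
  u <- cos(theta) * dc + sin(theta) * dr
  v <- -sin(theta) * dc + cos(theta) * dr
  inside <- (u / a)^2 + (v / b)^2 <= 1
  mask[rr, cc] <- mask[rr, cc] | inside
  mask
}

## Interior pixel coordinates of a closed polygon (row, col), via even-odd rule.
polygonInterior <- function(coords, dims) {
  rr <- max(1L, floor(min(coords[, 1]))):min(dims[1], ceiling(max(coords[, 1])))
  cc <- max(1L, floor(min(coords[, 2]))):min(dims[2], ceiling(max(coords[, 2])))
  grid <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
  inp <- sp::point.in.polygon(grid[, 1], grid[, 2], coords[, 1], coords[, 2])
  grid[inp > 0, , drop = FALSE]
}

polygonArea <- function(coords) {
  x <- coords[, 2]; y <- coords[, 1]
  n <- length(x)
  if (n < 3) return(0)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygonPerimeter <- function(coords) {
  d <- diff(rbind(coords, coords[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

## 8-neighbour count of TRUE pixels, computed by shifted sums.
neighborCount8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  out <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out + p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  out
}

## Rutovitz crossing number: 0->1 transitions in the ordered 8-neighbour ring.
crossingNumber <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  ring <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  sh <- lapply(ring, function(d)
    p[(2:(nr + 1L)) + d[1], (2:(nc + 1L)) + d[2]])
  out <- matrix(0L, nr, nc)
  for (i in seq_along(sh)) {
    j <- if (i == length(sh)) 1L else i + 1L
    out <- out + (sh[[i]] == 0L & sh[[j]] == 1L)
  }
  out
}

diceCoefficient <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
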