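# Binary-mask morphology on logical matrices. Masks are indexed [row, col]
# with x = column and y = row, so that (x, y) are Cartesian pixel coordinates.

shift_mat <- function(m, dr, dc, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Crofton perimeter of a binary mask
#'
#' Estimates the length of the region boundary by the Crofton formula with
#' four test directions, evaluated from the histogram of 2x2 pixel
#' configurations. Unlike a raw boundary-pixel count, this estimator
#' converges to the true Euclidean perimeter for smooth shapes (a digital
#' disc of radius r approaches 2*pi*r), which matters because circularity
#' is perimeter-derived.
#'
#' @param mask Logical (or 0/1) matrix; `TRUE` marks the region.
#'
#' @return Perimeter estimate in pixel units.
#' @examples
#' sq <- matrix(FALSE, 12, 12); sq[4:9, 4:9] <- TRUE
#' crofton_perimeter(sq)
#' @export
crofton_perimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask > 0) + 0L
  # 2x2 configuration code: pixel + 2*up + 4*left + 8*up-left
  code <- m + 2L * shift_mat(m, 1, 0) + 4L * shift_mat(m, 0, 1) +
    8L * shift_mat(m, 1, 1)
  h <- tabulate(code + 1L, nbins = 16L)
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2),
             0, pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2),
             pi / 4, pi / 2, pi / (4 * s2), pi / (4 * s2),
             pi / 4, pi / 2, 0, 0)
  sum(h * coefs)
}

# Area of the convex hull of the region, computed from pixel corner points
# so that a convex digital shape scores ~1 (hull of pixel *centres* would
# systematically undercount by a half-pixel rim).
hull_area <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  px <- c(x - 0.5, x + 0.5, x + 0.5, x - 0.5)
  py <- c(y - 0.5, y - 0.5, y + 0.5, y + 0.5)
  h <- grDevices::chull(px, py)
  hx <- px[h]; hy <- py[h]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Morphology metrics of a single connected region
#'
#' Computes the per-fibre shape descriptors used for filtering candidate
#' fibre cross-sections:
#' * `area`: pixel count (um^2 at IMC resolution);
#' * `perimeter`: Crofton boundary length (see [crofton_perimeter()]);
#' * `circularity`: `perimeter^2 / (4 * pi * area)`, 1 for a perfect disc
#'   and growing without bound for irregular outlines;
#' * `aspect_ratio`: major/minor axis ratio of the intensity-free best-fit
#'   ellipse (from second central moments of the pixel coordinates), >= 1;
#' * `convexity`: area divided by the area of the convex hull of the
#'   region, in (0, 1], 1 for convex shapes.
#'
#' @param mask Logical (or 0/1) matrix containing one connected region.
#'
#' @return A one-row tibble with columns `area`, `perimeter`,
#'   `circularity`, `aspect_ratio`, `convexity`.
#' @examples
#' disc <- outer(1:41, 1:41, function(r, c) (r - 21)^2 + (c - 21)^2 <= 15^2)
#' region_morphology(disc)
#' @export
region_morphology <- function(mask) {
  if (!any(mask > 0)) abort("empty mask")
  idx <- which(mask > 0, arr.ind = TRUE)
  area <- nrow(idx)
  per <- crofton_perimeter(mask)
  circ <- per^2 / (4 * pi * area)
  y <- idx[, 1]; x <- idx[, 2]
  # second central moments with the 1/12 term for finite pixel extent
  mxx <- mean((x - mean(x))^2) + 1 / 12
  myy <- mean((y - mean(y))^2) + 1 / 12
  mxy <- mean((x - mean(x)) * (y - mean(y)))
  tr <- mxx + myy
  det_ <- mxx * myy - mxy^2
  disc <- sqrt(max(tr^2 / 4 - det_, 0))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, .Machine$double.eps)
  ar <- sqrt(l1 / l2)
  conv <- min(area / hull_area(mask), 1)
  tibble(area = area, perimeter = per, circularity = circ,
         aspect_ratio = ar, convexity = conv)
}
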