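# Fibre segmentation from the membrane channel, morphology filtering and
# per-fibre feature extraction.

#' Gradient map of the mean channel image
#'
#' Averages all channels of a stack, optionally Gaussian-smooths the mean,
#' and returns the gradient magnitude (central finite differences, edges
#' replicated). Useful as a membrane surrogate when no single membrane
#' channel gives a clean outline: fibre boundaries are intensity edges in
#' many channels at once, so they stand out in the gradient of the mean.
#'
#' @param stack An [image_stack()].
#' @param sigma Gaussian smoothing sd in px applied before
#'   differentiation; `0` disables smoothing.
#'
#' @return A non-negative matrix of the same dimensions.
#' @export
gradient_map <- function(stack, sigma = 2) {
  stopifnot(inherits(stack, "image_stack"))
  avg <- Reduce(`+`, stack) / length(stack)
  if (sigma > 0) avg <- EBImage::gblur(avg, sigma = sigma)
  gx <- (shift_mat(avg, 0, -1, fill = NA) - shift_mat(avg, 0, 1, fill = NA)) / 2
  gy <- (shift_mat(avg, -1, 0, fill = NA) - shift_mat(avg, 1, 0, fill = NA)) / 2
  # replicate edges: one-sided differences at the frame
  gx[, 1] <- avg[, 2] - avg[, 1]
  gx[, ncol(avg)] <- avg[, ncol(avg)] - avg[, ncol(avg) - 1]
  gy[1, ] <- avg[2, ] - avg[1, ]
  gy[nrow(avg), ] <- avg[nrow(avg), ] - avg[nrow(avg) - 1, ]
  sqrt(gx^2 + gy^2)
}

#' Segment fibres from a membrane image
#'
#' Builds the membrane mask by Gaussian smoothing followed by Otsu
#' thresholding, then labels the connected components of the complement
#' (4-connectivity) as candidate fibres. No fibre pixel lies on the mask.
#' The caller is expected to remove implausible regions — including the
#' background frame, which exceeds any sensible `areamax` — with
#' [filter_regions()].
#'
#' @param membrane 2D non-negative matrix (the Dystrophin channel or a
#'   [gradient_map()]).
#' @param sigma Gaussian smoothing sd in px before thresholding.
#' @param erode If `TRUE`, erode each region by one pixel to avoid
#'   membrane bleed into interior means.
#' @param drop_border If `TRUE` (default), discard regions touching the
#'   image frame: cells cut by the field edge are incomplete
#'   cross-sections whose morphology and means are biased.
#'
#' @return Integer label matrix: 0 = membrane, k > 0 = fibre k, labels
#'   contiguous from 1. A uniformly bright image yields zero labels; an
#'   all-zero image yields a single full-frame region.
#' @export
segment_fibres <- function(membrane, sigma = 2, erode = FALSE,
                           drop_border = TRUE) {
  if (!is.matrix(membrane) || any(membrane < 0)) {
    abort("membrane must be a 2D non-negative image")
  }
  rng <- range(membrane)
  if (rng[1] == rng[2]) {
    # constant image: no membrane evidence at all
    if (rng[1] > 0) return(matrix(0L, nrow(membrane), ncol(membrane)))
    return(matrix(1L, nrow(membrane), ncol(membrane)))
  }
  sm <- if (sigma > 0) EBImage::gblur(membrane, sigma = sigma) else membrane
  sm01 <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- EBImage::otsu(EBImage::Image(sm01), range = c(0, 1))
  mask <- sm01 > thr
  interior <- !mask
  labs <- EBImage::bwlabel(EBImage::Image(interior + 0))
  labs <- matrix(as.integer(labs), nrow(membrane), ncol(membrane))
  if (drop_border) {
    touching <- setdiff(unique(c(labs[1, ], labs[nrow(labs), ],
                                 labs[, 1], labs[, ncol(labs)])), 0L)
    labs[labs %in% touching] <- 0L
    labs <- compact_labels(labs)
  }
  if (erode) {
    keep <- labs
    for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      keep[shift_mat(labs, s[1], s[2], fill = 0L) != labs] <- 0L
    }
    labs <- compact_labels(keep)
  }
  labs
}

compact_labels <- function(labs) {
  u <- sort(setdiff(unique(as.vector(labs)), 0L))
  if (length(u) == 0) return(labs)
  map <- integer(max(u)); map[u] <- seq_along(u)
  out <- labs
  out[labs > 0L] <- map[labs[labs > 0L]]
  out
}

#' Morphology filter bounds for candidate fibres
#'
#' Default bounds keep regions that plausibly are single transverse fibre
#' cross-sections: area between 500 and 17,500 px (um^2), circularity
#' between 0 and 100, ellipse aspect ratio between 0 and 10, and convexity
#' between 0.75 and 1. Circularity here is `perimeter^2 / (4 pi area)`
#' (>= 1, unbounded above), consistent with an upper bound of 100.
#'
#' @param areamin,areamax Area bounds in px.
#' @param circmin,circmax Circularity bounds.
#' @param ratiomin,ratiomax Aspect-ratio bounds.
#' @param convexmin,convexmax Convexity bounds.
#'
#' @return A list of class `morphology_filter`.
#' @export
morphology_filter <- function(areamin = 500, areamax = 17500,
                              circmin = 0, circmax = 100,
                              ratiomin = 0, ratiomax = 10,
                              convexmin = 0.75, convexmax = 1) {
  f <- list(areamin = areamin, areamax = areamax, circmin = circmin,
            circmax = circmax, ratiomin = ratiomin, ratiomax = ratiomax,
            convexmin = convexmin, convexmax = convexmax)
  pairs <- matrix(unlist(f), ncol = 2, byrow = TRUE)
  if (any(pairs[, 1] > pairs[, 2])) abort("each min bound must be <= its max")
  structure(f, class = "morphology_filter")
}

region_masks <- function(labels) {
  K <- max(labels)
  idx <- split(which(labels > 0L), labels[labels > 0L])
  lapply(seq_len(K), function(k) {
    m <- matrix(FALSE, nrow(labels), ncol(labels))
    m[idx[[as.character(k)]]] <- TRUE
    m
  })
}

#' Remove regions that fail morphology bounds
#'
#' Evaluates [region_morphology()] for every labelled region and removes
#' those outside any bound of the filter; surviving labels are recompacted
#' to 1..K in their original order. The removal log (region, metric,
#' value, bound violated) is attached as attribute `"removed"`.
#'
#' @param labels Integer label matrix from [segment_fibres()].
#' @param filter A [morphology_filter()].
#'
#' @return Filtered label matrix; `attr(, "removed")` is a tibble logging
#'   one row per removed region. Filtering is idempotent.
#' @export
filter_regions <- function(labels, filter = morphology_filter()) {
  stopifnot(inherits(filter, "morphology_filter"))
  K <- max(labels)
  if (K == 0) {
    out <- labels
    attr(out, "removed") <- tibble(region = integer(), reason = character())
    return(out)
  }
  morph <- dplyr::bind_rows(lapply(region_masks(labels), region_morphology))
  reason <- rep(NA_character_, K)
  chk <- function(v, lo, hi, nm) ifelse(v < lo | v > hi, nm, NA_character_)
  rs <- cbind(chk(morph$area, filter$areamin, filter$areamax, "area"),
              chk(morph$circularity, filter$circmin, filter$circmax, "circularity"),
              chk(morph$aspect_ratio, filter$ratiomin, filter$ratiomax, "aspect_ratio"),
              chk(morph$convexity, filter$convexmin, filter$convexmax, "convexity"))
  reason <- apply(rs, 1, function(r) paste(stats::na.omit(r), collapse = "+"))
  drop <- which(nzchar(reason))
  out <- labels
  out[labels %in% drop] <- 0L
  out <- compact_labels(out)
  attr(out, "removed") <- tibble(region = drop, reason = reason[drop])
  out
}

#' Extract per-fibre features from a label map and image stack
#'
#' For every labelled region: mean intensity in each channel over the
#' region's pixels, the centroid, and the morphology metrics of
#' [region_morphology()].
#'
#' @param labels Integer label matrix.
#' @param stack An [image_stack()] of the same dimensions.
#'
#' @return A tibble with one row per fibre: `fibre`, centroid `x`, `y`
#'   (px), `area`, `perimeter`, `circularity`, `aspect_ratio`,
#'   `convexity`, and one mean-intensity column per channel. Results are
#'   invariant to label renumbering up to row order.
#' @export
extract_features <- function(labels, stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (!identical(dim(labels), dim(stack[[1]]))) {
    abort("labels and stack dimensions differ")
  }
  K <- max(labels)
  if (K == 0) {
    return(tibble(fibre = integer(), x = numeric(), y = numeric()))
  }
  in_f <- labels > 0L
  lab_v <- labels[in_f]
  W <- ncol(labels); H <- nrow(labels)
  xs <- rep(1:W, each = H)[in_f]
  ys <- rep(1:H, W)[in_f]
  cnt <- tabulate(lab_v, K)
  base <- tibble(fibre = seq_len(K),
                 x = as.numeric(rowsum(xs, lab_v)) / cnt,
                 y = as.numeric(rowsum(ys, lab_v)) / cnt)
  morph <- dplyr::bind_rows(lapply(region_masks(labels), region_morphology))
  chans <- lapply(stack, function(img) as.numeric(rowsum(img[in_f], lab_v)) / cnt)
  dplyr::bind_cols(base, morph, tibble::as_tibble(chans))
}
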