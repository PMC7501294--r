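#' Create and validate a multichannel image stack
#'
#' An image stack is a named list of 2D intensity matrices, one per channel,
#' all of identical dimensions. Pixel size is fixed at 1 um^2 per pixel, the
#' native resolution of IMC pseudo-images, so pixel counts are areas in um^2
#' and pixel distances are distances in um. Intensities are non-negative ion
#' counts on the 16-bit scale (0--65535).
#'
#' @param ... Named 2D numeric matrices, or a single named list of them.
#'
#' @return An object of class `image_stack`: a named list of matrices.
#' @examples
#' st <- image_stack(DNA = matrix(0, 8, 8), Dystrophin = matrix(1, 8, 8))
#' names(st)
#' @export
image_stack <- function(...) {
  chans <- list(...)
  if (length(chans) == 1L && is.list(chans[[1]]) && !is.matrix(chans[[1]])) {
    chans <- chans[[1]]
  }
  if (length(chans) < 1L) {
    abort("an image stack needs at least one channel")
  }
  if (is.null(names(chans)) || any(!nzchar(names(chans)))) {
    abort("every channel must be named")
  }
  if (anyDuplicated(names(chans))) {
    abort("channel names must be unique")
  }
  dims <- lapply(chans, function(m) {
    if (!is.matrix(m) || !is.numeric(m)) {
      abort("each channel must be a 2D numeric matrix")
    }
    dim(m)
  })
  if (length(unique(dims)) != 1L) {
    abort("all channels must have identical dimensions")
  }
  if (any(vapply(chans, function(m) any(m < 0), logical(1)))) {
    abort("intensities must be non-negative")
  }
  structure(chans, class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("<image_stack> %d channel(s), %d x %d px\n", length(x), d[1], d[2]))
  cat("  channels:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Read an image stack from single-layer 16-bit TIFF files
#'
#' Each channel lives in its own single-layer TIFF, as exported by an MCD
#' viewer. Channel names are taken either from a named vector of paths or
#' from the file names, where the convention is `<sample>_<channel>.tiff`.
#'
#' @param paths Character vector of TIFF paths; names, if present, are used
#'   as channel names.
#'
#' @return An [image_stack()] with intensities on the original 16-bit count
#'   scale.
#' @export
read_image_stack <- function(paths) {
  if (length(paths) < 1L) abort("no TIFF paths given")
  nms <- names(paths)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- sub("\\.tiff?$", "", basename(paths), ignore.case = TRUE)
    nms <- sub("^.*_", "", nms)
  }
  chans <- lapply(paths, function(p) {
    if (!file.exists(p)) abort(paste0("TIFF not found: ", p))
    img <- tiff::readTIFF(p)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    round(img * 65535)
  })
  names(chans) <- nms
  image_stack(chans)
}

#' Write an image stack as one 16-bit TIFF per channel
#'
#' Files are named `<sample>_<channel>.tiff`. Intensities are clipped to
#' the 16-bit range before writing.
#'
#' @param stack An [image_stack()].
#' @param dir Output directory (created if absent).
#' @param sample Sample identifier used as the file-name prefix.
#'
#' @return Invisibly, the named vector of written paths.
#' @export
write_image_stack <- function(stack, dir, sample = "sample") {
  stopifnot(inherits(stack, "image_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(stack), function(ch) {
    p <- file.path(dir, paste0(sample, "_", ch, ".tiff"))
    m <- pmin(pmax(round(stack[[ch]]), 0), 65535)
    tiff::writeTIFF(m / 65535, p, bits.per.sample = 16L)
    p
  }, character(1))
  invisible(paths)
}
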