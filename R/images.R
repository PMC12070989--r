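#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix of intensities in `[0, 1]` (rows =
#' image rows). All images in the pipeline are normalized to this range
#' before any feature is computed.
#'
#' @param pixels numeric matrix with values in `[0, 1]`.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    cg_stop("cg_image_error", "image pixels must be a numeric matrix")
  }
  if (nrow(pixels) < 8 || ncol(pixels) < 8) {
    cg_stop("cg_image_error", "image must be at least 8x8, got %dx%d",
            nrow(pixels), ncol(pixels))
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    cg_stop("cg_image_error", "image intensities must lie in [0, 1]")
  }
  structure(list(pixels = pixels, height = nrow(pixels), width = ncol(pixels)),
            class = "gray_image")
}

#' Labeled region mask container
#'
#' Integer-valued matrix the same shape as its paired image: `0` is
#' background, positive integers are region ids.
#'
#' @param labels integer-valued matrix with non-negative entries.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels) {
  if (!is.matrix(labels) || !is.numeric(labels)) {
    cg_stop("cg_mask_error", "mask labels must be a numeric matrix")
  }
  if (anyNA(labels) || any(labels < 0) || any(labels != round(labels))) {
    cg_stop("cg_mask_error", "mask labels must be non-negative integers")
  }
  structure(list(labels = matrix(as.integer(labels), nrow(labels)),
                 height = nrow(labels), width = ncol(labels)),
            class = "label_mask")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d, intensity range [%.3f, %.3f]>\n",
              x$height, x$width, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  labs <- setdiff(sort(unique(as.vector(x$labels))), 0L)
  cat(sprintf("<label_mask %dx%d, %d region label(s)>\n",
              x$height, x$width, length(labs)))
  invisible(x)
}

check_pair <- function(image, mask) {
  stopifnot(inherits(image, "gray_image"), inherits(mask, "label_mask"))
  if (image$height != mask$height || image$width != mask$width) {
    cg_stop("cg_pair_error", "image (%dx%d) and mask (%dx%d) shapes differ",
            image$height, image$width, mask$height, mask$width)
  }
  invisible(TRUE)
}

#' Read and write grayscale PNG images
#'
#' Images are stored as 8-bit single-channel PNG; intensities are divided by
#' 255 on read so downstream features always see `[0, 1]` values.
#'
#' @param image a [gray_image()].
#' @param path file path.
#' @return `read_gray_png` returns a [gray_image()]; `write_gray_png`
#'   returns `path` invisibly.
#' @export
write_gray_png <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  # quantize explicitly so read(write(x)) is idempotent
  q <- round(image$pixels * 255) / 255
  png::writePNG(q, target = path)
  invisible(path)
}

#' @rdname write_gray_png
#' @export
read_gray_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  gray_image(px)
}

#' Read and write label masks as PNG
#'
#' Masks are stored as 8-bit grayscale PNG holding the raw label integers
#' (0 = background). Labels above 255 are rejected.
#'
#' @param mask a [label_mask()].
#' @param path file path.
#' @return `read_mask_png` returns a [label_mask()]; `write_mask_png`
#'   returns `path` invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 255) {
    cg_stop("cg_mask_error", "mask labels exceed 255; cannot store as 8-bit PNG")
  }
  png::writePNG(mask$labels / 255, target = path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  label_mask(round(px * 255))
}
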