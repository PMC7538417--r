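#' Image stack container
#'
#' A single-channel Z-stack of optical sections with its physical geometry.
#' Data are stored as a numeric array `rows x cols x sections`; `sections`
#' records which original acquisition sections the planes correspond to, so
#' that axially shifted (cropped) stacks keep a meaningful Z coordinate.
#'
#' @param data numeric array (rows x cols x sections), a matrix (single
#'   section), or a list of matrices.
#' @param pixel_size lateral pixel size in micrometres.
#' @param z_spacing spacing between optical sections in micrometres (after
#'   any axial distance correction).
#' @param sections integer vector of original section indices, one per plane.
#' @return an `image_stack` object.
#' @export
image_stack <- function(data, pixel_size, z_spacing, sections = NULL) {
  if (is.list(data)) {
    data <- simplify2array(data)
  }
  if (is.matrix(data)) {
    data <- array(data, dim = c(dim(data), 1L))
  }
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be a positive number (micrometres)")
  }
  if (!is.numeric(z_spacing) || z_spacing <= 0) {
    stop("z_spacing must be a positive number (micrometres)")
  }
  if (is.null(sections)) {
    sections <- seq_len(dim(data)[3L])
  }
  stopifnot(length(sections) == dim(data)[3L])
  structure(
    list(
      data = data,
      pixel_size = pixel_size,
      z_spacing = z_spacing,
      sections = as.integer(sections)
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d x %d px, %d sections (%.4f um/px, %.4f um/section)\n",
    d[1], d[2], d[3], x$pixel_size, x$z_spacing
  ))
  invisible(x)
}

#' Number of optical sections in a stack
#' @param stack an `image_stack`.
#' @return integer section count.
#' @export
n_sections <- function(stack) dim(stack$data)[3L]

#' Extract one optical section as a matrix
#' @param stack an `image_stack`.
#' @param i plane index (1-based, position within the stack).
#' @return numeric matrix.
#' @export
get_section <- function(stack, i) {
  stopifnot(i >= 1L, i <= n_sections(stack))
  stack$data[, , i]
}

#' Gaussian blur of a 2D image
#'
#' Convolution with a normalized Gaussian kernel, replicate boundary, so
#' constant images stay constant near the edges.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return blurred matrix of the same size.
#' @export
gaussian_blur <- function(img, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  size <- min(size, 2L * (min(dim(img)) %/% 2L) - 1L)
  if (size < 3L) return(img)
  brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  out <- EBImage::filter2(img, brush, boundary = "replicate")
  matrix(as.numeric(out), nrow(img))
}

#' Unsharp masking
#'
#' Sharpens by subtracting a weighted Gaussian-blurred copy and rescaling:
#' `(img - weight * blur(img)) / (1 - weight)`.
#'
#' @param img numeric matrix.
#' @param radius Gaussian sigma of the subtracted blur, pixels (> 0).
#' @param weight mask weight in (0, 1).
#' @return sharpened matrix.
#' @export
unsharp_mask <- function(img, radius, weight) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  if (!is.numeric(weight) || weight <= 0 || weight >= 1) {
    stop("weight must be in (0, 1)")
  }
  (img - weight * gaussian_blur(img, radius)) / (1 - weight)
}
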