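# ---------------------------------------------------------------------------
# Raster I/O and resizing, through EBImage.  Package-internal convention:
# an RGB image is an array of dim c(H, W, 3) with values in [0, 255];
# a mask/probability map is an H x W matrix.
# ---------------------------------------------------------------------------

#' Read an RGB image (PNG/JPEG/TIFF)
#'
#' @param path file path.
#' @return array of dim \code{c(H, W, 3)}, values in \code{[0, 255]}.
#' @export
read_image_rgb <- function(path) {
  img <- EBImage::readImage(path)
  a <- as.array(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  aperm(a, c(2, 1, 3)) * 255
}

#' Write an RGB image
#'
#' @param image array of dim \code{c(H, W, 3)} in \code{[0, 255]}.
#' @param path output path; format follows the extension.
#' @export
write_image_rgb <- function(image, path) {
  EBImage::writeImage(EBImage::Image(aperm(pmin(pmax(image / 255, 0), 1),
                                           c(2, 1, 3)),
                                     colormode = "Color"), path)
  invisible(path)
}

#' Write a single-channel mask as an 8-bit PNG (0/255)
#'
#' @param mask H x W matrix with entries in \code{[0, 1]} (binary masks are
#'   written as 0/255).
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(pmin(pmax(mask, 0), 1))), path)
  invisible(path)
}

#' Read a single-channel probability map or mask
#'
#' 8- and 16-bit PNGs are mapped to \code{[0, 1]}.
#'
#' @param path file path.
#' @return H x W matrix in \code{[0, 1]}.
#' @export
read_mask_png <- function(path) {
  a <- as.array(EBImage::readImage(path))
  if (length(dim(a)) == 3L) a <- a[, , 1]
  t(a)
}

#' Bilinearly resize an image, with nearest-neighbour masks
#'
#' Resizes an RGB image to \code{input_size x input_size} by bilinear
#' interpolation; an accompanying pseudo-label mask is resized with
#' nearest-neighbour interpolation so it stays binary.
#'
#' @param image array \code{c(H, W, 3)} in \code{[0, 255]}.
#' @param input_size target side length.
#' @param mask optional H x W binary matrix resized alongside.
#' @return the resized image, or \code{list(image, mask)} when a mask is
#'   given.
#' @export
resize_for_pretraining <- function(image, input_size = 512L, mask = NULL) {
  d <- dim(image)
  out <- if (d[1] == input_size && d[2] == input_size) image else {
    r <- bilinear_fwd_cpp(array(image, c(d[1], d[2], d[3], 1L)),
                          d[1], d[2], d[3], 1L,
                          as.integer(input_size), as.integer(input_size))
    array(r, c(input_size, input_size, d[3]))
  }
  if (is.null(mask)) return(out)
  mk <- if (all(dim(mask) == c(input_size, input_size))) mask else {
    ih <- pmin(pmax(floor((seq_len(input_size) - 0.5) * dim(mask)[1] /
                            input_size) + 1L, 1L), dim(mask)[1])
    iw <- pmin(pmax(floor((seq_len(input_size) - 0.5) * dim(mask)[2] /
                            input_size) + 1L, 1L), dim(mask)[2])
    mask[ih, iw]
  }
  list(image = out, mask = mk)
}
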