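# ---------------------------------------------------------------------------
# Whole-slide patch extraction, tissue filtering and sampling (the data
# preparation steps of the pretraining pipeline).
# ---------------------------------------------------------------------------

#' Patch-extraction specification
#'
#' @param magnification nominal magnification tag of the source image
#'   (metadata; plain raster images carry no pyramid).
#' @param patch_size side length of the square, non-overlapping patches.
#' @param intensity_low,intensity_high inclusive bounds on the mean 8-bit
#'   intensity (over all pixels and channels) a patch must satisfy to count
#'   as tissue.
#' @param sample_n number of patches to keep after random sampling.
#' @return a named list.
#' @export
patch_spec <- function(magnification = 20, patch_size = 1024L,
                       intensity_low = 50, intensity_high = 245,
                       sample_n = NULL) {
  if (!(intensity_low >= 0 && intensity_low < intensity_high &&
        intensity_high <= 255))
    stop("need 0 <= intensity_low < intensity_high <= 255", call. = FALSE)
  if (patch_size < 1L) stop("patch_size must be >= 1", call. = FALSE)
  list(magnification = magnification, patch_size = as.integer(patch_size),
       intensity_low = intensity_low, intensity_high = intensity_high,
       sample_n = sample_n)
}

#' Cut an image into non-overlapping patches
#'
#' Tiles from the top-left origin in row-major order; partial tiles at the
#' right/bottom edges are discarded. An image smaller than one patch yields
#' an empty list (with a warning), not an error.
#'
#' @param image array \code{c(H, W, 3)} (or H x W matrix).
#' @param spec a [patch_spec()].
#' @return list of patches; each carries attributes \code{row} and
#'   \code{col} (1-based grid coordinates).
#' @export
extract_patches <- function(image, spec = patch_spec()) {
  d <- dim(image)
  ps <- spec$patch_size
  nr <- d[1] %/% ps
  nc <- d[2] %/% ps
  if (nr == 0L || nc == 0L) {
    warning(sprintf("image %dx%d smaller than one %dx%d patch; nothing extracted",
                    d[1], d[2], ps, ps))
    return(list())
  }
  out <- vector("list", nr * nc)
  i <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    i <- i + 1L
    p <- if (length(d) == 3L)
      image[((r - 1L) * ps + 1L):(r * ps), ((cc - 1L) * ps + 1L):(cc * ps), ,
            drop = FALSE]
    else
      image[((r - 1L) * ps + 1L):(r * ps), ((cc - 1L) * ps + 1L):(cc * ps),
            drop = FALSE]
    attr(p, "row") <- r
    attr(p, "col") <- cc
    out[[i]] <- p
  }
  out
}

#' Tissue filter by mean intensity
#'
#' Keeps a patch iff its mean 8-bit intensity over all pixels and channels
#' lies inside \code{[intensity_low, intensity_high]} (inclusive bounds);
#' near-white background and near-black artefacts are discarded.
#'
#' @param patch 8-bit RGB patch (values 0..255); other scales are converted
#'   with a warning.
#' @param spec a [patch_spec()].
#' @return logical: keep (\code{TRUE}) or discard.
#' @export
tissue_filter <- function(patch, spec = patch_spec()) {
  if (max(patch) <= 1 && min(patch) >= 0) {
    warning("patch looks like [0,1] data; converting to 8-bit scale")
    patch <- patch * 255
  }
  m <- mean(patch)
  m >= spec$intensity_low && m <= spec$intensity_high
}

#' Uniform random subsample of patches
#'
#' Sampling without replacement, deterministic given the seed. If \code{n}
#' exceeds the number of patches, all patches are returned with a warning.
#'
#' @param patches list of patches.
#' @param n number to keep.
#' @param seed integer seed.
#' @return list of sampled patches (in sampled order).
#' @export
sample_patches <- function(patches, n, seed = 1L) {
  if (n > length(patches)) {
    warning(sprintf("requested %d of %d patches; taking all", n,
                    length(patches)))
    n <- length(patches)
  }
  set.seed(seed)
  patches[sample.int(length(patches), n)]
}

#' Run the patch pipeline: tile, filter, sample
#'
#' The data-preparation steps of the pretraining procedure in order:
#' non-overlapping tiling, tissue filtering by mean intensity, then uniform
#' sampling of the kept patches.
#'
#' @param image large RGB image, \code{c(H, W, 3)} in \code{[0, 255]}.
#' @param spec a [patch_spec()]; \code{sample_n} of NULL keeps every tissue
#'   patch.
#' @param seed sampling seed.
#' @return list with \code{patches} (sampled tissue patches), and
#'   \code{manifest}: a data.frame with one line per tile (row, col,
#'   mean_intensity, kept), plus counts \code{n_tiles}, \code{n_kept},
#'   \code{n_sampled}.
#' @export
run_patch_pipeline <- function(image, spec = patch_spec(), seed = 1L) {
  tiles <- extract_patches(image, spec)
  mi <- vapply(tiles, mean, numeric(1))
  kept <- mi >= spec$intensity_low & mi <= spec$intensity_high
  manifest <- data.frame(
    row = vapply(tiles, attr, 1L, "row"),
    col = vapply(tiles, attr, 1L, "col"),
    mean_intensity = mi, kept = kept)
  tissue <- tiles[kept]
  n <- if (is.null(spec$sample_n)) length(tissue) else spec$sample_n
  sampled <- sample_patches(tissue, n, seed)
  list(patches = sampled, manifest = manifest, n_tiles = length(tiles),
       n_kept = sum(kept), n_sampled = length(sampled))
}

#' Write patches and a manifest to a directory
#'
#' @param pipeline result of [run_patch_pipeline()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_patches <- function(pipeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- pipeline$manifest
  man$filename <- NA_character_
  for (i in seq_along(pipeline$patches)) {
    p <- pipeline$patches[[i]]
    fn <- sprintf("patch_r%03d_c%03d.png", attr(p, "row"), attr(p, "col"))
    write_image_rgb(p, file.path(dir, fn))
    man$filename[man$row == attr(p, "row") & man$col == attr(p, "col")] <- fn
  }
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE)
  invisible(mp)
}
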