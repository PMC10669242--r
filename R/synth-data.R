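# ---------------------------------------------------------------------------
# Synthetic H&E-like slide generator: eosin-pink background, hematoxylin-
# purple elliptical nucleus-like blobs, paired ground-truth masks, optional
# multi-class region labels, and toy downstream datasets.  Everything is
# seed-reproducible: identical params + seed regenerate bitwise-identical
# output.
# ---------------------------------------------------------------------------

#' Parameters of the synthetic slide generator
#'
#' @param width,height slide size in pixels.
#' @param n_blobs expected number of nucleus-like blobs (Poisson mean).
#' @param radius_range min/max semi-axis of the elliptical blobs (pixels).
#' @param background RGB triplet of the eosin-like background.
#' @param nucleus RGB triplet of the hematoxylin-like blobs.
#' @param noise_sd pixel noise standard deviation (8-bit scale).
#' @param n_regions number of texture regions for segmentation labels
#'   (1 = no regions).
#' @param color_shift additive RGB shift applied to the whole slide (used by
#'   the downstream generator to separate classes).
#' @return a named list of generator parameters.
#' @export
slide_params <- function(width = 256L, height = 256L, n_blobs = 40,
                         radius_range = c(4, 9),
                         background = c(231, 196, 214),
                         nucleus = c(96, 64, 138),
                         noise_sd = 7, n_regions = 1L,
                         color_shift = c(0, 0, 0)) {
  if (max(radius_range) * 2 > min(width, height))
    stop("blob radius exceeds the slide size", call. = FALSE)
  list(width = as.integer(width), height = as.integer(height),
       n_blobs = n_blobs, radius_range = radius_range,
       background = background, nucleus = nucleus, noise_sd = noise_sd,
       n_regions = as.integer(n_regions), color_shift = color_shift)
}

# paint one rotated ellipse into a logical mask, in place
paint_ellipse <- function(mask, cx, cy, a, b, theta) {
  H <- nrow(mask); W <- ncol(mask)
  r <- ceiling(max(a, b))
  hs <- max(1L, floor(cx - r)):min(H, ceiling(cx + r))
  ws <- max(1L, floor(cy - r)):min(W, ceiling(cy + r))
  dh <- outer(hs - cx, rep(1, length(ws)))
  dw <- outer(rep(1, length(hs)), ws - cy)
  u <- dh * cos(theta) + dw * sin(theta)
  v <- -dh * sin(theta) + dw * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  mask[hs, ws] <- mask[hs, ws] | inside
  mask
}

#' Generate a synthetic H&E-like slide with ground truth
#'
#' Renders an eosin-like background with hematoxylin-like elliptical blobs at
#' random positions and orientations. The nuclei mask is exactly the rendered
#' blob support; with \code{n_regions > 1} a Voronoi partition of the slide
#' provides per-pixel region labels whose classes modulate the local blob
#' density (used as segmentation ground truth).
#'
#' @param params from [slide_params()].
#' @param seed integer seed; regeneration with the same params and seed is
#'   bitwise identical.
#' @return list with \code{image} (H x W x 3, 0..255), \code{nuclei_mask}
#'   (H x W, 0/1 integer), \code{region_labels} (H x W integer in
#'   \code{0:(n_regions-1)}, or NULL), \code{generator_params}, \code{seed}.
#' @export
generate_slide <- function(params = slide_params(), seed = 1L) {
  set.seed(seed)
  H <- params$height; W <- params$width
  mask <- matrix(FALSE, H, W)
  regions <- NULL
  if (params$n_regions > 1L) {
    k <- params$n_regions
    cx <- runif(k, 1, H); cy <- runif(k, 1, W)
    gh <- matrix(seq_len(H), H, W); gw <- matrix(seq_len(W), H, W, byrow = TRUE)
    dmin <- matrix(Inf, H, W); regions <- matrix(0L, H, W)
    for (i in seq_len(k)) {
      d2 <- (gh - cx[i])^2 + (gw - cy[i])^2
      upd <- d2 < dmin
      regions[upd] <- i - 1L
      dmin[upd] <- d2[upd]
    }
  }
  n <- rpois(1, params$n_blobs)
  if (n > 0) for (i in seq_len(n)) {
    cx <- runif(1, 1, H); cy <- runif(1, 1, W)
    # region class modulates acceptance: denser blobs in higher classes
    if (!is.null(regions)) {
      cls <- regions[round(cx), round(cy)]
      if (runif(1) > (cls + 1) / params$n_regions) next
    }
    a <- runif(1, params$radius_range[1], params$radius_range[2])
    b <- runif(1, params$radius_range[1], params$radius_range[2])
    mask <- paint_ellipse(mask, cx, cy, a, b, runif(1, 0, pi))
  }
  img <- array(0, c(H, W, 3))
  bg <- params$background + params$color_shift
  fg <- params$nucleus + params$color_shift
  rshift <- c(-10, 8, -4)   # per-region tint so regions are visibly textured
  for (c in 1:3) {
    plane <- ifelse(mask, fg[c], bg[c])
    if (!is.null(regions)) plane <- plane + ifelse(mask, 0, regions * rshift[c])
    img[, , c] <- plane
  }
  img <- img + array(rnorm(H * W * 3, sd = params$noise_sd), c(H, W, 3))
  img <- round(pmin(pmax(img, 0), 255))
  list(image = img, nuclei_mask = matrix(as.integer(mask), H, W),
       region_labels = regions, generator_params = params, seed = seed)
}

#' Generate a labeled toy downstream dataset
#'
#' Classification: each class has its own generator parameters (blob density
#' scaled by \code{effect}, plus a class-specific color shift), making the
#' classes Bayes-separable by construction. Segmentation: each image carries
#' its Voronoi region labels as the ground-truth class mask.
#'
#' @param task \code{"cls"} or \code{"seg"}.
#' @param n_per_class images per class (classification) or images total
#'   (segmentation).
#' @param params base [slide_params()]; class variations are derived from it.
#' @param n_classes number of classes (>= 2).
#' @param seed integer seed.
#' @param effect multiplicative spacing of class-conditional blob densities.
#' @return list with \code{items} (each \code{list(image, label)} for cls or
#'   \code{list(image, mask)} for seg, the image carrying its nuclei
#'   probabilities as the \code{"nuclei_prob"} attribute), \code{n_classes},
#'   \code{task}, \code{class_params}.
#' @export
make_downstream_dataset <- function(task = c("cls", "seg"), n_per_class = 20L,
                                    params = slide_params(width = 64L,
                                                          height = 64L,
                                                          n_blobs = 6),
                                    n_classes = 2L, seed = 1L, effect = 3) {
  task <- match.arg(task)
  if (n_classes < 2L) stop("need at least 2 classes", call. = FALSE)
  items <- list()
  class_params <- vector("list", n_classes)
  if (task == "cls") {
    for (k in seq_len(n_classes)) {
      pk <- params
      pk$n_blobs <- params$n_blobs * effect^(k - 1)
      pk$color_shift <- params$color_shift + (k - 1) * c(-25, 18, -8)
      class_params[[k]] <- pk
    }
    if (length(unique(vapply(class_params, function(p) p$n_blobs, 1))) <
        n_classes)
      warning("classes share identical generator parameters; ",
              "they are inseparable by construction")
    idx <- 0L
    for (k in seq_len(n_classes)) for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      sl <- generate_slide(class_params[[k]], seed = seed * 100000L + idx)
      img <- sl$image
      attr(img, "nuclei_prob") <- sl$nuclei_mask
      items[[idx]] <- list(image = img, label = k - 1L)
    }
  } else {
    pk <- params
    pk$n_regions <- as.integer(n_classes)
    class_params[[1]] <- pk
    for (i in seq_len(n_per_class)) {
      sl <- generate_slide(pk, seed = seed * 100000L + i)
      img <- sl$image
      attr(img, "nuclei_prob") <- sl$nuclei_mask
      items[[i]] <- list(image = img, mask = sl$region_labels)
    }
  }
  list(items = items, n_classes = as.integer(n_classes), task = task,
       class_params = class_params)
}

#' Generate unlabeled pretraining patches with ground-truth nuclei
#'
#' Convenience wrapper producing a list of RGB patches, each carrying its
#' ground-truth nuclei mask as the \code{"nuclei_prob"} attribute so that
#' [teacher_mock()] can act as an oracle teacher.
#'
#' @param n number of patches.
#' @param params [slide_params()] of the patches.
#' @param seed integer seed.
#' @return list of image arrays.
#' @export
make_pretraining_patches <- function(n, params = slide_params(width = 64L,
                                                              height = 64L,
                                                              n_blobs = 12),
                                     seed = 1L) {
  lapply(seq_len(n), function(i) {
    sl <- generate_slide(params, seed = seed * 100000L + i)
    img <- sl$image
    attr(img, "nuclei_prob") <- sl$nuclei_mask
    img
  })
}
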