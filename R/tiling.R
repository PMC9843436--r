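#' Convert an RGB slide raster to grayscale
#'
#' Standard luminance combination `0.299 R + 0.587 G + 0.114 B`, returned on
#' the 0-255 scale.
#'
#' @param pixels h x w x 3 array (0-255).
#' @return numeric matrix h x w.
#' @export
rgb_to_gray <- function(pixels) {
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

# Otsu's threshold over an integer grayscale vector (0..255): the cut t
# maximizing the between-class variance of {gray <= t} vs {gray > t}.
otsu_threshold <- function(gray) {
  g <- as.integer(round(gray))
  counts <- tabulate(g + 1L, nbins = 256L)
  n <- sum(counts)
  p <- counts / n
  levels <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_total <- mu[256]
  w1 <- 1 - w0
  # between-class variance for thresholds t = 0..254 (index 1..255)
  num <- (mu_total * w0 - mu)^2
  den <- w0 * w1
  sigma_b <- ifelse(den > 0, num / den, -Inf)
  sigma_b <- sigma_b[1:255]
  if (all(!is.finite(sigma_b))) return(NA_real_)
  # ties (plateau of equal between-class variance) resolved by the plateau
  # midpoint, so a two-delta histogram yields a cut between the two modes
  best <- which(sigma_b >= max(sigma_b) - 1e-12)
  mean(levels[best])
}

#' Otsu foreground detection
#'
#' Separates tissue foreground from the bright glass background: the
#' grayscale threshold maximizes inter-class variance of the histogram, and
#' pixels on the darker side are foreground.
#'
#' @param slide a `SlideImage`.
#' @return a `ForegroundMask`: list with `mask` (0/1 integer matrix) and
#'   `threshold`. A constant image has no defined threshold; an
#'   all-background mask is returned with a warning and `threshold = NA`.
#' @export
otsu_foreground <- function(slide) {
  gray <- rgb_to_gray(slide$pixels)
  abort_if(length(gray) == 0, "empty raster")
  if (diff(range(gray)) == 0) {
    warning("constant image: Otsu threshold undefined, returning all-background")
    mask <- matrix(0L, nrow(gray), ncol(gray))
    return(structure(list(mask = mask, threshold = NA_real_),
                     class = "ForegroundMask"))
  }
  t <- otsu_threshold(gray)
  mask <- matrix(as.integer(round(gray) <= t), nrow(gray), ncol(gray))
  structure(list(mask = mask, threshold = t), class = "ForegroundMask")
}

# nearest-neighbour integer-factor upsampling of a matrix or h x w x c array
upsample_int <- function(x, factor) {
  if (factor == 1L) return(x)
  if (is.matrix(x)) {
    x[rep(seq_len(nrow(x)), each = factor),
      rep(seq_len(ncol(x)), each = factor), drop = FALSE]
  } else {
    d <- dim(x)
    x[rep(seq_len(d[1]), each = factor),
      rep(seq_len(d[2]), each = factor), , drop = FALSE]
  }
}

#' Tissue and tumor fractions of a patch region
#'
#' @param top_left 0-based (row, col) of the patch.
#' @param size_px patch edge length.
#' @param mask foreground 0/1 matrix (or `ForegroundMask`).
#' @param labelmap optional ground-truth/predicted label map; when given,
#'   the tumor fraction counts pixels of `tumor_classes`.
#' @param tumor_classes classes counted as tumor (default FP_like, FN_like,
#'   and mutant_like, which is planted inside tumor).
#' @return list with `tissue_fraction` and `tumor_fraction` (NA when no
#'   label map is given).
#' @export
patch_fractions <- function(top_left, size_px, mask, labelmap = NULL,
                            tumor_classes = c("FP_like", "FN_like", "mutant_like")) {
  if (inherits(mask, "ForegroundMask")) mask <- mask$mask
  r <- top_left[1] + seq_len(size_px)
  c <- top_left[2] + seq_len(size_px)
  abort_if(min(r) < 1 || min(c) < 1 || max(r) > nrow(mask) || max(c) > ncol(mask),
           "patch region out of bounds")
  tf <- sum(mask[r, c]) / size_px^2
  tumf <- NA_real_
  if (!is.null(labelmap)) {
    classes <- attr(labelmap, "classes")
    idx <- match(tumor_classes, classes)
    idx <- idx[!is.na(idx)]
    tumf <- sum(labelmap[r, c] %in% idx) / size_px^2
  }
  list(tissue_fraction = tf, tumor_fraction = tumf)
}

#' Randomly extract patches passing tissue/tumor-fraction filters
#'
#' Top-left coordinates are sampled uniformly over all in-bounds positions;
#' a candidate patch is accepted when its tissue fraction is at least
#' `min_tissue_fraction` and (when a label map is supplied) its tumor
#' fraction is at least `min_tumor_fraction`. Sampling stops when
#' `n_patches` have been accepted or the attempt budget (50 per requested
#' patch) is exhausted, in which case fewer patches are returned with a
#' warning flag. "20x" patches are cut from a 2x nearest-neighbour upsampled
#' raster when the source is a 10x (mpp = 1) slide.
#'
#' @param slide a `SlideImage`.
#' @param mask a `ForegroundMask` (or 0/1 matrix) at the slide's base
#'   resolution.
#' @param size_px patch edge length at the target magnification.
#' @param magnification_tag `"10x"` or `"20x"`.
#' @param n_patches patches requested.
#' @param min_tissue_fraction minimum foreground fraction (default 0.5).
#' @param min_tumor_fraction minimum tumor fraction; only enforced when
#'   `labelmap` is given (default 0, i.e. no filter).
#' @param labelmap optional label map at base resolution.
#' @param seed integer seed; extraction is deterministic given the seed.
#' @return list of `Patch` objects; attribute `budget_exhausted` is `TRUE`
#'   when fewer than `n_patches` could be collected.
#' @export
extract_patches <- function(slide, mask, size_px, magnification_tag = "10x",
                            n_patches = 10, min_tissue_fraction = 0.5,
                            min_tumor_fraction = 0, labelmap = NULL,
                            seed = 1L) {
  abort_if(!magnification_tag %in% c("10x", "20x"),
           "magnification_tag must be '10x' or '20x'")
  abort_if(min_tissue_fraction < 0 || min_tissue_fraction > 1 ||
             min_tumor_fraction < 0 || min_tumor_fraction > 1,
           "fractions must be in [0, 1]")
  if (inherits(mask, "ForegroundMask")) mask <- mask$mask
  pixels <- slide$pixels
  factor <- 1L
  if (magnification_tag == "20x" && slide$mpp > 0.75) factor <- 2L
  if (factor > 1L) {
    pixels <- upsample_int(pixels, factor)
    mask <- upsample_int(mask, factor)
    if (!is.null(labelmap)) {
      cls <- attr(labelmap, "classes")
      labelmap <- upsample_int(labelmap, factor)
      attr(labelmap, "classes") <- cls
    }
  }
  h <- nrow(mask); w <- ncol(mask)
  abort_if(size_px > min(h, w), "patch size exceeds slide dimensions")
  nr <- h - size_px + 1L
  nc <- w - size_px + 1L
  budget <- 50L * n_patches
  patches <- list()
  exhausted <- FALSE
  with_seed(seed, {
    attempts <- 0L
    while (length(patches) < n_patches && attempts < budget) {
      attempts <- attempts + 1L
      r0 <- sample.int(nr, 1L) - 1L
      c0 <- sample.int(nc, 1L) - 1L
      fr <- patch_fractions(c(r0, c0), size_px, mask, labelmap)
      if (fr$tissue_fraction < min_tissue_fraction) next
      if (!is.null(labelmap) && fr$tumor_fraction < min_tumor_fraction) next
      patches[[length(patches) + 1L]] <- new_patch(
        slide$slide_id, c(r0, c0), size_px, magnification_tag,
        fr$tissue_fraction, fr$tumor_fraction,
        pixels[r0 + seq_len(size_px), c0 + seq_len(size_px), , drop = FALSE])
    }
    if (length(patches) < n_patches) {
      exhausted <- TRUE
      warning(sprintf("attempt budget exhausted: %d of %d patches collected",
                      length(patches), n_patches))
    }
  })
  attr(patches, "budget_exhausted") <- exhausted
  patches
}

new_patch <- function(slide_id, top_left, size_px, magnification_tag,
                      tissue_fraction, tumor_fraction, pixels, label = NA) {
  structure(list(slide_id = slide_id, top_left = as.integer(top_left),
                 size_px = as.integer(size_px),
                 magnification_tag = magnification_tag,
                 tissue_fraction = tissue_fraction,
                 tumor_fraction = tumor_fraction, pixels = pixels,
                 label = label),
            class = "Patch")
}

#' Grid tiling of a slide
#'
#' Overlapping fixed-size tiles at a regular stride, as used for
#' tissue-microarray cores and for whole-slide segmentation stitching. The
#' final row/column of tiles is shifted inward so the grid always covers the
#' full canvas.
#'
#' @param slide a `SlideImage` (or bare h x w x 3 array).
#' @param size_px tile edge length.
#' @param stride step between tile origins (default `size_px / 2`).
#' @return list of `Patch` objects with tissue/tumor fractions `NA`.
#' @export
tile_grid <- function(slide, size_px, stride = max(1L, size_px %/% 2L)) {
  pixels <- if (inherits(slide, "SlideImage")) slide$pixels else slide
  id <- if (inherits(slide, "SlideImage")) slide$slide_id else "slide"
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  abort_if(size_px > min(h, w), "tile size exceeds slide dimensions")
  starts <- function(n) {
    s <- seq(0L, n - size_px, by = stride)
    if (s[length(s)] != n - size_px) s <- c(s, n - size_px)
    as.integer(s)
  }
  out <- list()
  for (r0 in starts(h)) {
    for (c0 in starts(w)) {
      out[[length(out) + 1L]] <- new_patch(
        id, c(r0, c0), size_px, "10x", NA_real_, NA_real_,
        pixels[r0 + seq_len(size_px), c0 + seq_len(size_px), , drop = FALSE])
    }
  }
  out
}

#' Write a patch manifest CSV
#'
#' @param patches list of `Patch`.
#' @param path CSV path.
#' @return the manifest data.frame invisibly.
#' @export
write_patch_manifest <- function(patches, path) {
  df <- do.call(rbind, lapply(patches, function(p) {
    data.frame(slide_id = p$slide_id, row = p$top_left[1], col = p$top_left[2],
               size = p$size_px, magnification = p$magnification_tag,
               tissue_fraction = p$tissue_fraction,
               tumor_fraction = p$tumor_fraction, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
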