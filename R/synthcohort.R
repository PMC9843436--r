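#' Texture class parameters
#'
#' Describes one renderable texture class. Textures are built as a stained
#' background color field plus Poisson-scattered dark elliptical blobs
#' (nucleus proxies) plus oriented band-pass noise, so that every class is
#' separable by locally computable statistics (blob density, blob radius,
#' orientation coherence) rather than histologic realism.
#'
#' @param class_name one of the class labels used by the pipeline
#'   (e.g. "background", "FP_like", "FN_like", "stroma", "necrosis",
#'   "mutant_like", "normal").
#' @param base_color RGB triple in 0-255.
#' @param spot_density expected nucleus-like blobs per 1e4 px^2.
#' @param spot_radius_px mean blob radius in pixels.
#' @param anisotropy orientation coherence in `[0, 1]`; 0 = isotropic,
#'   1 = strongly oriented streaks/elongated blobs.
#' @param noise_sd additive Gaussian noise standard deviation (8-bit units).
#' @return a `TextureClassParams` list.
#' @export
texture_params <- function(class_name, base_color, spot_density = 0,
                           spot_radius_px = 0, anisotropy = 0, noise_sd = 2) {
  stopifnot(length(base_color) == 3, all(base_color >= 0 & base_color <= 255))
  abort_if(anisotropy < 0 || anisotropy > 1, "anisotropy must be in [0, 1]")
  abort_if(spot_density < 0 || spot_radius_px < 0 || noise_sd < 0,
           "density, radius and noise_sd must be non-negative")
  structure(list(class_name = class_name, base_color = as.numeric(base_color),
                 spot_density = spot_density, spot_radius_px = spot_radius_px,
                 anisotropy = anisotropy, noise_sd = noise_sd),
            class = "TextureClassParams")
}

#' Default texture palette
#'
#' A high-margin palette: background is near-white glass; the tissue classes
#' differ strongly in at least one of blob density, blob radius, or
#' orientation coherence. `FP_like` emulates densely packed small round
#' nuclei, `FN_like` sparser larger nuclei, `stroma` oriented fibrous tissue
#' with few nuclei, `necrosis` grainy eosinophilic debris, `mutant_like` a
#' darker, denser variant planted inside tumor regions, and `normal` a
#' mildly textured non-tumor tissue.
#'
#' @return named list of [texture_params()] objects.
#' @export
default_texture_params <- function() {
  list(
    background  = texture_params("background",  c(245, 245, 246), 0,   0,   0,    2),
    FP_like     = texture_params("FP_like",     c(176, 150, 200), 55,  2.2, 0.05, 8),
    FN_like     = texture_params("FN_like",     c(208, 170, 196), 16,  3.8, 0.10, 8),
    stroma      = texture_params("stroma",      c(232, 192, 204), 4,   1.8, 0.85, 6),
    necrosis    = texture_params("necrosis",    c(216, 198, 178), 1.5, 2.5, 0.00, 18),
    mutant_like = texture_params("mutant_like", c(148, 126, 186), 85,  2.0, 0.05, 8),
    normal      = texture_params("normal",      c(226, 204, 214), 7,   2.0, 0.30, 6)
  )
}

#' Validate a texture palette
#'
#' Checks the two separability invariants: the background class must be
#' strictly brighter (mean luminance of the base color) than every tissue
#' class, and any two distinct tissue classes must differ in at least one of
#' spot density, spot radius, or anisotropy by a relative margin.
#'
#' @param textures named list of [texture_params()].
#' @param margin minimum relative difference required in at least one of the
#'   three local statistics (default 0.25).
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_textures <- function(textures, margin = 0.25) {
  lum <- function(tp) sum(c(0.299, 0.587, 0.114) * tp$base_color)
  bg <- textures[["background"]]
  abort_if(is.null(bg), "palette must contain a 'background' class")
  tissue <- textures[setdiff(names(textures), "background")]
  for (tp in tissue) {
    abort_if(lum(tp) >= lum(bg),
             "tissue class '%s' is not darker than background", tp$class_name)
  }
  rel_diff <- function(a, b) abs(a - b) / max(abs(a), abs(b), 1e-9)
  nm <- names(tissue)
  if (length(nm) > 1) {
    for (i in seq_len(length(nm) - 1)) {
      for (j in seq(i + 1, length(nm))) {
        a <- tissue[[i]]; b <- tissue[[j]]
        d <- c(rel_diff(a$spot_density, b$spot_density),
               rel_diff(a$spot_radius_px, b$spot_radius_px),
               rel_diff(a$anisotropy, b$anisotropy))
        abort_if(all(d < margin),
                 "classes '%s' and '%s' differ by less than the margin in all local statistics",
                 nm[i], nm[j])
      }
    }
  }
  invisible(TRUE)
}

# Canonical class order used for label maps throughout the package.
#' @export
class_order <- function() {
  c("background", "FP_like", "FN_like", "stroma", "necrosis", "mutant_like",
    "normal")
}

#' Construct a SlideImage
#'
#' @param pixels integer array h x w x 3 with values in 0-255.
#' @param mpp microns per pixel; convention 1.0 at "10x", 0.5 at "20x".
#' @param slide_id identifier string.
#' @return a `SlideImage`.
#' @export
slide_image <- function(pixels, mpp = 1.0, slide_id = "slide") {
  abort_if(length(dim(pixels)) != 3 || dim(pixels)[3] != 3,
           "pixels must be an h x w x 3 array")
  abort_if(any(dim(pixels)[1:2] < 1), "slide must have height, width >= 1")
  abort_if(mpp <= 0, "mpp must be positive")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, mpp = mpp, slide_id = slide_id),
            class = "SlideImage")
}

#' Rectangular region helper
#'
#' Builds the polygon (in (row, col) vertex order) of an axis-aligned
#' rectangle covering rows `row0..row0+height-1` and columns
#' `col0..col0+width-1` (0-based, half-open convention at the pixel level).
#'
#' @param class_name texture class drawn in the region.
#' @param row0,col0 0-based top-left corner.
#' @param height,width extent in pixels.
#' @return region list with `class_name` and a polygon matrix.
#' @export
rect_region <- function(class_name, row0, col0, height, width) {
  abort_if(height < 1 || width < 1, "region must have positive extent")
  poly <- rbind(c(row0, col0), c(row0, col0 + width),
                c(row0 + height, col0 + width), c(row0 + height, col0))
  list(class_name = class_name, poly = poly)
}

#' Synthetic slide specification
#'
#' @param width_px,height_px canvas size in pixels (positive).
#' @param regions list of regions (see [rect_region()]): each a list with
#'   `class_name` and `poly`, an n x 2 matrix of (row, col) vertices.
#'   Regions must not overlap; uncovered canvas is background.
#' @param mutant_fraction fraction of tumor-area pixels (FP_like/FN_like)
#'   replaced by contiguous `mutant_like` patches, emulating the mutant cell
#'   fraction (variant allele fraction proxy). In `[0, 1]`.
#' @param mpp microns per pixel of the base raster.
#' @param slide_id identifier.
#' @param seed integer seed; the generated slide is a pure function of the
#'   spec.
#' @return a `SyntheticSlideSpec`.
#' @export
slide_spec <- function(width_px, height_px, regions, mutant_fraction = 0,
                       mpp = 1.0, slide_id = "slide", seed = 1L) {
  abort_if(width_px < 1 || height_px < 1, "canvas must have positive area")
  abort_if(mutant_fraction < 0 || mutant_fraction > 1,
           "mutant_fraction must be in [0, 1]")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px), regions = regions,
                 mutant_fraction = mutant_fraction, mpp = mpp,
                 slide_id = slide_id, seed = as.integer(seed)),
            class = "SyntheticSlideSpec")
}

# vectorized even-odd (ray casting) point-in-polygon over pixel centers
points_in_polygon <- function(rows, cols, poly) {
  # pixel centers at (row + 0.5, col + 0.5) against vertex coordinates
  px <- cols + 0.5
  py <- rows + 0.5
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Render one texture class over an h x w canvas (numeric matrix per channel).
render_texture <- function(h, w, tp) {
  ch <- lapply(tp$base_color, function(v) {
    matrix(v + stats::rnorm(h * w, 0, tp$noise_sd), h, w)
  })
  theta <- stats::runif(1, 0, pi)
  if (tp$anisotropy > 0.05) {
    # oriented band-pass noise: white noise averaged along direction theta
    len <- 1L + round(12 * tp$anisotropy)
    noise <- matrix(stats::rnorm(h * w, 0, 18), h, w)
    acc <- matrix(0, h, w)
    for (k in seq(-len, len)) {
      dr <- round(k * sin(theta)); dc <- round(k * cos(theta))
      sr <- pmin(pmax(seq_len(h) + dr, 1L), h)
      sc <- pmin(pmax(seq_len(w) + dc, 1L), w)
      acc <- acc + noise[sr, sc, drop = FALSE]
    }
    acc <- acc / (2 * len + 1)
    for (c in 1:3) ch[[c]] <- ch[[c]] + acc
  }
  if (tp$spot_density > 0 && tp$spot_radius_px > 0) {
    n_blobs <- stats::rpois(1, tp$spot_density * h * w / 1e4)
    if (n_blobs > 0) {
      cy <- stats::runif(n_blobs, 1, h)
      cx <- stats::runif(n_blobs, 1, w)
      rr <- tp$spot_radius_px * stats::rgamma(n_blobs, shape = 9, rate = 9)
      elong <- 1 + 2.5 * tp$anisotropy
      for (b in seq_len(n_blobs)) {
        a_r <- rr[b] * elong; b_r <- rr[b] / sqrt(elong)
        rad <- ceiling(max(a_r, b_r)) + 1L
        r0 <- max(1L, floor(cy[b] - rad)); r1 <- min(h, ceiling(cy[b] + rad))
        c0 <- max(1L, floor(cx[b] - rad)); c1 <- min(w, ceiling(cx[b] + rad))
        if (r0 > r1 || c0 > c1) next
        dy <- (r0:r1) - cy[b]; dx <- (c0:c1) - cx[b]
        u <- outer(dy, dx, function(y, x) (y * sin(theta) + x * cos(theta)) / a_r)
        v <- outer(dy, dx, function(y, x) (-y * cos(theta) + x * sin(theta)) / b_r)
        d2 <- u^2 + v^2
        dark <- pmax(0, 1 - d2) * 95  # soft-edged darkening
        for (c in 1:3) {
          ch[[c]][r0:r1, c0:c1] <- ch[[c]][r0:r1, c0:c1] - dark
        }
      }
    }
  }
  ch
}

#' Generate a synthetic slide with pixel ground truth
#'
#' Paints the region layout onto the canvas (uncovered canvas is
#' background), plants spatially contiguous `mutant_like` disks inside the
#' tumor area (FP_like/FN_like pixels) until the requested fraction of tumor
#' pixels is reached, then renders each class texture. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [slide_spec()].
#' @param textures texture palette, default [default_texture_params()].
#' @return a `SyntheticSlide`: list with `image` (a `SlideImage`), `labels`
#'   (integer matrix indexing `attr(labels, "classes")`), and `spec`.
#' @export
generate_slide <- function(spec, textures = default_texture_params()) {
  abort_if(spec$width_px * spec$height_px <= 0, "zero-area canvas")
  validate_textures(textures)
  classes <- class_order()
  h <- spec$height_px; w <- spec$width_px
  with_seed(spec$seed, {
    labels <- matrix(match("background", classes), h, w)
    for (reg in spec$regions) {
      idx <- match(reg$class_name, classes)
      abort_if(is.na(idx), "unknown region class '%s'", reg$class_name)
      rows <- rep(seq_len(h) - 1L, times = w)
      cols <- rep(seq_len(w) - 1L, each = h)
      inside <- points_in_polygon(rows, cols, reg$poly)
      abort_if(any(labels[inside] != match("background", classes)),
               "regions overlap at class '%s'", reg$class_name)
      labels[inside] <- idx
    }
    # plant contiguous mutant_like disks inside the tumor area
    if (spec$mutant_fraction > 0) {
      tumor_idx <- match(c("FP_like", "FN_like"), classes)
      tumor <- labels %in% tumor_idx
      n_tumor <- sum(tumor)
      if (n_tumor > 0) {
        target <- round(spec$mutant_fraction * n_tumor)
        mut_idx <- match("mutant_like", classes)
        max_r <- max(2, floor(sqrt(0.02 * n_tumor / pi)))
        planted <- 0L
        guard <- 0L
        while (planted < target && guard < 10000L) {
          guard <- guard + 1L
          remaining <- target - planted
          r <- min(max_r, max(2, floor(sqrt(remaining / pi))))
          cand <- which(matrix(labels %in% tumor_idx, h, w))
          if (length(cand) == 0) break
          ctr <- cand[sample.int(length(cand), 1)]
          cr <- (ctr - 1L) %% h + 1L
          cc <- (ctr - 1L) %/% h + 1L
          r0 <- max(1L, cr - r); r1 <- min(h, cr + r)
          c0 <- max(1L, cc - r); c1 <- min(w, cc + r)
          dy <- (r0:r1) - cr; dx <- (c0:c1) - cc
          disk <- outer(dy, dx, function(y, x) y^2 + x^2 <= r^2)
          sub <- labels[r0:r1, c0:c1]
          hit <- disk & matrix(sub %in% tumor_idx, nrow(disk), ncol(disk))
          sub[hit] <- mut_idx
          labels[r0:r1, c0:c1] <- sub
          planted <- planted + sum(hit)
        }
      }
    }
    # render: one full-canvas texture per class present, composed by label
    pix <- array(0, dim = c(h, w, 3))
    for (idx in sort(unique(as.vector(labels)))) {
      cls <- classes[idx]
      tp <- textures[[cls]]
      abort_if(is.null(tp), "no texture parameters for class '%s'", cls)
      tex <- render_texture(h, w, tp)
      m <- labels == idx
      for (c in 1:3) pix[, , c][m] <- tex[[c]][m]
    }
    pix <- pmin(pmax(round(pix), 0), 255)
    attr(labels, "classes") <- classes
    structure(list(image = slide_image(pix, mpp = spec$mpp,
                                       slide_id = spec$slide_id),
                   labels = labels, spec = spec),
              class = "SyntheticSlide")
  })
}

#' Synthetic cohort specification
#'
#' @param n_slides number of slides.
#' @param class_balance named proportions over tumor classes, summing to 1
#'   (e.g. `c(FP_like = 0.5, FN_like = 0.5)`).
#' @param mutant_prevalence probability a slide carries the planted mutation.
#' @param mutant_fraction_dist function(n) drawing mutant fractions in
#'   `[0, 1]` for mutant slides; default uniform on `[0.2, 0.6]`.
#' @param survival list with `baseline_rate` (events/year),
#'   `log_hazard_coefficient` (effect of the planted image feature, the
#'   mutant fraction, on the log hazard), `censoring_rate` (/year;
#'   0 disables random censoring), `max_followup_years` (administrative
#'   censoring horizon; may be `Inf`).
#' @param seed integer seed.
#' @return a `SyntheticCohortSpec`.
#' @export
cohort_spec <- function(n_slides,
                        class_balance = c(FP_like = 0.5, FN_like = 0.5),
                        mutant_prevalence = 0.5,
                        mutant_fraction_dist = function(n) stats::runif(n, 0.2, 0.6),
                        survival = list(baseline_rate = 0.2,
                                        log_hazard_coefficient = 1.0,
                                        censoring_rate = 0.05,
                                        max_followup_years = 20),
                        seed = 1L) {
  abort_if(abs(sum(class_balance) - 1) > 1e-8, "class proportions must sum to 1")
  abort_if(any(unlist(survival[c("baseline_rate", "censoring_rate")]) < 0) ||
             survival$max_followup_years <= 0,
           "survival rates must be non-negative and follow-up positive")
  abort_if(n_slides < 1, "n_slides must be >= 1")
  structure(list(n_slides = as.integer(n_slides), class_balance = class_balance,
                 mutant_prevalence = mutant_prevalence,
                 mutant_fraction_dist = mutant_fraction_dist,
                 survival = survival, seed = as.integer(seed)),
            class = "SyntheticCohortSpec")
}

#' Generate a synthetic cohort of slides with survival labels
#'
#' Samples a tumor class and mutant status per slide, draws the mutant
#' fraction for mutant slides, and simulates right-censored survival. The
#' planted image risk feature is the centered mutant fraction
#' `f = 2 * mutant_fraction - 1` (in `[-1, 1]`, matching the scale of the
#' model's hazard output); event times are exponential with rate
#' `baseline_rate * exp(log_hazard_coefficient * f)`, censoring is
#' exponential and independent, and follow-up is capped at
#' `max_followup_years`. With `log_hazard_coefficient = 0` the planted
#' image feature and the event time are independent.
#'
#' @param spec a [cohort_spec()].
#' @param textures texture palette.
#' @param slide_px square slide edge length when rendering.
#' @param render if `FALSE`, only the cohort table is produced (no images),
#'   which is what the closed-form survival checks need.
#' @param dir optional directory: writes `cohort.csv` and one PNG per slide.
#' @return list with `table` (data.frame: slide_id, class, mutant,
#'   mutant_fraction, time_years, event) and `slides` (list of
#'   `SyntheticSlide` or `NULL`).
#' @export
generate_cohort <- function(spec, textures = default_texture_params(),
                            slide_px = 96, render = TRUE, dir = NULL) {
  n <- spec$n_slides
  sv <- spec$survival
  with_seed(spec$seed, {
    cls <- sample(names(spec$class_balance), n, replace = TRUE,
                  prob = spec$class_balance)
    mutant <- stats::rbinom(n, 1, spec$mutant_prevalence)
    mf <- numeric(n)
    if (any(mutant == 1)) mf[mutant == 1] <- spec$mutant_fraction_dist(sum(mutant))
    feature <- 2 * mf - 1
    rate <- sv$baseline_rate * exp(sv$log_hazard_coefficient * feature)
    t_event <- stats::rexp(n, rate)
    t_cens <- if (sv$censoring_rate > 0) stats::rexp(n, sv$censoring_rate) else rep(Inf, n)
    time <- pmin(t_event, t_cens, sv$max_followup_years)
    event <- as.integer(t_event <= t_cens & t_event <= sv$max_followup_years)
    ids <- sprintf("S%03d", seq_len(n))
    tab <- data.frame(slide_id = ids, class = cls, mutant = mutant,
                      mutant_fraction = mf, time_years = time, event = event,
                      stringsAsFactors = FALSE)
    slides <- NULL
    if (render) {
      seeds <- sample.int(.Machine$integer.max, n)
      slides <- vector("list", n)
      for (i in seq_len(n)) {
        inset <- max(4L, round(slide_px / 12))
        sp <- slide_spec(slide_px, slide_px,
                         list(rect_region(cls[i], inset, inset,
                                          slide_px - 2L * inset,
                                          slide_px - 2L * inset)),
                         mutant_fraction = mf[i], slide_id = ids[i],
                         seed = seeds[i])
        slides[[i]] <- generate_slide(sp, textures)
      }
      names(slides) <- ids
    }
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE)
      if (render) {
        for (i in seq_len(n)) {
          write_slide_png(slides[[i]]$image, file.path(dir, paste0(ids[i], ".png")))
        }
      }
    }
    list(table = tab, slides = slides)
  })
}

#' Generate a synthetic tissue microarray
#'
#' One circular core image per (patient, core): all cores of a patient share
#' the patient's class label, while the texture realization of each core is
#' independent (fresh noise and blob placement).
#'
#' @param n_patients number of patients.
#' @param cores_per_patient scalar or length-`n_patients` integer vector
#'   (e.g. duplicate cores for all but one patient with four).
#' @param core_diameter_px core diameter in pixels.
#' @param spec a [cohort_spec()] supplying `class_balance` and `seed`.
#' @param textures texture palette.
#' @param canvas_px square canvas edge; must be >= core diameter.
#' @return list of patients, each with `patient_id`, `class`, and `cores`
#'   (list of `SyntheticSlide` core images with ground-truth label maps).
#' @export
generate_tma <- function(n_patients, cores_per_patient, core_diameter_px,
                         spec, textures = default_texture_params(),
                         canvas_px = core_diameter_px + 8L) {
  abort_if(any(cores_per_patient < 1), "cores_per_patient must be >= 1")
  abort_if(core_diameter_px > canvas_px, "core diameter exceeds canvas")
  if (length(cores_per_patient) == 1L) {
    cores_per_patient <- rep(cores_per_patient, n_patients)
  }
  abort_if(length(cores_per_patient) != n_patients,
           "cores_per_patient must be scalar or length n_patients")
  classes <- class_order()
  with_seed(spec$seed, {
    pcls <- sample(names(spec$class_balance), n_patients, replace = TRUE,
                   prob = spec$class_balance)
    out <- vector("list", n_patients)
    for (p in seq_len(n_patients)) {
      cores <- vector("list", cores_per_patient[p])
      for (k in seq_len(cores_per_patient[p])) {
        core_seed <- sample.int(.Machine$integer.max, 1)
        cores[[k]] <- generate_core(canvas_px, core_diameter_px, pcls[p],
                                    textures, core_seed,
                                    sprintf("P%03d_core%d", p, k))
      }
      out[[p]] <- list(patient_id = sprintf("P%03d", p), class = pcls[p],
                       cores = cores)
    }
    out
  })
}

# render one circular core of the given class on a background canvas
generate_core <- function(canvas_px, diameter_px, cls, textures, seed, id) {
  classes <- class_order()
  with_seed(seed, {
    h <- w <- as.integer(canvas_px)
    ctr <- (h + 1) / 2
    rr <- diameter_px / 2
    dy <- seq_len(h) - ctr
    disk <- outer(dy, dy, function(y, x) y^2 + x^2 <= rr^2)
    labels <- matrix(match("background", classes), h, w)
    labels[disk] <- match(cls, classes)
    pix <- array(0, dim = c(h, w, 3))
    for (idx in sort(unique(as.vector(labels)))) {
      tex <- render_texture(h, w, textures[[classes[idx]]])
      m <- labels == idx
      for (c in 1:3) pix[, , c][m] <- tex[[c]][m]
    }
    pix <- pmin(pmax(round(pix), 0), 255)
    attr(labels, "classes") <- classes
    structure(list(image = slide_image(pix, slide_id = id), labels = labels,
                   spec = NULL),
              class = "SyntheticSlide")
  })
}

#' Write / read slides and label maps as PNG
#'
#' Slides are 8-bit RGB PNG; label maps are single-channel PNG whose gray
#' level encodes the 0-based class index.
#'
#' @param slide a `SlideImage`.
#' @param path file path.
#' @return `read_slide_png` returns a `SlideImage`; writers return the path
#'   invisibly.
#' @export
write_slide_png <- function(slide, path) {
  png::writePNG(slide$pixels / 255, path)
  invisible(path)
}

#' @rdname write_slide_png
#' @param mpp,slide_id metadata for the slide read back.
#' @export
read_slide_png <- function(path, mpp = 1.0, slide_id = basename(path)) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  if (dim(arr)[3] == 4) arr <- arr[, , 1:3, drop = FALSE]
  slide_image(round(arr * 255), mpp = mpp, slide_id = slide_id)
}

#' @rdname write_slide_png
#' @param labels integer label matrix with a `classes` attribute.
#' @export
write_labelmap_png <- function(labels, path) {
  png::writePNG((labels - 1L) / 255, path)
  invisible(path)
}

#' @rdname write_slide_png
#' @param classes class vector to attach when reading a label map.
#' @export
read_labelmap_png <- function(path, classes = class_order()) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  labels <- matrix(as.integer(round(m * 255)) + 1L, nrow(m), ncol(m))
  attr(labels, "classes") <- classes
  labels
}
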