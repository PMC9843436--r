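# Shared fixture builders for the test suite. Everything is generated in
# code at test time; nothing is stored on disk.

# a single-region slide of the given class
make_slide <- function(cls = "FN_like", px = 64, mutant_fraction = 0,
                       seed = 1L, inset = 6L) {
  generate_slide(slide_spec(px, px,
                            list(rect_region(cls, inset, inset,
                                             px - 2L * inset, px - 2L * inset)),
                            mutant_fraction = mutant_fraction,
                            slide_id = sprintf("%s_%d", cls, seed),
                            seed = seed))
}

# (pixels, labels) pairs for segmenter training
make_seg_pairs <- function(n, classes = c("FP_like", "FN_like"), px = 64,
                           seed0 = 1L) {
  lapply(seq_len(n), function(i) {
    s <- make_slide(classes[(i - 1L) %% length(classes) + 1L], px = px,
                    seed = seed0 + i)
    list(pixels = s$image$pixels, labels = s$labels)
  })
}

# feature matrix + labels for patch-classifier tests: patches from slides
# of the given classes; label = class index
make_patch_data <- function(classes, n_slides_per_class = 5, px = 64,
                            patch = 24, npp = 8, seed0 = 1L) {
  X <- NULL; y <- integer(0); slide <- character(0)
  for (ci in seq_along(classes)) {
    for (k in seq_len(n_slides_per_class)) {
      s <- make_slide(classes[ci], px = px, seed = seed0 + 100 * ci + k)
      ps <- extract_patches(s$image, otsu_foreground(s$image), patch,
                            n_patches = npp, seed = seed0 + 17 * ci + k)
      Xi <- t(vapply(ps, patch_features, patch_features(ps[[1]])))
      X <- rbind(X, Xi)
      y <- c(y, rep(ci, nrow(Xi)))
      slide <- c(slide, rep(s$image$slide_id, nrow(Xi)))
    }
  }
  list(X = X, y = y, slide = slide)
}

# exponential survival records with a binary planted feature
make_surv_records <- function(n, hr = 1, baseline = 0.2, seed = 1L) {
  histomil:::with_seed(seed, {
    f <- rep(0:1, length.out = n)
    t_ev <- stats::rexp(n, baseline * hr^f)
    data.frame(subject_id = sprintf("p%03d", seq_len(n)),
               time_years = t_ev, event = 1L, feature = f,
               stringsAsFactors = FALSE)
  })
}
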