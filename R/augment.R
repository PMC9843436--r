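#' Geometric augmentation vocabulary
#'
#' The eight-fold dihedral group restricted to the named operations:
#' `rot90`, `rot180`, `rot270` (clockwise rotations), `vflip` (reverse
#' rows), `hflip` (reverse columns), and `transpose` (main-diagonal
#' reflection). All are pixel-exact and label-preserving.
#'
#' @return character vector of op names.
#' @export
augment_ops <- function() {
  c("rot90", "rot180", "rot270", "vflip", "hflip", "transpose")
}

# apply one op to an h x w x c array (or matrix)
apply_op_array <- function(a, op) {
  is_mat <- is.matrix(a)
  if (is_mat) a <- array(a, dim = c(dim(a), 1))
  out <- switch(op,
    rot90 = aperm(a[dim(a)[1]:1, , , drop = FALSE], c(2, 1, 3)),
    rot180 = a[dim(a)[1]:1, dim(a)[2]:1, , drop = FALSE],
    rot270 = aperm(a[, dim(a)[2]:1, , drop = FALSE], c(2, 1, 3)),
    vflip = a[dim(a)[1]:1, , , drop = FALSE],
    hflip = a[, dim(a)[2]:1, , drop = FALSE],
    transpose = aperm(a, c(2, 1, 3)),
    abort_if(TRUE, "unknown augmentation op '%s'", op)
  )
  if (is_mat) out <- out[, , 1]
  out
}

#' Apply one geometric augmentation to a patch
#'
#' @param patch a `Patch` (or bare pixel array).
#' @param op an op name from [augment_ops()].
#' @return the transformed patch; the class label is unchanged.
#' @export
augment_patch <- function(patch, op) {
  abort_if(!op %in% augment_ops(), "unknown augmentation op '%s'", op)
  if (inherits(patch, "Patch")) {
    patch$pixels <- apply_op_array(patch$pixels, op)
    patch
  } else {
    apply_op_array(patch, op)
  }
}

#' Augmentation recipe
#'
#' @param ops ordered subset of [augment_ops()].
#' @param include_original keep the untransformed patch (default `TRUE`).
#' @return an `AugmentationRecipe` with `multiplicity = |ops| +
#'   include_original`.
#' @export
augmentation_recipe <- function(ops, include_original = TRUE) {
  abort_if(!all(ops %in% augment_ops()), "unknown op in recipe")
  abort_if(anyDuplicated(ops) > 0, "recipe ops must be distinct")
  structure(list(ops = ops, include_original = include_original,
                 multiplicity = length(ops) + as.integer(include_original)),
            class = "AugmentationRecipe")
}

#' Expand a patch set with an augmentation recipe
#'
#' Materializes the augmented dataset: originals first (when included),
#' then each op applied to every base patch, in recipe order. The output
#' count is exactly `length(base) * multiplicity` — e.g. 4,000 base patches
#' with 3 ops plus the original give 16,000; 5,200 with 6 ops plus the
#' original give 36,400; 4,000 with 4 ops plus the original give 20,000.
#'
#' @param base_patches non-empty list of patches (or pixel arrays).
#' @param recipe an [augmentation_recipe()].
#' @return list of patches of length `base * multiplicity`; each element
#'   carries an `applied_op` attribute (`"original"` or the op name).
#' @export
expand_with_recipe <- function(base_patches, recipe) {
  abort_if(length(base_patches) == 0, "base patch set is empty")
  out <- list()
  if (recipe$include_original) {
    for (p in base_patches) {
      attr(p, "applied_op") <- "original"
      out[[length(out) + 1L]] <- p
    }
  }
  for (op in recipe$ops) {
    for (p in base_patches) {
      q <- augment_patch(p, op)
      attr(q, "applied_op") <- op
      out[[length(out) + 1L]] <- q
    }
  }
  out
}

#' Oversample a patch set to a target count
#'
#' Minority-class balancing. Policy: when the target exceeds the input
#' size, every patch is taken once (in seeded random order) and the
#' remainder is drawn with replacement; when the target is at most the
#' input size, a without-replacement sample is taken — so a target equal to
#' the input size returns a permutation of the input.
#'
#' @param patches non-empty list when `target_n > 0`.
#' @param target_n number of patches to return.
#' @param seed integer seed.
#' @return list of `target_n` patches.
#' @export
oversample_to <- function(patches, target_n, seed = 1L) {
  abort_if(target_n < 0, "target_n must be >= 0")
  if (target_n == 0) return(list())
  abort_if(length(patches) == 0, "cannot oversample an empty patch set")
  n <- length(patches)
  idx <- with_seed(seed, {
    if (target_n <= n) {
      sample.int(n, target_n)
    } else {
      c(sample.int(n), sample.int(n, target_n - n, replace = TRUE))
    }
  })
  patches[idx]
}

#' Named recipes used for class balancing
#'
#' Convenience constructors for the three balancing recipes: a 4-fold
#' recipe (rot90, vflip, transpose + original), a 7-fold recipe (all six
#' ops + original), and a 5-fold recipe (rot90, rot270, vflip, transpose +
#' original).
#'
#' @return an `AugmentationRecipe`.
#' @export
recipe_x4 <- function() augmentation_recipe(c("rot90", "vflip", "transpose"))

#' @rdname recipe_x4
#' @export
recipe_x7 <- function() augmentation_recipe(augment_ops())

#' @rdname recipe_x4
#' @export
recipe_x5 <- function() augmentation_recipe(c("rot90", "rot270", "vflip", "transpose"))
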