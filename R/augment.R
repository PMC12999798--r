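#' Training-time augmentation
#'
#' Three techniques, applied stochastically to training samples only:
#' same-class mix-up (convex combination of two subjects of one class with
#' a uniform weight), horizontal flip along the declared left-right axis
#' (the first voxel axis), and rotation by a small random angle about a
#' randomly chosen grid axis.  Each technique fires independently with
#' probability `apply_prob` (default 0.10), in the fixed order
#' mix-up, flip, rotation.
#'
#' @name augment
NULL

#' Augmentation configuration
#'
#' @param apply_prob per-technique firing probability per sample (default
#'   0.10).
#' @param max_rotation_deg rotation angle bound in degrees (default 10).
#' @return An `augment_config` list.
#' @export
augment_config <- function(apply_prob = 0.10, max_rotation_deg = 10) {
  if (apply_prob < 0 || apply_prob > 1) stopf("apply_prob must be in [0, 1]")
  if (max_rotation_deg < 0) stopf("max_rotation_deg must be >= 0")
  structure(list(apply_prob = apply_prob,
                 max_rotation_deg = max_rotation_deg),
            class = "augment_config")
}

#' Mix-up of two same-class volumes
#'
#' `alpha * x1 + (1 - alpha) * x2`, voxelwise.  The caller guarantees the
#' two subjects share a class label, so the label stays hard.
#'
#' @param x1,x2 volumes (or arrays) on the same grid.
#' @param alpha mixing weight in \[0, 1\].
#' @return A volume (or array, matching the input type).
#' @export
mixup <- function(x1, x2, alpha) {
  if (alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1]")
  check_same_grid(x1, x2)
  out <- alpha * vol_data(x1) + (1 - alpha) * vol_data(x2)
  if (is_volume(x1)) new_volume(out, x1$spacing, x1$space) else out
}

#' Horizontal flip
#'
#' Mirrors the volume along the first voxel axis (the declared left-right
#' axis).  An involution that preserves the voxel multiset.
#'
#' @param x volume or 3D array.
#' @return Flipped volume/array.
#' @export
horizontal_flip <- function(x) {
  a <- vol_data(x)
  out <- a[dim(a)[1]:1, , , drop = FALSE]
  if (is_volume(x)) new_volume(out, x$spacing, x$space) else out
}

# Rotate about grid axis `axis` (1..3) by `deg` degrees around the volume
# centre, trilinear interpolation, zero fill.  deg == 0 returns x unchanged.
rotate_volume <- function(x, axis, deg) {
  a <- vol_data(x)
  if (deg == 0) return(x)
  d <- dim(a)
  th <- deg * pi / 180
  ax <- setdiff(1:3, axis)  # the rotation plane
  ctr <- (d + 1) / 2
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  co <- list(g$i, g$j, g$k)
  u <- co[[ax[1]]] - ctr[ax[1]]
  v <- co[[ax[2]]] - ctr[ax[2]]
  # inverse rotation of the target coordinates gives the source sample point
  su <- cos(th) * u + sin(th) * v + ctr[ax[1]]
  sv <- -sin(th) * u + cos(th) * v + ctr[ax[2]]
  src <- co
  src[[ax[1]]] <- su
  src[[ax[2]]] <- sv
  out <- array(trilinear_sample(a, src[[1]], src[[2]], src[[3]], fill = 0),
               dim = d)
  if (is_volume(x)) new_volume(out, x$spacing, x$space) else out
}

#' Random small rotation
#'
#' Rotates by an angle drawn uniformly in `[-max_deg, +max_deg]` about one
#' uniformly chosen grid axis, with trilinear interpolation and zero fill
#' outside the original support.
#'
#' @param x volume or 3D array.
#' @param max_deg maximum absolute rotation angle in degrees.
#' @return Rotated volume/array.  `max_deg = 0` returns `x` unchanged.
#' @export
random_rotation <- function(x, max_deg = 10) {
  if (max_deg < 0) stopf("max_deg must be >= 0")
  if (max_deg == 0) return(x)
  axis <- sample.int(3, 1)
  deg <- stats::runif(1, -max_deg, max_deg)
  rotate_volume(x, axis, deg)
}

#' Apply the stochastic augmentation pipeline to one training sample
#'
#' Each technique fires independently with probability `cfg$apply_prob`, in
#' the order mix-up, flip, rotation.  The mix-up partner is drawn uniformly
#' from `same_class_pool` (volumes of the *same class* as `x`); an empty
#' pool skips mix-up with a warning.  Uses the session RNG: seed it for
#' reproducibility.
#'
#' @param x volume or array.
#' @param same_class_pool list of candidate mix-up partners (may include
#'   `x` itself).
#' @param cfg an [augment_config()].
#' @return Augmented volume/array, with an attribute `fired` (named logical
#'   triple) recording which techniques were applied.
#' @export
augment_sample <- function(x, same_class_pool, cfg = augment_config()) {
  fire <- stats::runif(3) < cfg$apply_prob
  if (fire[1]) {
    if (length(same_class_pool) == 0) {
      warnf("empty same-class pool: skipping mix-up")
    } else {
      partner <- same_class_pool[[sample.int(length(same_class_pool), 1)]]
      x <- mixup(x, partner, stats::runif(1))
    }
  }
  if (fire[2]) x <- horizontal_flip(x)
  if (fire[3]) x <- random_rotation(x, cfg$max_rotation_deg)
  attr(x, "fired") <- stats::setNames(fire, c("mixup", "flip", "rotation"))
  x
}
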