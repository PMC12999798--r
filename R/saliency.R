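#' Grad-CAM saliency
#'
#' Saliency for the binary models targets their last convolutional feature
#' map, the context-module output: channel weights are the spatially
#' averaged gradients of the target-class logit with respect to that map
#' (for a global-average-pooled linear head this gradient is exact in
#' closed form), the weighted channel sum is rectified, and the coarse map
#' is upsampled to the input grid by trilinear interpolation.  Class-level
#' maps average the subject-level maps of correctly classified subjects
#' and are min-max normalized to \[0, 1\]; regions whose normalized
#' saliency exceeds a threshold (default 0.7) are reported against the
#' atlas.  The multiclass model is excluded from saliency reporting.
#'
#' @name saliency
NULL

#' Grad-CAM map for one subject
#'
#' @param model a trained `binary_model`.
#' @param x input `volume` (of the model's image type).
#' @param target_class class name or index (into `model$spec$classes`).
#' @return A `volume` of nonnegative (unnormalized) relevance values on
#'   the input grid.
#' @export
grad_cam <- function(model, x, target_class) {
  if (!inherits(model, "binary_model"))
    stopf("grad_cam is defined for the binary models (the multiclass model is excluded)")
  classes <- model$spec$classes
  ci <- if (is.character(target_class)) match(target_class, classes)
        else as.integer(target_class)
  if (is.na(ci) || ci < 1L || ci > length(classes))
    stopf("target_class out of range")
  arr <- vol_data(x)
  fwd <- backbone_fwd(model$params, model$spec$arch, arr)
  n <- ncol(fwd$ctx)
  # d logit_ci / d ctx[k, j] = fc$W[ci, k] / n; spatial average = W[ci, k]/n
  alpha <- model$params$fc$W[ci, ] / n
  cam <- as.vector(alpha %*% fwd$ctx)
  cam <- pmax(cam, 0)
  up <- resample_to_grid(array(cam, dim = fwd$ctx_sp), dim(arr))
  new_volume(up, spacing = if (is_volume(x)) x$spacing else c(1, 1, 1),
             space = if (is_volume(x)) x$space else "phantom")
}

#' Class-averaged, normalized saliency maps
#'
#' For each of the model's two classes: collect the split's subjects of
#' that class, keep those the model classifies correctly, average their
#' Grad-CAM maps (targeting the true class), zero the map outside the
#' brain mask, and min-max normalize to \[0, 1\].  A class with no
#' correctly classified subject yields `NULL` (absent, not zero); a
#' constant map normalizes to all-zero with a warning.
#'
#' @param model a trained `binary_model`.
#' @param manifest preprocessed manifest.
#' @param split which split to use (default `"test"`).
#' @param brain_mask optional mask applied before normalization.
#' @return Named list (one element per model class) of saliency `volume`s
#'   with attribute `n_subjects`.
#' @export
class_mean_saliency <- function(model, manifest, split = "test",
                                brain_mask = NULL) {
  classes <- model$spec$classes
  img_col <- paste0(model$spec$image_type, "_path")
  out <- stats::setNames(vector("list", length(classes)), classes)
  for (cls in classes) {
    rows <- which(manifest$split == split & manifest$label == cls)
    acc <- NULL; nok <- 0L
    for (i in rows) {
      x <- read_volume(manifest[[img_col]][i], space = "phantom")
      p <- model_probs(model, x)
      if (names(p)[which.max(p)] != cls) next
      m <- vol_data(grad_cam(model, x, cls))
      acc <- if (is.null(acc)) m else acc + m
      nok <- nok + 1L
    }
    if (nok == 0L) {
      message(sprintf("no correctly classified %s subject in split %s; map absent",
                      cls, split))
      next
    }
    avg <- acc / nok
    if (!is.null(brain_mask)) avg[!mask_which(brain_mask)] <- 0
    rng <- range(avg)
    if (rng[2] - rng[1] < 1e-12) {
      warnf("constant saliency map for class %s; emitting all-zero", cls)
      avg[] <- 0
    } else {
      avg <- (avg - rng[1]) / (rng[2] - rng[1])
    }
    v <- new_volume(avg)
    attr(v, "n_subjects") <- nok
    out[[cls]] <- v
  }
  out
}

#' Extract suprathreshold atlas regions from a saliency map
#'
#' Lists every atlas region containing at least one voxel whose
#' (normalized) saliency exceeds `threshold`, with laterality relative to
#' the left-right axis midline (the first voxel axis; lower indices are
#' the left side, `bilateral` when both sides exceed the threshold),
#' sorted by peak saliency, descending.
#'
#' @param saliency a normalized saliency `volume` (values in \[0, 1\]).
#' @param atlas a `phantom_atlas` (or compatible labeled atlas).
#' @param threshold saliency threshold in (0, 1), default 0.7.
#' @return A data.frame with columns `region`, `laterality`,
#'   `peak_saliency`, `voxel_frac_above`.
#' @export
extract_rois <- function(saliency, atlas, threshold = 0.7) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  s <- vol_data(saliency)
  lab <- vol_data(atlas$labels)
  if (!identical(dim(s), dim(lab)))
    stopf("saliency and atlas grids differ")
  d1 <- dim(s)[1]
  xi <- slice.index(s, 1)
  rows <- list()
  for (r in seq_len(nrow(atlas$region_table))) {
    rid <- atlas$region_table$region_id[r]
    inr <- lab == rid
    if (!any(inr)) next
    hot <- inr & s > threshold
    if (!any(hot)) next
    left <- any(hot & xi <= d1 / 2)
    right <- any(hot & xi > d1 / 2)
    rows[[length(rows) + 1L]] <- data.frame(
      region = atlas$region_table$region[r],
      laterality = if (left && right) "bilateral" else if (left) "left" else "right",
      peak_saliency = max(s[inr]),
      voxel_frac_above = sum(hot) / sum(inr),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(region = character(), laterality = character(),
                      peak_saliency = numeric(), voxel_frac_above = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(-out$peak_saliency), , drop = FALSE]
}
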