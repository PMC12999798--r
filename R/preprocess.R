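#' SUVR and SRP preprocessing
#'
#' FDG-PET intensities are made comparable across subjects by dividing each
#' volume by its mean uptake over the cerebellar gray-matter reference
#' region (SUVR).  Subject residual profiles (SRP) then remove the
#' remaining global scale and the cohort-average spatial pattern:
#' log-SUVR values are doubly centered by subtracting each subject's
#' whole-brain mean log-SUVR and each voxel's across-subject mean
#' (the scaled-subprofile-model convention), restricted to a study-specific
#' gray-matter mask.  No smoothing is applied anywhere.
#'
#' @name preprocess
NULL

SUVR_FLOOR <- 1e-6

#' Compute a SUVR volume
#'
#' Divides the PET volume by its mean intensity over the reference mask and
#' zeroes everything outside the brain mask.  The result is dimensionless,
#' has mean exactly 1 over the reference region, and is invariant to global
#' rescaling of the input.
#'
#' @param pet PET `volume`.
#' @param reference_mask cerebellar gray-matter reference mask.
#' @param brain_mask brain mask on the same grid.
#' @return A SUVR `volume`.
#' @examples
#' pet <- new_volume(array(5, c(4, 4, 4)))
#' m <- new_mask(array(TRUE, c(4, 4, 4)))
#' range(vol_data(compute_suvr(pet, m, m)))
#' @export
compute_suvr <- function(pet, reference_mask, brain_mask) {
  check_same_grid(pet, reference_mask, brain_mask)
  ref <- mask_which(reference_mask)
  if (!any(ref)) stopf("reference mask is empty")
  x <- vol_data(pet)
  m <- mean(x[ref])
  if (!is.finite(m) || m <= 0)
    stopf("nonpositive mean PET intensity (%g) over the reference region", m)
  out <- x / m
  out[!mask_which(brain_mask)] <- 0
  new_volume(out, spacing = if (is_volume(pet)) pet$spacing else c(1, 1, 1),
             space = if (is_volume(pet)) pet$space else "phantom")
}

#' Build the study-specific group gray-matter mask
#'
#' Per subject, the striatal mask is merged into the gray-matter
#' probability map by a voxelwise maximum; the merged maps are averaged
#' across subjects, and voxels below `threshold_frac` of the maximum of the
#' averaged map are excluded (default 30%).
#'
#' @param gm_prob_maps list of gray-matter probability `volume`s.
#' @param striatal_masks list of striatal masks (same length and grid), or
#'   a single mask recycled across subjects.
#' @param threshold_frac fraction of the maximum averaged probability below
#'   which voxels are excluded; in (0, 1), default 0.30.
#' @return A mask `volume` with attributes `threshold_frac` and
#'   `n_subjects`.
#' @export
build_group_gm_mask <- function(gm_prob_maps, striatal_masks,
                                threshold_frac = 0.30) {
  if (length(gm_prob_maps) == 0) stopf("no gray-matter probability maps given")
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stopf("threshold_frac must be in (0, 1)")
  if (is_volume(striatal_masks)) striatal_masks <- list(striatal_masks)
  if (length(striatal_masks) == 1L)
    striatal_masks <- rep(striatal_masks, length(gm_prob_maps))
  if (length(striatal_masks) != length(gm_prob_maps))
    stopf("need one striatal mask per subject (or a single shared mask)")
  acc <- NULL
  for (i in seq_along(gm_prob_maps)) {
    check_same_grid(gm_prob_maps[[1]], gm_prob_maps[[i]], striatal_masks[[i]])
    merged <- pmax(vol_data(gm_prob_maps[[i]]),
                   as.numeric(mask_which(striatal_masks[[i]])))
    acc <- if (is.null(acc)) merged else acc + merged
  }
  avg <- acc / length(gm_prob_maps)
  thr <- threshold_frac * max(avg)
  keep <- array(avg >= thr, dim = dim(avg))
  if (!any(keep)) stopf("group GM mask is empty at threshold %g", threshold_frac)
  m <- new_mask(keep,
                spacing = if (is_volume(gm_prob_maps[[1]])) gm_prob_maps[[1]]$spacing else c(1, 1, 1),
                space = if (is_volume(gm_prob_maps[[1]])) gm_prob_maps[[1]]$space else "phantom")
  attr(m, "threshold_frac") <- threshold_frac
  attr(m, "n_subjects") <- length(gm_prob_maps)
  m
}

# subject-centered transformed field: v = f(suvr); v - mean(v over brain mask)
.centered_field <- function(suvr, brain_mask, center_scale) {
  x <- vol_data(suvr)
  bm <- mask_which(brain_mask)
  if (center_scale == "log") {
    nbad <- sum(x[bm] <= 0)
    if (nbad > 0)
      warnf("%d nonpositive SUVR voxel(s) inside the brain mask floored at %g before log",
            nbad, SUVR_FLOOR)
    x <- pmax(x, SUVR_FLOOR)
    v <- log(x)
  } else v <- x
  v - mean(v[bm])
}

#' Fit the training-cohort voxel-mean profile
#'
#' For every training subject the log-SUVR field is centered by its own
#' whole-brain mean; the profile is the per-voxel mean of these centered
#' fields across subjects, restricted to the group GM mask (zero outside).
#' The persisted profile is what centers validation and test subjects, so
#' no test-set statistic ever enters preprocessing.
#'
#' @param suvr_set list of SUVR `volume`s (>= 2 subjects).
#' @param gm_mask group gray-matter mask from [build_group_gm_mask()].
#' @param brain_mask brain mask (support of the subject-centering mean).
#' @param center_scale `"log"` (canonical) or `"linear"`: scale on which
#'   the double centering operates.
#' @return A `volume` holding the profile, with attribute `n_subjects`.
#' @export
fit_voxel_mean_profile <- function(suvr_set, gm_mask, brain_mask,
                                   center_scale = c("log", "linear")) {
  center_scale <- match.arg(center_scale)
  if (length(suvr_set) < 2) stopf("need >= 2 subjects to fit a voxel-mean profile")
  gm <- mask_which(gm_mask)
  if (!any(gm)) stopf("GM mask is empty")
  check_same_grid(suvr_set[[1]], gm_mask, brain_mask)
  acc <- 0
  for (s in suvr_set) {
    check_same_grid(suvr_set[[1]], s)
    acc <- acc + .centered_field(s, brain_mask, center_scale)
  }
  prof <- acc / length(suvr_set)
  prof[!gm] <- 0
  out <- new_volume(prof,
                    spacing = if (is_volume(gm_mask)) gm_mask$spacing else c(1, 1, 1),
                    space = if (is_volume(gm_mask)) gm_mask$space else "phantom")
  attr(out, "n_subjects") <- length(suvr_set)
  attr(out, "center_scale") <- center_scale
  out
}

#' Compute a subject-residual-profile (SRP) volume
#'
#' `srp = [log(suvr) - mean_brain(log suvr)] - profile` on the GM mask,
#' zero elsewhere.  With a profile fit on the subject's own cohort the
#' per-voxel mean of SRP over that cohort is zero; with the persisted
#' training profile, out-of-sample subjects are centered without touching
#' their cohort's statistics.
#'
#' @param suvr SUVR `volume`.
#' @param gm_mask group GM mask.
#' @param brain_mask brain mask.
#' @param profile voxel-mean profile from [fit_voxel_mean_profile()].
#' @param center_scale `"log"` (canonical) or `"linear"`; must match the
#'   profile's scale.
#' @return An SRP `volume` (signed, dimensionless, zero outside the mask).
#' @export
compute_srp <- function(suvr, gm_mask, brain_mask, profile,
                        center_scale = c("log", "linear")) {
  center_scale <- match.arg(center_scale)
  check_same_grid(suvr, gm_mask, brain_mask, profile)
  pscale <- attr(profile, "center_scale")
  if (!is.null(pscale) && !identical(pscale, center_scale))
    stopf("profile was fit on the %s scale but center_scale = %s",
          pscale, center_scale)
  gm <- mask_which(gm_mask)
  srp <- .centered_field(suvr, brain_mask, center_scale) - vol_data(profile)
  srp[!gm] <- 0
  new_volume(srp, spacing = if (is_volume(suvr)) suvr$spacing else c(1, 1, 1),
             space = if (is_volume(suvr)) suvr$space else "phantom")
}

#' Preprocess a whole cohort
#'
#' Runs the SUVR/SRP pipeline over a manifest: computes per-subject SUVR
#' against the atlas's cerebellar gray-matter reference, builds the group
#' GM mask and the voxel-mean profile from *training-split subjects only*,
#' applies them unchanged to validation and test subjects, and persists
#' everything (`suvr_*.nii.gz`, `srp_*.nii.gz`, `gm_mask.nii.gz`,
#' `voxel_mean_profile.nii.gz`, augmented `manifest.csv`) under `out_dir`.
#'
#' @param manifest cohort manifest data.frame with assigned splits.
#' @param atlas a `phantom_atlas` (or compatible list with `labels` +
#'   `region_table`) supplying the cerebellar reference and striatal
#'   regions.
#' @param out_dir output directory.
#' @param threshold_frac GM-mask threshold, default 0.30.
#' @param center_scale `"log"` (default) or `"linear"`.
#' @return The augmented manifest (with `suvr_path`, `srp_path`), invisibly
#'   also written to `out_dir/manifest.csv`.
#' @export
preprocess_cohort <- function(manifest, atlas, out_dir,
                              threshold_frac = 0.30,
                              center_scale = c("log", "linear")) {
  center_scale <- match.arg(center_scale)
  train_idx <- which(manifest$split == "train")
  if (length(train_idx) == 0) stopf("training split is empty")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ref_mask <- atlas_region_mask(atlas, "cerebellar_gm")
  striatal <- atlas_region_mask(atlas, STRIATAL_REGIONS)

  n <- nrow(manifest)
  suvr_paths <- character(n); srp_paths <- character(n)
  suvr_list <- vector("list", n)
  brain_list <- vector("list", n)
  for (i in seq_len(n)) {
    pet <- read_volume(manifest$pet_path[i], space = "phantom")
    brain <- read_volume(manifest$brain_mask_path[i], space = "phantom")
    check_same_grid(pet, atlas$labels)
    suvr_list[[i]] <- compute_suvr(pet, ref_mask, brain)
    brain_list[[i]] <- brain
  }
  gm_maps <- lapply(train_idx, function(i)
    read_volume(manifest$gm_prob_path[i], space = "phantom"))
  gm_mask <- build_group_gm_mask(gm_maps, striatal, threshold_frac)
  profile <- fit_voxel_mean_profile(suvr_list[train_idx], gm_mask,
                                    brain_list[[train_idx[1]]], center_scale)
  write_volume(gm_mask, file.path(out_dir, "gm_mask.nii.gz"), datatype = "uint8")
  write_volume(profile, file.path(out_dir, "voxel_mean_profile.nii.gz"))

  for (i in seq_len(n)) {
    sid <- manifest$subject_id[i]
    srp <- compute_srp(suvr_list[[i]], gm_mask, brain_list[[i]], profile,
                       center_scale)
    suvr_paths[i] <- sprintf("suvr_%s.nii.gz", sid)
    srp_paths[i] <- sprintf("srp_%s.nii.gz", sid)
    write_volume(suvr_list[[i]], file.path(out_dir, suvr_paths[i]))
    write_volume(srp, file.path(out_dir, srp_paths[i]))
  }
  out <- manifest
  out$suvr_path <- file.path(normalizePath(out_dir), suvr_paths)
  out$srp_path <- file.path(normalizePath(out_dir), srp_paths)
  save_manifest(out, file.path(out_dir, "manifest.csv"))
  out
}
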