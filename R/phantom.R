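#' Synthetic brain phantoms with class-specific metabolic signatures
#'
#' The phantom module stands in for a registered clinical FDG-PET cohort:
#' a labeled region atlas on a regular grid, and per-subject PET volumes in
#' which each region's tracer uptake is the gray/white-matter baseline
#' multiplied by a class-specific regional factor, scaled by a per-subject
#' global factor (emulating injected dose / scanner gain, which SUVR must
#' remove) and corrupted by additive unsmoothed Gaussian voxel noise.
#'
#' @name phantom
NULL

REGION_VOCAB <- c("cerebellar_gm", "occipital", "parietal", "lateral_temporal",
                  "motor_cortex", "pallidum", "putamen", "caudate",
                  "hippocampus", "amygdala", "frontal", "background_gm",
                  "white_matter")

GM_REGIONS <- setdiff(REGION_VOCAB, "white_matter")
STRIATAL_REGIONS <- c("putamen", "caudate")

# Baseline tracer uptake (arbitrary intensity units): cortex ~100, white
# matter ~60, outside brain 0 -- so cortical SUVR sits near 1 after
# cerebellar normalization.
BASELINE_GM <- 100
BASELINE_WM <- 60

# region centres as fractions of the grid; x is the left-right axis
.atlas_geometry <- function() {
  sub <- list( # subcortical balls inside the white-matter core (paired)
    pallidum    = list(x = c(0.40, 0.60), y = 0.56, z = 0.46),
    putamen     = list(x = c(0.30, 0.70), y = 0.58, z = 0.54),
    caudate     = list(x = c(0.42, 0.58), y = 0.70, z = 0.58),
    hippocampus = list(x = c(0.32, 0.68), y = 0.40, z = 0.38),
    amygdala    = list(x = c(0.32, 0.68), y = 0.56, z = 0.32))
  ctx <- list( # cortical Voronoi seeds: position (paired via two x), weight
    cerebellar_gm    = list(x = 0.50, y = 0.20, z = 0.25, w = 1.0),
    occipital        = list(x = 0.50, y = 0.15, z = 0.52, w = 0.9),
    parietal         = list(x = 0.50, y = 0.38, z = 0.82, w = 0.9),
    frontal          = list(x = 0.50, y = 0.82, z = 0.60, w = 1.1),
    motor_cortex     = list(x = c(0.32, 0.68), y = 0.55, z = 0.80, w = 0.6),
    lateral_temporal = list(x = c(0.12, 0.88), y = 0.48, z = 0.40, w = 0.7),
    background_gm    = list(x = c(0.30, 0.50, 0.70, 0.50), y = c(0.65, 0.50, 0.65, 0.35),
                            z = c(0.45, 0.95, 0.45, 0.60), w = 1.5))
  list(sub = sub, ctx = ctx)
}

#' Generate a labeled phantom atlas
#'
#' Builds a deterministic, seed-jittered region atlas on the requested grid:
#' an ellipsoidal brain mask, a white-matter core, subcortical nuclei as
#' paired balls inside the core, and cortical regions as weighted-Voronoi
#' cells of anatomically arranged seeds (cerebellar gray matter
#' posterior-inferior, occipital posterior, parietal superior, frontal
#' anterior, paired motor and lateral-temporal cortex, plus unlabeled
#' `background_gm` filler).  Every region in the vocabulary gets at least
#' 27 voxels or the call errors.
#'
#' @param grid_shape integer triple, each dimension at least 16.
#' @param seed integer seed controlling the (small) jitter of region seeds.
#' @param spacing voxel spacing in mm.
#' @return A `phantom_atlas`: list with `labels` (integer-labeled `volume`,
#'   0 = outside brain), `region_table` (data.frame `region_id`, `region`),
#'   and `brain_mask` (a mask `volume`).
#' @examples
#' atl <- make_atlas(c(32, 32, 32), seed = 1)
#' table(vol_data(atl$labels))[-1]
#' @export
make_atlas <- function(grid_shape, seed = 1L, spacing = c(2, 2, 2)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stopf("grid_shape must be a triple with every dimension >= 16")
  d <- grid_shape
  geo <- .atlas_geometry()
  jit <- with_seed(seed, stats::runif(256, -0.015, 0.015))
  ji <- 0L
  nxt <- function() { ji <<- ji + 1L; jit[ji] }

  ax <- (seq_len(d[1]) - 0.5) / d[1]
  ay <- (seq_len(d[2]) - 0.5) / d[2]
  az <- (seq_len(d[3]) - 0.5) / d[3]
  G <- expand.grid(x = ax, y = ay, z = az)
  ell <- function(cx, cy, cz, rx, ry, rz)
    ((G$x - cx) / rx)^2 + ((G$y - cy) / ry)^2 + ((G$z - cz) / rz)^2
  brain <- ell(0.5, 0.5, 0.5, 0.46, 0.48, 0.44) <= 1
  core <- ell(0.5, 0.54, 0.50, 0.30, 0.33, 0.28) <= 1

  labels <- integer(nrow(G))
  rid <- stats::setNames(seq_along(REGION_VOCAB), REGION_VOCAB)
  labels[brain & core] <- rid[["white_matter"]]

  # subcortical nuclei: nearest-ball assignment within the core
  rad <- max(2.2, 0.072 * min(d)) / min(d)  # fraction of the smallest axis
  sub_pts <- do.call(rbind, lapply(names(geo$sub), function(nm) {
    g <- geo$sub[[nm]]
    do.call(rbind, lapply(g$x, function(xx)
      data.frame(region = nm, x = xx + nxt(), y = g$y + nxt(), z = g$z + nxt())))
  }))
  in_core <- which(brain & core)
  dist2 <- sapply(seq_len(nrow(sub_pts)), function(s)
    ((G$x[in_core] - sub_pts$x[s]) * (d[1] / min(d)))^2 +
    ((G$y[in_core] - sub_pts$y[s]) * (d[2] / min(d)))^2 +
    ((G$z[in_core] - sub_pts$z[s]) * (d[3] / min(d)))^2)
  nearest <- max.col(-dist2, ties.method = "first")
  nd <- dist2[cbind(seq_along(nearest), nearest)]
  hit <- nd <= rad^2
  labels[in_core[hit]] <- rid[sub_pts$region[nearest[hit]]]

  # cortical shell: weighted Voronoi over the named cortical seeds
  ctx_pts <- do.call(rbind, lapply(names(geo$ctx), function(nm) {
    g <- geo$ctx[[nm]]
    n <- max(length(g$x), length(g$y), length(g$z))
    data.frame(region = nm,
               x = rep_len(g$x, n) + vapply(seq_len(n), function(i) nxt(), 0),
               y = rep_len(g$y, n) + vapply(seq_len(n), function(i) nxt(), 0),
               z = rep_len(g$z, n) + vapply(seq_len(n), function(i) nxt(), 0),
               w = g$w)
  }))
  shell <- which(brain & !core)
  sdist <- sapply(seq_len(nrow(ctx_pts)), function(s)
    (((G$x[shell] - ctx_pts$x[s]) * (d[1] / min(d)))^2 +
     ((G$y[shell] - ctx_pts$y[s]) * (d[2] / min(d)))^2 +
     ((G$z[shell] - ctx_pts$z[s]) * (d[3] / min(d)))^2) / ctx_pts$w[s]^2)
  labels[shell] <- rid[ctx_pts$region[max.col(-sdist, ties.method = "first")]]

  lab_arr <- array(labels, dim = d)
  counts <- tabulate(labels, nbins = length(REGION_VOCAB))
  if (any(counts < 27L))
    stopf("grid %s too small to host all regions (short: %s)",
          paste(d, collapse = "x"),
          paste(REGION_VOCAB[counts < 27L], collapse = ", "))
  structure(list(
    labels = new_volume(lab_arr, spacing = spacing, space = "phantom"),
    region_table = data.frame(region_id = unname(rid), region = REGION_VOCAB,
                              stringsAsFactors = FALSE),
    brain_mask = new_mask(lab_arr > 0, spacing = spacing, space = "phantom")
  ), class = "phantom_atlas")
}

#' Extract a region mask from an atlas
#'
#' @param atlas a `phantom_atlas` (or an integer-labeled `volume` plus a
#'   region table).
#' @param regions character vector of region names.
#' @return A mask `volume` covering the union of the named regions.
#' @export
atlas_region_mask <- function(atlas, regions) {
  unknown <- setdiff(regions, atlas$region_table$region)
  if (length(unknown) > 0)
    stopf("unknown region(s): %s", paste(unknown, collapse = ", "))
  ids <- atlas$region_table$region_id[atlas$region_table$region %in% regions]
  lab <- vol_data(atlas$labels)
  new_mask(array(lab %in% ids, dim = dim(lab)),
           spacing = atlas$labels$spacing, space = atlas$labels$space)
}

# deviations at full effect (effect = 1); shared dementia component plus
# disease-specific components, composed multiplicatively for Mixed
.SIG_COMMON <- c(motor_cortex = 1.20, pallidum = 1.20, cerebellar_gm = 1.10,
                 parietal = 0.80, lateral_temporal = 0.82)
.SIG_AD   <- c(hippocampus = 0.78)
.SIG_DLB  <- c(occipital = 0.72)

#' Class-specific regional metabolic signatures
#'
#' Returns the per-region multiplicative uptake factor (1 = healthy-control
#' baseline) for each of the four classes.  All dementia classes share
#' relative hypermetabolism in motor cortex, pallidum and cerebellum and
#' hypometabolism in parietal and lateral-temporal cortex; AD additionally
#' carries hippocampal hypometabolism, DLB the characteristic occipital
#' deficit, and Mixed is the multiplicative composition of the AD- and
#' DLB-specific deviations on top of the shared dementia pattern (so every
#' Mixed factor lies between, or equals, the AD and DLB extremes).  Factor
#' deviations from 1 scale linearly with `effect`.
#'
#' @param effect effect-strength multiplier in (0, 1]; 1 gives the full
#'   planted deviations.
#' @return Named list `AD`, `DLB`, `Mixed`, `HC`; each element is a named
#'   numeric vector over the full region vocabulary.
#' @examples
#' sig <- default_signatures(1)
#' sig$DLB["occipital"] < sig$AD["occipital"]
#' @export
default_signatures <- function(effect = 1) {
  if (!is.numeric(effect) || length(effect) != 1 || effect <= 0 || effect > 1)
    stopf("effect must be a single number in (0, 1]")
  base <- stats::setNames(rep(1, length(REGION_VOCAB)), REGION_VOCAB)
  full <- list(HC = base,
               AD = base, DLB = base, Mixed = base)
  full$AD[names(.SIG_COMMON)] <- .SIG_COMMON
  full$DLB[names(.SIG_COMMON)] <- .SIG_COMMON
  full$Mixed[names(.SIG_COMMON)] <- .SIG_COMMON
  full$AD[names(.SIG_AD)] <- full$AD[names(.SIG_AD)] * .SIG_AD
  full$DLB[names(.SIG_DLB)] <- full$DLB[names(.SIG_DLB)] * .SIG_DLB
  full$Mixed[names(.SIG_AD)] <- full$Mixed[names(.SIG_AD)] * .SIG_AD
  full$Mixed[names(.SIG_DLB)] <- full$Mixed[names(.SIG_DLB)] * .SIG_DLB
  lapply(full, function(f) 1 + effect * (f - 1))
}

#' Phantom simulation parameters
#'
#' @param grid_shape grid dimensions (each >= 16, and divisible by 16 if the
#'   volumes will feed the networks).
#' @param global_scale_range per-subject multiplicative global intensity
#'   factor is drawn uniformly from this interval (default `c(0.8, 1.2)`),
#'   emulating dose/scanner gain variation that SUVR normalization removes.
#' @param noise_sd additive Gaussian voxel noise SD in intensity units
#'   (default 5, i.e. 5% of the cortical baseline; no spatial smoothing).
#' @param effect planted effect strength in (0, 1], see
#'   [default_signatures()].
#' @param seed integer master seed for the cohort.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(grid_shape = c(32, 32, 32),
                           global_scale_range = c(0.8, 1.2),
                           noise_sd = 5, effect = 0.7, seed = 1L) {
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (any(global_scale_range <= 0) || diff(global_scale_range) < 0)
    stopf("global_scale_range must be a positive increasing interval")
  structure(list(grid_shape = as.integer(grid_shape),
                 global_scale_range = global_scale_range,
                 noise_sd = noise_sd, effect = effect,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# noise-free expected uptake field for a signature on an atlas
.baseline_field <- function(atlas, signature) {
  lab <- vol_data(atlas$labels)
  present <- sort(unique(lab[lab > 0]))
  missing <- setdiff(atlas$region_table$region[atlas$region_table$region_id %in% present],
                     names(signature))
  if (length(missing) > 0)
    stopf("signature missing region(s) present in atlas: %s",
          paste(missing, collapse = ", "))
  fac <- numeric(length(REGION_VOCAB) + 1L)  # index = label + 1
  base <- ifelse(REGION_VOCAB == "white_matter", BASELINE_WM, BASELINE_GM)
  fac[1L] <- 0
  fac[atlas$region_table$region_id + 1L] <-
    base * signature[atlas$region_table$region]
  array(fac[lab + 1L], dim = dim(lab))
}

#' Simulate one phantom subject
#'
#' Produces a PET volume `global_scale * baseline(region) * factor(region) +
#' N(0, noise_sd)` clipped at zero, a gray-matter probability map (near 1 in
#' gray-matter regions with small jitter, near 0 in white matter and outside
#' the brain), and the brain mask.  Fully deterministic given
#' `subject_seed`.
#'
#' @param label class label, one of `AD`, `DLB`, `Mixed`, `HC`.
#' @param atlas a [make_atlas()] result on the same grid as `params`.
#' @param signature named factor vector for this subject's class (one
#'   element of [default_signatures()]).
#' @param params a [phantom_params()] object.
#' @param subject_seed integer seed for this subject's random draws.
#' @return List with `pet`, `gm_prob` (volumes) and `brain_mask` (mask).
#' @export
simulate_subject <- function(label, atlas, signature, params, subject_seed) {
  lab <- vol_data(atlas$labels)
  if (!identical(dim(lab), as.integer(params$grid_shape)))
    stopf("atlas grid does not match params grid")
  field <- .baseline_field(atlas, signature)
  with_seed(subject_seed, {
    gs <- stats::runif(1, params$global_scale_range[1], params$global_scale_range[2])
    pet <- gs * field
    if (params$noise_sd > 0)
      pet <- pet + stats::rnorm(length(pet), sd = params$noise_sd)
    pet[pet < 0] <- 0
    gm <- array(0, dim = dim(lab))
    is_gm <- lab > 0 & lab != which(REGION_VOCAB == "white_matter")
    gm[is_gm] <- stats::runif(sum(is_gm), 0.9, 1.0)
    gm[lab == which(REGION_VOCAB == "white_matter")] <-
      stats::runif(sum(lab == which(REGION_VOCAB == "white_matter")), 0, 0.05)
    sp <- atlas$labels$spacing
    list(pet = new_volume(array(pet, dim(lab)), sp, "phantom"),
         gm_prob = new_volume(gm, sp, "phantom"),
         brain_mask = atlas$brain_mask)
  })
}

# Largest-remainder apportionment of n into shares p (sums to n).
largest_remainder <- function(n, p) {
  q <- n * p
  fl <- floor(q)
  rem <- n - sum(fl)
  if (rem > 0) {
    extra <- order(q - fl, seq_along(p), decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

#' Simulate and write a full phantom cohort
#'
#' Generates `n_per_class` subjects per class, writes their NIfTI volumes,
#' the atlas and a cohort manifest under `out_dir`, and assigns per-class
#' train/val/test splits 70/10/20 by largest remainder.  The whole cohort
#' is a pure function of `params$seed` and `n_per_class`.
#'
#' @param n_per_class named integer vector, e.g.
#'   `c(AD = 40, DLB = 40, Mixed = 40, HC = 20)`.
#' @param params a [phantom_params()] object.
#' @param out_dir output directory (created; errors if it already contains
#'   a manifest unless `overwrite = TRUE`).
#' @param overwrite allow writing into a populated directory.
#' @return List with `manifest` (data.frame, also written as
#'   `manifest.csv`) and `atlas`.
#' @export
simulate_cohort <- function(n_per_class, params, out_dir, overwrite = FALSE) {
  n_per_class <- n_per_class[order(match(names(n_per_class), CLASS_LABELS))]
  if (is.null(names(n_per_class)) || !all(names(n_per_class) %in% CLASS_LABELS))
    stopf("n_per_class must be named with the four class labels")
  if (any(n_per_class < 0)) stopf("counts must be >= 0")
  mpath <- file.path(out_dir, "manifest.csv")
  if (file.exists(mpath) && !overwrite)
    stopf("%s already exists; use overwrite = TRUE", mpath)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  atlas <- make_atlas(params$grid_shape, seed = derive_seed(params$seed, 0L))
  sigs <- default_signatures(params$effect)
  write_volume(atlas$labels, file.path(out_dir, "atlas_labels.nii.gz"),
               datatype = "int16")
  write_volume(atlas$brain_mask, file.path(out_dir, "brain_mask.nii.gz"),
               datatype = "uint8")
  utils::write.csv(atlas$region_table, file.path(out_dir, "atlas_regions.csv"),
                   row.names = FALSE)

  rows <- list()
  k <- 0L
  for (cls in names(n_per_class)) {
    n <- n_per_class[[cls]]
    if (n == 0) next
    counts <- largest_remainder(n, c(train = 0.7, val = 0.1, test = 0.2))
    splits <- rep(c("train", "val", "test"), counts)
    ord <- with_seed(derive_seed(params$seed, 1000L + match(cls, CLASS_LABELS)),
                     sample.int(n))
    splits <- splits[order(ord)]  # deterministic shuffle of split labels
    for (i in seq_len(n)) {
      k <- k + 1L
      sid <- sprintf("%s_%03d", cls, i)
      subj <- simulate_subject(cls, atlas, sigs[[cls]], params,
                               derive_seed(params$seed, 10000L + k))
      pp <- sprintf("%s_pet.nii.gz", sid)
      gp <- sprintf("%s_gm.nii.gz", sid)
      write_volume(subj$pet, file.path(out_dir, pp))
      write_volume(subj$gm_prob, file.path(out_dir, gp))
      rows[[k]] <- data.frame(subject_id = sid, label = cls, pet_path = pp,
                              gm_prob_path = gp,
                              brain_mask_path = "brain_mask.nii.gz",
                              split = splits[i], stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  save_manifest(manifest, mpath)
  list(manifest = load_manifest(mpath), atlas = atlas)
}
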