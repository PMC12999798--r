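test_that("SUVR normalizes to the reference mean and masks the background", {
  d <- c(4, 4, 4)
  all_m <- new_mask(array(TRUE, d))
  pet <- new_volume(array(5, d))
  s <- compute_suvr(pet, all_m, all_m)
  expect_equal(unique(as.vector(vol_data(s))), 1)
  # brain-masked voxels become 0
  half <- array(FALSE, d); half[1:2, , ] <- TRUE
  s2 <- compute_suvr(pet, all_m, new_mask(half))
  expect_equal(unique(vol_data(s2)[!half]), 0)
  # scale invariance
  s3 <- compute_suvr(new_volume(array(10, d)), all_m, all_m)
  expect_equal(vol_data(s3), vol_data(s))
  # 3x3x3 toy: reference voxels {2, 4}, target 6 -> 6 / 3 = 2
  a <- array(1, c(3, 3, 3)); a[1, 1, 1] <- 2; a[2, 1, 1] <- 4; a[3, 3, 3] <- 6
  ref <- array(FALSE, c(3, 3, 3)); ref[1:2, 1, 1] <- TRUE
  s4 <- compute_suvr(new_volume(a), new_mask(ref), new_mask(array(TRUE, c(3, 3, 3))))
  expect_equal(vol_data(s4)[3, 3, 3], 2.0)
  expect_equal(mean(vol_data(s4)[ref]), 1)  # reference mean identity
  expect_error(compute_suvr(pet, new_mask(array(FALSE, d)), all_m), "empty")
  expect_error(compute_suvr(new_volume(array(0, d)), all_m, all_m), "onpositive")
})

test_that("group GM mask thresholds at a fraction of the averaged maximum", {
  d <- c(4, 4, 4)
  ones <- new_volume(array(1, d))
  nostr <- new_mask(array(FALSE, d))
  m <- build_group_gm_mask(list(ones), nostr, 0.30)
  expect_true(all(mask_which(m)))
  # a voxel at 0.29 of the max is excluded at threshold 0.30
  a <- array(1, d); a[2, 2, 2] <- 0.29; a[3, 3, 3] <- 0.31
  m2 <- build_group_gm_mask(list(new_volume(a)), nostr, 0.30)
  expect_false(mask_which(m2)[2, 2, 2])
  expect_true(mask_which(m2)[3, 3, 3])
  # striatal voxels are forced to 1 before averaging
  g1 <- array(0, d); g2 <- array(0, d)
  g1[1, 1, 1] <- 1  # only subject 1 has GM here
  str_mask <- array(FALSE, d); str_mask[4, 4, 4] <- TRUE
  m3 <- build_group_gm_mask(list(new_volume(g1), new_volume(g2)),
                            new_mask(str_mask), 0.30)
  # striatal voxel averaged to 1.0 (max), GM-only voxel averaged to 0.5
  expect_true(mask_which(m3)[4, 4, 4])
  expect_true(mask_which(m3)[1, 1, 1])   # 0.5 >= 0.3 * 1.0
  m4 <- build_group_gm_mask(list(new_volume(g1), new_volume(g2)),
                            new_mask(str_mask), 0.60)
  expect_false(mask_which(m4)[1, 1, 1])  # 0.5 < 0.6
  expect_error(build_group_gm_mask(list(), nostr), "no gray-matter")
})

test_that("raising the GM threshold never adds voxels", {
  set.seed(1)
  maps <- lapply(1:3, function(i) new_volume(array(runif(64), c(4, 4, 4))))
  nostr <- new_mask(array(FALSE, c(4, 4, 4)))
  sizes <- sapply(c(0.2, 0.4, 0.6, 0.8), function(th)
    sum(mask_which(build_group_gm_mask(maps, nostr, th))))
  expect_true(all(diff(sizes) <= 0))
  for (th in c(0.3, 0.6)) {
    lo <- mask_which(build_group_gm_mask(maps, nostr, th))
    hi <- mask_which(build_group_gm_mask(maps, nostr, th + 0.2))
    expect_true(all(lo[hi]))  # higher-threshold mask is a subset
  }
})

test_that("voxel-mean profile matches hand-computed subject-centered means", {
  # 3 subjects on a 2-voxel grid (all voxels in both masks)
  V <- rbind(c(exp(1), exp(3)),
             c(exp(2), exp(2)),
             c(exp(4), exp(1)))
  vols <- lapply(1:3, function(i) toy_vol(V[i, ]))
  m <- toy_mask(c(TRUE, TRUE))
  prof <- fit_voxel_mean_profile(vols, m, m)
  # by hand: log rows (1,3),(2,2),(4,1); row means 2,2,2.5
  # centered rows (-1,1),(0,0),(1.5,-1.5); column means (1/6, -1/6)
  expect_equal(as.vector(vol_data(prof)), c(1 / 6, -1 / 6))
  # identical subjects: profile equals either centered field
  vols2 <- lapply(1:2, function(i) toy_vol(c(exp(1), exp(3))))
  expect_equal(as.vector(vol_data(fit_voxel_mean_profile(vols2, m, m))), c(-1, 1))
  # global rescalings share one centered field
  vols3 <- list(toy_vol(c(1, exp(2))), toy_vol(2 * c(1, exp(2))))
  expect_equal(as.vector(vol_data(fit_voxel_mean_profile(vols3, m, m))), c(-1, 1))
  expect_error(fit_voxel_mean_profile(vols2[1], m, m), ">= 2 subjects")
})

test_that("SRP matches hand arithmetic and self-centers to zero", {
  m <- toy_mask(c(TRUE, TRUE))
  zero_prof <- toy_vol(c(0, 0))
  # suvr {e, e^3}: logs (1,3), subject mean 2 -> SRP (-1, +1)
  s <- compute_srp(toy_vol(c(exp(1), exp(3))), m, m, zero_prof)
  expect_equal(as.vector(vol_data(s)), c(-1, 1))
  # a subject from the profile's own cohort of identical subjects -> 0
  vols <- lapply(1:3, function(i) toy_vol(c(exp(1), exp(3))))
  prof <- fit_voxel_mean_profile(vols, m, m)
  expect_equal(as.vector(vol_data(compute_srp(vols[[1]], m, m, prof))), c(0, 0))
  # global rescaling removed by subject centering
  expect_equal(as.vector(vol_data(compute_srp(
    toy_vol(2 * c(exp(1), exp(3))), m, m, prof))), c(0, 0))
})

test_that("SRP equals the independent log/row-center/column-center oracle", {
  # 4 subjects x 10 voxels, GM mask a strict subset of the brain
  set.seed(42)
  V <- matrix(exp(rnorm(40, sd = 0.4)), 4, 10)
  gm <- c(rep(TRUE, 7), rep(FALSE, 3))
  vols <- lapply(1:4, function(i) toy_vol(V[i, ]))
  brain <- toy_mask(rep(TRUE, 10))
  gm_mask <- toy_mask(gm)
  prof <- fit_voxel_mean_profile(vols, gm_mask, brain)
  S <- t(sapply(1:4, function(i)
    as.vector(vol_data(compute_srp(vols[[i]], gm_mask, brain, prof)))))
  expect_equal(S, oracle_srp_matrix(V, gm), tolerance = 1e-10)
  # training-cohort per-voxel SRP mean is 0 on the mask
  expect_lt(max(abs(colMeans(S)[gm])), 1e-12)
  expect_true(all(S[, !gm] == 0))
})

test_that("SUVR and SRP are invariant to global PET rescaling", {
  fx <- tiny_cohort()
  atl <- fx$atlas
  ref <- atlas_region_mask(atl, "cerebellar_gm")
  pet <- read_volume(fx$manifest$pet_path[1], space = "phantom")
  brain <- read_volume(fx$manifest$brain_mask_path[1], space = "phantom")
  s1 <- compute_suvr(pet, ref, brain)
  s2 <- compute_suvr(new_volume(3.7 * vol_data(pet), pet$spacing), ref, brain)
  expect_equal(vol_data(s1), vol_data(s2), tolerance = 1e-12)
  expect_equal(mean(vol_data(s1)[mask_which(ref)]), 1, tolerance = 1e-6)
})

test_that("cohort preprocessing uses training statistics only", {
  fx <- tiny_cohort()
  pp <- fx$manifest
  ppdir <- dirname(pp$suvr_path[1])
  gm <- mask_which(read_volume(file.path(ppdir, "gm_mask.nii.gz")))
  # stored profile equals a train-only refit, not an all-subject refit
  atl <- fx$atlas
  ref <- atlas_region_mask(atl, "cerebellar_gm")
  suvr_of <- function(i) {
    pet <- read_volume(pp$pet_path[i], space = "phantom")
    brain <- read_volume(pp$brain_mask_path[i], space = "phantom")
    compute_suvr(pet, ref, brain)
  }
  tr <- which(pp$split == "train")
  brain1 <- read_volume(pp$brain_mask_path[tr[1]], space = "phantom")
  gm_vol <- read_volume(file.path(ppdir, "gm_mask.nii.gz"), space = "phantom")
  prof_train <- fit_voxel_mean_profile(lapply(tr, suvr_of), gm_vol, brain1)
  prof_all <- fit_voxel_mean_profile(lapply(seq_len(nrow(pp)), suvr_of),
                                     gm_vol, brain1)
  stored <- read_volume(file.path(ppdir, "voxel_mean_profile.nii.gz"))
  expect_equal(vol_data(stored), vol_data(prof_train), tolerance = 1e-6)
  expect_gt(max(abs(vol_data(prof_all) - vol_data(stored))), 1e-4)
  # training-split per-voxel SRP mean is ~0 on the GM mask
  acc <- 0
  for (i in tr) acc <- acc + vol_data(read_volume(pp$srp_path[i]))
  expect_lt(max(abs((acc / length(tr))[gm])), 1e-5)
})
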