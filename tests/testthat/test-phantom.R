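test_that("atlas is deterministic, complete and well-formed", {
  a1 <- make_atlas(c(32, 32, 32), seed = 1)
  a2 <- make_atlas(c(32, 32, 32), seed = 1)
  expect_identical(vol_data(a1$labels), vol_data(a2$labels))
  counts <- table(factor(vol_data(a1$labels), levels = a1$region_table$region_id))
  expect_length(counts, 13L)
  expect_true(all(counts >= 27L))  # every region can host a 3^3 neighbourhood
  # all non-background labels inside the brain mask
  expect_true(all(vol_data(a1$labels)[!mask_which(a1$brain_mask)] == 0))
  expect_error(make_atlas(c(8, 8, 8)), ">= 16")
})

test_that("paired structures have left and right instances", {
  a <- make_atlas(c(32, 32, 32), seed = 2)
  lab <- vol_data(a$labels)
  xi <- slice.index(lab, 1)
  for (region in c("hippocampus", "putamen", "motor_cortex")) {
    rid <- a$region_table$region_id[a$region_table$region == region]
    expect_true(any(lab == rid & xi <= 16), label = paste(region, "left"))
    expect_true(any(lab == rid & xi > 16), label = paste(region, "right"))
  }
})

test_that("class signatures encode the planted disease patterns", {
  sig <- default_signatures(1)
  expect_true(all(sig$HC == 1))
  for (cls in c("AD", "DLB", "Mixed")) {
    expect_true(all(sig[[cls]][c("motor_cortex", "pallidum", "cerebellar_gm")] > 1))
    expect_true(all(sig[[cls]][c("parietal", "lateral_temporal")] < 1))
  }
  expect_lt(sig$DLB[["occipital"]], sig$AD[["occipital"]])
  expect_lt(sig$AD[["hippocampus"]], 1)
  expect_lt(sig$Mixed[["occipital"]], 1)
  expect_lt(sig$Mixed[["hippocampus"]], 1)
  expect_equal(sig$AD[["occipital"]], 1)
  expect_equal(sig$DLB[["hippocampus"]], 1)
  # Mixed between or equal to the AD / DLB extremes, per region
  for (r in names(sig$AD)) {
    lo <- min(sig$AD[[r]], sig$DLB[[r]]); hi <- max(sig$AD[[r]], sig$DLB[[r]])
    expect_gte(sig$Mixed[[r]], lo - 1e-12)
    expect_lte(sig$Mixed[[r]], hi + 1e-12)
  }
  expect_error(default_signatures(0), "in \\(0, 1\\]")
  expect_error(default_signatures(1.5), "in \\(0, 1\\]")
})

test_that("signature deviations scale linearly and monotonically with effect", {
  effects <- c(0.2, 0.5, 0.8, 1.0)
  devs <- sapply(effects, function(e) {
    s <- default_signatures(e)
    abs(s$DLB[["occipital"]] - 1)
  })
  expect_true(all(diff(devs) > 0))
  s5 <- default_signatures(0.5); s1 <- default_signatures(1)
  expect_equal(s5$AD - 1, 0.5 * (s1$AD - 1))
  # effect -> 0 limit: all classes approach HC
  s0 <- default_signatures(1e-9)
  expect_equal(unname(s0$Mixed), rep(1, 13), tolerance = 1e-6)
})

test_that("noise-free HC subject at unit scale reproduces the baseline field", {
  atl <- make_atlas(c(32, 32, 32), seed = 3)
  par <- phantom_params(global_scale_range = c(1, 1), noise_sd = 0, seed = 1)
  sub <- simulate_subject("HC", atl, default_signatures(1)$HC, par, 7)
  lab <- vol_data(atl$labels)
  pet <- vol_data(sub$pet)
  expect_equal(unique(pet[lab == 0]), 0)
  wm <- a_id <- atl$region_table$region_id[atl$region_table$region == "white_matter"]
  expect_equal(unique(pet[lab == wm]), 60)
  expect_equal(unique(pet[lab > 0 & lab != wm]), 100)
  # gm_prob near 1 in GM, near 0 in WM
  gm <- vol_data(sub$gm_prob)
  expect_true(all(gm[lab > 0 & lab != wm] >= 0.9))
  expect_true(all(gm[lab == wm] <= 0.05))
})

test_that("subjects are deterministic given the seed and differ across seeds", {
  atl <- make_atlas(c(32, 32, 32), seed = 3)
  par <- phantom_params(seed = 1)
  s1 <- simulate_subject("AD", atl, default_signatures(0.7)$AD, par, 42)
  s2 <- simulate_subject("AD", atl, default_signatures(0.7)$AD, par, 42)
  s3 <- simulate_subject("AD", atl, default_signatures(0.7)$AD, par, 43)
  expect_identical(vol_data(s1$pet), vol_data(s2$pet))
  expect_false(identical(vol_data(s1$pet), vol_data(s3$pet)))
})

test_that("AD hypometabolism shows up against a matched HC subject", {
  atl <- make_atlas(c(32, 32, 32), seed = 3)
  par <- phantom_params(global_scale_range = c(1, 1), noise_sd = 0, seed = 1)
  sig <- default_signatures(1)
  ad <- simulate_subject("AD", atl, sig$AD, par, 9)
  hc <- simulate_subject("HC", atl, sig$HC, par, 9)
  parietal <- mask_which(atlas_region_mask(atl, "parietal"))
  expect_lt(mean(vol_data(ad$pet)[parietal]), mean(vol_data(hc$pet)[parietal]))
  motor <- mask_which(atlas_region_mask(atl, "motor_cortex"))
  expect_gt(mean(vol_data(ad$pet)[motor]), mean(vol_data(hc$pet)[motor]))
})

test_that("simulated cohorts split 70/10/20 per class and conserve counts", {
  fx <- tiny_cohort()
  m <- fx$raw_manifest
  expect_equal(nrow(m), 24L)
  # per-class 6 -> 4/1/1 by largest remainder (4.2 / 0.6 / 1.2)
  tab <- table(m$label, m$split)
  for (cls in c("AD", "DLB", "Mixed", "HC")) {
    expect_equal(unname(tab[cls, "train"]), 4L)
    expect_equal(unname(tab[cls, "val"]), 1L)
    expect_equal(unname(tab[cls, "test"]), 1L)
  }
  # 10 per class gives exactly 7/1/2
  expect_equal(fdgensemble:::largest_remainder(10, c(0.7, 0.1, 0.2)),
               c(7L, 1L, 2L))
})

test_that("cohort generation is a pure function of seed and counts", {
  p1 <- file.path(tempdir(), "coh_det1"); p2 <- file.path(tempdir(), "coh_det2")
  par <- phantom_params(seed = 77)
  c1 <- simulate_cohort(c(AD = 3, DLB = 0, Mixed = 3, HC = 3), par, p1,
                        overwrite = TRUE)
  c2 <- simulate_cohort(c(AD = 3, DLB = 0, Mixed = 3, HC = 3), par, p2,
                        overwrite = TRUE)
  expect_equal(nrow(c1$manifest), 9L)
  expect_false(any(c1$manifest$label == "DLB"))
  expect_identical(c1$manifest$split, c2$manifest$split)
  v1 <- vol_data(read_volume(c1$manifest$pet_path[1]))
  v2 <- vol_data(read_volume(c2$manifest$pet_path[1]))
  expect_identical(v1, v2)
})
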