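test_that("cohort splitting is a stratified 70/10/20 partition", {
  man <- data.frame(subject_id = sprintf("s%02d", 1:40),
                    label = rep(c("AD", "DLB", "Mixed", "HC"), each = 10),
                    pet_path = "", gm_prob_path = "", brain_mask_path = "",
                    split = "")
  sp <- split_cohort(man, seed = 3)
  tab <- table(sp$label, sp$split)
  for (cls in c("AD", "DLB", "Mixed", "HC")) {
    expect_equal(unname(tab[cls, "train"]), 7L)
    expect_equal(unname(tab[cls, "val"]), 1L)
    expect_equal(unname(tab[cls, "test"]), 2L)
  }
  expect_true(all(sp$split %in% c("train", "val", "test")))  # exhaustive
  expect_identical(split_cohort(man, seed = 3)$split, sp$split)
  expect_false(identical(split_cohort(man, seed = 4)$split, sp$split))
  tiny <- man[c(1:2, 11:20, 21:30, 31:40), ]
  expect_error(split_cohort(tiny), "need >= 3")
})

test_that("fold assignment is stratified, balanced and excludes the test set", {
  man <- data.frame(subject_id = sprintf("s%02d", 1:44),
                    label = rep(c("AD", "DLB", "Mixed", "HC"), each = 11),
                    split = "")
  man$split[c(1, 2, 12, 23, 34)] <- "test"
  f <- fdgensemble:::assign_folds(man, n_folds = 5, seed = 1)
  expect_true(all(is.na(f[man$split == "test"])))
  pool <- man$split != "test"
  expect_false(anyNA(f[pool]))
  for (cls in unique(man$label)) {
    sizes <- table(f[pool & man$label == cls])
    expect_lte(diff(range(sizes)), 1)
  }
})

test_that("training with zero learning rate is a null update", {
  fx <- tiny_cohort()
  cfg <- train_config(epochs = 1, lr = 0, seed = 5,
                      augment = augment_config(0))
  m <- train_binary(c("AD", "HC"), "suvr", fx$manifest, cfg)
  init <- build_backbone(c("AD", "HC"), "suvr",
                         net_arch(grid = c(32, 32, 32)),
                         seed = fdgensemble:::derive_seed(5L, 7L))
  expect_equal(m$params, init$params)
  expect_equal(nrow(m$extras$history), 1L)
})

test_that("binary training demands both classes and a validation split", {
  fx <- tiny_cohort()
  man <- fx$manifest
  man$split[man$label == "HC"] <- "test"  # no HC left in train
  expect_error(train_binary(c("AD", "HC"), "suvr", man, train_config(1)),
               "both classes")
  man2 <- fx$manifest
  man2$split[man2$split == "val"] <- "train"
  expect_error(train_binary(c("AD", "HC"), "suvr", man2, train_config(1)),
               "validation split is empty")
})

test_that("frozen multiclass training leaves donor backbones untouched", {
  fx <- tiny_cohort()
  cfg <- train_config(epochs = 2, seed = 8, augment = augment_config(0))
  arch <- net_arch(grid = c(32, 32, 32))
  backbones <- lapply(fdgensemble:::MULTICLASS_ORDER, function(nm) {
    parts <- strsplit(nm, "_")[[1]]
    build_backbone(strsplit(parts[1], ".", fixed = TRUE)[[1]], parts[2],
                   arch, seed = 60)
  })
  ext <- lapply(seq_along(backbones), function(i)
    build_feature_extractor(backbones[[i]], seed = 70 + i))
  mc <- train_multiclass(ext, fx$manifest, cfg)
  for (i in 1:6) {
    expect_identical(mc$params$ext[[i]]$stages, backbones[[i]]$params$stages)
    expect_identical(mc$params$ext[[i]]$context, backbones[[i]]$params$context)
    # the added convolution did train
    expect_false(identical(mc$params$ext[[i]]$added, ext[[i]]$params$added))
  }
  suvr <- read_volume(fx$manifest$suvr_path[1], space = "phantom")
  srp <- read_volume(fx$manifest$srp_path[1], space = "phantom")
  expect_length(multiclass_logits(mc, suvr, srp), 3L)
})

test_that("cross-validation rotates folds without touching the test set", {
  fx <- tiny_cohort()
  cfg <- train_config(epochs = 1, seed = 2, patience = 1,
                      augment = augment_config(0))
  cv <- cross_validate(fx$raw_manifest, fx$atlas,
                       file.path(tempdir(), "cv_work"), cfg, n_folds = 5)
  expect_length(cv$folds, 5L)
  pool_ids <- fx$raw_manifest$subject_id[fx$raw_manifest$split != "test"]
  test_ids <- fx$raw_manifest$subject_id[fx$raw_manifest$split == "test"]
  val_seen <- character()
  for (fd in cv$folds) {
    mf <- fd$manifest
    # the fixed test split is preserved verbatim
    expect_setequal(mf$subject_id[mf$split == "test"], test_ids)
    # no test subject ever enters train or val
    expect_length(intersect(test_ids, mf$subject_id[mf$split != "test"]), 0)
    val_seen <- c(val_seen, mf$subject_id[mf$split == "val"])
    # one metric set (ROC per class) per fold
    expect_equal(nrow(fd$metrics$class_metrics), 4L)
  }
  # every pool subject appears in exactly one validation fold
  expect_setequal(val_seen, pool_ids)
  expect_equal(anyDuplicated(val_seen), 0L)
  expect_equal(nrow(cv$summary), 4L)
  expect_true(all(c("mean_auroc", "ci_lo", "ci_hi") %in% names(cv$summary)))
})
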