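#' Training configuration
#'
#' All models train with softmax cross-entropy under Adam, selecting the
#' epoch checkpoint with the lowest validation loss and stopping early
#' when validation loss has not improved for `patience` epochs.
#'
#' @param epochs maximum number of epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param seed master seed (splits, init, shuffling, augmentation).
#' @param patience early-stopping patience on validation loss.
#' @param freeze_extractors if `TRUE` (default) multiclass training updates
#'   only the added convolutions and the head; the donor backbones stay
#'   frozen.
#' @param augment an [augment_config()]; set `apply_prob = 0` to disable.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 30L, batch_size = 8L, lr = 1e-3, seed = 1L,
                         patience = 8L, freeze_extractors = TRUE,
                         augment = augment_config()) {
  if (epochs < 1L) stopf("epochs must be >= 1")
  if (batch_size < 1L) stopf("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed), patience = as.integer(patience),
                 freeze_extractors = isTRUE(freeze_extractors),
                 augment = augment),
            class = "train_config")
}

#' Assign train/val/test splits to a cohort
#'
#' Per class, 70/10/20 train/val/test by largest-remainder apportionment
#' of the class size, deterministic under `seed`.
#'
#' @param manifest cohort manifest data.frame.
#' @param seed integer seed.
#' @param fractions split fractions, default `c(train = .7, val = .1,
#'   test = .2)`.
#' @return The manifest with its `split` column assigned.
#' @export
split_cohort <- function(manifest, seed = 1L,
                         fractions = c(train = 0.7, val = 0.1, test = 0.2)) {
  manifest$split <- ""
  for (cls in unique(manifest$label)) {
    idx <- which(manifest$label == cls)
    if (length(idx) < 3L)
      stopf("class %s has %d subject(s); need >= 3 to split", cls, length(idx))
    counts <- largest_remainder(length(idx), fractions)
    splits <- rep(names(fractions), counts)
    ord <- with_seed(derive_seed(seed, match(cls, CLASS_LABELS)),
                     sample.int(length(idx)))
    manifest$split[idx[ord]] <- splits
  }
  manifest
}

# stratified fold indices (0-based) over the non-test pool
assign_folds <- function(manifest, n_folds = 5L, seed = 1L) {
  fold <- rep(NA_integer_, nrow(manifest))
  pool <- which(manifest$split != "test")
  for (cls in unique(manifest$label[pool])) {
    idx <- pool[manifest$label[pool] == cls]
    ord <- with_seed(derive_seed(seed, 50L + match(cls, CLASS_LABELS)),
                     sample(idx))
    fold[ord] <- (seq_along(ord) - 1L) %% n_folds
  }
  fold
}

# read the image each model consumes for a set of manifest rows
load_image_set <- function(manifest, rows, image_type) {
  col <- paste0(image_type, "_path")
  if (is.null(manifest[[col]]))
    stopf("manifest has no %s column; run preprocess_cohort() first", col)
  out <- lapply(rows, function(i) vol_data(read_volume(manifest[[col]][i],
                                                       space = "phantom")))
  names(out) <- manifest$subject_id[rows]
  out
}

.mean_ce_binary <- function(model, xs, ys) {
  tot <- 0; corr <- 0
  for (i in seq_along(xs)) {
    z <- backbone_fwd(model$params, model$spec$arch, xs[[i]])$logits
    sc <- softmax_ce(z, ys[i])
    tot <- tot + sc$loss
    corr <- corr + (which.max(z) == ys[i])
  }
  c(loss = tot / length(xs), acc = corr / length(xs))
}

#' Train a binary classifier
#'
#' Trains the backbone on the two named classes only (training split, with
#' stochastic augmentation) and selects the checkpoint with the lowest
#' validation loss.
#'
#' @param classes length-2 character vector; the model's name becomes
#'   `<c1>.<c2>_<image_type>`.
#' @param image_type `"suvr"` or `"srp"`.
#' @param manifest preprocessed manifest (with `suvr_path`/`srp_path`).
#' @param cfg a [train_config()].
#' @param arch a [net_arch()] matching the volume grid.
#' @return A trained `binary_model` with `extras$history` (per-epoch train
#'   and validation loss) and `extras$best_epoch`.
#' @export
train_binary <- function(classes, image_type, manifest, cfg = train_config(),
                         arch = NULL) {
  tr_rows <- which(manifest$split == "train" & manifest$label %in% classes)
  va_rows <- which(manifest$split == "val" & manifest$label %in% classes)
  if (length(unique(manifest$label[tr_rows])) < 2L)
    stopf("both classes must be present in the training split")
  if (length(va_rows) == 0L) stopf("validation split is empty for %s",
                                   paste(classes, collapse = "/"))
  xs <- load_image_set(manifest, tr_rows, image_type)
  if (is.null(arch)) arch <- net_arch(grid = dim(xs[[1]]))
  ys <- match(manifest$label[tr_rows], classes)
  vx <- load_image_set(manifest, va_rows, image_type)
  vy <- match(manifest$label[va_rows], classes)
  pools <- lapply(seq_along(classes), function(k) xs[ys == k])

  model <- build_backbone(classes, image_type, arch,
                          seed = derive_seed(cfg$seed, 7L))
  flat <- flatten_params(model$params)
  st <- adam_init(flat)
  best <- list(loss = Inf, flat = flat, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_acc = numeric())
  wait <- 0L
  set.seed(derive_seed(cfg$seed, 11L))
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample(seq_along(xs))
    ep_loss <- 0
    for (b0 in seq(1L, length(perm), by = cfg$batch_size)) {
      bidx <- perm[b0:min(b0 + cfg$batch_size - 1L, length(perm))]
      grads <- NULL
      for (i in bidx) {
        x <- augment_sample(xs[[i]], pools[[ys[i]]], cfg$augment)
        fwd <- backbone_fwd(model$params, arch, vol_data(x), keep = TRUE)
        sc <- softmax_ce(fwd$logits, ys[i])
        ep_loss <- ep_loss + sc$loss
        grads <- acc_grads(grads, backbone_bwd(model$params, arch, fwd, sc$dz))
      }
      upd <- adam_step(flat, scale_grads(grads, 1 / length(bidx)), st, lr = cfg$lr)
      flat <- upd$flat; st <- upd$state
      model$params <- unflatten_into(model$params, flat)
    }
    vm <- .mean_ce_binary(model, vx, vy)
    hist <- rbind(hist, data.frame(epoch = ep,
                                   train_loss = ep_loss / length(perm),
                                   val_loss = vm[["loss"]],
                                   val_acc = vm[["acc"]]))
    if (vm[["loss"]] < best$loss - 1e-6) {
      best <- list(loss = vm[["loss"]], flat = flat, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$params <- unflatten_into(model$params, best$flat)
  model$extras <- list(history = hist, best_epoch = best$epoch,
                       best_val_loss = best$loss)
  model
}

# consistent augmentation of a (suvr, srp) pair for the multiclass model
augment_pair <- function(suvr, srp, pool_suvr, pool_srp, cfg) {
  fire <- stats::runif(3) < cfg$apply_prob
  fired <- any(fire)
  if (fire[1] && length(pool_suvr) > 0) {
    j <- sample.int(length(pool_suvr), 1)
    al <- stats::runif(1)
    suvr <- mixup(suvr, pool_suvr[[j]], al)
    srp <- mixup(srp, pool_srp[[j]], al)
  }
  if (fire[2]) {
    suvr <- horizontal_flip(suvr)
    srp <- horizontal_flip(srp)
  }
  if (fire[3]) {
    axis <- sample.int(3, 1)
    deg <- stats::runif(1, -cfg$max_rotation_deg, cfg$max_rotation_deg)
    suvr <- rotate_volume(suvr, axis, deg)
    srp <- rotate_volume(srp, axis, deg)
  }
  list(suvr = suvr, srp = srp, fired = fired)
}

# context outputs of the six extractor backbones for one (suvr, srp) pair
.six_ctx <- function(ext_params, arch, suvr, srp, keep = FALSE) {
  ctx <- vector("list", 6L); caches <- vector("list", 6L); sp <- NULL
  for (i in 1:6) {
    fwd <- backbone_fwd(ext_params[[i]], arch,
                        vol_data(if (i <= 3L) suvr else srp), keep = keep)
    ctx[[i]] <- fwd$ctx; caches[[i]] <- fwd$cache; sp <- fwd$ctx_sp
  }
  list(ctx = ctx, sp = sp, caches = caches)
}

#' Train the multiclass disease model
#'
#' Trains the 768 -> 384 -> 50 -> 3 head (and the six added convolutions;
#' the donor backbones too when `cfg$freeze_extractors` is `FALSE`) on the
#' AD/DLB/Mixed training subjects only, with cross-entropy over three
#' classes.
#'
#' @param extractors list of six `feature_extractor`s in canonical order.
#' @param manifest preprocessed manifest.
#' @param cfg a [train_config()].
#' @return A trained `multiclass_model` with training history in
#'   `extras`.
#' @export
train_multiclass <- function(extractors, manifest, cfg = train_config()) {
  model <- build_multiclass_model(extractors,
                                  seed = derive_seed(cfg$seed, 13L))
  arch <- model$spec$arch
  dp <- arch$dropout
  tr <- which(manifest$split == "train" & manifest$label %in% DISEASE_CLASSES)
  va <- which(manifest$split == "val" & manifest$label %in% DISEASE_CLASSES)
  if (length(tr) == 0L || length(va) == 0L)
    stopf("multiclass training needs AD/DLB/Mixed subjects in train and val")
  suvr <- load_image_set(manifest, tr, "suvr")
  srp <- load_image_set(manifest, tr, "srp")
  ys <- match(manifest$label[tr], DISEASE_CLASSES)
  vsuvr <- load_image_set(manifest, va, "suvr")
  vsrp <- load_image_set(manifest, va, "srp")
  vy <- match(manifest$label[va], DISEASE_CLASSES)
  frozen <- cfg$freeze_extractors

  # cache context outputs of the unaugmented subjects (frozen path)
  cache_ctx <- lapply(seq_along(tr), function(i)
    .six_ctx(model$params$ext, arch, suvr[[i]], srp[[i]]))
  val_ctx <- lapply(seq_along(va), function(i)
    .six_ctx(model$params$ext, arch, vsuvr[[i]], vsrp[[i]]))

  trainable <- if (frozen) {
    c(unlist(lapply(1:6, function(i)
        sprintf("ext.e%d.added.%s", i, c("W", "b")))),
      as.vector(outer(paste0("head.l", 1:3), c("W", "b"), paste, sep = ".")))
  } else NULL  # all parameters
  flat <- flatten_params(model$params)
  if (!is.null(trainable)) flat <- flat[trainable]
  st <- adam_init(flat)
  best <- list(loss = Inf, flat = flat, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_acc = numeric())
  wait <- 0L
  set.seed(derive_seed(cfg$seed, 17L))
  pools <- lapply(1:3, function(k) which(ys == k))
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample(seq_along(tr))
    ep_loss <- 0
    for (b0 in seq(1L, length(perm), by = cfg$batch_size)) {
      bidx <- perm[b0:min(b0 + cfg$batch_size - 1L, length(perm))]
      grads <- NULL
      for (i in bidx) {
        same <- pools[[ys[i]]]
        ap <- augment_pair(suvr[[i]], srp[[i]], suvr[same], srp[same],
                           cfg$augment)
        need_fresh <- ap$fired || !frozen
        cx <- if (need_fresh)
          .six_ctx(model$params$ext, arch, ap$suvr, ap$srp, keep = !frozen)
        else cache_ctx[[i]]
        fwd <- multiclass_fwd_from_ctx(model$params, cx$ctx, cx$sp,
                                       train = TRUE, dropout = dp,
                                       keep = TRUE)
        sc <- softmax_ce(fwd$logits, ys[i])
        ep_loss <- ep_loss + sc$loss
        bw <- multiclass_bwd(model$params, fwd, sc$dz, need_dctx = !frozen)
        g <- bw$grads
        if (!frozen) {
          for (e in 1:6) {
            gb <- backbone_body_bwd(model$params$ext[[e]], arch,
                                    cx$caches[[e]], bw$dctx[[e]])
            names(gb) <- sprintf("ext.e%d.%s", e, names(gb))
            g <- c(g, gb)
          }
        }
        grads <- acc_grads(grads, g)
      }
      upd <- adam_step(flat, scale_grads(grads, 1 / length(bidx)), st,
                       lr = cfg$lr)
      flat <- upd$flat; st <- upd$state
      model$params <- unflatten_into(model$params, flat)
      if (!frozen) {  # backbones moved: refresh the cached contexts lazily
        cache_ctx <- NULL
      }
    }
    if (!frozen) {
      cache_ctx <- lapply(seq_along(tr), function(i)
        .six_ctx(model$params$ext, arch, suvr[[i]], srp[[i]]))
      val_ctx <- lapply(seq_along(va), function(i)
        .six_ctx(model$params$ext, arch, vsuvr[[i]], vsrp[[i]]))
    }
    vloss <- 0; vcorr <- 0
    for (i in seq_along(va)) {
      z <- multiclass_fwd_from_ctx(model$params, val_ctx[[i]]$ctx,
                                   val_ctx[[i]]$sp)$logits
      sc <- softmax_ce(z, vy[i])
      vloss <- vloss + sc$loss
      vcorr <- vcorr + (which.max(z) == vy[i])
    }
    vloss <- vloss / length(va)
    hist <- rbind(hist, data.frame(epoch = ep,
                                   train_loss = ep_loss / length(perm),
                                   val_loss = vloss,
                                   val_acc = vcorr / length(va)))
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, flat = flat, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$params <- unflatten_into(model$params, best$flat)
  model$extras <- list(history = hist, best_epoch = best$epoch,
                       best_val_loss = best$loss)
  model
}

BINARY_TASKS <- list(
  list(classes = c("AD", "HC"), image = "suvr"),
  list(classes = c("DLB", "HC"), image = "suvr"),
  list(classes = c("Mixed", "HC"), image = "suvr"),
  list(classes = c("AD", "HC"), image = "srp"),
  list(classes = c("DLB", "HC"), image = "srp"),
  list(classes = c("Mixed", "HC"), image = "srp"),
  list(classes = c("AD", "Mixed"), image = "suvr"))

#' Train the full model set
#'
#' Trains the six HC-versus-dementia binary models plus the AD-versus-
#' Mixed specialist, derives the six feature extractors, and trains the
#' multiclass head.  Returns everything the hierarchical ensemble needs.
#'
#' @param manifest preprocessed manifest.
#' @param cfg a [train_config()].
#' @param verbose print per-model progress lines.
#' @return Named list of trained models: the seven binary model names plus
#'   `AD.DLB.Mixed_suvr.srp`.
#' @export
train_all_models <- function(manifest, cfg = train_config(), verbose = FALSE) {
  models <- list()
  for (k in seq_along(BINARY_TASKS)) {
    task <- BINARY_TASKS[[k]]
    cfg_k <- cfg; cfg_k$seed <- derive_seed(cfg$seed, 100L + k)
    m <- train_binary(task$classes, task$image, manifest, cfg_k)
    models[[m$spec$name]] <- m
    if (verbose)
      message(sprintf("%s: best val loss %.4f (epoch %d)", m$spec$name,
                      m$extras$best_val_loss, m$extras$best_epoch))
  }
  extractors <- lapply(seq_along(MULTICLASS_ORDER), function(i)
    build_feature_extractor(models[[MULTICLASS_ORDER[i]]],
                            seed = derive_seed(cfg$seed, 200L + i)))
  cfg_m <- cfg; cfg_m$seed <- derive_seed(cfg$seed, 300L)
  mc <- train_multiclass(extractors, manifest, cfg_m)
  models[[mc$spec$name]] <- mc
  if (verbose)
    message(sprintf("%s: best val loss %.4f (epoch %d)", mc$spec$name,
                    mc$extras$best_val_loss, mc$extras$best_epoch))
  models
}

#' Stratified 5-fold cross-validation
#'
#' The test split stays fixed and excluded from fold rotation.  The
#' remaining pool is split into `n_folds` stratified folds; for each fold
#' the preprocessing statistics (group GM mask, voxel-mean profile) are
#' refit on that fold's training portion, the full model set is retrained,
#' and the ensemble is evaluated on the common held-out test set.
#'
#' @param manifest raw cohort manifest with a fixed `test` split.
#' @param atlas phantom atlas (reference + striatal regions).
#' @param work_dir scratch directory for per-fold preprocessing artifacts.
#' @param cfg a [train_config()].
#' @param n_folds number of folds, default 5.
#' @return List with `folds` (per fold: models, metrics, fold manifest)
#'   and `summary` (per-class AUROC mean and normal-approximation 95% CI
#'   across folds).
#' @export
cross_validate <- function(manifest, atlas, work_dir, cfg = train_config(),
                           n_folds = 5L) {
  if (!any(manifest$split == "test")) stopf("manifest has no test split")
  fold <- assign_folds(manifest, n_folds, cfg$seed)
  folds <- vector("list", n_folds)
  for (f in seq_len(n_folds) - 1L) {
    mf <- manifest
    pool <- which(mf$split != "test")
    mf$split[pool] <- ifelse(fold[pool] == f, "val", "train")
    miss <- setdiff(unique(manifest$label), unique(mf$label[mf$split == "train"]))
    if (length(miss) > 0)
      stopf("fold %d training portion lacks class %s", f, paste(miss, collapse = ","))
    pp <- preprocess_cohort(mf, atlas, file.path(work_dir, sprintf("fold%d", f)))
    cfg_f <- cfg; cfg_f$seed <- derive_seed(cfg$seed, 400L + f)
    models <- train_all_models(pp, cfg_f)
    ev <- evaluate_ensemble(pp, models)
    folds[[f + 1L]] <- list(fold = f, manifest = pp, models = models,
                            metrics = ev)
  }
  auroc <- do.call(rbind, lapply(folds, function(fd)
    fd$metrics$class_metrics$auroc))
  colnames(auroc) <- folds[[1]]$metrics$class_metrics$class
  mu <- colMeans(auroc)
  se <- apply(auroc, 2, stats::sd) / sqrt(n_folds)
  summary <- data.frame(class = names(mu), mean_auroc = as.numeric(mu),
                        ci_lo = as.numeric(mu - 1.96 * se),
                        ci_hi = as.numeric(mu + 1.96 * se))
  list(folds = folds, summary = summary, fold_assignment = fold)
}
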