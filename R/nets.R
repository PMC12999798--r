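#' Network architectures
#'
#' The binary backbone is a small 3D CNN: five sequential 3x3x3
#' convolution stages with stride schedule (2,2,2,2,1) (instance
#' normalization + ReLU after each), ending at 128 channels; a multi-scale
#' context module (parallel dilated-convolution branches, dilations 1/2/4,
#' merged by a 1x1x1 convolution); global average pooling; and a final
#' 128 -> 2 linear layer.  On the canonical 96x112x96 grid the feature map
#' entering pooling is 128 x (6,7,6).  A feature extractor is a trained
#' backbone truncated after the context module plus one added 3x3x3
#' stride-2 convolution (output 128 x (3,3,3) on the canonical grid); the
#' multiclass head concatenates six extractor outputs (768 channels),
#' pools, and reduces 768 -> 384 -> 50 -> 3 through linear layers with
#' dropout.
#'
#' @name nets
NULL

CANONICAL_GRID <- c(96L, 112L, 96L)

#' Architecture hyper-parameters
#'
#' @param grid input grid shape; every axis must be divisible by 16 (four
#'   stride-2 stages).
#' @param channels per-stage output channels; the last entry must be 128.
#' @param strides per-stage strides, default `c(2, 2, 2, 2, 1)`.
#' @param branch_channels channels per context-module branch.
#' @param dilations dilation factor of each context branch.
#' @param head_dims hidden widths of the multiclass head.
#' @param dropout dropout rate in the multiclass head.
#' @return A `net_arch` list.
#' @export
net_arch <- function(grid = CANONICAL_GRID,
                     channels = c(8L, 16L, 32L, 64L, 128L),
                     strides = c(2L, 2L, 2L, 2L, 1L),
                     branch_channels = 64L,
                     dilations = c(1L, 2L, 4L),
                     head_dims = c(384L, 50L),
                     dropout = 0.5) {
  grid <- as.integer(grid)
  if (any(grid %% 16L != 0L))
    stopf("grid %s not divisible by 16 in every axis",
          paste(grid, collapse = "x"))
  if (utils::tail(channels, 1) != 128L)
    stopf("backbone must end at 128 channels")
  if (length(channels) != 5L || length(strides) != 5L)
    stopf("backbone has five convolution stages")
  structure(list(grid = grid, channels = as.integer(channels),
                 strides = as.integer(strides),
                 branch_channels = as.integer(branch_channels),
                 dilations = as.integer(dilations),
                 head_dims = as.integer(head_dims), dropout = dropout),
            class = "net_arch")
}

# spatial shape entering global average pooling
backbone_feature_shape <- function(arch) {
  sp <- arch$grid
  for (s in arch$strides) sp <- (sp + 2L - 3L) %/% s + 1L
  sp
}

# padding rule for the added stride-2 convolution: even axis -> pad 1
# (out = n/2), odd -> pad 0 (out = (n-1)/2); a degenerate axis of 1 is
# padded so the output keeps extent 1.  Reproduces (1,0,1) on 6x7x6 -> 3x3x3.
added_conv_pad <- function(sp) ifelse(sp == 1L, 1L, ifelse(sp %% 2L == 0L, 1L, 0L))

new_conv <- function(cout, cin, k3 = 27L) list(W = he_init(cout, cin * k3), b = numeric(cout))
new_norm <- function(c) list(g = rep(1, c), b = numeric(c))

.backbone_params <- function(arch) {
  ch <- c(1L, arch$channels)
  stages <- lapply(1:5, function(i) list(conv = new_conv(ch[i + 1L], ch[i]),
                                         norm = new_norm(ch[i + 1L])))
  names(stages) <- paste0("s", 1:5)
  branches <- lapply(arch$dilations, function(d)
    list(conv = new_conv(arch$branch_channels, 128L), norm = new_norm(arch$branch_channels)))
  names(branches) <- paste0("b", seq_along(branches))
  list(stages = stages,
       context = list(branches = branches,
                      merge = list(conv = new_conv(128L,
                                     arch$branch_channels * length(arch$dilations), 1L),
                                   norm = new_norm(128L))),
       fc = list(W = he_init(2L, 128L), b = numeric(2L)))
}

#' Build a binary backbone model
#'
#' All layers are He-initialized (`init = "he_random"`); alternatively an
#' existing bundle may donate every layer except the final linear, which
#' is always freshly He-initialized (`init = <loaded bundle>`).
#'
#' @param classes length-2 character vector, e.g. `c("AD", "HC")`; logits
#'   follow this order.
#' @param image_type `"suvr"` or `"srp"`.
#' @param arch a [net_arch()].
#' @param init `"he_random"` or a model object whose backbone weights to
#'   reuse (final linear layer re-initialized).
#' @param seed integer seed for the weight draws.
#' @return A `binary_model` object (list with `spec` and `params`).
#' @export
build_backbone <- function(classes, image_type = c("suvr", "srp"),
                           arch = net_arch(), init = "he_random", seed = 1L) {
  image_type <- match.arg(image_type)
  if (length(classes) != 2L) stopf("a binary backbone needs exactly 2 classes")
  params <- with_seed(seed, .backbone_params(arch))
  if (!identical(init, "he_random")) {
    if (!is.list(init) || is.null(init$params$stages))
      stopf("init must be \"he_random\" or a compatible backbone model")
    donor <- init$params
    if (!identical(dim(donor$stages$s1$conv$W), dim(params$stages$s1$conv$W)))
      stopf("pretrained bundle does not match this architecture")
    params$stages <- donor$stages
    params$context <- donor$context
  }
  structure(list(
    spec = list(kind = "binary",
                name = paste0(paste(classes, collapse = "."), "_", image_type),
                classes = classes, image_type = image_type, arch = arch),
    params = params),
    class = c("binary_model", "fdg_model"))
}

# ---- forward / backward -----------------------------------------------------

# x: 3D array (or 1 x N matrix with sp supplied).  Returns logits, the
# context-module output (the Grad-CAM target layer), and optionally the
# full cache for backprop.
backbone_fwd <- function(params, arch, x, keep = FALSE) {
  if (is.array(x) && length(dim(x)) == 3L) {
    sp <- dim(x)
    X <- matrix(as.vector(x), 1L)
  } else stopf("backbone_fwd expects a 3D array")
  cache <- if (keep) list(stages = vector("list", 5L)) else NULL
  for (i in 1:5) {
    st <- params$stages[[i]]
    plan <- conv_plan(sp, rep(arch$strides[i], 3L), c(1L, 1L, 1L))
    cv <- conv_fwd(st$conv$W, st$conv$b, X, plan)
    nm <- inorm_fwd(st$norm$g, st$norm$b, cv$Y)
    out <- relu_fwd(nm$Y)
    if (keep) cache$stages[[i]] <- list(plan = plan, P = cv$P, norm = nm,
                                        pre_relu = nm$Y)
    X <- out
    sp <- plan$out_sp
  }
  A5 <- X
  br_out <- vector("list", length(arch$dilations))
  if (keep) cache$branches <- vector("list", length(arch$dilations))
  for (j in seq_along(arch$dilations)) {
    d <- arch$dilations[j]
    br <- params$context$branches[[j]]
    plan <- conv_plan(sp, c(1L, 1L, 1L), rep(d, 3L), rep(d, 3L))
    cv <- conv_fwd(br$conv$W, br$conv$b, A5, plan)
    nm <- inorm_fwd(br$norm$g, br$norm$b, cv$Y)
    br_out[[j]] <- relu_fwd(nm$Y)
    if (keep) cache$branches[[j]] <- list(plan = plan, P = cv$P, norm = nm,
                                          pre_relu = nm$Y)
  }
  M <- do.call(rbind, br_out)
  mplan <- conv_plan(sp, c(1L, 1L, 1L), c(0L, 0L, 0L), k = c(1L, 1L, 1L))
  mg <- params$context$merge
  mc <- conv_fwd(mg$conv$W, mg$conv$b, M, mplan)
  mn <- inorm_fwd(mg$norm$g, mg$norm$b, mc$Y)
  ctx <- relu_fwd(mn$Y)
  f <- rowMeans(ctx)
  logits <- if (is.null(params$fc)) NULL else
    as.vector(params$fc$W %*% f + params$fc$b)
  if (keep) {
    cache$merge <- list(plan = mplan, P = mc$P, norm = mn, pre_relu = mn$Y)
    cache$f <- f
    cache$sp <- sp
  }
  list(logits = logits, ctx = ctx, ctx_sp = sp, cache = cache)
}

# backward through context + stages given the gradient at the context
# output; returns flat grads (without fc) and nothing else.
backbone_body_bwd <- function(params, arch, cache, dCtx) {
  g <- list()
  mg <- params$context$merge
  d <- relu_bwd(cache$merge$pre_relu, dCtx)
  nb <- inorm_bwd(mg$norm$g, cache$merge$norm, d)
  g[["context.merge.norm.g"]] <- nb$dg
  g[["context.merge.norm.b"]] <- nb$db
  cb <- conv_bwd(mg$conv$W, cache$merge$P, nb$dX, cache$merge$plan)
  g[["context.merge.conv.W"]] <- cb$dW
  g[["context.merge.conv.b"]] <- cb$db
  dM <- cb$dX
  bc <- arch$branch_channels
  dA5 <- NULL
  for (j in seq_along(arch$dilations)) {
    br <- params$context$branches[[j]]
    rows <- (j - 1L) * bc + seq_len(bc)
    d <- relu_bwd(cache$branches[[j]]$pre_relu, dM[rows, , drop = FALSE])
    nb <- inorm_bwd(br$norm$g, cache$branches[[j]]$norm, d)
    g[[sprintf("context.branches.b%d.norm.g", j)]] <- nb$dg
    g[[sprintf("context.branches.b%d.norm.b", j)]] <- nb$db
    cb <- conv_bwd(br$conv$W, cache$branches[[j]]$P, nb$dX,
                   cache$branches[[j]]$plan)
    g[[sprintf("context.branches.b%d.conv.W", j)]] <- cb$dW
    g[[sprintf("context.branches.b%d.conv.b", j)]] <- cb$db
    dA5 <- if (is.null(dA5)) cb$dX else dA5 + cb$dX
  }
  dX <- dA5
  for (i in 5:1) {
    st <- params$stages[[i]]
    sc <- cache$stages[[i]]
    d <- relu_bwd(sc$pre_relu, dX)
    nb <- inorm_bwd(st$norm$g, sc$norm, d)
    g[[sprintf("stages.s%d.norm.g", i)]] <- nb$dg
    g[[sprintf("stages.s%d.norm.b", i)]] <- nb$db
    cb <- conv_bwd(st$conv$W, sc$P, nb$dX, sc$plan, need_dx = i > 1L)
    g[[sprintf("stages.s%d.conv.W", i)]] <- cb$dW
    g[[sprintf("stages.s%d.conv.b", i)]] <- cb$db
    if (i > 1L) dX <- cb$dX
  }
  g
}

# full backward from dlogits for a binary backbone
backbone_bwd <- function(params, arch, fwd, dlogits) {
  cache <- fwd$cache
  g <- list()
  g[["fc.W"]] <- dlogits %o% cache$f
  g[["fc.b"]] <- dlogits
  df <- as.vector(crossprod(params$fc$W, dlogits))
  n <- ncol(fwd$ctx)
  dCtx <- matrix(df / n, nrow = length(df), ncol = n)
  c(g, backbone_body_bwd(params, arch, cache, dCtx))
}

#' Forward pass of a binary model
#'
#' @param model a `binary_model`.
#' @param x a `volume`, 3D array, or list of them (a batch).
#' @return For a single input, the logit vector (named by class); for a
#'   batch, a matrix with one row per input.
#' @export
model_logits <- function(model, x) {
  if (is.list(x) && !is_volume(x)) {
    out <- t(vapply(x, function(xi) model_logits(model, xi),
                    numeric(length(model$spec$classes))))
    colnames(out) <- model$spec$classes
    return(out)
  }
  z <- backbone_fwd(model$params, model$spec$arch, vol_data(x))$logits
  stats::setNames(z, model$spec$classes)
}

#' Class probabilities of a model
#'
#' @inheritParams model_logits
#' @return Named probability vector (softmax of the logits).
#' @export
model_probs <- function(model, x) {
  z <- model_logits(model, x)
  p <- exp(z - max(z))
  p / sum(p)
}

#' Build a feature extractor from a trained backbone
#'
#' Copies the backbone up to (and including) the context-module output and
#' appends a fresh He-initialized 3x3x3 stride-2 convolution with 128
#' output channels; the backbone's final linear layer is discarded.
#'
#' @param backbone a trained `binary_model`.
#' @param seed seed for the added convolution's init.
#' @return A `feature_extractor` object.
#' @export
build_feature_extractor <- function(backbone, seed = 1L) {
  if (!inherits(backbone, "binary_model") || is.null(backbone$params$stages))
    stopf("backbone must be a binary_model with trained parameters")
  structure(list(
    spec = list(kind = "extractor", name = paste0("FE_", backbone$spec$name),
                source = backbone$spec$name,
                image_type = backbone$spec$image_type,
                arch = backbone$spec$arch),
    params = list(stages = backbone$params$stages,
                  context = backbone$params$context,
                  added = with_seed(seed, new_conv(128L, 128L)))),
    class = c("extractor_model", "fdg_model"))
}

# added conv + ReLU on a cached context output
extractor_head_fwd <- function(added, ctx, sp) {
  pad <- added_conv_pad(sp)
  plan <- conv_plan(sp, c(2L, 2L, 2L), pad)
  cv <- conv_fwd(added$W, added$b, ctx, plan)
  list(out = relu_fwd(cv$Y), pre_relu = cv$Y, P = cv$P, plan = plan)
}

#' Run a feature extractor
#'
#' @param extractor a `feature_extractor`.
#' @param x volume or 3D array on the extractor's grid.
#' @return List with `features` (128 x N matrix) and `sp` (spatial shape,
#'   `c(3, 3, 3)` on the canonical grid).
#' @export
extract_features <- function(extractor, x) {
  fwd <- backbone_fwd(extractor$params, extractor$spec$arch, vol_data(x))
  eh <- extractor_head_fwd(extractor$params$added, fwd$ctx, fwd$ctx_sp)
  list(features = eh$out, sp = eh$plan$out_sp)
}

MULTICLASS_ORDER <- c("AD.HC_suvr", "DLB.HC_suvr", "Mixed.HC_suvr",
                      "AD.HC_srp", "DLB.HC_srp", "Mixed.HC_srp")
DISEASE_CLASSES <- c("AD", "DLB", "Mixed")

#' Build the multiclass model from six feature extractors
#'
#' Extractors must be supplied in the fixed order
#' `AD.HC_suvr, DLB.HC_suvr, Mixed.HC_suvr, AD.HC_srp, DLB.HC_srp,
#' Mixed.HC_srp`.  The SUVR-origin extractors consume the SUVR image and
#' the SRP-origin extractors the SRP image; their 128-channel outputs are
#' concatenated to 768 channels, pooled, and passed through the
#' 768 -> 384 -> 50 -> 3 head with dropout.
#'
#' @param extractors list of six `feature_extractor`s in canonical order.
#' @param seed seed for the head init.
#' @return A `multiclass_model`.
#' @export
build_multiclass_model <- function(extractors, seed = 1L) {
  if (length(extractors) != 6L) stopf("need exactly six feature extractors")
  srcs <- vapply(extractors, function(e) e$spec$source, character(1))
  if (!identical(srcs, MULTICLASS_ORDER))
    stopf("extractors out of order: got %s", paste(srcs, collapse = ", "))
  arch <- extractors[[1]]$spec$arch
  hd <- arch$head_dims
  ext <- lapply(extractors, function(e) e$params)
  names(ext) <- paste0("e", 1:6)
  head <- with_seed(seed, list(
    l1 = list(W = he_init(hd[1], 768L), b = numeric(hd[1])),
    l2 = list(W = he_init(hd[2], hd[1]), b = numeric(hd[2])),
    l3 = list(W = he_init(3L, hd[2]), b = numeric(3L))))
  structure(list(
    spec = list(kind = "multiclass", name = "AD.DLB.Mixed_suvr.srp",
                classes = DISEASE_CLASSES, image_type = c("suvr", "srp"),
                extractor_order = MULTICLASS_ORDER, arch = arch),
    params = list(ext = ext, head = head)),
    class = c("multiclass_model", "fdg_model"))
}

# forward from six cached context outputs (frozen-backbone path).
# ctx_list: list of 6 (128 x N) matrices; sp: context spatial shape.
multiclass_fwd_from_ctx <- function(params, ctx_list, sp, train = FALSE,
                                    dropout = 0.5, keep = FALSE) {
  eh <- lapply(1:6, function(i)
    extractor_head_fwd(params$ext[[i]]$added, ctx_list[[i]], sp))
  Fcat <- do.call(rbind, lapply(eh, `[[`, "out"))   # 768 x No
  f <- rowMeans(Fcat)
  h <- params$head
  z1 <- as.vector(h$l1$W %*% f + h$l1$b); r1 <- pmax(z1, 0)
  m1 <- if (train && dropout > 0) (stats::runif(length(r1)) > dropout) / (1 - dropout) else 1
  d1 <- r1 * m1
  z2 <- as.vector(h$l2$W %*% d1 + h$l2$b); r2 <- pmax(z2, 0)
  m2 <- if (train && dropout > 0) (stats::runif(length(r2)) > dropout) / (1 - dropout) else 1
  d2 <- r2 * m2
  logits <- as.vector(h$l3$W %*% d2 + h$l3$b)
  out <- list(logits = logits, n_spatial = ncol(Fcat))
  if (keep) out$cache <- list(eh = eh, f = f, z1 = z1, m1 = m1, d1 = d1,
                              z2 = z2, m2 = m2, d2 = d2)
  out
}

# backward of the frozen-path multiclass model; returns flat grads for the
# added convolutions and the head (and, if need_dctx, gradients at each
# context output for unfrozen training).
multiclass_bwd <- function(params, fwd, dlogits, need_dctx = FALSE) {
  cc <- fwd$cache
  h <- params$head
  g <- list()
  g[["head.l3.W"]] <- dlogits %o% cc$d2
  g[["head.l3.b"]] <- dlogits
  dd2 <- as.vector(crossprod(h$l3$W, dlogits)) * cc$m2
  dz2 <- dd2 * (cc$z2 > 0)
  g[["head.l2.W"]] <- dz2 %o% cc$d1
  g[["head.l2.b"]] <- dz2
  dd1 <- as.vector(crossprod(h$l2$W, dz2)) * cc$m1
  dz1 <- dd1 * (cc$z1 > 0)
  g[["head.l1.W"]] <- dz1 %o% cc$f
  g[["head.l1.b"]] <- dz1
  df <- as.vector(crossprod(h$l1$W, dz1))
  n <- fwd$n_spatial
  dF <- matrix(df / n, nrow = length(df), ncol = n)
  dctx <- if (need_dctx) vector("list", 6L) else NULL
  for (i in 1:6) {
    rows <- (i - 1L) * 128L + seq_len(128L)
    ehc <- cc$eh[[i]]
    d <- relu_bwd(ehc$pre_relu, dF[rows, , drop = FALSE])
    cb <- conv_bwd(params$ext[[i]]$added$W, ehc$P, d, ehc$plan,
                   need_dx = need_dctx)
    g[[sprintf("ext.e%d.added.W", i)]] <- cb$dW
    g[[sprintf("ext.e%d.added.b", i)]] <- cb$db
    if (need_dctx) dctx[[i]] <- cb$dX
  }
  list(grads = g, dctx = dctx)
}

#' Forward pass of the multiclass model
#'
#' @param model a `multiclass_model`.
#' @param suvr,srp the subject's SUVR and SRP volumes (or arrays).
#' @return Named 3-logit vector over `AD`, `DLB`, `Mixed`.
#' @export
multiclass_logits <- function(model, suvr, srp) {
  arch <- model$spec$arch
  ctx <- vector("list", 6L)
  sp <- NULL
  for (i in 1:6) {
    x <- if (i <= 3L) suvr else srp
    fwd <- backbone_fwd(model$params$ext[[i]], arch, vol_data(x))
    ctx[[i]] <- fwd$ctx
    sp <- fwd$ctx_sp
  }
  z <- multiclass_fwd_from_ctx(model$params, ctx, sp)$logits
  stats::setNames(z, model$spec$classes)
}

#' @rdname multiclass_logits
#' @export
multiclass_probs <- function(model, suvr, srp) {
  z <- multiclass_logits(model, suvr, srp)
  p <- exp(z - max(z))
  p / sum(p)
}
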