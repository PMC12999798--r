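# Minimal 3D CNN primitives.
#
# Feature maps are stored as C x N matrices (channels by voxels) with the
# spatial dims carried separately; convolution is im2col + BLAS matmul with
# an exact hand-derived backward pass.  This keeps the whole network in
# vectorized base R, which is fast enough at phantom scale.

.plan_cache <- new.env(parent = emptyenv())

# Gather-index plan for a 3x3x3 (or 1x1x1) convolution over a padded grid.
conv_plan <- function(in_sp, stride, pad, dil = c(1, 1, 1), k = c(3, 3, 3)) {
  key <- paste(c(in_sp, stride, pad, dil, k), collapse = ",")
  hit <- .plan_cache[[key]]
  if (!is.null(hit)) return(hit)
  pd <- in_sp + 2L * pad
  out_sp <- (pd - dil * (k - 1L) - 1L) %/% stride + 1L
  if (any(out_sp < 1L))
    stopf("convolution output would be empty for input %s",
          paste(in_sp, collapse = "x"))
  base_i <- (seq_len(out_sp[1]) - 1L) * stride[1] + 1L
  base_j <- (seq_len(out_sp[2]) - 1L) * stride[2] + 1L
  base_k <- (seq_len(out_sp[3]) - 1L) * stride[3] + 1L
  gi <- rep(base_i, times = out_sp[2] * out_sp[3])
  gj <- rep(rep(base_j, each = out_sp[1]), times = out_sp[3])
  gk <- rep(base_k, each = out_sp[1] * out_sp[2])
  offs <- expand.grid(a = 0:(k[1] - 1L), b = 0:(k[2] - 1L), c = 0:(k[3] - 1L))
  K3 <- nrow(offs)
  idx <- matrix(0L, K3, length(gi))
  for (t in seq_len(K3)) {
    idx[t, ] <- (gi + offs$a[t] * dil[1]) +
      pd[1] * (gj + offs$b[t] * dil[2] - 1L) +
      pd[1] * pd[2] * (gk + offs$c[t] * dil[3] - 1L)
  }
  inner <- NULL
  if (any(pad > 0L)) {
    ii <- rep(seq_len(in_sp[1]) + pad[1], times = in_sp[2] * in_sp[3])
    jj <- rep(rep(seq_len(in_sp[2]) + pad[2], each = in_sp[1]), times = in_sp[3])
    kk <- rep(seq_len(in_sp[3]) + pad[3], each = in_sp[1] * in_sp[2])
    inner <- ii + pd[1] * (jj - 1L) + pd[1] * pd[2] * (kk - 1L)
  }
  plan <- list(in_sp = in_sp, pd = pd, out_sp = out_sp, K3 = K3,
               idxv = as.vector(idx), idx = idx, inner = inner,
               n_out = length(gi))
  assign(key, plan, envir = .plan_cache)
  plan
}

conv_fwd <- function(W, b, X, plan) {
  Cin <- nrow(X)
  Xp <- if (is.null(plan$inner)) X else {
    tmp <- matrix(0, Cin, prod(plan$pd))
    tmp[, plan$inner] <- X
    tmp
  }
  P <- Xp[, plan$idxv, drop = FALSE]
  dim(P) <- c(Cin * plan$K3, plan$n_out)
  Y <- W %*% P + b
  list(Y = Y, P = P)
}

conv_bwd <- function(W, P, dY, plan, need_dx = TRUE) {
  out <- list(dW = dY %*% t(P), db = rowSums(dY))
  if (need_dx) {
    Cin <- ncol(W) / plan$K3
    dP <- crossprod(W, dY)
    dXp <- matrix(0, Cin, prod(plan$pd))
    for (t in seq_len(plan$K3)) {
      cols <- plan$idx[t, ]
      dXp[, cols] <- dXp[, cols] +
        dP[(t - 1L) * Cin + seq_len(Cin), , drop = FALSE]
    }
    out$dX <- if (is.null(plan$inner)) dXp else dXp[, plan$inner, drop = FALSE]
  }
  out
}

INORM_EPS <- 1e-5

inorm_fwd <- function(g, b, X) {
  n <- ncol(X)
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowSums(xc * xc) / n
  istd <- 1 / sqrt(v + INORM_EPS)
  xhat <- xc * istd
  list(Y = g * xhat + b, xhat = xhat, istd = istd)
}

inorm_bwd <- function(g, cache, dY) {
  n <- ncol(dY)
  xhat <- cache$xhat
  dxhat <- dY * g
  s1 <- rowSums(dxhat) / n
  s2 <- rowSums(dxhat * xhat) / n
  list(dX = cache$istd * (dxhat - s1 - xhat * s2),
       dg = rowSums(dY * xhat), db = rowSums(dY))
}

relu_fwd <- function(X) pmax(X, 0)
relu_bwd <- function(X, dY) dY * (X > 0)

# softmax cross-entropy on a logit vector; returns loss, probs, dlogits
softmax_ce <- function(z, y) {
  z <- z - max(z)
  p <- exp(z); p <- p / sum(p)
  d <- p; d[y] <- d[y] - 1
  list(loss = -log(max(p[y], 1e-12)), p = as.vector(p), dz = d)
}

he_init <- function(nout, nin, seed = NULL) {
  draw <- function() matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# ---- parameter tree helpers -------------------------------------------------

flatten_params <- function(p, prefix = "") {
  if (is.list(p)) {
    out <- list()
    for (nm in names(p))
      out <- c(out, flatten_params(p[[nm]], paste0(prefix, nm, ".")))
    out
  } else stats::setNames(list(p), substr(prefix, 1, nchar(prefix) - 1))
}

unflatten_into <- function(p, flat) {
  assign_path <- function(tree, path, value) {
    if (length(path) == 1L) { tree[[path]] <- value; return(tree) }
    tree[[path[1]]] <- assign_path(tree[[path[1]]], path[-1], value)
    tree
  }
  for (nm in names(flat)) p <- assign_path(p, strsplit(nm, ".", fixed = TRUE)[[1]], flat[[nm]])
  p
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

adam_step <- function(flat, grads, state, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(flat = flat, state = state)
}

# elementwise sum of two grad lists with identical names
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)
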