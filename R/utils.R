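#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a base seed and a stream index, kept inside the
# 32-bit signed range so set.seed() accepts it.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1103515245 + 12345 + 97 * as.double(stream)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Trilinear interpolation of a 3D array `x` at fractional voxel coordinates
# (1-based).  Coordinates outside the grid return `fill`.
trilinear_sample <- function(x, i, j, k, fill = 0) {
  d <- dim(x)
  i0 <- floor(i); j0 <- floor(j); k0 <- floor(k)
  fi <- i - i0; fj <- j - j0; fk <- k - k0
  out <- numeric(length(i))
  # valid when the whole 2x2x2 neighbourhood can be clamped meaningfully
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  cl <- function(v, n) pmin(pmax(v, 1), n)
  i0c <- cl(i0, d[1]); i1c <- cl(i0 + 1, d[1])
  j0c <- cl(j0, d[2]); j1c <- cl(j0 + 1, d[2])
  k0c <- cl(k0, d[3]); k1c <- cl(k0 + 1, d[3])
  idx <- function(a, b, c) a + d[1] * (b - 1L) + d[1] * d[2] * (c - 1L)
  v000 <- x[idx(i0c, j0c, k0c)]; v100 <- x[idx(i1c, j0c, k0c)]
  v010 <- x[idx(i0c, j1c, k0c)]; v110 <- x[idx(i1c, j1c, k0c)]
  v001 <- x[idx(i0c, j0c, k1c)]; v101 <- x[idx(i1c, j0c, k1c)]
  v011 <- x[idx(i0c, j1c, k1c)]; v111 <- x[idx(i1c, j1c, k1c)]
  v00 <- v000 * (1 - fi) + v100 * fi
  v10 <- v010 * (1 - fi) + v110 * fi
  v01 <- v001 * (1 - fi) + v101 * fi
  v11 <- v011 * (1 - fi) + v111 * fi
  v0 <- v00 * (1 - fj) + v10 * fj
  v1 <- v01 * (1 - fj) + v11 * fj
  out[] <- fill
  val <- v0 * (1 - fk) + v1 * fk
  out[ok] <- val[ok]
  out
}

# Resample a 3D array to a new grid by trilinear interpolation, mapping voxel
# centres proportionally (used to upsample saliency maps to the input grid).
resample_to_grid <- function(x, out_dim) {
  d <- dim(x)
  sc <- d / out_dim
  ii <- (seq_len(out_dim[1]) - 0.5) * sc[1] + 0.5
  jj <- (seq_len(out_dim[2]) - 0.5) * sc[2] + 0.5
  kk <- (seq_len(out_dim[3]) - 0.5) * sc[3] + 0.5
  g <- expand.grid(i = ii, j = jj, k = kk)
  # clamp into the source grid so border voxels extrapolate flatly
  g$i <- pmin(pmax(g$i, 1), d[1]); g$j <- pmin(pmax(g$j, 1), d[2])
  g$k <- pmin(pmax(g$k, 1), d[3])
  array(trilinear_sample(x, g$i, g$j, g$k), dim = out_dim)
}
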