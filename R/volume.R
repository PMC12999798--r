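#' 3D brain volume container
#'
#' A `volume` is a light container for a 3D scalar field on a regular grid:
#' the voxel `data` array, the voxel `spacing` in millimetres, and a
#' `space` tag recording which coordinate frame the grid lives in
#' (`"mni_like"` for registered clinical-style grids, `"phantom"` for
#' synthetic cohorts).  All volumes taking part in one analysis must share
#' shape and spacing; the package checks grid equality instead of
#' resampling, consistent with consuming pre-registered images.
#'
#' @param data numeric 3D array of voxel values (all finite).
#' @param spacing positive numeric triple, voxel size in mm.
#' @param space character scalar, coordinate-frame tag.
#' @return An object of class `volume`.
#' @examples
#' v <- new_volume(array(1, c(4, 4, 4)), spacing = c(2, 2, 2))
#' dim(vol_data(v))
#' @export
new_volume <- function(data, spacing = c(1, 1, 1), space = "phantom") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("volume data must be a 3D array, got %d dims", length(dim(data)))
  nbad <- sum(!is.finite(data))
  if (nbad > 0L)
    stopf("volume contains %d non-finite voxel%s", nbad, if (nbad == 1L) "" else "s")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be a positive numeric triple")
  structure(list(data = data, spacing = spacing, space = as.character(space)[1]),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume %s: %s voxels, spacing %s mm, range [%.4g, %.4g]>\n",
              x$space, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname new_volume
#' @param x object to test or extract from.
#' @export
is_volume <- function(x) inherits(x, "volume")

#' @rdname new_volume
#' @export
vol_data <- function(x) {
  if (is_volume(x)) x$data else x
}

# Binary mask on the same grid: stored as a volume whose data is 0/1.
#' Construct a binary mask volume
#'
#' @param data logical or 0/1 numeric 3D array.
#' @inheritParams new_volume
#' @return A `volume` whose data is a 0/1 array.
#' @export
new_mask <- function(data, spacing = c(1, 1, 1), space = "phantom") {
  m <- new_volume(array(as.numeric(data != 0), dim = dim(data)), spacing, space)
  m
}

# TRUE where the mask is on, as a logical array.
mask_which <- function(mask) vol_data(mask) != 0

# Abort unless all volumes share one grid (shape + spacing).
check_same_grid <- function(...) {
  vols <- list(...)
  ref <- vols[[1]]
  for (v in vols[-1]) {
    if (!identical(dim(vol_data(v)), dim(vol_data(ref))))
      stopf("grid mismatch: shapes %s vs %s",
            paste(dim(vol_data(ref)), collapse = "x"),
            paste(dim(vol_data(v)), collapse = "x"))
    if (is_volume(v) && is_volume(ref) &&
        max(abs(v$spacing - ref$spacing)) > 1e-6)
      stopf("grid mismatch: spacings differ")
  }
  invisible(TRUE)
}
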