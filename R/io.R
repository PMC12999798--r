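#' Read a 3D NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file into a [new_volume()] container.  4D images
#' with a singleton trailing axis are squeezed to 3D; anything else that is
#' not 3D is rejected, as are images containing non-finite voxels.
#'
#' @param path path to an existing NIfTI file.
#' @param space space tag to record on the returned volume.
#' @return A `volume`.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, space = "mni_like") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  arr <- unclass(img)
  attributes(arr) <- list(dim = dim(img))
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) {
    arr <- array(arr, dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stopf("%s: expected a 3D image, got %s dims", path, length(d))
  nbad <- sum(!is.finite(arr))
  if (nbad > 0L)
    stopf("%s: %d non-finite voxel%s", path, nbad, if (nbad == 1L) "" else "s")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  new_volume(arr, spacing = sp, space = space)
}

#' Write a volume to NIfTI
#'
#' Voxel data are stored as 32-bit float (masks and label volumes may use
#' `datatype = "uint8"`/`"int16"`); spacing is written into the header.
#'
#' @param volume a `volume` (or plain 3D array).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype NIfTI storage type, default `"float"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, datatype = "float") {
  dir <- dirname(path)
  if (!dir.exists(dir)) stopf("parent directory does not exist: %s", dir)
  arr <- vol_data(volume)
  sp <- if (is_volume(volume)) volume$spacing else c(1, 1, 1)
  img <- RNifti::asNifti(structure(arr, pixdim = sp), datatype = datatype)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

CLASS_LABELS <- c("AD", "DLB", "Mixed", "HC")

# Normalize label strings case-insensitively onto the canonical four classes.
normalize_labels <- function(x) {
  key <- tolower(trimws(as.character(x)))
  lut <- stats::setNames(CLASS_LABELS, tolower(CLASS_LABELS))
  out <- lut[key]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stopf("unknown class label(s): %s (expected one of %s)",
          paste(bad, collapse = ", "), paste(CLASS_LABELS, collapse = ", "))
  }
  unname(out)
}

MANIFEST_COLS <- c("subject_id", "label", "pet_path", "gm_prob_path",
                   "brain_mask_path", "split")

#' Load a cohort manifest
#'
#' The manifest is a CSV/TSV table with header columns
#' `subject_id,label,pet_path,gm_prob_path,brain_mask_path,split`.  Labels
#' are normalized case-insensitively to `AD`, `DLB`, `Mixed`, `HC`; the
#' `split` column may be empty (unassigned) or one of
#' `train`/`val`/`test`.  Relative file paths are resolved against the
#' manifest's own directory.
#'
#' @param path manifest file path.
#' @param check_files if `TRUE` (default) every referenced volume file must
#'   exist.
#' @return A `data.frame` with the manifest columns (plus any extras such as
#'   `suvr_path`/`srp_path` written by [preprocess_cohort()]).
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  need <- setdiff(setdiff(MANIFEST_COLS, "split"), names(df))
  if (length(need) > 0)
    stopf("manifest missing column(s): %s", paste(need, collapse = ", "))
  if (is.null(df$split)) df$split <- ""
  df$split[is.na(df$split)] <- ""
  bad_split <- setdiff(unique(df$split), c("", "train", "val", "test"))
  if (length(bad_split) > 0)
    stopf("unknown split value(s): %s", paste(bad_split, collapse = ", "))
  df$label <- normalize_labels(df$label)
  dup <- unique(df$subject_id[duplicated(df$subject_id)])
  if (length(dup) > 0)
    stopf("duplicate subject_id(s): %s", paste(dup, collapse = ", "))
  root <- dirname(normalizePath(path))
  for (col in grep("_path$", names(df), value = TRUE)) {
    rel <- !grepl("^(/|[A-Za-z]:)", df[[col]]) & nzchar(df[[col]])
    df[[col]][rel] <- file.path(root, df[[col]][rel])
    if (check_files) {
      missing <- df[[col]][nzchar(df[[col]]) & !file.exists(df[[col]])]
      if (length(missing) > 0)
        stopf("manifest references missing file(s): %s",
              paste(utils::head(missing, 3), collapse = ", "))
    }
  }
  df
}

#' Save a cohort manifest
#'
#' @param manifest data.frame as returned by [load_manifest()].
#' @param path output CSV (or TSV) path.
#' @return `path`, invisibly.
#' @export
save_manifest <- function(manifest, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(manifest, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Save / load a trained model bundle
#'
#' A bundle is a directory holding the model weights (an RDS blob), a JSON
#' manifest describing the model spec (name, image type, class set, grid),
#' and references to the preprocessing artifacts (gray-matter mask and
#' voxel-mean profile) in force when the model was trained.  Saving then
#' loading then saving again reproduces the weight blob byte-identically.
#'
#' @param model a trained model object from [train_binary()] or
#'   [train_multiclass()].
#' @param dir bundle directory (created if needed).
#' @return `save_bundle()` returns `dir`; `load_bundle()` returns the model
#'   object.
#' @export
save_bundle <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  strip_classes <- function(x) if (is.list(x)) lapply(x, strip_classes) else x
  meta <- strip_classes(model$spec)
  meta$n_params <- count_params(model$params)
  jsonlite::write_json(meta, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(model$params, file.path(dir, "weights.rds"), version = 2)
  if (!is.null(model$extras))
    saveRDS(model$extras, file.path(dir, "extras.rds"), version = 2)
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  jf <- file.path(dir, "bundle.json")
  wf <- file.path(dir, "weights.rds")
  if (!file.exists(jf) || !file.exists(wf))
    stopf("not a model bundle: %s", dir)
  spec <- jsonlite::read_json(jf, simplifyVector = TRUE)
  model <- list(spec = spec, params = readRDS(wf))
  ef <- file.path(dir, "extras.rds")
  if (file.exists(ef)) model$extras <- readRDS(ef)
  class(model) <- c(paste0(spec$kind, "_model"), "fdg_model")
  model
}

count_params <- function(p) {
  if (is.list(p)) sum(vapply(p, count_params, numeric(1))) else length(p)
}
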