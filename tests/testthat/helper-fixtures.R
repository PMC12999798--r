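# Shared fixtures, memoised per test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, make) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- make()
  .fixture_env[[key]]
}

# small preprocessed phantom cohort (6 subjects/class on a 32^3 grid)
tiny_cohort <- function() {
  memo("tiny_cohort", function() {
    dir <- file.path(tempdir(), "tiny_cohort")
    sc <- simulate_cohort(c(AD = 6, DLB = 6, Mixed = 6, HC = 6),
                          phantom_params(grid_shape = c(32, 32, 32),
                                         effect = 0.9, noise_sd = 5,
                                         seed = 404L),
                          dir, overwrite = TRUE)
    pp <- preprocess_cohort(sc$manifest, sc$atlas,
                            file.path(tempdir(), "tiny_pp"))
    list(manifest = pp, raw_manifest = sc$manifest, atlas = sc$atlas,
         dir = dir)
  })
}

# independent matrix-form oracle for the SRP double centering:
# V is a subjects x voxels SUVR matrix; gm is a logical voxel mask
# (subject centering runs over all voxels = the brain mask of the toy).
oracle_srp_matrix <- function(V, gm = rep(TRUE, ncol(V))) {
  L <- log(V)
  Lc <- L - rowMeans(L)              # row (subject) centering
  prof <- colMeans(Lc)               # column (voxel) means over subjects
  S <- sweep(Lc, 2, prof)
  S[, !gm] <- 0
  S
}

# toy volumes: wrap a vector of voxel values as an n x 1 x 1 volume
toy_vol <- function(values) new_volume(array(values, c(length(values), 1, 1)))
toy_mask <- function(flags) new_mask(array(flags, c(length(flags), 1, 1)))

# hand-coded oracle of the three-step ensemble prose, written against the
# decision text: all-HC votes -> HC; else multiclass DLB -> DLB; else the
# AD-vs-Mixed specialist decides.
oracle_decision <- function(votes_hc, mc, am) {
  if (votes_hc[1] && votes_hc[2] && votes_hc[3]) "HC"
  else if (mc == "DLB") "DLB"
  else if (am == "AD") "AD" else "Mixed"
}
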