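#' Three-step hierarchical ensemble
#'
#' Inference proceeds in three gated steps.  Step 1: the SUVR image goes
#' to the AD-vs-HC and Mixed-vs-HC models and the SRP image to the
#' DLB-vs-HC model; if all three vote HC the subject is HC and inference
#' stops.  Step 2: otherwise the multiclass AD/DLB/Mixed model runs; if
#' its argmax is DLB the subject is DLB and inference stops.  Step 3:
#' otherwise the AD-vs-Mixed specialist makes the final AD/Mixed call,
#' regardless of the multiclass AD/Mixed preference.
#'
#' @name ensemble
NULL

STEP1_MODELS <- c("AD.HC_suvr", "Mixed.HC_suvr", "DLB.HC_srp")
ENSEMBLE_MODELS <- c(STEP1_MODELS, "AD.DLB.Mixed_suvr.srp", "AD.Mixed_suvr")

#' The ensemble decision rule
#'
#' Pure decision logic, separated from the networks so it can be checked
#' exhaustively: (a) all three step-1 votes HC -> HC; (b) otherwise the
#' multiclass argmax; DLB is final; (c) an AD/Mixed multiclass call is
#' overridden by the AD-vs-Mixed specialist.
#'
#' @param votes_hc logical 3-vector: did each step-1 model vote HC?
#' @param multiclass_label `"AD"`, `"DLB"` or `"Mixed"`.
#' @param admixed_label `"AD"` or `"Mixed"`.
#' @return The final class label.
#' @export
ensemble_decision <- function(votes_hc, multiclass_label, admixed_label) {
  stopifnot(length(votes_hc) == 3L)
  if (all(votes_hc)) return("HC")
  if (multiclass_label == "DLB") return("DLB")
  admixed_label
}

#' Composed continuous class scores
#'
#' The hard-gated ensemble has no native continuous output; for ROC
#' analysis the step probabilities are chained:
#' `HC = prod(step-1 HC probabilities)`, `DLB = (1 - HC) * P_mc(DLB)`,
#' `AD = (1 - HC) * (1 - P_mc(DLB)) * P_am(AD)` and analogously for
#' Mixed.  When every model's probabilities sum to one, the four scores
#' sum to one.
#'
#' @param p_hc length-3 vector: each step-1 model's HC probability.
#' @param p_mc length-3 vector of multiclass probabilities (AD, DLB,
#'   Mixed).
#' @param p_am length-2 vector of AD-vs-Mixed probabilities (AD, Mixed).
#' @return Named score vector over `HC`, `AD`, `DLB`, `Mixed`.
#' @export
class_scores <- function(p_hc, p_mc, p_am) {
  ok <- function(p) all(is.finite(p)) && all(p >= -1e-9) && all(p <= 1 + 1e-9)
  if (!ok(p_hc) || !ok(p_mc) || !ok(p_am))
    stopf("probabilities must lie in [0, 1]")
  pick <- function(p, nm, i) if (!is.null(names(p)) && nm %in% names(p))
    unname(p[[nm]]) else unname(p[i])
  s_hc <- prod(p_hc)
  p_dlb <- pick(p_mc, "DLB", 2)
  rest <- 1 - s_hc
  c(HC = s_hc,
    AD = rest * (1 - p_dlb) * pick(p_am, "AD", 1),
    DLB = rest * p_dlb,
    Mixed = rest * (1 - p_dlb) * pick(p_am, "Mixed", 2))
}

#' Predict one subject with the hierarchical ensemble
#'
#' @param suvr,srp the subject's SUVR and SRP volumes.
#' @param models named model list containing `AD.HC_suvr`,
#'   `Mixed.HC_suvr`, `DLB.HC_srp`, `AD.DLB.Mixed_suvr.srp` and
#'   `AD.Mixed_suvr` (as produced by [train_all_models()]).
#' @return An `ensemble_prediction`: step-1 votes, step-2/step-3 labels
#'   (`NA` when a step never ran), the final label, and the composed
#'   4-class score vector.
#' @export
predict_subject <- function(suvr, srp, models) {
  miss <- setdiff(ENSEMBLE_MODELS, names(models))
  if (length(miss) > 0)
    stopf("missing model bundle(s): %s", paste(miss, collapse = ", "))
  s1 <- lapply(STEP1_MODELS, function(nm) {
    m <- models[[nm]]
    x <- if (m$spec$image_type == "suvr") suvr else srp
    model_probs(m, x)
  })
  names(s1) <- STEP1_MODELS
  votes_hc <- vapply(s1, function(p) names(which.max(p)) == "HC", logical(1))
  p_mc <- multiclass_probs(models[["AD.DLB.Mixed_suvr.srp"]], suvr, srp)
  p_am <- model_probs(models[["AD.Mixed_suvr"]], suvr)
  mc_label <- names(p_mc)[which.max(p_mc)]
  am_label <- names(p_am)[which.max(p_am)]
  final <- ensemble_decision(votes_hc, mc_label, am_label)
  step2 <- if (all(votes_hc)) NA_character_ else mc_label
  step3 <- if (all(votes_hc) || identical(step2, "DLB")) NA_character_ else am_label
  structure(list(
    step1_votes = votes_hc,
    step1_probs_hc = vapply(s1, function(p) unname(p[["HC"]]), numeric(1)),
    step2_label = step2, step3_label = step3, final_label = final,
    scores = class_scores(vapply(s1, function(p) unname(p[["HC"]]), numeric(1)),
                          p_mc, p_am)),
    class = "ensemble_prediction")
}

#' One-vs-rest confusion metrics
#'
#' @param tp,fn,fp,tn confusion-cell counts.
#' @return Named vector: sensitivity, specificity, PPV, NPV (each `NaN`
#'   when its denominator is zero).
#' @export
binary_metrics <- function(tp, fn, fp, tn) {
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = tp / (tp + fp), npv = tn / (tn + fn))
}

#' Evaluate the ensemble on a manifest split
#'
#' Runs [predict_subject()] over the chosen split and reports the 4x4
#' confusion matrix, one-vs-rest sensitivity/specificity/PPV/NPV per
#' class from the final hard labels, and per-class one-vs-rest AUROC from
#' the composed continuous scores.
#'
#' @param manifest preprocessed manifest.
#' @param models model list from [train_all_models()].
#' @param split which split to evaluate (default `"test"`).
#' @return List with `predictions` (per-subject data.frame),
#'   `confusion` (table, truth in rows), and `class_metrics`
#'   (data.frame; AUROC is `NA` for a class absent from the split).
#' @export
evaluate_ensemble <- function(manifest, models, split = "test") {
  rows <- which(manifest$split == split)
  if (length(rows) == 0L) stopf("split %s is empty", split)
  preds <- vector("list", length(rows))
  for (j in seq_along(rows)) {
    i <- rows[j]
    suvr <- read_volume(manifest$suvr_path[i], space = "phantom")
    srp <- read_volume(manifest$srp_path[i], space = "phantom")
    pr <- predict_subject(suvr, srp, models)
    preds[[j]] <- data.frame(
      subject_id = manifest$subject_id[i], label = manifest$label[i],
      vote_ad_hc = pr$step1_votes[1], vote_mixed_hc = pr$step1_votes[2],
      vote_dlb_hc = pr$step1_votes[3],
      step2 = pr$step2_label, step3 = pr$step3_label,
      final = pr$final_label,
      score_HC = pr$scores[["HC"]], score_AD = pr$scores[["AD"]],
      score_DLB = pr$scores[["DLB"]], score_Mixed = pr$scores[["Mixed"]],
      stringsAsFactors = FALSE)
  }
  preds <- do.call(rbind, preds)
  truth <- factor(preds$label, levels = CLASS_LABELS)
  final <- factor(preds$final, levels = CLASS_LABELS)
  confusion <- table(truth = truth, predicted = final)
  cm <- lapply(CLASS_LABELS, function(cls) {
    if (!any(truth == cls))
      return(data.frame(class = cls, n = 0L, sensitivity = NA_real_,
                        specificity = NA_real_, ppv = NA_real_,
                        npv = NA_real_, auroc = NA_real_))
    tp <- sum(truth == cls & final == cls)
    fn <- sum(truth == cls & final != cls)
    fp <- sum(truth != cls & final == cls)
    tn <- sum(truth != cls & final != cls)
    bm <- binary_metrics(tp, fn, fp, tn)
    roc <- pROC::roc(response = truth == cls,
                     predictor = preds[[paste0("score_", cls)]],
                     quiet = TRUE, direction = "<", levels = c(FALSE, TRUE))
    data.frame(class = cls, n = tp + fn, sensitivity = bm[["sensitivity"]],
               specificity = bm[["specificity"]], ppv = bm[["ppv"]],
               npv = bm[["npv"]], auroc = as.numeric(pROC::auc(roc)))
  })
  list(predictions = preds, confusion = confusion,
       class_metrics = do.call(rbind, cm))
}
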