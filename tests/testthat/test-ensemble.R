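test_that("decision table matches the hand-coded oracle over all 48 combinations", {
  votes <- expand.grid(v1 = c(TRUE, FALSE), v2 = c(TRUE, FALSE),
                       v3 = c(TRUE, FALSE))
  for (r in seq_len(nrow(votes))) {
    for (mc in c("AD", "DLB", "Mixed")) {
      for (am in c("AD", "Mixed")) {
        vh <- as.logical(votes[r, ])
        got <- ensemble_decision(vh, mc, am)
        expect_identical(got, oracle_decision(vh, mc, am),
                         label = sprintf("votes=%s mc=%s am=%s",
                                         paste(vh, collapse = ","), mc, am))
        # gate consistency: HC iff all three votes are HC
        expect_identical(got == "HC", all(vh))
      }
    }
  }
})

test_that("class scores follow the chain composition and sum to one", {
  # all step-1 HC probabilities 1 -> pure HC score
  s <- class_scores(c(1, 1, 1), c(AD = 1 / 3, DLB = 1 / 3, Mixed = 1 / 3),
                    c(AD = 0.5, Mixed = 0.5))
  expect_equal(unname(s[c("HC", "AD", "DLB", "Mixed")]), c(1, 0, 0, 0))
  # uniform probabilities: HC = 1/8, remainder split per the chain
  s2 <- class_scores(c(0.5, 0.5, 0.5), c(AD = 1 / 3, DLB = 1 / 3, Mixed = 1 / 3),
                     c(AD = 0.5, Mixed = 0.5))
  expect_equal(unname(s2[["HC"]]), 1 / 8)
  expect_equal(unname(s2[["DLB"]]), (7 / 8) * (1 / 3))
  expect_equal(unname(s2[["AD"]]), (7 / 8) * (2 / 3) * 0.5)
  expect_equal(unname(s2[["Mixed"]]), (7 / 8) * (2 / 3) * 0.5)
  # normalization identity on random probability tuples
  set.seed(21)
  for (i in 1:200) {
    p_hc <- runif(3)
    p_mc <- {x <- runif(3); x / sum(x)}
    p_am <- {x <- runif(2); x / sum(x)}
    names(p_mc) <- c("AD", "DLB", "Mixed"); names(p_am) <- c("AD", "Mixed")
    expect_equal(sum(class_scores(p_hc, p_mc, p_am)), 1, tolerance = 1e-9)
  }
  expect_error(class_scores(c(1.2, 0.5, 0.5), c(AD = 1, DLB = 0, Mixed = 0),
                            c(AD = 1, Mixed = 0)), "\\[0, 1\\]")
})

test_that("score argmax agrees with the hard decision for confident models", {
  # the chain composition only guarantees agreement when each model is
  # decisive; probe with per-model confidence >= 0.9
  set.seed(22)
  for (i in 1:300) {
    conf <- runif(6, 0.9, 1)
    vh <- runif(3) < 0.5
    p_hc <- ifelse(vh, conf[1:3], 1 - conf[1:3])
    mc <- sample(c("AD", "DLB", "Mixed"), 1)
    rest <- (1 - conf[4]) * {x <- runif(2); x / sum(x)}
    p_mc <- stats::setNames(numeric(3), c("AD", "DLB", "Mixed"))
    p_mc[mc] <- conf[4]; p_mc[setdiff(names(p_mc), mc)] <- rest
    am <- sample(c("AD", "Mixed"), 1)
    p_am <- stats::setNames(c(conf[5], 1 - conf[5]), c(am, setdiff(c("AD", "Mixed"), am)))
    s <- class_scores(p_hc, p_mc, p_am)
    expect_identical(names(which.max(s)), ensemble_decision(vh, mc, am))
  }
})

test_that("one-vs-rest confusion metrics match hand arithmetic", {
  bm <- binary_metrics(tp = 3, fn = 1, fp = 2, tn = 4)
  expect_equal(unname(bm["sensitivity"]), 0.75)
  expect_equal(unname(bm["specificity"]), 2 / 3)
  expect_equal(unname(bm["ppv"]), 0.6)
  expect_equal(unname(bm["npv"]), 0.8)
  # degenerate denominators come back NaN, not 0
  expect_true(is.nan(binary_metrics(0, 0, 2, 4)[["sensitivity"]]))
})

test_that("predict_subject composes step outputs per the gating rule", {
  fx <- tiny_cohort()
  arch <- net_arch(grid = c(32, 32, 32))
  # untrained (He-initialized) models suffice to exercise the plumbing
  mk <- function(classes, img) build_backbone(classes, img, arch, seed = 31)
  models <- list("AD.HC_suvr" = mk(c("AD", "HC"), "suvr"),
                 "Mixed.HC_suvr" = mk(c("Mixed", "HC"), "suvr"),
                 "DLB.HC_srp" = mk(c("DLB", "HC"), "srp"),
                 "AD.Mixed_suvr" = mk(c("AD", "Mixed"), "suvr"))
  ext <- lapply(seq_along(fdgensemble:::MULTICLASS_ORDER), function(i) {
    nm <- fdgensemble:::MULTICLASS_ORDER[i]
    parts <- strsplit(nm, "_")[[1]]
    build_feature_extractor(mk(strsplit(parts[1], ".", fixed = TRUE)[[1]],
                               parts[2]), seed = 40 + i)
  })
  models[["AD.DLB.Mixed_suvr.srp"]] <- build_multiclass_model(ext, seed = 50)
  suvr <- read_volume(fx$manifest$suvr_path[1], space = "phantom")
  srp <- read_volume(fx$manifest$srp_path[1], space = "phantom")
  pr <- predict_subject(suvr, srp, models)
  expect_s3_class(pr, "ensemble_prediction")
  expect_length(pr$step1_votes, 3L)
  expect_equal(sum(pr$scores), 1, tolerance = 1e-9)
  expect_identical(pr$final_label == "HC", all(pr$step1_votes))
  if (all(pr$step1_votes)) {
    expect_true(is.na(pr$step2_label))
  } else if (identical(pr$step2_label, "DLB")) {
    expect_identical(pr$final_label, "DLB")
    expect_true(is.na(pr$step3_label))
  } else {
    expect_identical(pr$final_label, pr$step3_label)
  }
  expect_error(predict_subject(suvr, srp, models[-1]), "missing model")
})
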