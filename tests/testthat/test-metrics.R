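test_that("confusion counts follow the >= cutoff convention", {
  cm <- confusion(c(3, 4), c(1, 2), 2.5)
  expect_equal(unlist(cm[c("TP", "FP", "TN", "FN")]),
               c(TP = 2L, FP = 0L, TN = 2L, FN = 0L))
  # boundary scores are called positive
  cm2 <- confusion(2.0, 2.0, 2.0)
  expect_equal(cm2$TP, 1)
  expect_equal(cm2$FP, 1)
  expect_error(confusion(numeric(0), 1, 2), "non-empty")

  set.seed(111)
  for (i in 1:50) {
    pos <- runif(sample(1:30, 1), 0, 5)
    neg <- runif(sample(1:30, 1), 0, 5)
    cut <- runif(1, 0, 5)
    cm <- confusion(pos, neg, cut)
    tp <- 0; for (p in pos) if (p >= cut) tp <- tp + 1
    tn <- 0; for (q in neg) if (q < cut) tn <- tn + 1
    expect_equal(cm$TP, tp)
    expect_equal(cm$TN, tn)
    expect_equal(cm$TP + cm$FN, length(pos))
    expect_equal(cm$TN + cm$FP, length(neg))
  }
})

test_that("diagnostic summaries reproduce the clinical worked examples", {
  # OPML vs patient normal: 40 sites per class
  d1 <- format_diagnostics(diagnostics(list(TP = 39, FN = 1, FP = 3, TN = 37)))
  expect_equal(d1$sensitivity, 97.5)
  expect_equal(d1$specificity, 92.5)
  expect_equal(d1$ppv, 0.929)
  expect_equal(d1$npv, 0.974)

  # abnormal (OPML + SCC) vs patient normal: 89 per class
  d2 <- format_diagnostics(diagnostics(list(TP = 73, FN = 16, FP = 3, TN = 86)))
  expect_equal(d2$sensitivity, 82.02)
  expect_equal(d2$specificity, 96.63)
  expect_equal(d2$ppv, 0.961)
  expect_equal(d2$npv, 0.843)

  d3 <- diagnostics(list(TP = 10, FN = 0, FP = 0, TN = 10))
  expect_equal(d3$sensitivity, 100)
  expect_equal(d3$specificity, 100)
  expect_equal(d3$ppv, 1)
  expect_equal(d3$npv, 1)
})

test_that("sensitivity identity holds exactly before rounding", {
  set.seed(112)
  for (i in 1:25) {
    cm <- list(TP = sample(0:50, 1), FN = sample(1:50, 1),
               FP = sample(1:50, 1), TN = sample(0:50, 1))
    d <- diagnostics(cm)
    expect_equal(d$sensitivity * (cm$TP + cm$FN), 100 * cm$TP)
    expect_equal(d$specificity * (cm$TN + cm$FP), 100 * cm$TN)
  }
  # division guards yield NA, not errors
  d <- diagnostics(list(TP = 0, FN = 5, FP = 0, TN = 5))
  expect_true(is.na(d$ppv))
  expect_equal(d$npv, 0.5)
})

test_that("ROC-AUC equals the pairwise win fraction and its symmetries", {
  expect_equal(roc_auc(c(3, 4), c(1, 2)), 1)
  expect_equal(roc_auc(c(1, 3), 2), 0.5)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)

  set.seed(113)
  for (i in 1:200) {
    pos <- sample(seq(0, 5, by = 0.25), sample(1:50, 1), replace = TRUE)
    neg <- sample(seq(0, 5, by = 0.25), sample(1:50, 1), replace = TRUE)
    expect_equal(roc_auc(pos, neg), oracle_auc(pos, neg))
  }

  # complement symmetry on tie-free inputs, invariance to monotone transforms
  for (i in 1:20) {
    scores <- sample(seq(1, 400), 40)
    pos <- scores[1:20]; neg <- scores[21:40]
    expect_equal(roc_auc(pos, neg) + roc_auc(neg, pos), 1)
    expect_equal(roc_auc(exp(pos / 100), exp(neg / 100)), roc_auc(pos, neg))
  }
})

test_that("ROC-AUC agrees with an established reference implementation", {
  set.seed(114)
  pos <- rlnorm(60, log(3), 0.3)
  neg <- rlnorm(80, log(1.5), 0.3)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 60), rep(0, 80)),
    predictor = c(pos, neg), quiet = TRUE
  )))
  expect_equal(roc_auc(pos, neg), ref, tolerance = 1e-12)
})

test_that("class summaries interpolate quartiles and count fence outliers", {
  s <- class_summary(c(1, 2, 3, 4, 5))
  expect_equal(s$q1, 2); expect_equal(s$median, 3); expect_equal(s$q3, 4)
  expect_equal(s$iqr, 2)
  expect_equal(s$n_above_upper_fence, 0)

  # Q1 1.27, Q3 1.82 imply IQR 0.55 (healthy-class arithmetic)
  expect_equal(1.82 - 1.27, 0.55)

  s2 <- class_summary(c(1, 1, 1, 1, 10))
  expect_equal(s2$q1, 1); expect_equal(s2$q3, 1); expect_equal(s2$iqr, 0)
  expect_equal(s2$n_above_upper_fence, 1)

  set.seed(115)
  x <- rlnorm(200, 1, 0.4)
  s3 <- class_summary(x)
  expect_lte(s3$q1, s3$median); expect_lte(s3$median, s3$q3)
  expect_equal(s3$iqr, s3$q3 - s3$q1)
  expect_lte(s3$min, s3$q1); expect_lte(s3$q3, s3$max)
  expect_equal(c(s3$q1, s3$median, s3$q3),
               unname(quantile(x, c(0.25, 0.5, 0.75))))
})

test_that("cohort evaluation matches a straight-line reimplementation", {
  coh <- generate_cohort(c(normal = 5000, OPML = 5000, SCC = 5000), seed = 16)
  cutoff <- 2.3
  rep <- evaluate_cohort(coh, cutoff, positive_labels = c("OPML", "SCC"))

  pos <- coh$score[coh$label %in% c("OPML", "SCC")]
  neg <- coh$score[coh$label == "normal"]
  expect_equal(rep$diagnostics$sensitivity, 100 * mean(pos >= cutoff))
  expect_equal(rep$diagnostics$specificity, 100 * mean(neg < cutoff))
  expect_equal(rep$diagnostics$ppv,
               sum(pos >= cutoff) / (sum(pos >= cutoff) + sum(neg >= cutoff)))
  expect_equal(rep$diagnostics$auc, oracle_auc_fast(pos, neg))
  expect_equal(nrow(rep$class_summaries), 3)
  expect_equal(rep$class_summaries$label, c("normal", "OPML", "SCC"))
  expect_equal(rep$class_summaries$median[1], median(neg))

  expect_error(evaluate_cohort(coh[coh$label == "normal", ], 2),
               "lacks a class")
  # a threshold model's normal/suspect cutoff is accepted directly
  m <- fit_model(coh)
  viamodel <- evaluate_cohort(coh, m, positive_labels = "OPML")
  expect_equal(viamodel$diagnostics$cutoff, m$t_opml)
})

test_that("perfectly separated cohorts reach ceiling metrics", {
  coh <- tibble::tibble(
    site_id = sprintf("s%02d", 1:20),
    anatomical_site = "gingiva",
    score = c(seq(1, 1.5, length.out = 10), seq(3, 4, length.out = 10)),
    label = rep(c("normal", "OPML"), each = 10),
    source = "patient"
  )
  rep <- evaluate_cohort(coh, 2.0, positive_labels = "OPML")
  expect_equal(rep$diagnostics$sensitivity, 100)
  expect_equal(rep$diagnostics$specificity, 100)
  expect_equal(rep$diagnostics$auc, 1)
})
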