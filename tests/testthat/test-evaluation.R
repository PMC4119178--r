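test_that("confusion tables count with deleterious as the positive class", {
  labs <- rep(c("deleterious", "benign"), each = 5)
  ct <- confusion_table(labs, labs)
  expect_equal(ct$fp, 0); expect_equal(ct$fn, 0)
  expect_equal(ct$tp, 5); expect_equal(ct$tn, 5)
  ct2 <- confusion_table(c("deleterious", "benign"), c("benign", "deleterious"))
  expect_equal(unlist(ct2[c("tp", "tn", "fp", "fn")]),
               c(tp = 0, tn = 0, fp = 1, fn = 1))
  # 50-row seeded fixture against an independent tally
  set.seed(61)
  truth <- sample(c("benign", "deleterious"), 50, replace = TRUE)
  pred <- sample(c("benign", "deleterious"), 50, replace = TRUE)
  ct3 <- confusion_table(truth, pred)
  expect_equal(ct3$tp, sum(truth == "deleterious" & pred == "deleterious"))
  expect_equal(ct3$tn, sum(truth == "benign" & pred == "benign"))
  expect_equal(ct3$fp, sum(truth == "benign" & pred == "deleterious"))
  expect_equal(ct3$fn, sum(truth == "deleterious" & pred == "benign"))
  expect_error(confusion_table(truth, pred[1:10]),
               class = "cypvar_alignment_error")
})

test_that("metrics reproduce published benchmark rows to two decimals", {
  m1 <- classification_metrics(new_confusion(tp = 184, tn = 55, fp = 18, fn = 13))
  expect_equal(round(m1$q2, 2), 88.52)
  expect_equal(round(m1$recall, 2), 93.40)
  expect_equal(round(m1$precision, 2), 91.09)
  expect_equal(round(m1$mcc, 2), 0.70)
  m2 <- classification_metrics(new_confusion(tp = 108, tn = 50, fp = 18, fn = 31))
  expect_equal(round(m2$q2, 2), 76.33)
  expect_equal(round(m2$mcc, 2), 0.49)
  # perfect table
  m3 <- classification_metrics(new_confusion(tp = 7, tn = 3, fp = 0, fn = 0))
  expect_equal(m3$mcc, 1); expect_equal(m3$q2, 100)
})

test_that("metric conventions: zero marginals and undefined ratios", {
  # all predictions benign: zero TP+FP marginal -> MCC 0, precision NA
  m <- classification_metrics(new_confusion(tp = 0, tn = 5, fp = 0, fn = 5))
  expect_equal(m$mcc, 0)
  expect_true(is.na(m$precision))
  # no deleterious instances at all: recall NA
  m2 <- classification_metrics(new_confusion(tp = 0, tn = 5, fp = 2, fn = 0))
  expect_true(is.na(m2$recall))
  expect_error(classification_metrics(new_confusion(0, 0, 0, 0)),
               class = "cypvar_domain_error")
})

test_that("Q2 is the prevalence-weighted mix of recall and TN-rate", {
  set.seed(62)
  for (i in 1:10) {
    truth <- sample(c("benign", "deleterious"), 40, replace = TRUE,
                    prob = c(0.3, 0.7))
    pred <- sample(c("benign", "deleterious"), 40, replace = TRUE)
    if (length(unique(truth)) < 2) next
    ct <- confusion_table(truth, pred)
    m <- classification_metrics(ct)
    prev <- (ct$tp + ct$fn) / 40
    tnr <- ct$tn / (ct$tn + ct$fp) * 100
    expect_equal(m$q2, prev * m$recall + (1 - prev) * tnr, tolerance = 1e-12)
  }
})

test_that("MCC flips sign when the true labels are swapped", {
  set.seed(63)
  truth <- sample(c("benign", "deleterious"), 60, replace = TRUE)
  pred <- sample(c("benign", "deleterious"), 60, replace = TRUE)
  m <- classification_metrics(confusion_table(truth, pred))$mcc
  swapped <- ifelse(truth == "benign", "deleterious", "benign")
  m2 <- classification_metrics(confusion_table(swapped, pred))$mcc
  expect_equal(m2, -m, tolerance = 1e-12)
})

test_that("trapezoid AUC equals the pairwise Mann-Whitney statistic", {
  set.seed(64)
  labs <- sample(c("benign", "deleterious"), 300, replace = TRUE)
  # discretized scores to force ties
  scores <- round(stats::rnorm(300, ifelse(labs == "deleterious", 0.8, 0.2),
                               0.6), 1)
  roc <- roc_curve(scores, labs)
  pos <- scores[labs == "deleterious"]; neg <- scores[labs == "benign"]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  expect_equal(roc$auc, mean(cmp), tolerance = 1e-12)
})

test_that("AUC conventions and invariances hold", {
  labs <- rep(c("benign", "deleterious"), each = 5)
  expect_equal(roc_curve(c(1:5 / 10, 6:10 / 10), labs)$auc, 1)
  expect_equal(roc_curve(rep(0.7, 10), labs)$auc, 0.5)
  # invariance under strictly monotone transforms
  set.seed(65)
  s <- stats::runif(40); l <- sample(c("benign", "deleterious"), 40,
                                     replace = TRUE)
  expect_equal(roc_curve(s, l)$auc, roc_curve(qlogis(s * 0.98 + 0.01), l)$auc,
               tolerance = 1e-12)
  expect_error(roc_curve(s, rep("benign", 40)),
               class = "cypvar_degenerate_labels")
})

test_that("AUC agrees with an independent reference implementation", {
  set.seed(66)
  labs <- sample(c("benign", "deleterious"), 120, replace = TRUE)
  scores <- stats::rnorm(120, ifelse(labs == "deleterious", 1, 0))
  ref <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(labs, scores, levels = c("benign",
                                                            "deleterious"),
                                   direction = "<"))))
  expect_equal(roc_curve(scores, labs)$auc, ref, tolerance = 1e-12)
})

test_that("cross-validation partitions correctly and is reproducible", {
  d <- simulate_dataset(sim_config(n_benign = 73, n_deleterious = 197),
                        seed = 67)
  cv <- cross_validate(d, d$label, model = "lda", seed = 5)
  # test folds partition the data
  expect_equal(sort(unlist(lapply(1:5, function(f)
    which(cv$assignments == f)))), seq_len(nrow(d)))
  # stratification: both classes in every fold
  for (f in 1:5) {
    expect_equal(sort(unique(as.character(d$label[cv$assignments == f]))),
                 c("benign", "deleterious"))
  }
  # validation subsets live inside the fold's training portion
  for (f in 1:5) {
    expect_length(intersect(cv$val_sets[[f]], which(cv$assignments == f)), 0)
    expect_equal(length(cv$val_sets[[f]]) /
                   sum(cv$assignments != f), 0.2, tolerance = 0.02)
  }
  # determinism
  cv2 <- cross_validate(d, d$label, model = "lda", seed = 5)
  expect_identical(cv$assignments, cv2$assignments)
  expect_equal(cv$folds, cv2$folds)
})

test_that("cross-validated LDA recovers a strong signal and no false one", {
  d <- simulate_dataset(sim_config(
    n_benign = 73, n_deleterious = 197,
    f_targets = stats::setNames(rep(2.5, 5), model_features())), seed = 68)
  cv <- cross_validate(d, d$label, model = "lda", seed = 7)
  expect_gte(mean(cv$folds$mcc), 0.9)
  set.seed(69)
  dp <- d; dp$label <- sample(dp$label)
  cvp <- cross_validate(dp, dp$label, model = "lda", seed = 7)
  expect_lte(abs(mean(cvp$folds$mcc)), 0.15)
})

test_that("final-model choice maximizes test MCC with the smallest val gap", {
  fake <- structure(list(
    folds = tibble::tibble(fold = 1:5,
                           mcc = c(0.5, 0.7, 0.7, 0.6, 0.4),
                           val_mcc = c(0.55, 0.72, 0.80, 0.65, 0.50)),
    models = as.list(letters[1:5])), class = "cyp_cv")
  pick <- select_final_model(fake)
  expect_equal(pick$fold, 2L)        # 0.7 test MCC, gap 0.02 beats gap 0.10
  expect_equal(pick$model, "b")
  single <- structure(list(
    folds = tibble::tibble(fold = 1, mcc = 0.3, val_mcc = 0.2),
    models = list("only")), class = "cyp_cv")
  expect_equal(select_final_model(single)$model, "only")
})

test_that("method comparison reports correlations, calls, and unanimity", {
  set.seed(70)
  n <- 80
  base <- stats::runif(n)
  tbl <- tibble::tibble(
    m1 = base,
    m2 = pmin(pmax(base + stats::rnorm(n, 0, 0.1), 0), 1),
    m3 = 1 - base)
  labs <- sample(c("benign", "deleterious"), n, replace = TRUE)
  cmp <- compare_methods(tbl, labels = labs)
  # self-comparison sanity via the duplicated-column route
  self <- compare_methods(tibble::tibble(a = base, b = base))
  expect_equal(self$correlations$r, 1)
  expect_equal(self$unanimity, 1)
  r13 <- cmp$correlations$r[cmp$correlations$method_a == "m1" &
                              cmp$correlations$method_b == "m3"]
  expect_equal(r13, -1, tolerance = 1e-12)
  # independent recomputation of calls and unanimity
  calls <- cbind(tbl$m1 >= 0.5, tbl$m2 >= 0.5, tbl$m3 >= 0.5)
  expect_equal(cmp$calls$deleterious, colSums(calls))
  expect_equal(cmp$unanimity, mean(rowSums(calls) %in% c(0, 3)))
  # missing predictions are dropped pairwise with counts reported
  tbl$m2[1:10] <- NA
  cmp2 <- compare_methods(tbl)
  n12 <- cmp2$correlations$n[cmp2$correlations$method_a == "m1" &
                               cmp2$correlations$method_b == "m2"]
  expect_equal(n12, n - 10)
})
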