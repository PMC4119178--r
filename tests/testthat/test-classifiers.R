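make_sep_data <- function(n_b = 80, n_d = 120, sep = 2.5, seed = 41) {
  cfg <- sim_config(n_benign = n_b, n_deleterious = n_d,
                    f_targets = stats::setNames(rep(sep, 5), model_features()))
  simulate_dataset(cfg, seed = seed)
}

test_that("LDA separates well-separated clouds and places a symmetric boundary", {
  d <- make_sep_data()
  m <- lda_fit(d, d$label)
  pred <- predict(m, d)
  expect_equal(as.character(pred$label), as.character(d$label))
  # mirror-symmetric 1-D data: boundary at the mirror point
  d1 <- data.frame(Abs_dSS = c(-3, -2, -1, 1, 2, 3))
  y1 <- rep(c("benign", "deleterious"), each = 3)
  m1 <- lda_fit(d1, y1, features = "Abs_dSS")
  # projected threshold corresponds to the midpoint (0 on the feature scale)
  z0 <- (0 - m1$center) / m1$scale
  expect_equal(unname(z0 * m1$w), unname(m1$threshold), tolerance = 1e-12)
})

test_that("LDA direction matches the closed-form pooled-covariance solution", {
  d <- make_sep_data(sep = 0.7, seed = 43)
  m <- lda_fit(d, d$label)
  # independent closed form on the standardized features
  X <- as.matrix(d[model_features()])
  Z <- scale(X)
  ben <- d$label == "benign"
  S <- ((sum(ben) - 1) * stats::cov(Z[ben, ]) +
          (sum(!ben) - 1) * stats::cov(Z[!ben, ])) / (nrow(Z) - 2)
  w_ref <- solve(S, colMeans(Z[!ben, ]) - colMeans(Z[ben, ]))
  cosine <- sum(m$w * w_ref) / sqrt(sum(m$w^2) * sum(w_ref^2))
  expect_gte(cosine, 1 - 1e-9)
})

test_that("LDA agrees with an independent reference implementation", {
  # equal class sizes so both implementations use a midpoint boundary
  d <- make_sep_data(n_b = 100, n_d = 100, sep = 0.7, seed = 44)
  m <- lda_fit(d, d$label)
  ref <- MASS::lda(as.matrix(scale(d[model_features()])),
                   grouping = d$label)
  w_ref <- drop(ref$scaling)
  cosine <- abs(sum(m$w * w_ref)) / sqrt(sum(m$w^2) * sum(w_ref^2))
  expect_gte(cosine, 1 - 1e-6)
  # hard calls agree
  pred_ref <- predict(ref, as.matrix(scale(d[model_features()])))$class
  expect_equal(as.character(predict(m, d)$label), as.character(pred_ref))
})

test_that("LDA is affine-equivariant: rescaling a feature leaves calls unchanged", {
  d <- make_sep_data(sep = 0.6, seed = 45)
  base <- predict(lda_fit(d, d$label), d)
  d2 <- d
  d2$predRSA <- d2$predRSA * 1000 + 7
  rescaled <- predict(lda_fit(d2, d2$label), d2)
  expect_equal(base$score, rescaled$score, tolerance = 1e-8)
})

test_that("the net solves XOR with resilient backpropagation", {
  X <- data.frame(Abs_dSS = c(0, 0, 1, 1), ss_Abs_dSize = c(0, 1, 0, 1),
                  zsEntropy21 = 0, predRSA = 0, varPredRSA21 = 0)
  y <- c("benign", "deleterious", "deleterious", "benign")
  m <- nn_fit(X, y, epochs = 1000, seed = 42)
  expect_equal(as.character(predict(m, X)$label), y)
})

test_that("the net reaches MCC 1 on a linearly separable feature set", {
  d <- make_sep_data(n_b = 70, n_d = 130, seed = 46)
  m <- nn_fit(d, d$label, epochs = 300, seed = 3)
  pred <- predict(m, d)
  ct <- confusion_table(d$label, pred$label)
  expect_equal(classification_metrics(ct)$mcc, 1)
})

test_that("training is reproducible: same seed gives identical weights", {
  d <- make_sep_data(n_b = 30, n_d = 50, seed = 47)
  m1 <- nn_fit(d, d$label, epochs = 50, seed = 9)
  m2 <- nn_fit(d, d$label, epochs = 50, seed = 9)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$b, m2$b)
  expect_identical(m1$log, m2$log)
})

test_that("resilient-backpropagation step sizes stay within their bounds", {
  d <- make_sep_data(n_b = 30, n_d = 50, seed = 48)
  m <- nn_fit(d, d$label, epochs = 120, seed = 5)
  steps <- m$log[, c("step_min", "step_max")]
  expect_true(all(steps$step_min >= 1e-6))
  expect_true(all(steps$step_max <= 50))
})

test_that("a non-finite loss is reported as divergence, never silent", {
  d <- make_sep_data(n_b = 30, n_d = 50, seed = 49)
  d$Abs_dSS[3] <- NA_real_
  expect_error(nn_fit(d, d$label, epochs = 50, seed = 2),
               "epoch", class = "cypvar_divergence_error")
})

test_that("standard backpropagation also learns the separable set", {
  d <- make_sep_data(n_b = 70, n_d = 130, seed = 55)
  m <- nn_fit(d, d$label, algorithm = "stdbp", lr = 0.2, epochs = 500,
              seed = 3)
  ct <- confusion_table(d$label, predict(m, d)$label)
  expect_gte(classification_metrics(ct)$mcc, 0.95)
})

test_that("prediction scores follow the two-output-node conventions", {
  d <- make_sep_data(n_b = 30, n_d = 50, seed = 50)
  m <- nn_fit(d, d$label, epochs = 100, seed = 4)
  pred <- predict(m, d)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  # label rule: deleterious iff score >= 0.5 (ties break deleterious)
  expect_equal(as.character(pred$label),
               ifelse(pred$score >= 0.5, "deleterious", "benign"))
  # score is monotone in the deleterious output at fixed benign output
  o_ben <- 0.3
  o_del <- seq(0, 1, by = 0.05)
  s <- o_del / (o_del + o_ben)
  expect_true(all(diff(s) > 0))
})

test_that("feature-count mismatches raise a shape error", {
  d <- make_sep_data(n_b = 30, n_d = 50, seed = 51)
  m <- nn_fit(d, d$label, epochs = 20, seed = 1)
  expect_error(predict(m, d[c("Abs_dSS", "predRSA")]),
               class = "cypvar_shape_error")
})

test_that("consensus votes match a hand tally on a fixed fixture", {
  # 20 mutations, 5 predictors; expectation from an independent vote tally
  set.seed(52)
  preds <- replicate(5, sample(c("benign", "deleterious"), 20, replace = TRUE),
                     simplify = FALSE)
  votes <- rowSums(vapply(preds, function(p) p == "deleterious", logical(20)))
  maj <- consensus(preds, mode = "majority")
  uni <- consensus(preds, mode = "union")
  expect_equal(as.character(maj),
               ifelse(votes >= 2.5, "deleterious", "benign"))
  expect_equal(as.character(uni),
               ifelse(votes > 0, "deleterious", "benign"))
  # the stated examples
  expect_equal(as.character(consensus(list(c("deleterious"), c("deleterious"),
                                           c("benign"), c("benign"),
                                           c("deleterious")))), "deleterious")
  expect_equal(as.character(consensus(list("benign", "benign", "deleterious"),
                                      mode = "union")), "deleterious")
  expect_equal(as.character(consensus(list("benign", "benign", "deleterious"),
                                      mode = "majority")), "benign")
  # even split breaks toward deleterious
  expect_equal(as.character(consensus(list("benign", "deleterious"))),
               "deleterious")
  expect_error(consensus(list(rep("benign", 3), rep("benign", 4))),
               class = "cypvar_alignment_error")
})

test_that("models survive a save/load round trip with identical predictions", {
  d <- make_sep_data(n_b = 40, n_d = 60, seed = 53)
  for (fit in list(lda_fit(d, d$label),
                   nn_fit(d, d$label, epochs = 60, seed = 8))) {
    path <- withr::local_tempfile(fileext = ".json")
    write_model(fit, path)
    back <- read_model(path)
    expect_equal(predict(back, d)$score, predict(fit, d)$score,
                 tolerance = 1e-12)
  }
})

test_that("single-class training data is refused", {
  d <- make_sep_data(n_b = 30, n_d = 50, seed = 54)
  expect_error(lda_fit(d, rep("benign", nrow(d))),
               class = "cypvar_degenerate_labels")
  expect_error(nn_fit(d, rep("deleterious", nrow(d))),
               class = "cypvar_degenerate_labels")
})
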