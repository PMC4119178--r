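# Confusion tables, accuracy metrics, ROC/AUC, the cross-validation protocol,
# final-model selection, and method-comparison reports.

#' Confusion table for binary mutation calls
#'
#' Deleterious is the positive class: benign-called-benign is TN,
#' benign-called-deleterious FP, deleterious-called-benign FN,
#' deleterious-called-deleterious TP.
#'
#' @param labels True labels (`benign`/`deleterious`).
#' @param predictions Predicted labels, aligned with `labels`.
#' @return A `confusion_table`: list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_table <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    rlang::abort("labels and predictions are not aligned",
                 class = "cypvar_alignment_error")
  }
  truth <- as_class_factor(labels) == "deleterious"
  pred <- as_class_factor(predictions) == "deleterious"
  new_confusion(tp = sum(truth & pred), tn = sum(!truth & !pred),
                fp = sum(!truth & pred), fn = sum(truth & !pred))
}

#' @rdname confusion_table
#' @param tp,tn,fp,fn Nonnegative integer counts, for building a table
#'   directly (e.g. from a published confusion matrix).
#' @export
new_confusion <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) {
    rlang::abort("confusion counts must be nonnegative",
                 class = "cypvar_domain_error")
  }
  structure(as.list(counts), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' Accuracy metrics from a confusion table
#'
#' Two-class accuracy `Q2 = (TP+TN)/total * 100`, recall `R = TP/(TP+FN) *
#' 100`, precision `P = TP/(TP+FP) * 100`, and the Matthews correlation
#' coefficient `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`.
#' A zero marginal makes the MCC 0 by convention; an undefined recall or
#' precision (zero denominator) is reported as `NA`, never silently 0.
#'
#' @param ct A [confusion_table()].
#' @param scores,labels Optional raw scores and true labels; when given, the
#'   ROC AUC is included.
#' @return A tibble with `q2`, `recall`, `precision` (percent), `mcc`, and
#'   `auc` when scores are supplied.
#' @examples
#' classification_metrics(new_confusion(tp = 184, tn = 55, fp = 18, fn = 13))
#' @export
classification_metrics <- function(ct, scores = NULL, labels = NULL) {
  tp <- ct$tp; tn <- ct$tn; fp <- ct$fp; fn <- ct$fn
  total <- tp + tn + fp + fn
  if (total == 0) rlang::abort("empty confusion table", class = "cypvar_domain_error")
  q2 <- (tp + tn) / total * 100
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn) * 100
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp) * 100
  den <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  out <- tibble::tibble(q2 = q2, recall = recall, precision = precision,
                        mcc = mcc)
  if (!is.null(scores)) out$auc <- roc_curve(scores, labels)$auc
  out
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores in descending order
#' (deleterious = positive class, called when `score >= threshold`) and
#' integrates by the trapezoid rule, which credits ties with one half — the
#' Mann-Whitney convention, so the AUC equals the probability that a random
#' deleterious score exceeds a random benign one plus half the tie
#' probability.
#'
#' @param scores Numeric prediction scores (higher = more deleterious).
#' @param labels True labels; both classes must be present.
#' @return A `cyp_roc`: list with `points` (tibble of `threshold`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  truth <- as_class_factor(labels) == "deleterious"
  if (!any(truth) || all(truth)) {
    rlang::abort("both classes must be present for a ROC curve",
                 class = "cypvar_degenerate_labels")
  }
  if (any(!is.finite(scores))) {
    rlang::abort("scores must be finite", class = "cypvar_domain_error")
  }
  np <- sum(truth); nn <- sum(!truth)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(truth & scores >= t) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(!truth & scores >= t) / nn, numeric(1))
  points <- tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fpr),
                           tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc), class = "cyp_roc")
}

#' @export
print.cyp_roc <- function(x, ...) {
  cat(sprintf("<cyp_roc> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

## ------------------------------------------------------ cross-validation ----

# Deterministic sub-seed derivation, kept within the 32-bit integer range.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)
}

# Stratified assignment of fold ids 1..k, balanced within each class.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in levels(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validate a classifier under the training protocol
#'
#' Stratified 5-fold cross-validation: each fold's test portion is held out;
#' from the remaining training portion a further stratified 20% is withdrawn
#' as a validation subset. For the neural network, `n_restarts` candidate
#' nets (differing in initialization seed) are trained per fold and the one
#' maximizing validation MCC is kept; the kept model is then evaluated on the
#' fold's test portion. The LDA has no stochastic element, so it is fit once
#' per fold and the validation subset only reports its validation MCC.
#'
#' @param data Data frame with the feature columns and one row per mutation.
#' @param labels Vector with levels `benign`/`deleterious`.
#' @param model `"nn"` or `"lda"`.
#' @param features Feature columns (default the model features in `data`).
#' @param k Number of folds (default 5).
#' @param val_frac Fraction of each training portion withdrawn for validation
#'   (default 0.2).
#' @param n_restarts Candidate nets per fold (default 10; ignored for LDA).
#' @param seed Integer seed controlling fold assignment and net
#'   initialization.
#' @param ... Passed to [nn_fit()] (e.g. `algorithm`, `epochs`, `hidden`).
#' @return A `cyp_cv` object: per-fold metrics (`folds`), `summary` (mean and
#'   sd per metric over test folds), fold assignments, and the per-fold
#'   models.
#' @export
cross_validate <- function(data, labels, model = c("nn", "lda"),
                           features = intersect(model_features(), names(data)),
                           k = 5L, val_frac = 0.2, n_restarts = 10L,
                           seed = 1L, ...) {
  model <- match.arg(model)
  y <- as_class_factor(labels)
  if (anyNA(y)) rlang::abort("all rows must be labeled", class = "cypvar_format_error")
  data <- as.data.frame(data)
  fold <- stratified_folds(y, k, seed)
  if (any(tapply(seq_along(y), list(fold, y), length) %in% c(0, NA))) {
    rlang::abort("a fold is missing a class; dataset too small to stratify",
                 class = "cypvar_stratification_error")
  }
  fold_rows <- vector("list", k)
  models <- vector("list", k)
  val_sets <- vector("list", k)
  for (f in seq_len(k)) {
    test_i <- which(fold == f)
    train_i <- which(fold != f)
    # stratified 20% of the training portion becomes the validation subset
    set.seed(sub_seed(seed, 1000L + f))
    val_i <- unlist(lapply(levels(y), function(cls) {
      cand <- train_i[y[train_i] == cls]
      sample(cand, max(1L, round(val_frac * length(cand))))
    }))
    fit_i <- setdiff(train_i, val_i)
    val_sets[[f]] <- sort(val_i)
    if (model == "lda") {
      m <- lda_fit(data[fit_i, ], y[fit_i], features = features)
      val_pred <- predict(m, data[val_i, ])
      val_mcc <- mcc_binary(y[val_i] == "deleterious",
                            val_pred$label == "deleterious")
      best <- list(model = m, val_mcc = val_mcc, restart = NA_integer_)
    } else {
      best <- list(model = NULL, val_mcc = -Inf, restart = NA_integer_)
      for (r in seq_len(n_restarts)) {
        m <- nn_fit(data[fit_i, ], y[fit_i], features = features,
                    val_data = data[val_i, ], val_labels = y[val_i],
                    seed = sub_seed(seed, f * 100L + r), ...)
        if (m$best_val_mcc > best$val_mcc) {
          best <- list(model = m, val_mcc = m$best_val_mcc, restart = r)
        }
      }
    }
    test_pred <- predict(best$model, data[test_i, ])
    ct <- confusion_table(y[test_i], test_pred$label)
    met <- classification_metrics(ct, scores = test_pred$score,
                                  labels = y[test_i])
    fold_rows[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = f, n_test = length(test_i),
                     restart = best$restart, val_mcc = best$val_mcc),
      met)
    models[[f]] <- best$model
  }
  folds <- dplyr::bind_rows(fold_rows)
  summary <- folds |>
    tidyr::pivot_longer(c("q2", "recall", "precision", "mcc", "auc"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE),
                     .groups = "drop")
  structure(list(folds = folds, summary = summary, assignments = fold,
                 val_sets = val_sets, models = models, model_type = model,
                 seed = seed),
            class = "cyp_cv")
}

#' @export
print.cyp_cv <- function(x, ...) {
  m <- x$summary[x$summary$metric == "mcc", ]
  cat(sprintf("<cyp_cv> %s, %d folds: test MCC %.3f +/- %.3f\n",
              x$model_type, nrow(x$folds), m$mean, m$sd))
  invisible(x)
}

#' @exportS3Method
tidy.cyp_cv <- function(x, ...) x$folds

#' @exportS3Method
glance.cyp_cv <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  dplyr::bind_cols(tibble::tibble(model = x$model_type, k = nrow(x$folds),
                                  seed = x$seed), wide)
}

#' Choose the final single model from a cross-validation run
#'
#' The deployed classifier is the single per-fold winner that generalizes
#' best: maximal test MCC, with ties broken by the smallest absolute gap
#' between validation and test MCC.
#'
#' @param cv A `cyp_cv` from [cross_validate()].
#' @return List with `model`, `fold`, `test_mcc`, `gap`.
#' @export
select_final_model <- function(cv) {
  test_mcc <- cv$folds$mcc
  gap <- abs(cv$folds$val_mcc - test_mcc)
  cand <- which(test_mcc == max(test_mcc))
  pick <- cand[which.min(gap[cand])]
  list(model = cv$models[[pick]], fold = pick,
       test_mcc = test_mcc[pick], gap = gap[pick])
}

## ------------------------------------------------------------ comparison ----

#' Compare score tables from several methods
#'
#' Computes pairwise Pearson correlations of raw scores (rows with a missing
#' score in either method of a pair are dropped pairwise, with the retained
#' count reported), each method's benign/deleterious call counts at the given
#' threshold, and the fraction of mutations classified unanimously by all
#' methods.
#'
#' @param scores Data frame: one row per mutation, one numeric score column
#'   per method (non-score id columns are ignored). `NA` marks a missing
#'   prediction.
#' @param labels Optional true labels; adds per-method metrics.
#' @param threshold Score threshold for the deleterious call (default 0.5).
#' @return List with `correlations` (tibble of method pairs, `r`, `n`),
#'   `calls` (per-method call counts), `unanimity` (fraction in `[0, 1]`),
#'   and `metrics` when labels are given.
#' @export
compare_methods <- function(scores, labels = NULL, threshold = 0.5) {
  scores <- as.data.frame(scores)
  methods <- names(scores)[vapply(scores, is.numeric, logical(1))]
  if (length(methods) < 2L) {
    rlang::abort("need scores from at least two methods",
                 class = "cypvar_alignment_error")
  }
  S <- as.matrix(scores[methods])
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  correlations <- purrr::map_dfr(pairs, function(p) {
    ok <- stats::complete.cases(S[, p])
    if (sum(ok) < 3L) {
      rlang::abort(sprintf("methods %s and %s share too few mutations",
                           p[1], p[2]), class = "cypvar_alignment_error")
    }
    tibble::tibble(method_a = p[1], method_b = p[2],
                   r = pearson_r(S[ok, p[1]], S[ok, p[2]]), n = sum(ok))
  })
  call_mat <- S >= threshold
  calls <- tibble::tibble(
    method = methods,
    benign = unname(colSums(!call_mat, na.rm = TRUE)),
    deleterious = unname(colSums(call_mat, na.rm = TRUE)),
    missing = unname(colSums(is.na(call_mat))))
  complete <- stats::complete.cases(S)
  unam <- mean(apply(call_mat[complete, , drop = FALSE], 1,
                     function(v) all(v) || all(!v)))
  out <- list(correlations = correlations, calls = calls, unanimity = unam)
  if (!is.null(labels)) {
    y <- as_class_factor(labels)
    out$metrics <- purrr::map_dfr(methods, function(m) {
      ok <- !is.na(S[, m])
      pred <- ifelse(S[ok, m] >= threshold, "deleterious", "benign")
      dplyr::bind_cols(tibble::tibble(method = m, n = sum(ok)),
                       classification_metrics(confusion_table(y[ok], pred),
                                              scores = S[ok, m],
                                              labels = y[ok]))
    })
  }
  out
}
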