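# F-score feature ranking with a Pearson-correlation redundancy filter.

#' F-score of a candidate feature
#'
#' Discriminatory power of one feature between the neutral (benign) and
#' deleterious classes: `|mean_n - mean_d| / (sd_n + sd_d)` with sample
#' standard deviations. The magnitude is reported. When both spreads are zero
#' the F-score is 0 for equal means and `Inf` (infinite separation) otherwise.
#'
#' @param values_neutral,values_deleterious Numeric samples of the feature in
#'   each class (each of size >= 2 for a finite result).
#' @return A single nonnegative number (possibly `Inf`).
#' @examples
#' f_score(rnorm(50, 0, 0.5), rnorm(50, 1, 0.5))  # about 1
#' @export
f_score <- function(values_neutral, values_deleterious) {
  if (length(values_neutral) == 0L || length(values_deleterious) == 0L) {
    rlang::abort("both class samples must be nonempty", class = "cypvar_domain_error")
  }
  dn <- abs(mean(values_neutral) - mean(values_deleterious))
  sp <- stats::sd(values_neutral) + stats::sd(values_deleterious)
  if (is.na(sp)) sp <- 0
  if (sp == 0) return(if (dn == 0) 0 else Inf)
  dn / sp
}

#' Pearson correlation between two feature vectors
#'
#' Standard product-moment correlation; errors on zero variance rather than
#' returning `NA` silently.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    rlang::abort("need equal-length vectors of size >= 3",
                 class = "cypvar_domain_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("correlation undefined: zero variance",
                 class = "cypvar_domain_error")
  }
  stats::cor(x, y)
}

new_feature_selection <- function(report, cor_matrix, f_min, r_max) {
  structure(list(report = report, cor_matrix = cor_matrix,
                 f_min = f_min, r_max = r_max),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  kept <- x$report$feature[x$report$kept]
  cat(sprintf("<feature_selection> %d/%d kept (F >= %g, |r| < %g): %s\n",
              length(kept), nrow(x$report), x$f_min, x$r_max,
              paste(kept, collapse = ", ")))
  invisible(x)
}

#' @exportS3Method
tidy.feature_selection <- function(x, ...) x$report

# Greedy inclusion: order candidates by descending F (ties lexicographic),
# drop those under f_min, then keep a candidate iff its max |r| against the
# already-kept set stays below r_max.
select_from_stats <- function(f, cmat, f_min, r_max) {
  ord <- order(-f, names(f))
  kept <- character(0)
  reason <- stats::setNames(rep(NA_character_, length(f)), names(f))
  keep_flag <- stats::setNames(rep(FALSE, length(f)), names(f))
  for (nm in names(f)[ord]) {
    if (f[[nm]] < f_min) { reason[nm] <- "below F-score threshold"; next }
    rs <- if (length(kept)) abs(cmat[nm, kept, drop = TRUE]) else numeric(0)
    if (length(rs) && max(rs) >= r_max) {
      reason[nm] <- paste0("redundant with ", kept[which.max(rs)])
      next
    }
    kept <- c(kept, nm); keep_flag[nm] <- TRUE
  }
  tibble::tibble(feature = names(f)[ord], f_score = unname(f[ord]),
                 kept = unname(keep_flag[ord]),
                 rank = ifelse(keep_flag[ord],
                               cumsum(keep_flag[ord]), NA_integer_),
                 reason = unname(reason[ord]))
}

#' Select features by F-score and correlation redundancy
#'
#' Implements the two inclusion criteria: a candidate must (i) discriminate
#' the classes with F-score at least `f_min` and (ii) be non-redundant —
#' absolute Pearson correlation below `r_max` — against every feature already
#' kept. Survivors are considered in descending F-score order (ties broken
#' lexicographically), so a weaker candidate is rejected in favor of the
#' stronger feature it duplicates. Every rejection carries a reason.
#'
#' @param data Data frame of candidate feature columns (one row per mutation),
#'   or a named numeric vector of precomputed F-scores (then `cor_matrix` must
#'   be supplied and `labels` is ignored).
#' @param labels Factor/character vector with levels `benign`/`deleterious`.
#' @param f_min Minimum F-score (default 0.4).
#' @param r_max Maximum absolute pairwise correlation among kept features
#'   (default 0.8).
#' @param cor_matrix Precomputed correlation matrix (candidates x candidates),
#'   required when `data` is a vector of F-scores.
#' @param within_class Compute correlations within each class and average,
#'   instead of pooled over all rows (default pooled).
#' @return A `feature_selection` object; `tidy()` returns the per-candidate
#'   report (F-score, kept flag, rank, rejection reason).
#' @export
select_features <- function(data, labels = NULL, f_min = 0.4, r_max = 0.8,
                            cor_matrix = NULL, within_class = FALSE) {
  if (is.numeric(data) && !is.null(names(data))) {
    f <- data
    if (is.null(cor_matrix)) {
      rlang::abort("cor_matrix is required with precomputed F-scores",
                   class = "cypvar_config_error")
    }
    cmat <- cor_matrix[names(f), names(f)]
  } else {
    data <- as.data.frame(data)[vapply(as.data.frame(data), is.numeric, logical(1))]
    if (ncol(data) < 2L) {
      rlang::abort("need at least two candidate features",
                   class = "cypvar_domain_error")
    }
    labels <- as.character(labels)
    if (length(unique(labels[!is.na(labels)])) < 2L) {
      rlang::abort("both classes must be present", class = "cypvar_degenerate_labels")
    }
    ben <- labels == "benign"; del <- labels == "deleterious"
    f <- vapply(data, function(col) f_score(col[ben], col[del]), numeric(1))
    if (within_class) {
      cmat <- (stats::cor(data[ben, , drop = FALSE]) +
                 stats::cor(data[del, , drop = FALSE])) / 2
    } else {
      cmat <- stats::cor(data)
    }
  }
  report <- select_from_stats(f, cmat, f_min, r_max)
  new_feature_selection(report, cmat, f_min, r_max)
}

#' Exhaustive MCC-maximizing feature-subset search
#'
#' Complements the F-score screen: evaluates every nonempty subset of the
#' candidate features by the mean test MCC of a cross-validated linear
#' discriminant, and ranks subsets by it. Practical only for small candidate
#' pools (at most 15 features, i.e. 32767 subsets).
#'
#' @param data Data frame holding the candidate feature columns.
#' @param labels Vector with levels `benign`/`deleterious`.
#' @param candidates Candidate column names (default all numeric columns).
#' @param k Folds for the inner cross-validation (default 5).
#' @param seed Seed for the fold assignment (shared across subsets, so
#'   subsets are compared on identical splits).
#' @return A tibble of subsets (comma-joined `features`, `size`, `mcc`),
#'   sorted by decreasing MCC.
#' @export
mcc_subset_search <- function(data, labels,
                              candidates = names(data)[vapply(data, is.numeric,
                                                              logical(1))],
                              k = 5L, seed = 1L) {
  if (length(candidates) > 15L) {
    rlang::abort("exhaustive search is limited to 15 candidate features",
                 class = "cypvar_config_error")
  }
  subsets <- unlist(lapply(seq_along(candidates), function(m)
    utils::combn(candidates, m, simplify = FALSE)), recursive = FALSE)
  rows <- purrr::map_dfr(subsets, function(fs) {
    cv <- cross_validate(data, labels, model = "lda", features = fs,
                         k = k, seed = seed)
    tibble::tibble(features = paste(fs, collapse = ","),
                   size = length(fs), mcc = mean(cv$folds$mcc))
  })
  dplyr::arrange(rows, dplyr::desc(.data$mcc))
}
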