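# Two-class classifiers: Fisher linear discriminant and a small feed-forward
# neural network trained by standard or resilient backpropagation.

CLASS_LEVELS <- c("benign", "deleterious")

as_class_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- !is.na(labels) & !(labels %in% CLASS_LEVELS)
  if (any(bad)) {
    rlang::abort(sprintf("unknown class label(s): %s",
                         paste(unique(labels[bad]), collapse = ", ")),
                 class = "cypvar_format_error")
  }
  factor(labels, levels = CLASS_LEVELS)
}

feature_matrix <- function(data, features) {
  data <- as.data.frame(data)
  missing <- setdiff(features, names(data))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("feature column(s) missing: %s",
                         paste(missing, collapse = ", ")),
                 class = "cypvar_shape_error")
  }
  as.matrix(data[features])
}

standardize <- function(X, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(X, 2, center, "-"), 2, scale, "/")
}

## ---------------------------------------------------------------- LDA ----

#' Fit a two-class Fisher linear discriminant
#'
#' Features are z-scaled by training-set statistics (stored in the model, so
#' the fit is equivariant to rescaling any input feature). The projection
#' direction is the Fisher solution `w = pooled_covariance^{-1} (mu_del -
#' mu_ben)`; a singular pooled covariance is regularized with a ridge of
#' `1e-6 * trace / d`. The decision threshold sits at the midpoint of the
#' projected class means, oriented so that higher scores mean deleterious.
#'
#' @param data Data frame containing the feature columns.
#' @param labels Vector with levels `benign`/`deleterious`.
#' @param features Feature column names (default the five model features
#'   present in `data`).
#' @return A `cyp_lda` model.
#' @export
lda_fit <- function(data, labels, features = intersect(model_features(),
                                                       names(data))) {
  y <- as_class_factor(labels)
  if (nlevels(droplevels(y)) < 2L) {
    rlang::abort("both classes must be present", class = "cypvar_degenerate_labels")
  }
  X <- feature_matrix(data, features)
  center <- colMeans(X); scl <- apply(X, 2, stats::sd)
  Z <- standardize(X, center, scl)
  ben <- y == "benign"; del <- y == "deleterious"
  mu_b <- colMeans(Z[ben, , drop = FALSE])
  mu_d <- colMeans(Z[del, , drop = FALSE])
  Sb <- stats::cov(Z[ben, , drop = FALSE]) * (sum(ben) - 1)
  Sd <- stats::cov(Z[del, , drop = FALSE]) * (sum(del) - 1)
  Sp <- (Sb + Sd) / (length(y) - 2)
  d <- ncol(Z)
  ridge <- 1e-6 * sum(diag(Sp)) / d
  w <- tryCatch(solve(Sp, mu_d - mu_b),
                error = function(e) solve(Sp + diag(ridge, d), mu_d - mu_b))
  proj_b <- sum(w * mu_b); proj_d <- sum(w * mu_d)
  structure(
    list(features = features, center = center, scale = scl, w = w,
         threshold = (proj_b + proj_d) / 2,
         proj_means = c(benign = proj_b, deleterious = proj_d)),
    class = "cyp_lda")
}

#' @export
print.cyp_lda <- function(x, ...) {
  cat(sprintf("<cyp_lda> %d features; projected class means %.3f (benign) / %.3f (deleterious)\n",
              length(x$features), x$proj_means[1], x$proj_means[2]))
  invisible(x)
}

#' @rdname lda_fit
#' @param object A fitted `cyp_lda`.
#' @param newdata Data frame with the model's feature columns.
#' @param threshold Decision threshold on the score (default 0.5; ties
#'   classify deleterious).
#' @param ... Unused.
#' @return For `predict`: a tibble with `score` in `(0, 1)` and `label`.
#' @export
predict.cyp_lda <- function(object, newdata, threshold = 0.5, ...) {
  X <- feature_matrix(newdata, object$features)
  Z <- standardize(X, object$center, object$scale)
  margin <- drop(Z %*% object$w) - object$threshold
  score <- stats::plogis(margin)
  tibble::tibble(score = score,
                 label = factor(ifelse(score >= threshold, "deleterious",
                                       "benign"), levels = CLASS_LEVELS))
}

#' @exportS3Method
tidy.cyp_lda <- function(x, ...) {
  tibble::tibble(term = x$features, weight = unname(x$w),
                 center = unname(x$center), scale = unname(x$scale))
}

#' @exportS3Method
glance.cyp_lda <- function(x, ...) {
  tibble::tibble(n_features = length(x$features), threshold = x$threshold,
                 separation = unname(diff(x$proj_means)))
}

## ----------------------------------------------------------------- NN ----

sigmoid <- function(z) 1 / (1 + exp(-z))

nn_init <- function(layers, seed) {
  set.seed(seed)
  W <- list(); b <- list()
  for (l in seq_len(length(layers) - 1L)) {
    W[[l]] <- matrix(stats::runif(layers[l] * layers[l + 1L], -0.5, 0.5),
                     layers[l], layers[l + 1L])
    b[[l]] <- stats::runif(layers[l + 1L], -0.5, 0.5)
  }
  list(W = W, b = b)
}

nn_forward <- function(W, b, X) {
  A <- list(X)
  for (l in seq_along(W)) {
    A[[l + 1L]] <- sigmoid(sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+"))
  }
  A
}

# Gradient of the sum-of-squares error wrt weights and biases.
nn_grad <- function(W, b, X, Tmat) {
  A <- nn_forward(W, b, X)
  L <- length(W)
  out <- A[[L + 1L]]
  delta <- 2 * (out - Tmat) * out * (1 - out)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      Al <- A[[l]]
      delta <- (delta %*% t(W[[l]])) * Al * (1 - Al)
    }
  }
  list(gW = gW, gb = gb, sse = sum((out - Tmat)^2))
}

mcc_binary <- function(truth, pred) {
  tp <- sum(truth & pred); tn <- sum(!truth & !pred)
  fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  den <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Fit the feed-forward neural network
#'
#' A fully connected net with logistic activations throughout, two output
#' nodes one-hot encoding (deleterious, benign), and sum-of-squares loss,
#' trained full-batch by either standard backpropagation (`stdbp`, fixed
#' learning rate) or resilient backpropagation (`rprop`: per-weight step
#' sizes adapted by the sign of the gradient, with constants eta+ = 1.2,
#' eta- = 0.5, initial step 0.1, bounds `[1e-6, 50]`). The default hidden
#' architecture is 10 then 5 nodes, i.e. a 5-10-5-2 net over the five model
#' features. Weights start uniform in `[-0.5, 0.5]` from `seed`; runs are
#' fully reproducible.
#'
#' When a validation set is supplied, the validation MCC is tracked every
#' epoch and the returned model is the epoch snapshot that maximized it
#' (earliest on ties); training stops early after `patience` epochs without
#' improvement.
#'
#' @param data Data frame containing the feature columns.
#' @param labels Vector with levels `benign`/`deleterious`.
#' @param features Feature column names (default the five model features).
#' @param hidden Integer vector of hidden-layer sizes (default `c(10, 5)`).
#' @param algorithm `"rprop"` (default) or `"stdbp"`.
#' @param epochs Maximum training epochs (default 300).
#' @param lr Learning rate for `stdbp` (default 0.2).
#' @param val_data,val_labels Optional validation set for snapshot selection.
#' @param patience Early-stop patience on validation MCC (default 100).
#' @param seed Integer seed for weight initialization.
#' @return A `cyp_nn` model with a per-epoch training `log` tibble.
#' @export
nn_fit <- function(data, labels, features = intersect(model_features(),
                                                      names(data)),
                   hidden = c(10L, 5L), algorithm = c("rprop", "stdbp"),
                   epochs = 300L, lr = 0.2, val_data = NULL, val_labels = NULL,
                   patience = 100L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  y <- as_class_factor(labels)
  if (nlevels(droplevels(y)) < 2L) {
    rlang::abort("both classes must be present", class = "cypvar_degenerate_labels")
  }
  X <- feature_matrix(data, features)
  center <- colMeans(X); scl <- apply(X, 2, stats::sd)
  Z <- standardize(X, center, scl)
  Tmat <- cbind(deleterious = as.numeric(y == "deleterious"),
                benign = as.numeric(y == "benign"))
  layers <- c(ncol(Z), hidden, 2L)
  net <- nn_init(layers, seed)
  W <- net$W; b <- net$b
  has_val <- !is.null(val_data)
  if (has_val) {
    Zv <- standardize(feature_matrix(val_data, features), center, scl)
    yv <- as_class_factor(val_labels) == "deleterious"
  }
  L <- length(W)
  if (algorithm == "rprop") {
    eta_p <- 1.2; eta_m <- 0.5; d0 <- 0.1; dmax <- 50; dmin <- 1e-6
    DW <- lapply(W, function(w) array(d0, dim(w)))
    Db <- lapply(b, function(v) rep(d0, length(v)))
    pW <- lapply(W, function(w) array(0, dim(w)))
    pb <- lapply(b, function(v) rep(0, length(v)))
  }
  log_rows <- vector("list", epochs)
  best <- list(W = W, b = b, mcc = -Inf, epoch = 0L)
  stale <- 0L
  for (ep in seq_len(epochs)) {
    g <- nn_grad(W, b, Z, Tmat)
    if (!is.finite(g$sse)) {
      rlang::abort(sprintf("training diverged (non-finite loss) at epoch %d", ep),
                   class = "cypvar_divergence_error")
    }
    if (algorithm == "stdbp") {
      for (l in seq_len(L)) {
        W[[l]] <- W[[l]] - lr * g$gW[[l]]
        b[[l]] <- b[[l]] - lr * g$gb[[l]]
      }
      step_rng <- c(NA_real_, NA_real_)
    } else {
      for (l in seq_len(L)) {
        sgn <- sign(g$gW[[l]] * pW[[l]])
        DW[[l]] <- pmin(pmax(
          DW[[l]] * ifelse(sgn > 0, eta_p, ifelse(sgn < 0, eta_m, 1)),
          dmin), dmax)
        gcur <- ifelse(sgn < 0, 0, g$gW[[l]])   # Rprop-: suppress after sign flip
        W[[l]] <- W[[l]] - sign(gcur) * DW[[l]]
        pW[[l]] <- gcur
        sgnb <- sign(g$gb[[l]] * pb[[l]])
        Db[[l]] <- pmin(pmax(
          Db[[l]] * ifelse(sgnb > 0, eta_p, ifelse(sgnb < 0, eta_m, 1)),
          dmin), dmax)
        gbc <- ifelse(sgnb < 0, 0, g$gb[[l]])
        b[[l]] <- b[[l]] - sign(gbc) * Db[[l]]
        pb[[l]] <- gbc
      }
      steps <- c(unlist(DW), unlist(Db))
      step_rng <- range(steps)
    }
    val_mcc <- NA_real_
    if (has_val) {
      ov <- nn_forward(W, b, Zv)[[L + 1L]]
      sc <- ov[, 1] / pmax(ov[, 1] + ov[, 2], .Machine$double.eps)
      val_mcc <- mcc_binary(yv, sc >= 0.5)
      if (val_mcc > best$mcc) {
        best <- list(W = W, b = b, mcc = val_mcc, epoch = ep)
        stale <- 0L
      } else stale <- stale + 1L
    }
    log_rows[[ep]] <- tibble::tibble(epoch = ep, sse = g$sse,
                                     step_min = step_rng[1],
                                     step_max = step_rng[2],
                                     val_mcc = val_mcc)
    if (has_val && stale >= patience) break
  }
  log <- dplyr::bind_rows(log_rows)
  if (has_val && best$epoch > 0L) { W <- best$W; b <- best$b }
  structure(
    list(features = features, layers = layers, W = W, b = b,
         center = center, scale = scl, algorithm = algorithm, seed = seed,
         log = log,
         best_val_mcc = if (has_val) best$mcc else NA_real_,
         best_epoch = if (has_val) best$epoch else nrow(log)),
    class = "cyp_nn")
}

#' @export
print.cyp_nn <- function(x, ...) {
  cat(sprintf("<cyp_nn> %s net, %s-trained, %d epochs logged\n",
              paste(x$layers, collapse = "-"), x$algorithm, nrow(x$log)))
  invisible(x)
}

#' @rdname nn_fit
#' @param object A fitted `cyp_nn`.
#' @param newdata Data frame with the model's feature columns.
#' @param threshold Decision threshold (default 0.5; ties classify
#'   deleterious).
#' @param ... Unused.
#' @return For `predict`: a tibble with `score = o_del / (o_del + o_ben)` and
#'   `label`.
#' @export
predict.cyp_nn <- function(object, newdata, threshold = 0.5, ...) {
  Z <- standardize(feature_matrix(newdata, object$features),
                   object$center, object$scale)
  out <- nn_forward(object$W, object$b, Z)[[length(object$W) + 1L]]
  tot <- out[, 1] + out[, 2]
  score <- ifelse(tot == 0, 0.5, out[, 1] / tot)
  tibble::tibble(score = score,
                 label = factor(ifelse(score >= threshold, "deleterious",
                                       "benign"), levels = CLASS_LEVELS))
}

#' @exportS3Method
tidy.cyp_nn <- function(x, ...) {
  purrr::map_dfr(seq_along(x$W), function(l) {
    tibble::tibble(layer = l, n_in = nrow(x$W[[l]]), n_out = ncol(x$W[[l]]),
                   weight_norm = sqrt(sum(x$W[[l]]^2) + sum(x$b[[l]]^2)))
  })
}

#' @exportS3Method
glance.cyp_nn <- function(x, ...) {
  tibble::tibble(architecture = paste(x$layers, collapse = "-"),
                 algorithm = x$algorithm, epochs = nrow(x$log),
                 final_sse = x$log$sse[nrow(x$log)],
                 best_val_mcc = x$best_val_mcc, seed = x$seed)
}

## ----------------------------------------------------------- consensus ----

#' Combine predictions from several models
#'
#' `majority`: deleterious when more than half the models vote deleterious;
#' even splits break toward deleterious (recall-favoring). `union`:
#' deleterious when any model votes deleterious.
#'
#' @param predictions List (length >= 2) of aligned label vectors with levels
#'   `benign`/`deleterious`.
#' @param mode `"majority"` (default) or `"union"`.
#' @return Factor of consensus labels.
#' @export
consensus <- function(predictions, mode = c("majority", "union")) {
  mode <- match.arg(mode)
  if (length(predictions) < 2L) {
    rlang::abort("need at least two predictors", class = "cypvar_domain_error")
  }
  lens <- lengths(predictions)
  if (length(unique(lens)) != 1L) {
    rlang::abort("prediction vectors are not aligned (unequal lengths)",
                 class = "cypvar_alignment_error")
  }
  votes <- vapply(predictions,
                  function(p) as.character(p) == "deleterious",
                  logical(lens[1]))
  if (lens[1] == 1L) votes <- matrix(votes, nrow = 1L)
  n_del <- rowSums(votes)
  del <- if (mode == "union") n_del > 0 else 2L * n_del >= length(predictions)
  factor(ifelse(del, "deleterious", "benign"), levels = CLASS_LEVELS)
}

## --------------------------------------------------------- persistence ----

#' Save or load a trained classifier
#'
#' Models are serialized to a self-describing JSON file holding the model
#' type, architecture, weights, standardization statistics, and provenance,
#' so a reloaded model reproduces predictions exactly.
#'
#' @param model A `cyp_lda` or `cyp_nn`.
#' @param path File path.
#' @return `write_model` returns `path` invisibly; `read_model` returns the
#'   model.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "cyp_lda")) {
    obj <- list(type = "lda", features = model$features,
                center = model$center, scale = model$scale, w = model$w,
                threshold = model$threshold, proj_means = model$proj_means)
  } else if (inherits(model, "cyp_nn")) {
    obj <- list(type = "nn", features = model$features, layers = model$layers,
                W = model$W, b = model$b, center = model$center,
                scale = model$scale, algorithm = model$algorithm,
                seed = model$seed)
  } else {
    rlang::abort("unsupported model type", class = "cypvar_shape_error")
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$type == "lda") {
    structure(list(features = obj$features,
                   center = stats::setNames(unlist(obj$center), obj$features),
                   scale = stats::setNames(unlist(obj$scale), obj$features),
                   w = stats::setNames(unlist(obj$w), obj$features),
                   threshold = obj$threshold,
                   proj_means = unlist(obj$proj_means)),
              class = "cyp_lda")
  } else if (obj$type == "nn") {
    structure(list(features = obj$features, layers = unlist(obj$layers),
                   W = lapply(obj$W, as.matrix),
                   b = lapply(obj$b, as.numeric),
                   center = stats::setNames(unlist(obj$center), obj$features),
                   scale = stats::setNames(unlist(obj$scale), obj$features),
                   algorithm = obj$algorithm, seed = obj$seed,
                   log = tibble::tibble(), best_val_mcc = NA_real_,
                   best_epoch = NA_integer_),
              class = "cyp_nn")
  } else {
    rlang::abort(sprintf("unknown model type '%s'", obj$type),
                 class = "cypvar_format_error")
  }
}
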