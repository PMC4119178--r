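# Per-position conservation and accessibility descriptors.

#' Shannon entropy of a residue distribution
#'
#' Entropy in bits of the (normalized) observed residue percentages at one
#' position: `H = -sum(p * log2(p))` over the nonzero entries. An all-zero
#' row — a position with no observed residues — returns `log2(20)`, the
#' maximal-uncertainty fallback.
#'
#' @param observed_pct Numeric vector of 20 nonnegative percentages (any
#'   positive total; normalized internally).
#' @param base Logarithm base; 2 (bits, default) or `exp(1)` (nats).
#' @return Entropy as a single number.
#' @examples
#' shannon_entropy(c(100, rep(0, 19)))   # fully conserved: 0 bits
#' shannon_entropy(rep(5, 20))           # uniform: log2(20)
#' @export
shannon_entropy <- function(observed_pct, base = 2) {
  if (any(observed_pct < 0)) {
    rlang::abort("observed percentages must be nonnegative",
                 class = "cypvar_domain_error")
  }
  tot <- sum(observed_pct)
  if (tot == 0) return(log(20, base = base))
  p <- observed_pct[observed_pct > 0] / tot
  -sum(p * log(p, base = base))
}

# Clipped window index range around `pos` for an odd window `width`.
window_range <- function(pos, n, width) {
  half <- (width - 1L) %/% 2L
  seq.int(max(1L, pos - half), min(n, pos + half))
}

#' Windowed Z-score of per-position entropy
#'
#' Standardizes each position's entropy against the mean and sample standard
#' deviation (n-1 denominator) of its surrounding window (default 21 residues,
#' center included, clipped at the termini). Windows with zero spread return a
#' Z-score of 0. The statistic is invariant to the logarithm base used for the
#' entropies, since linear rescaling cancels.
#'
#' @param entropies Numeric vector of per-position entropies.
#' @param pos Optional 1-based position(s); default all positions.
#' @param width Odd window width (default 21).
#' @param include_center Include the center residue in the window statistics
#'   (default `TRUE`).
#' @return Numeric vector of Z-scores.
#' @export
entropy_zscore <- function(entropies, pos = seq_along(entropies), width = 21L,
                           include_center = TRUE) {
  n <- length(entropies)
  if (n == 0L) rlang::abort("empty entropy track", class = "cypvar_domain_error")
  stopifnot(width >= 1L, width %% 2L == 1L)
  if (any(pos < 1L | pos > n)) {
    rlang::abort("position outside the profile", class = "cypvar_coordinate_error")
  }
  vapply(pos, function(i) {
    w <- window_range(i, n, width)
    if (!include_center) w <- setdiff(w, i)
    if (length(w) < 2L) return(0)
    mu <- mean(entropies[w]); s <- stats::sd(entropies[w])
    if (s == 0) 0 else (entropies[i] - mu) / s
  }, numeric(1))
}

#' Windowed variance of predicted RSA
#'
#' Sample variance (n-1 denominator) of the RSA values in the clipped window
#' around each position (default 21 residues, center included). Degenerate
#' windows of size 1 return 0.
#'
#' @inheritParams entropy_zscore
#' @param rsa Numeric vector of per-position RSA values in `[0, 1]`.
#' @return Numeric vector of window variances.
#' @export
rsa_window_variance <- function(rsa, pos = seq_along(rsa), width = 21L,
                                include_center = TRUE) {
  n <- length(rsa)
  if (n == 0L) rlang::abort("empty RSA track", class = "cypvar_domain_error")
  stopifnot(width >= 1L, width %% 2L == 1L)
  if (any(pos < 1L | pos > n)) {
    rlang::abort("position outside the profile", class = "cypvar_coordinate_error")
  }
  vapply(pos, function(i) {
    w <- window_range(i, n, width)
    if (!include_center) w <- setdiff(w, i)
    if (length(w) < 2L) return(0)
    stats::var(rsa[w])
  }, numeric(1))
}

#' Per-position descriptor table for a profile
#'
#' Computes, for every position of a profile: Shannon entropy of the observed
#' residue percentages (bits), its windowed Z-score, the predicted RSA, and
#' the windowed RSA variance.
#'
#' @param profile A [protein_profile()]; the RSA track may be absent, in which
#'   case the RSA columns are `NA`.
#' @param width Odd window width (default 21).
#' @param include_center Include the center residue in window statistics.
#' @return A tibble with columns `pos`, `residue`, `entropy`, `entropy_z`,
#'   `rsa`, `rsa_var`.
#' @export
position_descriptors <- function(profile, width = 21L, include_center = TRUE) {
  n <- length(profile$residues)
  ent <- vapply(seq_len(n), function(i) shannon_entropy(profile$obs_pct[i, ]),
                numeric(1))
  z <- entropy_zscore(ent, width = width, include_center = include_center)
  if (is.null(profile$rsa)) {
    rsa <- rep(NA_real_, n); rv <- rep(NA_real_, n)
  } else {
    rsa <- profile$rsa
    rv <- rsa_window_variance(rsa, width = width, include_center = include_center)
  }
  tibble::tibble(pos = seq_len(n), residue = profile$residues,
                 entropy = ent, entropy_z = z, rsa = rsa, rsa_var = rv)
}
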