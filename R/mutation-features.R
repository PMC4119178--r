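# The five-feature vector for a missense mutation.

similarity_score <- function(profile, pos, aa) {
  profile$log_odds[cbind(pos, match(aa, colnames(profile$log_odds)))]
}

#' Absolute similarity-score difference for mutations
#'
#' `|SS(pos, wt) - SS(pos, mut)|` where SS is the PSSM log-odds score. This is
#' the strongest single discriminator between benign and deleterious
#' substitutions: deleterious mutations tend to swap a favored residue for a
#' heavily penalized one.
#'
#' @param profile A [protein_profile()].
#' @param mutations Validated mutation tibble (see [validate_mutations()]).
#' @return Numeric vector of nonnegative score differences.
#' @export
abs_dss <- function(profile, mutations) {
  mutations <- validate_mutations(mutations, profile)
  abs(similarity_score(profile, mutations$pos, mutations$wt) -
        similarity_score(profile, mutations$pos, mutations$mut))
}

#' Similarity-weighted absolute size difference
#'
#' `|size(wt) - size(mut)| * |SS(wt) - SS(mut)|` with residue sizes on the
#' min-max normalized volume scale (see [aa_size_scale()]). Large physical
#' changes at positions where the profile strongly distinguishes the two
#' residues score highest. With `signed = TRUE` the weight keeps the sign of
#' the score difference.
#'
#' @inheritParams abs_dss
#' @param scale Named size scale over the 20 amino acids; defaults to the
#'   normalized volume scale.
#' @param signed Use signed `SS(wt) - SS(mut)` as the weight instead of its
#'   absolute value.
#' @return Numeric vector (nonnegative unless `signed = TRUE`).
#' @export
ss_abs_dsize <- function(profile, mutations, scale = aa_size_scale(),
                         signed = FALSE) {
  mutations <- validate_mutations(mutations, profile)
  dss <- similarity_score(profile, mutations$pos, mutations$wt) -
    similarity_score(profile, mutations$pos, mutations$mut)
  w <- if (signed) dss else abs(dss)
  unname(abs(scale[mutations$wt] - scale[mutations$mut])) * w
}

#' Feature vectors for a set of mutations
#'
#' Assembles, for each mutation, the five model features — `Abs_dSS`,
#' `ss_Abs_dSize`, `zsEntropy21`, `predRSA`, `varPredRSA21` — plus the named
#' intermediates `dSS` (signed score difference), `Entropy` (position entropy
#' in bits), and `Abs_dSize` (unweighted normalized size change). The three
#' positional features depend only on the site, so two mutations at the same
#' position share them. Column names follow the published spellings
#' regardless of the configured window width.
#'
#' @inheritParams ss_abs_dsize
#' @param width Odd window width for the entropy Z-score and RSA variance
#'   (default 21).
#' @param include_center Include the center residue in window statistics.
#' @return A tibble, one row per mutation: `protein_id`, `mutation`, `wt`,
#'   `pos`, `mut`, `label` (if present), the five features, and the
#'   intermediates.
#' @export
mutation_features <- function(profile, mutations, width = 21L,
                              include_center = TRUE, scale = aa_size_scale(),
                              signed = FALSE) {
  if (is.null(profile$rsa)) {
    rlang::abort(paste0(
      "profile ", profile$protein_id, " has no RSA track; supply a predicted ",
      "RSA file (read_rsa) and attach it with set_rsa() before computing features"),
      class = "cypvar_config_error")
  }
  mutations <- validate_mutations(mutations, profile)
  desc <- position_descriptors(profile, width = width,
                               include_center = include_center)
  at <- desc[mutations$pos, ]
  ss_wt <- similarity_score(profile, mutations$pos, mutations$wt)
  ss_mut <- similarity_score(profile, mutations$pos, mutations$mut)
  dss <- ss_wt - ss_mut
  dsize <- unname(abs(scale[mutations$wt] - scale[mutations$mut]))
  out <- tibble::tibble(
    protein_id = if ("protein_id" %in% names(mutations)) mutations$protein_id
                 else profile$protein_id,
    mutation = mutations$mutation,
    wt = mutations$wt, pos = mutations$pos, mut = mutations$mut,
    Abs_dSS = abs(dss),
    ss_Abs_dSize = dsize * (if (signed) dss else abs(dss)),
    zsEntropy21 = at$entropy_z,
    predRSA = at$rsa,
    varPredRSA21 = at$rsa_var,
    dSS = dss,
    Entropy = at$entropy,
    Abs_dSize = unname(dsize))
  if ("label" %in% names(mutations)) out$label <- mutations$label
  out
}

# The five model feature names, in the order they enter the classifiers.
MODEL_FEATURES <- c("Abs_dSS", "ss_Abs_dSize", "zsEntropy21", "predRSA",
                    "varPredRSA21")

#' Names of the five model features
#'
#' @return Character vector of the feature column names, in model order.
#' @export
model_features <- function() MODEL_FEATURES
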