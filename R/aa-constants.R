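# Amino-acid constants shared across the package.

# Column order used by NCBI ASCII PSSMs (and adopted everywhere internally).
PSSM_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Zamyatnin residue volumes (cubic angstroms). Gly is the smallest, Trp the
# largest; Leu and Ile share a volume, so Leu<->Ile substitutions carry zero
# size change by construction.
AA_VOLUME <- c(
  A = 88.6,  R = 173.4, N = 114.1, D = 111.1, C = 108.5,
  Q = 143.8, E = 138.4, G = 60.1,  H = 153.2, I = 166.7,
  L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
  S = 89.0,  T = 116.1, W = 227.8, Y = 193.6, V = 140.0
)

#' Amino-acid size scale
#'
#' Residue volumes used by the size-change feature. The raw scale is the
#' Zamyatnin volume in cubic angstroms; the normalized scale rescales it
#' min-max to `[0, 1]` (glycine = 0, tryptophan = 1) so that the
#' similarity-weighted size difference is dimensionless.
#'
#' @param normalized Return the min-max normalized copy (default) or raw
#'   volumes in cubic angstroms.
#' @return Named numeric vector over the 20 standard amino acids.
#' @examples
#' aa_size_scale()[c("G", "W")]
#' @export
aa_size_scale <- function(normalized = TRUE) {
  if (!normalized) return(AA_VOLUME)
  (AA_VOLUME - min(AA_VOLUME)) / (max(AA_VOLUME) - min(AA_VOLUME))
}

is_standard_aa <- function(x) x %in% PSSM_AA
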