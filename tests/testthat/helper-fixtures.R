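# Shared fixtures, built in code at test time.

# A hand-written 3-position ASCII PSSM in the NCBI layout. The query spells
# "MKV"; log-odds and percentages below are the ground truth the parser must
# recover (asserted against these literals, which were written first).
pssm_fixture_lines <- function() {
  aa_hdr <- paste0("           ",
                   paste(sprintf("%3s", cypvar_aa_order()), collapse = ""), " ",
                   paste(sprintf("%4s", cypvar_aa_order()), collapse = ""))
  c("",
    paste("Last position-specific scoring matrix computed, weighted observed",
          "percentages rounded down, information per position, and relative",
          "weight of gapless real matches to pseudocounts"),
    aa_hdr,
    paste("    1 M ",
          " -1 -1 -2 -3 -1  0 -2 -3 -2  1  2 -1  8  0 -2 -1 -1 -1 -1  1",
          "    0   0   0   0   0   0   0   0   0   0   0   0 100   0   0   0   0   0   0   0  0.90     0.09"),
    paste("    2 K ",
          " -1  2  0 -1 -3  1  1 -2 -1 -3 -2  5 -1 -3 -1  0 -1 -3 -2 -2",
          "    0  10   0   0   0   5   5   0   0   0   0  70   0   0   0   5   0   0   0   5  0.60     0.20"),
    paste("    3 V ",
          "  0 -3 -3 -3 -1 -2 -2 -3 -3  3  1 -2  1 -1 -2 -2  0 -3 -1  4",
          "    5   0   0   0   0   0   0   0   0  20  10   0   0   0   0   0   5   0   0  60  0.45     0.30"),
    "", "")
}

# The column order the fixture above uses (the package's PSSM order).
cypvar_aa_order <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# Hand-parsed ground truth for the fixture: position 1 log-odds row.
pssm_fixture_row1_logodds <- function() {
  stats::setNames(c(-1, -1, -2, -3, -1, 0, -2, -3, -2, 1,
                    2, -1, 8, 0, -2, -1, -1, -1, -1, 1), cypvar_aa_order())
}

# Small deterministic profile, built directly (no parsing involved):
# `conserved` positions put all mass on the query residue; others spread it.
make_test_profile <- function(n = 30, seed = 101, rsa = TRUE) {
  set.seed(seed)
  aa <- cypvar_aa_order()
  residues <- sample(aa, n, replace = TRUE)
  obs <- matrix(0, n, 20, dimnames = list(NULL, aa))
  lo <- matrix(0, n, 20, dimnames = list(NULL, aa))
  for (i in seq_len(n)) {
    p <- stats::rgamma(20, shape = 0.5)
    p[match(residues[i], aa)] <- p[match(residues[i], aa)] + 5
    p <- p / sum(p)
    obs[i, ] <- round(p * 100)
    lo[i, ] <- pmax(pmin(round(2 * log2(pmax(p, 1e-4) * 20)), 13), -10)
  }
  r <- if (rsa) round(stats::runif(n), 4) else NULL
  protein_profile("testprot", paste(residues, collapse = ""), lo, obs, rsa = r)
}

# Mutations at given positions of a profile, choosing a mutant amino acid
# different from the wild type.
make_test_mutations <- function(profile, positions, seed = 7) {
  set.seed(seed)
  aa <- cypvar_aa_order()
  purrr::map_dfr(positions, function(p) {
    wt <- profile$residues[p]
    mut <- sample(setdiff(aa, wt), 1)
    tibble::tibble(mutation = paste0(wt, p, mut), wt = wt,
                   pos = as.integer(p), mut = mut)
  })
}
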