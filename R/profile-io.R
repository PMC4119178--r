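#' Protein profile container
#'
#' Bundles the per-position information needed to score mutations on one
#' protein: the sequence, the PSSM log-odds ("similarity scores") and weighted
#' observed residue percentages, and optionally a predicted relative solvent
#' accessibility (RSA) track.
#'
#' @param protein_id Identifier for the protein.
#' @param sequence Amino-acid sequence (one-letter codes; `X` permitted).
#' @param log_odds Numeric matrix, one row per position, 20 columns named by
#'   amino acid: PSSM log-odds scores.
#' @param obs_pct Numeric matrix of the same shape: weighted observed residue
#'   percentages in `[0, 100]`.
#' @param rsa Optional numeric vector of predicted RSA values in `[0, 1]`,
#'   one per position.
#' @return An object of class `protein_profile`.
#' @export
protein_profile <- function(protein_id, sequence, log_odds, obs_pct, rsa = NULL) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L)
  residues <- strsplit(sequence, "")[[1]]
  n <- length(residues)
  bad <- !(residues %in% c(PSSM_AA, "X"))
  if (any(bad)) {
    rlang::abort(
      sprintf("non-standard residue(s) in sequence at position(s) %s",
              paste(which(bad), collapse = ", ")),
      class = "cypvar_alphabet_error")
  }
  log_odds <- as.matrix(log_odds)
  obs_pct <- as.matrix(obs_pct)
  if (nrow(log_odds) != n || nrow(obs_pct) != n) {
    rlang::abort("profile matrices must have one row per sequence position",
                 class = "cypvar_format_error")
  }
  if (ncol(log_odds) != 20L || ncol(obs_pct) != 20L ||
      !setequal(colnames(log_odds), PSSM_AA) || !setequal(colnames(obs_pct), PSSM_AA)) {
    rlang::abort("profile matrices need exactly the 20 standard amino-acid columns",
                 class = "cypvar_format_error")
  }
  log_odds <- log_odds[, PSSM_AA, drop = FALSE]
  obs_pct <- obs_pct[, PSSM_AA, drop = FALSE]
  if (any(obs_pct < 0)) {
    rlang::abort("observed percentages must be nonnegative",
                 class = "cypvar_domain_error")
  }
  if (!is.null(rsa)) {
    if (length(rsa) != n) {
      rlang::abort("RSA track length must equal sequence length",
                   class = "cypvar_format_error")
    }
    if (any(rsa < 0 | rsa > 1)) {
      rlang::abort("RSA values must lie in [0, 1]", class = "cypvar_range_error")
    }
  }
  structure(
    list(protein_id = protein_id, sequence = sequence, residues = residues,
         log_odds = log_odds, obs_pct = obs_pct, rsa = rsa),
    class = "protein_profile")
}

#' @export
print.protein_profile <- function(x, ...) {
  cat(sprintf("<protein_profile> %s: %d residues, RSA %s\n",
              x$protein_id, length(x$residues),
              if (is.null(x$rsa)) "absent" else "present"))
  invisible(x)
}

#' @export
length.protein_profile <- function(x) length(x$residues)

#' Attach a predicted RSA track to a profile
#'
#' @param profile A [protein_profile()].
#' @param rsa Numeric vector in `[0, 1]`, one value per residue.
#' @return The profile with the RSA track attached.
#' @export
set_rsa <- function(profile, rsa) {
  protein_profile(profile$protein_id, profile$sequence,
                  profile$log_odds, profile$obs_pct, rsa = rsa)
}

#' Parse an NCBI PSI-BLAST ASCII PSSM
#'
#' Reads the plain-text PSSM emitted by `psiblast -out_ascii_pssm`. The
#' column-to-amino-acid assignment is taken from the file's own header row,
#' never assumed fixed. Rows must carry the position index, the query residue,
#' 20 integer log-odds, 20 weighted observed percentages, and optionally the
#' two trailing per-position statistics.
#'
#' @param path Path to the ASCII PSSM file, or a character vector of lines via
#'   `text`.
#' @param text Optional character vector of file lines (overrides `path`).
#' @param protein_id Identifier to record; defaults to the file name.
#' @return A [protein_profile()] without an RSA track.
#' @export
read_pssm <- function(path, text = NULL, protein_id = NULL) {
  if (is.null(text) && !file.exists(path)) {
    rlang::abort(sprintf("PSSM file not found: %s", path),
                 class = "cypvar_io_error")
  }
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  if (is.null(protein_id)) {
    protein_id <- if (is.null(text)) sub("\\.[^.]*$", "", basename(path)) else "query"
  }
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  header_i <- which(vapply(toks, function(tk) {
    length(tk) == 40L && all(nchar(tk) == 1L) && all(tk %in% PSSM_AA)
  }, logical(1)))
  if (length(header_i) == 0L) {
    rlang::abort("no amino-acid header row found; not an ASCII PSSM?",
                 class = "cypvar_format_error")
  }
  header_i <- header_i[1]
  aa_lo <- toks[[header_i]][1:20]
  aa_pc <- toks[[header_i]][21:40]

  rows <- list(); residues <- character(); idx <- integer()
  for (i in seq(header_i + 1L, length(lines))) {
    tk <- toks[[i]]
    if (length(tk) == 0L) break                      # blank line ends the matrix
    if (!grepl("^[0-9]+$", tk[1])) break             # trailing K/Lambda block
    if (!(length(tk) %in% c(42L, 44L))) {
      rlang::abort(sprintf("malformed PSSM row at line %d: %d fields (expected 42 or 44)",
                           i, length(tk)),
                   class = "cypvar_parse_error")
    }
    idx <- c(idx, as.integer(tk[1]))
    residues <- c(residues, tk[2])
    rows[[length(rows) + 1L]] <- as.numeric(tk[3:42])
  }
  if (length(rows) == 0L) {
    rlang::abort("PSSM contains no data rows", class = "cypvar_format_error")
  }
  if (anyDuplicated(idx) || any(diff(idx) != 1L) || idx[1] != 1L) {
    rlang::abort("position indices must be 1..n, strictly increasing without gaps",
                 class = "cypvar_format_error")
  }
  m <- do.call(rbind, rows)
  log_odds <- m[, 1:20, drop = FALSE]; colnames(log_odds) <- aa_lo
  obs_pct <- m[, 21:40, drop = FALSE]; colnames(obs_pct) <- aa_pc
  protein_profile(protein_id, paste(residues, collapse = ""), log_odds, obs_pct)
}

#' Write a profile in NCBI ASCII PSSM layout
#'
#' Emits the same layout [read_pssm()] consumes, so profiles round-trip
#' exactly (log-odds and percentages are written as integers, matching the
#' upstream tool's output).
#'
#' @param profile A [protein_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  hdr <- paste0(
    "\nLast position-specific scoring matrix computed, weighted observed ",
    "percentages rounded down, information per position, and relative weight ",
    "of gapless real matches to pseudocounts")
  aa_line <- paste0("           ",
                    paste(sprintf("%3s", PSSM_AA), collapse = ""), " ",
                    paste(sprintf("%4s", PSSM_AA), collapse = ""))
  body <- vapply(seq_along(profile$residues), function(i) {
    paste0(sprintf("%5d %s ", i, profile$residues[i]),
           paste(sprintf("%3d", round(profile$log_odds[i, ])), collapse = " "), " ",
           paste(sprintf("%4d", round(profile$obs_pct[i, ])), collapse = " "),
           sprintf("  %4.2f %8.2f", 0, 0))
  }, character(1))
  writeLines(c(hdr, aa_line, body, ""), path)
  invisible(path)
}

#' Read a predicted RSA profile
#'
#' Accepts either a two-column table (position, value) or one value per line.
#' Values are expected in `[0, 1]`; set `scale = "percent"` for files on the
#' 0-100 scale, which are divided by 100.
#'
#' @param path File path, or lines via `text`.
#' @param text Optional character vector of lines.
#' @param scale `"fraction"` (default, values in `[0, 1]`) or `"percent"`.
#' @return Numeric vector of RSA values in `[0, 1]`.
#' @export
read_rsa <- function(path, text = NULL, scale = c("fraction", "percent")) {
  scale <- match.arg(scale)
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  nf <- lengths(toks)
  if (all(nf == 1L)) {
    vals <- as.numeric(vapply(toks, `[`, character(1), 1))
  } else if (all(nf == 2L)) {
    pos <- as.integer(vapply(toks, `[`, character(1), 1))
    vals <- as.numeric(vapply(toks, `[`, character(1), 2))[order(pos)]
    pos <- sort(pos)
    missing <- setdiff(seq_len(max(pos)), pos)
    if (length(missing) > 0L) {
      rlang::abort(sprintf("RSA profile is missing position(s) %s",
                           paste(missing, collapse = ", ")),
                   class = "cypvar_format_error")
    }
  } else {
    rlang::abort("RSA file must have one or two columns throughout",
                 class = "cypvar_format_error")
  }
  if (anyNA(vals)) {
    rlang::abort("non-numeric RSA value encountered", class = "cypvar_parse_error")
  }
  upper <- if (scale == "percent") 100 else 1
  if (any(vals < 0 | vals > upper)) {
    rlang::abort(sprintf("RSA value outside [0, %g] on the declared scale", upper),
                 class = "cypvar_range_error")
  }
  if (scale == "percent") vals <- vals / 100
  vals
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return A tibble with columns `protein_id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    return(tibble::tibble(protein_id = ids,
                          sequence = unname(as.character(ss))))
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1), collapse = "")
  tibble::tibble(protein_id = ids, sequence = unname(toupper(seqs)))
}

#' Parse mutation tokens in one-letter notation
#'
#' Accepts tokens such as `"I462V"`: wild-type residue, 1-based position,
#' mutant residue.
#'
#' @param token Character vector of mutation tokens.
#' @return A tibble with columns `mutation`, `wt`, `pos`, `mut`.
#' @examples
#' parse_mutation(c("I462V", "T297A"))
#' @export
parse_mutation <- function(token) {
  m <- regmatches(token, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", token))
  bad <- lengths(m) != 4L
  if (any(bad)) {
    rlang::abort(sprintf("cannot parse mutation token(s): %s",
                         paste(token[bad], collapse = ", ")),
                 class = "cypvar_parse_error")
  }
  wt <- toupper(vapply(m, `[`, character(1), 2))
  pos <- as.integer(vapply(m, `[`, character(1), 3))
  mut <- toupper(vapply(m, `[`, character(1), 4))
  nonstd <- !is_standard_aa(wt) | !is_standard_aa(mut)
  if (any(nonstd)) {
    rlang::abort(sprintf("non-standard amino acid in token(s): %s",
                         paste(token[nonstd], collapse = ", ")),
                 class = "cypvar_alphabet_error")
  }
  syn <- wt == mut
  if (any(syn)) {
    rlang::abort(sprintf("synonymous substitution(s) (wild type equals mutant): %s",
                         paste(token[syn], collapse = ", ")),
                 class = "cypvar_synonymous_error")
  }
  if (any(pos < 1L)) {
    rlang::abort("positions must be >= 1", class = "cypvar_coordinate_error")
  }
  tibble::tibble(mutation = token, wt = wt, pos = pos, mut = mut)
}

#' Read a mutation table
#'
#' Tab-separated file with columns `protein_id`, `mutation` (one-letter
#' token), and optionally `label` (`"benign"` or `"deleterious"`).
#'
#' @param path File path.
#' @return A tibble with `protein_id`, `mutation`, `wt`, `pos`, `mut`, and
#'   `label` (factor, `NA` when absent).
#' @export
read_mutations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("protein_id", "mutation") %in% names(df))) {
    rlang::abort("mutation table needs columns protein_id and mutation",
                 class = "cypvar_format_error")
  }
  parsed <- parse_mutation(df$mutation)
  lab <- if ("label" %in% names(df)) df$label else rep(NA_character_, nrow(df))
  bad_lab <- !is.na(lab) & !(lab %in% c("benign", "deleterious"))
  if (any(bad_lab)) {
    rlang::abort(sprintf("labels must be benign/deleterious; got: %s",
                         paste(unique(lab[bad_lab]), collapse = ", ")),
                 class = "cypvar_format_error")
  }
  tibble::tibble(protein_id = df$protein_id, parsed,
                 label = factor(lab, levels = c("benign", "deleterious")))
}

#' Validate mutations against a protein profile
#'
#' Confirms each mutation's position lies within the sequence and that the
#' recorded wild-type residue matches the profile sequence at that position.
#' Mutations at `X` positions are rejected.
#'
#' @param mutations Tibble from [parse_mutation()] or [read_mutations()].
#' @param profile A [protein_profile()].
#' @return The input tibble, unchanged, if every row validates.
#' @export
validate_mutations <- function(mutations, profile) {
  n <- length(profile$residues)
  out_of_range <- mutations$pos < 1L | mutations$pos > n
  if (any(out_of_range)) {
    rlang::abort(sprintf(
      "position(s) outside 1..%d: %s", n,
      paste(mutations$mutation[out_of_range], collapse = ", ")),
      class = "cypvar_coordinate_error")
  }
  obs <- profile$residues[mutations$pos]
  mismatch <- obs != mutations$wt
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    rlang::abort(sprintf(
      "wild-type mismatch for %s: expected %s at position %d, profile has %s",
      mutations$mutation[i], mutations$wt[i], mutations$pos[i], obs[i]),
      class = "cypvar_wt_mismatch_error")
  }
  mutations
}
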