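# Synthetic profiles, RSA tracks, and labeled mutation sets with controllable
# class structure, so every pipeline stage is testable without external
# databases.

#' Configuration for the synthetic generators
#'
#' Defaults mirror the structure of the training conditions: 197 deleterious
#' and 73 benign mutations, deleterious sites conserved and buried, benign
#' sites variable and exposed, and per-feature F-score separations of
#' 0.73/0.61/0.49/0.47/0.45 for the direct feature-level generator.
#'
#' @param length Protein length for profile-level simulation.
#' @param n_benign,n_deleterious Mutation counts per class.
#' @param conc_deleterious,conc_benign Dirichlet concentration placed on the
#'   wild-type residue at deleterious vs benign sites; larger = more
#'   conserved.
#' @param rsa_smooth Moving-average window (residues) giving the RSA track
#'   its autocorrelation.
#' @param rsa_buried,rsa_exposed Target RSA level near deleterious vs benign
#'   sites.
#' @param f_targets Named per-feature F-score targets for
#'   `simulate_dataset(mode = "features")`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(length = 600L, n_benign = 73L, n_deleterious = 197L,
                       conc_deleterious = 50, conc_benign = 0.8,
                       rsa_smooth = 10L, rsa_buried = 0.12, rsa_exposed = 0.6,
                       f_targets = c(Abs_dSS = 0.73, ss_Abs_dSize = 0.61,
                                     zsEntropy21 = 0.49, predRSA = 0.47,
                                     varPredRSA21 = 0.45)) {
  stopifnot(length >= 1L, n_benign >= 1L, n_deleterious >= 1L,
            conc_deleterious > 0, conc_benign > 0)
  structure(list(length = length, n_benign = n_benign,
                 n_deleterious = n_deleterious,
                 conc_deleterious = conc_deleterious,
                 conc_benign = conc_benign, rsa_smooth = rsa_smooth,
                 rsa_buried = rsa_buried, rsa_exposed = rsa_exposed,
                 f_targets = f_targets),
            class = "sim_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# Integer log-odds synthesized from the column distribution, mimicking the
# range of PSI-BLAST output: round(2 * log2(p / background)), clamped.
synth_log_odds <- function(p, background = 1 / 20) {
  pmax(pmin(round(2 * log2(pmax(p, 1e-4) / background)), 13), -10)
}

smooth_track <- function(x, w) {
  if (w <= 1L) return(x)
  stats::filter(x, rep(1 / w, w), sides = 2) |>
    (\(f) ifelse(is.na(f), x, f))() |> as.numeric()
}

#' Simulate a protein profile with designated mutation sites
#'
#' Draws a per-position residue distribution from a Dirichlet whose
#' concentration depends on the site class — deleterious-designated sites are
#' strongly conserved, benign-designated sites variable — converts it to
#' integer observed percentages and log-odds, and lays an autocorrelated RSA
#' track that is depressed (buried, homogeneous) around deleterious sites and
#' raised and roughened (exposed, heterogeneous) around benign sites.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the profile exactly.
#' @param protein_id Identifier for the simulated protein.
#' @return A [protein_profile()] with attributes `del_sites` and `ben_sites`
#'   (1-based positions).
#' @export
simulate_profile <- function(cfg, seed = 1L, protein_id = "synthetic") {
  set.seed(seed)
  n <- cfg$length
  if (cfg$n_benign + cfg$n_deleterious > n) {
    rlang::abort("more designated sites than sequence positions",
                 class = "cypvar_config_error")
  }
  n_sites <- cfg$n_deleterious + cfg$n_benign
  # place sites one per 21-residue cell when the protein is long enough, so
  # neighboring site windows do not collide; fall back to random placement
  n_cells <- n %/% 21L
  if (n_cells >= n_sites) {
    cells <- sample(seq_len(n_cells), n_sites)
    sites <- (cells - 1L) * 21L + 11L
  } else {
    sites <- sample(seq_len(n), n_sites)
  }
  sites <- sample(sites)
  del_sites <- sites[seq_len(cfg$n_deleterious)]
  ben_sites <- sites[-seq_len(cfg$n_deleterious)]
  site_class <- rep("background", n)
  site_class[del_sites] <- "deleterious"
  site_class[ben_sites] <- "benign"

  residues <- character(n)
  obs_pct <- matrix(0, n, 20, dimnames = list(NULL, PSSM_AA))
  log_odds <- matrix(0L, n, 20, dimnames = list(NULL, PSSM_AA))
  for (i in seq_len(n)) {
    wt <- sample(PSSM_AA, 1)
    conc <- switch(site_class[i],
                   deleterious = cfg$conc_deleterious,
                   benign = cfg$conc_benign,
                   stats::runif(1, cfg$conc_benign, cfg$conc_deleterious))
    alpha <- rep(0.3, 20)
    alpha[match(wt, PSSM_AA)] <- alpha[match(wt, PSSM_AA)] + conc
    p <- rdirichlet1(alpha)
    residues[i] <- PSSM_AA[which.max(p)]
    obs_pct[i, ] <- round(p * 100)
    log_odds[i, ] <- synth_log_odds(p)
  }

  rsa <- smooth_track(stats::runif(n), cfg$rsa_smooth)
  rsa <- 0.2 + 0.6 * (rsa - min(rsa)) / max(1e-12, diff(range(rsa)))
  # benign neighborhoods: exposed and rough; deleterious neighborhoods
  # overwritten last with a flat buried level, so their 21-residue windows
  # are homogeneous even where site windows overlap
  for (s in ben_sites) {
    w <- window_range(s, n, 21L)
    mix <- 1 - abs(w - s) / 11
    rsa[w] <- (1 - mix) * rsa[w] + mix * cfg$rsa_exposed +
      stats::rnorm(length(w), 0, 0.08)
  }
  for (s in del_sites) {
    w <- window_range(s, n, 21L)
    rsa[w] <- cfg$rsa_buried + stats::rnorm(length(w), 0, 0.01)
  }
  rsa <- pmin(pmax(rsa, 0), 1)

  prof <- protein_profile(protein_id, paste(residues, collapse = ""),
                          log_odds, obs_pct, rsa = rsa)
  attr(prof, "del_sites") <- sort(del_sites)
  attr(prof, "ben_sites") <- sort(ben_sites)
  prof
}

# Mutations placed on the designated sites: deleterious swaps the conserved
# wild type for the worst-scoring residue; benign swaps for the residue the
# profile penalizes least.
sim_mutations <- function(profile) {
  mk <- function(sites, label, pick) {
    purrr::map_dfr(sites, function(s) {
      wt <- profile$residues[s]
      cand <- setdiff(PSSM_AA, wt)
      lo <- profile$log_odds[s, cand]
      mut <- cand[pick(lo)]
      tibble::tibble(protein_id = profile$protein_id,
                     mutation = paste0(wt, s, mut),
                     wt = wt, pos = s, mut = mut,
                     label = factor(label, levels = CLASS_LEVELS))
    })
  }
  dplyr::bind_rows(
    mk(attr(profile, "del_sites"), "deleterious", which.min),
    mk(attr(profile, "ben_sites"), "benign", which.max))
}

#' Simulate a labeled mutation dataset
#'
#' Two generation paths. `mode = "features"` draws the five features directly
#' from class-conditional Gaussians with unit standard deviation and mean
#' separation `2 * F_target` per feature (so the realized F-score estimates
#' the target), with the class direction matching the observed biology:
#' deleterious mutations score higher on `Abs_dSS`/`ss_Abs_dSize` and lower
#' on `zsEntropy21`/`predRSA`/`varPredRSA21`. `mode = "profiles"` runs the
#' full path — simulate a profile, place labeled mutations on its designated
#' sites, and extract features with [mutation_features()].
#'
#' @param cfg A [sim_config()]; `cfg$f_targets` drives the feature mode.
#' @param seed Integer seed.
#' @param mode `"features"` (direct, default) or `"profiles"` (end-to-end).
#' @return A tibble with the five feature columns and `label`; in profile
#'   mode, also the mutation identity columns, and the profile as attribute
#'   `profile`.
#' @export
simulate_dataset <- function(cfg, seed = 1L, mode = c("features", "profiles")) {
  mode <- match.arg(mode)
  if (mode == "profiles") {
    prof <- simulate_profile(cfg, seed = seed)
    muts <- sim_mutations(prof)
    feats <- mutation_features(prof, muts)
    attr(feats, "profile") <- prof
    return(feats)
  }
  set.seed(seed)
  n_b <- cfg$n_benign; n_d <- cfg$n_deleterious
  dir <- c(Abs_dSS = 1, ss_Abs_dSize = 1, zsEntropy21 = -1, predRSA = -1,
           varPredRSA21 = -1)
  cols <- purrr::imap(cfg$f_targets, function(f, nm) {
    shift <- 2 * f * dir[[nm]]
    c(stats::rnorm(n_b, 0, 1), stats::rnorm(n_d, shift, 1))
  })
  out <- tibble::as_tibble(cols)
  out$label <- factor(rep(c("benign", "deleterious"), c(n_b, n_d)),
                      levels = CLASS_LEVELS)
  out
}

#' Write a simulated fixture set to disk
#'
#' Emits the files the readers consume: an ASCII PSSM, an RSA table
#' (position, value), a mutation table with labels, a FASTA sequence, and a
#' JSON manifest recording the seed and configuration.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Named list of the written file paths, invisibly.
#' @export
sim_write_dir <- function(cfg, out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prof <- simulate_profile(cfg, seed = seed)
  muts <- sim_mutations(prof)
  paths <- list(
    pssm = file.path(out_dir, "synthetic.pssm"),
    rsa = file.path(out_dir, "synthetic.rsa.tsv"),
    mutations = file.path(out_dir, "synthetic.mutations.tsv"),
    fasta = file.path(out_dir, "synthetic.fasta"),
    manifest = file.path(out_dir, "manifest.json"))
  write_pssm(prof, paths$pssm)
  writeLines(paste(seq_along(prof$rsa), sprintf("%.6f", prof$rsa), sep = "\t"),
             paths$rsa)
  utils::write.table(
    data.frame(protein_id = muts$protein_id, mutation = muts$mutation,
               label = as.character(muts$label)),
    paths$mutations, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(paste0(">", prof$protein_id), prof$sequence), paths$fasta)
  jsonlite::write_json(
    list(seed = seed, config = unclass(cfg)[setdiff(names(cfg), "f_targets")],
         f_targets = as.list(cfg$f_targets),
         n_mutations = nrow(muts)),
    paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
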