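---
title: "Classifying CYP missense mutations from sequence-derived features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying CYP missense mutations from sequence-derived features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypvar)
library(dplyr)
```

## The problem

Cytochrome P450 monooxygenases (CYPs) are a family of 57 heme-thiolate
enzymes in humans, involved in steroid and fatty-acid metabolism and in the
biotransformation of drugs and xenobiotics. Missense mutations in CYP genes
are a recurrent cause of metabolic disease, but most human CYPs have no
solved 3D structure, so structure-based effect predictors cannot be applied.
At the same time, CYPs carry highly variable substrate-recognition regions
and functionally critical surface residues (redox-partner interfaces), which
general-purpose predictors tend to misjudge.

`cypvar` classifies a missense mutation — written `I462V`: wild-type
residue, 1-based position, mutant residue — as *benign* or *deleterious*
using only sequence-derived information: a PSI-BLAST position-specific
scoring matrix (PSSM) for the protein and a per-residue predicted relative
solvent accessibility (RSA) track. Computing the RSA prediction itself is
out of scope; the package consumes an existing real-valued RSA profile in
`[0, 1]`.

## The five features

For a mutation at position $i$ replacing residue $w$ with $m$, with $S(i,a)$
the PSSM log-odds ("similarity") score of amino acid $a$ at position $i$:

* **Abs_dSS** $= |S(i,w) - S(i,m)|$. Deleterious substitutions tend to swap
  a favored residue for a heavily penalized one.
* **ss_Abs_dSize** $= |\mathrm{size}(w) - \mathrm{size}(m)| \cdot
  |S(i,w) - S(i,m)|$. Physical size change weighted by how strongly the
  profile distinguishes the two residues. Sizes are Zamyatnin residue
  volumes (cubic angstroms), min–max normalized to `[0, 1]` so the product
  is scale-free; glycine maps to 0 and tryptophan to 1, and Leu/Ile share a
  volume, so Leu↔Ile substitutions carry zero size change.
* **zsEntropy21**: the Shannon entropy (bits) of the PSSM's weighted
  observed residue percentages at $i$, standardized against the mean and
  sample standard deviation of the entropies in the surrounding 21-residue
  window. Negative values flag positions more conserved than their
  neighborhood.
* **predRSA**: the predicted RSA at $i$. Deleterious mutations concentrate
  at buried positions.
* **varPredRSA21**: the sample variance of RSA over the 21-residue window.
  Low variance indicates a homogeneous (typically buried) neighborhood.

The intermediates `dSS` (signed score difference), `Entropy`, and
`Abs_dSize` are reported alongside, because they are the named candidates
that the selection procedure weighs and, for entropy, discards.

### Windowing conventions

The window is 21 residues wide, centered on the position, and clipped at
the sequence termini (so terminal windows hold between 11 and 21
positions). The center residue is included in the window statistics:
including it keeps the statistic well defined at the termini and is the
common convention; excluding it is available via `include_center = FALSE`
since the original definition of the windowed statistics leaves this open.
Both the Z-score and the variance use the sample ($n-1$) denominator —
small clipped windows at the termini bias the population form downward.
A zero-spread window returns a Z-score of 0 by convention, and a window of
size 1 returns variance 0. The entropy Z-score is invariant to the
logarithm base of the entropy, since a linear rescaling cancels; entropies
are reported in bits.

An all-zero percentage row (a position with no observed residues) is given
the maximal entropy $\log_2 20$ rather than an error: such rows occur in
real PSSMs at positions dominated by gaps, and treating them as maximally
uncertain is the conservative choice.

### Feature naming

The feature columns keep their published spellings (`Abs_dSS`,
`ss_Abs_dSize`, `zsEntropy21`, `predRSA`, `varPredRSA21`) even if a
different window width is configured: the names are the model's contract
with downstream consumers; the width is recorded as a parameter.

### Two open choices, made explicit

The source material never states which PSSM block the "similarity score"
comes from. This package reads it as the **log-odds** block (the analogous
feature in other predictors is defined on log-odds, and log-odds is what a
profile search optimizes); both blocks are retained in the parsed profile,
so the percentage-based variant remains one line of code away. Likewise the
sign convention of the size-change weight is not stated; the default uses
$|\Delta S|$, keeping the feature nonnegative and consistent with its
one-sided empirical distribution, with the signed variant available via
`signed = TRUE`.

## Feature selection

Candidates are scored by the F-score
$$F = \frac{|\bar{x}_n - \bar{x}_d|}{\sigma_n + \sigma_d}$$
(class means and sample standard deviations over neutral and deleterious
mutations; the magnitude is reported). Selection applies two inclusion
criteria: $F \ge 0.4$, and non-redundancy $|r| < 0.8$ (Pearson) against
every feature already kept. The published account states the criteria but
not the order of application; this package reconstructs it as a greedy pass
in descending-F order (ties broken lexicographically), which reproduces
both published outcomes — the five features above are all kept (their
largest mutual correlation is $|0.73|$), and raw entropy, despite a strong
$F = 0.66$, is rejected for its $|r| = 0.82$ correlation with `Abs_dSS`.
The redundancy criterion is explicitly on $|r|$: the kept set contains
pairs with $r = -0.72$.

Degenerate cases: two identical class samples give $F = 0$; zero pooled
spread with unequal means reports `Inf` (infinite separation, always
kept). Correlations are pooled over both classes by default;
`within_class = TRUE` averages the per-class matrices instead, since the
published table does not say which was used.

## Classifiers

**LDA.** A two-class Fisher discriminant: features are z-scaled by
training-set statistics (stored in the model — this makes the fit
equivariant to any rescaling of an input feature), the direction is
$w = S_p^{-1}(\mu_d - \mu_b)$ with the pooled covariance $S_p$, and the
threshold sits at the midpoint of the projected class means. A singular
$S_p$ falls back to a ridge of $10^{-6}\,\mathrm{tr}(S_p)/d$. The reported
score is the logistic of the signed margin, so higher means more likely
deleterious.

**Neural network.** A fully connected feed-forward net, by default
5–10–5–2: five inputs, hidden layers of 10 and 5, and two output nodes
one-hot encoding (deleterious, benign). Activations are logistic
throughout, the loss is sum-of-squares, and weights initialize uniformly in
$[-0.5, 0.5]$ from a seed — the defaults of the classic simulator era this
architecture comes from, since no hyperparameters are stated in the source.
Training is full batch, by either standard backpropagation (`stdbp`, fixed
learning rate, default 0.2) or resilient backpropagation (`rprop`). Rprop
uses per-weight step sizes adapted only by the gradient's sign, with the
classic constants $\eta^+ = 1.2$, $\eta^- = 0.5$, $\Delta_0 = 0.1$,
$\Delta \in [10^{-6}, 50]$. The variant implemented has no weight
backtracking; after a sign flip the step shrinks and that weight's update
is suppressed for one epoch (the modern default, often labeled iRprop–).
The prediction score is $o_{del}/(o_{del} + o_{ben})$, with an exact-zero
sum guarded to 0.5, and ties at the 0.5 threshold classify deleterious —
a recall-favoring convention matching the method's operating point.

**Consensus.** `consensus()` combines aligned label vectors by majority
vote (even splits break deleterious) or union (any deleterious vote wins).

## Validation protocol

`cross_validate()` reproduces the training protocol: stratified 5-fold
cross-validation; within each fold a further stratified 20% of the training
portion is withdrawn as a validation subset; for the net, several
candidates (default 10 restarts, configurable — the source says only that
multiple networks were evaluated) are trained and the one with the best
validation MCC is kept and then scored on the fold's held-out test portion.
Stratification is by class — it is not stated in the source, but with only
73 negatives over 5 folds unstratified splits are unstable. Fold summary
rows report mean and standard deviation (labeled as such; the source's
"±" is not identified as sd or sem).

`select_final_model()` operationalizes "best generalization from the
validation to test subsets" as: maximal test MCC, ties broken by the
smallest $|MCC_{val} - MCC_{test}|$ gap.

Metrics follow the standard two-class definitions with deleterious as the
positive class: $Q_2$ (accuracy, %), recall, precision, and MCC, with a
zero marginal giving MCC 0 and undefined recall/precision reported as `NA`
rather than silently 0. ROC curves sweep thresholds over the unique scores;
AUC is the trapezoid integral, which equals the Mann–Whitney pairwise
statistic with half-credit for ties — the identity the tests assert to
1e-12.

## The synthetic generator

Because the original training data require external resources (curated
variant lists, profile searches against a clustered sequence database, and
an RSA predictor), the package ships a generator that emulates the
*statistical* structure of those inputs so every stage is testable:

* **Profiles** (`simulate_profile()`): per-position residue distributions
  drawn from a Dirichlet whose concentration depends on the site class —
  deleterious-designated sites strongly conserved (default concentration
  50 on the wild type), benign-designated sites variable (0.8) — converted
  to integer percentages and log-odds via
  $\mathrm{round}(2\log_2(p/0.05))$ clamped to $[-10, 13]$, mimicking the
  integer range of real PSSMs (any monotone variant would do, as the
  features use score differences). The RSA track is moving-average-smoothed
  uniform noise (window 10, so the 21-window variance is informative),
  depressed to a flat 0.12 around deleterious sites and raised to a noisy
  0.6 around benign sites. Designated sites are placed one per 21-residue
  cell when the protein is long enough, so neighboring site windows do not
  collide; deleterious neighborhoods are written last, which keeps them
  homogeneous even when windows overlap.
* **Feature-level datasets** (`simulate_dataset(mode = "features")`):
  class-conditional Gaussians with unit standard deviation and mean
  separation $2F$ per feature, so the realized F-score estimates the target
  directly; directions follow the biology (deleterious higher on the two
  score-difference features, lower on the three position features). The
  default targets are the published magnitudes 0.73/0.61/0.49/0.47/0.45 and
  the default class sizes the training composition 197 deleterious : 73
  benign.

What the generator does **not** emulate: CYP family phylogenetics, real
PSI-BLAST pseudocount structure, the error structure of a real RSA
predictor, or correlated features at the published pairwise $r$ values
(feature-level draws are independent across features). Consequently,
passing tests demonstrate that the machinery — parsing, feature algebra,
selection, training, evaluation — is correct and calibrated on data *shaped
like* the study's, not that the published headline accuracy would be
reproduced on the real datasets, which would require the external inputs
above.

## Problem sizes and determinism

The test-suite and acceptance runs use desk-scale problem sizes chosen to
exercise every code path while keeping a full run near half a minute:
training sets of 200–270 vectors (matching the study's scale), 2 × 1000 per
class for generator calibration, 3 restarts × 200 epochs per fold for the
cross-validated net, and 300 scores for the ROC oracle. All randomness
flows from explicit integer seeds; derived sub-seeds are reduced modulo
$2^{31} - 1$ so any 32-bit seed is safe, and every seeded run is
bit-reproducible.

## Worked example

```{r example}
cfg <- sim_config(length = 2000, n_benign = 30, n_deleterious = 60)
d <- simulate_dataset(cfg, seed = 42, mode = "profiles")

sel <- select_features(d[model_features()], d$label)
tidy(sel)

cv <- cross_validate(d, d$label, model = "lda", seed = 42)
glance(cv)

fit <- lda_fit(d, d$label)
pred <- predict(fit, d)
classification_metrics(confusion_table(d$label, pred$label),
                       scores = pred$score, labels = d$label)
```

```{r plots, fig.width = 6, fig.height = 4}
plot_feature_distributions(d)
autoplot(roc_curve(pred$score, d$label))
```

## Known limitations

* The package scores mutations; it does not compute RSA predictions or run
  profile searches — both are consumed as files.
* The published candidate-feature catalog beyond the five kept features and
  entropy is not reconstructible from the available text, so the optional
  exhaustive-search mode operates on whatever candidate columns the user
  supplies.
* Decision thresholds are fixed at 0.5 by default; no calibration of the
  scores is attempted.
* The greedy selection order and the final-model tie-break are documented
  reconstructions of procedures the source describes only qualitatively.
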