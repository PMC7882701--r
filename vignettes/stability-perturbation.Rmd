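---
title: "Evaluating protein stability perturbation as a pathogenicity signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating protein stability perturbation as a pathogenicity signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A missense variant changes one amino acid, and computational stability
predictors (FoldX, INPS3D, Rosetta, PoPMuSiC, and friends) estimate the
resulting change in folding free energy, ddG, in kcal/mol. The magnitude
of that change — |ddG|, the stability *perturbation*, regardless of
whether the protein becomes less or more stable — carries information
about pathogenicity: pathogenic missense variants tend to perturb
stability more than benign ones. `ddgpath` implements the statistical
machinery to quantify that signal and, in particular, to ask whether it
is stronger in genes with particular inheritance mechanisms.

The biological motivation: in a haploinsufficient (HI) gene, losing the
function of a single allele is enough to cause disease. A variant that
destabilizes the protein enough to unfold or degrade it is effectively a
loss-of-function allele, so in HI genes stability perturbation should be
close to the pathogenic mechanism itself. In dominant genes acting
through gain-of-function, or in recessive genes where one working copy
suffices, the link should be weaker.

## The evaluation model

**Scores.** All analyses use |ddG|. Because tools disagree on sign
conventions (some report destabilization as positive ddG, some as
negative), the data model carries a per-predictor convention and
`harmonize_signs()` maps everything to positive-means-destabilizing
before any analysis. Harmonization never changes |ddG|.

**Balanced AUC.** The discriminative power of a score is its ROC AUC:
the probability that a randomly chosen pathogenic variant outscores a
randomly chosen benign one, ties counted half. This equals the
Mann-Whitney statistic divided by `n_pos * n_neg`, which is how
`roc_auc()` computes it. Real variant sets are heavily imbalanced
(benign variants dominate), so the AUC and all precision estimates are
averaged over balanced replicates: each replicate keeps every
minority-class record and draws an equal-sized subset of the majority
class without replacement (100 replicates by default). Subsampling the
*majority* class rather than specifically the benign class keeps the
procedure well-defined in strata where pathogenic variants happen to
dominate. Records missing a predictor's score are removed *before* the
replicate plan is built, so every replicate is exactly balanced among
scored records.

**Strata.** The procedure runs on the full dataset, per gene, and per
gene group with its complement. Gene groups come from three curated
lists (haploinsufficient, autosomal dominant, autosomal recessive) via
boolean flags; the canonical predicates are HI = `is_hi`,
dominant-not-HI = `is_ad & !is_hi` (HI takes precedence, making the two
disjoint), and recessive = `is_ar`. A gene on no list belongs only to
complements.

**Group comparison.** Whether a predictor performs differently in a
group than in its complement is tested by a two-sided Mann-Whitney U
test. The default comparison unit is the per-gene mean balanced AUC:
genes are the exchangeable units. The alternative unit — per-replicate
AUCs of the pooled group versus pooled complement — is available
(`comparison_unit = "per_rep_auc"`) but is anticonservative, because
replicates of one stratum share most of their records and are strongly
dependent; it is provided for sensitivity analysis only. p-values are
exact (permutation null) for combined samples up to 16 without ties,
else normal approximation with tie and continuity corrections. No
multiple-testing correction is applied; the manifest records how many
tests were run so readers can adjust.

**Enrichment curves.** For a grid of thresholds t (default 0 to the
stratum maximum in steps of 0.1 kcal/mol), the precision (positive
predictive value) is the fraction of variants with |ddG| >= t that are
pathogenic. "Above" is a closed bound (>= t), so a score exactly at the
threshold counts. On balanced replicates the precision at t = 0 is the
balanced prevalence, exactly 0.5, which anchors the curves. Replicates
where nothing reaches t contribute nothing; grid points unsupported in
every replicate are dropped rather than zero-filled.
`threshold_for_precision()` returns the smallest grid threshold whose
estimated precision reaches a target with a minimum support, or `NULL`
when the target is unreachable — reaching, say, 96% precision turns a
stability predictor into a highly specific (not sensitive)
pathogenicity test. A balanced curve answers "how enriched are
pathogenic variants above t once class imbalance is removed"; the
`balanced = FALSE` mode gives the raw PPV on the observed imbalance,
which is the operationally relevant number for a screening use but
depends on the benign:pathogenic ratio of the input.

**Consensus predictors.** `add_consensus()` averages member |ddG|
values into a pseudo-predictor (e.g. the mean of FoldX and INPS3D
perturbations). Averaging absolute rather than signed values is the
default: it is invariant to member sign conventions and matches the
interpretation of |ddG| as perturbation; a signed mean is available
behind `signed = TRUE` for sensitivity analysis, since with few
stabilizing variants the two differ little. A consensus value is
missing whenever *any* member is missing — the alternative
(mean-of-available) would silently change the effective predictor's
composition across records and make its AUC incomparable.

**Destabilizing-only analyses.** `destabilizing_subset()` restricts to
records with harmonized ddG strictly greater than 0 for the evaluated
predictor (0 counts as non-destabilizing; "destabilizing" is judged per
evaluated predictor, not by a consensus). The pipeline repeats the
ranking, group and enrichment analyses on these subsets.

## The synthetic world

Real inputs for this kind of analysis are an external benchmark of
13 predictors on 13,508 missense variants from 100 disease genes plus
curated inheritance gene lists, none of which is redistributed here. The
generator `generate_dataset()` produces datasets with the statistical
structure the analysis assumes, so every stage is testable offline:

- Genes carry a mode (`hi`, `ad_only`, `ar`, `unlisted`); each variant
  draws a latent true |ddG| from a non-negative class law. Benign:
  Gamma(shape 1, scale 1 kcal/mol), i.e. Exponential(1). Pathogenic: the
  same family with scale multiplied by `1 + delta[mode]`.
- The mode effect sizes default to `delta = 2` for HI genes and `0.5`
  elsewhere. With exponential laws the population AUC is
  `scale_path / (scale_path + scale_benign)`, so these defaults put the
  HI stratum at AUC 0.75 and the others at 0.60 — a strong-versus-weak
  contrast of the kind the analysis is meant to detect, while staying
  far from perfect separation.
- Each predictor observes `w * latent + (1 - w) * independent_draw +
  Gaussian noise`, truncated below at 0, capped at its output cap if it
  has one, reported with its sign convention, and masked missing at its
  missing rate. The shared-latent weight `w` is what makes predictors
  mutually correlated, emulating the observed similarity of ddG tools
  without modelling tool internals.
- A small fraction of variants (10% by default) is reported with
  stabilizing (negative harmonized) sign; |ddG|-based analyses are
  unaffected, but the destabilizing-only filter and sign plumbing get
  exercised.
- Seed discipline: one master seed; every gene and every predictor gets
  a deterministically derived substream (`derive_seed()`), so adding a
  predictor never changes existing columns and any stratum can be
  recomputed in isolation bit-identically.

`emulate_paper_shape()` fixes the per-mode pathogenic/benign counts to
the published benchmark's marginals (13,508 variants; 3,338/10,170;
1,217/1,252 HI, 753/1,819 dominant, 635/4,253 recessive, remainder
unlisted; 100 genes) with synthetic scores, giving a realistic-scale
fixture for end-to-end runs.

What a green test on synthetic data does *not* establish: anything
about real predictors' error structure (noise here is Gaussian and
mode-independent), about gene-level heterogeneity beyond the mode
effect (all genes of a mode share one effect size), about the realism
of the exponential/gamma perturbation scale, or about the correctness
of the shipped sign-convention map. That map
(`inst/extdata/predictor_conventions.yaml`) is an editable placeholder:
tool sign conventions and caps must be verified against actual tool
output before analysing real data.

## Numerical and design choices

- AUC ties get exactly 0.5 credit via midranks; no jitter is applied.
- The threshold grid defaults to steps of 0.1 kcal/mol from 0; the
  finder reports the smallest qualifying grid point. Estimating a
  crossing point from a noisy monotone curve by first passage is biased
  low by roughly the precision SE divided by the curve slope; with a
  few hundred supporting records near a high-precision crossing that
  bias can exceed one grid step, so reported thresholds should be read
  with that uncertainty in mind (the acceptance tests quantify it
  explicitly).
- Equal-sized classes leave the balanced resampler no freedom: every
  replicate is the full stratum, the replicate SD is exactly 0 and the
  balanced AUC equals the plain AUC. This identity is tested.
- Per-gene AUCs skip genes with fewer than `min_per_class` (default 1)
  scored records in either class and report them in a skip list; the
  upstream benchmark already guaranteed 10+ pathogenic variants per
  protein, and that filter is deliberately not re-imposed.
- Undefined strata (a class empty after filtering) signal a typed
  condition; group/complement analyses report the affected side as
  undefined and continue with the other.
- Gene symbols are uppercased and trimmed, nothing more; alias
  resolution would drag in an external annotation dependency and is out
  of scope. `variant_id` is opaque; protein positions are never
  interpreted.
- Labels outside the configured vocabulary are hard errors rather than
  silent drops, because a silently dropped class biases every
  downstream estimate.

## Limitations

- The Mann-Whitney exact path is limited to combined n of 16; beyond
  that the normal approximation is used (with tie and continuity
  corrections), which is standard but approximate.
- Precision curves at high thresholds rest on few records; the support
  column (`n_above`) must be consulted before trusting a point, and
  `min_support` guards the threshold finder for exactly this reason.
- The pipeline evaluates unfitted scores; there is no training, hence
  no cross-validation, and no calibration of ddG scales across tools.
- Figures are conveniences mirroring the tables, not publication
  graphics.
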