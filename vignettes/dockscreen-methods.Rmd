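---
title: "Evaluating and triaging structure-based virtual screens with dockscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and triaging structure-based virtual screens with dockscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockscreen)
```

## The problem

Predicted protein structures — from homology modeling or from machine
learning — are increasingly used as docking targets when no experimental
structure exists. Before committing to a multi-million-compound
prospective screen against such a model, one wants to know whether the
model's binding site can *enrich* known ligands over matched non-binders,
and afterwards one needs a reproducible way to turn a ranked library into
a short, chemically diverse candidate list and to score the outcome of
the experimental follow-up. `dockscreen` implements that evaluation and
triage arithmetic end to end:

1. **Retrospective evaluation** — ROC construction, adjusted
   semilogarithmic LogAUC, enrichment factors, ensemble summaries, and
   percentile-based model selection.
2. **Decoy generation** — property-matched decoys with a topological
   dissimilarity exclusion.
3. **Prospective triage** — ensemble best-score ranking, interference
   (PAINS) and known-ligand similarity filters, leader clustering,
   candidate export.
4. **Hit statistics** — hit rates (plain and overlap-adjusted), top-k
   list overlap, potency summaries, response normalisation, pre-pulse
   inhibition, and brain-penetrance AUC ratios.
5. **Structural comparison** — per-region Kabsch superposition and
   symmetry-corrected RMSD.

A synthetic-data generator with known ground truth (`sim_score_matrix()`,
`sim_compound_library()`, `sim_toy_structures()`,
`sim_assay_fixtures()`) makes every stage testable without any external
download.

Scores follow the docking-energy convention everywhere: **lower is
better**. Missing scores (compounds that failed to dock) are `NA`; the
missingness mask is `is.na()` on the score matrix, never a numeric
sentinel.

## Adjusted LogAUC

Early enrichment is what matters in virtual screening: only the extreme
top of a ranked multi-million-compound library is ever inspected. The
ordinary ROC AUC is dominated by the bulk of the curve, so the package
uses the adjusted, semilogarithmic LogAUC: the area under TPR as a
function of $\log_{10}$ FPR over $[\lambda, 1]$, normalised by
$\log_{10}(1/\lambda)$, expressed in percent, minus the same quantity
for the random classifier. Random ranking therefore scores 0; a perfect
ROC scores $100 - 100\,(1-\lambda)/(\ln 10 \cdot \log_{10}(1/\lambda))
= 85.54$ at the default $\lambda = 0.001$, and the metric is bounded
below by $-14.46$.

Numerical choices, fixed once and asserted in tests:

* The empirical ROC has one vertex per distinct score (ties form a
  single threshold group and contribute a diagonal segment).
* TPR at FPR $=\lambda$ is obtained by linear interpolation in FPR;
  vertices below $\lambda$ are then dropped.
* The semilog integral is computed **exactly**: between vertices TPR is
  linear in FPR, and $\int (a + bx)\,\mathrm d \log_{10} x$ has the
  closed form $(a \ln(x_2/x_1) + b(x_2 - x_1))/\ln 10$. No quadrature
  grid is involved, the two-point diagonal ROC scores exactly 0, and
  the value is invariant under strictly monotone score transforms.
* $\lambda$ is exposed as a parameter (`lambda_low`); 0.001 is the
  conventional default for benchmark sets of ~$10^4$ decoys.

The enrichment factor at fraction $f$ is
$\mathrm{EF}_f = (\text{actives in top } \lceil fN\rceil / \text{total
actives})/f$ with $N$ the number of docked (non-missing) compounds. The
ceiling guarantees a non-empty top set for any $f > 0$; ranking ties are
broken by compound id so EF at a boundary is deterministic. EF = 1 is
the random expectation, $1/f$ the maximum.

```{r logauc-example}
m <- sim_score_matrix(n_models = 10, n_actives = 100, n_decoys = 6500,
                      separation = seq(0, 2, length.out = 10),
                      noise_sd = 1, seed = 1)
ens <- evaluate_ensemble(m, lambda_low = 0.001, fractions = 0.01)
summary(ens)
```

## Model selection

The *p*-th-percentile subset of an ensemble of $n$ models is defined by
nearest rank as the top $\lceil(1 - p/100)\,n\rceil$ models by LogAUC —
a convention chosen so that "the 98th percentile of 1000 models" is
exactly 20 models. From that subset, `select_models()` returns the top
$k$ by LogAUC, or — when a pairwise model distance matrix is supplied —
a greedy max-min selection seeded by the best-LogAUC model, so the
chosen models are both enriching and mutually diverse. The diversity
measure is deliberately left to the user (binding-site RMSD is the
natural choice); any symmetric distance matrix works. Ties are broken
by (higher LogAUC, model id), making selection deterministic.

## Property-matched decoys

`match_decoys()` reproduces the benchmark-construction logic: for each
active, the `ratio` pool compounds closest in normalised property space
(molecular weight, cLogP, H-bond donors/acceptors, net charge,
rotatable bonds) are selected, subject to a global exclusion of any
candidate whose ECFP4 Tanimoto similarity to *any* active exceeds
`tc_exclude` — decoys must be physically similar but topologically
dissimilar, so they are presumed non-binders. Defaults: `ratio = 65`
(the usual ~65 decoys per ligand, e.g. 11,392 decoys for 173 ligands)
and `tc_exclude = 0.35`, a conventional chemotype-novelty threshold;
both are parameters because published decoy pipelines differ in these
knobs. Properties are scaled by their pool interquartile range (robust
to outliers; an IQR of 0 falls back to 1). Assignment is greedy in
active order with global de-duplication: reproducible and
$O(|\text{pool}|\cdot|\text{actives}|)$.

## Prospective triage

The cascade mirrors a prospective screen's post-processing:

1. `ensemble_best_score()` — each compound keeps its best (minimum)
   score over the selected models; compounds that docked in no model
   are dropped and logged.
2. `filter_pains()` — SMARTS substructure exclusion. The shipped
   catalog is a compact, versioned starter set of well-known
   interference chemotypes (quinones, catechols, rhodanines, azo
   compounds, aryl hydrazones, aminothiophenes, alkylidene
   barbiturates, isothiazolones); the catalog file is an input, so any
   full published PAINS dialect in `name<TAB>SMARTS` format can be
   substituted. Unparseable SMILES are quarantined with a reason,
   never silently dropped.
3. `filter_known_similarity()` — compounds with ECFP4 Tanimoto
   similarity **strictly greater** than `tc_known` (default 0.5) to
   any known ligand are excluded; a compound at exactly the threshold
   is kept. Tanimoto on two all-zero fingerprints (0/0) is defined
   as 0.
4. `cluster_select()` — leader (sphere-exclusion) clustering in rank
   order at `tc_cluster = 0.5` over the `top_n_input = 40000`
   top-ranked survivors: a compound founds a new cluster iff its
   similarity to every existing leader is below the threshold,
   otherwise it joins the first leader at or above it. Rank-ordered
   passes make each leader the best-scoring member of its chemotype.
   The leaders of the `top_n_clusters = 2000` best clusters form the
   candidate list.

The human step of inspecting candidates for key binding-site
interactions is not modelled; the package exports the top-cluster
leaders with per-compound annotations instead.

Fingerprints are Morgan/ECFP4 (radius 2) computed via OpenBabel and
folded to 1024 bits by bitwise OR, the conventional length for
similarity work. Filters are independent predicates, so applying PAINS
then similarity equals similarity then PAINS as sets (asserted in
tests).

## Hit statistics

`hit_rate()` counts compounds whose efficacy exceeded 50% of the
reference agonist's maximum; percentages are reported raw and rounded
half-up to the integer (21.875% prints as 22%). When two screens share
compounds, `adjusted_hit_rate()` removes the shared ids from both
numerator and denominator — the one convention computable from a
tested-compound table alone. `overlap_fraction()` reports
$100\,|topK(A)\cap topK(B)|/k$. Potency helpers convert between pEC50
and micromolar EC50 ($10^{6-p}$, two decimals by default) and compute
direction-sensitive fold potencies ($10^{\Delta \mathrm{pEC50}}$).
`ppi_percent()` implements
$[1 - \text{pre-pulse}/\text{startle}] \times 100$ with the mean over
the pre-pulse intensities, and `brain_penetrance()` computes
$K_{p,\text{brain}} = \mathrm{AUC}_\text{brain}/\mathrm{AUC}_\text{plasma}$
by linear trapezoid with the brain homogenate dilution correction
(concentrations multiplied by 4 for a 1:3 w/v homogenate) applied
before integration.

The package ships `taar1_tested_compounds()`, the 62-compound tested
set of the TAAR1 screens this pipeline was built around (30 from the
AlphaFold-model screen, 32 from the homology-model screen, 25 confirmed
agonists with published pEC50/Emax, plus the β-PEA and Ulotaront
reference rows). The printed tables list only the agonists; the non-hit
rows are reconstructed from the per-screen totals and carry `NA`
potency columns. The two rank numbers printed per agonist are carried
as `rank_primary`/`rank_secondary` without interpreting which is the
cluster rank and which the library rank, since the source does not say.

```{r hitstats-example}
tab <- taar1_tested_compounds()
hit_rate(tab[tab$origin == "AF", ])[c("percent", "n_hits", "n_tested")]
fold_potency(7.5, tab$pec50[tab$id == "Ulotaront"])
```

## Symmetry-corrected structural comparison

`region_report()` compares a predicted structure to a reference
region by region: each region is superposed on its own paired Cα atoms
(Kabsch, proper rotation enforced) and the Cα RMSD is reported; for the
binding-site region the side-chain heavy-atom RMSD is additionally
computed under the same superposition. Because chemically equivalent
atoms (the two halves of a Phe/Tyr ring, Asp/Glu carboxylate oxygens,
Arg guanidinium nitrogens) carry arbitrary labels, a naive RMSD can be
inflated by a pure labeling artifact; `rmsd_symmetric()` applies, per
residue, the catalog relabeling that minimises that residue's
contribution and recomputes the global value. The per-residue choices
are independent, so the residue-wise minimum is the exact global
minimum over all $2^k$ relabeling combinations (asserted against
exhaustive enumeration in tests), the correction never re-fits the
superposition, and corrected ≤ plain always.

Conventions: residues are paired by identical author numbering (or an
explicit pairing map — full sequence alignment is out of scope);
altlocs resolve to the highest-occupancy conformer; hydrogens are
ignored; whether the side-chain RMSD is taken after a binding-site fit
(default) or a whole-structure fit is a flag, since both conventions
appear in practice. The default binding-site residue list
(`taar1_default_regions()`) is the union of the TAAR1 orthosteric
pocket residues named in the source analysis, in author numbering.

## The synthetic-data generator

The generator emulates, at desk scale, the study conditions the
pipeline was designed for:

* `sim_score_matrix()` — decoy scores from $N(0, \sigma)$, active
  scores from $N(-\delta_m, \sigma)$ per model, each cell failing to
  dock independently with probability `fail_rate` (large screens
  routinely fail to dock a substantial minority of a library). The
  separation vector $\delta_m$ is the ground-truth model-quality
  gradient: across models with increasing $\delta$, downstream LogAUC
  recovers the order (Spearman ≥ 0.95 over 50 models at 200 actives /
  13,000 decoys — the benchmark composition — with $\delta$ from 0.05
  to 2.5 score units and unit noise).
* `sim_compound_library()` — random fingerprints at a tunable bit
  density and property vectors uniform within fragment-like bounds
  (MW < 250 Da, cLogP < 3.5 by default, matching fragment screening
  criteria); optionally appends the shipped PAINS fixtures with real
  fingerprints and properties, flagged in ground truth.
* `sim_toy_structures()` — an idealised helical peptide with full Phe
  rings and Asp carboxylates, a rigid-motion-plus-noise copy, and
  recorded symmetric label swaps, so the symmetry correction can be
  validated exactly (zero noise ⇒ corrected RMSD 0 while plain > 0;
  noise $\sigma$ ⇒ post-fit RMSD ≈ $\sigma\sqrt 3$).
* `sim_assay_fixtures()` — tested-compound, startle and
  concentration-time tables constructed so that PPI% and
  $K_{p,\text{brain}}$ have known exact values.

What the generator does **not** emulate: docking-energy physics,
conformer sampling, correlated failure patterns, realistic chemistry in
the random fingerprints, or inter-model score correlation. Passing
tests on synthetic data therefore demonstrate the correctness of the
*arithmetic and algorithms*, not the screening performance of any
receptor model on real chemical matter.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale by design:
ensembles of 8–50 models, libraries of $10^2$–$10^3$ compounds,
13,000-decoy benchmark composition for the parameter-recovery check,
50-compound clustering oracles, and toy structures of ≤ 30 residues.
Every stochastic stage takes an explicit seed, and identical spec +
seed gives bit-identical output; pipeline runs write a manifest with
the config hash and seed so reruns are verifiable.

## Limitations

* Fingerprints come from OpenBabel's ECFP4 implementation; other
  toolkits' ECFP4 bits differ in detail, so Tanimoto values are
  comparable only within one toolkit.
* The shipped SMARTS catalog is a starter set, not the full published
  PAINS list; reproducing a specific published filter requires
  supplying that catalog file.
* cLogP is OpenBabel's additive model; decoy matching is insensitive
  to the specific logP flavour as long as actives and pool use the
  same one.
* The adjusted hit rate's shared-compound convention is one of several
  possible; it is documented rather than claimed to match any specific
  published adjustment.
* Structural comparison assumes shared residue numbering (or an
  explicit map) and reads PDB only — no mmCIF.
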