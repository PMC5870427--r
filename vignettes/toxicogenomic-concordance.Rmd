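---
title: "Measuring concordance between toxicogenomic testing systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring concordance between toxicogenomic testing systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgxprank)
```

## The problem

Preclinical toxicology uses several transcriptomic testing systems on the
same compounds — cultured primary hepatocytes, short single-dose animal
studies, long repeat-dose studies. Each produces, per compound, a
fold-change profile over the transcriptome. Whether a cheap or fast
system can stand in for an expensive one is not a question about
individual genes but about *structure*: does the system rank compound
similarity the same way? `tgxprank` quantifies that structural agreement
at the gene level (PRank), the therapeutic-class level (stability
ratios) and the pathway level (enrichment-ranking overlap, POP), and
provides a generative model with known ground truth to validate the
whole chain.

## Model and assumptions

**Signatures.** A compound's signature is the `k` most up- and `k` most
down-regulated genes by log2 fold change (default `k = 200`, a 400-gene
signature). This is deliberately a pure fold-change ranking: no variance
model and no per-gene p-values, which matches how these panels are
typically screened (few replicates, many compounds). Signatures assume
the matrix has at least `2k` genes and that fold changes are on the log2
scale; ratio-scale input is declared as such on read and transformed, so
"up" and "down" are symmetric around 0. Ties at a selection boundary are
broken by ascending gene id so results are reproducible and independent
of row order. A profile so degenerate that the top and bottom lists
would overlap (mass ties, e.g. a near-constant profile) is rejected
rather than silently resolved, because no tie rule can keep the two
directions disjoint *and* preserve the up/down symmetry under negation
in that case.

**Similarity.** Direction-aware Dice: overlaps are counted within the up
sets and within the down sets, never across directions, and there is no
penalty for cross-direction overlap. For two top/bottom-`k` signatures
the denominator is fixed at `4k` (800 genes at the default), so
`Dice = (N_up + N_down) / (2k)`. For threshold-mode signatures (sizes
data-dependent) the generalized denominator `|sig_a| + |sig_b|` is used;
a fixed-denominator variant is available behind a flag because the
fixed-800 convention is only meaningful when all signatures have 400
genes. Two empty signatures get similarity 0 — emptiness is absence of
evidence, not evidence of agreement. The diagonal is 1 by definition and
excluded from every mean and every downstream ranking.

**PRank.** To compare systems A and B: binarize A's pairwise
similarities at a cutoff (pair is "positive" when Dice is strictly
greater), score those labels with B's similarities, and compute the
rank-based ROC-AUC (Mann–Whitney formulation; tied scores contribute
1/2). Nothing distinguishes A and B conceptually, so both directions are
computed and averaged into the reported PRank score, which makes the
score exactly symmetric; the per-direction AUCs are always retained. The
AUC depends on B's scores only through their ranks, so any strictly
increasing transform of a system's similarities leaves the score
unchanged. If one direction has single-class labels (no pair, or every
pair, above the cutoff) that AUC is undefined; the result then carries
the defined direction only and is flagged `partial` rather than dropped.
Compound sets are intersected automatically (with a message) when
systems share only part of the panel.

**The cutoff.** The conventional cutoff on real whole-transcriptome
data is Dice > 0.4, which sits near the 95% quantile of pairwise
values there; 0.4 is therefore the package default. The quantile itself
is the transferable parameter, though: on data with a different
similarity scale (including this package's synthetic bundles, whose
off-diagonal Dice distribution is lower), `binarize(quantile = 0.95)`
reproduces the intent of the cutoff — "the top ~5% most similar pairs
are the positives" — where the absolute 0.4 would produce no positives
at all. Synthetic validation runs in this package therefore use the
quantile mode.

**Stability ratios.** For a focal therapeutic category (ATC level-2
code), the within pool holds pairs whose two compounds both carry the
code, and the across pool holds pairs with exactly one member where the
two compounds share *no* code at all; pairs sharing some other code are
excluded from both pools. Compounds carry multiple codes in real
annotations (antibacterials that are also ophthalmologicals, and the
anti-inflammatory/joint-pain pair are classic overlaps), and such pairs
would otherwise count as "across" while being biologically within-class.
The across pool is computed per focal category by default; a global pool
(all code-disjoint pairs) is available and recorded in the output. A
category needs at least 5 annotated members in the matrix (configurable)
for a defined ratio.

**Pathway level.** Each compound's pooled 2k-gene signature (direction
is irrelevant to over-representation) is tested against every pathway
with the one-sided Fisher exact (hypergeometric upper-tail) test over
the universe of measured genes, with Benjamini–Hochberg adjustment
across pathways *within one compound* — the family a practitioner gets
from standard enrichment tools. Pathways are ranked by perturbation
frequency: the number of compounds with adjusted p ≤ 0.05 (the adjusted
value is used both for the significance call and the frequency count;
ties broken lexicographically). POP(L) is the fraction of the two
systems' top-L pathways in common, reported as a curve over L = 5..60
plus its mean; no single L is privileged because any scalar summary of
the curve is a convention. Gene-set collections read from GMT keep only
sets with strictly more than 200 genes (after optional homology
translation, where a source id maps to all its targets, ids already in
the target namespace pass through, and anything else is dropped — the
only rule that makes translation idempotent).

## The synthetic generator

`generate_bundle()` emulates S assay systems observing the same compound
panel. Its generative model is a mechanism (factor) model, per compound
`c` and system `s`, on the log2 scale:

    x_sc = B f_sc + m_c + eps_sc

- `B` (genes × mechanisms, default 30 mechanisms) holds sparse gene
  programs, each covering about `signal_sparsity * n_genes / n_active`
  genes with N(0, effect_sd²) weights — shared by all systems, the way
  real pathways are.
- `f_sc` are per-system mechanism loadings:
  `f_sc = alpha_c * g_cat(c) + (1 - alpha_c) * sum_j A_sj h_jc`, where
  the channel loadings `h_jc` are sparse (about `n_active = 4` of the
  mechanisms active, N(0,1) weights) and `A A' = rho`, so the
  cross-system correlation of the compound-specific signal equals the
  configured `rho` exactly (the mixing matrix is an eigendecomposition
  square root, which also handles rho = 1 pairs). The category loading
  prototype `g` is shared by a category's members in every system with
  weight `alpha`.
- `m_c` adds a fixed log2 shift (default 2) on a planted pathway's genes
  for compounds of its affected categories, identically in every system.
- `eps` is iid N(0, noise_sd²) measurement noise.

Why a factor model: compound similarity must vary *smoothly* so that
"which pairs look alike" is a meaningful, rankable property. If each
compound perturbed an independent random gene set, unrelated-pair Dice
would be near-zero integer noise and even strongly correlated systems
would agree on pair ranking no better than chance; conversely, category
effects shared identically across systems would saturate concordance for
every pair of systems. Routing the compound-specific loadings through
the rho-mixing makes rho the genuine dial for inter-system concordance,
which `expected_ordering()` exposes as the recovery oracle.

Default conditions: 5000 genes, 60 compounds, systems
InVitro / InVivo_S / InVivo_R with rho(S,R) = 0.9 >
rho(InVitro,R) = 0.7 > rho(InVitro,S) = 0.55 — the qualitative triad
seen in real rat liver testing systems; four categories (C10, N02, A10,
J01) of 6/6/5/5 members with coherence alpha 0.8/0.55/0.5/0 (J01 is a
deliberate incoherent control); two 250-gene planted pathways at effect
2 affecting C10 and N02; eight random decoy gene sets of 210–300 genes
so enrichment specificity is testable; noise_sd = 1. The noise level and
loading sparsity were fixed once so that the resulting PRank triad spans
a realistic high/moderate/lower range rather than saturating near 1, and
are not revisited per analysis.

What the generator does *not* emulate: probe-level microarray noise and
normalization artifacts, batch effects, dose–response kinetics,
heavy-tailed or gene-dependent variance, and correlated annotation
errors. Passing recovery tests on these bundles therefore demonstrates
that the statistical machinery detects the structures it claims to
detect — not that any particular real pair of assay systems is
concordant.

## Numerical choices and degenerate inputs

- Strict inequalities follow the conventions "more than": the 0.4 Dice
  cutoff, the 1.5 fold-change threshold (two-sided on the ratio scale:
  |log2FC| > log2 1.5), and the >200 gene-set size filter.
- ROC-AUC uses midranks, so its value equals the exact fraction of
  concordant positive–negative pairs with ties counted 1/2 (the test
  suite checks this identity by enumeration).
- BH adjustment validates inputs in (0, 1] and delegates to the standard
  step-up implementation; Fisher p-values come from the hypergeometric
  upper tail. Both are checked against choose()-based enumeration.
- Fold-change matrices are written with 17 significant digits so a
  write/read round trip is bit-exact.
- Single-class binarizations yield `partial` PRank results, never silent
  drops; a pathway where no gene passes the threshold for any compound
  yields an `NA`-scored, flagged row in `prank_by_geneset()`.
- All randomness in a `run_all()` analysis flows from the single config
  seed; rerunning a config is byte-identical.

## Worked run

```{r, eval = FALSE}
bundle <- generate_bundle(synthetic_config(seed = 1))
sims <- lapply(bundle$matrices, function(m)
  pairwise_similarity(system_signatures(m, k = 200), m$system_id))
prank_score(sims$InVivo_S, sims$InVivo_R, quantile = 0.95)
stability_table(sims, bundle$annotations)
enrich_system(bundle$matrices$InVivo_R, bundle$gene_sets)$ranking
```

The problem sizes used throughout the package's own validation — 60
compounds × 5000 genes per system, 20 generator seeds for recovery
rates, 1000 permutations for the null, 200 label shuffles for the
stability null — were chosen as the default study conditions and are the
same sizes the acceptance script reports alongside each value.

## Known limitations

- The mean-over-L summary of the POP curve is one convention among
  several; the full curve is always written.
- Threshold-mode Dice with widely different signature sizes is dominated
  by the larger signature's denominator share; the fixed-denominator
  flag exists for comparability with fixed-size conventions.
- The stability ratio has no significance test attached (none is
  standard); the shuffled-label null in the acceptance script shows its
  calibration instead.
- Chemical similarity is consumed, never computed: fingerprints are
  upstream of this package.
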