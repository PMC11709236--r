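---
title: "Comparative transcriptomics of thermal tolerance: methods and design"
author: "ThermoTrout maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative transcriptomics of thermal tolerance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ThermoTrout)
```

## The problem

Rainbow trout strains differ in how well individual fish withstand an acute
thermal challenge. A standard design phenotypes fish by critical thermal
maximum, keeps the most and least tolerant individuals (H and L groups) plus
unchallenged controls (C) in each of two strains, and profiles liver gene
expression by bulk RNA-seq: two strains x three groups x six biological
replicates. The analytical questions are (i) which genes respond
differentially between groups within each strain, (ii) which responses are
shared across strains, (iii) which high-level functions (GO-slim terms,
pathways, upstream regulators, functional-effect categories) distinguish
tolerant from intolerant fish, and (iv) how the salmonid genome duplication —
many trout genes per mammalian orthologue — should be handled when expression
tables are projected onto mammalian annotation.

ThermoTrout implements this pipeline end to end, together with a seeded
synthetic-data generator that plants known truth at every level, so each
stage is testable without the original sequencing data.

## Normalization and differential expression

Counts are normalized as TPM (`1e6 * (c/L) / sum(c'/L')`, columns sum to one
million) or RPKM (`1e9 * c / (L * N)`). Differential expression between two
groups is a per-gene negative-binomial Wald test:

* size factors are `library size / mean library size`; group means `m_A`,
  `m_B` are means of normalized counts;
* the NB dispersion `phi` (Var = `mu + phi mu^2`) is estimated per gene by
  method of moments, floored at `1e-8`, and shrunk 50/50 toward the mean
  dispersion of the filtered gene set. The floor avoids degenerate zero
  variances; the shrinkage stabilizes the noisy 6-vs-6 moment estimate;
* the effect is `log2((m_B + 0.5) / (m_A + 0.5))` (0.5 pseudo-count), its
  Wald statistic is referred to the standard normal. With the shrunken
  dispersion the statistic is close to standard normal at the simulator's
  default depth and dispersion; at high dispersion (`phi` around 0.4) the
  test becomes mildly anticonservative, a known limitation;
* *filtered FDR*: genes whose mean normalized count across the tested
  samples falls below `filterThreshold` (default 1) are excluded **before**
  Benjamini-Hochberg correction and carry a sentinel `qvalue = NA`. They are
  never called significant. Significance is `q <= 0.01` by default.

The direction convention is that a positive log2FC means "up in the focal
group": H in HvC and HvL, L in LvC.

Cross-strain accounting intersects the two strains' significant sets,
records per-strain directions, ranks shared genes by the average log2 fold
change (ties by gene ID, for determinism), and reports Venn counts and
per-strain shared/upregulated proportions. Whether a "shared" gene must
agree in direction across strains is genuinely ambiguous; we retain
direction-discordant genes with a `discordant` flag rather than dropping
them, so both readings can be recovered downstream.

PCA is correlation-matrix PCA of samples (centred, unit-scaled genes).
Zero-variance genes would divide by zero during scaling and are dropped
with a warning. By default the pipeline restricts the PCA to genes
significant in at least one strain-comparison (configurable), and retains
the smallest number of components whose cumulative variance reaches the
`varianceTarget` (default 0.843).

## Duplicate-gene consolidation

Many trout genes map to one mammalian orthologue ID. Per strain the copy
with the largest |log2FC| is selected ("strongest change, either sign");
ties break toward the larger raw log2FC, then lexicographic gene ID. The
additive total log2FC over all copies is kept alongside, with a flag when
it opposes the selected copy's sign. A duplicated orthologue whose selected
copies disagree in sign between the two strains is a *mismatch*; mismatches
are flagged and retained, never removed, because removing them could delete
key regulatory genes. The mismatch count is reported against three
denominators — unique duplicated IDs, all mapped DEG records, and unique
mapped IDs — because published summaries quote rates on different bases.
Percentages round half-up to one decimal, matching how such tables are
printed.

## GO-slim overrepresentation by backward-elimination G-test

For two disjoint gene sets (up in each side of a comparison), per-namespace
term counts are tabulated (a gene with k terms contributes k counts), and
percent counts within each column give a signed percent difference `d_i`
used for ranking. Overrepresented terms are found by backward elimination:
while the overall heterogeneity G (`2 sum O ln(O/E)`, df = R-1) is
significant at `alpha` and more than one term remains, each remaining
term's 2x2 partition G (term vs pooled remainder) is computed, the maximal
one is removed (ties by larger |d_i|, then term ID), and its step, partition
G and enriched side (`sign(d_i)` at removal) are recorded.

The greedy criterion is justified by the exact additive decomposition
`G_full = G_2x2(i) + G_rest`, which holds to numerical precision without
continuity corrections — for that reason no Williams correction is applied
by default (an optional flag exists on `gStatistic()`). The stopping level
`alpha` defaults to 0.05. Namespaces (BP/CC/MF) are tested independently.
Because the first removal happens only when the overall G test rejects,
the procedure's family-wise type-I rate on homogeneous tables equals the
nominal level of that first test (~5%), which the test suite verifies by
simulation.

## Pathways, upstream regulators, and the FE_g score

Pathway and regulator tables arrive from an external network-analysis
knowledge base; the package implements the filtering and ranking rules
applied to them. Directional pathways (z-score non-zero) are dropped when
`-log10(p) < 1.3` (p = 0.05; the `-log(p)` threshold is interpreted base
10); neutral pathways (z missing or 0) are retained only when
`-log10(p) > 1.3`. Regulators without a significant expression record are
dropped; |z| >= 2 marks a *major* regulator; a *match* requires a
predicted-activated regulator (z >= 2) observed up in H or a
predicted-inhibited one (z <= -2) observed up in L. Top-10 lists are built
separately by |z| rank and |log2FC| rank among matching regulators of each
group; we use |log2FC| (within each group's expected direction) because the
expression ranking is applied after the direction has already been fixed by
the match rule.

The Functional Effects Group score summarizes, per function and group, the
annotated consequence of the group's enhanced genes:

FE_g = (n_increase - n_decrease) / (n_increase + n_decrease + n_affect)

bounded in [-1, 1], antisymmetric under swapping increase/decrease. The two
groups' category proportions are compared by a G-test on the
groups-by-categories table (categories empty in both groups dropped; a
Fisher exact test replaces the G-test when any expected cell is below 1). A
group is called *increased*/*decreased* only when its score is
non-zero-signed and the test rejects at `alpha`; otherwise *indeterminate*.
The exact published formula lives in a deposited script rather than the
methods text, so this reconstruction — the simplest signed proportion
consistent with the verbal definition — is flagged as such.

## The synthetic-data generator

`simulateStudy()` emulates the study design with planted truth:

* **Design**: 2 strains x (C, L, H) x 6 replicates; gene relative
  abundances log-normal (sdlog 1); gene lengths log-uniform on
  [300, 10000] bp; library sizes log-normal with mean 2e6 and CV 0.2.
  The depth is chosen so that a 5000-gene transcriptome has a realistic
  spread of per-gene means at desk scale; the published study's dispersion
  and depth distributions are not reported, so these are conventional
  choices, not fits.
* **Effects**: a fraction `fracDE` (default 0.1) of genes receives an H
  effect and, disjointly, a further `fracDE` an L effect; magnitudes
  |N(1.5, 0.5)| floored at 0.25, signs 50/50; half of each pool (the
  `sharedFraction`) carries identical effects in both strains, the rest is
  strain-specific. Disjoint H/L pools keep every H-vs-L truth effect
  single-signed per gene — without this, a gene H-up in one strain's unique
  set and L-up in the other's would create cross-strain sign flips outside
  the planted discordant set and the exact truth-recovery property below
  could not hold.
* **Counts**: NB with `Var = mu + phi mu^2` (`phi` default 0.1; 0 gives the
  Poisson limit). Library sizes recorded in the metadata are the realized
  column sums.
* **Orthologue map**: orthologue IDs receive 2-3 trout copies with
  probability `dupFraction`; a `discordRate` fraction of duplicated IDs is
  planted discordant by overriding two copies' true effects (one up-copy
  dominating strain 1 at +2.5 vs +0.8, one down-copy dominating strain 2 at
  -0.8 vs -2.5) so the selected copies disagree in sign between strains
  while each copy stays direction-concordant across strains. Because the
  discordance plan must shape the true effects before counts are drawn, the
  generator plans effects, then the map, then simulates counts; the planted
  discordant set is recovered *exactly* when consolidation is fed the true
  fold changes, and only approximately from estimated ones (sampling noise
  can flip a selected copy's sign near zero).
* **Annotations**: each (gene, namespace, term) triple is an independent
  Bernoulli draw at rate `termsPerGeneMean / nTerms`, multiplied (capped at
  1) for genes up in an enriched term's target group — so a planted
  multiplier is also the expected frequency ratio, which makes the binomial
  oracle in the tests exact.
* **Function associations**: effect labels drawn from per-group
  increase/decrease/affect mixes conditioned on each gene's planted
  enhanced group.

All randomness flows through one master seed; per-artifact sub-streams are
derived deterministically from it, so identical parameters reproduce every
artifact bit-for-bit.

What the generator does **not** emulate: batch effects beyond strain,
GC/length biases, isoforms, correlated genes within pathways, annotation
errors, and the long-tailed library-size failures of real sequencing runs.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to every artefact of real
data.

## Numerical and design choices

* BH q-values are computed only within the filtered set; filtering does not
  alter p-values or their order among retained genes.
* All ranking ties (shared-gene ranking, copy selection, term elimination,
  regulator lists) break deterministically (gene/term ID order).
* Degenerate inputs: all-zero samples, missing lengths, single-row G
  tables, empty maps, functions with no covered genes, and invalid
  thresholds raise early, named errors; empty-but-valid cases (no shared
  genes, zero duplicates) return empty results with zero rates.
* Problem sizes in the test-suite simulations (for example 5000 genes for
  calibration checks, 200-500 genes per seed in repeated-seed loops,
  2000-replicate type-I studies) were chosen to keep sampling error well
  inside the asserted bands while the whole suite stays quick to run.

## Known limitations

* The DE test's normal reference is slightly anticonservative at high
  dispersion; a quasi-likelihood or exact NB test would be better at
  `phi > 0.3`.
* Library-size normalization (as specified for this pipeline) is biased
  under strong asymmetric composition shifts; at the default planted DE
  fraction the bias in recovered log2FC is about -0.15 for a 4-fold
  effect. Median-of-ratios normalization would remove most of this but is
  deliberately not substituted.
* The backward elimination tests each namespace separately and does not
  correct across namespaces.
* FE_g and the pathway/regulator rules operate on externally produced
  tables; the package validates and filters them but cannot check the
  upstream network inference that generated them.
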