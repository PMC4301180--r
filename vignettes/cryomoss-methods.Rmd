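---
title: "Methods: models, parameters and design choices in cryomoss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in cryomoss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryomoss)
```

cryomoss implements the inferential chain of a time-series cold-stress
transcriptome study: a control condition and several durations of cold
exposure, a few biological replicates each, measured as linear-scale
intensities on a whole-genome array. This vignette documents the models,
the tunable parameters and their defaults, the synthetic-data generator,
the numerical conventions, and the design decisions taken where the
methodology left genuine choices open.

## Differential expression model

Intensities are first **median normalized**: each sample column is
multiplied by a constant so that its median equals the grand median of all
per-sample medians. This removes array-level scale differences while
preserving within-sample rank order; a sample whose median is zero is
rejected as degenerate rather than silently rescaled.

Per gene, a **one-way fixed-effects ANOVA** compares the K time-point
groups. The test is computed on log2 intensities: replicate noise on
microarrays is multiplicative, so the log scale both stabilizes the
variance across the intensity range and makes the Gaussian error model of
the F test tenable. The F statistic uses the usual between/within
sums-of-squares decomposition with (K − 1, N − K) degrees of freedom. A
gene with zero variance both within and between groups is reported with
F = 0 and p = 1 — it is evidence of no change, not missing data — while
zero within-group variance with differing means yields p = 0.

**Multiplicity** is handled in two tiers, mirroring the two questions
asked of the data:

* across genes, the ANOVA p-values receive Benjamini–Hochberg step-up
  adjustment, and genes with adjusted p below `alpha` (default 0.05) form
  the candidate set;
* within each candidate gene, Tukey's HSD assigns a studentized-range
  p-value to every time-point pair, and these are Bonferroni-multiplied by
  the number of pairs (10 for five time points), capped at 1.

The Bonferroni dimension deserves a note: "Tukey HSD with Bonferroni
correction" can be read as correcting across genes, across pairs, or both.
We correct across the pairwise comparisons *within* each gene, because the
per-pair DEG decision is the unit of downstream analysis and the
gene-level family-wise burden is already carried by the BH gate. Genes
failing the BH gate get no post-hoc calls at all — their per-pair fields
are marked not tested rather than set to p = 1, so they can never leak
into pair-level summaries.

**Effect sizes** are linear fold changes, the ratio of normalized group
means with the later time point in the numerator: values above 1 are
induction, below 1 repression (so a two-fold filter keeps FC ≥ 2 or
≤ 0.5). Fold changes are computed for every gene and pair; direction
labels (`induced`/`repressed`) are only attached to significant pairs. The
GLM module works on log2 fold changes instead, because the log scale
symmetrizes induction and repression so that the *sign* of a mean carries
the direction of regulation; the linear scale is kept for reporting
because published fold-change tables are linear. Per-pair summary tables
report DEG counts, induced/repressed splits, two-fold counts and
fold-change ranges among DEGs only — whether such summaries should average
over DEGs or all genes is unstated in the underlying methodology, and
averaging over non-significant genes would shrink every entry toward 1.

A gene is **persistently induced** if it is an induced DEG in the
control-versus-t comparison for every sampled t, and analogously for
persistent repression.

## Enrichment and stage partitioning

Term enrichment uses **Fisher's exact test** on the 2×2 table of set
membership against term annotation. One-sided tails come from the
hypergeometric distribution; the two-sided p follows the
minimum-likelihood convention (sum of the probabilities of all tables with
the same margins whose point probability does not exceed the observed
one, compared with a 1e-7 relative tolerance to absorb floating-point
ties). This is the convention of `fisher.test`, and the two agree to
numerical precision in the test suite. BH correction runs across terms;
significant terms are labelled over- or under-represented by their smaller
tail. One caveat of the minimum-likelihood rule worth knowing: the
two-sided p always contains the smaller tail, but it is *not* bounded by
twice the smaller tail — the far tail can contribute probability mass of
its own.

Terms are tested exactly as annotated: no propagation up the ontology
graph is performed, because the ontology structure is not an input of this
package. The default universe is every gene on the input matrix; analysts
who prefer the annotated-genes universe can pass it explicitly.

The time course is partitioned into **early (1, 3 h), intermediate (8 h)
and late (24 h)** response stages. A stage's gene set is the union of DEGs
from the control comparisons of its member time points, so stage sets may
overlap — a gene significant at 3 h and 24 h is evidence for both an early
and a late response.

## Orphan-gene statistics

Orphan (species-specific) status arrives as an input flag; the package
quantifies its association with the response. Percentages are reported
with round-half-away-from-zero at the requested precision, matching the
convention of printed count-derived percentages.

For the **stage test**, every DEG is assigned to its *earliest*
significant control comparison. This makes the early ({1, 3 h}) and later
({8, 24 h}) sets disjoint, which a 2×2 exact test requires; assigning a
gene to every stage it appears in would double-count it. The test is then
one-sided (is the orphan proportion higher early?), and the **direction
test** (induced vs repressed DEGs) is two-sided. Both reduce literally to
the same `fisher_2x2` kernel used for term enrichment — the test suite
asserts bit-identical equality.

## TAP family classification

TAP (transcription-associated protein) family membership tables of two
species are pooled, and each gene's process class is derived from its GO
annotations: *developmental* (GO:0032502), *stimulus/stress* (GO:0050896
or GO:0006950), *both*, or *none*. Unannotated genes stay in the family
totals but not in the class tabulation.

Per family and candidate class, a one-sided Fisher test asks whether the
class is enriched among the family's annotated members relative to all
other TAP-annotated genes of both species — the background is the TAP
complement, not the genome, because the question is specialization
*within* the regulatory apparatus. One-sided testing is deliberate:
two-sided would let a class *depletion* masquerade as specialization.
Genes annotated to both sides count toward each side's total (evidence
for both roles), a choice the source methodology leaves open. BH runs once
across all family × class tests of the run, not per family.

Families are then assigned a class at one of three **quality tiers**:
tier 1 when the BH-adjusted p of the best class is below α; tier 2 when
only the raw p is; tier 3 otherwise, by the maximal annotated member
count, with ties (or families without annotated members) flagged
`unspecialized`. The tiers are mutually exclusive and exhaustive for
non-empty families.

## GLM regulatory trends

The trend models are Gaussian GLMs with identity link — ordinary least
squares with Wald t inference — on the log2 fold changes of TAP-coding
DEGs, one observation per gene × control comparison. The Gaussian/identity
choice reflects the response: a continuous, sign-symmetric quantity whose
mean is the estimand; the underlying methodology names only "GLMs" without
family, and a mean-level contrast is the only reading consistent with the
reported induction/repression conclusions. Class-level tests are
intercept-only fits per specialization class (equivalently one-sample
t-tests), globally and per time point; family-level trend tests are the
same per family. Two-sided p-values are reported with signed estimates,
rather than presuming a direction.

Observations are treated as independent across genes and comparisons — no
gene-level random effect — which matches the simplicity of the original
analysis but understates correlation when the same gene contributes
several comparisons; p-values for classes dominated by persistent genes
are therefore somewhat optimistic. Classes or families with fewer than 3
responses in scope are skipped with a warning rather than fitted on
degenerate degrees of freedom. A perfect fit (zero residual variance) is
flagged and its p-values reported at the machine floor instead of 0.

## The synthetic-data generator

`sim_config()` / `simulate_experiment()` emulate the statistical structure
the pipeline assumes, with these defaults:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 10000 | free parameter of the design; large enough for calibration checks, small enough for desk-scale runs |
| `time_points` | 0, 1, 3, 8, 24 h | the study design |
| `n_replicates` | 3 | the study design |
| `baseline_log2_mean`, `baseline_log2_sd` | 8, 1.5 | typical dynamic range of array intensities |
| `noise_log2_sd` | 0.25 | replicate scatter of biological microarray replicates |
| `de_fraction` | 0.10 | of the order of the ~12% of array genes affected in cold time courses |
| stage fractions | 3/7/45/45% at 1/3/8/24 h | mirrors the strong accumulation of DEGs toward 8–24 h |
| stage effect means | 1.2/1.2/1.5/1.8 log2 | detected fold changes grow with exposure time |
| `induced_fraction` | 0.6 | induced DEGs outnumber repressed ones |
| `orphan_fraction` | 0.12 | genome-wide orphan rate of the moss gene complement |
| `orphan_early_enrichment` | 2 | orphans are about twice as frequent among early responders |
| `class_direction` | stress 0.9 / developmental 0.2 induced | the antagonistic regulatory pattern: stress regulators accumulate, developmental regulators decline |
| TAP family sizes | decaying spectrum, largest 27 | dominance of one large family (AP2/EREBP-like) over many small ones |
| `class_bias` | 0.8 | most family members share the family's process class |

Intensities are generated as baseline + planted effect + Gaussian noise on
the log2 scale and then exponentiated, so noise is multiplicative and
planted log2 effects translate exactly into fold changes. Planted effects
are **step functions**: a gene first responding at stage s carries its
effect at s and all later time points (a configurable fraction can be
transient instead), which reproduces the accumulation of DEGs over time.
Orphan enrichment is applied to the *planted* stage, with the rate of the
remaining genes renormalized so the marginal orphan fraction stays at its
configured value — recovery of the enrichment by the pipeline is therefore
a genuine end-to-end test, not an artifact of labeling called DEGs.

What the generator deliberately does **not** model: probe-level artifacts
(spatial effects, dye bias, background), missing values, gene–gene
correlation, sequencing count distributions, and annotation errors.
Passing tests consequently demonstrate the statistical machinery under the
assumed noise model, not robustness to array-specific artifacts.

`simulate_tap_tables()` generates the two-species classifier inputs
directly: a configurable number of stimulus/stress-specialized,
developmental and unbiased families whose members split across species and
draw class labels with a configurable bias.

## Numerical conventions

* BH adjustment delegates to `stats::p.adjust`; the test suite checks it
  against a literal implementation of the step-up definition.
* Tukey p-values come from `stats::ptukey`. Inside `call_degs()`, batches
  above 2048 values are evaluated on a 4096-point grid with monotone
  cubic interpolation (absolute error below 1e-6, far inside any
  significance margin); the exported `tukey_pairwise_p()` is always exact.
* Genes whose residual variance is exactly zero after the gate get
  pairwise p-values of 0 or 1 by direct comparison of means.
* Exact-test tie comparisons use a 1e-7 relative tolerance.
* Reported percentages round half away from zero.
* All generator randomness flows through a single integer seed via
  `withr::with_seed`; identical seed and configuration give bit-identical
  output.

## Problem sizes and known limitations

The packaged checks run at desk scale: calibration at 10000 genes,
null-error control over 20 seeds × 5000 genes, classifier recovery on a
planted 30/15/5 family partition over 10 seeds, GLM coverage over 500
replicates, and orphan stage-test power over 50 seeds at 10000 genes.

Two limitations are worth stating plainly. First, the orphan stage test
has modest power under the default conditions: only ~10% of planted DE
genes respond early, so the early set holds roughly a hundred genes and
the measured rejection rate at a planted two-fold enrichment is about
0.7 at α = 0.05 — the planted early orphan rate itself fluctuates
substantially at that set size, and three replicates recover only ~80% of
early responders. Analysts should treat a non-significant stage test on
data of this shape as weakly informative. Second, the GLM independence
assumption noted above means class-level p-values are anti-conservative in
the presence of persistently responding genes; a gene-level random effect
would be the principled extension.
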