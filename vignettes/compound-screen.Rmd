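---
title: "A two-branch in-silico screen for pathway-modulating compounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-branch in-silico screen for pathway-modulating compounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dartmap)
```

## The problem

Perturbational expression compendia pair the transcriptome of cells treated
with a compound against vehicle-treated controls from the same experiment
(one *instance* = one treated sample plus its controls). Given a
transcriptional pathway known to be dysregulated in a disease — here the
motivating case is breast cancer, where a cell-cycle/proliferation pathway
driven by the FOXM1 transcription factor is up-regulated and a
lipid-metabolism pathway driven by PPARA is down-regulated, most strongly in
the triple-negative subtype — the screening question is: *which compounds
push that pathway back toward its normal state?*

`dartmap` answers it with two independent scoring branches and a
rank-and-intersect selection:

1. **Activity branch.** A per-sample pathway *activity score* is computed
   with a relevance-network denoising estimator (the DART family of
   methods). Each instance contributes an activity difference
   $AS_d = AS_t - AS_c$: treatment score minus aggregated control score. A
   negative $AS_d$ means the treatment repressed the pathway.
2. **Connectivity branch.** Each instance's genes are ranked by
   treatment-minus-control change and the signature's up/down tag sets are
   scored with the weighted Kolmogorov–Smirnov statistic of connectivity
   mapping, scaled to $[-1, 1]$ batch-wide. A negative connectivity score
   means the treatment *reversed* the signature's expression pattern.

A compound is a hit when it lands in the top $N$ of **both** branches.
Requiring agreement between a network-weighted activity estimator and an
unweighted rank statistic is the screen's main guard against branch-specific
artefacts.

## Directional signatures

A signature is a named pair of disjoint tag sets: genes up-regulated in the
disease state ("up" tags, prior sign $\sigma = +1$) and genes down-regulated
("down" tags, $\sigma = -1$). Signatures are built from a *direction table*
(gene, direction, and optionally an `is_core` flag marking the enrichment
leading-edge members) and travel as two GMT lines, `<name>_UP` and
`<name>_DN`.

Three worked signatures ship with the package: the 40-gene FOXM1-pathway
signature (27 up / 13 down), the 57-gene PPARA-pathway signature
(12 up / 45 down), and a combined signature taking the 21 core up-tags of
the first and the 26 core down-tags of the second:

```{r signatures}
bundled_signature("FOXM1")
bundled_signature("FOXM1_PPARA")
```

Gene symbols are opaque, case-sensitive tokens; no alias resolution is
attempted, because the signatures are consumed as literal lists. When a
platform query needs probe identifiers, `map_genes_to_probes()` expands each
gene to all of its probes (sign inherited), drops and reports genes without
probes, and treats a probe that would inherit conflicting signs as an error.
Unmappable symbols (e.g. retired histone gene names) are therefore dropped
*visibly* — a policy choice; silently keeping stale identifiers would bias
the KS statistic's tag counts.

## The activity estimator

`dart()` fits, in order:

1. **Standardization.** Every gene row is z-scored (mean 0, sd 1, $n-1$
   denominator). Zero-variance rows are set to zero and flagged rather than
   dropped, so matrix shapes are stable; such genes can never gain an edge.
2. **Relevance network.** For every pair of signature genes present in the
   matrix, the Pearson correlation $r_{ij}$ across samples, with a
   two-sided p-value from the Fisher z-transform
   ($z = \mathrm{atanh}\,r$, $se = 1/\sqrt{n-3}$). An edge is kept iff
   $p < \alpha$, default $\alpha = 10^{-6}$ — a deliberately stringent fixed
   cutoff, conservative in the Bonferroni sense for the $\sim 10^4$ pairs a
   ~100-gene signature generates. It is applied to raw p-values as a fixed
   threshold, not as an adaptive FDR procedure. Exactly-zero correlations
   carry no sign and are excluded outright. Note the practical consequence:
   with true inter-gene correlation $\rho \approx 0.6$, edges only become
   detectable at this $\alpha$ from roughly 55 samples upward, which is why
   the estimator is fitted on the *whole* perturbational batch rather than
   per instance.
3. **Prior-consistency pruning.** An edge is consistent when
   $\mathrm{sign}(r_{ij}) = \sigma_i\sigma_j$; inconsistent edges are
   removed. The retained fraction $f$ is tested by permuting the signs over
   the nodes ($p = (1 + \#\{f_{perm} \ge f_{obs}\})/(n_{perm}+1)$, default
   1000 permutations).
4. **Scoring.** Over the maximally connected component of the pruned
   network (isolated nodes excluded; ties between equal-sized components
   broken toward the one containing the alphabetically first gene):
   $$A_s = \frac{\sum_i \sigma_i k_i z_{is}}{\sqrt{\sum_i k_i^2}}$$
   with $k_i$ the node degree. Hub genes — those whose correlations best
   survive the prior filter — dominate the score; the normalizer makes the
   score invariant to a common rescaling of all degrees. A high positive
   $A_s$ indicates pathway stimulation in sample $s$.

The degree-weighted metric, the component restriction, the Pearson/two-sided
choice, and standardization before network construction follow the
estimator's reference implementation conventions; all are fixed here and
documented rather than configurable knobs, except $\alpha$ and the
permutation count.

The fitted object behaves like any R model: `print()`, `summary()`,
`coef()` (the per-gene weights $\sigma_i k_i / \sqrt{\sum k^2}$), `fitted()`
(per-sample scores), `predict(fit, newdata)` (new samples standardized with
the *training* means and sds), and `plot()`.

## From samples to compounds

* **Control aggregation.** With $\ge 3$ controls, one maximum and one
  minimum score are dropped as outliers and the rest averaged; with 1–2
  controls the plain mean is used (trimming two of two would leave
  nothing).
* **Replicates.** Instances sharing (compound, dose) are averaged; $N$ is
  reported. For connectivity, the default aggregation is also the mean, with
  `"best"` (most negative) exposed as an alternative; the mean is the
  default for symmetry with the activity branch.
* **Ranking.** `direction = "suppress"` sorts ascending $AS_d$,
  `"stimulate"` descending; desirable connectivity is always the most
  negative. Ties break by compound name, making ranked tables
  byte-reproducible.
* **Selection.** `intersect_top()` intersects the top-$N$ compounds of the
  two branches (default $N = 50$), carrying both ranks. With $N$ covering
  everything it degenerates to the plain set intersection. Selection
  operates on (compound, dose) summaries rather than raw instances; with
  the published tables' layout both interpretations of "top instances"
  coincide after replicate averaging, and summary-level selection is the
  less noisy of the two.
* **Census.** `sign_census()` counts negative / zero / positive scores with
  zeros in neither signed bucket.

For cohort comparisons (tumour subtypes vs normal tissue),
`group_comparison()` runs a one-way ANOVA followed by all pairwise Welch
t-tests with Benjamini–Hochberg adjustment within the family. Welch rather
than pooled-variance is used because subtype groups have unequal sizes and
variances. `minmax_normalize()` maps score vectors onto $[0,1]$ when scores
from different cohorts share a figure.

## The KS connectivity statistic

For a tag set with $t$ members at sorted positions $V(1) < \dots < V(t)$ of
an $n$-long ranked list:

$$a = \max_j\left(\frac{j}{t} - \frac{V(j)}{n}\right),\qquad
  b = \max_j\left(\frac{V(j)}{n} - \frac{j-1}{t}\right)$$

and the score is $a$ if $a > b$, else $-b$; on the exact tie $a = b$ the
non-negative branch is returned (the classical "whichever is larger"
formulation leaves the tie open; a deterministic choice is documented
here). The raw instance score is $s = ks_{up} - ks_{down}$, zeroed when the
two share a sign; batch-wide scaling divides positive $s$ by the largest
positive and negative $s$ by the largest-magnitude negative, so the extremes
attain $\pm 1$. Null instances (no tags present, or only one tag set
present) are flagged and excluded from scaling rather than dropped
silently; zero raw scores map to connectivity 0, as the original tool
reports them.

Synthetic instances are ranked by the plain treatment-minus-control
difference (ties lexicographic). Production compendia use internal
ratio-based rankings that cannot be reconstructed without their rank
matrices, but only the *order* enters the statistic.

## What the simulator emulates — and what it does not

`simulate_instances()` generates the structure every stage consumes:

* Signature genes load on a latent pathway factor with sign-directed
  loadings, $x_g = \sigma_g\sqrt{\rho}\,f + \sqrt{1-\rho}\,\varepsilon$:
  same-tag pairs correlate at $\rho$, cross-tag pairs at $-\rho$. A single
  equicorrelated factor is the simplest structure that makes the relevance
  network non-trivially recoverable; the sign-directed loading is
  deliberate, because a pathway-activity factor should drive up- and
  down-tags in opposite directions — with a uniformly positive loading every
  cross-tag edge would be prior-inconsistent and pruning would disconnect
  the two tag sets by construction.
* The factor is drawn **once per instance** and shared by the treated
  sample and its vehicle controls: they come from the same culture batch,
  so pathway-level biological noise largely cancels in the paired
  contrast, exactly as a paired design intends. Across the batch the
  gene–gene correlation is unaffected.
* A `"reverser"` compound shifts affected up-tags by $-\delta$ within-gene
  standard deviations and affected down-tags by $+\delta$
  (`"mimicker"`: mirrored; `"null"`: nothing). Effects are additive on the
  log-intensity scale and planted at the compound level, so replicate
  averaging has signal to aggregate. Defaults: $\delta = 2$, $\rho = 0.6$,
  2 replicates, 3 controls, 100 background genes, 10% reversers and 10%
  mimickers — the conditions under which the package's power claims are
  stated.
* `simulate_cohort()` produces labelled group matrices (per-group
  sign-directed mean shifts, factor independent per sample) for the
  group-comparison branch.

Not emulated: probe-level artefacts, batch effects across chip types,
dose–response structure, and non-Gaussian expression noise. Passing the
package's recovery tests therefore shows the *pipeline logic* is sound
under its stated noise model, not that any particular real compendium would
yield the same hit lists.

## Numerical choices and degenerate inputs

* Probe collapse keeps, per gene and per sample, the maximum across the
  gene's single-mapped probes; multi- and zero-mapped probes are discarded
  (their identity is recorded on the result). Collapse order relative to
  upstream corrections is the caller's choice; the function is agnostic.
* FPKM→TPM renormalizes each column to $10^6$ exactly before
  $\log_2(x+1)$; RSEM scaled estimates are scaled by $10^6$ with a
  pseudocount of 1, chosen for consistency with the FPKM rule (the
  upstream convention leaves it unstated).
* $n \le 3$ samples is an error for network construction (the Fisher z
  needs $n > 3$); an empty pruned component is an error that advises
  relaxing $\alpha$ rather than silently returning zeros.
* Permutation p-values use the add-one estimator, so they are never
  exactly zero.

## Problem sizes used in the validation suite

The shipped tests exercise the screen at 20–100 compounds per batch with
40-gene signatures and 100 background genes, 100 seeded replicates for the
power claims (planted reversers recovered by the top-50 intersection in
$\ge$ 95 of 100 replicates under the default conditions), 1000 replicates
for the type-I-error calibration of the group comparison, and exhaustive
oracle checks of the KS statistic over every tag placement for list lengths
up to 8. These sizes were chosen to make every stochastic claim
reproducible in minutes on a laptop while keeping the Monte-Carlo error of
each asserted rate well inside its asserted band.

## Known limitations

* The activity estimator needs enough samples for edges to clear the
  stringent $\alpha$; on small batches it will rightly refuse to score
  rather than degrade into an unweighted average.
* Database-wide signed-instance counts and hit lists of a real compendium
  (thousands of instances, multiple chip types) depend on that compendium's
  preprocessing; the package validates the machinery on synthetic ground
  truth and on the published worked values it ships, not by re-running the
  original download.
* Replicate aggregation to per-compound rows uses the mean by default; if
  a compound's replicates disagree strongly, inspect the per-instance
  records before trusting its summary row.
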