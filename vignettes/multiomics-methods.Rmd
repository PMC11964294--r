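---
title: "Methods: multi-omics response integration in heatomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics response integration in heatomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatomics)
```

# Overview

heatomics integrates three molecular levels of a treated-vs-control
experiment — transcript log2 fold changes with p-values, replicate-level
protein log2 abundance ratios from stable-isotope labelling, and GC/MS
metabolite peak areas — into one analysis: per-functional-category
transcript–protein concordance, cross-species signature
overrepresentation, term enrichment over an expressed background, and the
level-specific summarisation each of those consumes. This vignette is the
package's account of the statistical procedures, their assumptions, the
parameter defaults and why they were chosen, and what the synthetic
benchmarks do and do not establish.

# Transcript–protein category correlation

Each protein group is paired with its gene's transcript through a
protein-to-gene map; several protein groups on one gene form several
pairs, each reusing the transcript value. Pairing at protein-group
granularity preserves the unit at which the proteomics quantification was
made; gene-level averaging is available (`gene_level = TRUE`) for users
who prefer one pair per gene. Pairs with a non-finite fold change on
either side (one group's mean zero) are excluded and counted, never
imputed.

For each term of the annotation hierarchy with at least `min_pairs`
member pairs, the Pearson correlation $r$ between the paired log2 fold
changes is reported with $r^2 = r \cdot r$ and the usual two-sided
p-value from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom.
Assumptions are those of the Pearson/t machinery: approximately bivariate
normal fold changes within a category and independent genes. Fold changes
of co-regulated genes are not strictly independent, so per-category
p-values should be read as descriptive; they are reported raw (the
primary quantities are $r$ and $r^2$), with an optional BH column across
terms.

Numerical conventions: a term whose pairs have zero variance on either
axis is skipped and counted as degenerate rather than reported with an
undefined $r$; exactly collinear pairs give $r = \pm 1$ with $p = 0$.
Hierarchical membership is the ancestry closure of the dot-delimited term
codes ("1.3.4" is a member of "1.3" and "1"), applied once at
construction and idempotent.

`min_pairs` defaults to 5, mirroring the "at least 5 entries mapped"
convention of the term-enrichment stage; there is no principled universal
floor, and the parameter is exposed because the choice of which
categories are reportable is a study-level decision.

# Cross-species signature enrichment

The counting universe ("working set") is the intersection of the
ortholog-converted expressed genes of the source study with the expressed
genes of the target study, as a set — duplicates introduced by
many-to-one orthology collapse. Response lists are ortholog-converted and
deduplicated independently so that each target gene contributes once per
scenario; a gene landing in both the up and the down list after collapse
is retained in both with a warning, since dropping it from either would
silently bias the margins.

Each signature × response combination is cross-classified within the
working set and tested with Fisher's exact test. The default is
two-sided, with the upper-tail ("greater") p reported alongside: the
screen's aim is overrepresentation, but a two-sided default avoids
claiming directionality the table itself does not force. Significance is
a raw P < 0.01 threshold with no correction across signatures — the
screen is a per-signature decision rule — and a BH column can be added by
the caller across whatever family of records they consider one family.

# Term enrichment with BY control

Overrepresentation of annotation terms in a query list against a
background of expressed genes uses the hypergeometric upper tail
$P(X \ge k)$, inclusive at the observed count. The expressed background
is the set of genes with mean RPKM strictly above 20 in the control group
and in the treatment group; RPKM is computed with library size equal to
the column sum of the supplied counts. Aligner-reported totals (which
include reads not assigned to genes) would give slightly smaller RPKM;
the package is self-contained by design and documents rather than
resolves this divergence.

A term is called significant when the raw p < 0.05, the
Benjamini–Yekutieli adjusted value is < 0.1, and at least 5 query genes
map to the term. BY rather than BH is used because term memberships
overlap heavily (parents contain children), which violates the
independence/PRDS conditions under which plain BH is known to control
FDR; BY's harmonic-sum penalty is valid under arbitrary dependence.
Both adjustments wrap `stats::p.adjust`; `NA` p-values pass through as
`NA` and do not count towards the family size (p.adjust's convention).

# Proteomics summarisation and census

Per protein, the replicate log2 ratios (treatment channel over control
channel) are averaged and tested against 0 with a two-sided one-sample t
on $n_\text{detected} - 1$ degrees of freedom. A protein detected in
fewer than `min_detected = 3` of `n_total = 5` replicates is excluded
from every downstream statistic — exclusion, not imputation, because a
ratio seen in one or two replicates carries no usable within-protein
variance estimate. Zero replicate variance with enough detections is
flagged degenerate and given no p-value rather than $p = 0$.

The fold-change census over an annotation class bins detection-passing
members by their linear ratio $R = 2^{\bar{x}}$: decreased 20–90% iff
$0.10 \le R \le 0.80$ (both edges closed), increased more than 20% iff
$R > 1.20$. The prose conventions "between" and "more than" are
directional but not edge-exact, so the package fixes closed down-bin
edges and an open up-bin edge and warns when any protein sits exactly on
an edge, making the convention auditable. The census uses the mean log2
ratio and ignores significance: it describes abundance change, not
evidence strength. Both choices (mean vs median; censusing regardless of
p) are configurable-by-construction in the sense that the summary table
exposes all inputs.

# Metabolomics QC and ratio statistics

A sample passes QC iff its internal-standard peak area is at least
1×10⁵ (inclusive, "at least") and its absolute deviation from the batch
median internal-standard area is strictly less than 70% of that median
("less than"). The median is taken over all samples in the batch before
any rejection; a post-rejection median would make the filter's outcome
order-dependent. Peak areas are then divided by the same sample's
internal-standard area.

Each metabolite's response is the ratio of group means — explicitly not
the mean of per-sample ratios, which is biased upward for noisy
denominators; a regression test pins this convention with a constructed
counterexample. The p-value is a two-sided Welch t with
Welch–Satterthwaite degrees of freedom, computed on the normalised
intensities. Missing values are excluded pairwise per metabolite. A zero
control mean flags the ratio non-finite rather than erroring; two
constant identical groups give $p = 1$ by convention, flagged degenerate.

# The synthetic-data generator

Every pipeline input can be generated with known truth, fully determined
by one integer seed (per-generator substreams are derived
deterministically from it). Identifier shapes follow the field's
conventions (Si######m-style source ids, AT#G#####-style target ids) so
the id-join code paths are exercised realistically.

Defaults, chosen once as plausible study conditions and not revisited:

* paired fold changes: marginal sd 1.0 (transcript) and 0.6 (protein) —
  protein responses in ratio proteomics are typically damped relative to
  transcripts; mean 0.
* protein replicates: 5 per protein (the emulated design), measurement
  noise sd 0.3 on the log2 scale.
* metabolites: 5 samples per group, multiplicative log-normal noise with
  CV 0.1, internal standard around 2×10⁵ area units with CV 0.05;
  planted QC failures draw areas below 1×10⁵.
* counts: negative binomial with dispersion 0.05, library size 2×10⁷,
  3 samples per group, log-normal baseline means, gene lengths uniform
  on [300, 5000] bp, planted DE split half up / half down.
* signature experiments: the 2×2 joint law of (signature membership,
  response membership) is solved from the two marginals and the requested
  odds ratio (Plackett's quadratic), and genes are drawn independently
  from it — so set sizes are random around their targets but the
  population odds ratio is exact, and infeasible marginal/odds
  combinations are rejected.

What the generator does **not** emulate: count-level mean–variance trends
beyond a single dispersion, batch effects, missingness that depends on
abundance (proteomics missingness is missing-completely-at-random here,
while real label-based data are left-censored), retention-time drift or
peak-integration artefacts, and orthology errors. Passing the recovery
benchmarks therefore shows the statistics are implemented correctly and
behave as designed under their own assumptions — it does not certify
performance on real data, where those violated assumptions dominate.

One measurement subtlety: the internal-standard channel is shared by all
metabolites of a sample, so Welch tests within one simulated batch are
correlated, and the false-positive fraction of a single batch is a noisy
estimate of the test's type-I rate. The benchmark therefore pools ten
independent 1,000-metabolite batches when estimating that rate.

# Problem sizes and numerical checks

The test suite verifies the exact tests against brute-force oracles
(exhaustive enumeration of all 2×2 tables with total ≤ 30; direct
combinatorial tail sums for the hypergeometric, exhaustive to N = 20 and
randomised to N = 50; hand step-up FDR oracles), hand-derived
micro-examples, and parameter recovery at desk scale: 200 replicate
draws of 4 × 500-gene categories for correlation recovery, 1,000 draws
for the Fisher screen's type-I rate, and 10,000 null features for the
Welch and one-sample-t type-I rates. These sizes were chosen so the whole
suite runs in well under a minute on one CPU while keeping Monte Carlo
error small relative to the bands being checked.

# Known limitations

* The DESeq-style count model is consumed, not fitted: the package
  classifies externally computed per-gene statistics and computes RPKM
  backgrounds, by design.
* Orthology is an input; no ortholog inference is attempted.
* Pearson correlation is the only reported association measure per
  category (rank-based alternatives would be natural extensions).
* Census bin edges are a fixed documented convention; studies using
  different edge rules must adjust `down_lo`/`down_hi`/`up_min`.
* The scatter export is a static self-contained HTML/SVG artefact, not an
  interactive viewer.
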