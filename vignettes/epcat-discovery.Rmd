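---
title: "Outlier-profile discovery of cancer-associated transcripts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outlier-profile discovery of cancer-associated transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epcatr)
```

# The problem

Prostate cancer, like several other tumor types, overexpresses certain long
non-coding RNAs in a *subset* of patients only. A transcript present at high
levels in 20% of tumors and silent everywhere else is invisible to mean-based
differential expression, because the subset signal is averaged away. epcatr
implements a discovery pipeline built around cancer outlier profile analysis
(COPA): instead of comparing group means, every feature is rescaled by robust
statistics so that subset-specific overexpression stands out, and unannotated
features showing such outlier profiles — consistently, across independent
cohorts — are assembled into candidate lncRNA loci and pushed through
regulatory, prognostic, diagnostic and conservation follow-up analyses.

The features are exon-array *transcript clusters* (TCs): sets of probes
covering a putative transcribed region, including many regions with no known
gene annotation. Because a single array design is shared by all cohorts, the
same TC coordinates recur in every dataset, which is what makes cross-cohort
reconciliation meaningful.

# The discovery model

## COPA transform and outlier calling

For one TC with log2 expression vector $x$ over the samples of one dataset,

$$\mathrm{copa}(x_s) = \frac{x_s - \mathrm{median}(x)}{\mathrm{MAD}(x)},
\qquad \mathrm{MAD}(x) = \mathrm{median}_s\,|x_s - \mathrm{median}(x)|.$$

The MAD in the transform is deliberately *unscaled*: the normal-consistency
constant $0.6745$ enters only in the outlier threshold

$$t = \frac{2\,\mathrm{MAD}(\mathrm{copa}(x))}{0.6745},$$

and a sample is an outlier iff its score strictly exceeds $t$. This
reproduces the published formula literally rather than folding the constant
into the transform; the two choices differ in the numeric threshold value and
we follow the printed expression. Calling is one-sided because the target
phenomenon is subset-specific *over*expression.

The threshold MAD is computed over **all** samples of a dataset (controls
and cancers). The alternative — cancer samples only — is defensible, but the
formula refers to the full z-score vector without subsetting, so that is
what we implement.

Degenerate rows (raw MAD = 0, i.e. flat probes) get all-zero scores and an
empty outlier set rather than an error: a flat probe is uninformative, not
exceptional.

## TC filters

A TC is retained when it is (a) unannotated, (b) has **zero** outliers among
control-class samples, and (c) has outlier fraction $\geq$ 5% among
cancer-class samples. The boundary is inclusive: exactly 5% is retained
(the removal rule reads "fewer than 5%").

## Grouping and cross-cohort reconciliation

Within one dataset, retained TCs are joined by an edge when they share
chromosome and strand, the gap between their intervals is below 250 kb, and
the Spearman correlation of their COPA score vectors is $\geq 0.5$.
Candidate loci are connected components (single linkage; singletons are
legal). Proximity is the *gap between intervals*, not midpoint distance —
"less than 250 kb apart" reads as separation. Correlation is computed on the
continuous COPA profiles over all samples rather than on binary outlier
masks; the masks discard magnitude information and make ties ubiquitous at
small outlier counts.

Across datasets, loci are linked by same-strand span overlap of at least
1 bp; each component seen in $\geq 2$ datasets becomes a single candidate
(an "EPCAT"), its TC set the union over datasets (maximizing locus size),
its probe total summed over the *unique* member TCs. Candidates with fewer
than 12 probes are dropped. Names encode location:
`EPCAT<chrom><F|R><ordinal>`, `F`/`R` for forward/reverse strand, ordinal by
genomic start within (chromosome, strand). The original study's ordinals are
not reconstructible from public information and are not claimed.

## Positional classification

Against a known-gene annotation, the classifier applies a fixed precedence:
contains a same-strand gene's 5′ end → `overlap_5prime`; contains its 3′
end → `overlap_3prime`; any other same-strand overlap → `intronic`;
opposite-strand overlap only → `antisense`; no overlap → `intergenic`.

Two points here were genuinely open and are package decisions. First, the
precedence order when several gene relationships apply (5′ before 3′ before
containment) is ours. Second, a same-strand overlap that contains neither
gene end is necessarily full containment in the gene body; the five-class
vocabulary offers no separate label for containment that touches an exon, so
all such cases are labelled `intronic`. The annotation generator does create
two-exon gene models and places intronic test loci genuinely inside introns,
but the classifier itself does not consult exon structure.

# Downstream analyses

**Regulation.** Locus expression is the mean of member-TC log2 values per
sample. Treated/untreated comparison uses Welch's unequal-variance t-test
with Benjamini–Hochberg correction across tested loci; a call of `up`
requires q < 0.05 *and* linear fold change > 1.5 (`down`: < 1/1.5) — "more
than 50% change" is read symmetrically on the ratio scale. The expressed
filter is a configurable mean-intensity threshold (the source analysis used
one without stating it; the default here is no filter). Driver coexpression
flags require Spearman $\rho \geq 0.5$ and p < 0.05. ChIP-seq support means
at least one peak inside the locus span extended by 50 kb flanks.

**Prognosis.** Per locus, samples are split by exact k = 2
partition-around-medoids on the one-dimensional expression values
(exhaustive medoid-pair search; cost ties broken toward the
lexicographically smaller medoid pair, so the split is deterministic; the
larger-medoid group is "high"). The association statistic is the number of
event-positive patients in the high group; its p-value comes from 10,000
label permutations at fixed group sizes, with $p = \Pr(\text{perm} \geq
\text{observed})$. The $\geq$ convention (rather than strictly "more")
guarantees $p > 0$ and validity. Only enrichment in the high group counts:
the method screens overexpression markers of poor outcome. BH correction is
applied across loci within an endpoint; Kaplan–Meier curves and the
two-group log-rank test (delegated to the survival package) accompany each
split, with the no-events case reported as p = 1 with a warning.

**Diagnostics.** Empirical AUC uses the Mann–Whitney formulation with ties
counted half. The panel is a *linear* score $Xw$ — the minimal reading of
"weighing each marker" — and the weights are found by multi-start
Nelder–Mead over unit-norm weight vectors (empirical AUC is piecewise
constant, so gradient methods are excluded and the optimum is approached
from many starts: every single-marker unit vector, the equal-weight vector,
and seeded random directions). Because the single-marker vectors are
candidates, the returned training AUC can never fall below the best single
marker. ISH panels are binary: a core is positive iff its integer score
exceeds 0, the combined call is the union over markers, and the binary-score
AUC equals (sensitivity + specificity)/2. Fisher's exact test is two-sided
by the point-probability ("minlike") convention, the default of the original
analysis ecosystem. Printed percentages are reproduced by
half-away-from-zero rounding at the printed precision.

**Conservation.** Exon bases are concatenated in genomic order, tiled into
non-overlapping 50 bp windows, and the maximum window mean is the locus
score. Tiling (not sliding) follows the wording "averaged in 50 bp windows".
Two details are invented for determinism: a final short window stands alone
when it has $\geq$ 10 bases and is merged into the previous window
otherwise, and missing bases are excluded from means. Windows are
exon-concatenated rather than genomic because the score targets transcript
sequence, not intronic DNA. Control comparisons use Wilcoxon rank-sum tests
in both directions against coding-gene and repeat-region score sets supplied
as precomputed lists (sampling real annotation is out of scope).

# The synthetic world

Every stage is testable without downloads because the generator builds
multi-cohort worlds with known truth:

* **Shared array design.** One TC coordinate table for all cohorts, as on a
  real array platform. Synthetic chromosomes, deterministic layout.
* **True loci** (default 5): 3–5 member TCs of 4–10 probes each within a
  100 kb span. Per locus *and* dataset, a random 30% of cancer samples
  receive a +4 log2 shift — the same sample subset for every member TC, so
  members share one outlier profile, which is what grouping relies on.
* **Background** (default 300 TCs): baseline drawn per TC uniformly from
  log2 4–8 (arbitrary-unit array intensities without probe-effect
  modelling), Gaussian noise, SD 0.3.
* **Decoys**: 20% of background TCs are flagged annotated; half of those
  also carry an implanted outlier profile, so the annotation filter — not
  luck — must remove them.
* **Clinical tables**: Bernoulli events at group-specific rates;
  exponential times (mean 36 months for events, 60 for censoring). The
  cohort size used in calibration studies is 54 patients.
* **Peaks/conservation**: peaks inside the span for designated hit loci and
  far outside the flanked window otherwise; conservation tracks are
  Gaussian noise with designated elevated windows.

All randomness flows from one root seed through a fixed splitting scheme
(`root*1000 + purpose offset`), so every fixture is reproducible and
independent of evaluation order.

Defaults were verified *before* the suite was frozen: over 20 seeds the full
pipeline recovers 100/100 implanted loci with zero false candidates in
20/20 seeds. One default was set by that verification: with probe counts up
to 12 per TC, a single pure-noise TC can carry 12 probes and defeat the
minimum-probe filter on its own; 4–10 probes per TC (realistic for
exon-array TCs) restores the filter's intent that candidates need
corroboration from several grouped TCs.

What a green recovery test does **not** establish: the generator's Gaussian
shift is a stand-in — the distribution of outlier magnitudes in real tumors
is unknown; there are no batch effects, no probe GC/affinity structure, no
correlated background, and survival times are exponential. Green tests
certify the pipeline's logic, not array physics.

# Numerical choices and degenerate inputs

* Constant expression rows: degenerate, no outliers, no error.
* Constant vectors in Spearman correlation: undefined $\rho$, flag false,
  warning.
* PAM with all-equal values: error (no partition exists); ties in medoid
  cost broken deterministically.
* Log-rank with zero events: p = 1 with warning, curves constant at 1.
* Fisher's p compares point probabilities with the same relative tolerance
  (1e-7) used by `stats::fisher.test`, avoiding spurious inclusion or
  exclusion of tables at floating-point ties.
* Percentages round half away from zero (base `round()` is half-even and
  would print 22.535 → 22.5 anyway, but 63.05-type boundaries differ).
* Coordinates are 0-based half-open everywhere; BED I/O is shift-free.

# Known limitations

* The permutation association test is conservative at n = 54: its event-count
  statistic is discrete, so attainable p-values near 0.05 are coarsely
  spaced and the type-I error at $\alpha = 0.05$ is ≈ 0.027 rather than
  0.05 (verified against the exact hypergeometric tail). This is a property
  of the method at this cohort size, not an implementation artifact; the
  test never exceeds the nominal level.
* `optimize_panel_weights` guarantees no regression below the best single
  marker but is a heuristic: the global AUC optimum over weights is not
  certified (the objective is piecewise constant with combinatorially many
  plateaus).
* Cross-dataset locus identity is 1 bp same-strand span overlap — the
  simplest rule consistent with "detected in at least two datasets"; fuzzier
  matching (reciprocal-overlap fractions) was not required by the synthetic
  or described data.
* Whether pairwise $\rho \geq 0.5$ should hold between *all* locus members
  or only along linkage edges is undefined in the source description;
  connected components with edge-level thresholds are implemented, matching
  the published grouping figure.
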