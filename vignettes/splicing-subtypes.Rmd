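---
title: "Classifying tumour cohorts by prognostic alternative splicing"
author: "SpliceTypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tumour cohorts by prognostic alternative splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpliceTypes)
```

## The problem

Alternative splicing (AS) reshapes the transcriptome of tumours, and the
inclusion level of individual splice features — the percent-spliced-in
(PSI) value, a fraction in [0, 1] per event per sample — carries
prognostic information in glioma and other cancers. `SpliceTypes`
implements a complete cohort-analysis pipeline around that idea:

1. **Survival screening** of every splicing event: samples are split at
   the event's mean PSI and the two groups are compared by the log-rank
   test; events with `p < 0.01` are called prognostic.
2. **Consensus clustering** of samples on the prognostic events'
   standardized PSI, with a Monte-Carlo hypothesis test (null reference
   datasets) to decide how many splicing subtypes the cohort supports.
3. **Subtype signatures**: events whose mean PSI in one subtype exceeds
   every other subtype by a fold threshold at a controlled FDR, plus a
   two-group variant (e.g. IDH mutant vs wild type).
4. **Splicing-factor network**: signed Spearman edges between
   splicing-factor expression and event PSI, with a per-factor prognostic
   direction.
5. **Clinical characterization** of the subtypes: Kaplan-Meier
   summaries, annotation cross-tabs with association tests,
   therapy-stratified survival, and a PCA projection of the signature
   events.

Events come in the seven categories produced by exon-level splicing
quantification of RNA-seq: exon skip (ES), retained intron (RI),
alternate promoter (AP), alternate terminator (AT), alternate
donor/acceptor site (AD/AA) and mutually exclusive exons (ME).

## Survival screen

For event $e$ with PSI vector $x_e$ over $n$ samples, samples with
$x \ge \bar{x}_e$ form the high group (ties at the mean deliberately go
high so the split is deterministic; a constant event puts everyone in
the high group and is then excluded by the size filter). An event enters
the screen only if

* no sample has missing PSI for it, and
* both groups contain at least $\lceil 0.05\,n \rceil$ samples.

The 5% floor guards the log-rank test against splits driven by a few
outlying samples. For a 154-sample cohort the floor is 8; for 665
samples the ceiling rule gives 34, and a published convention of 33 can
be reproduced with the `minGroup` override of `inclusionFilter()` —
the fraction rule and a fixed count disagree by one sample at that
cohort size, so both are exposed.

The test is the unstratified, unweighted (Mantel-Cox) log-rank with a
1-df chi-square approximation, computed by `survival::survdiff()`. No
multiplicity correction is applied at this stage: the screen reproduces
a raw `p < 0.01` call, and the package's null-cohort tests check that
this keeps the type-I error at the nominal 1%.

Samples lacking survival time or status are dropped from the screen
(with a reported count) but retained for every non-survival operation.
The mean cutoff is computed on the post-alignment samples — i.e. after
dropping samples without survival data — so the split and the test see
the same cohort.

## Monte-Carlo consensus clustering

`consensusCluster()` follows the consensus-clustering recipe with a
simulated-null hypothesis test:

* For each candidate $k$ (default 2–8), draw `nResamples = 100`
  subsamples of 80% of the samples, cluster each with k-means (10
  random restarts; PAM is available as an option), and record for every
  sample pair the fraction of co-occurring resamples in which the pair
  co-clustered — the **consensus matrix**.
* The **PAC** (proportion of ambiguous clustering) is the mass of
  upper-triangle consensus entries inside the window (0.1, 0.9):
  0 when every pair is always or never co-clustered, 1 when all pairs
  sit mid-window.
* `nNull = 25` **null reference datasets** are drawn as multivariate
  normal noise whose feature covariance eigenstructure matches the
  input (sampled through the input's principal-component
  decomposition): cluster structure destroyed, correlation structure
  preserved. Each null is run through the identical consensus
  machinery, giving a null PAC distribution per $k$.
* **RCSI** $= \ln(\overline{\mathrm{PAC}}_{null} / \mathrm{PAC})$ and
  the add-one **empirical p** $= (1 + \#\{\mathrm{PAC}_{null} \le
  \mathrm{PAC}\}) / (1 + n_{null})$ summarize how much more stable the
  real data are than noise. The add-one estimator can never reach zero;
  note it also cannot fall below $1/(n_{null}+1)$, so at least 20 null
  datasets are needed before any $k$ can reach significance at 0.05.
* `selectK()` picks the significant $k$ with maximal RCSI, or declares
  "no structure". The full per-k table is always returned so an analyst
  can deliberately prefer a different significant $k$ (e.g. a larger
  one for finer granularity).

**A numerical subtlety.** With well-separated data, several $k$ can
reach PAC exactly 0 (e.g. $k = 2$ merging two of three true clusters
perfectly stably), making the raw RCSI ratio infinite for all of them.
Inside the wrapper the observed PAC is therefore clamped at the
resolution of the resampling scheme ($1/(\texttt{nResamples} \cdot n)$)
before the log-ratio, which ranks perfectly-stable $k$ by how unstable
their matched null is — and the null is most unstable at the finest
real partition. `rcsiAndPvalue()` itself keeps the documented
$+\infty$ sentinel so the formula-level contract is unchanged. Null
PACs are clamped at the same resolution so a degenerate all-zero null
cannot yield $-\infty$.

Final labels cut an average-linkage dendrogram of $1 - $consensus at
the chosen $k$ and are renumbered by decreasing cluster size. Features
(events) are standardized before clustering and must be complete —
guaranteed for events that passed the screen's missingness filter.

The resampling inner loop (subsample, k-means restarts, co-clustering
accumulation) is implemented in C++ (RcppArmadillo) and draws from R's
RNG, so a single `set.seed()`/`seed =` reproduces entire runs exactly.

## Signature rules

**Subtype-specific events.** Event $e$ is a signature of subtype $s$
when $\mu_{e,s} \ge 1.3\,\mu_{e,t}$ for *every* other subtype $t$ and
the BH-adjusted two-sided Mann-Whitney q of $s$ vs each $t$ is below
0.05. "30% higher" is read as a *relative* fold change (the absolute
reading, a PSI difference of 0.3, is one `fold` argument away). The BH
family is the full event-by-comparison set in a single pass — the most
conservative of the common choices, since the analysis does not state a
family. The fold rule makes signature sets provably disjoint: two
positive means cannot each exceed 1.3 times the other.

**Two-group events.** The published phrasing "exceeded twice the
difference between groups" is internally inconsistent (a mean cannot
exceed twice a difference in any dimension-consistent reading), so the
rule is implemented as a group-mean ratio $\ge 2$, consistent in style
with the signature rule, with a pseudocount $\varepsilon = 10^{-3}$
added to both means so near-zero PSI cannot produce unbounded ratios.
The rule is symmetric under relabelling: the selected set is invariant
and the direction labels flip.

Mann-Whitney tests use the normal approximation with tie correction
(`wilcox.test(exact = FALSE)`): PSI values tie frequently at 0 and 1,
where exact small-sample enumeration is unavailable anyway.

`rescaleUnit()` maps each event row onto [0, 1] for heatmap display;
constant rows map to 0 by convention and missing cells stay missing.

## Splicing-factor network

For each factor: expression is dichotomized at its mean, the groups are
log-rank tested, and the factor is *unfavorable* when the
high-expression arm has the smaller restricted-mean survival time
(integrating each KM curve to the shorter of the two arms' last
follow-up — a median can be unreached in either arm, an RMST cannot).
Edges are Spearman correlations between factor expression and event
PSI over shared samples; the network keeps $|\rho| > 0.45$ and
$p < 0.05$ (uncorrected by default, matching the published convention;
BH adjustment is a flag). The absolute-value reading of the coefficient
threshold is used so strong negative regulators qualify. The default
22-factor panel (12 reported cancer promoters, 10 suppressors) ships as
a replaceable text file; prognostic directions are always computed from
the data at hand, never hard-coded.

## Clinical report

Kaplan-Meier medians are defined as the first time the product-limit
curve drops to $\le 0.5$ — *not* survfit's midpoint interpolation when
the curve hits 0.5 exactly — with log-log 95% confidence intervals
(the CI method is not fixed by convention; log-log is the standard
choice that respects the [0, 1] range), and "NA" reported for unreached
medians or bounds. Cross-tab percentages are `100 * count /
denominator` rounded to one decimal, with unknowns excluded from
denominators and reported separately, so the emitted tables are
diffable against published clinical tables; a self-consistency check
recomputes every percentage from its counts on report emission.
Association uses chi-square with a Fisher fallback when any expected
cell is below 5. The PCA panel is centered and unscaled, with the
deterministic sign convention that each component's largest-magnitude
loading is positive.

## The synthetic cohort generator

`simulateCohort()` draws cohorts with known ground truth so every
stage is testable without controlled-access data:

* **Subtypes**: cluster labels from configurable proportions;
  *informative* events get cluster-specific beta means at two levels
  (defaults 0.3/0.7 — a 0.4 mean gap, comfortably above typical
  within-cluster spread at the default concentration of 50, whose beta
  s.d. is about 0.07); uninformative events share one mean per event.
* **Survival**: exponential times with log-hazard = per-cluster
  baseline (defaults 0.08/0.04/0.02 per month, i.e. median survival
  roughly 9–35 months, spanning the glioblastoma-to-low-grade range) +
  $\sum_e \beta_e \mathrm{PSI}_e$ over planted prognostic events
  (centered), times a per-cluster therapy hazard ratio for treated
  samples. Censoring is an independent exponential whose rate is
  matched per-sample so the configured censoring probability holds
  exactly in expectation.
* **Factors**: expression $= \exp(1 + s \cdot 3 \cdot
  \overline{\mathrm{PSI}}_{targets} + \mathcal{N}(0, \sigma))$ with a
  known link sign $s$. Each factor's target events additionally share a
  per-sample latent activity (a logit-scale shift of their beta means,
  s.d. 0.8). This coupling is deliberate: if targets were independent,
  the correlation between one target and the mean of $t$ targets is
  bounded by $1/\sqrt{t}$ — exactly 0.45 at $t = 5$ — and no edge could
  ever clear the network threshold, making sign-recovery tests vacuous.
  Co-varying targets are also what the correlation analysis biologically
  presumes: events under one trans-acting regulator move together.
  Planted hazard signs are blocked so one factor's targets share a
  direction, giving each factor a well-defined ground-truth prognostic
  direction.
* Missing PSI cells are inserted uniformly at the configured rate;
  clinical annotations (grade, histology, IDH, 1p/19q, MGMT, ...) are
  drawn with cluster-linked probabilities so cross-tabs carry signal.

What the generator does **not** emulate: TCGA's marginal PSI
distributions (multimodality, category-specific shapes), non-proportional
hazards, informative censoring, batch structure, or correlated
missingness. Tests passing on these cohorts therefore validate the
*algorithms and their calibration*, not performance on any particular
real dataset.

## Problem sizes and seeds used by the test suite

The packaged checks run at desk scale, chosen to keep the full suite in
a few minutes while leaving each property comfortable statistical room:
screen calibration on 300 samples x 2,000 null events across 5 seeds
(pooled 3-binomial-s.d. band around 0.01); cluster recovery on 150
samples, 40 events, planted $k = 3$ across 20 seeds (chosen $k$ and
ARI $\ge 0.9$ required in at least 18); pure-noise runs at 60 x 20
across 40 seeds (no significant $k$ allowed in more than 4); signature
brute-force agreement on 200 events; 1,000 random BH vectors; network
sign recovery and therapy stratification on 150–300-sample cohorts with
fixed seeds. All randomness flows through explicit seeds.

## Known limitations

* The screen is univariate: no multivariable Cox adjustment, no
  competing risks, and no multiple-testing control (by design, to match
  the published call rule).
* Consensus clustering inherits k-means' spherical-cluster bias; PAM
  mitigates but does not remove it.
* The network is signed correlation, not causal inference; factor
  directions are mean-split log-rank calls and share the screen's
  limitations.
* The event-id dialect requires gene symbols free of the `|`
  character.
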