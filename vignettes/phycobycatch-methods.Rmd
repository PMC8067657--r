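---
title: "Methods: filtering, diversity and prevalence analysis of heterotroph bycatch communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: filtering, diversity and prevalence analysis of heterotroph bycatch communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycobycatch)
```

## The problem

Long-term seawater enrichment cultures of the picocyanobacteria
*Prochlorococcus* and *Synechococcus* carry a "bycatch" community of
heterotrophic bacteria that persists for hundreds to thousands of
generations on host-derived organic carbon. Characterizing those communities
from 16S V4 amplicon data raises three method problems that this package
addresses end to end:

1. **Decontamination.** Libraries are prepared on 96-well plates, so a small
   fraction of each well's amplicon pool bleeds into neighbouring wells.
   Since most reads in a well come from the cyanobacterial host, even weak
   leakage plants convincing-looking low-abundance features in neighbours.
2. **Composition.** After host-read exclusion the communities must be
   compared by presence/absence phylogenetic distance (unweighted UniFrac),
   permutation statistics (PERMANOVA, beta-dispersion, indicator species
   analysis), and cross-dataset OTU clustering, because read abundances in
   host-dominated libraries are not quantitatively trustworthy.
3. **Context.** Culture prevalence must be compared against occupancy across
   ocean survey sites to ask which bycatch taxa are cosmopolitan, which are
   sparse, and which track picocyanobacterial abundance.

The raw study data are not required: a synthetic-data module generates
plates, mock communities and ocean site tables with the statistical
structure the analysis assumes, together with ground truth, so every filter
and estimator is testable for recovery of planted signal.

## The filters

Both filters act on the per-sample **relative abundance** table (each row of
the count table divided by its row sum), computed over all reads, host
included, because contamination physically involves the whole amplicon pool.
Host exclusion happens after filtering; both orders are supported.

**Adjacency rule.** For well $w$ and feature $a$, with $r_{w,a}$ the
relative abundance and $N(w)$ the occupied neighbouring wells,

$$ r_{w,a} \leftarrow 0 \quad \text{iff} \quad 0 < r_{w,a} < \theta \cdot \max_{w' \in N(w)} r_{w',a}, $$

with $\theta = 0.10$ by default. All comparisons are evaluated against the
input table simultaneously, so the result does not depend on well order.
The neighbourhood is the 8-cell ring (orthogonal plus diagonal,
`edge8`) by default, with the 4-cell rook neighbourhood selectable:
plate-scale contamination (aerosols, pipetting) is not axis-aligned, and the
8-cell choice is the conservative one (it can only remove more). The
inequality is strict on both sides, so an entry exactly at
$\theta \cdot \max$ is retained.

**Abundance floor.** Entries with $0 < r_{w,a} < 0.002$ (0.2%) are zeroed;
entries exactly at the floor are retained. The floor is calibrated from mock
communities: eleven members with distinct V4 regions combined either
equimolar or in a two-fold dilution series (most concentrated member
$2^{10} = 1024\times$ the least), three technical replicates.
`calibrate_floor()` reports the largest relative abundance reached by any
feature outside the design, i.e. the smallest floor that removes every
observed contaminant; the 0.2% default is retained when that maximum stays
below it.

Filtered tables are **not renormalized**: renormalization would silently
change other features' pass/fail status, and downstream presence/absence and
richness work directly on the filtered values.

**Order of the two rules.** The pipeline fixes adjacency → floor. A
structural note: with any ratio $\theta < 1$ the two orders provably agree
on the final table — an adjacent maximum large enough to zero an
above-floor entry ($> r/\theta \ge \text{floor}/\theta$) itself survives the
floor, while a below-floor maximum can only condemn entries that the floor
removes anyway. What does depend on the order is which rule the filter
report credits for entries below both thresholds; the test suite pins both
facts.

## Synthetic data: what it emulates, and what it does not

`simulate_plate()` gives each well one host feature (host fraction uniform
in 0.5–0.95 of reads, matching host-dominated libraries), a heterotroph
membership of 2–24 members drawn from a 300-feature pool, and within-well
proportions drawn log-normal ($\sigma = 1.5$) and normalized — a
few-dominant/many-rare shape. Cross-well leakage replaces each well's
expected composition by
$(1-\sum_k \varepsilon_k)\,m_w + \sum_k \varepsilon_k\, m_{w_k}$ over its
neighbours $w_k$, with independent $\varepsilon_k$ uniform in a configured
range (default 0.001–0.02); counts are multinomial at a depth drawn from
50,000–200,000 reads per well, around the study's average library depth.
Ground truth records every leaked (receiver, source, feature) triple and its
expected proportion, and the simulator's adjacency matches the filter's, so
truth and filter are commensurable.

The leakage model is a declared stand-in: the physical mechanism (index
hopping versus pipetting aerosols) is not modelled, nor are PCR errors,
chimeras or read-level quality. Passing recovery tests therefore shows the
filter removes *this* kind of diffuse neighbour-proportional contamination,
not that it is optimal for any particular mechanism.

`simulate_mock()` draws multinomial counts over the intended member
proportions plus a few spurious features whose expected relative abundance
is bounded by `contaminant_max_rel` (default 0.0015, i.e. below the 0.2%
floor, mirroring a mock run in which no contaminant exceeds the floor).

`simulate_sites()` emulates an ocean transect survey: 500 sites with
truncated-exponential depths (mean 300 m, max 5000 m, surface-weighted);
OTUs in three occupancy archetypes (cosmopolitan 0.9, intermediate 0.5,
sparse 0.05 site-occupancy probability); host read fractions that decay with
depth; and one designated cosmopolitan OTU whose log-abundance is generated
from the *normal scores* of the host fraction through a Gaussian copula with
Pearson parameter $2\sin(\pi\rho_s/6)$, so its Spearman correlation with
host abundance hits the configured target (default 0.3) in expectation.
Rank-based coupling was chosen precisely because the recovered statistic is
a rank correlation: the planted and measured quantities coincide by
construction. Optional depth-restricted OTUs (present only below a cut)
support depth-partition experiments.

All simulators are pure functions of their parameters and seed; row sums of
every simulated count table equal the drawn depths.

## Diversity machinery

**Unweighted UniFrac** is computed by accumulating, per branch, whether any
tip of its subtree is present in each sample; for a sample pair the distance
is unique branch length over branch length present in either sample.
Presence is "value > 0 after filtering"; abundances are otherwise ignored. A
root edge above the deepest split is excluded from numerator and denominator
— it subtends every tip, can never be unique, and conventions differ across
implementations; the choice is pinned by test, and the suite also checks
exact agreement with an independent implementation (picante) and
pseudometric behaviour on random instances.

**PCoA** performs Gower double-centering of $-d^2/2$ and returns
coordinates separately for positive- and negative-eigenvalue axes, so
squared distances are recoverable as (positive-block) − (negative-block)
squared differences. **Beta-dispersion** measures each sample's distance to
its group centroid as $\sqrt{\max(0, d_+^2 - d_-^2)}$ and tests the one-way
ANOVA F on those distances by permutation of group labels. The permutation
recomputes centroids and distances from scratch under each permuted
labelling (rather than permuting fixed distances), making observed and null
statistics exchangeable under the null — the type-I simulations below
confirm nominal behaviour. **Ward clustering** runs Lance–Williams updates
on squared distances with heights reported on the distance scale (the
`ward.D2` convention, matched against `hclust` in tests), with a
deterministic smallest-pair tie-break.

**Rarefaction richness** subsamples without replacement to a common depth
(default: the minimum per-sample total) and averages distinct features over
100 replicates; the replicate count and depth are package defaults, chosen
so the Monte-Carlo error is small relative to the hypergeometric closed form
$E[S] = \sum_i \left(1 - \binom{N-N_i}{d}\big/\binom{N}{d}\right)$ that the
tests use as the oracle.

## Permutation statistics

For a distance matrix with $N$ samples in $a$ groups, PERMANOVA uses

$$ SS_{total} = \tfrac{1}{N}\sum_{i<j} d_{ij}^2, \qquad
   SS_{within} = \sum_g \tfrac{1}{n_g} \sum_{i<j \in g} d_{ij}^2, \qquad
   F = \frac{(SS_{total}-SS_{within})/(a-1)}{SS_{within}/(N-a)}, $$

which reduces to the classical one-way ANOVA F for Euclidean 1-D input (an
identity the tests assert to 1e-8). The indicator statistic for feature
presence is $\sqrt{A_g B_g}$ maximized over groups, with fidelity
$B_g = I_g/n_g$ and group-size-equalized specificity
$A_g = (I_g/n_g) / \sum_k (I_k/n_k)$ — the presence/absence, size-corrected
IndVal variant. Every permutation p-value uses the
$(1+\#\{\text{null} \ge \text{obs}\})/(1+n_{perm})$ convention (never
exactly zero), defaults to 1000 permutations, and is seed-reproducible;
pairwise post-hocs (both pairwise PERMANOVA and pairwise dispersion are
provided, labelled) are Bonferroni-adjusted for the number of pairs.

Classical pieces use their textbook forms: the Fisher 2×2 two-sided p sums
hypergeometric probabilities not exceeding the observed table's (1e-7
relative slack, validated against exhaustive enumeration for all margins up
to 15); Spearman is Pearson on mid-ranks with a t approximation for
$n > 9$ and exact enumeration of all $n!$ pairings for $n \le 9$; and
Goodman–Kruskal $\tau(x \to y)$ is the proportional reduction in Gini
variation of $y$ given $x$ — asymmetric, 1 exactly when $y$ is a function of
$x$ (clades nested in ecotypes), 0 under independence.

A note on discreteness: permutation tests on presence/absence statistics are
exact but conservative, because the statistic takes few distinct values and
ties at the observed value inflate p. In the null calibration the rejection
rate at $\alpha = 0.05$ is nominal for PERMANOVA and beta-dispersion at 20
samples, while the indicator test needs larger communities (the suite uses
100 samples) before its attainable p-values are dense enough for the rate to
approach nominal; it remains conservative (about 0.03–0.04), never
anticonservative.

## OTU clustering

Pairwise identity is computed from a Needleman–Wunsch global alignment
(match +5, mismatch −4, gap open −10, gap extend −1) as matching columns
over alignment columns **excluding terminal-gap columns**, so amplicons
nested inside longer ones — the actual cross-dataset situation, where
different primer pairs yield nested V4 spans — are compared over their
shared span. Alternative definitions (count terminal gaps; divide by the
shorter length) are selectable, because the identity formula of the tool
this approximates is not its documented behaviour. `N` never counts as a
match. Greedy clustering processes sequences in decreasing abundance (ties:
longer first, then lexicographic id) and joins each sequence to the *first*
centroid, in founding order, at or above the threshold (97% default) —
first-fit, not best-fit, the standard greedy-centroid convention; the rule
is pinned by a fixture where first-fit and best-fit disagree. Membership is
verifiable post hoc: every member is within threshold of its centroid under
exhaustive recomputation, and lowering the threshold never increases the
OTU count.

## Prevalence and ocean context

Taxon prevalence aggregates features to a rank (a taxon is present when any
member feature is) and per-taxon 2×2 host-genus contingencies feed the
Fisher test with Bonferroni adjustment across taxa. Site tables normalize
OTU counts by non-host reads; occupancy-based labels use cut points 0.75
(Cosmopolitan) and 0.25 (Sparse) — invented, configurable defaults for a
qualitative published classification, reported alongside every result. The
depth partition fixes its cut at 200 m (the epipelagic base), assigning
sites exactly at 200 m to "above". Combined host abundance is the sum of
both host genera's assigned reads.

## Numerical and degenerate-input conventions

* Samples with zero reads stay all-zero through normalization; pairs of
  empty samples get `NA` UniFrac distances; samples with zero host reads are
  flagged and emitted as missing by host normalization, never as infinities.
* PERMANOVA with zero within-group variance returns a flagged missing
  statistic rather than an infinite F.
* Absent-everywhere features are emitted as missing by the indicator
  analysis; constant inputs give a flagged missing Spearman rho.
* Readers reject malformed input (duplicate labels, negative counts,
  off-grid wells, double-booked wells) with coordinates, rather than coerce.
* Well labels are case-insensitive and zero-padding-insensitive
  ("a01" ≡ "A1").

## Problem sizes used by the test suite and acceptance script

Oracle-equivalence runs use 200 random 96-well/50-feature plates;
pseudometric and agreement properties use 100 random tree/presence draws;
type-I calibration uses 500 null data sets per test at 199 permutations
(20-sample communities for PERMANOVA/dispersion, 100 for the indicator
test); Fisher enumeration covers every 2×2 table with all margins ≤ 15;
parameter recovery uses 500-site surveys. These sizes make Monte-Carlo
standard errors small relative to the tested tolerances while keeping the
default run fast.

## Known limitations

* The leakage model is proportional and neighbour-local; plate-wide
  index-hopping background is not modelled.
* Greedy clustering is exact (all-pairs alignment), intended for the
  hundreds-of-features scale of culture collections, not for
  metagenome-scale input; no k-mer prefilter is provided.
* Only univariate (and two-group restricted) PERMANOVA is implemented;
  marginal multi-factor decompositions with interactions are out of scope
  and deliberately not approximated.
* The synthetic plate draws well memberships independently of host identity,
  so host-associated composition effects are absent unless planted; null
  results of the bundled analysis scripts on those factors reflect the
  simulation, not the method's power.
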