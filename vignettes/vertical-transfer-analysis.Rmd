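---
title: "Quantifying mother-to-child microbiota transfer with the weighted-ratio statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mother-to-child microbiota transfer with the weighted-ratio statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific setting

A child delivered vaginally meets its first large microbial inoculum in the
birth canal. Whether that exposure seeds the infant gut and airway
microbiota is a question about *vertical transfer*: are the taxa present in
a mother's vaginal community at birth over-represented in *her own* child,
relative to what unrelated mother-child pairings would show? vertiseq
implements an analysis pipeline for longitudinal 16S rRNA OTU tables from
mother-child cohorts — vaginal samples at pregnancy weeks 24 and 36 and at
birth, child feces and airway samples at one week — together with a
synthetic cohort generator so that every stage can be validated without
sequence data.

## The transfer model

### Per-OTU Fisher scan

For one child compartment and $n$ dyads, each OTU yields a $2 \times 2$
table crossing presence (count $> 0$) in the mother's vaginal birth sample
with presence in her child's sample. Only OTUs with presence counts
strictly between $0$ and $n$ on **both** margins are informative: an OTU
carried by every mother (or no child) cannot discriminate matched from
mismatched pairs. Each eligible table is summarised by its sample odds
ratio $OR_i$ (with the Haldane–Anscombe $+0.5$ on all four cells when any
cell is zero, so log-odds stay finite) and a two-sided Fisher exact
p-value $p_i$, computed by summing hypergeometric probabilities not
exceeding that of the observed table — the convention of standard Fisher
implementations, including the $(1 + 10^{-7})$ relative slack against
floating-point ties.

### The weighted ratio

Individual OTU tests at cohort scale are underpowered, and in practice few
or none survive FDR control. The pipeline therefore aggregates the whole
scan into an enrichment statistic, the weighted ratio

$$
WR \;=\; \frac{\sum_{i \,:\, OR_i > 1} \log(OR_i)\,\log(p_i)}
              {\sum_{i \,:\, OR_i < 1} -\log(OR_i)\,\log(p_i)},
$$

the ratio of "association mass" carried by positively versus negatively
associated OTUs, where each OTU's weight grows with both the magnitude of
its odds ratio and the strength of its evidence ($\log p_i \le 0$, so both
sums are negative and WR is positive). Under no mother-child association
the two sides are exchangeable and the expectation of WR is 1. Properties
worth noting:

* **Log-base invariance.** WR is a ratio of products of two logarithms, so
  any common base cancels; natural logs are used internally.
* **Equivariance.** Swapping the roles of positive and negative
  associations ($OR \to 1/OR$) maps $WR \to 1/WR$.
* **Conventions at the boundary.** $OR_i = 1$ contributes to neither sum;
  $p_i = 1$ carries zero weight. An empty denominator with a non-empty
  numerator returns `Inf` (flagged, and ranked above every finite value in
  the permutation test); the mirror case returns 0; both sides empty is
  undefined (`NaN`, p reported as `NA`).

### Permutation null

Significance comes from scrambling the dyad pairing: a uniformly random
permutation of the child assignment (identity permitted), full re-scan,
and WR recomputation, repeated $B = 999$ times by default; the one-sided
upper-tail p is $(1 + \#\{WR_{null} \ge WR_{obs}\})/(B+1)$. Because both
margins of every table are invariant under permutation of the child
labels, the eligibility set is identical across draws — this is asserted
in the tests and exploited for speed: per margin pair $(m, c)$ the Fisher
p and log-OR are precomputed for every attainable concordant count, so a
permutation draw reduces to a row-sum and a table lookup.

### Descriptors around the scan

* **Abundance vs odds**: Spearman correlation between an OTU's mean
  relative abundance in the vaginal birth samples and $\ln OR$, asking
  whether abundant taxa transfer more readily.
* **Phylogenetic signal**: a Mantel-type statistic correlating patristic
  distances with pairwise $|\Delta \ln OR|$ (Spearman version), squared to
  an $R^2$, with p from leaf-label permutations. The method behind
  published "phylogeny vs transfer odds" correlations is generally
  under-specified; this variant is one reasonable choice and its $R^2$
  scale should not be compared across implementations.
* **Dyad distances**: mean beta-diversity distance between matched
  mother-child pairs versus the same mean under random re-pairing,
  one-sided lower tail. Jensen–Shannon divergence is the default metric,
  being the most sensitive to shared presence structure.

## The synthetic cohort generator

`simulate_cohort()` produces cohorts with the statistical structure the
analysis assumes, plus ground truth for recovery tests. Defaults define
the study conditions:

* **Design**: 57 dyads, each with vaginal samples at w24/w36/birth and
  child feces + airway samples at week 1; 300 OTUs on a random bifurcating
  tree (exponential branch lengths, mean 0.1) partitioned into five
  monophyletic clades with order-like names.
* **Vaginal succession**: the Lactobacillus-like clade holds an expected
  share $\mathrm{logit}^{-1}(\mathrm{logit}(0.8) - 0.5\,t)$ at timepoint
  $t = 0, 1, 2$ — roughly $0.80 \to 0.73 \to 0.64$ — emulating declining
  *Lactobacillus* dominance toward birth. Within-clade profiles combine a
  cohort-level base profile with subject-specific lognormal offsets
  (SD 1.0 on the log scale) shared across a mother's three timepoints,
  giving each woman a persistent individual signature.
* **Child communities**: expected composition
  $\pi \cdot (\text{mother's birth composition masked to transfer-prone
  clades, renormalised}) + (1-\pi) \cdot \text{environmental pool}$.
  The pools are cohort-level Dirichlet draws — feces over 60% of OTUs,
  airway over a sparser 30%, echoing the lower richness of early airway
  communities — so unrelated dyads share plenty of OTUs, as real data do
  through ubiquitous taxa. $\pi = 0$ is the null; $\pi = 0.3$ is the
  signal preset used in power checks.
* **Counts**: Dirichlet-multinomial with precision 200 (moderate
  overdispersion beyond multinomial noise) at lognormal depths. The
  "study" preset has median depth ~40,000 reads; the "test" preset
  (median ~2,000) is used throughout the test suite and acceptance
  computations — presence/absence-based statistics are insensitive to the
  depth scale, and simulation studies then run in seconds.

What the generator deliberately does **not** emulate: strain-level
structure, compositional interactions between taxa (counts are
conditionally independent given the expected composition), missing
samples, cesarean deliveries (a `delivery_mode` column exists and is
honoured by the pipeline filter, but the default cohort is all-vaginal),
and any fitted correspondence to a real cohort's parameters. Passing
recovery tests on these cohorts shows the statistics behave as designed
under the stated model, not that real transfer effects are of any
particular size.

## Diversity and succession components

* **Alpha diversity**: richness, Shannon entropy (natural log), and
  Faith's PD. PD is rooted-inclusive — the total branch length of the
  union of root-to-leaf paths of observed taxa — following the original
  definition's common implementation.
* **Variance split**: per-sample diversity is decomposed by sequential
  (type-I) ANOVA into subject and timepoint contributions, subject first
  by default, so the subject fraction reads as "variation allocated to
  the individual mother". Both orders are available since sequential SS
  are order-dependent.
* **Beta diversity**: unweighted UniFrac (branch presence), normalised
  weighted UniFrac (values in $[0,1]$), Jaccard, Bray–Curtis, and JSD
  (natural log, no square root; finite without pseudocounts since
  $0 \ln 0 = 0$).
* **Ordination**: classical PCoA via double-centring; axes with
  eigenvalues below $10^{-10} \times \lambda_{max}$ (or negative) are
  dropped and the proportion explained is taken over positive eigenvalues.
  No Lingoes/Cailliez correction is applied.
* **PERMANOVA**: vegan's `adonis2` with sequential terms and free row
  permutation, the default of the tool this reproduces. With repeated
  measures per woman, free permutation is a faithful reproduction of
  common practice rather than a statistical endorsement; a
  restricted-permutation design would be stricter.

## Sharing partition and co-occurrence network

OTUs are partitioned by the seven regions of the vaginal/feces/airway
Venn diagram ("ubiquitous" = present in all three), with each region's
share of total reads. Within-compartment correlations use SparCC —
Dirichlet(count + 1) resampling of fractions, log-ratio variances reduced
to basis variances under the sparsity approximation, iterative exclusion
of the most correlated pair (up to 10 rounds, threshold 0.1), median over
20 inner iterations — implemented here from the original algorithm, since
no R implementation ships with the supported stack. Edges keep the
maximum correlation across compartments and prune at $r \le 0.2$ on the
signed value, so strong negative correlations are excluded by design.

## Genus-level testing

The top 15 genera by mean relative abundance over all vaginal samples are
tested across the three timepoints (Kruskal–Wallis; a genus with
literally constant abundance is reported at $p = 1$), with all pairwise
paired Wilcoxon contrasts within mother (exact distribution up to $n=25$
pairs, normal approximation beyond; mothers missing a timepoint are
dropped from that contrast). Benjamini–Hochberg control is applied
*within the top-15 family only*, so the q-values of the reported set do
not depend on genera outside it. A $+10^{-6}$ pseudocount log transform
is provided for display only and never feeds the tests.

## Numerical and engineering choices

* The 2000-read depth filter reads "below" strictly: a sample with
  exactly 2000 reads is retained. The filter is applied before any dyad
  restriction.
* Presence means count $> 0$; no relative-abundance floor.
* Rarefaction is a single multivariate-hypergeometric draw per sample
  (without replacement), seeded.
* Unassigned taxa at the aggregation rank are pooled under their deepest
  assigned ancestor as `unclassified_<ancestor>`.
* All randomness flows from explicit integer seeds; `simulate_cohort()`
  uses `seed` for the tree and `seed + 1` for everything else, and the
  pipeline derives stage seeds as `seed + 1, 2, 3` (recorded in its
  manifest). Identical configuration implies byte-identical outputs.
* Problem sizes in the test suite: oracle checks run at exhaustive-small
  scale (all $2\times2$ tables to $n = 12$, 8-leaf trees, 6-20-sample
  distance matrices); calibration and recovery studies use 200 replicate
  cohorts at the full 57-dyad design with the test depth preset, and
  50 paired replicates for the $\pi = 0.3$ vs $\pi = 0$ comparison —
  sizes chosen so the whole suite completes in about a minute while
  keeping Monte Carlo error well inside the asserted bands.

## Known limitations

* The per-OTU scan treats OTUs independently; no FDR-controlled claims
  are made at the OTU level, and the WR aggregates evidence rather than
  identifying individual transferred taxa.
* Free permutation in PERMANOVA ignores the repeated-measures design.
* The phylogenetic-signal Mantel variant has limited power when
  transfer-prone clades are small or branch lengths uninformative.
* SparCC estimates degrade below a few dozen samples per compartment;
  the network stage caps the OTU set by abundance for tractability.
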