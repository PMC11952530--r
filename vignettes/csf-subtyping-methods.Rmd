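---
title: "Methods: harmonization, co-expression modules and proteomic subtyping of CSF cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonization, co-expression modules and proteomic subtyping of CSF cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`csfsub` implements a complete analysis chain for multi-batch tandem-mass-tag
(TMT) cerebrospinal-fluid proteomics: harmonization of log2 relative
abundances across TMT batches and proteomic sets, weighted co-expression
module discovery, modularity-based clustering of *samples* into proteomic
subtypes, cross-cohort subtype transfer, and the statistics used to
characterize subtypes (demographic enrichment, biomarker contrasts, and the
response of protein modules to plasma spiked into CSF). Because the real
cohorts behind such analyses are controlled-access, the package ships a
synthetic cohort generator whose planted structure supplies ground truth for
every stage; all tests and the acceptance script run on it.

## The generative model behind the synthetic cohorts

Each planted module $m$ is driven by one latent factor per sample,

$$F_{m}(i) \;=\; \delta_{m,\,s(i)} \;+\; \sum_t \beta_{m,t}\, x_t(i) \;+\;
\varepsilon_{m}(i), \qquad \varepsilon \sim \mathcal N(0, 1),$$

where $s(i)$ is sample $i$'s planted subtype, $\delta$ the module-by-subtype
mean shift, and $x_t$ the encoded clinical traits (z-scored age, male sex,
self-identified race, diagnosis). A protein $p$ in module $m$ is

$$y_p(i) \;=\; \mu_p + a_p F_m(i) + e_p(i) + b_{p,\mathrm{batch}(i)} +
s_{p,\mathrm{set}(i)},$$

with loading $a_p$ set from the requested within-module correlation $r$ via
the closed form $r = a^2 / (a^2 + \sigma^2)$ (residual SD $\sigma$ =
`noise_sd`, default 0.5 log2 units), and independent Gaussian batch and set
offsets per protein. This latent-factor model is the minimal one under which
correlation-network modules and modularity-based sample subtypes are *both*
well defined, so planted labels are a meaningful oracle for the whole chain.

Three design choices in the generator matter enough to call out:

* **The GIS is a fixed pool.** Global internal standard channels are modeled
  as one cohort-wide mean profile re-measured in every batch with that
  batch's offset (plus channel noise of SD `noise_sd`/2). A reference whose
  *composition* varied per batch would make GIS centering strip each batch's
  biological make-up — in our tracing that cost about a quarter of a planted
  sex effect — which is not what a pooled standard does.
* **Subtypes come in opposite pairs.** Each subtype elevates one dedicated
  module and depresses the module of its opposite subtype (pairs 1–4, 2–5,
  3–6; default magnitude 3 factor-SD units). Subtype 3 is the
  blood–brain-barrier-like state (high plasma module M1, low tau/neuronal
  module M2, male- and AA-enriched, driving the albumin-ratio trait of
  replication cohorts) and subtype 6 its neuronal mirror image. This
  geometry keeps all inter-module factor covariances non-positive, so a
  *signed* network never confuses module separation with subtype structure,
  while the subtypes stay far apart in factor space. With six subtypes and
  ten modules, mutual orthogonality of more than six subtype-carrying rows
  is impossible; any same-sign sharing of a subtype between two modules
  re-couples their factors, and an eigenprotein merge at cut height 0.7
  (correctly) fuses modules whose factors correlate above 0.3.
* **Trait-effect modules are subtype-neutral.** Planted trait effects live
  on M1 (sex, race up), M2 (diagnosis up; sex and race *down*, matching the
  direction of tau differences reported in CSF cohorts), M4 (diagnosis,
  age) and M7 (age, sex); M4 and M7 carry no subtype shifts. A module whose
  factor SD is inflated to ~2 by subtype structure dilutes a 0.4-log2 trait
  effect to a correlation of ~0.1 — below per-seed sampling noise, hence a
  sign that no method could recover reliably. Effects are sized so every
  planted sign sits at least ~3.5 standard errors from zero at 200 samples.

Missingness is abundance-dependent (logistic in the z-scored log2 value,
slope `abundance_dependence`, intercept solved so the marginal rate matches
`rate`), emulating left-censoring in MS data. Immunoassay tTau, pTau and
Abeta are generated from designated planted proteins (a "MAPT-like" protein
in M2 and an amyloid-like protein in M4) on set-specific platform scales, so
the per-set z-scoring step is load-bearing. The tTau/Abeta ratio is
constructed so that roughly 4–6% of samples violate the 0.226 diagnosis rule,
exercising QC.

What the generator does *not* emulate: peptide-level structure, ratio
compression, isotope-channel cross-talk, non-Gaussian heavy tails, and
module overlap (each protein belongs to at most one planted module). Passing
tests therefore demonstrate correctness of the algorithms under the stated
model, not performance guarantees on real spectra.

## Harmonization

`tampor()` is an iterative two-way median polish of abundance ratios on the
linear scale: per protein and batch, divide by the median over that batch's
center samples (GIS channels, or a designated reference group); per sample,
divide by the median ratio across proteins; alternate until the largest
per-cell log2 change falls below `tol` (default 1e-8, cap 250 iterations —
random 200 x 60 matrices converge in well under 20). After convergence the
center-sample median is exactly 0 (log2) for every protein in every batch.
`two_round_harmonize()` applies the GIS round within each set, then one
reference-group round across sets (set treated as batch), dropping the GIS
channels it has consumed.

Two properties deserve emphasis. First, TAMPOR's sample-median step removes
whatever trait signal lives in the proteome median; that is intrinsic to
median normalization, so "preserving biology" is always relative to the
median-normalized target. Second, the GIS channels' own measurement noise
re-enters as an irreducible per-batch offset of SD
$\sigma/(2\sqrt{g_{\mathrm{GIS}}})$; TAMPOR alone therefore leaves a few
percent of batch variance, and the stage is only complete after
`regress_batch()` — per protein, dummy-coded batch/set coefficients averaged
over 50 seeded bootstrap resamples (a single full-sample fit reduces to
plain OLS removal), subtracting only the nuisance component while age, sex,
race and diagnosis stay untouched. Nuisance factors nested in one another
(set inside batch) are silently redundant; a protected covariate confounded
with a nuisance factor raises an error naming it.

`variance_explained()` attributes per-protein variance by sequential OLS
sums of squares in a fixed factor order. Order matters: a factor placed
early collects the chance-collinear share of everything after it (a pure
noise protein hands a k-level factor about $(k-1)/(n-1)$ of its variance).
When we report "residual batch variance" we therefore order batch last, so
the number is batch's *unique* contribution.

Imputation is a deterministic protein-profile KNN (`impute_knn`): distances
are mean squared differences of row-standardized profiles over co-observed
samples; a missing cell takes the mean of the k = 10 nearest proteins
observed there, falling back to the protein median when no co-observed
neighbor exists.

## Co-expression network

The statistic throughout is the biweight midcorrelation: observations
weighted by the Tukey biweight around the row median, weights vanishing
beyond 9 MADs, with a Pearson fallback for zero-MAD rows. The network is
*signed* — adjacency $((1+\mathrm{cor})/2)^\beta$ with $\beta = 6$ — so the
anticorrelation between the plasma and neuronal modules (the core of the
subtype biology) maps to adjacency near zero rather than being folded into
similarity. Topological overlap is the standard
$(\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$.

Branch cutting (`cluster_and_cut`) descends the average-linkage tree of
$1-\mathrm{TOM}$ top-down. A node splits when both children hold at least
`min_module_size` proteins and the merge sits above the children's core
heights (the 60th percentile of their internal merge heights, a tolerance of
up to ~40% chained stray proteins per branch) by a gap mapped from
`deep_split`: fractions 0.20 / 0.12 / 0.06 / 0.03 / 0.015 of the tree's
height span for sensitivities 0–4 (default 2). Single stray branches chained
onto a large one are shed and re-attached afterwards by a midpoint rule:
a stray joins its closest module only if its average dissimilarity to it is
below the midpoint of that module's internal and between-module levels.
A tree without height structure yields no modules. Modules whose
eigenproteins (first right singular vector of the row-standardized
submatrix, sign-aligned so mean member kME is positive, scaled to unit
variance) correlate above $1 - 0.7$ are merged iteratively, then labels are
re-ordered by size (M1 largest). Module–trait associations are eigenprotein
bicor values with Student-t p-values, using only the set-1 sample of
replicated subjects; marker-set enrichment is the one-tailed hypergeometric
(Fisher) test against the network background.

## Sample subtyping

Features are the top 30 members of each module by own-module kME. Sample
similarity is the signed transform of sample–sample bicor at soft power 13,
sparsified by keeping the $\lceil nk/2 \rceil$ globally heaviest edges
(target mean degree $k$). Community detection is a seeded multilevel greedy
modularity maximization (weighted Newman–Girvan $Q$, ten restarts, best $Q$
kept) with the size constraints applied afterwards: communities above the
maximum size are recursively re-clustered on their induced subgraph,
communities below the minimum are dissolved into their strongest neighbor
(or left unassigned when isolated). On graphs small enough to enumerate all
partitions the detector reaches the global optimum in at least 95% of random
instances; `modularity_q` itself is exact against direct evaluation and an
independent graph library.

The grid search over minimum size $i \in \{10,15,20,25\}$, maximum size
$j \in \{100,\dots,400\}$ and degree $k \in \{25,50\}$ scores each cell by
replicate-pair consistency first (same-subject samples measured in both sets
landing in the same subtype), modularity $Q$ as tie-break, under the
constraint of 2–12 communities; the full score table is returned for audit.
That winner criterion is our reading of "selected based on performance":
technical replicates are the only label-free ground truth a real cohort
offers. Pairs split across subtypes are listed for exclusion; such samples
are systematically peripheral, which `hub_correlation` (Pearson correlation
of each sample with its subtype's leave-self-out mean hub profile) makes
visible.

## Cross-cohort transfer

Transfer operates on the hub proteins shared with the query cohort, each
standardized *within its own cohort* so platform scale and global abundance
shifts cancel. The deterministic default (`linear_fallback`) reduces the
standardized features by PCA (at most 20 components) and fits a linear
discriminant analysis; assignment uses Euclidean distance to class centroids
in the full $(c-1)$-dimensional whitened discriminant space, with the first
two dimensions serving as plot coordinates. We deliberately do not assign in
only two dimensions: with six classes the centroid geometry is
five-dimensional, and any 2-D linear projection collapses some class pair
enough to cost several percent of self-consistency. The stochastic
`supervised_umap` mode (label-supervised 2-D embedding, n_neighbors = 10,
min_dist = 0.1, Euclidean) reproduces the nonlinear variant. A query
strictly more than `cutoff` (default 3) embedding units from every centroid
is left unassigned; the boundary itself assigns. The cutoff is
scale-dependent — in fallback mode one unit is one within-class SD — and is
exposed with that caveat.

Subtype signatures are per-protein subtype means minus the reference-subtype
mean, z-scored across the non-reference subtypes with the sample (n−1) SD;
the reference column is dropped and constant proteins removed. Cross-study
comparison is bicor between signature columns over shared proteins.

## Dilution response and figure statistics

`generate_dilution_series()` spikes plasma volume fractions (default 0,
0.001, 0.01, 0.1, 1 — percent units) into a pooled baseline: plasma-like
proteins gain linearly ($1 + 2.8 f$, about +280% at the top fraction),
neuronal-like proteins decay multiplicatively ($e^{-0.3 f}$, about −26%),
a protected class and bystanders stay flat. `dilution_response()` reports
percent-of-baseline per protein (linear scale; the baseline row is exactly
100 by construction), module mean curves over the subtyping hubs, the
log2-ratio-on-fraction slope per module, and a Tukey-adjusted one-way ANOVA
between baseline and top fraction with proteins as repeated units — an
explicit simplification of a repeated-measures layout.

Group contrasts use type-II sums of squares (robust to imbalance) with Tukey
HSD over factor-combination cells; with two groups the Tukey p-value equals
the pooled-variance t-test. Subtype demographic enrichment is a 2x2
chi-squared without continuity correction per subtype against the rest,
falling back to Fisher's exact test when an expected cell drops below 1.
The 3-SD trim is a plotting convention only and never feeds statistics.

## Problem sizes and reproducibility

The test suite and the acceptance script use desk-scale instances chosen to
make each property measurable: 600-protein / 200–400-subject cohorts for
module and subtype recovery, a 2,000 x ~300 instance for harmonization at
scale, 100 random graphs of up to 8 nodes for exhaustive modularity
enumeration, and a 1,000-protein / 430-subject cohort (two sets, ~30
replicate pairs, a 120-sample replication cohort at 40% protein overlap) for
the end-to-end acceptance run. Every stochastic step is seeded; rerunning
the pipeline with the same configuration reproduces byte-identical outputs,
which `run_pipeline()` checks via checksums in its manifest.

## Known limitations

* The generator's modules are disjoint and factor-driven; real CSF modules
  overlap and carry hierarchical correlation structure beyond one factor.
* Replicate pairs share their latent factors exactly, so consistency is
  optimistic relative to re-drawn aliquots; a weaker-separation regime is
  used to study the behavior of split pairs.
* The dynamic branch cut is a re-implementation from the published
  description of the hybrid method, validated by planted-structure recovery
  rather than numeric agreement with the reference implementation.
* The distance cutoff for transfer unassignment is meaningful only relative
  to the embedding's scale.
* MoCA-based QC incongruence is off by default: the exact rule behind the
  reported exclusions is not stated, and we prefer not to invent thresholds.
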