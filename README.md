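# csfsub — co-expression network subtyping of CSF proteomic cohorts

Cerebrospinal-fluid (CSF) proteomes measured by multiplexed tandem-mass-tag
(TMT) mass spectrometry carry strong technical structure — per-plex ("batch")
and per-study ("set") offsets, reference channels, missing values — on top of
the biology of interest: co-regulated protein modules whose abundance
patterns stratify individuals into molecular subtypes of Alzheimer's disease
and related states. `csfsub` is an R package plus a scripted analysis
workflow for that problem, aimed at proteomics analysts who need the whole
chain in one tested place:

1. **Harmonization** — TAMPOR, an iterative two-way median polish of
   abundance ratios centred on global internal standard (GIS) channels and a
   reference group, followed by seeded bootstrap regression that removes
   remaining batch/set variance while protecting age, sex, race and
   diagnosis; ≥50% missingness filtering, deterministic KNN imputation,
   per-set biomarker z-scoring and tTau/Aβ ≥ 0.226 diagnosis QC.
2. **Module discovery** — signed weighted co-expression network from the
   biweight midcorrelation (`bicor`): adjacency ((1+cor)/2)^β with β = 6,
   topological overlap TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j)+1−a_ij),
   average-linkage tree with a dynamic branch cut (deepSplit 2, minimum
   module size 10), eigenproteins (first principal component per module),
   kME, eigenprotein merging at cut height 0.7, module–trait bicor tables
   and one-tailed Fisher marker enrichment.
3. **Sample subtyping** — the top 30 hub proteins per module by kME feed a
   signed sample-similarity graph at soft power 13, sparsified to a target
   mean degree; subtypes are communities maximizing weighted Newman–Girvan
   modularity Q = Σ_c (e_c/m − (d_c/2m)²) under min/max size constraints,
   selected over the grid i ∈ {10,15,20,25}, j ∈ {100..400}, k ∈ {25,50} by
   replicate-pair consistency, with per-sample hub-correlation diagnostics.
4. **Cross-cohort transfer** — a supervised embedding of the reference
   cohort on the hub proteins shared with a query cohort (deterministic
   PCA+LDA fallback, or supervised UMAP), nearest-centroid assignment with a
   ">3 embedding units from every centroid ⇒ unassigned" rule, and
   mean-centred z-score subtype signatures correlated across studies by
   bicor.
5. **Response statistics** — three-way type-II ANOVA with Tukey HSD,
   chi-squared subtype demographic enrichment, the 3-SD plotting trim, and
   the plasma-dilution analysis: module abundance as percent of baseline
   across spiked plasma fractions, dose slopes and baseline-vs-top tests.

Real cohorts of this kind are controlled-access, so the package ships a
**synthetic cohort generator** (`cohort_spec()` / `generate_cohort()`) that
plants modules, subtypes, trait effects, batch structure, GIS channels,
cross-set technical replicates, immunoassay scales and left-censored
missingness — ground truth for every downstream stage. The methods vignette
(`vignettes/csf-subtyping-methods.Rmd`) documents the model and all
numerical choices.

## Worked example

The `analysis/` directory is a numbered workflow over the package; each
script reads its predecessor's tables from `results/`:

```sh
Rscript analysis/01_simulate.R    # synthetic two-set TMT cohort
Rscript analysis/02_harmonize.R   # TAMPOR + bootstrap regression + QC
Rscript analysis/03_network.R     # signed network, modules, trait table
Rscript analysis/04_subtype.R     # hub graph, grid search, consistency
Rscript analysis/05_transfer.R    # replication cohort, transfer, signatures
Rscript analysis/06_dilution.R    # plasma-dilution module response
```

A run at the default settings prints, among other things:

```
cohort: 1000 proteins x 362 channels (321 biological, 41 GIS)
TAMPOR: round iterations 2/54, converged: TRUE
residual variance fractions (median): batch 0.26%, set 0.01%
network: 10 modules, 160 proteins unassigned
agreement with planted modules (ARI): 1.000
grid winner: i=10 j=100 k=25 -> 6 subtypes, Q=0.613
replicate consistency: 95.2% of 21 pairs
reference self-consistency: 96.2%
queries: 110 assigned, 10 unassigned (> 3 from every centroid)
highest CSF/serum albumin ratio in assigned subtype S3
plasma-like    modules at top fraction: +281% of baseline
neuronal-like  modules at top fraction: -26% of baseline
tau-like protein at top fraction: -24%
```

Reading this: harmonization removed essentially all planted batch/set
variance; the network stage recovered the ten planted modules exactly,
leaving the 160 unstructured background proteins unassigned; modularity
clustering of samples found the six planted subtypes with same-subject
replicate pairs agreeing 95% of the time; queries from a partial-overlap
replication cohort transfer onto the reference subtypes, the
blood–brain-barrier-like subtype S3 showing the highest CSF/serum albumin
ratio; and spiking plasma into pooled CSF raises plasma-derived modules
~4-fold while depleting neuronal/tau modules by about a quarter, with the
protected module flat.

Equivalent programmatic use:

```r
library(csfsub)
coh  <- generate_cohort(cohort_spec(n_proteins = 1000, n_samples = 300, seed = 1))
expr <- filter_missingness(coh$expression, 0.5)
refs <- with(coh$traits, sample_id[!is_gis & diagnosis == "Control" & race == "NHW"])
harm <- impute_knn(two_round_harmonize(expr, coh$traits, refs)$harmonized)
cov  <- coh$traits[match(colnames(harm), coh$traits$sample_id),
                   c("sample_id","batch","set","age","sex","race","diagnosis")]
harm <- regress_batch(harm, cov, n_boot = 50, seed = 1)
net  <- build_network(harm)                       # modules, eigenproteins, kME
hubs <- select_hubs(net$kme, net$labels, 30)
subjects <- coh$traits$subject_id[match(colnames(harm), coh$traits$sample_id)]
part <- grid_search_subtypes(harm[hubs$protein, ], subjects, seed = 1)
```

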