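#!/usr/bin/env Rscript
## Stage 5 - cross-cohort transfer: a partial-overlap replication cohort is
## projected through the supervised reference embedding and assigned by
## nearest centroid (> 3 embedding units from every centroid = unassigned);
## mean-centered subtype signatures are correlated across the two cohorts.

suppressPackageStartupMessages(library(csfsub))
out <- "results/transfer"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

harm <- read_matrix("results/harmonized/harmonized.tsv")
hubs <- utils::read.delim("results/subtypes/hubs.tsv")
subtypes <- utils::read.delim("results/subtypes/subtypes.tsv")
memb <- stats::setNames(subtypes$subtype, subtypes$sample)

qspec <- cohort_spec(n_proteins = 1000L, n_samples = 120L, seed = 1L)
repc <- generate_replication_cohort(qspec, overlap_fraction = 0.4)
qtr <- repc$traits
qexpr <- impute_knn(filter_missingness(repc$expression[, !qtr$is_gis], 0.5))

shared <- intersect(hubs$protein, rownames(qexpr))
cat(sprintf("overlap hub proteins: %d of %d\n", length(shared), nrow(hubs)))
model <- fit_reference_embedding(harm[shared, ], memb)
cat(sprintf("reference self-consistency: %.1f%%\n",
            100 * model$self_consistency))
res <- project_and_assign(model, qexpr, cutoff = 3)
a <- res$assignments
cat(sprintf("queries: %d assigned, %d unassigned (> 3 from every centroid)\n",
            sum(a$assigned), sum(!a$assigned)))
write_tsv(a, file.path(out, "assignments.tsv"))

## albumin ratio by assigned subtype (BBB-like subtype should be highest)
alb <- qtr$albumin_ratio[match(a$sample, qtr$sample_id)]
alb_tab <- stats::aggregate(alb ~ a$label, FUN = mean)
names(alb_tab) <- c("subtype", "mean_albumin_ratio")
write_tsv(alb_tab, file.path(out, "albumin_by_subtype.tsv"))
cat(sprintf("highest CSF/serum albumin ratio in assigned subtype %s\n",
            alb_tab$subtype[which.max(alb_tab$mean_albumin_ratio)]))

sig_ref <- subtype_signature(harm[rownames(harm) %in% rownames(qexpr), ],
                             memb, reference_label = "S1")
sig_rep <- subtype_signature(qexpr, repc$truth_subtypes[colnames(qexpr)],
                             reference_label = "S1")
sc <- signature_correlation(sig_ref, sig_rep)
write_matrix(sc$bicor, file.path(out, "signature_correlation.tsv"))
cat(sprintf("max cross-cohort signature bicor: %.2f over %d shared proteins\n",
            max(sc$bicor), sc$n_shared))
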