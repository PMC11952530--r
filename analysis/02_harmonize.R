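#!/usr/bin/env Rscript
## Stage 2 - harmonize: 50% missingness filter, two-round TAMPOR (GIS round
## per set, reference-group round across sets), KNN imputation, bootstrap
## batch/set regression, diagnosis QC, variance report.

suppressPackageStartupMessages(library(csfsub))
cohort_dir <- "results/cohort"
out <- "results/harmonized"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

expr <- read_matrix(file.path(cohort_dir, "expression.tsv"))
traits <- utils::read.delim(file.path(cohort_dir, "traits.tsv"))

kept <- filter_missingness(expr, 0.5)
cat(sprintf("missingness filter: %d of %d proteins kept (>= 50%% observed)\n",
            nrow(kept), nrow(expr)))

qc <- qc_exclude(traits, ratio_cutoff = 0.226)
write_tsv(qc$excluded, file.path(out, "qc_exclusions.tsv"))
cat(sprintf("QC: %d samples flagged by the tTau/Abeta 0.226 rule\n",
            nrow(qc$excluded)))

refs <- traits$sample_id[!traits$is_gis & traits$diagnosis == "Control" &
                           traits$race == "NHW"]
hr <- two_round_harmonize(kept, traits, reference_samples = refs)
cat(sprintf("TAMPOR: round iterations %s, converged: %s\n",
            paste(hr$iterations_per_round, collapse = "/"), hr$converged))

harm <- impute_knn(hr$harmonized, k = 10)
cov <- traits[match(colnames(harm), traits$sample_id),
              c("sample_id", "batch", "set", "age", "sex", "race", "diagnosis")]
harm <- regress_batch(harm, cov, n_boot = 50, seed = 1)
write_matrix(harm, file.path(out, "harmonized.tsv"))

ve <- variance_explained(harm, cov,
                         factors = c("set", "age", "sex", "race",
                                     "diagnosis", "batch"))
write_tsv(cbind(protein = rownames(ve), ve), file.path(out, "variance_report.tsv"))
cat(sprintf("residual variance fractions (median): batch %.2f%%, set %.2f%%\n",
            100 * median(ve$batch), 100 * median(ve$set)))
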