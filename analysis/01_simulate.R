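#!/usr/bin/env Rscript
## Stage 1 - build the synthetic study cohort.
##
## Emulates a two-set, multi-batch TMT CSF cohort: 300 subjects, ten planted
## co-expression modules, six planted subtypes in opposite pairs, GIS
## reference channels, cross-set technical replicate pairs, set-specific
## immunoassay scales, abundance-dependent missingness.

suppressPackageStartupMessages(library(csfsub))
out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- cohort_spec(n_proteins = 1000L, n_samples = 300L, seed = 1L)
coh <- generate_cohort(spec)

write_matrix(coh$expression, file.path(out, "expression.tsv"))
write_tsv(coh$traits, file.path(out, "traits.tsv"))
write_tsv(data.frame(protein = names(coh$truth_modules),
                     module = coh$truth_modules),
          file.path(out, "truth_modules.tsv"))
write_tsv(data.frame(sample = names(coh$truth_subtypes),
                     subtype = coh$truth_subtypes),
          file.path(out, "truth_subtypes.tsv"))

bio <- !coh$traits$is_gis
cat(sprintf("cohort: %d proteins x %d channels (%d biological, %d GIS)\n",
            nrow(coh$expression), ncol(coh$expression), sum(bio), sum(!bio)))
cat(sprintf("missingness (biological cells): %.1f%%\n",
            100 * mean(is.na(coh$expression[, bio]))))
cat(sprintf("replicate pairs across sets: %d\n",
            sum(table(coh$traits$subject_id[bio]) == 2)))
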