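#!/usr/bin/env Rscript
## Stage 4 - subtype the samples: top-30 kME hubs per module, signed sample
## graph at soft power 13, modularity community detection over the
## (i, j, k) grid, replicate-pair consistency validation.

suppressPackageStartupMessages(library(csfsub))
out <- "results/subtypes"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

harm <- read_matrix("results/harmonized/harmonized.tsv")
traits <- utils::read.delim("results/cohort/traits.tsv")
modules <- utils::read.delim("results/network/modules.tsv")
kme <- read_matrix("results/network/kme.tsv")
truth <- utils::read.delim("results/cohort/truth_subtypes.tsv")

labels <- stats::setNames(modules$module, modules$protein)
hubs <- select_hubs(kme, labels, hubs_per_module = 30L)
cat(sprintf("hub features: %d proteins from %d modules\n",
            nrow(hubs), length(unique(hubs$module))))
write_tsv(hubs, file.path(out, "hubs.tsv"))

hub_expr <- harm[hubs$protein, , drop = FALSE]
subjects <- traits$subject_id[match(colnames(hub_expr), traits$sample_id)]
part <- grid_search_subtypes(hub_expr, subjects,
                             grid_i = c(10L, 15L, 20L, 25L),
                             grid_j = seq(100L, 400L, 50L),
                             grid_k = c(25L, 50L), power = 13, seed = 1)
cat(sprintf("grid winner: i=%d j=%d k=%d -> %d subtypes, Q=%.3f\n",
            part$params$i, part$params$j, part$params$k,
            length(unique(stats::na.omit(part$membership))), part$Q))
cat(sprintf("replicate consistency: %.1f%% of %d pairs\n",
            100 * part$consistency, part$n_pairs))
truth_map <- stats::setNames(truth$subtype, truth$sample)
cat(sprintf("agreement with planted subtypes (ARI): %.3f\n",
            adjusted_rand_index(part$membership,
                                truth_map[names(part$membership)])))

write_tsv(data.frame(sample = names(part$membership),
                     subtype = part$membership,
                     hub_correlation = part$hub_correlation),
          file.path(out, "subtypes.tsv"))
write_tsv(part$score_table, file.path(out, "gridsearch.tsv"))
write_tsv(data.frame(subject = part$excluded_pairs),
          file.path(out, "excluded_pairs.tsv"))

## demographic enrichment per subtype (set-1 sample per subject)
bio <- traits[match(names(part$membership), traits$sample_id), ]
first <- !duplicated(bio$subject_id[order(bio$set)])
keep <- names(part$membership)[order(bio$set)][first]
memb1 <- part$membership[keep]
tr1 <- traits[match(keep, traits$sample_id), ]
enrich <- rbind(
  cbind(trait = "AD", chisq_enrichment(memb1, as.numeric(tr1$diagnosis == "AD"))),
  cbind(trait = "Male", chisq_enrichment(memb1, as.numeric(tr1$sex == "M"))),
  cbind(trait = "AA", chisq_enrichment(memb1, as.numeric(tr1$race == "AA"))))
write_tsv(enrich, file.path(out, "demographic_enrichment.tsv"))
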