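#!/usr/bin/env Rscript
## Stage 3 - co-expression network: bicor, signed adjacency (power 6), TOM,
## dynamic branch cut (deepSplit 2, min size 10), eigenprotein merge (0.7),
## kME, module-trait correlations, marker enrichment against planted truth.

suppressPackageStartupMessages(library(csfsub))
out <- "results/network"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

harm <- read_matrix("results/harmonized/harmonized.tsv")
traits <- utils::read.delim("results/cohort/traits.tsv")
truth <- utils::read.delim("results/cohort/truth_modules.tsv")

net <- build_network(harm, power = 6, deep_split = 2L, min_module_size = 10L,
                     merge_cut_height = 0.7)
n_mod <- length(unique(net$labels[!is.na(net$labels)]))
cat(sprintf("network: %d modules, %d proteins unassigned\n",
            n_mod, sum(is.na(net$labels))))
truth_map <- stats::setNames(truth$module, truth$protein)
cat(sprintf("agreement with planted modules (ARI): %.3f\n",
            adjusted_rand_index(net$labels, truth_map[names(net$labels)])))

own_kme <- vapply(seq_along(net$labels), function(i)
  if (is.na(net$labels[i])) NA_real_ else net$kme[i, net$labels[i]], numeric(1))
write_tsv(data.frame(protein = names(net$labels), module = net$labels,
                     own_kme = own_kme), file.path(out, "modules.tsv"))
write_matrix(net$eigenproteins, file.path(out, "eigenproteins.tsv"))
write_matrix(net$kme, file.path(out, "kme.tsv"))

et <- encode_traits(traits)
tr_num <- cbind(traits[match(rownames(et), traits$sample_id),
                       c("sample_id", "subject_id", "set")], et)
rownames(tr_num) <- tr_num$sample_id
tt <- module_trait_correlation(net$eigenproteins, tr_num,
                               trait_cols = c("age_z", "sex", "race",
                                              "diagnosis", "moca", "ttau_z",
                                              "ptau_z", "abeta_z", "apoe_risk"))
write_tsv(tt, file.path(out, "trait_correlation.tsv"))
strongest <- tt[which.max(abs(tt$bicor)), ]
cat(sprintf("strongest module-trait link: %s x %s, bicor %.2f (p %.1e)\n",
            strongest$module, strongest$trait, strongest$bicor, strongest$p))

## planted modules double as marker sets: enrichment sanity check
sets <- split(truth$protein, truth$module)
enr <- marker_enrichment(net$labels, sets, background = names(net$labels))
write_tsv(enr, file.path(out, "enrichment.tsv"))
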