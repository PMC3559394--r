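#!/usr/bin/env Rscript
# Stage 4 -- dyadic affiliation indices and the opportunity table.
#
# Builds scan-based affiliation indices (five behaviors, scan-level OR,
# engaged / co-present) and assembles the (conflict x eligible bystander)
# covariate table that the occurrence GLMMs consume.

suppressMessages(library(pcmckit))

dataset <- load_dataset("results/dataset")
perb <- read.csv("results/labels_perb.csv")
affil <- affiliation_matrix(dataset)
opp <- build_opportunity_table(dataset, perb, affil)

write.csv(affil, "results/affiliation.csv", row.names = FALSE)
write.csv(opp, "results/opportunities.csv", row.names = FALSE)

kin <- is_kin(dataset$roster, affil$id_a, affil$id_b)
cat(sprintf("affiliation indices for %d dyads; kin mean %.3f vs non-kin %.3f\n",
            nrow(affil), mean(affil$index[kin]), mean(affil$index[!kin])))
cat(sprintf("%d consolation opportunities across %d conflicts (outcome rate %.3f)\n",
            nrow(opp), length(unique(opp$conflict_id)),
            mean(opp$consoled)))
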