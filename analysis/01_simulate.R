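#!/usr/bin/env Rscript
# Stage 1 -- simulate the observation campaign.
#
# Generates the study colony's records at campaign scale: the packaged
# two-group roster (36 subjects + 6 dependent infants), a latent dyadic
# affinity structure with a mother-offspring kinship boost, and 301 + 152
# observation hours of conflicts, PC/MC focal follows and scan samples under
# the default response model. Writes the four-file CSV dataset plus the
# generator ground truth under results/dataset/.

suppressMessages(library(pcmckit))
seed <- as.integer(Sys.getenv("PCMC_SEED", "1"))

roster <- lola_roster()
affinity <- simulate_affiliation(roster, seed = seed)
dataset <- simulate_observation(roster, affinity, colony_config(),
                                response_model(),
                                hours = c(G1 = 301, G2 = 152), seed = seed)

dir.create("results/dataset", recursive = TRUE, showWarnings = FALSE)
write_dataset(dataset, "results/dataset")
gt <- attr(dataset, "ground_truth")
jsonlite::write_json(
  list(response = lapply(unclass(gt$response), unclass), seed = seed,
       hours = as.list(gt$hours)),
  "results/dataset/ground_truth.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d conflicts over %d individuals (%d scans); %d PCs have a matched control\n",
            nrow(dataset$conflicts), nrow(roster), nrow(dataset$scans),
            sum(pair_table(dataset)$has_mc)))
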