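#!/usr/bin/env Rscript
# Stage 3 -- PC/MC pair classification and tendency scores.
#
# Labels every retained pair attracted/dispersed/neutral for consolation
# (any bystander), reconciliation (between opponents) and per eligible
# bystander, then derives per-victim TCT/CCT, per-dyad TCT and the
# consolation index.

suppressMessages(library(pcmckit))

dataset <- load_dataset("results/dataset")
cons <- label_dataset(dataset, "consolation")
rec <- label_dataset(dataset, "reconciliation")
perb <- label_dataset(dataset, "per_bystander")

tct <- tendency_scores(cons, by = "victim_id")
cct <- tendency_scores(rec, by = "victim_id")
dyadic <- tendency_scores(perb, by = c("victim_id", "bystander_id"))
ci <- consolation_index(dataset, perb)

for (nm in c("cons", "rec", "perb", "tct", "cct", "dyadic", "ci")) {
  write.csv(get(nm), sprintf("results/labels_%s.csv", nm),
            row.names = FALSE)
}

cat(sprintf("labeled %d pairs: %d attracted / %d dispersed / %d neutral (consolation)\n",
            nrow(cons), sum(cons$label == "attracted"),
            sum(cons$label == "dispersed"), sum(cons$label == "neutral")))
cat(sprintf("per-victim mean TCT = %.2f%%, mean CCT = %.2f%% over %d focal victims\n",
            mean(tct$tendency), mean(cct$tendency), nrow(tct)))
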