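#!/usr/bin/env Rscript
# Stage 5 -- occurrence, latency and stress-proxy statistics.
#
# Per-focal Wilcoxon signed-rank tests of attracted vs dispersed
# proportions, Kaplan-Meier/log-rank comparison of censored first-contact
# latencies, and the self-directed-behavior contrasts at the Bonferroni
# threshold.

suppressMessages(library(pcmckit))

dataset <- load_dataset("results/dataset")
cons <- label_dataset(dataset, "consolation")
rec <- label_dataset(dataset, "reconciliation")
tct <- tendency_scores(cons)
cct <- tendency_scores(rec)

w_cons <- wilcoxon_paired(tct$prop_attracted, tct$prop_dispersed)
w_rec <- wilcoxon_paired(cct$prop_attracted, cct$prop_dispersed)
lr_cons <- logrank_compare(cons$pc_latency, cons$mc_latency)
lr_rec <- logrank_compare(rec$pc_latency, rec$mc_latency)
scratch <- stress_rates(dataset, cons, rec, measure = "scratch")
groom <- stress_rates(dataset, cons, rec, measure = "groom")
mc_ctrl <- mc_contact_control(dataset)

stats <- list(
  consolation = list(
    mean_pct_attracted = 100 * mean(tct$prop_attracted),
    mean_pct_dispersed = 100 * mean(tct$prop_dispersed),
    wilcoxon = w_cons[c("z", "p", "n_effective")],
    mean_tct = mean(tct$tendency),
    logrank = lr_cons[c("chisq", "df", "p", "n")]),
  reconciliation = list(
    mean_pct_attracted = 100 * mean(cct$prop_attracted),
    mean_pct_dispersed = 100 * mean(cct$prop_dispersed),
    wilcoxon = w_rec[c("z", "p", "n_effective")],
    mean_cct = mean(cct$tendency),
    logrank = lr_rec[c("chisq", "df", "p", "n")]),
  stress = list(
    alpha = scratch$alpha,
    pc_categories = as.list(scratch$pc_category_counts),
    scratch_means = setNames(as.list(scratch$summary$mean_rate),
                             scratch$summary$condition),
    groom_means = setNames(as.list(groom$summary$mean_rate),
                           groom$summary$condition),
    scratch_comparisons = scratch$comparisons,
    mc_contact_control = mc_ctrl$test[c("z", "p", "n_effective")]))
jsonlite::write_json(stats, "results/stats.json", auto_unbox = TRUE,
                     digits = NA)

cat(sprintf("consolation: %.1f%% attracted vs %.1f%% dispersed (Z = %.2f, p = %.2g); log-rank chisq = %.1f\n",
            stats$consolation$mean_pct_attracted,
            stats$consolation$mean_pct_dispersed, w_cons$z, w_cons$p,
            lr_cons$chisq))
cat(sprintf("reconciliation: %.1f%% vs %.1f%% (Z = %.2f); log-rank chisq = %.1f\n",
            stats$reconciliation$mean_pct_attracted,
            stats$reconciliation$mean_pct_dispersed, w_rec$z, lr_rec$chisq))
sm <- setNames(scratch$summary$mean_rate, scratch$summary$condition)
cat(sprintf("scratch bouts/min: MC = %.2f, PC without affiliation = %.2f, PC with consolation = %.2f (alpha = %.3f)\n",
            sm[["MC"]], sm[["PC_no_affiliation"]], sm[["PC_consolation"]],
            scratch$alpha))
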