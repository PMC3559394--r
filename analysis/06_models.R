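#!/usr/bin/env Rscript
# Stage 6 -- mixed-model selection for the determinants of consolation.
#
# AIC model selection over the occurrence GLMM predictor pool, the two
# reduced runs (without mother-reared bystanders; mature individuals only),
# and the dyadic TCT LMM with simulation-based significance.

suppressMessages(library(pcmckit))
seed <- as.integer(Sys.getenv("PCMC_SEED", "1"))

dataset <- load_dataset("results/dataset")
opp <- read.csv("results/opportunities.csv")
pool <- c("proximity_num", "bystander_juvenile", "bystander_adolescent",
          "bystander_mother_reared", "log_affil_bv", "kin_bystander_victim",
          "kin_bystander_aggressor", "context_feed",
          "reconciliation_occurred", "redirection_occurred")

sel <- enumerate_and_select(pool, opp, "consoled", method = "stepwise")
cat(sprintf("occurrence GLMM: best of %d fitted models keeps %d predictors (AIC = %.1f; LRT vs null chisq = %.1f, df = %d, p = %.2g)\n",
            nrow(sel$ranking), length(sel$best$spec$fixed_effects),
            sel$best$aic, sel$lrt$chisq, sel$lrt$df, sel$lrt$p))
print(sel$best$coefficients, digits = 3)

red_mr <- reduced_model_runs(opp, "mother_reared_bystanders", pool = pool,
                             response = "consoled", method = "stepwise")
cat(sprintf("reduced run without mother-reared bystanders: %d -> %d rows (%d -> %d bystanders)\n",
            red_mr$n_before, red_mr$n_after,
            red_mr$n_bystanders_before, red_mr$n_bystanders_after))
red_j <- reduced_model_runs(opp, "juvenile_bystanders", pool = pool,
                            response = "consoled", method = "stepwise")
cat(sprintf("mature-only run: %d rows retained; best model keeps %s\n",
            red_j$n_after,
            paste(red_j$selection$best$spec$fixed_effects, collapse = ", ")))

# dyadic TCT with kinship/age predictors
perb <- read.csv("results/labels_perb.csv")
dy <- tendency_scores(perb, by = c("victim_id", "bystander_id"))
r <- dataset$roster
dy$bystander_juvenile <-
  as.integer(r$age_class[match(dy$bystander_id, r$id)] == "juvenile")
dy$kin_bystander_victim <- as.integer(is_kin(r, dy$bystander_id,
                                             dy$victim_id))
dy$group_id <- r$group_id[match(dy$victim_id, r$id)]
lmm <- lmm_dyadic("tendency", dy, c("bystander_juvenile",
                                    "kin_bystander_victim"), seed = seed)
est <- setNames(lmm$coefficients$estimate, lmm$coefficients$term)
cat(sprintf("dyadic TCT LMM: kin coefficient %.1f (sim p = %.3g), juvenile coefficient %.1f (sim p = %.3g)\n",
            est[["kin_bystander_victim"]],
            lmm$sim_p[["kin_bystander_victim"]],
            est[["bystander_juvenile"]],
            lmm$sim_p[["bystander_juvenile"]]))

reportify <- function(fit) list(
  fixed = fit$spec$fixed_effects, aic = fit$aic,
  log_likelihood = fit$log_likelihood, k = fit$k,
  coefficients = fit$coefficients)
jsonlite::write_json(
  list(occurrence = c(reportify(sel$best),
                      list(lrt = sel$lrt, method = sel$method,
                           n_models = nrow(sel$ranking))),
       reduced_no_mother_reared = reportify(red_mr$selection$best),
       mature_only = reportify(red_j$selection$best),
       dyadic_tct = c(reportify(lmm), list(sim_p = as.list(lmm$sim_p)))),
  "results/models.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/models.json\n")
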