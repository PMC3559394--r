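#' Run the full post-conflict analysis pipeline
#'
#' End-to-end orchestration over a synthetic observation campaign: simulate
#' (roster, affinity, observation), validate, label PC/MC pairs, compute
#' tendency scores and affiliation metrics, run the occurrence tests
#' (Wilcoxon on per-focal attracted vs dispersed proportions), the latency
#' survival comparison, the stress-proxy contrasts, and -- optionally -- the
#' GLMM/LMM model-selection stage. Returns a report whose sections mirror a
#' post-conflict results narrative (occurrence, latency, determinants,
#' relationship dynamics, stress, reconciliation) plus a reproducibility
#' manifest. Identical config + seed reproduce identical manifests.
#'
#' @param roster roster data frame; default the packaged colony roster.
#' @param config a [colony_config()].
#' @param response a [response_model()].
#' @param hours observation hours (scalar or named by group); default the
#'   campaign scale, 301 h for group 1 and 152 h for group 2.
#' @param seed master integer seed (all stage seeds derive from it).
#' @param fit_models run the model-selection stage (slowest stage).
#' @param model_pool candidate predictors for the occurrence GLMM.
#' @param selection_method forwarded to [enumerate_and_select()].
#' @param out_dir if non-`NULL`, write the dataset CSVs, result tables and
#'   the manifest there.
#' @return a list of class `pcmc_report`.
#' @export
run_all <- function(roster = lola_roster(),
                    config = colony_config(),
                    response = response_model(),
                    hours = c(G1 = 301, G2 = 152),
                    seed = 1L,
                    fit_models = TRUE,
                    model_pool = c("proximity_num", "bystander_juvenile",
                                   "bystander_adolescent",
                                   "bystander_mother_reared",
                                   "log_affil_bv", "kin_bystander_victim",
                                   "kin_bystander_aggressor", "context_feed",
                                   "reconciliation_occurred",
                                   "redirection_occurred"),
                    selection_method = "stepwise",
                    out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  affinity <- simulate_affiliation(roster, seed = substream_seed(seed, 1))
  d <- simulate_observation(roster, affinity, config, response, hours,
                            seed = substream_seed(seed, 2))
  tick("simulate")

  validate_dataset(d)
  mc_checks <- check_matched_controls(d)
  tick("validate")

  cons <- label_dataset(d, "consolation")
  rec <- label_dataset(d, "reconciliation")
  perb <- label_dataset(d, "per_bystander")
  tct <- tendency_scores(cons, by = "victim_id")
  cct <- tendency_scores(rec, by = "victim_id")
  dyadic_tct <- tendency_scores(perb, by = c("victim_id", "bystander_id"))
  ci <- consolation_index(d, perb)
  tick("label")

  w_cons <- wilcoxon_paired(tct$prop_attracted, tct$prop_dispersed)
  w_rec <- wilcoxon_paired(cct$prop_attracted, cct$prop_dispersed)
  no_lr <- list(chisq = NA_real_, df = 1L, p = NA_real_, n = 0L,
                fit = NULL, defined = FALSE)
  lr_cons <- if (nrow(cons)) logrank_compare(cons$pc_latency,
                                             cons$mc_latency) else no_lr
  lr_rec <- if (nrow(rec)) logrank_compare(rec$pc_latency,
                                           rec$mc_latency) else no_lr
  tick("occurrence_latency")

  affil <- if (nrow(d$scans)) affiliation_matrix(d) else NULL
  opp <- if (nrow(perb)) build_opportunity_table(d, perb, affil) else
    data.frame()
  tick("metrics")

  scratch <- stress_rates(d, cons, rec, measure = "scratch")
  groom <- stress_rates(d, cons, rec, measure = "groom")
  mc_ctrl <- mc_contact_control(d)
  tick("stress")

  models <- NULL
  if (fit_models && nrow(opp) > 0) {
    pool <- model_pool[model_pool %in% names(opp)]
    sel <- enumerate_and_select(pool, opp, response = "consoled",
                                method = selection_method)
    dy <- merge(dyadic_tct, ci, by = c("victim_id", "bystander_id"),
                all.x = TRUE)
    r <- d$roster
    dy$bystander_juvenile <-
      as.integer(r$age_class[match(dy$bystander_id, r$id)] == "juvenile")
    dy$kin_bystander_victim <-
      as.integer(is_kin(r, dy$bystander_id, dy$victim_id))
    dy$bystander_mother_reared <-
      as.integer(r$rearing[match(dy$bystander_id, r$id)] == "mother_reared")
    dy$group_id <- r$group_id[match(dy$victim_id, r$id)]
    lmm_tct <- lmm_dyadic("tendency", dy,
                          c("bystander_juvenile", "kin_bystander_victim"),
                          seed = substream_seed(seed, 3))
    models <- list(occurrence = sel, dyadic_table = dy, lmm_tct = lmm_tct)
    tick("models")
  }

  report <- structure(list(
    occurrence = list(
      n_conflicts = nrow(d$conflicts),
      n_pairs = nrow(cons),
      mean_prop_attracted = mean(tct$prop_attracted),
      sd_prop_attracted = sd(tct$prop_attracted),
      mean_prop_dispersed = mean(tct$prop_dispersed),
      sd_prop_dispersed = sd(tct$prop_dispersed),
      wilcoxon = w_cons,
      mean_tct = mean(tct$tendency),
      sd_tct = sd(tct$tendency),
      n_focals = nrow(tct)),
    reconciliation = list(
      mean_prop_attracted = mean(cct$prop_attracted),
      mean_prop_dispersed = mean(cct$prop_dispersed),
      wilcoxon = w_rec,
      mean_cct = mean(cct$tendency),
      n_focals = nrow(cct)),
    latency = list(consolation = lr_cons, reconciliation = lr_rec),
    determinants = models,
    stress = list(scratch = scratch, groom = groom,
                  mc_contact = mc_ctrl),
    tables = list(tct = tct, cct = cct, dyadic_tct = dyadic_tct,
                  consolation_index = ci, opportunities = opp,
                  affiliation = affil, mc_checks = mc_checks),
    dataset = d,
    manifest = NULL), class = "pcmc_report")

  manifest <- list(seed = seed, hours = as.list(hours),
                   n_conflicts = nrow(d$conflicts),
                   n_pairs = nrow(cons),
                   package_version = as.character(
                     utils::packageVersion("pcmckit")),
                   timings_s = as.list(timings))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data_dir <- file.path(out_dir, "dataset")
    paths <- write_dataset(d, data_dir)
    write.csv(tct, file.path(out_dir, "tct_per_victim.csv"),
              row.names = FALSE)
    write.csv(cct, file.path(out_dir, "cct_per_victim.csv"),
              row.names = FALSE)
    if (nrow(opp)) {
      write.csv(opp, file.path(out_dir, "opportunities.csv"),
                row.names = FALSE)
    }
    gt <- attr(d, "ground_truth")
    jsonlite::write_json(
      list(config = unclass(gt$config)[setdiff(names(gt$config),
                                               "roster_counts")],
           response = lapply(unclass(gt$response), unclass), seed = seed),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE,
      digits = NA)
    manifest$checksums <- as.list(tools::md5sum(
      c(paths, file.path(out_dir, c("tct_per_victim.csv",
                                    "cct_per_victim.csv")))))
    names(manifest$checksums) <- basename(names(manifest$checksums))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report$manifest <- manifest
  report
}

#' @exportS3Method base::print
print.pcmc_report <- function(x, ...) {
  oc <- x$occurrence
  cat("<pcmc_report>\n")
  cat(sprintf("  %d conflicts, %d PC/MC pairs, %d focal victims\n",
              oc$n_conflicts, oc$n_pairs, oc$n_focals))
  cat(sprintf("  consolation: attracted %.1f%% vs dispersed %.1f%% (Z = %.2f, p = %.3g); mean TCT = %.2f\n",
              100 * oc$mean_prop_attracted, 100 * oc$mean_prop_dispersed,
              oc$wilcoxon$z, oc$wilcoxon$p, oc$mean_tct))
  rc <- x$reconciliation
  cat(sprintf("  reconciliation: attracted %.1f%% vs dispersed %.1f%%; mean CCT = %.2f\n",
              100 * rc$mean_prop_attracted, 100 * rc$mean_prop_dispersed,
              rc$mean_cct))
  cat(sprintf("  latency log-rank: consolation chisq = %.1f, reconciliation chisq = %.1f\n",
              x$latency$consolation$chisq, x$latency$reconciliation$chisq))
  sc <- x$stress$scratch$summary
  cat("  scratch rates (bouts/min): ",
      paste(sprintf("%s = %.2f", sc$condition, sc$mean_rate),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
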