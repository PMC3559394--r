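#' Simulate a bystander-opportunity table with known coefficients
#'
#' Draws (conflict x bystander) consolation opportunities directly from a
#' binomial-logit model with known fixed effects and random intercepts for
#' victim, bystander and conflict. This bypasses the full colony mechanism
#' and is the ground-truth generator for GLMM parameter-recovery and
#' AIC-selection-consistency checks: the covariates are drawn independently,
#' so every coefficient is identified.
#'
#' Covariates mirror the observational opportunity table
#' ([build_opportunity_table()]): `proximity_num` (0/1/2), bystander age
#' dummies, rearing, log affiliation, kinship flags, feeding context,
#' reconciliation and redirection indicators, plus optional pure-noise
#' covariates `noise1..noiseK`.
#'
#' @param n number of opportunity rows.
#' @param beta named fixed-effect vector; names must be covariate column
#'   names plus `intercept`. Covariates not named get coefficient 0.
#' @param re_sd named vector of random-intercept SDs for `victim_id`,
#'   `bystander_id`, `conflict_id`.
#' @param n_victims,n_bystanders,n_per_conflict population sizes.
#' @param n_noise number of additional standard-normal noise covariates.
#' @param seed integer seed.
#' @return list with `table` (data frame including the binary `consoled`
#'   outcome), `beta`, and `re_sd`.
#' @export
simulate_opportunities <- function(n = 2000,
                                   beta = c(intercept = -1,
                                            proximity_num = -1,
                                            log_affil_bv = 0.5,
                                            bystander_juvenile = 0.8),
                                   re_sd = c(victim_id = 0.5,
                                             bystander_id = 0.5,
                                             conflict_id = 0.3),
                                   n_victims = 32, n_bystanders = 34,
                                   n_per_conflict = 8, n_noise = 0,
                                   seed = 1L) {
  set.seed(seed)
  n_conflicts <- max(1L, ceiling(n / n_per_conflict))
  conflict <- sample.int(n_conflicts, n, replace = TRUE)
  victim_of <- sample.int(n_victims, n_conflicts, replace = TRUE)
  tab <- data.frame(
    conflict_id = sprintf("c%04d", conflict),
    victim_id = sprintf("v%02d", victim_of[conflict]),
    bystander_id = sprintf("b%02d", sample.int(n_bystanders, n, TRUE)),
    proximity_num = sample(0:2, n, TRUE, prob = c(0.35, 0.30, 0.35)),
    bystander_juvenile = rbinom(n, 1, 0.3),
    bystander_adolescent = rbinom(n, 1, 0.3),
    bystander_mother_reared = rbinom(n, 1, 0.25),
    log_affil_bv = rnorm(n, -2.1, 0.7),
    kin_bystander_victim = rbinom(n, 1, 0.08),
    kin_bystander_aggressor = rbinom(n, 1, 0.08),
    context_feed = rbinom(n, 1, 0.25),
    reconciliation_occurred = rbinom(n, 1, 0.3),
    redirection_occurred = rbinom(n, 1, 0.12))
  tab$bystander_adolescent[tab$bystander_juvenile == 1] <- 0L
  if (n_noise > 0) {
    for (j in seq_len(n_noise)) tab[[paste0("noise", j)]] <- rnorm(n)
  }
  covars <- setdiff(names(beta), "intercept")
  missing <- setdiff(covars, names(tab))
  assert_that(length(missing) == 0,
              sprintf("unknown covariates in beta: %s",
                      paste(missing, collapse = ", ")),
              class = "pcmc_config_error")
  eta <- rep(beta[["intercept"]] %||% 0, n)
  for (v in covars) eta <- eta + beta[[v]] * tab[[v]]
  for (re in names(re_sd)) {
    lev <- unique(tab[[re]])
    u <- setNames(rnorm(length(lev), 0, re_sd[[re]]), lev)
    eta <- eta + u[tab[[re]]]
  }
  tab$consoled <- rbinom(n, 1, plogis(eta))
  tab$group_id <- "G1"
  tab$aggressor_id <- "a00"
  list(table = tab, beta = beta, re_sd = re_sd)
}
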