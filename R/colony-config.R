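# Demographic cells are keyed "SEX.age_class", e.g. "M.adolescent". Infants
# never appear as opponents or bystanders, so class-probability vectors range
# over the eight non-infant cells.

noninfant_cells <- function() {
  as.vector(outer(SEXES, setdiff(AGE_CLASSES, "infant"), paste, sep = "."))
}

default_class_probs <- function(named) {
  cells <- noninfant_cells()
  p <- setNames(rep((1 - sum(named)) / (length(cells) - length(named)),
                    length(cells)), cells)
  p[names(named)] <- named
  p
}

#' Colony generator configuration
#'
#' Defaults reproduce the study conditions of the field campaign the package
#' is calibrated against: the Table-style two-group roster (36 study subjects
#' plus 6 dependent infants), a conflict rate of 356 conflicts per 453
#' observation hours, victim class shares peaking at adolescent males (33.1%)
#' and juvenile females (32.5%) with the remainder spread uniformly, aggressor
#' shares peaking at adult females (51.2%) and adult males (25.4%), the
#' printed six-level intensity distribution (14.2 / 2.5 / 34 / 32 / 12.5 /
#' 4.1%, normalized), and an MC failure rate of 10/356. Context and proximity
#' shares are not printed and carry field-realistic defaults (see the methods
#' vignette).
#'
#' @param roster_counts data frame `group_id`, `sex`, `age_class`, `rearing`,
#'   `n` giving demographic cell counts for [simulate_roster()]; defaults to
#'   the packaged roster's cells.
#' @param conflict_rate conflicts per observation hour.
#' @param victim_class_probs,aggressor_class_probs named probability vectors
#'   over the eight non-infant `"SEX.age_class"` cells.
#' @param intensity_probs length-6 probability vector over intensity 1-6.
#' @param context_probs named probability vector over conflict contexts.
#' @param proximity_probs named probability vector over proximity bands.
#' @param bystander_presence_prob probability a non-opponent group member is a
#'   visible bystander at a conflict (and hence through its PC).
#' @param mc_presence_prob probability a group member is present during an MC.
#' @param mc_failure_prob probability a PC never obtains a valid MC.
#' @param redirection_prob_adult_female,redirection_prob_other per-PC
#'   probability that the victim redirects aggression at a bystander.
#' @param mc_day_probs probabilities of scheduling the MC 1 or 2 days after
#'   the conflict.
#' @param day_hours observation hours per day.
#' @param scan_interval_s seconds between instantaneous scans.
#' @param scan_presence_prob probability an individual is visible in a scan.
#' @return a list of class `colony_config`.
#' @export
colony_config <- function(roster_counts = NULL,
                          conflict_rate = 356 / 453,
                          victim_class_probs = default_class_probs(
                            c("M.adolescent" = 0.331, "F.juvenile" = 0.325)),
                          aggressor_class_probs = default_class_probs(
                            c("F.adult" = 0.512, "M.adult" = 0.254)),
                          intensity_probs = normalize_probs(
                            c(0.142, 0.025, 0.34, 0.32, 0.125, 0.041)),
                          context_probs = c(feed = 0.25, rest = 0.20,
                                            play = 0.15,
                                            object_food_competition = 0.15,
                                            arrival = 0.10,
                                            anticipating_feed = 0.10,
                                            social_tension_display = 0.05),
                          proximity_probs = c(lt5m = 0.35, "5to10m" = 0.30,
                                              gt10m = 0.35),
                          bystander_presence_prob = 0.8,
                          mc_presence_prob = 0.8,
                          mc_failure_prob = 10 / 356,
                          redirection_prob_adult_female = 0.25,
                          redirection_prob_other = 0.08,
                          mc_day_probs = c("1" = 0.8, "2" = 0.2),
                          day_hours = 8,
                          scan_interval_s = 1350,
                          scan_presence_prob = 0.8) {
  if (is.null(roster_counts)) {
    r <- lola_roster()
    roster_counts <- aggregate(list(n = r$id),
                               r[c("group_id", "sex", "age_class", "rearing")],
                               length)
  }
  assert_that(all(roster_counts$n >= 0), "cell counts must be nonnegative",
              class = "pcmc_config_error")
  for (p in list(victim_class_probs, aggressor_class_probs, intensity_probs,
                 context_probs, proximity_probs, mc_day_probs)) {
    assert_that(abs(sum(p) - 1) < 1e-9 && all(p >= 0),
                "probability vectors must be simplexes",
                class = "pcmc_config_error")
  }
  assert_that(length(intensity_probs) == 6L,
              "intensity_probs must have length 6",
              class = "pcmc_config_error")
  assert_that(all(names(context_probs) %in% CONTEXTS),
              "unknown context in context_probs",
              class = "pcmc_config_error")
  structure(list(roster_counts = roster_counts,
                 conflict_rate = conflict_rate,
                 victim_class_probs = victim_class_probs,
                 aggressor_class_probs = aggressor_class_probs,
                 intensity_probs = intensity_probs,
                 context_probs = context_probs,
                 proximity_probs = proximity_probs,
                 bystander_presence_prob = bystander_presence_prob,
                 mc_presence_prob = mc_presence_prob,
                 mc_failure_prob = mc_failure_prob,
                 redirection_prob_adult_female = redirection_prob_adult_female,
                 redirection_prob_other = redirection_prob_other,
                 mc_day_probs = mc_day_probs,
                 day_hours = day_hours,
                 scan_interval_s = scan_interval_s,
                 scan_presence_prob = scan_presence_prob),
            class = "colony_config")
}

#' Behavioral response model of the synthetic colony
#'
#' Latent parameters of the post-conflict response process. Consolation is a
#' per-bystander logistic hazard over the covariates the occurrence analyses
#' model (proximity band, bystander age class and rearing, log victim-
#' bystander affiliation, kinship to victim and aggressor, feeding context,
#' reconciliation, redirection); a consoling bystander's first-contact latency
#' is exponential with scale `tau_pc`, right-censored at follow end.
#' Reconciliation is an analogous logistic over opponent covariates. Matched
#' controls carry a flat per-bystander contact probability `p_mc` (latency
#' scale `tau_mc`) and an opponent contact probability `p_mc_opponent`.
#' Self-scratching is a piecewise-constant Poisson process (bouts/min) that
#' switches from `lambda_pc` to `lambda_pc_consoled` at the first consolatory
#' contact; MCs scratch at `lambda_mc`. Self-grooming totals target the
#' configured seconds-per-minute rates. Scratch-rate defaults are the printed
#' field values (0.37 / 0.43 / 0.19 bouts per min); contact probabilities and
#' latency scales were derived once from the printed attracted/dispersed
#' shares (see the methods vignette).
#'
#' @param consolation named coefficient vector of the consolation logit.
#' @param reconciliation named coefficient vector of the reconciliation logit.
#' @param p_mc per-bystander MC contact probability.
#' @param p_mc_opponent per-MC opponent contact probability.
#' @param tau_pc,tau_mc,tau_recon exponential latency scales (seconds).
#' @param lambda_pc,lambda_pc_consoled,lambda_mc scratch rates (bouts/min).
#' @param groom_pc,groom_pc_consoled,groom_mc self-groom rates (s/min).
#' @param groom_bouts expected groom bouts per follow.
#' @param victim_contact_rate per-PC probability of a victim-initiated
#'   contact toward a bystander (exercises the initiator-direction rule; such
#'   contacts never count as consolation).
#' @return a list of class `response_model`.
#' @export
response_model <- function(consolation = c(intercept = -1.2,
                                           proximity = -0.9,
                                           bystander_juvenile = 0.9,
                                           bystander_adolescent = 0.4,
                                           bystander_mother_reared = 0.8,
                                           log_affiliation = 0.5,
                                           kin_victim = 1.2,
                                           kin_aggressor = 0.4,
                                           context_feed = -0.7,
                                           reconciliation = 0.5,
                                           redirection = 0.6),
                           reconciliation = c(intercept = -0.3,
                                              log_affiliation = 0.5,
                                              victim_mother_reared = 0.8,
                                              aggressor_juvenile = 0.6,
                                              victim_adolescent = 0.4),
                           p_mc = 0.045,
                           p_mc_opponent = 0.06,
                           tau_pc = 140,
                           tau_mc = 300,
                           tau_recon = 140,
                           lambda_pc = 0.43,
                           lambda_pc_consoled = 0.19,
                           lambda_mc = 0.37,
                           groom_pc = 2.90,
                           groom_pc_consoled = 1.98,
                           groom_mc = 3.88,
                           groom_bouts = 0.6,
                           victim_contact_rate = 0.15) {
  assert_that(p_mc > 0 && p_mc < 1 && p_mc_opponent >= 0 && p_mc_opponent < 1,
              "contact probabilities must lie in (0,1)",
              class = "pcmc_config_error")
  assert_that(tau_pc > 0 && tau_mc > 0 && tau_recon > 0,
              "latency scales must be positive", class = "pcmc_config_error")
  assert_that(all(c(lambda_pc, lambda_pc_consoled, lambda_mc) >= 0),
              "scratch rates must be nonnegative",
              class = "pcmc_config_error")
  structure(list(consolation = consolation, reconciliation = reconciliation,
                 p_mc = p_mc, p_mc_opponent = p_mc_opponent,
                 tau_pc = tau_pc, tau_mc = tau_mc, tau_recon = tau_recon,
                 lambda_pc = lambda_pc,
                 lambda_pc_consoled = lambda_pc_consoled,
                 lambda_mc = lambda_mc,
                 groom_pc = groom_pc, groom_pc_consoled = groom_pc_consoled,
                 groom_mc = groom_mc, groom_bouts = groom_bouts,
                 victim_contact_rate = victim_contact_rate),
            class = "response_model")
}

#' Null response model: PC and MC streams exchangeable
#'
#' Sets every covariate effect to zero, equalizes PC and MC contact
#' probabilities and latency scales, and equalizes all scratch rates, so that
#' the PC and MC streams of a pair are statistically identical. Used for
#' type-I-error and TCT null calibration.
#'
#' @param p common per-bystander contact probability.
#' @param p_opponent common opponent contact probability.
#' @param tau common latency scale (seconds).
#' @param lambda common scratch rate (bouts/min).
#' @return a [response_model()].
#' @export
null_response_model <- function(p = 0.045, p_opponent = 0.06, tau = 300,
                                lambda = 0.37) {
  cons <- c(intercept = qlogis(p), proximity = 0, bystander_juvenile = 0,
            bystander_adolescent = 0, bystander_mother_reared = 0,
            log_affiliation = 0, kin_victim = 0, kin_aggressor = 0,
            context_feed = 0, reconciliation = 0, redirection = 0)
  rec <- c(intercept = qlogis(p_opponent), log_affiliation = 0,
           victim_mother_reared = 0, aggressor_juvenile = 0,
           victim_adolescent = 0)
  response_model(consolation = cons, reconciliation = rec,
                 p_mc = p, p_mc_opponent = p_opponent,
                 tau_pc = tau, tau_mc = tau, tau_recon = tau,
                 lambda_pc = lambda, lambda_pc_consoled = lambda,
                 lambda_mc = lambda,
                 groom_pc = 3.0, groom_pc_consoled = 3.0, groom_mc = 3.0)
}
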