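test_that("fit contract: AIC identity, nesting, separation, rank checks", {
  sim <- simulate_opportunities(n = 800, seed = 3)
  tab <- sim$table
  re <- c("victim_id", "bystander_id", "conflict_id")
  null <- fit_mixed(model_spec("consoled", random_effects = re), tab)
  one <- fit_mixed(model_spec("consoled", "proximity_num",
                              random_effects = re), tab)
  two <- fit_mixed(model_spec("consoled",
                              c("proximity_num", "log_affil_bv"),
                              random_effects = re), tab)
  for (f in list(null, one, two)) {
    expect_equal(f$aic, -2 * f$log_likelihood + 2 * f$k)
    expect_equal(f$aic, stats::AIC(f$model), tolerance = 1e-8)
  }
  # likelihood is monotone under nesting
  expect_lte(null$log_likelihood, one$log_likelihood + 1e-6)
  expect_lte(one$log_likelihood, two$log_likelihood + 1e-6)

  # constant outcome flags separation instead of fitting
  tab0 <- tab; tab0$consoled <- 0
  f0 <- fit_mixed(model_spec("consoled", "proximity_num",
                             random_effects = re), tab0)
  expect_false(f0$converged)
  expect_match(f0$notes, "separation")

  # duplicated predictor columns are rank-deficient
  tab$dup <- tab$proximity_num
  expect_error(fit_mixed(model_spec("consoled", c("proximity_num", "dup"),
                                    random_effects = re), tab),
               class = "pcmc_rank_error")

  # a model spec without random effects is rejected
  expect_error(model_spec("consoled", random_effects = character()),
               class = "pcmc_config_error")
})

test_that("coefficients are recovered on well-specified simulations", {
  beta <- c(intercept = -1, proximity_num = -1, log_affil_bv = 0.5,
            bystander_juvenile = 0.8)
  sim <- simulate_opportunities(n = 2000, beta = beta, seed = 17)
  fit <- fit_mixed(model_spec("consoled",
                              c("proximity_num", "log_affil_bv",
                                "bystander_juvenile"),
                              random_effects = c("victim_id",
                                                 "bystander_id",
                                                 "conflict_id")),
                   sim$table)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  se <- setNames(fit$coefficients$se, fit$coefficients$term)
  for (term in c("proximity_num", "log_affil_bv", "bystander_juvenile")) {
    expect_lt(abs(est[term] - beta[term]) / se[term], 3.5)
  }
})

test_that("selection compares subsets by AIC and reports the null LRT", {
  sim <- simulate_opportunities(n = 800, seed = 23)
  re <- c("victim_id", "bystander_id", "conflict_id")
  # pool of one predictor: exactly two models
  sel1 <- enumerate_and_select("proximity_num", sim$table, "consoled",
                               random_effects = re)
  expect_equal(nrow(sel1$ranking), 2)
  # best AIC never exceeds any enumerated AIC
  sel <- enumerate_and_select(c("proximity_num", "log_affil_bv",
                                "context_feed"),
                              sim$table, "consoled", random_effects = re)
  expect_equal(nrow(sel$ranking), 8)
  expect_true(all(sel$ranking$aic[1] <= sel$ranking$aic + 1e-9))
  expect_true(is.finite(sel$lrt$chisq))
  # the LRT compares best against the random-effects-only null
  expect_equal(sel$lrt$df, sel$best$k - sel$null$k)

  # empty pool returns the null model
  sel0 <- enumerate_and_select(character(), sim$table, "consoled",
                               random_effects = re)
  expect_equal(length(sel0$best$spec$fixed_effects), 0)
})

test_that("collinear predictors are blocked from joint inclusion", {
  sim <- simulate_opportunities(n = 500, seed = 29)
  tab <- sim$table
  tab$near_copy <- tab$proximity_num + rnorm(nrow(tab), 0, 0.1)
  sel <- enumerate_and_select(c("proximity_num", "near_copy"),
                              tab, "consoled",
                              random_effects = c("victim_id",
                                                 "conflict_id"))
  expect_equal(length(sel$blocked_pairs), 1)
  expect_false(any(sel$ranking$fixed == "proximity_num+near_copy"))
})

test_that("reduced runs filter the table and keep the pipeline identical", {
  sim <- simulate_opportunities(n = 600, seed = 31)
  tab <- sim$table
  re <- c("victim_id", "bystander_id", "conflict_id")
  red <- reduced_model_runs(tab, "mother_reared_bystanders",
                            pool = c("proximity_num", "log_affil_bv"),
                            response = "consoled", random_effects = re)
  expect_equal(red$n_after, sum(tab$bystander_mother_reared == 0))
  expect_lt(red$n_after, red$n_before)
  # an exclusion matching nothing reproduces the full-table fits
  tab2 <- tab; tab2$bystander_mother_reared <- 0L
  red2 <- reduced_model_runs(tab2, "mother_reared_bystanders",
                             pool = c("proximity_num", "log_affil_bv"),
                             response = "consoled", random_effects = re)
  full <- enumerate_and_select(c("proximity_num", "log_affil_bv"), tab2,
                               "consoled", random_effects = re)
  expect_equal(red2$selection$best$aic, full$best$aic)
  expect_equal(red2$n_after, red2$n_before)
  # a filter that empties the table errors
  tab3 <- tab; tab3$bystander_mother_reared <- 1L
  expect_error(reduced_model_runs(tab3, "mother_reared_bystanders",
                                  pool = "proximity_num",
                                  response = "consoled",
                                  random_effects = re),
               class = "pcmc_contract_error")
})

test_that("dyadic LMM significance is simulation-based and stable", {
  set.seed(5)
  n <- 400
  dy <- data.frame(victim_id = sample(sprintf("v%02d", 1:20), n, TRUE),
                   bystander_id = sample(sprintf("b%02d", 1:20), n, TRUE),
                   group_id = sample(c("G1", "G2"), n, TRUE),
                   kin = rbinom(n, 1, 0.1),
                   juv = rbinom(n, 1, 0.3))
  dy$tendency <- 10 + 20 * dy$kin + 8 * dy$juv + rnorm(n, 0, 15)
  fit <- lmm_dyadic("tendency", dy, c("kin", "juv"), n_sim = 10000,
                    seed = 1)
  expect_lt(fit$sim_p[["kin"]], 0.01)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_lt(abs(est[["kin"]] - 20), 6)
  # doubling the iterations moves p by no more than Monte-Carlo error
  fit2 <- lmm_dyadic("tendency", dy, c("kin", "juv"), n_sim = 20000,
                     seed = 2)
  mc_err <- 3 * sqrt(0.5 / 10000)
  expect_lt(abs(fit2$sim_p[["juv"]] - fit$sim_p[["juv"]]), mc_err + 0.01)

  # zero-variance response: all slopes zero, flagged
  dy0 <- dy; dy0$tendency <- 5
  fit0 <- lmm_dyadic("tendency", dy0, c("kin", "juv"))
  expect_equal(unname(fit0$coefficients$estimate[-1]), c(0, 0))
  expect_match(fit0$notes, "zero-variance")
})

test_that("simulated kin tendency offsets are detected reliably", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 300
    dy <- data.frame(victim_id = sample(sprintf("v%02d", 1:20), n, TRUE),
                     bystander_id = sample(sprintf("b%02d", 1:20), n, TRUE),
                     group_id = sample(c("G1", "G2"), n, TRUE),
                     kin = rbinom(n, 1, 0.12))
    dy$tendency <- 5 + 20 * dy$kin + rnorm(n, 0, 18)
    fit <- lmm_dyadic("tendency", dy, "kin", n_sim = 2000, seed = s)
    est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
    est[["kin"]] > 0 && fit$sim_p[["kin"]] < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
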