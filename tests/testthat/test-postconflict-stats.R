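test_that("signed-rank test handles degenerate and extreme inputs", {
  # identical vectors: no informative pairs
  res <- wilcoxon_paired(rep(1, 10), rep(1, 10))
  expect_false(res$defined)
  # near-identical with one tiny shared difference pattern: Z = 0, p = 1
  a <- c(1, 2, 3, 4); b <- c(2, 1, 4, 3)
  res2 <- wilcoxon_paired(a, b)
  expect_equal(res2$z, 0)
  expect_equal(res2$p, 1)
  # all 20 differences positive: smallest attainable two-sided p = 2/2^20
  res3 <- wilcoxon_paired(21:40, 1:20, exact_max = 20)
  expect_equal(res3$p, 2 / 2^20)
  expect_gt(res3$z, 3.5)
})

test_that("exact p equals the sign-pattern enumeration oracle", {
  set.seed(99)
  for (i in 1:30) {
    n <- sample(4:10, 1)
    a <- round(rnorm(n), 1)   # rounding induces ties
    b <- round(rnorm(n), 1)
    if (all(a == b)) next
    got <- wilcoxon_paired(a, b)
    expect_equal(got$p, oracle_wilcoxon_p(a, b), tolerance = 1e-12,
                 info = sprintf("case %d", i))
  }
})

test_that("exact p matches stats::wilcox.test when ties are absent", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    a <- rnorm(n); b <- rnorm(n)
    got <- wilcoxon_paired(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
    expect_equal(got$p, ref, tolerance = 1e-12)
  }
})

test_that("log-rank comparison matches a hand-computed statistic", {
  # small textbook-style arms with censoring
  pc <- c(6, 13, 21, 30, Inf, 31)
  mc <- c(36, 46, 43, Inf, Inf, 42)
  res <- logrank_compare(pc, mc, horizon = 600)
  want <- oracle_logrank_chisq(pmin(pc, 600), as.integer(pc <= 600),
                               pmin(mc, 600), as.integer(mc <= 600))
  expect_equal(res$chisq, want, tolerance = 1e-6)
  expect_equal(res$df, 1L)

  # identical arms: statistic approximately zero
  res0 <- logrank_compare(pc, pc)
  expect_lt(res0$chisq, 1e-9)
  # label swap leaves the statistic unchanged
  res_swap <- logrank_compare(mc, pc)
  expect_equal(res_swap$chisq, res$chisq, tolerance = 1e-9)
  # maximal separation
  res_max <- logrank_compare(rep(1, 30), rep(Inf, 30))
  expect_lt(res_max$p, 0.001)
  # fully censored arms are undefined
  expect_false(logrank_compare(rep(Inf, 5), rep(Inf, 5))$defined)
})

test_that("self-directed rates are bouts (or seconds) per minute", {
  pc_self <- data.frame(time_s = seq(10, 510, by = 100),
                        kind = "scratch_bout", duration_s = 0)
  mc_self <- data.frame(time_s = c(100, 400), kind = "groom_interval",
                        duration_s = c(40, 20))
  d <- pair_dataset(pc_contacts = ct_row(50, "Ana", "Cleo"),
                    pc_self = pc_self, mc_self = mc_self)
  sc <- stress_rates(d)
  # 6 bouts in a 600-s PC follow = 0.6 bouts/min
  pc_rate <- sc$follow_rates$rate[sc$follow_rates$condition ==
                                    "PC_consolation"]
  expect_equal(pc_rate, 0.6)
  gr <- stress_rates(d, measure = "groom")
  mc_rate <- gr$follow_rates$rate[gr$follow_rates$condition == "MC"]
  expect_equal(mc_rate, 6.0)  # 60 s of grooming in 10 min
})

test_that("PC outcome categories split by consolation and reconciliation", {
  # consolation only
  d1 <- pair_dataset(pc_contacts = ct_row(50, "Ana", "Cleo"))
  expect_equal(unname(stress_rates(d1)$pc_category_counts["PC_consolation"]),
               1)
  # reconciliation only
  d2 <- pair_dataset(pc_contacts = ct_row(50, "Bea", "Cleo"))
  expect_equal(
    unname(stress_rates(d2)$pc_category_counts["PC_reconciliation"]), 1)
  # both
  d3 <- pair_dataset(pc_contacts = rbind(ct_row(50, "Bea", "Cleo"),
                                         ct_row(70, "Ana", "Cleo")))
  expect_equal(unname(stress_rates(d3)$pc_category_counts["PC_both"]), 1)
  # none
  d4 <- pair_dataset()
  expect_equal(
    unname(stress_rates(d4)$pc_category_counts["PC_no_affiliation"]), 1)
})

test_that("three-comparison Bonferroni threshold truncates to 0.016", {
  expect_equal(bonferroni_alpha(0.05, 3), 0.016)
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  d <- pair_dataset()
  expect_equal(stress_rates(d)$alpha, 0.016)
})

test_that("consolation lowers simulated scratch rates below both controls", {
  r <- lola_roster()
  means <- sapply(1:10, function(s) {
    a <- simulate_affiliation(r, seed = s)
    d <- simulate_observation(r, a, colony_config(), response_model(),
                              hours = 60, seed = s, include_scans = FALSE)
    sc <- stress_rates(d)
    sm <- sc$summary
    setNames(sm$mean_rate, sm$condition)[c("MC", "PC_no_affiliation",
                                           "PC_consolation")]
  })
  avg <- rowMeans(means)
  expect_lt(avg["PC_consolation"], avg["MC"])
  expect_lt(avg["PC_consolation"], avg["PC_no_affiliation"])
})

test_that("MC contact control is calibrated under the null", {
  # contact occurrence independent of scratching: rejection rate at most
  # alpha (the exact signed-rank test is conservative at the small per-focal
  # sample sizes this control analysis yields) and clearly nonzero
  r <- lola_roster()
  rejections <- vapply(1:200, function(s) {
    g1 <- r[r$group_id == "G1", ]
    a <- simulate_affiliation(g1, seed = s)
    d <- simulate_observation(g1, a, colony_config(), null_response_model(),
                              hours = 60, seed = 10000 + s,
                              include_scans = FALSE)
    res <- mc_contact_control(d)
    isTRUE(res$test$defined) && res$test$p < 0.05
  }, TRUE)
  rate <- mean(rejections)
  # upper 99% binomial band around 0.05 at 200 replicates; lower bound
  # allows the discreteness-induced conservatism
  expect_lt(rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / 200))
  expect_gt(rate, 0.005)
  # identical rates in both categories: p = 1 on a hand-built case
  pcf <- data.frame(time_s = 10, kind = "scratch_bout", duration_s = 0)
  d0 <- pair_dataset(mc_contacts = ct_row(50, "Ana", "Cleo"),
                     mc_self = pcf)
  res0 <- mc_contact_control(d0)
  expect_false(res0$test$defined)  # single focal, one category each
})
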