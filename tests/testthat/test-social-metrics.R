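mk_scan_dataset <- function(engagements, n_scans, present = c("Ana", "Bea"),
                            roster = tiny_roster()) {
  scans <- data.frame(scan_id = seq_len(n_scans), group_id = "G1",
                      date = "2011-06-01",
                      time_s = 600 * seq_len(n_scans))
  sp <- do.call(rbind, lapply(seq_len(n_scans), function(s) {
    data.frame(scan_id = s, id = present)
  }))
  pcmc_dataset(roster, scans = scans, scan_presence = sp,
               scan_engaged = engagements)
}

test_that("affiliation index divides engaged by co-present scans", {
  eng <- data.frame(scan_id = 1:4, id_a = "Ana", id_b = "Bea",
                    behavior = "groom")
  d <- mk_scan_dataset(eng, 20)
  af <- affiliation_matrix(d)
  expect_equal(af$index[af$id_a == "Ana" & af$id_b == "Bea"], 0.20)
  expect_equal(af$copresent_scans[1], 20)
})

test_that("multiple behaviors in one scan count once under OR combining", {
  eng <- data.frame(scan_id = c(1, 1), id_a = "Ana", id_b = "Bea",
                    behavior = c("groom", "play"))
  d <- mk_scan_dataset(eng, 10)
  expect_equal(affiliation_matrix(d)$index, 0.10)
  expect_equal(affiliation_matrix(d, combine = "sum")$index, 0.20)
})

test_that("dyads never co-present are omitted and the table is well-formed", {
  # Cleo never scanned together with Ana/Bea
  eng <- data.frame(scan_id = 1, id_a = "Ana", id_b = "Bea",
                    behavior = "play")
  d <- mk_scan_dataset(eng, 5)
  af <- affiliation_matrix(d)
  expect_false("Cleo" %in% c(af$id_a, af$id_b))
  expect_true(all(af$index >= 0 & af$index <= 1))
  expect_true(all(af$id_a < af$id_b))
})

test_that("scan-sample indices recover a known affinity", {
  r <- tiny_roster()[1:2, ]
  a <- simulate_affiliation(r, seed = 8)
  a[1, 2] <- a[2, 1] <- 0.3
  cfg <- small_config(scan_interval_s = 60, scan_presence_prob = 1)
  d <- simulate_observation(r, a, cfg, null_response_model(), hours = 20,
                            seed = 8)
  af <- affiliation_matrix(d)
  n <- af$copresent_scans[1]
  expect_gte(n, 1000)
  ci <- stats::binom.test(af$engaged_scans[1], n, 0.3,
                          conf.level = 0.99)$conf.int
  expect_gt(0.3, ci[1])
  expect_lt(0.3, ci[2])
})

test_that("log transform handles zeros and preserves order", {
  expect_equal(log_transform(0, epsilon = 0.01), log(0.01))
  expect_true(is.finite(log_transform(0, epsilon = 1e-6)))
  expect_equal(log_transform(c(0.4, 0.4), epsilon = 0.1)[1],
               log_transform(c(0.4, 0.4), epsilon = 0.1)[2])
  expect_error(log_transform(0.5, epsilon = 0), class = "pcmc_config_error")
  set.seed(1)
  for (i in 1:20) {
    x <- runif(30)
    lt <- log_transform(x)
    expect_equal(order(lt), order(x))
  }
  # default epsilon: half the smallest positive index
  x <- c(0, 0.2, 0.05)
  expect_equal(log_transform(x)[1], log(0.025))
})

test_that("eligibility requires presence in both follows", {
  # 3 conflict bystanders; only Ana and Dan reappear in the MC
  d <- pair_dataset(bystanders = c("Ana", "Dan", "Edo"),
                    pc_contacts = ct_row(40, "Ana", "Cleo"),
                    mc_bystanders = c("Ana", "Dan", "Bea"))
  affil <- data.frame(id_a = c("Ana", "Ana", "Bea"),
                      id_b = c("Cleo", "Bea", "Cleo"),
                      engaged_scans = c(1L, 2L, 1L),
                      copresent_scans = c(10L, 10L, 10L),
                      index = c(0.1, 0.2, 0.1))
  opp <- suppressWarnings(build_opportunity_table(d, affil = affil))
  expect_equal(sort(opp$bystander_id), c("Ana", "Dan"))
  expect_equal(opp$consoled[opp$bystander_id == "Ana"], 1)
  expect_equal(opp$consoled[opp$bystander_id == "Dan"], 0)
  # affiliation fallback flagged for the dyad lacking scan data
  expect_true(opp$affil_floor_flag[opp$bystander_id == "Dan"])
  expect_false(opp$affil_floor_flag[opp$bystander_id == "Ana"])
})

test_that("redirection targets keep their opportunity row with the flag set", {
  d <- pair_dataset(bystanders = c("Ana", "Dan"),
                    mc_bystanders = c("Ana", "Dan", "Bea"),
                    redirection_target = "Dan")
  opp <- build_opportunity_table(
    d, affil = data.frame(id_a = character(), id_b = character(),
                          engaged_scans = integer(),
                          copresent_scans = integer(), index = numeric()))
  expect_true("Dan" %in% opp$bystander_id)
  expect_true(all(opp$redirection_occurred == 1))
})

test_that("kinship coding is mother-offspring or none", {
  r <- tiny_roster()
  expect_true(is_kin(r, "Ana", "Cleo"))
  expect_true(is_kin(r, "Cleo", "Ana"))
  expect_true(is_kin(r, "Bea", "Edo"))
  expect_false(is_kin(r, "Ana", "Bea"))
  expect_false(is_kin(r, "Cleo", "Edo"))  # siblings-by-proxy are not kin
})

test_that("opportunity rows and covariates agree with a brute-force count", {
  r <- lola_roster()
  a <- simulate_affiliation(r, seed = 31)
  d <- simulate_observation(r, a, colony_config(), response_model(),
                            hours = 25, seed = 31)
  lab <- label_dataset(d, "per_bystander")
  opp <- build_opportunity_table(d, lab)
  # row count = sum over retained conflicts of eligible bystanders
  pt <- pair_table(d); pt <- pt[pt$has_mc, ]
  fb <- d$follow_bystanders
  n_oracle <- 0
  for (k in seq_len(nrow(pt))) {
    pcb <- fb$id[fb$follow_id == pt$pc_follow_id[k]]
    mcb <- fb$id[fb$follow_id == pt$mc_follow_id[k]]
    n_oracle <- n_oracle + length(setdiff(intersect(pcb, mcb),
                                          c(pt$victim_id[k],
                                            pt$aggressor_id[k])))
  }
  expect_equal(nrow(opp), n_oracle)
  # outcome coding: consoled == 1 iff specific-bystander label attracted
  expect_equal(opp$consoled, as.integer(lab$label == "attracted"))
  # intensity and context copied from the conflict record
  i <- match(opp$conflict_id, d$conflicts$conflict_id)
  expect_equal(opp$intensity, d$conflicts$intensity[i])
  expect_equal(opp$context_feed,
               as.integer(d$conflicts$context[i] == "feed"))
})
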