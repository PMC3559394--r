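test_that("first-contact extraction respects the initiator direction rule", {
  # victim-initiated contact at 20 s is ignored; bystander contact at 45 s
  # defines the consolation latency
  ct <- rbind(ct_row(45, "Ana", "Cleo"), ct_row(20, "Cleo", "Ana", "groom"))
  sel <- relationship_selector("consolation_any_bystander")
  expect_equal(first_contact_latency(ct, "Cleo", "Bea", sel), 45)
  # aggressor-initiated contact counts as reconciliation, not consolation
  ct2 <- rbind(ct_row(30, "Bea", "Cleo"), ct_row(50, "Dan", "Cleo"))
  expect_equal(first_contact_latency(ct2, "Cleo", "Bea", sel), 50)
  expect_equal(first_contact_latency(
    ct2, "Cleo", "Bea", relationship_selector("reconciliation")), 30)
  # earliest of several qualifying contacts
  ct3 <- rbind(ct_row(30, "Ana", "Cleo"), ct_row(12, "Dan", "Cleo"))
  expect_equal(first_contact_latency(ct3, "Cleo", "Bea", sel), 12)
  # no contacts -> censored
  expect_identical(first_contact_latency(ct3[0, ], "Cleo", "Bea", sel), Inf)
  # specific-bystander mode needs an id
  expect_error(relationship_selector("consolation_specific_bystander"),
               class = "pcmc_contract_error")
})

test_that("pair classification follows the attracted/dispersed/neutral rule", {
  expect_equal(classify_pair(45, Inf), "attracted")
  expect_equal(classify_pair(Inf, 45), "dispersed")
  expect_equal(classify_pair(Inf, Inf), "neutral")
  expect_equal(classify_pair(30, 30), "neutral")
  expect_equal(classify_pair(29, 30), "attracted")
  expect_equal(classify_pair(30, 29), "dispersed")
})

test_that("identical PC and MC streams label every pair neutral", {
  ct <- rbind(ct_row(100, "Ana", "Cleo"), ct_row(200, "Bea", "Cleo"))
  d <- pair_dataset(pc_contacts = ct, mc_contacts = ct)
  for (mode in c("consolation", "reconciliation", "per_bystander")) {
    lab <- label_dataset(d, mode)
    expect_true(all(lab$label == "neutral"), info = mode)
  }
})

test_that("pairs lacking a matched control are excluded entirely", {
  d <- pair_dataset(pc_contacts = ct_row(10, "Ana", "Cleo"),
                    with_mc = FALSE)
  expect_equal(nrow(label_dataset(d, "consolation")), 0)
})

test_that("labels match the brute-force oracle on random datasets", {
  for (s in 1:50) {
    d <- random_tiny_dataset(s)
    for (mode in c("consolation", "reconciliation", "per_bystander")) {
      got <- label_dataset(d, mode)
      want <- oracle_labels(d, mode)
      if (nrow(want) == 0) {
        expect_equal(nrow(got), 0)
        next
      }
      if (mode == "per_bystander") {
        key <- function(x) order(x$conflict_id, x$bystander_id)
        expect_equal(got$label[key(got)], want$label[key(want)],
                     info = sprintf("seed %d mode %s", s, mode))
      } else {
        expect_equal(got$label[order(got$conflict_id)],
                     want$label[order(want$conflict_id)],
                     info = sprintf("seed %d mode %s", s, mode))
      }
      # conservation: every retained pair gets exactly one label
      expect_equal(nrow(got), nrow(want))
    }
  }
})

test_that("swapping PC and MC streams swaps attracted and dispersed", {
  swap_follows <- function(d) {
    k <- d$follows$kind
    d$follows$kind <- ifelse(k == "PC", "MC", "PC")
    # keep dates/start plausible; labels only read contacts and kinds
    d
  }
  for (s in 1:10) {
    d <- random_tiny_dataset(s)
    lab <- label_dataset(d, "consolation")
    d2 <- unclass(d)
    d2 <- structure(swap_follows(d), class = "pcmc_dataset")
    lab2 <- label_dataset(d2, "consolation")
    o1 <- order(lab$conflict_id); o2 <- order(lab2$conflict_id)
    mapped <- c(attracted = "dispersed", dispersed = "attracted",
                neutral = "neutral")[lab$label[o1]]
    expect_equal(lab2$label[o2], unname(mapped))
  }
})

test_that("tendency formula is applied exactly", {
  mk <- function(A, D, N) {
    data.frame(victim_id = "v",
               label = rep(c("attracted", "dispersed", "neutral"),
                           c(A, D, N)))
  }
  expect_equal(tendency_scores(mk(5, 2, 3))$tendency, 30)
  expect_equal(tendency_scores(mk(4, 4, 2))$tendency, 0)
  expect_equal(tendency_scores(mk(10, 0, 0))$tendency, 100)
  ts <- tendency_scores(mk(5, 2, 3))
  expect_equal(ts$n_pairs, 10)
  expect_equal(ts$prop_attracted, 0.5)
})

test_that("randomized count triples satisfy the tendency identity", {
  set.seed(42)
  for (i in 1:200) {
    A <- sample(0:20, 1); D <- sample(0:20, 1); N <- sample(0:20, 1)
    if (A + D + N == 0) next
    lab <- data.frame(victim_id = "v",
                      label = rep(c("attracted", "dispersed", "neutral"),
                                  c(A, D, N)))
    ts <- tendency_scores(lab)
    expect_equal(ts$tendency, 100 * (A - D) / (A + D + N))
    expect_gte(ts$tendency, -100)
    expect_lte(ts$tendency, 100)
    expect_equal(ts$n_attracted + ts$n_dispersed + ts$n_neutral, ts$n_pairs)
  }
})

test_that("a baseline without contacts yields no dispersed pairs", {
  r <- lola_roster()
  a <- simulate_affiliation(r, seed = 21)
  resp <- response_model(p_mc = 1e-12, p_mc_opponent = 0)
  d <- simulate_observation(r, a, colony_config(), resp, hours = 40,
                            seed = 21, include_scans = FALSE)
  lab <- label_dataset(d, "consolation")
  expect_equal(sum(lab$label == "dispersed"), 0)
  expect_gt(sum(lab$label == "attracted"), 0)
})

test_that("consolation index counts global first-consoler opportunities", {
  # Ana consoles first at 40 s; Dan later at 90 s. Both eligible.
  d <- pair_dataset(pc_contacts = rbind(ct_row(40, "Ana", "Cleo"),
                                        ct_row(90, "Dan", "Cleo")),
                    mc_contacts = NULL)
  ci <- consolation_index(d)
  ana <- ci[ci$bystander_id == "Ana", ]
  dan <- ci[ci$bystander_id == "Dan", ]
  expect_equal(ana$index, 1)
  expect_equal(dan$index, 0)
  expect_equal(dan$n_opportunities, 1)
  # a bystander absent from the MC has no opportunity and is omitted
  d2 <- pair_dataset(pc_contacts = ct_row(40, "Edo", "Cleo"),
                     mc_bystanders = c("Ana", "Dan", "Bea"))
  ci2 <- consolation_index(d2)
  expect_false("Edo" %in% ci2$bystander_id)
})

test_that("consolation index equals a brute-force count on random data", {
  for (s in 1:15) {
    d <- random_tiny_dataset(s)
    ci <- consolation_index(d)
    lab <- oracle_labels(d, "per_bystander")
    if (nrow(lab) == 0) next
    # oracle: first consolatory contact per PC from raw logs
    pt <- pair_table(d); pt <- pt[pt$has_mc, ]
    firsts <- list()
    for (k in seq_len(nrow(pt))) {
      ct <- d$contacts[d$contacts$follow_id == pt$pc_follow_id[k], ]
      q <- ct[ct$recipient_id == pt$victim_id[k] &
                !ct$initiator_id %in% c(pt$victim_id[k],
                                        pt$aggressor_id[k]), ]
      if (nrow(q)) {
        firsts[[as.character(pt$conflict_id[k])]] <-
          q$initiator_id[which.min(q$time_s)]
      }
    }
    for (j in seq_len(nrow(ci))) {
      opp <- lab[lab$bystander_id == ci$bystander_id[j], , drop = FALSE]
      vict <- d$conflicts$victim_id[match(opp$conflict_id,
                                          d$conflicts$conflict_id)]
      opp <- opp[vict == ci$victim_id[j], , drop = FALSE]
      n_first <- sum(vapply(opp$conflict_id, function(cid) {
        identical(firsts[[as.character(cid)]], ci$bystander_id[j])
      }, TRUE))
      expect_equal(ci$n_first[j], n_first)
      expect_equal(ci$n_opportunities[j], nrow(opp))
    }
  }
})
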