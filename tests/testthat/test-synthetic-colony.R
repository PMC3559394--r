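test_that("simulated rosters honor cell counts, kinship and determinism", {
  cfg <- colony_config()
  r1 <- simulate_roster(cfg, seed = 7)
  expect_equal(sum(r1$age_class != "infant"), 36)
  got <- aggregate(list(n = r1$id),
                   r1[c("group_id", "sex", "age_class", "rearing")], length)
  want <- cfg$roster_counts
  key <- function(x) paste(x$group_id, x$sex, x$age_class, x$rearing)
  expect_equal(got$n[order(key(got))], want$n[order(key(want))])
  expect_silent(validate_dataset(pcmc_dataset(r1)))
  expect_identical(r1, simulate_roster(cfg, seed = 7))
  expect_false(identical(r1, simulate_roster(cfg, seed = 8)))

  # zero individuals -> empty roster
  empty <- colony_config(roster_counts = data.frame(
    group_id = "G1", sex = "F", age_class = "adult",
    rearing = "orphan", n = 0))
  expect_equal(nrow(simulate_roster(empty, seed = 1)), 0)

  # more mother-reared juveniles than adult females is infeasible
  bad <- colony_config(roster_counts = data.frame(
    group_id = "G1",
    sex = c("F", "F"), age_class = c("adult", "juvenile"),
    rearing = c("orphan", "mother_reared"), n = c(1, 3)))
  expect_error(simulate_roster(bad, seed = 1), class = "pcmc_config_error")
})

test_that("latent affinity is symmetric, bounded and kin-elevated", {
  r <- lola_roster()
  for (s in 1:20) {
    a <- simulate_affiliation(r, kin_boost = 1.5, seed = s)
    in_range <- a[!is.na(a)]
    expect_true(all(in_range > 0 & in_range < 1))
    expect_true(isTRUE(all.equal(a, t(a))))
    kin <- is_kin(r, rep(r$id, each = nrow(r)), rep(r$id, nrow(r)))
    km <- matrix(kin, nrow(r))
    expect_gt(mean(a[km & !is.na(a)]), mean(a[!km & !is.na(a)]))
  }
  # with no kin boost the two distributions coincide in expectation;
  # check the gap is small over pooled seeds
  gaps <- vapply(1:20, function(s) {
    a <- simulate_affiliation(r, kin_boost = 0, seed = s)
    kin <- matrix(is_kin(r, rep(r$id, each = nrow(r)), rep(r$id, nrow(r))),
                  nrow(r))
    mean(a[kin & !is.na(a)]) - mean(a[!kin & !is.na(a)])
  }, 0)
  expect_lt(abs(mean(gaps)), 0.05)
})

test_that("scan engagement frequency recovers the latent affinity", {
  # two-individual colony with a known affinity: engagement probability in
  # co-present scans must sit inside the binomial 99% interval
  r <- tiny_roster()[1:2, ]
  a <- simulate_affiliation(r, seed = 3)
  aff <- a["Ana", "Bea"]
  cfg <- small_config(scan_interval_s = 60, scan_presence_prob = 1)
  d <- simulate_observation(r, a, cfg, null_response_model(),
                            hours = 20, seed = 3)
  n <- nrow(d$scans)
  expect_gt(n, 800)
  eng <- length(unique(d$scan_engaged$scan_id))
  ci <- stats::binom.test(eng, n, aff, conf.level = 0.99)$conf.int
  expect_gt(aff, ci[1])
  expect_lt(aff, ci[2])
})

test_that("victim and aggressor class shares match the configured probabilities", {
  r <- lola_roster()
  a <- simulate_affiliation(r, seed = 9)
  cfg <- colony_config()
  d <- simulate_observation(r, a, cfg, response_model(),
                            hours = c(G1 = 301, G2 = 152), seed = 9,
                            include_scans = FALSE)
  n <- nrow(d$conflicts)
  expect_gt(n, 300)
  cls <- function(ids) {
    paste(r$sex[match(ids, r$id)], r$age_class[match(ids, r$id)], sep = ".")
  }
  vshare <- cls(d$conflicts$victim_id)
  ashare <- cls(d$conflicts$aggressor_id)
  checks <- list(c("victim", "M.adolescent", 0.331),
                 c("victim", "F.juvenile", 0.325),
                 c("aggressor", "F.adult", 0.512),
                 c("aggressor", "M.adult", 0.254))
  for (ch in checks) {
    x <- if (ch[1] == "victim") vshare else ashare
    k <- sum(x == ch[2])
    ci <- stats::binom.test(k, n, as.numeric(ch[3]),
                            conf.level = 0.99)$conf.int
    expect_gt(as.numeric(ch[3]), ci[1])
    expect_lt(as.numeric(ch[3]), ci[2])
  }
})

test_that("conflict counts follow the configured Poisson rate", {
  r <- lola_roster()
  a <- simulate_affiliation(r, seed = 2)
  cfg <- colony_config(conflict_rate = 0.8)
  counts <- vapply(1:5, function(s) {
    d <- simulate_observation(r[r$group_id == "G1", ], a, cfg,
                              null_response_model(), hours = 40, seed = s,
                              include_scans = FALSE)
    nrow(d$conflicts)
  }, 0L)
  # each draw within 3 SD of Poisson mean 32
  expect_true(all(abs(counts - 32) <= 3 * sqrt(32)))
})

test_that("degenerate response models produce degenerate streams", {
  r <- lola_roster()
  a <- simulate_affiliation(r, seed = 4)
  # consolation impossible: no bystander-initiated PC contacts at all
  imp <- response_model()
  imp$consolation["intercept"] <- -Inf
  d <- simulate_observation(r, a, colony_config(), imp, hours = 40,
                            seed = 4, include_scans = FALSE)
  pc_ids <- d$follows$follow_id[d$follows$kind == "PC"]
  ct <- d$contacts[d$contacts$follow_id %in% pc_ids, ]
  v_of <- setNames(d$follows$focal_id, as.character(d$follows$follow_id))
  a_of <- setNames(
    d$conflicts$aggressor_id[match(d$follows$conflict_id,
                                   d$conflicts$conflict_id)],
    as.character(d$follows$follow_id))
  bystander_init <- ct$initiator_id != v_of[as.character(ct$follow_id)] &
    ct$initiator_id != a_of[as.character(ct$follow_id)]
  expect_equal(sum(bystander_init), 0)
})

test_that("equal scratch intensities yield equal PC and MC scratch rates", {
  r <- lola_roster()
  a <- simulate_affiliation(r, seed = 6)
  d <- simulate_observation(r, a, colony_config(), null_response_model(),
                            hours = c(G1 = 301, G2 = 152), seed = 6,
                            include_scans = FALSE)
  sb <- d$self_directed[d$self_directed$kind == "scratch_bout", ]
  cnt <- table(factor(sb$follow_id, levels = d$follows$follow_id))
  rate <- as.numeric(cnt) / 10
  pc_mean <- mean(rate[d$follows$kind == "PC"])
  mc_mean <- mean(rate[d$follows$kind == "MC"])
  # both arms share lambda = 0.37; Monte-Carlo error at ~350 follows/arm
  expect_lt(abs(pc_mean - mc_mean), 3 * sqrt(2 * 0.37 / 10 / 350))
})

test_that("identical config and seed give byte-identical output files", {
  r <- lola_roster()
  a <- simulate_affiliation(r, seed = 12)
  cfg <- colony_config()
  d1 <- simulate_observation(r, a, cfg, response_model(), hours = 10,
                             seed = 12)
  d2 <- simulate_observation(r, a, cfg, response_model(), hours = 10,
                             seed = 12)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_dataset(d1, dir1); write_dataset(d2, dir2)
  for (f in list.files(dir1)) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))), info = f)
  }
  # generated datasets always validate
  expect_silent(validate_dataset(d1))
})
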