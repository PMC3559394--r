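# Shared fixtures and independent brute-force oracles. The oracles are kept
# deliberately naive (explicit loops over raw event logs) so they share no
# code path with the package implementations they check.

tiny_roster <- function() {
  data.frame(
    id = c("Ana", "Bea", "Cleo", "Dan", "Edo", "Fia"),
    code = c("AN", "BE", "CL", "DA", "ED", "FI"),
    sex = c("F", "F", "F", "M", "M", "F"),
    age_years = c(15, 14, 6, 12, 5, 9),
    age_class = c("adult", "adult", "juvenile", "adult", "juvenile",
                  "adolescent"),
    rearing = c("orphan", "orphan", "mother_reared", "orphan",
                "mother_reared", "orphan"),
    mother_id = c(NA, NA, "Ana", NA, "Bea", NA),
    group_id = "G1")
}

small_config <- function(...) {
  r <- tiny_roster()
  counts <- aggregate(list(n = r$id),
                      r[c("group_id", "sex", "age_class", "rearing")],
                      length)
  colony_config(roster_counts = counts, ...)
}

# Build a one-conflict dataset with explicit PC/MC contact streams.
# pc_contacts / mc_contacts: data frames time_s, initiator_id, recipient_id,
# behavior (defaults to "touch").
pair_dataset <- function(victim = "Cleo", aggressor = "Bea",
                         bystanders = c("Ana", "Dan", "Edo"),
                         pc_contacts = NULL, mc_contacts = NULL,
                         pc_bystanders = bystanders,
                         mc_bystanders = c(bystanders, aggressor),
                         with_mc = TRUE, roster = tiny_roster(),
                         context = "rest", redirection_target = NA,
                         pc_self = NULL, mc_self = NULL) {
  fix_ct <- function(x, fid) {
    if (is.null(x) || nrow(x) == 0) return(NULL)
    x$behavior <- x$behavior %||% "touch"
    if (is.null(x$behavior)) x$behavior <- "touch"
    cbind(follow_id = fid, x)
  }
  conflicts <- data.frame(conflict_id = 1L, group_id = "G1",
                          date = "2011-06-01", time_s = 10000,
                          victim_id = victim, aggressor_id = aggressor,
                          context = context, intensity = 3L,
                          redirection_target = redirection_target)
  cb <- data.frame(conflict_id = 1L, id = bystanders,
                   proximity = rep_len(c("lt5m", "5to10m", "gt10m"),
                                       length(bystanders)))
  follows <- data.frame(follow_id = 1L, conflict_id = 1L, kind = "PC",
                        focal_id = victim, date = "2011-06-01",
                        start_s = 10000, duration_s = 600)
  fb <- data.frame(follow_id = 1L, id = pc_bystanders,
                   proximity = rep_len(c("lt5m", "5to10m", "gt10m"),
                                       length(pc_bystanders)))
  if (with_mc) {
    follows <- rbind(follows,
                     data.frame(follow_id = 2L, conflict_id = 1L,
                                kind = "MC", focal_id = victim,
                                date = "2011-06-02", start_s = 10050,
                                duration_s = 600))
    fb <- rbind(fb, data.frame(follow_id = 2L, id = mc_bystanders,
                               proximity = rep_len(c("lt5m", "5to10m"),
                                                   length(mc_bystanders))))
  }
  contacts <- rbind(fix_ct(pc_contacts, 1L),
                    if (with_mc) fix_ct(mc_contacts, 2L))
  selfd <- rbind(if (!is.null(pc_self)) cbind(follow_id = 1L, pc_self),
                 if (with_mc && !is.null(mc_self))
                   cbind(follow_id = 2L, mc_self))
  pcmc_dataset(roster, conflicts, cb, follows, fb, contacts, selfd)
}

ct_row <- function(t, ini, rec, behavior = "touch") {
  data.frame(time_s = t, initiator_id = ini, recipient_id = rec,
             behavior = behavior)
}

# A random multi-conflict dataset built by hand (independent of the
# generator): up to n_conflicts conflicts among the tiny roster with random
# bystander rosters and uniformly random contacts in both follows.
random_tiny_dataset <- function(seed, n_conflicts = 6) {
  set.seed(seed)
  r <- tiny_roster()
  ids <- r$id
  conflicts <- cb <- follows <- fb <- contacts <- list()
  fid <- 0L
  for (k in seq_len(n_conflicts)) {
    vic_agg <- sample(ids, 2)
    bys <- setdiff(ids, vic_agg)
    bys <- bys[runif(length(bys)) < 0.7]
    conflicts[[k]] <- data.frame(conflict_id = k, group_id = "G1",
                                 date = "2011-06-01",
                                 time_s = 1000 * k,
                                 victim_id = vic_agg[1],
                                 aggressor_id = vic_agg[2],
                                 context = sample(c("feed", "rest"), 1),
                                 intensity = sample(1:6, 1),
                                 redirection_target = NA_character_)
    if (length(bys)) {
      cb[[k]] <- data.frame(conflict_id = k, id = bys,
                            proximity = sample(c("lt5m", "5to10m", "gt10m"),
                                               length(bys), TRUE))
    }
    for (kind in c("PC", "MC")) {
      fid <- fid + 1L
      follows[[fid]] <- data.frame(
        follow_id = fid, conflict_id = k, kind = kind,
        focal_id = vic_agg[1],
        date = if (kind == "PC") "2011-06-01" else "2011-06-02",
        start_s = 1000 * k, duration_s = 600)
      present <- if (kind == "PC") bys else
        unique(c(bys[runif(length(bys)) < 0.8], vic_agg[2]))
      if (length(present)) {
        fb[[fid]] <- data.frame(follow_id = fid, id = present,
                                proximity = sample(c("lt5m", "5to10m",
                                                     "gt10m"),
                                                   length(present), TRUE))
      }
      n_ct <- rpois(1, 2)
      if (n_ct > 0) {
        pool <- c(vic_agg, bys)
        ini <- sample(pool, n_ct, TRUE)
        rec <- vapply(ini, function(i) sample(setdiff(pool, i), 1), "")
        contacts[[length(contacts) + 1L]] <- data.frame(
          follow_id = fid, time_s = sample(0:600, n_ct, TRUE),
          initiator_id = ini, recipient_id = unname(rec),
          behavior = sample(c("touch", "groom", "embrace"), n_ct, TRUE))
      }
    }
  }
  pcmc_dataset(r, do.call(rbind, conflicts), do.call(rbind, cb),
               do.call(rbind, follows), do.call(rbind, fb),
               do.call(rbind, contacts), NULL)
}

# Brute-force attracted/dispersed/neutral labels from raw event logs.
oracle_labels <- function(d, mode) {
  out <- list()
  for (k in seq_len(nrow(d$conflicts))) {
    cid <- d$conflicts$conflict_id[k]
    v <- d$conflicts$victim_id[k]
    a <- d$conflicts$aggressor_id[k]
    pc_id <- mc_id <- NA
    for (j in seq_len(nrow(d$follows))) {
      if (d$follows$conflict_id[j] == cid) {
        if (d$follows$kind[j] == "PC") pc_id <- d$follows$follow_id[j]
        if (d$follows$kind[j] == "MC") mc_id <- d$follows$follow_id[j]
      }
    }
    if (is.na(pc_id) || is.na(mc_id)) next
    qualifies <- function(ini, rec, b = NULL) {
      if (mode == "reconciliation") {
        (ini == v && rec == a) || (ini == a && rec == v)
      } else if (is.null(b)) {
        rec == v && ini != v && ini != a
      } else {
        rec == v && ini == b
      }
    }
    firstlat <- function(flw, b = NULL) {
      best <- Inf
      for (j in seq_len(nrow(d$contacts))) {
        if (d$contacts$follow_id[j] == flw &&
            qualifies(d$contacts$initiator_id[j],
                      d$contacts$recipient_id[j], b)) {
          best <- min(best, d$contacts$time_s[j])
        }
      }
      best
    }
    lab_of <- function(p, m) {
      if (p < m) "attracted" else if (m < p) "dispersed" else "neutral"
    }
    if (mode %in% c("consolation", "reconciliation")) {
      p <- firstlat(pc_id); m <- firstlat(mc_id)
      out[[length(out) + 1L]] <- data.frame(conflict_id = cid,
                                            label = lab_of(p, m))
    } else {
      pres <- function(flw) {
        d$follow_bystanders$id[d$follow_bystanders$follow_id == flw]
      }
      elig <- sort(setdiff(intersect(pres(pc_id), pres(mc_id)), c(v, a)))
      for (b in elig) {
        p <- firstlat(pc_id, b); m <- firstlat(mc_id, b)
        out[[length(out) + 1L]] <- data.frame(conflict_id = cid,
                                              bystander_id = b,
                                              label = lab_of(p, m))
      }
    }
  }
  if (length(out) == 0) return(data.frame())
  do.call(rbind, out)
}

# Exact two-sided signed-rank p by direct enumeration of sign patterns.
oracle_wilcoxon_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Hand-computed log-rank chi-square (pooled hypergeometric variance).
oracle_logrank_chisq <- function(time1, event1, time2, event2) {
  times <- sort(unique(c(time1[event1 == 1], time2[event2 == 1])))
  OE <- V <- 0
  for (t in times) {
    n1 <- sum(time1 >= t); n2 <- sum(time2 >= t); n <- n1 + n2
    d1 <- sum(time1 == t & event1 == 1)
    d2 <- sum(time2 == t & event2 == 1)
    dd <- d1 + d2
    OE <- OE + d1 - dd * n1 / n
    if (n > 1) V <- V + dd * (n1 / n) * (n2 / n) * (n - dd) / (n - 1)
  }
  OE^2 / V
}
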