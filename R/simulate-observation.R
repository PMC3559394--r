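#' Simulate an observation campaign over a colony
#'
#' Generative mirror of the field protocol: conflicts arrive as a Poisson
#' process at the configured rate over daily observation sessions; each
#' conflict draws opponents by demographic class, a context, an intensity and
#' a visible bystander roster with proximity bands; its PC follow draws
#' per-bystander consolatory contacts through the response model's logistic
#' hazard (exponential latencies, right-censored at follow end),
#' reconciliation between the opponents, optional redirection by the victim,
#' and self-directed behavior whose scratch rate switches at the first
#' consolatory contact. A matched control is scheduled on the same victim one
#' or two days later at the same time of day (postponed past any conflict of
#' the focal in the preceding 10 minutes), with the aggressor within 10 m,
#' flat contact probabilities and baseline scratch. A configurable fraction of
#' PCs obtains no valid MC. Instantaneous scans on a fixed grid engage
#' co-present dyads with probability equal to their latent affinity.
#'
#' Identical inputs and seed give a byte-identical dataset.
#'
#' @param roster roster data frame (infants may be present; they never
#'   participate).
#' @param affinity matrix from [simulate_affiliation()].
#' @param config a [colony_config()].
#' @param response a [response_model()].
#' @param hours observation hours: scalar (per group) or named vector by
#'   group id.
#' @param seed integer seed.
#' @param include_scans emit scan samples (default `TRUE`; replicate-heavy
#'   simulations that do not need affiliation indices can skip them).
#' @return a validated [pcmc_dataset()] with a `ground_truth` attribute
#'   holding the generator parameters.
#' @export
simulate_observation <- function(roster, affinity, config, response, hours,
                                 seed = 1L, include_scans = TRUE) {
  assert_that(all(hours > 0), "hours must be positive",
              class = "pcmc_config_error")
  set.seed(seed)
  date0 <- as.Date("2011-05-01")
  groups <- sort(unique(roster$group_id))
  if (is.null(names(hours))) {
    hours <- setNames(rep_len(as.numeric(hours), length(groups)), groups)
  }
  ids <- roster$id
  idx <- setNames(seq_along(ids), ids)
  a_class <- setNames(roster$age_class, ids)
  a_sex <- setNames(roster$sex, ids)
  a_rear <- setNames(roster$rearing, ids)
  a_mom <- setNames(roster$mother_id, ids)
  kin2 <- function(x, y) {
    (!is.na(a_mom[x]) & a_mom[x] == y) | (!is.na(a_mom[y]) & a_mom[y] == x)
  }
  laff <- function(x, y) {
    v <- affinity[cbind(idx[x], idx[y])]
    log(pmax(ifelse(is.na(v), 1e-4, v), 1e-4))
  }
  bands <- PROXIMITY_BANDS
  cons <- response$consolation
  rec <- response$reconciliation

  ## ---- conflicts ----
  cf <- list()
  for (g in groups) {
    members <- ids[roster$group_id == g & roster$age_class != "infant"]
    if (length(members) < 2) next
    h <- hours[[g]]
    n_days <- max(1L, ceiling(h / config$day_hours))
    n_c <- rpois(1, config$conflict_rate * h)
    if (n_c == 0) next
    cell <- paste(a_sex[members], a_class[members], sep = ".")
    cells_avail <- intersect(names(config$victim_class_probs), unique(cell))
    by_cell <- split(members, cell)
    draw_individual <- function(probs, n) {
      p <- probs[cells_avail] / sum(probs[cells_avail])
      cl <- sample(cells_avail, n, replace = TRUE, prob = p)
      vapply(cl, function(cc) {
        m <- by_cell[[cc]]
        if (length(m) == 1) m else sample(m, 1)
      }, "")
    }
    victim <- draw_individual(config$victim_class_probs, n_c)
    aggressor <- draw_individual(config$aggressor_class_probs, n_c)
    for (k in which(aggressor == victim)) {
      repeat {
        cand <- draw_individual(config$aggressor_class_probs, 1)
        if (cand != victim[k]) { aggressor[k] <- cand; break }
        aggressor[k] <- sample(setdiff(members, victim[k]), 1)
        break
      }
    }
    day <- sample.int(n_days, n_c, replace = TRUE) - 1L
    time_s <- floor(runif(n_c, 0, config$day_hours * 3600 - 1300))
    o <- order(day, time_s)
    cf[[g]] <- data.frame(
      group_id = g, day = day[o], time_s = time_s[o],
      victim_id = unname(victim[o]), aggressor_id = unname(aggressor[o]),
      context = sample(names(config$context_probs), n_c, replace = TRUE,
                       prob = config$context_probs),
      intensity = sample.int(6L, n_c, replace = TRUE,
                             prob = config$intensity_probs))
  }
  cf <- do.call(rbind, cf)
  if (is.null(cf) || nrow(cf) == 0) {
    d <- pcmc_dataset(roster)
    attr(d, "ground_truth") <- list(config = config, response = response,
                                    hours = hours, seed = seed)
    return(d)
  }
  rownames(cf) <- NULL
  n_c <- nrow(cf)
  cf$conflict_id <- seq_len(n_c)
  cf$date <- as.character(date0 + cf$day)
  cf$redirection_target <- NA_character_

  members_of <- lapply(setNames(groups, groups), function(g) {
    ids[roster$group_id == g & roster$age_class != "infant"]
  })

  ## per-conflict accumulators
  cb_cid <- cb_id <- cb_prox <- vector("list", n_c)
  fl_rows <- vector("list", 2L * n_c)
  fb_fid <- fb_id <- fb_prox <- vector("list", 2L * n_c)
  ct_fid <- ct_t <- ct_ini <- ct_rec <- ct_beh <- vector("list", 4L * n_c)
  sd_fid <- sd_t <- sd_kind <- sd_dur <- vector("list", 4L * n_c)
  ct_n <- 0L
  sd_n <- 0L
  fid <- 0L

  add_contacts <- function(fidv, t, ini, recp) {
    ct_n <<- ct_n + 1L
    ct_fid[[ct_n]] <<- rep(fidv, length(t))
    ct_t[[ct_n]] <<- t
    ct_ini[[ct_n]] <<- ini
    ct_rec[[ct_n]] <<- recp
    ct_beh[[ct_n]] <<- sample(CONTACT_BEHAVIORS, length(t), replace = TRUE)
  }
  add_sd <- function(fidv, t, kind, dur) {
    sd_n <<- sd_n + 1L
    sd_fid[[sd_n]] <<- rep(fidv, length(t))
    sd_t[[sd_n]] <<- t
    sd_kind[[sd_n]] <<- kind
    sd_dur[[sd_n]] <<- dur
  }
  groom_events <- function(rate_s_per_min) {
    nb <- rpois(1, response$groom_bouts)
    if (nb == 0) return(NULL)
    t <- sort(floor(runif(nb, 0, FOLLOW_DURATION_S)))
    mean_dur <- rate_s_per_min * 10 / response$groom_bouts
    dur <- round(pmin(rexp(nb, 1 / mean_dur), FOLLOW_DURATION_S - t))
    list(t = t, dur = dur)
  }
  scratch_events <- function(l1, l2, t_switch) {
    n1 <- rpois(1, l1 * t_switch / 60)
    n2 <- rpois(1, l2 * (FOLLOW_DURATION_S - t_switch) / 60)
    t1 <- if (n1) floor(runif(n1, 0, t_switch)) else numeric()
    t2 <- if (n2) t_switch + floor(runif(n2, 0, FOLLOW_DURATION_S - t_switch))
          else numeric()
    sort(c(t1, t2))
  }

  for (k in seq_len(n_c)) {
    g <- cf$group_id[k]
    v <- cf$victim_id[k]
    a <- cf$aggressor_id[k]
    others <- setdiff(members_of[[g]], c(v, a))
    bys <- others[runif(length(others)) < config$bystander_presence_prob]
    prox <- sample(bands, length(bys), replace = TRUE,
                   prob = config$proximity_probs)
    cb_cid[[k]] <- rep(cf$conflict_id[k], length(bys))
    cb_id[[k]] <- bys
    cb_prox[[k]] <- prox

    ## redirection
    p_red <- if (a_sex[v] == "F" && a_class[v] == "adult")
      config$redirection_prob_adult_female else config$redirection_prob_other
    redirected <- length(bys) > 0 && runif(1) < p_red
    if (redirected) {
      cf$redirection_target[k] <- if (length(bys) == 1) bys else
        sample(bys, 1)
    }

    ## PC follow
    fid <- fid + 1L
    pc_fid <- fid
    fl_rows[[pc_fid]] <- data.frame(
      follow_id = pc_fid, conflict_id = cf$conflict_id[k], kind = "PC",
      focal_id = v, date = cf$date[k], start_s = cf$time_s[k],
      duration_s = FOLLOW_DURATION_S)
    fb_fid[[pc_fid]] <- rep(pc_fid, length(bys))
    fb_id[[pc_fid]] <- bys
    fb_prox[[pc_fid]] <- prox

    ## reconciliation in the PC
    eta_rec <- rec[["intercept"]] +
      rec[["log_affiliation"]] * laff(v, a) +
      rec[["victim_mother_reared"]] * (a_rear[[v]] == "mother_reared") +
      rec[["aggressor_juvenile"]] * (a_class[[a]] == "juvenile") +
      rec[["victim_adolescent"]] * (a_class[[v]] == "adolescent")
    rec_lat <- Inf
    if (runif(1) < plogis(eta_rec)) {
      lt <- ceiling(rexp(1, 1 / response$tau_recon))
      if (lt <= FOLLOW_DURATION_S) rec_lat <- lt
    }
    rec_occurred <- is.finite(rec_lat)
    if (rec_occurred) {
      ini <- if (runif(1) < 0.5) a else v
      add_contacts(pc_fid, rec_lat, ini, setdiff(c(v, a), ini))
    }

    ## consolation hazards per bystander
    cons_lat <- Inf
    if (length(bys)) {
      eta <- cons[["intercept"]] +
        cons[["proximity"]] * (match(prox, bands) - 1) +
        cons[["bystander_juvenile"]] * (a_class[bys] == "juvenile") +
        cons[["bystander_adolescent"]] * (a_class[bys] == "adolescent") +
        cons[["bystander_mother_reared"]] * (a_rear[bys] == "mother_reared") +
        cons[["log_affiliation"]] * laff(bys, v) +
        cons[["kin_victim"]] * kin2(bys, v) +
        cons[["kin_aggressor"]] * kin2(bys, a) +
        cons[["context_feed"]] * (cf$context[k] == "feed") +
        cons[["reconciliation"]] * rec_occurred +
        cons[["redirection"]] * redirected
      doit <- runif(length(bys)) < plogis(unname(eta))
      lat <- ceiling(rexp(length(bys), 1 / response$tau_pc))
      keep <- doit & lat <= FOLLOW_DURATION_S
      if (any(keep)) {
        add_contacts(pc_fid, lat[keep], bys[keep], rep(v, sum(keep)))
        cons_lat <- min(lat[keep])
      }
    }

    ## victim-initiated contact (never counts as consolation)
    if (length(bys) && runif(1) < response$victim_contact_rate) {
      tgt <- if (length(bys) == 1) bys else sample(bys, 1)
      add_contacts(pc_fid, floor(runif(1, 0, FOLLOW_DURATION_S)), v, tgt)
    }

    ## self-directed behavior in the PC
    t_switch <- min(cons_lat, FOLLOW_DURATION_S)
    st <- scratch_events(response$lambda_pc, response$lambda_pc_consoled,
                         t_switch)
    if (length(st)) add_sd(pc_fid, st, rep("scratch_bout", length(st)),
                           rep(0, length(st)))
    gr_rate <- if (is.finite(cons_lat)) response$groom_pc_consoled else
      response$groom_pc
    ge <- groom_events(gr_rate)
    if (!is.null(ge)) add_sd(pc_fid, ge$t,
                             rep("groom_interval", length(ge$t)), ge$dur)

    ## matched control
    if (runif(1) < config$mc_failure_prob) next
    fid <- fid + 1L
    mc_fid <- fid
    day_off <- sample(as.integer(names(config$mc_day_probs)), 1,
                      prob = config$mc_day_probs)
    mc_day <- cf$day[k] + day_off
    mc_date <- as.character(date0 + mc_day)
    start <- cf$time_s[k] + floor(runif(1, -600, 600))
    start <- min(max(start, 0), config$day_hours * 3600 - 601)
    for (tries in 1:5) {
      clash <- cf$day == mc_day & cf$group_id == g &
        (cf$victim_id == v | cf$aggressor_id == v) &
        cf$time_s < start & cf$time_s >= start - 600
      if (!any(clash)) break
      start <- max(cf$time_s[clash]) + 601
    }
    fl_rows[[mc_fid]] <- data.frame(
      follow_id = mc_fid, conflict_id = cf$conflict_id[k], kind = "MC",
      focal_id = v, date = mc_date, start_s = start,
      duration_s = FOLLOW_DURATION_S)
    mc_bys <- others[runif(length(others)) < config$mc_presence_prob]
    mc_prox <- sample(bands, length(mc_bys), replace = TRUE,
                      prob = config$proximity_probs)
    agg_band <- sample(c("lt5m", "5to10m"), 1)
    fb_fid[[mc_fid]] <- rep(mc_fid, length(mc_bys) + 1L)
    fb_id[[mc_fid]] <- c(mc_bys, a)
    fb_prox[[mc_fid]] <- c(mc_prox, agg_band)

    if (length(mc_bys)) {
      doit <- runif(length(mc_bys)) < response$p_mc
      lat <- ceiling(rexp(length(mc_bys), 1 / response$tau_mc))
      keep <- doit & lat <= FOLLOW_DURATION_S
      if (any(keep)) {
        add_contacts(mc_fid, lat[keep], mc_bys[keep], rep(v, sum(keep)))
      }
    }
    if (runif(1) < response$p_mc_opponent) {
      lt <- ceiling(rexp(1, 1 / response$tau_mc))
      if (lt <= FOLLOW_DURATION_S) {
        ini <- if (runif(1) < 0.5) a else v
        add_contacts(mc_fid, lt, ini, setdiff(c(v, a), ini))
      }
    }
    st <- scratch_events(response$lambda_mc, response$lambda_mc,
                         FOLLOW_DURATION_S)
    if (length(st)) add_sd(mc_fid, st, rep("scratch_bout", length(st)),
                           rep(0, length(st)))
    ge <- groom_events(response$groom_mc)
    if (!is.null(ge)) add_sd(mc_fid, ge$t,
                             rep("groom_interval", length(ge$t)), ge$dur)
  }

  conflicts <- cf[c("conflict_id", "group_id", "date", "time_s", "victim_id",
                    "aggressor_id", "context", "intensity",
                    "redirection_target")]
  conflict_bystanders <- data.frame(
    conflict_id = unlist(cb_cid) %||% integer(),
    id = unlist(cb_id) %||% character(),
    proximity = unlist(cb_prox) %||% character())
  follows <- do.call(rbind, fl_rows[!vapply(fl_rows, is.null, TRUE)])
  follow_bystanders <- data.frame(
    follow_id = unlist(fb_fid) %||% integer(),
    id = unlist(fb_id) %||% character(),
    proximity = unlist(fb_prox) %||% character())
  contacts <- data.frame(
    follow_id = unlist(ct_fid[seq_len(ct_n)]) %||% integer(),
    time_s = unlist(ct_t[seq_len(ct_n)]) %||% numeric(),
    initiator_id = unlist(ct_ini[seq_len(ct_n)]) %||% character(),
    recipient_id = unlist(ct_rec[seq_len(ct_n)]) %||% character(),
    behavior = unlist(ct_beh[seq_len(ct_n)]) %||% character())
  self_directed <- data.frame(
    follow_id = unlist(sd_fid[seq_len(sd_n)]) %||% integer(),
    time_s = unlist(sd_t[seq_len(sd_n)]) %||% numeric(),
    kind = unlist(sd_kind[seq_len(sd_n)]) %||% character(),
    duration_s = unlist(sd_dur[seq_len(sd_n)]) %||% numeric())

  ## ---- scans ----
  scans <- scan_presence <- scan_engaged <- NULL
  if (include_scans) {
    sc_list <- sp_list <- se_list <- list()
    sid0 <- 0L
    for (g in groups) {
      members <- members_of[[g]]
      if (length(members) < 2) next
      h <- hours[[g]]
      n_days <- max(1L, ceiling(h / config$day_hours))
      tms <- seq(0, config$day_hours * 3600 - 1,
                 by = config$scan_interval_s)
      grid <- expand.grid(time_s = tms, day = seq_len(n_days) - 1L)
      keep_h <- (grid$day * config$day_hours + grid$time_s / 3600) < h
      grid <- grid[keep_h, , drop = FALSE]
      ns <- nrow(grid)
      if (ns == 0) next
      sids <- sid0 + seq_len(ns)
      sid0 <- sid0 + ns
      sc_list[[g]] <- data.frame(scan_id = sids, group_id = g,
                                 date = as.character(date0 + grid$day),
                                 time_s = grid$time_s)
      P <- matrix(runif(ns * length(members)) < config$scan_presence_prob,
                  ns, length(members))
      colnames(P) <- members
      hits <- which(P, arr.ind = TRUE)
      o <- order(hits[, 1], hits[, 2])
      sp_list[[g]] <- data.frame(
        scan_id = sids[hits[o, 1]],
        id = members[hits[o, 2]])
      pairs <- combn(members, 2)
      eng <- list()
      for (j in seq_len(ncol(pairs))) {
        ia <- pairs[1, j]; ib <- pairs[2, j]
        aff <- affinity[idx[[ia]], idx[[ib]]]
        if (is.na(aff)) next
        co <- P[, ia] & P[, ib]
        hit <- co & (runif(ns) < aff)
        if (any(hit)) {
          eng[[length(eng) + 1L]] <- data.frame(
            scan_id = sids[hit], id_a = min(ia, ib), id_b = max(ia, ib),
            behavior = sample(SCAN_BEHAVIORS, sum(hit), replace = TRUE))
        }
      }
      if (length(eng)) se_list[[g]] <- do.call(rbind, eng)
    }
    scans <- if (length(sc_list)) do.call(rbind, sc_list) else NULL
    scan_presence <- if (length(sp_list)) do.call(rbind, sp_list) else NULL
    scan_engaged <- if (length(se_list)) do.call(rbind, se_list) else NULL
    if (!is.null(scan_engaged)) {
      scan_engaged <- scan_engaged[order(scan_engaged$scan_id,
                                         scan_engaged$id_a,
                                         scan_engaged$id_b), , drop = FALSE]
    }
  }

  d <- pcmc_dataset(roster, conflicts, conflict_bystanders, follows,
                    follow_bystanders, contacts, self_directed,
                    scans, scan_presence, scan_engaged)
  attr(d, "ground_truth") <- list(config = config, response = response,
                                  hours = hours, seed = seed)
  d
}
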