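#' Relationship selector for first-contact extraction
#'
#' Chooses which contacts of a follow define the focal relationship:
#' `consolation_any_bystander` takes contacts initiated by any uninvolved
#' bystander (neither opponent) toward the victim; `consolation_specific_bystander`
#' restricts the initiator to one given bystander; `reconciliation` takes
#' contacts between the two opponents in either direction. Victim-initiated
#' contacts toward bystanders never qualify as consolation.
#'
#' @param mode one of `"consolation_any_bystander"`,
#'   `"consolation_specific_bystander"`, `"reconciliation"`.
#' @param bystander_id required for the specific-bystander mode.
#' @return a list of class `relationship_selector`.
#' @export
relationship_selector <- function(mode = c("consolation_any_bystander",
                                           "consolation_specific_bystander",
                                           "reconciliation"),
                                  bystander_id = NULL) {
  mode <- match.arg(mode)
  if (mode == "consolation_specific_bystander") {
    assert_that(!is.null(bystander_id),
                "specific-bystander selector needs a bystander_id",
                class = "pcmc_contract_error")
  }
  structure(list(mode = mode, bystander_id = bystander_id),
            class = "relationship_selector")
}

#' First qualifying contact latency of a follow
#'
#' Minimum event time among the contacts selected by the relationship
#' selector; `Inf` (censored at follow end) when none qualifies.
#'
#' @param contacts contacts of one follow (data frame with `time_s`,
#'   `initiator_id`, `recipient_id`).
#' @param victim_id,aggressor_id the conflict's opponents.
#' @param selector a [relationship_selector()].
#' @return numeric latency in seconds, or `Inf` if censored.
#' @export
first_contact_latency <- function(contacts, victim_id, aggressor_id,
                                  selector) {
  if (is.null(contacts) || nrow(contacts) == 0) return(Inf)
  q <- switch(selector$mode,
    consolation_any_bystander =
      contacts$recipient_id == victim_id &
      contacts$initiator_id != victim_id &
      contacts$initiator_id != aggressor_id,
    consolation_specific_bystander =
      contacts$recipient_id == victim_id &
      contacts$initiator_id == selector$bystander_id,
    reconciliation =
      (contacts$initiator_id == victim_id &
         contacts$recipient_id == aggressor_id) |
      (contacts$initiator_id == aggressor_id &
         contacts$recipient_id == victim_id))
  if (!any(q)) return(Inf)
  min(contacts$time_s[q])
}

#' Classify a PC/MC pair from its two first-contact latencies
#'
#' `attracted` when the contact came earlier in the PC than the MC or only in
#' the PC; `dispersed` symmetrically for the MC; `neutral` when the contact
#' fell at the same time (1-second resolution) in both or occurred in
#' neither. Censored follows are encoded as `Inf` latency.
#'
#' @param pc_latency,mc_latency latencies from [first_contact_latency()].
#' @return `"attracted"`, `"dispersed"` or `"neutral"`.
#' @export
classify_pair <- function(pc_latency, mc_latency) {
  ifelse(pc_latency < mc_latency, "attracted",
         ifelse(mc_latency < pc_latency, "dispersed", "neutral"))
}

#' Label every retained PC/MC pair of a dataset
#'
#' Computes first-contact latencies in the PC and MC of each conflict that
#' has a valid matched control (pairs lacking one are excluded entirely) and
#' classifies the pair as attracted/dispersed/neutral. With the
#' any-bystander or reconciliation selector the result has one row per
#' retained pair. With `mode = "per_bystander"` the specific-bystander
#' selector is applied to every bystander eligible for that conflict --
#' present in both the PC and the MC -- giving one row per (pair x eligible
#' bystander), the granularity the occurrence GLMM consumes.
#'
#' @param d a validated [pcmc_dataset()].
#' @param mode `"consolation"` (any bystander), `"reconciliation"`, or
#'   `"per_bystander"`.
#' @return data frame with `conflict_id`, `victim_id`, `aggressor_id`,
#'   `group_id`, (`bystander_id` for per-bystander mode), `pc_latency`,
#'   `mc_latency` (seconds, `Inf` = censored) and `label`.
#' @export
label_dataset <- function(d, mode = c("consolation", "reconciliation",
                                      "per_bystander")) {
  mode <- match.arg(mode)
  pt <- pair_table(d)
  pt <- pt[pt$has_mc, , drop = FALSE]
  if (nrow(pt) == 0) {
    out <- data.frame(conflict_id = integer(), victim_id = character(),
                      aggressor_id = character(), group_id = character(),
                      pc_latency = numeric(), mc_latency = numeric(),
                      label = character())
    if (mode == "per_bystander") out$bystander_id <- character()
    return(out)
  }
  ct_by_follow <- split(d$contacts, d$contacts$follow_id)
  get_ct <- function(fid) ct_by_follow[[as.character(fid)]]

  if (mode != "per_bystander") {
    sel_mode <- if (mode == "consolation") "consolation_any_bystander" else
      "reconciliation"
    sel <- relationship_selector(sel_mode)
    pc_lat <- mc_lat <- numeric(nrow(pt))
    for (k in seq_len(nrow(pt))) {
      pc_lat[k] <- first_contact_latency(get_ct(pt$pc_follow_id[k]),
                                         pt$victim_id[k], pt$aggressor_id[k],
                                         sel)
      mc_lat[k] <- first_contact_latency(get_ct(pt$mc_follow_id[k]),
                                         pt$victim_id[k], pt$aggressor_id[k],
                                         sel)
    }
    return(data.frame(conflict_id = pt$conflict_id,
                      victim_id = pt$victim_id,
                      aggressor_id = pt$aggressor_id,
                      group_id = pt$group_id,
                      pc_latency = pc_lat, mc_latency = mc_lat,
                      label = classify_pair(pc_lat, mc_lat)))
  }

  fb_by_follow <- split(d$follow_bystanders$id,
                        d$follow_bystanders$follow_id)
  out <- vector("list", nrow(pt))
  for (k in seq_len(nrow(pt))) {
    pc_b <- fb_by_follow[[as.character(pt$pc_follow_id[k])]] %||% character()
    mc_b <- fb_by_follow[[as.character(pt$mc_follow_id[k])]] %||% character()
    eligible <- setdiff(intersect(pc_b, mc_b),
                        c(pt$victim_id[k], pt$aggressor_id[k]))
    if (length(eligible) == 0) next
    eligible <- sort(eligible)
    pc_ct <- get_ct(pt$pc_follow_id[k])
    mc_ct <- get_ct(pt$mc_follow_id[k])
    pc_lat <- mc_lat <- numeric(length(eligible))
    for (j in seq_along(eligible)) {
      sel <- relationship_selector("consolation_specific_bystander",
                                   bystander_id = eligible[j])
      pc_lat[j] <- first_contact_latency(pc_ct, pt$victim_id[k],
                                         pt$aggressor_id[k], sel)
      mc_lat[j] <- first_contact_latency(mc_ct, pt$victim_id[k],
                                         pt$aggressor_id[k], sel)
    }
    out[[k]] <- data.frame(conflict_id = pt$conflict_id[k],
                           victim_id = pt$victim_id[k],
                           aggressor_id = pt$aggressor_id[k],
                           group_id = pt$group_id[k],
                           bystander_id = eligible,
                           pc_latency = pc_lat, mc_latency = mc_lat,
                           label = classify_pair(pc_lat, mc_lat))
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0) {
    return(data.frame(conflict_id = integer(), victim_id = character(),
                      aggressor_id = character(), group_id = character(),
                      bystander_id = character(), pc_latency = numeric(),
                      mc_latency = numeric(), label = character()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
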