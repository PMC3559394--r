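#' Assemble a PC/MC observational dataset
#'
#' Bundles the normalized record tables of one observation campaign into a
#' single validated object: the individual roster, agonistic conflicts with
#' their bystander rosters, 10-minute post-conflict (PC) and matched-control
#' (MC) focal follows with timed affiliative contacts and self-directed
#' behavior, and instantaneous scan samples.
#'
#' All tables are plain data frames. Times are seconds; `date` columns are ISO
#' `YYYY-MM-DD` strings; event times within a follow are latencies from follow
#' start at 1-second resolution.
#'
#' @param roster data frame with columns `id`, `code`, `sex` (`F`/`M`),
#'   `age_years`, `age_class` (`adult`/`adolescent`/`juvenile`/`infant`),
#'   `rearing` (`mother_reared`/`orphan`), `mother_id` (`NA` allowed),
#'   `group_id`.
#' @param conflicts data frame: `conflict_id`, `group_id`, `date`, `time_s`,
#'   `victim_id`, `aggressor_id`, `context`, `intensity` (1-6),
#'   `redirection_target` (`NA` allowed).
#' @param conflict_bystanders long table: `conflict_id`, `id`, `proximity`
#'   (`lt5m`/`5to10m`/`gt10m`).
#' @param follows data frame: `follow_id`, `conflict_id`, `kind` (`PC`/`MC`),
#'   `focal_id`, `date`, `start_s`, `duration_s`.
#' @param follow_bystanders long table: `follow_id`, `id`, `proximity`.
#' @param contacts long table: `follow_id`, `time_s`, `initiator_id`,
#'   `recipient_id`, `behavior`.
#' @param self_directed long table: `follow_id`, `time_s`, `kind`
#'   (`scratch_bout`/`groom_interval`), `duration_s` (0 for scratch bouts).
#' @param scans data frame: `scan_id`, `group_id`, `date`, `time_s`.
#' @param scan_presence long table: `scan_id`, `id`.
#' @param scan_engaged long table: `scan_id`, `id_a`, `id_b`, `behavior`.
#' @param validate run [validate_dataset()] before returning (default `TRUE`).
#'
#' @return An object of class `pcmc_dataset` (a named list of the ten tables).
#' @export
pcmc_dataset <- function(roster,
                         conflicts = NULL, conflict_bystanders = NULL,
                         follows = NULL, follow_bystanders = NULL,
                         contacts = NULL, self_directed = NULL,
                         scans = NULL, scan_presence = NULL,
                         scan_engaged = NULL,
                         validate = TRUE) {
  proto <- dataset_prototypes()
  d <- structure(list(
    roster = coerce_table(roster, proto$roster, "roster"),
    conflicts = coerce_table(conflicts, proto$conflicts, "conflicts"),
    conflict_bystanders = coerce_table(conflict_bystanders,
                                       proto$conflict_bystanders,
                                       "conflict_bystanders"),
    follows = coerce_table(follows, proto$follows, "follows"),
    follow_bystanders = coerce_table(follow_bystanders,
                                     proto$follow_bystanders,
                                     "follow_bystanders"),
    contacts = coerce_table(contacts, proto$contacts, "contacts"),
    self_directed = coerce_table(self_directed, proto$self_directed,
                                 "self_directed"),
    scans = coerce_table(scans, proto$scans, "scans"),
    scan_presence = coerce_table(scan_presence, proto$scan_presence,
                                 "scan_presence"),
    scan_engaged = coerce_table(scan_engaged, proto$scan_engaged,
                                "scan_engaged")
  ), class = "pcmc_dataset")
  d <- canonicalize_dataset(d)
  if (validate) validate_dataset(d)
  d
}

# Canonical row order makes datasets comparable and written files
# deterministic: load(write(d)) == d holds exactly.
canonicalize_dataset <- function(d) {
  ord <- list(
    roster = c("group_id", "id"),
    conflicts = "conflict_id",
    conflict_bystanders = c("conflict_id", "id"),
    follows = "follow_id",
    follow_bystanders = c("follow_id", "id"),
    contacts = c("follow_id", "time_s", "initiator_id", "recipient_id"),
    self_directed = c("follow_id", "time_s", "kind"),
    scans = "scan_id",
    scan_presence = c("scan_id", "id"),
    scan_engaged = c("scan_id", "id_a", "id_b"))
  for (tab in names(ord)) {
    x <- d[[tab]]
    if (nrow(x) > 1) {
      o <- do.call(order, unname(x[ord[[tab]]]))
      x <- x[o, , drop = FALSE]
      rownames(x) <- NULL
      d[[tab]] <- x
    }
  }
  d
}

dataset_prototypes <- function() {
  list(
    roster = c(id = "character", code = "character", sex = "character",
               age_years = "numeric", age_class = "character",
               rearing = "character", mother_id = "character",
               group_id = "character"),
    conflicts = c(conflict_id = "integer", group_id = "character",
                  date = "character", time_s = "numeric",
                  victim_id = "character", aggressor_id = "character",
                  context = "character", intensity = "integer",
                  redirection_target = "character"),
    conflict_bystanders = c(conflict_id = "integer", id = "character",
                            proximity = "character"),
    follows = c(follow_id = "integer", conflict_id = "integer",
                kind = "character", focal_id = "character",
                date = "character", start_s = "numeric",
                duration_s = "numeric"),
    follow_bystanders = c(follow_id = "integer", id = "character",
                          proximity = "character"),
    contacts = c(follow_id = "integer", time_s = "numeric",
                 initiator_id = "character", recipient_id = "character",
                 behavior = "character"),
    self_directed = c(follow_id = "integer", time_s = "numeric",
                      kind = "character", duration_s = "numeric"),
    scans = c(scan_id = "integer", group_id = "character",
              date = "character", time_s = "numeric"),
    scan_presence = c(scan_id = "integer", id = "character"),
    scan_engaged = c(scan_id = "integer", id_a = "character",
                     id_b = "character", behavior = "character")
  )
}

coerce_table <- function(x, proto, name) {
  if (is.null(x)) return(empty_df(proto))
  assert_that(is.data.frame(x), sprintf("`%s` must be a data frame", name))
  missing <- setdiff(names(proto), names(x))
  assert_that(length(missing) == 0,
              sprintf("`%s` is missing columns: %s", name,
                      paste(missing, collapse = ", ")),
              class = "pcmc_schema_error")
  x <- x[names(proto)]
  for (j in names(proto)) {
    x[[j]] <- switch(proto[[j]],
                     character = as.character(x[[j]]),
                     integer = as.integer(x[[j]]),
                     numeric = as.numeric(x[[j]]))
  }
  rownames(x) <- NULL
  x
}

#' @exportS3Method base::print
print.pcmc_dataset <- function(x, ...) {
  cat("<pcmc_dataset>\n")
  cat(sprintf("  %d individuals (%d non-infant) in %d group(s)\n",
              nrow(x$roster),
              sum(x$roster$age_class != "infant"),
              length(unique(x$roster$group_id))))
  npc <- sum(x$follows$kind == "PC")
  nmc <- sum(x$follows$kind == "MC")
  cat(sprintf("  %d conflicts; %d PC / %d MC follows; %d contacts\n",
              nrow(x$conflicts), npc, nmc, nrow(x$contacts)))
  cat(sprintf("  %d scans\n", nrow(x$scans)))
  invisible(x)
}

#' Validate the referential and domain integrity of a dataset
#'
#' Checks id uniqueness, controlled vocabularies, opponent distinctness,
#' bystander exclusion of opponents, redirection targets, event-time bounds,
#' the one-MC-per-PC rule, and mother links (a mother must be a female of the
#' same group). Violations raise classed errors (`pcmc_schema_error` for
#' vocabulary/domain violations, `pcmc_integrity_error` for dangling
#' references).
#'
#' @param d a [pcmc_dataset()].
#' @return `d`, invisibly.
#' @export
validate_dataset <- function(d) {
  r <- d$roster
  assert_that(!anyDuplicated(r$id), "roster ids must be unique",
              class = "pcmc_integrity_error")
  assert_that(all(r$sex %in% SEXES), "roster: bad sex code",
              class = "pcmc_schema_error")
  assert_that(all(r$age_class %in% AGE_CLASSES), "roster: bad age_class",
              class = "pcmc_schema_error")
  assert_that(all(r$rearing %in% REARING), "roster: bad rearing code",
              class = "pcmc_schema_error")
  assert_that(all(r$age_years >= 0, na.rm = TRUE),
              "roster: negative age", class = "pcmc_schema_error")
  has_mother <- !is.na(r$mother_id) & r$mother_id != ""
  if (any(has_mother)) {
    m <- match(r$mother_id[has_mother], r$id)
    assert_that(!anyNA(m), "roster: mother_id not in roster",
                class = "pcmc_integrity_error")
    assert_that(all(r$sex[m] == "F"),
                "roster: mother_id must refer to a female",
                class = "pcmc_integrity_error")
    assert_that(all(r$group_id[m] == r$group_id[has_mother]),
                "roster: mother must belong to the same group",
                class = "pcmc_integrity_error")
  }

  cf <- d$conflicts
  if (nrow(cf)) {
    assert_that(!anyDuplicated(cf$conflict_id),
                "conflict_id must be unique", class = "pcmc_integrity_error")
    assert_that(all(cf$victim_id %in% r$id) && all(cf$aggressor_id %in% r$id),
                "conflicts: opponent id not in roster",
                class = "pcmc_integrity_error")
    assert_that(all(cf$victim_id != cf$aggressor_id),
                "conflicts: victim and aggressor must differ",
                class = "pcmc_schema_error")
    assert_that(all(cf$intensity >= 1L & cf$intensity <= 6L),
                "conflicts: intensity must be in 1..6",
                class = "pcmc_schema_error")
    assert_that(all(cf$context %in% CONTEXTS), "conflicts: bad context",
                class = "pcmc_schema_error")
  }

  cb <- d$conflict_bystanders
  if (nrow(cb)) {
    assert_that(all(cb$conflict_id %in% cf$conflict_id),
                "conflict_bystanders: dangling conflict_id",
                class = "pcmc_integrity_error")
    assert_that(all(cb$id %in% r$id),
                "conflict_bystanders: id not in roster",
                class = "pcmc_integrity_error")
    assert_that(all(cb$proximity %in% PROXIMITY_BANDS),
                "conflict_bystanders: bad proximity band",
                class = "pcmc_schema_error")
    i <- match(cb$conflict_id, cf$conflict_id)
    assert_that(all(cb$id != cf$victim_id[i] & cb$id != cf$aggressor_id[i]),
                "conflict_bystanders: opponents cannot be bystanders",
                class = "pcmc_schema_error")
  }
  if (nrow(cf)) {
    has_red <- !is.na(cf$redirection_target)
    if (any(has_red)) {
      keys <- paste(cf$conflict_id[has_red], cf$redirection_target[has_red])
      assert_that(all(keys %in% paste(cb$conflict_id, cb$id)),
                  "conflicts: redirection target must be a bystander",
                  class = "pcmc_integrity_error")
    }
  }

  fl <- d$follows
  if (nrow(fl)) {
    assert_that(!anyDuplicated(fl$follow_id),
                "follow_id must be unique", class = "pcmc_integrity_error")
    assert_that(all(fl$kind %in% FOLLOW_KINDS), "follows: bad kind",
                class = "pcmc_schema_error")
    assert_that(all(fl$conflict_id %in% cf$conflict_id),
                "follows: dangling conflict_id",
                class = "pcmc_integrity_error")
    assert_that(all(fl$focal_id %in% r$id),
                "follows: focal not in roster",
                class = "pcmc_integrity_error")
    i <- match(fl$conflict_id, cf$conflict_id)
    assert_that(all(fl$focal_id == cf$victim_id[i]),
                "follows: focal must be the conflict victim",
                class = "pcmc_integrity_error")
    per <- table(fl$conflict_id, fl$kind)
    assert_that(all(per <= 1L),
                "follows: at most one PC and one MC per conflict",
                class = "pcmc_schema_error")
  }

  fb <- d$follow_bystanders
  if (nrow(fb)) {
    assert_that(all(fb$follow_id %in% fl$follow_id),
                "follow_bystanders: dangling follow_id",
                class = "pcmc_integrity_error")
    assert_that(all(fb$id %in% r$id),
                "follow_bystanders: id not in roster",
                class = "pcmc_integrity_error")
    assert_that(all(fb$proximity %in% PROXIMITY_BANDS),
                "follow_bystanders: bad proximity band",
                class = "pcmc_schema_error")
  }

  ct <- d$contacts
  if (nrow(ct)) {
    assert_that(all(ct$follow_id %in% fl$follow_id),
                "contacts: dangling follow_id",
                class = "pcmc_integrity_error")
    assert_that(all(ct$behavior %in% CONTACT_BEHAVIORS),
                "contacts: behavior outside the affiliative ethogram",
                class = "pcmc_schema_error")
    assert_that(all(ct$initiator_id != ct$recipient_id),
                "contacts: initiator must differ from recipient",
                class = "pcmc_schema_error")
    dur <- fl$duration_s[match(ct$follow_id, fl$follow_id)]
    assert_that(all(ct$time_s >= 0 & ct$time_s <= dur),
                "contacts: event time outside the follow window",
                class = "pcmc_schema_error")
  }

  sdb <- d$self_directed
  if (nrow(sdb)) {
    assert_that(all(sdb$follow_id %in% fl$follow_id),
                "self_directed: dangling follow_id",
                class = "pcmc_integrity_error")
    assert_that(all(sdb$kind %in% SELF_DIRECTED_KINDS),
                "self_directed: bad kind", class = "pcmc_schema_error")
    dur <- fl$duration_s[match(sdb$follow_id, fl$follow_id)]
    assert_that(all(sdb$time_s >= 0 & sdb$time_s <= dur),
                "self_directed: event time outside the follow window",
                class = "pcmc_schema_error")
    assert_that(all(sdb$duration_s >= 0),
                "self_directed: negative duration",
                class = "pcmc_schema_error")
  }

  sc <- d$scans
  if (nrow(sc)) {
    assert_that(!anyDuplicated(sc$scan_id), "scan_id must be unique",
                class = "pcmc_integrity_error")
  }
  sp <- d$scan_presence
  if (nrow(sp)) {
    assert_that(all(sp$scan_id %in% sc$scan_id),
                "scan_presence: dangling scan_id",
                class = "pcmc_integrity_error")
    assert_that(all(sp$id %in% r$id), "scan_presence: id not in roster",
                class = "pcmc_integrity_error")
  }
  se <- d$scan_engaged
  if (nrow(se)) {
    assert_that(all(se$scan_id %in% sc$scan_id),
                "scan_engaged: dangling scan_id",
                class = "pcmc_integrity_error")
    assert_that(all(se$behavior %in% SCAN_BEHAVIORS),
                "scan_engaged: bad behavior", class = "pcmc_schema_error")
    pres <- paste(sp$scan_id, sp$id)
    assert_that(all(paste(se$scan_id, se$id_a) %in% pres) &&
                  all(paste(se$scan_id, se$id_b) %in% pres),
                "scan_engaged: engaged pair must be present in the scan",
                class = "pcmc_integrity_error")
  }
  invisible(d)
}

#' The packaged study-colony roster
#'
#' Composition of the two semi-free bonobo study groups at the Lola ya Bonobo
#' sanctuary (Kinshasa, DRC): 36 named study subjects plus 6 dependent infants
#' carried by their mothers (Group 1: 21 subjects + 4 infants = 25 members;
#' Group 2: 15 subjects + 2 infants = 17). Age classes are adult, adolescent
#' and juvenile; individuals born at the sanctuary are `mother_reared` with
#' their mother's id recorded, all others arrived as orphans. Dependent-infant
#' ages are not individually documented and are coded as 1 year.
#'
#' @param include_infants keep dependent-infant rows (default `TRUE`; the
#'   analyses exclude infants via [non_infant_ids()]).
#' @return roster data frame (see [pcmc_dataset()] for the schema).
#' @export
lola_roster <- function(include_infants = TRUE) {
  path <- system.file("extdata", "lola_roster.csv", package = "pcmckit",
                      mustWork = TRUE)
  r <- read_roster_file(path)
  if (!include_infants) r <- r[r$age_class != "infant", , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Published summary counts of the original field study
#'
#' Reference totals reported for the field campaign the synthetic colony is
#' calibrated against: recorded conflicts, analyzed PC/MC pairs, the
#' distribution of post-conflict outcome types (consolation only,
#' reconciliation only, both, no affiliation), focal-victim count, observation
#' hours and scan counts per group. Shipped as a plain-text fixture so that
#' internal-consistency checks can be asserted against it.
#'
#' @return named numeric vector.
#' @export
published_counts <- function() {
  path <- system.file("extdata", "published_counts.csv", package = "pcmckit",
                      mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  setNames(as.numeric(tab$value), tab$quantity)
}

#' Ids of non-infant individuals
#'
#' The analyses exclude interactions involving dependent infants; this helper
#' returns the ids retained.
#'
#' @param roster roster data frame.
#' @return character vector of ids.
#' @export
non_infant_ids <- function(roster) {
  roster$id[roster$age_class != "infant"]
}

#' Mother-offspring kinship indicator for dyads
#'
#' Kinship in this colony is codable only as mother-offspring or none; returns
#' `TRUE` for dyads where either member is the recorded mother of the other.
#'
#' @param roster roster data frame.
#' @param id_a,id_b equal-length id vectors.
#' @return logical vector.
#' @export
is_kin <- function(roster, id_a, id_b) {
  mom <- setNames(roster$mother_id, roster$id)
  ma <- mom[id_a]
  mb <- mom[id_b]
  (!is.na(ma) & ma == id_b) | (!is.na(mb) & mb == id_a)
}
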