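# CSV dialect: four delimited files with header rows (roster.csv,
# conflicts.csv, follows.csv, scans.csv). Nested event lists are packed into
# string columns -- ";" separates records, "|" separates fields within a
# record, ":" binds an id to its proximity band. Ids therefore must not
# contain these separator characters (checked on write).

SEP_CHARS <- c(";", "|", ":")

pack_bystanders <- function(ids, bands) {
  if (length(ids) == 0) return("")
  paste(paste(ids, bands, sep = ":"), collapse = ";")
}

unpack_bystanders <- function(s) {
  out <- lapply(s, function(x) {
    if (is.na(x) || x == "") {
      return(data.frame(id = character(), proximity = character()))
    }
    parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(id = vapply(parts, `[`, "", 1L),
               proximity = vapply(parts, `[`, "", 2L))
  })
  out
}

pack_records <- function(df, cols) {
  if (nrow(df) == 0) return("")
  fields <- do.call(paste, c(unname(df[cols]), list(sep = "|")))
  paste(fields, collapse = ";")
}

unpack_records <- function(s, cols, types) {
  recs <- if (is.na(s) || s == "") character() else
    strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- strsplit(recs, "|", fixed = TRUE)
  out <- lapply(seq_along(cols), function(j) {
    v <- vapply(parts, `[`, "", j)
    if (types[j] == "numeric") as.numeric(v) else v
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Write a dataset to its four-file CSV layout
#'
#' Emits `roster.csv`, and -- when the corresponding tables are non-empty --
#' `conflicts.csv`, `follows.csv` and `scans.csv` under `dir`. Event lists are
#' packed into string columns (see the package README for the schemas); the
#' layout round-trips through [load_dataset()] exactly.
#'
#' @param d a validated [pcmc_dataset()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(d, dir) {
  validate_dataset(d)
  bad <- vapply(SEP_CHARS, function(ch) any(grepl(ch, d$roster$id, fixed = TRUE)),
                logical(1))
  assert_that(!any(bad), "ids may not contain ';', '|' or ':'",
              class = "pcmc_schema_error")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()

  w <- function(df, file) {
    p <- file.path(dir, file)
    write.csv(df, p, row.names = FALSE, quote = TRUE, na = "")
    p
  }

  paths <- c(paths, w(d$roster, "roster.csv"))

  if (nrow(d$conflicts)) {
    cf <- d$conflicts[order(d$conflicts$conflict_id), , drop = FALSE]
    cb <- d$conflict_bystanders
    cf$bystanders <- vapply(cf$conflict_id, function(cid) {
      b <- cb[cb$conflict_id == cid, , drop = FALSE]
      b <- b[order(b$id), , drop = FALSE]
      pack_bystanders(b$id, b$proximity)
    }, "")
    paths <- c(paths, w(cf, "conflicts.csv"))
  }

  if (nrow(d$follows)) {
    fl <- d$follows[order(d$follows$follow_id), , drop = FALSE]
    fb <- d$follow_bystanders
    ct <- d$contacts
    sdb <- d$self_directed
    fl$bystanders <- vapply(fl$follow_id, function(fid) {
      b <- fb[fb$follow_id == fid, , drop = FALSE]
      b <- b[order(b$id), , drop = FALSE]
      pack_bystanders(b$id, b$proximity)
    }, "")
    fl$contacts <- vapply(fl$follow_id, function(fid) {
      x <- ct[ct$follow_id == fid, , drop = FALSE]
      x <- x[order(x$time_s, x$initiator_id, x$recipient_id), , drop = FALSE]
      pack_records(x, c("time_s", "initiator_id", "recipient_id", "behavior"))
    }, "")
    fl$self_directed <- vapply(fl$follow_id, function(fid) {
      x <- sdb[sdb$follow_id == fid, , drop = FALSE]
      x <- x[order(x$time_s, x$kind), , drop = FALSE]
      pack_records(x, c("time_s", "kind", "duration_s"))
    }, "")
    paths <- c(paths, w(fl, "follows.csv"))
  }

  if (nrow(d$scans)) {
    sc <- d$scans[order(d$scans$scan_id), , drop = FALSE]
    sp <- d$scan_presence
    se <- d$scan_engaged
    sc$present <- vapply(sc$scan_id, function(sid) {
      paste(sort(sp$id[sp$scan_id == sid]), collapse = ";")
    }, "")
    sc$engaged <- vapply(sc$scan_id, function(sid) {
      x <- se[se$scan_id == sid, , drop = FALSE]
      x <- x[order(x$id_a, x$id_b), , drop = FALSE]
      pack_records(x, c("id_a", "id_b", "behavior"))
    }, "")
    paths <- c(paths, w(sc, "scans.csv"))
  }
  invisible(paths)
}

read_roster_file <- function(path) {
  r <- tryCatch(read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character"),
                error = function(e) pcmc_abort(
                  sprintf("cannot parse %s: %s", path, conditionMessage(e)),
                  "pcmc_parse_error"))
  r$age_years <- as.numeric(r$age_years)
  r$mother_id[!is.na(r$mother_id) & r$mother_id == ""] <- NA_character_
  coerce_table(r, dataset_prototypes()$roster, basename(path))
}

read_packed_csv <- function(path) {
  tryCatch(read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character"),
           error = function(e) pcmc_abort(
             sprintf("cannot parse %s: %s", path, conditionMessage(e)),
             "pcmc_parse_error"))
}

#' Load a dataset from its four-file CSV layout
#'
#' Reads the files written by [write_dataset()], unpacks the event-list
#' columns, validates schemas and referential integrity, and returns the
#' in-memory dataset. `conflicts.csv`, `follows.csv` and `scans.csv` may be
#' absent (an empty campaign loads without error); a follow referencing an
#' unknown conflict, or any other dangling id, raises a
#' `pcmc_integrity_error`.
#'
#' @param dir directory containing the files, or a named list/vector with
#'   entries `roster`, `conflicts`, `follows`, `scans` giving explicit paths.
#' @return a validated [pcmc_dataset()].
#' @export
load_dataset <- function(dir) {
  if (is.character(dir) && length(dir) == 1 && is.null(names(dir))) {
    paths <- list(roster = file.path(dir, "roster.csv"),
                  conflicts = file.path(dir, "conflicts.csv"),
                  follows = file.path(dir, "follows.csv"),
                  scans = file.path(dir, "scans.csv"))
  } else {
    paths <- as.list(dir)
  }
  assert_that(!is.null(paths$roster) && file.exists(paths$roster),
              "roster file not found", class = "pcmc_parse_error")
  roster <- read_roster_file(paths$roster)

  conflicts <- conflict_bystanders <- NULL
  if (!is.null(paths$conflicts) && file.exists(paths$conflicts)) {
    cf <- read_packed_csv(paths$conflicts)
    need <- c("conflict_id", "group_id", "date", "time_s", "victim_id",
              "aggressor_id", "context", "intensity",
              "redirection_target", "bystanders")
    missing <- setdiff(need, names(cf))
    assert_that(length(missing) == 0,
                sprintf("%s: missing columns %s", paths$conflicts,
                        paste(missing, collapse = ", ")),
                class = "pcmc_parse_error")
    if (nrow(cf)) {
      bl <- unpack_bystanders(cf$bystanders)
      nb <- vapply(bl, nrow, 0L)
      conflict_bystanders <- data.frame(
        conflict_id = rep(as.integer(cf$conflict_id), nb),
        id = unlist(lapply(bl, `[[`, "id"), use.names = FALSE) %||% character(),
        proximity = unlist(lapply(bl, `[[`, "proximity"),
                           use.names = FALSE) %||% character())
      cf$bystanders <- NULL
      cf$redirection_target[cf$redirection_target == ""] <- NA_character_
      conflicts <- cf
    }
  }

  follows <- follow_bystanders <- contacts <- self_directed <- NULL
  if (!is.null(paths$follows) && file.exists(paths$follows)) {
    fl <- read_packed_csv(paths$follows)
    if (nrow(fl)) {
      fid <- as.integer(fl$follow_id)
      bl <- unpack_bystanders(fl$bystanders)
      nb <- vapply(bl, nrow, 0L)
      follow_bystanders <- data.frame(
        follow_id = rep(fid, nb),
        id = unlist(lapply(bl, `[[`, "id"), use.names = FALSE) %||% character(),
        proximity = unlist(lapply(bl, `[[`, "proximity"),
                           use.names = FALSE) %||% character())
      ctl <- lapply(fl$contacts, unpack_records,
                    cols = c("time_s", "initiator_id", "recipient_id",
                             "behavior"),
                    types = c("numeric", "character", "character",
                              "character"))
      contacts <- cbind(follow_id = rep(fid, vapply(ctl, nrow, 0L)),
                        do.call(rbind, ctl))
      sdl <- lapply(fl$self_directed, unpack_records,
                    cols = c("time_s", "kind", "duration_s"),
                    types = c("numeric", "character", "numeric"))
      self_directed <- cbind(follow_id = rep(fid, vapply(sdl, nrow, 0L)),
                             do.call(rbind, sdl))
      fl$bystanders <- fl$contacts <- fl$self_directed <- NULL
      follows <- fl
    }
  }

  scans <- scan_presence <- scan_engaged <- NULL
  if (!is.null(paths$scans) && file.exists(paths$scans)) {
    sc <- read_packed_csv(paths$scans)
    if (nrow(sc)) {
      sid <- as.integer(sc$scan_id)
      pres <- strsplit(ifelse(is.na(sc$present), "", sc$present), ";",
                       fixed = TRUE)
      scan_presence <- data.frame(
        scan_id = rep(sid, lengths(pres)),
        id = unlist(pres, use.names = FALSE) %||% character())
      sel <- lapply(sc$engaged, unpack_records,
                    cols = c("id_a", "id_b", "behavior"),
                    types = c("character", "character", "character"))
      scan_engaged <- cbind(scan_id = rep(sid, vapply(sel, nrow, 0L)),
                            do.call(rbind, sel))
      sc$present <- sc$engaged <- NULL
      scans <- sc
    }
  }

  pcmc_dataset(roster, conflicts, conflict_bystanders, follows,
               follow_bystanders, contacts, self_directed,
               scans, scan_presence, scan_engaged)
}

#' Matching rules for MC validity
#'
#' The matched control must be conducted on the same victim on a later day
#' within `day_window`, at the same time of day within `time_tolerance_s`,
#' with both opponents present within 10 m of the focal at MC start, and with
#' the focal conflict-free for at least `min_gap_s` before MC start. The
#' printed protocol's "the following day (+/- 2 days)" is read as a day offset
#' of 1-2 days; override `day_window` to widen it.
#'
#' @param day_window integer vector `c(min, max)` of allowed day offsets.
#' @param time_tolerance_s allowed absolute clock-time difference (seconds).
#' @param presence_bands proximity bands counting as "within 10 m".
#' @param min_gap_s required conflict-free gap before MC start (seconds).
#' @param presence_scope `"any"` (default) or `"start"`: whether the
#'   bystander-presence eligibility used downstream refers to presence at any
#'   point of a follow or at its start (recorded here; presence is stored per
#'   follow).
#' @return a list of class `matching_rules`.
#' @export
matching_rules <- function(day_window = c(1L, 2L),
                           time_tolerance_s = 3600,
                           presence_bands = c("lt5m", "5to10m"),
                           min_gap_s = 600,
                           presence_scope = c("any", "start")) {
  structure(list(day_window = as.integer(day_window),
                 time_tolerance_s = time_tolerance_s,
                 presence_bands = presence_bands,
                 min_gap_s = min_gap_s,
                 presence_scope = match.arg(presence_scope)),
            class = "matching_rules")
}

#' Validate a candidate matched control against its conflict
#'
#' Applies the MC protocol: day offset within the window, time-of-day offset
#' within tolerance, both opponents within 10 m at MC start (the aggressor
#' must appear among the MC bystanders in a `<5m` or `5-10m` band; the victim
#' is the focal), and no conflict involving the focal within the preceding
#' `min_gap_s`. If the focal fought within that gap the verdict is
#' `"postpone"` (the MC is to be rescheduled at least 10 minutes after that
#' conflict ends), otherwise `"valid"` or `"invalid"` with a reason.
#'
#' @param conflict one-row data frame (or list) from the conflicts table.
#' @param pc the PC follow row for this conflict (list or one-row df).
#' @param mc_candidate the candidate MC follow (list or one-row df).
#' @param mc_bystanders data frame `id`, `proximity` of bystanders recorded
#'   for the candidate MC.
#' @param history conflicts table used to check the conflict-free gap.
#' @param rules a [matching_rules()] object.
#' @return list with `status` (`"valid"`, `"invalid"`, `"postpone"`) and
#'   `reason`.
#' @export
validate_matched_control <- function(conflict, pc, mc_candidate,
                                     mc_bystanders, history,
                                     rules = matching_rules()) {
  conflict <- as.list(conflict)
  pc <- as.list(pc)
  mc <- as.list(mc_candidate)
  assert_that(identical(mc$focal_id, conflict$victim_id),
              "MC candidate is for a different focal individual",
              class = "pcmc_contract_error")

  day_off <- as.integer(as.Date(mc$date) - as.Date(conflict$date))
  if (day_off < rules$day_window[1] || day_off > rules$day_window[2]) {
    return(list(status = "invalid", reason = "day_window"))
  }
  if (abs(mc$start_s - pc$start_s) > rules$time_tolerance_s) {
    return(list(status = "invalid", reason = "time_of_day"))
  }
  agg <- mc_bystanders[mc_bystanders$id == conflict$aggressor_id, ,
                       drop = FALSE]
  if (nrow(agg) == 0 || !any(agg$proximity %in% rules$presence_bands)) {
    return(list(status = "invalid", reason = "opponents_not_within_10m"))
  }
  if (nrow(history)) {
    h <- history[history$date == mc$date &
                   (history$victim_id == mc$focal_id |
                      history$aggressor_id == mc$focal_id), , drop = FALSE]
    recent <- h$time_s < mc$start_s & h$time_s >= mc$start_s - rules$min_gap_s
    if (any(recent)) {
      return(list(status = "postpone", reason = "recent_conflict"))
    }
  }
  list(status = "valid", reason = NA_character_)
}

#' PC/MC pair table of a dataset
#'
#' One row per conflict that has a PC follow, with the matching MC follow id
#' where one exists. Conflicts lacking a valid MC are flagged (`has_mc =
#' FALSE`) and excluded from all downstream labeling, mirroring the protocol
#' of excluding cases lacking matched controls.
#'
#' @param d a [pcmc_dataset()].
#' @return data frame: `conflict_id`, `pc_follow_id`, `mc_follow_id` (`NA` if
#'   none), `has_mc`, `victim_id`, `aggressor_id`, `group_id`.
#' @export
pair_table <- function(d) {
  fl <- d$follows
  pc <- fl[fl$kind == "PC", c("follow_id", "conflict_id")]
  mc <- fl[fl$kind == "MC", c("follow_id", "conflict_id")]
  i <- match(pc$conflict_id, mc$conflict_id)
  cf <- d$conflicts
  j <- match(pc$conflict_id, cf$conflict_id)
  data.frame(conflict_id = pc$conflict_id,
             pc_follow_id = pc$follow_id,
             mc_follow_id = mc$follow_id[i],
             has_mc = !is.na(i),
             victim_id = cf$victim_id[j],
             aggressor_id = cf$aggressor_id[j],
             group_id = cf$group_id[j])
}

#' Check every stored PC/MC pair against the matching rules
#'
#' @param d a [pcmc_dataset()].
#' @param rules a [matching_rules()] object.
#' @return data frame of per-pair verdicts (`conflict_id`, `status`,
#'   `reason`).
#' @export
check_matched_controls <- function(d, rules = matching_rules()) {
  pt <- pair_table(d)
  pt <- pt[pt$has_mc, , drop = FALSE]
  if (nrow(pt) == 0) {
    return(data.frame(conflict_id = integer(), status = character(),
                      reason = character()))
  }
  fl <- d$follows
  fb <- d$follow_bystanders
  out <- lapply(seq_len(nrow(pt)), function(k) {
    cid <- pt$conflict_id[k]
    conflict <- d$conflicts[d$conflicts$conflict_id == cid, ]
    pc <- fl[fl$follow_id == pt$pc_follow_id[k], ]
    mc <- fl[fl$follow_id == pt$mc_follow_id[k], ]
    mb <- fb[fb$follow_id == pt$mc_follow_id[k], c("id", "proximity")]
    v <- validate_matched_control(conflict, pc, mc, mb, d$conflicts, rules)
    data.frame(conflict_id = cid, status = v$status,
               reason = v$reason %||% NA_character_)
  })
  do.call(rbind, out)
}
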