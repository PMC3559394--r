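#' Dyadic affiliation indices from scan samples
#'
#' For every dyad co-present in at least one scan: the number of scans in
#' which the dyad was engaged in any of the five affiliative scan behaviors
#' (grooming, contact sitting, sitting within arm's reach, play, sexual
#' contact), divided by the number of scans in which both were visible. A
#' scan counts at most once toward engagement regardless of how many
#' behaviors the dyad shows in it (`combine = "or"`, the default); with
#' `combine = "sum"` engagements are summed per scan instead, so the index
#' can exceed 1.
#'
#' @param d a [pcmc_dataset()] with scan tables (or a list with
#'   `scan_presence`/`scan_engaged`).
#' @param combine `"or"` (scan-level any-behavior, default) or `"sum"`.
#' @return data frame `id_a`, `id_b` (unordered, `id_a < id_b`),
#'   `engaged_scans`, `copresent_scans`, `index`; dyads never co-present are
#'   omitted.
#' @export
affiliation_matrix <- function(d, combine = c("or", "sum")) {
  combine <- match.arg(combine)
  sp <- d$scan_presence
  se <- d$scan_engaged
  assert_that(nrow(sp) > 0, "no scan samples in dataset",
              class = "pcmc_contract_error")
  ids <- sort(unique(sp$id))
  scan_ids <- sort(unique(sp$scan_id))
  M <- matrix(0L, length(scan_ids), length(ids),
              dimnames = list(NULL, ids))
  M[cbind(match(sp$scan_id, scan_ids), match(sp$id, ids))] <- 1L
  CP <- crossprod(M)
  ut <- which(upper.tri(CP) & CP > 0, arr.ind = TRUE)
  if (nrow(ut) == 0) {
    return(data.frame(id_a = character(), id_b = character(),
                      engaged_scans = integer(), copresent_scans = integer(),
                      index = numeric()))
  }
  keys <- dyad_key(ids[ut[, 1]], ids[ut[, 2]])
  o <- order(keys)
  keys <- keys[o]
  copresent <- CP[ut][o]
  eng <- setNames(rep(0L, length(keys)), keys)
  if (nrow(se)) {
    k <- dyad_key(se$id_a, se$id_b)
    if (combine == "or") {
      u <- unique(data.frame(scan_id = se$scan_id, k = k))
      tt <- table(u$k)
    } else {
      tt <- table(k)
    }
    tt <- tt[names(tt) %in% keys]
    eng[names(tt)] <- as.integer(tt)
  }
  dd <- dyad_split(keys)
  data.frame(id_a = dd$id_a, id_b = dd$id_b,
             engaged_scans = unname(eng),
             copresent_scans = as.integer(copresent),
             index = unname(eng) / as.numeric(copresent))
}

#' Log-transform affiliation indices
#'
#' `log(index + epsilon)`: the transform applied to affiliation measures so
#' that they approximate normality; `epsilon` keeps zero indices finite and
#' defaults to half the smallest positive index observed.
#'
#' @param index numeric vector of nonnegative indices.
#' @param epsilon positive offset; `NULL` (default) uses half the smallest
#'   positive value of `index` (1e-3 if all are zero).
#' @return numeric vector; the transform is monotone in `index`.
#' @export
log_transform <- function(index, epsilon = NULL) {
  assert_that(all(index >= 0, na.rm = TRUE), "indices must be nonnegative",
              class = "pcmc_contract_error")
  if (is.null(epsilon)) {
    pos <- index[index > 0 & !is.na(index)]
    epsilon <- if (length(pos)) min(pos) / 2 else 1e-3
  }
  assert_that(epsilon > 0, "epsilon must be positive",
              class = "pcmc_config_error")
  log(index + epsilon)
}

affil_lookup <- function(affil) {
  setNames(affil$index, dyad_key(affil$id_a, affil$id_b))
}

#' Assemble the bystander-opportunity covariate table
#'
#' One row per (retained conflict x eligible bystander), where eligibility
#' requires presence in both the PC and the MC. The binary outcome
#' `consoled` is 1 when that bystander's specific pair label is attracted.
#' Covariates are populated from the roster (bystander and victim age class,
#' sex, rearing), the conflict record (proximity band, context, intensity,
#' redirection), the pair labels (reconciliation occurrence), kinship coding
#' (mother-offspring or none) and log-transformed dyadic affiliation indices
#' (bystander-victim, bystander-aggressor, victim-aggressor). Dyads lacking
#' scan data get the epsilon floor and are flagged.
#'
#' @param d a validated [pcmc_dataset()].
#' @param labels per-bystander labels from
#'   `label_dataset(d, "per_bystander")` (recomputed if `NULL`).
#' @param affil affiliation table from [affiliation_matrix()] (recomputed
#'   from the dataset's scans if `NULL`).
#' @param epsilon zero offset for [log_transform()]; `NULL` = data-driven.
#' @return data frame, one row per opportunity.
#' @export
build_opportunity_table <- function(d, labels = NULL, affil = NULL,
                                    epsilon = NULL) {
  labels <- labels %||% label_dataset(d, "per_bystander")
  if (nrow(labels) == 0) {
    return(data.frame())
  }
  affil <- affil %||% affiliation_matrix(d)
  rec <- label_dataset(d, "reconciliation")
  rec_by_cid <- setNames(rec$label == "attracted",
                         as.character(rec$conflict_id))
  r <- d$roster
  look <- function(col) setNames(r[[col]], r$id)
  cls <- look("age_class"); sx <- look("sex"); rr <- look("rearing")

  aff <- affil_lookup(affil)
  if (is.null(epsilon)) {
    pos <- aff[aff > 0 & !is.na(aff)]
    epsilon <- if (length(pos)) min(pos) / 2 else 1e-3
  }
  aff_of <- function(x, y) {
    v <- aff[dyad_key(x, y)]
    flag <- is.na(v)
    v[flag] <- 0
    list(log = log(v + epsilon), flag = flag)
  }

  cf <- d$conflicts
  ci <- match(labels$conflict_id, cf$conflict_id)
  cb_key <- paste(d$conflict_bystanders$conflict_id,
                  d$conflict_bystanders$id)
  prox <- d$conflict_bystanders$proximity[
    match(paste(labels$conflict_id, labels$bystander_id), cb_key)]
  # eligible bystanders were present in the PC, whose roster equals the
  # conflict's; a missing band can only arise from hand-built data
  prox[is.na(prox)] <- "gt10m"

  bv <- aff_of(labels$bystander_id, labels$victim_id)
  ba <- aff_of(labels$bystander_id, labels$aggressor_id)
  va <- aff_of(labels$victim_id, labels$aggressor_id)

  out <- data.frame(
    conflict_id = labels$conflict_id,
    group_id = labels$group_id,
    victim_id = labels$victim_id,
    aggressor_id = labels$aggressor_id,
    bystander_id = labels$bystander_id,
    consoled = as.integer(labels$label == "attracted"),
    proximity = prox,
    proximity_num = match(prox, PROXIMITY_BANDS) - 1L,
    bystander_sex = unname(sx[labels$bystander_id]),
    bystander_age_class = unname(cls[labels$bystander_id]),
    bystander_juvenile = as.integer(cls[labels$bystander_id] == "juvenile"),
    bystander_adolescent =
      as.integer(cls[labels$bystander_id] == "adolescent"),
    bystander_mother_reared =
      as.integer(rr[labels$bystander_id] == "mother_reared"),
    victim_sex = unname(sx[labels$victim_id]),
    victim_age_class = unname(cls[labels$victim_id]),
    victim_juvenile = as.integer(cls[labels$victim_id] == "juvenile"),
    victim_adolescent = as.integer(cls[labels$victim_id] == "adolescent"),
    victim_mother_reared =
      as.integer(rr[labels$victim_id] == "mother_reared"),
    kin_bystander_victim =
      as.integer(is_kin(r, labels$bystander_id, labels$victim_id)),
    kin_bystander_aggressor =
      as.integer(is_kin(r, labels$bystander_id, labels$aggressor_id)),
    log_affil_bv = unname(bv$log),
    log_affil_ba = unname(ba$log),
    log_affil_va = unname(va$log),
    affil_floor_flag = unname(bv$flag | ba$flag | va$flag),
    context_feed = as.integer(cf$context[ci] == "feed"),
    intensity = cf$intensity[ci],
    reconciliation_occurred = as.integer(
      !is.na(rec_by_cid[as.character(labels$conflict_id)]) &
        rec_by_cid[as.character(labels$conflict_id)]),
    redirection_occurred = as.integer(!is.na(cf$redirection_target[ci])))
  rownames(out) <- NULL
  out
}
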