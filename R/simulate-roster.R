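#' Simulate a colony roster from demographic cell counts
#'
#' Draws a roster with exactly the configured number of individuals per
#' (group x sex x age class x rearing) cell. Ages are sampled uniformly
#' within class-typical ranges (adult 12-20, adolescent 8-11, juvenile 3-7,
#' infant 0-2 years). Every mother-reared juvenile or infant is linked to an
#' adult female of the same group; each female can mother at most one
#' juvenile and one infant, so a cell request exceeding the number of adult
#' females in a group is a configuration error.
#'
#' @param config a [colony_config()].
#' @param seed integer seed; identical seeds yield identical rosters.
#' @return roster data frame (schema of [pcmc_dataset()]).
#' @export
simulate_roster <- function(config, seed = 1L) {
  set.seed(seed)
  rc <- config$roster_counts
  rc <- rc[rc$n > 0, , drop = FALSE]
  if (nrow(rc) == 0) {
    return(empty_df(dataset_prototypes()$roster))
  }
  rc <- rc[order(rc$group_id, rc$sex, rc$age_class, rc$rearing), ,
           drop = FALSE]
  age_range <- list(adult = c(12, 20), adolescent = c(8, 11),
                    juvenile = c(3, 7), infant = c(0, 2))
  rows <- lapply(seq_len(nrow(rc)), function(k) {
    n <- rc$n[k]
    cls <- rc$age_class[k]
    id <- sprintf("%s_%s_%s_%s_%02d", rc$group_id[k], rc$sex[k],
                  substr(cls, 1, 3), substr(rc$rearing[k], 1, 3),
                  seq_len(n))
    data.frame(id = id, code = id, sex = rc$sex[k],
               age_years = floor(runif(n, age_range[[cls]][1],
                                       age_range[[cls]][2] + 1)),
               age_class = cls, rearing = rc$rearing[k],
               mother_id = NA_character_, group_id = rc$group_id[k])
  })
  roster <- do.call(rbind, rows)

  for (g in unique(roster$group_id)) {
    in_g <- roster$group_id == g
    mothers <- roster$id[in_g & roster$sex == "F" &
                           roster$age_class == "adult"]
    for (cls in c("juvenile", "infant")) {
      kids <- which(in_g & roster$age_class == cls &
                      roster$rearing == "mother_reared")
      assert_that(length(kids) <= length(mothers),
                  sprintf(paste0("group %s: %d mother-reared %ss requested",
                                 " but only %d adult females available"),
                          g, length(kids), cls, length(mothers)),
                  class = "pcmc_config_error")
      if (length(kids)) {
        roster$mother_id[kids] <- sample(mothers, length(kids))
      }
    }
  }
  rownames(roster) <- NULL
  roster
}

#' Simulate a latent dyadic affinity matrix
#'
#' Within-group dyads receive an affinity in (0,1) drawn from a Beta
#' distribution whose mean is `mean_affinity` on the logit scale, shifted up
#' by `kin_boost` logits for mother-offspring dyads. The matrix is symmetric;
#' cross-group dyads and the diagonal are `NA`. The affinity of a dyad is, by
#' construction, the probability that the dyad is engaged in an affiliative
#' scan behavior when both members are visible in a scan.
#'
#' @param roster roster data frame.
#' @param kin_boost logit-scale affinity increment for kin dyads (>= 0 makes
#'   mean kin affinity exceed mean non-kin affinity by construction).
#' @param concentration Beta concentration (larger = less dyadic spread).
#' @param mean_affinity baseline mean affinity of non-kin dyads.
#' @param seed integer seed.
#' @return symmetric numeric matrix with id dimnames.
#' @export
simulate_affiliation <- function(roster, kin_boost = 1.5, concentration = 8,
                                 mean_affinity = 0.12, seed = 1L) {
  assert_that(nrow(roster) > 0, "roster must be nonempty",
              class = "pcmc_config_error")
  set.seed(seed)
  ids <- roster$id
  n <- length(ids)
  A <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  grp <- roster$group_id
  idx <- which(upper.tri(A), arr.ind = TRUE)
  same <- grp[idx[, 1]] == grp[idx[, 2]]
  idx <- idx[same, , drop = FALSE]
  if (nrow(idx)) {
    kin <- is_kin(roster, ids[idx[, 1]], ids[idx[, 2]])
    mu <- plogis(qlogis(mean_affinity) + kin_boost * kin)
    a <- stats::rbeta(nrow(idx), mu * concentration,
                      (1 - mu) * concentration)
    a <- pmin(pmax(a, 1e-4), 1 - 1e-4)
    A[idx] <- a
    A[idx[, c(2, 1), drop = FALSE]] <- a
  }
  A
}
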