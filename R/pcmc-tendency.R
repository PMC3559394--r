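#' Contact tendency scores from labeled pairs
#'
#' Applies the tendency formula `100 * (attracted - dispersed) / n_pairs`
#' within groups of labeled pairs. Grouped by victim over any-bystander
#' consolation labels this is the per-victim Triadic Contact Tendency (TCT);
#' over reconciliation labels, the Conciliatory Contact Tendency (CCT);
#' grouped by (victim, bystander) over per-bystander labels it is the dyadic
#' TCT the relationship LMMs consume. Groups with zero pairs are omitted
#' with a warning.
#'
#' @param labels output of [label_dataset()].
#' @param by character vector of grouping columns (default `"victim_id"`;
#'   use `c("victim_id", "bystander_id")` for dyadic scores).
#' @return data frame with the grouping columns, `n_attracted`,
#'   `n_dispersed`, `n_neutral`, `n_pairs`, `tendency` (percent in
#'   \eqn{[-100, 100]}), `prop_attracted`, `prop_dispersed`.
#' @export
tendency_scores <- function(labels, by = "victim_id") {
  if (nrow(labels) == 0) {
    warning("no labeled pairs; returning empty tendency table")
    out <- data.frame(matrix(character(), 0, length(by),
                             dimnames = list(NULL, by)))
    out$n_attracted <- out$n_dispersed <- out$n_neutral <- integer()
    out$n_pairs <- integer()
    out$tendency <- out$prop_attracted <- out$prop_dispersed <- numeric()
    return(out)
  }
  key <- interaction(labels[by], drop = TRUE, lex.order = TRUE)
  agg <- function(lbl) {
    as.vector(tapply(labels$label == lbl, key, sum))
  }
  grp <- unique(labels[by])
  grp <- grp[order(interaction(grp, drop = TRUE, lex.order = TRUE)), ,
             drop = FALSE]
  out <- grp
  out$n_attracted <- agg("attracted")
  out$n_dispersed <- agg("dispersed")
  out$n_neutral <- agg("neutral")
  out$n_pairs <- out$n_attracted + out$n_dispersed + out$n_neutral
  out$tendency <- 100 * (out$n_attracted - out$n_dispersed) / out$n_pairs
  out$prop_attracted <- out$n_attracted / out$n_pairs
  out$prop_dispersed <- out$n_dispersed / out$n_pairs
  rownames(out) <- NULL
  out
}

#' Per-dyad consolation index
#'
#' For every (victim, bystander) dyad: the number of retained PCs in which
#' the bystander was the first individual to provide consolatory contact to
#' the victim (globally first bystander-initiated contact in that PC),
#' divided by the bystander's opportunities -- retained conflicts of that
#' victim in which the bystander was present in both the PC and the MC.
#' Dyads with zero opportunities are omitted.
#'
#' @param d a validated [pcmc_dataset()].
#' @param per_bystander_labels optional precomputed
#'   `label_dataset(d, "per_bystander")` (recomputed if `NULL`).
#' @return data frame `victim_id`, `bystander_id`, `n_first`,
#'   `n_opportunities`, `index` in \eqn{[0, 1]}.
#' @export
consolation_index <- function(d, per_bystander_labels = NULL) {
  lab <- per_bystander_labels %||% label_dataset(d, "per_bystander")
  if (nrow(lab) == 0) {
    return(data.frame(victim_id = character(), bystander_id = character(),
                      n_first = integer(), n_opportunities = integer(),
                      index = numeric()))
  }
  pt <- pair_table(d)
  pt <- pt[pt$has_mc, , drop = FALSE]
  sel <- relationship_selector("consolation_any_bystander")
  ct_by_follow <- split(d$contacts, d$contacts$follow_id)
  first_consoler <- setNames(rep(NA_character_, nrow(pt)),
                             as.character(pt$conflict_id))
  for (k in seq_len(nrow(pt))) {
    ct <- ct_by_follow[[as.character(pt$pc_follow_id[k])]]
    if (is.null(ct) || nrow(ct) == 0) next
    q <- ct$recipient_id == pt$victim_id[k] &
      ct$initiator_id != pt$victim_id[k] &
      ct$initiator_id != pt$aggressor_id[k]
    if (!any(q)) next
    qt <- ct[q, , drop = FALSE]
    first_consoler[k] <- qt$initiator_id[which.min(qt$time_s)]
  }
  lab$first <- !is.na(first_consoler[as.character(lab$conflict_id)]) &
    first_consoler[as.character(lab$conflict_id)] == lab$bystander_id
  key <- paste(lab$victim_id, lab$bystander_id, sep = "\r")
  n_opp <- tapply(rep(1L, nrow(lab)), key, sum)
  n_first <- tapply(lab$first, key, sum)
  ks <- sort(names(n_opp))
  parts <- strsplit(ks, "\r", fixed = TRUE)
  data.frame(victim_id = vapply(parts, `[`, "", 1L),
             bystander_id = vapply(parts, `[`, "", 2L),
             n_first = as.integer(n_first[ks]),
             n_opportunities = as.integer(n_opp[ks]),
             index = as.numeric(n_first[ks] / n_opp[ks]))
}
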