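#' Self-directed-behavior rates by post-conflict outcome category
#'
#' Computes per-follow self-scratch rates (bouts per minute) and self-groom
#' rates (seconds per minute), assigns each retained PC to an outcome
#' category -- consolation only, reconciliation only, both, or no affiliation
#' (occurrence meaning the corresponding pair label is attracted) -- and
#' compares per-focal mean rates across the three stress contrasts (MC vs PC
#' without affiliation, MC vs PC with consolation, PC without vs with
#' consolation) with paired Wilcoxon tests at the Bonferroni-corrected
#' threshold. PCs with reconciliation are excluded from the consolation /
#' no-affiliation categories to remove its confounding effect.
#'
#' @param d a validated [pcmc_dataset()].
#' @param cons_labels,rec_labels outputs of [label_dataset()] for modes
#'   `"consolation"` and `"reconciliation"` (recomputed if `NULL`).
#' @param measure `"scratch"` (bouts/min) or `"groom"` (s/min).
#' @return list: `follow_rates` (per follow), `focal_rates` (per focal x
#'   condition mean), `summary` (condition means over focals),
#'   `comparisons` (three paired Wilcoxon rows), `alpha` (corrected
#'   threshold), `pc_category_counts` (named counts of the four PC types).
#' @export
stress_rates <- function(d, cons_labels = NULL, rec_labels = NULL,
                         measure = c("scratch", "groom")) {
  measure <- match.arg(measure)
  cons_labels <- cons_labels %||% label_dataset(d, "consolation")
  rec_labels <- rec_labels %||% label_dataset(d, "reconciliation")
  pt <- pair_table(d)
  pt <- pt[pt$has_mc, , drop = FALSE]
  if (nrow(pt) == 0) {
    empty <- data.frame(focal_id = character(), condition = character(),
                        rate = numeric())
    return(list(follow_rates = empty, focal_rates = empty,
                summary = data.frame(condition = character(),
                                     mean_rate = numeric(),
                                     sd_rate = numeric()),
                comparisons = data.frame(), alpha = bonferroni_alpha(),
                pc_category_counts = c(PC_consolation = 0L,
                                       PC_reconciliation = 0L,
                                       PC_both = 0L,
                                       PC_no_affiliation = 0L),
                measure = measure))
  }

  rate_of <- function(follow_ids) {
    dur <- d$follows$duration_s[match(follow_ids, d$follows$follow_id)]
    sdb <- d$self_directed
    if (measure == "scratch") {
      ev <- sdb[sdb$kind == "scratch_bout", , drop = FALSE]
      cnt <- tapply(rep(1, nrow(ev)), ev$follow_id, sum)
      v <- as.numeric(cnt[as.character(follow_ids)])
    } else {
      ev <- sdb[sdb$kind == "groom_interval", , drop = FALSE]
      cnt <- tapply(ev$duration_s, ev$follow_id, sum)
      v <- as.numeric(cnt[as.character(follow_ids)])
    }
    v[is.na(v)] <- 0
    v / (dur / 60)
  }

  cons <- setNames(cons_labels$label == "attracted",
                   as.character(cons_labels$conflict_id))
  rec <- setNames(rec_labels$label == "attracted",
                  as.character(rec_labels$conflict_id))
  cid <- as.character(pt$conflict_id)
  has_c <- unname(cons[cid]); has_c[is.na(has_c)] <- FALSE
  has_r <- unname(rec[cid]); has_r[is.na(has_r)] <- FALSE
  pc_cat <- ifelse(has_c & has_r, "PC_both",
                   ifelse(has_c, "PC_consolation",
                          ifelse(has_r, "PC_reconciliation",
                                 "PC_no_affiliation")))
  pc_counts <- c(PC_consolation = sum(pc_cat == "PC_consolation"),
                 PC_reconciliation = sum(pc_cat == "PC_reconciliation"),
                 PC_both = sum(pc_cat == "PC_both"),
                 PC_no_affiliation = sum(pc_cat == "PC_no_affiliation"))

  follow_rates <- rbind(
    data.frame(focal_id = pt$victim_id, follow_id = pt$pc_follow_id,
               condition = pc_cat, rate = rate_of(pt$pc_follow_id)),
    data.frame(focal_id = pt$victim_id, follow_id = pt$mc_follow_id,
               condition = "MC", rate = rate_of(pt$mc_follow_id)))

  focal_rates <- aggregate(rate ~ focal_id + condition, follow_rates, mean)
  summary <- aggregate(rate ~ condition, focal_rates, mean)
  names(summary)[2] <- "mean_rate"
  summary$sd_rate <- aggregate(rate ~ condition, focal_rates,
                               sd)$rate

  alpha <- bonferroni_alpha(0.05, 3L)
  pairings <- list(c("MC", "PC_no_affiliation"),
                   c("MC", "PC_consolation"),
                   c("PC_no_affiliation", "PC_consolation"))
  comparisons <- do.call(rbind, lapply(pairings, function(pp) {
    wide <- merge(focal_rates[focal_rates$condition == pp[1],
                              c("focal_id", "rate")],
                  focal_rates[focal_rates$condition == pp[2],
                              c("focal_id", "rate")],
                  by = "focal_id")
    wt <- wilcoxon_paired(wide$rate.x, wide$rate.y)
    data.frame(condition_a = pp[1], condition_b = pp[2],
               n_focals = nrow(wide), z = wt$z, p = wt$p,
               significant = !is.na(wt$p) & wt$p < alpha)
  }))

  list(follow_rates = follow_rates, focal_rates = focal_rates,
       summary = summary, comparisons = comparisons, alpha = alpha,
       pc_category_counts = pc_counts, measure = measure)
}

#' Scratch rates in MCs with vs without received contact
#'
#' Control analysis: whether receiving affiliative contact per se (outside
#' any conflict context) reduces scratching. MC follows are split by whether
#' the focal received any contact; per-focal mean scratch rates are compared
#' with a paired Wilcoxon test over focals observed in both categories.
#'
#' @param d a validated [pcmc_dataset()].
#' @return list: `focal_rates` (focal x category means), `test` (a
#'   [wilcoxon_paired()] result; `defined = FALSE` when a category is
#'   absent), `n_focals`.
#' @export
mc_contact_control <- function(d) {
  fl <- d$follows
  mc <- fl[fl$kind == "MC", , drop = FALSE]
  if (nrow(mc) == 0) {
    return(list(focal_rates = data.frame(), n_focals = 0L,
                test = list(defined = FALSE)))
  }
  ct <- d$contacts
  focal_map <- setNames(mc$focal_id, as.character(mc$follow_id))
  received <- ct$follow_id %in% mc$follow_id &
    ct$recipient_id == unname(focal_map[as.character(ct$follow_id)])
  mc$contact <- ifelse(mc$follow_id %in% ct$follow_id[received],
                       "contact", "no_contact")
  sdb <- d$self_directed
  sb <- sdb[sdb$kind == "scratch_bout", , drop = FALSE]
  cnt <- tapply(rep(1, nrow(sb)), sb$follow_id, sum)
  mc$rate <- as.numeric(cnt[as.character(mc$follow_id)])
  mc$rate[is.na(mc$rate)] <- 0
  mc$rate <- mc$rate / (mc$duration_s / 60)
  focal_rates <- aggregate(rate ~ focal_id + contact, mc, mean)
  wide <- merge(focal_rates[focal_rates$contact == "contact",
                            c("focal_id", "rate")],
                focal_rates[focal_rates$contact == "no_contact",
                            c("focal_id", "rate")],
                by = "focal_id")
  test <- if (nrow(wide) >= 2) wilcoxon_paired(wide$rate.x, wide$rate.y)
          else list(w = NA_real_, z = NA_real_, p = NA_real_,
                    n_effective = nrow(wide), method = "undefined",
                    defined = FALSE)
  list(focal_rates = focal_rates, test = test, n_focals = nrow(wide))
}
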