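#' Log-rank (Mantel-Cox) comparison of PC and MC first-contact latencies
#'
#' Compares the censored first-contact latency distributions of the PC and MC
#' arms with the standard log-rank statistic (via [survival::survdiff()]);
#' follows with no qualifying contact are right-censored at follow end.
#' Kaplan-Meier survival curves for both arms are returned for plotting the
#' first-minute peak.
#'
#' @param pc_latencies,mc_latencies numeric vectors of latencies in seconds,
#'   `Inf` (or values beyond `horizon`) meaning censored.
#' @param horizon censoring horizon in seconds (follow duration).
#' @return list: `chisq`, `df` (1), `p`, `n`, `fit` (the
#'   [survival::survfit()] object), `defined` (`FALSE` when both arms are
#'   fully censored).
#' @export
logrank_compare <- function(pc_latencies, mc_latencies,
                            horizon = FOLLOW_DURATION_S) {
  assert_that(length(pc_latencies) > 0 && length(mc_latencies) > 0,
              "both arms must be nonempty", class = "pcmc_contract_error")
  time <- c(pmin(pc_latencies, horizon), pmin(mc_latencies, horizon))
  event <- c(pc_latencies <= horizon, mc_latencies <= horizon) * 1L
  arm <- factor(rep(c("PC", "MC"), c(length(pc_latencies),
                                     length(mc_latencies))),
                levels = c("PC", "MC"))
  df <- data.frame(time = time, event = event, arm = arm)
  fit <- survival::survfit(survival::Surv(time, event) ~ arm, data = df)
  if (sum(event) == 0) {
    return(list(chisq = NA_real_, df = 1L, p = NA_real_, n = nrow(df),
                fit = fit, defined = FALSE))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = df)
  list(chisq = unname(sd$chisq), df = 1L,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = nrow(df), fit = fit, defined = TRUE)
}

#' First-contact latency samples of all retained pairs
#'
#' Extracts the paired PC and MC first-contact latencies (censored at follow
#' end) for a selector mode, one observation per follow.
#'
#' @param d a validated [pcmc_dataset()].
#' @param mode `"consolation"` or `"reconciliation"`.
#' @return list with `pc` and `mc` numeric vectors (`Inf` = censored) and
#'   `n_pairs`.
#' @export
latency_samples <- function(d, mode = c("consolation", "reconciliation")) {
  mode <- match.arg(mode)
  lab <- label_dataset(d, mode)
  list(pc = lab$pc_latency, mc = lab$mc_latency, n_pairs = nrow(lab))
}
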