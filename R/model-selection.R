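#' Exhaustive AIC model selection over a predictor pool
#'
#' Fits all fixed-effect subsets of the candidate pool (plus any declared
#' two-way interactions whose main effects are present), ranks converged
#' fits by AIC (ties broken by fewer parameters), and compares the best
#' model against the null model (random effects only) with a
#' likelihood-ratio test. Numeric predictor pairs with absolute correlation
#' above `cor_threshold` are blocked from joint inclusion and reported.
#' For pools larger than `cap`, exhaustive enumeration is replaced by
#' forward-backward stepwise AIC search over the same constrained space.
#'
#' @param pool character vector of candidate main-effect columns.
#' @param table data frame of observations.
#' @param response response column name.
#' @param random_effects random-intercept grouping columns.
#' @param interactions candidate `"a:b"` terms.
#' @param family model family (see [model_spec()]).
#' @param cap maximum pool size for exhaustive enumeration.
#' @param cor_threshold collinearity screen on numeric predictors.
#' @param nAGQ integration setting used during enumeration (binomial).
#' @param refit_nAGQ setting used to refit the winning model for reporting.
#' @param method `"auto"` (exhaustive up to `cap`), `"exhaustive"` or
#'   `"stepwise"`.
#' @return a list of class `pcmc_selection`: `ranking` (data frame of every
#'   fitted spec with AIC, k, convergence), `best` and `null` ([fit_mixed()]
#'   objects), `lrt` (`chisq`, `df`, `p`), `blocked_pairs`, `method`.
#' @export
enumerate_and_select <- function(pool, table, response,
                                 random_effects = c("victim_id",
                                                    "aggressor_id",
                                                    "bystander_id",
                                                    "group_id",
                                                    "conflict_id"),
                                 interactions = character(),
                                 family = "binomial_logit",
                                 cap = 10L, cor_threshold = 0.7,
                                 nAGQ = 0L, refit_nAGQ = 1L,
                                 method = c("auto", "exhaustive",
                                            "stepwise")) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (length(pool) <= cap) "exhaustive" else "stepwise"
  }
  blocked <- blocked_pairs(pool, table, cor_threshold)
  spec_of <- function(fe) {
    ia <- interactions[vapply(interactions, function(x) {
      all(strsplit(x, ":", fixed = TRUE)[[1]] %in% fe)
    }, TRUE)]
    model_spec(response, fe, ia, random_effects, family)
  }
  allowed <- function(fe) {
    !any(vapply(blocked, function(bp) all(bp %in% fe), TRUE))
  }
  null_fit <- fit_mixed(model_spec(response, character(), character(),
                                   random_effects, family),
                        table, nAGQ = refit_nAGQ)
  fits <- list()

  if (method == "exhaustive") {
    assert_that(length(pool) <= 16,
                "pool too large for exhaustive enumeration",
                class = "pcmc_config_error")
    subsets <- list(character())
    for (p in pool) {
      subsets <- c(subsets, lapply(subsets, c, p))
    }
    subsets <- Filter(allowed, subsets)
    fits <- lapply(subsets, function(fe) {
      if (length(fe) == 0) null_fit else
        fit_mixed(spec_of(fe), table, nAGQ = nAGQ)
    })
  } else {
    current <- character()
    current_fit <- null_fit
    fits <- list(null_fit)
    repeat {
      moves <- c(lapply(setdiff(pool, current),
                        function(p) sort(c(current, p))),
                 lapply(current, function(p) sort(setdiff(current, p))))
      moves <- Filter(allowed, moves)
      moves <- moves[!vapply(moves, function(m)
        identical(m, sort(current)), TRUE)]
      if (length(moves) == 0) break
      cand <- lapply(moves, function(fe) {
        if (length(fe) == 0) null_fit else
          fit_mixed(spec_of(fe), table, nAGQ = nAGQ)
      })
      fits <- c(fits, cand)
      aics <- vapply(cand, function(f)
        if (isTRUE(f$converged)) f$aic else Inf, 0)
      best_aic <- if (isTRUE(current_fit$converged)) current_fit$aic else Inf
      if (min(aics) < best_aic - 1e-9) {
        j <- which.min(aics)
        current <- moves[[j]]
        current_fit <- cand[[j]]
      } else break
    }
  }

  ranking <- do.call(rbind, lapply(fits, function(f) {
    data.frame(fixed = paste(c(f$spec$fixed_effects, f$spec$interactions),
                             collapse = "+"),
               n_fixed = length(f$spec$fixed_effects) +
                 length(f$spec$interactions),
               k = f$k, log_likelihood = f$log_likelihood, aic = f$aic,
               converged = f$converged)
  }))
  ranking <- ranking[!duplicated(ranking$fixed), , drop = FALSE]
  ok <- ranking[ranking$converged & is.finite(ranking$aic), , drop = FALSE]
  assert_that(nrow(ok) > 0, "no model converged",
              class = "pcmc_fit_error")
  ok <- ok[order(ok$aic, ok$k), , drop = FALSE]
  ranking <- ranking[order(ranking$aic), , drop = FALSE]
  rownames(ranking) <- NULL
  best_fixed <- ok$fixed[1]
  best_fe <- if (best_fixed == "") character() else
    setdiff(strsplit(best_fixed, "+", fixed = TRUE)[[1]], interactions)
  best <- if (length(best_fe) == 0) null_fit else
    fit_mixed(spec_of(best_fe), table, nAGQ = refit_nAGQ)

  lrt <- list(chisq = NA_real_, df = NA_integer_, p = NA_real_)
  if (!is.null(best$model) && length(best_fe) > 0 &&
      isTRUE(null_fit$converged)) {
    chisq <- max(0, 2 * (best$log_likelihood - null_fit$log_likelihood))
    dfree <- best$k - null_fit$k
    lrt <- list(chisq = chisq, df = dfree,
                p = pchisq(chisq, dfree, lower.tail = FALSE))
  }
  structure(list(ranking = ranking, best = best, null = null_fit,
                 lrt = lrt, blocked_pairs = blocked, method = method),
            class = "pcmc_selection")
}

blocked_pairs <- function(pool, table, cor_threshold) {
  num <- pool[vapply(pool, function(p) is.numeric(table[[p]]), TRUE)]
  out <- list()
  if (length(num) >= 2) {
    cm <- suppressWarnings(stats::cor(table[num],
                                      use = "pairwise.complete.obs"))
    cm[is.na(cm)] <- 0
    hits <- which(abs(cm) > cor_threshold & upper.tri(cm), arr.ind = TRUE)
    out <- lapply(seq_len(nrow(hits)), function(i) {
      c(num[hits[i, 1]], num[hits[i, 2]])
    })
  }
  out
}

#' @exportS3Method base::print
print.pcmc_selection <- function(x, ...) {
  cat(sprintf("<pcmc_selection> %s search over %d fitted models\n",
              x$method, nrow(x$ranking)))
  cat(sprintf("  best: %s (AIC = %.2f)\n",
              ifelse(nchar(x$ranking$fixed[1]), x$ranking$fixed[1], "<null>"),
              x$ranking$aic[1]))
  if (is.finite(x$lrt$chisq %||% NA)) {
    cat(sprintf("  vs null: chisq = %.3f, df = %d, p = %.4g\n",
                x$lrt$chisq, x$lrt$df, x$lrt$p))
  }
  invisible(x)
}

#' Re-run the selection pipeline on a filtered opportunity table
#'
#' Reduced-model runs mirror the reporting convention of excluding a
#' bystander stratum: `"mother_reared_bystanders"` removes rows whose
#' bystander was mother-reared; `"juvenile_bystanders"` removes rows whose
#' bystander is a juvenile (the mature-individuals analysis).
#'
#' @param table opportunity table.
#' @param exclusion which stratum to drop.
#' @param pool,... forwarded to [enumerate_and_select()]; predictors made
#'   constant by the filter are dropped from the pool.
#' @return list: `selection` (a `pcmc_selection`), `n_before`, `n_after`,
#'   `n_bystanders_before`, `n_bystanders_after`.
#' @export
reduced_model_runs <- function(table, exclusion = c("mother_reared_bystanders",
                                                    "juvenile_bystanders"),
                               pool, ...) {
  exclusion <- match.arg(exclusion)
  keep <- if (exclusion == "mother_reared_bystanders") {
    table$bystander_mother_reared == 0
  } else {
    table$bystander_juvenile == 0
  }
  sub <- table[keep, , drop = FALSE]
  assert_that(nrow(sub) > 0, "exclusion filter emptied the table",
              class = "pcmc_contract_error")
  pool2 <- pool[vapply(pool, function(p) {
    length(unique(sub[[p]])) > 1
  }, TRUE)]
  list(selection = enumerate_and_select(pool2, sub, ...),
       n_before = nrow(table), n_after = nrow(sub),
       n_bystanders_before = length(unique(table$bystander_id)),
       n_bystanders_after = length(unique(sub$bystander_id)))
}

#' Gaussian mixed model for dyadic tendency responses
#'
#' Fits the dyadic TCT or consolation-index LMM (random intercepts for
#' victim, bystander and group) and computes simulation-based two-sided
#' p-values for each fixed effect by drawing `n_sim` coefficient vectors
#' from the normal approximation of the fitted coefficients' sampling
#' distribution (a seedable stand-in for posterior simulation).
#'
#' @param response response column (`tendency` or `index`).
#' @param table dyadic table containing response, predictors and grouping
#'   columns.
#' @param fixed_effects predictor columns.
#' @param random_effects grouping columns (default victim, bystander,
#'   group).
#' @param n_sim number of simulation draws (default 10000).
#' @param seed integer seed for the draws.
#' @return a [fit_mixed()] result augmented with `sim_p` (named vector) and
#'   `n_sim`. A zero-variance response returns the null fit with all slopes
#'   zero and a note.
#' @export
lmm_dyadic <- function(response, table, fixed_effects,
                       random_effects = c("victim_id", "bystander_id",
                                          "group_id"),
                       n_sim = 10000L, seed = 1L) {
  if (sd(table[[response]]) == 0) {
    fit <- structure(list(spec = model_spec(response, fixed_effects,
                                            character(), random_effects,
                                            "gaussian_identity"),
                          coefficients = data.frame(
                            term = c("(Intercept)", fixed_effects),
                            estimate = c(table[[response]][1],
                                         rep(0, length(fixed_effects))),
                            se = 0, statistic = NA_real_),
                          log_likelihood = NA_real_, k = NA_integer_,
                          aic = NA_real_, n_obs = nrow(table),
                          converged = TRUE,
                          notes = "zero-variance response; slopes are zero",
                          model = NULL),
                     class = "pcmc_fit")
    fit$sim_p <- setNames(rep(NA_real_, length(fixed_effects)),
                          fixed_effects)
    fit$n_sim <- 0L
    return(fit)
  }
  fit <- fit_mixed(model_spec(response, fixed_effects, character(),
                              random_effects, "gaussian_identity"),
                   table)
  assert_that(!is.null(fit$model), paste("LMM failed:", fit$notes),
              class = "pcmc_fit_error")
  set.seed(seed)
  beta <- lme4::fixef(fit$model)
  V <- as.matrix(vcov(fit$model))
  L <- chol(V)
  draws <- matrix(rnorm(n_sim * length(beta)), n_sim) %*% L
  draws <- sweep(draws, 2, beta, "+")
  colnames(draws) <- names(beta)
  sim_p <- apply(draws, 2, function(col) {
    pos <- sum(col > 0)
    2 * (min(pos, n_sim - pos) + 1) / (n_sim + 1)
  })
  fit$sim_p <- pmin(sim_p, 1)
  fit$n_sim <- n_sim
  fit
}
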