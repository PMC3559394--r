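#' Specify a mixed model for occurrence or tendency responses
#'
#' @param response name of the response column (e.g. `consoled` for the
#'   binomial occurrence models, `tendency` or `index` for the Gaussian
#'   dyadic models).
#' @param fixed_effects character vector of main-effect column names (may be
#'   empty for the null model).
#' @param interactions character vector of `"a:b"` two-way terms; both main
#'   effects must be included.
#' @param random_effects nonempty character vector of grouping-factor
#'   columns fitted as random intercepts (the occurrence analyses use
#'   victim, aggressor and bystander identity, group, and the post-conflict
#'   interaction number, i.e. the conflict id).
#' @param family `"binomial_logit"` or `"gaussian_identity"`.
#' @return a list of class `model_spec`.
#' @export
model_spec <- function(response, fixed_effects = character(),
                       interactions = character(),
                       random_effects = c("victim_id", "aggressor_id",
                                          "bystander_id", "group_id",
                                          "conflict_id"),
                       family = c("binomial_logit", "gaussian_identity")) {
  family <- match.arg(family)
  assert_that(length(random_effects) >= 1,
              "at least one random effect is required",
              class = "pcmc_config_error")
  for (ia in interactions) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1]]
    assert_that(length(parts) == 2 && all(parts %in% fixed_effects),
                sprintf("interaction %s requires both main effects", ia),
                class = "pcmc_config_error")
  }
  structure(list(response = response, fixed_effects = fixed_effects,
                 interactions = interactions,
                 random_effects = random_effects, family = family),
            class = "model_spec")
}

spec_formula <- function(spec) {
  fe <- c("1", spec$fixed_effects, spec$interactions)
  re <- sprintf("(1 | %s)", spec$random_effects)
  as.formula(paste(spec$response, "~",
                   paste(c(fe, re), collapse = " + ")))
}

#' Fit a mixed model specification
#'
#' Binomial-logit models are fitted by maximum likelihood with lme4's
#' Laplace-type approximation ([lme4::glmer()]; `nAGQ = 0` uses the faster
#' PIRLS-only approximation employed during model enumeration); Gaussian
#' models by ML ([lme4::lmer()], `REML = FALSE`) so AIC values are
#' comparable across fixed-effect sets. Complete separation (an all-0 or
#' all-1 binary outcome) and rank-deficient fixed-effect matrices are
#' flagged before fitting; non-convergence is flagged on the returned fit
#' and such fits are excluded from selection.
#'
#' @param spec a [model_spec()].
#' @param table data frame holding all referenced columns.
#' @param nAGQ integration setting for binomial fits (0 or 1).
#' @return a list of class `pcmc_fit`: `spec`, `coefficients` (term,
#'   estimate, se, statistic, p), `log_likelihood`, `k` (estimated
#'   parameters), `aic` (\eqn{-2\ell + 2k}), `n_obs`, `converged`, `notes`,
#'   and `model` (the underlying merMod).
#' @export
fit_mixed <- function(spec, table, nAGQ = 1L) {
  need <- c(spec$response, spec$fixed_effects, spec$random_effects)
  missing <- setdiff(need, names(table))
  assert_that(length(missing) == 0,
              sprintf("table lacks columns: %s",
                      paste(missing, collapse = ", ")),
              class = "pcmc_contract_error")
  y <- table[[spec$response]]
  if (spec$family == "binomial_logit") {
    assert_that(all(y %in% c(0, 1)), "binomial outcome must be 0/1",
                class = "pcmc_contract_error")
    if (length(unique(y)) < 2) {
      return(structure(list(spec = spec, coefficients = NULL,
                            log_likelihood = NA_real_, k = NA_integer_,
                            aic = NA_real_, n_obs = nrow(table),
                            converged = FALSE,
                            notes = "complete separation: outcome constant",
                            model = NULL),
                       class = "pcmc_fit"))
    }
  }
  if (length(spec$fixed_effects)) {
    X <- stats::model.matrix(
      as.formula(paste("~", paste(c(spec$fixed_effects, spec$interactions),
                                  collapse = "+"))), table)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      aliased <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
      pcmc_abort(sprintf("rank-deficient fixed effects; aliased: %s",
                         paste(aliased, collapse = ", ")),
                 "pcmc_rank_error")
    }
  }
  fml <- spec_formula(spec)
  msgs <- character()
  fit <- withCallingHandlers(
    tryCatch({
      if (spec$family == "binomial_logit") {
        lme4::glmer(fml, data = table, family = binomial(link = "logit"),
                    nAGQ = nAGQ,
                    control = lme4::glmerControl(calc.derivs = FALSE))
      } else {
        lme4::lmer(fml, data = table, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE))
      }
    }, error = function(e) e),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  if (inherits(fit, "error")) {
    return(structure(list(spec = spec, coefficients = NULL,
                          log_likelihood = NA_real_, k = NA_integer_,
                          aic = NA_real_, n_obs = nrow(table),
                          converged = FALSE,
                          notes = conditionMessage(fit), model = NULL),
                     class = "pcmc_fit"))
  }
  conv_msgs <- c(msgs, unlist(fit@optinfo$conv$lme4$messages))
  converged <- !any(grepl("failed to converge|Model failed", conv_msgs))
  ll <- as.numeric(logLik(fit))
  k <- attr(logLik(fit), "df")
  sm <- summary(fit)$coefficients
  stat_col <- if (spec$family == "binomial_logit") "z value" else "t value"
  coefs <- data.frame(term = rownames(sm),
                      estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"],
                      statistic = sm[, stat_col],
                      row.names = NULL)
  if ("Pr(>|z|)" %in% colnames(sm)) coefs$p <- sm[, "Pr(>|z|)"]
  structure(list(spec = spec, coefficients = coefs,
                 log_likelihood = ll, k = k, aic = -2 * ll + 2 * k,
                 n_obs = stats::nobs(fit), converged = converged,
                 notes = if (length(conv_msgs))
                   paste(conv_msgs, collapse = "; ") else NA_character_,
                 model = fit),
            class = "pcmc_fit")
}

#' @exportS3Method base::print
print.pcmc_fit <- function(x, ...) {
  cat(sprintf("<pcmc_fit> %s (%s)\n", x$spec$response, x$spec$family))
  cat(sprintf("  fixed: %s\n",
              paste(c(x$spec$fixed_effects, x$spec$interactions),
                    collapse = " + ") %||% "1"))
  cat(sprintf("  logLik = %.2f, k = %d, AIC = %.2f, n = %d, converged = %s\n",
              x$log_likelihood, x$k, x$aic, x$n_obs, x$converged))
  if (!is.null(x$coefficients)) {
    print(x$coefficients, digits = 3)
  }
  invisible(x)
}
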