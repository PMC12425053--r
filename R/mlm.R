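# Multilevel analysis of diary-memory outcomes.
#
# The modelling convention follows the study design: observations (events or
# days) are nested in participants; models carry a participant random
# intercept and, where requested, participant random slopes for continuous
# predictors. A requested random-slope structure that produces a singular or
# non-converged fit is refitted with the random intercept only, and the
# fallback is recorded -- the refit happens at most once.
#
# Estimation is REML (ML for likelihood-ratio comparisons) via lme4/lmerTest;
# inference for contrasts and simple slopes uses Satterthwaite denominator
# degrees of freedom, the convention of the lmerTest/emmeans stack.

SINGULAR_TOL <- 1e-6  # a variance component below tol * residual variance is "at boundary"

#' Fit a participant-level mixed model
#'
#' Fits `formula` (fixed effects only, e.g.
#' `vividness ~ regularity * rss + res`) with participant random effects.
#' Under `random = "intercept_and_slopes"` the model carries a random
#' intercept plus random slopes for the continuous predictors (all of them by
#' default, or the subset in `slope_terms`). If that fit is singular -- any
#' random-effect variance essentially at the zero boundary -- or fails to
#' converge, the model is refitted with the random intercept only and
#' `fallback_applied` is flagged. `random = "none"` fits ordinary least
#' squares, for designs without repeated measures.
#'
#' Rows with non-finite values in any model variable (for example events
#' carrying the infinite-similarity RES sentinel) are excluded listwise and
#' the count is reported.
#'
#' @param formula fixed-effects formula.
#' @param data data.frame containing the outcome, predictors and `group`.
#' @param group grouping variable name (default `"participant_id"`).
#' @param random requested random-effects structure.
#' @param slope_terms continuous predictors given random slopes under
#'   `"intercept_and_slopes"`; defaults to every numeric predictor in the
#'   formula.
#' @param reml fit by REML (default) or ML.
#' @param center if `TRUE`, mean-center the numeric predictors before fitting
#'   (slopes are unchanged; intercept and factor-level effects are then
#'   evaluated at covariate means).
#' @return An object of class `novelty_lmm` with components `fit` (the
#'   underlying `lmerModLmerTest` or `lm` fit), `coefficients` (fixed effects
#'   with SE, Satterthwaite df, 95% CI and p), `varcor`, and `fit_log` with
#'   flags `singular_fit`, `converged`, `fallback_applied`.
#' @export
fit_mixed <- function(formula, data,
                      group = "participant_id",
                      random = c("intercept_and_slopes", "intercept_only", "none"),
                      slope_terms = NULL, reml = TRUE, center = FALSE) {
  random <- match.arg(random)
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  outcome <- all.vars(formula[[2]])
  rhs_vars <- all.vars(formula[[3]])
  need <- unique(c(outcome, rhs_vars, if (random != "none") group))
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    nd_spec_error("variable(s) not found in data: %s", paste(missing, collapse = ", "))
  }
  df <- data[, need, drop = FALSE]

  # logical predictors enter as 0/1, factors as factors
  for (v in rhs_vars) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])

  num_cols <- vapply(df[need], is.numeric, logical(1))
  keep <- rep(TRUE, nrow(df))
  for (v in need[num_cols]) keep <- keep & is.finite(df[[v]])
  keep <- keep & !Reduce(`|`, lapply(df[need], is.na))
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(sprintf("fit_mixed: excluded %d row(s) with missing or non-finite model variables",
                    n_dropped))
  }
  df <- df[keep, , drop = FALSE]
  if (random != "none") {
    df[[group]] <- factor(df[[group]])
    if (nlevels(df[[group]]) < 2L) {
      nd_spec_error("mixed model needs >= 2 groups in '%s'", group)
    }
  }

  if (center) {
    for (v in setdiff(rhs_vars, group)) {
      if (is.numeric(df[[v]]) && !is.logical(df[[v]])) {
        df[[v]] <- df[[v]] - mean(df[[v]])
      }
    }
  }

  # rank check on the fixed design, naming aliased columns
  mm <- stats::model.matrix(formula, df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    nd_spec_error("fixed-effects design is rank deficient; aliased term(s): %s",
                  paste(aliased, collapse = ", "))
  }

  if (random == "none") {
    fit <- stats::lm(formula, data = df)
    out <- new_novelty_lmm(fit, formula, group = NULL, random_requested = random,
                           random_final = "none", data = df,
                           fit_log = list(singular_fit = FALSE, converged = TRUE,
                                          fallback_applied = FALSE),
                           n_dropped = n_dropped)
    return(out)
  }

  if (is.null(slope_terms)) {
    slope_terms <- rhs_vars[vapply(rhs_vars, function(v)
      is.numeric(df[[v]]) && !is.logical(df[[v]]), logical(1))]
  }
  re_term <- if (random == "intercept_and_slopes" && length(slope_terms) > 0L) {
    sprintf("(1 + %s | %s)", paste(slope_terms, collapse = " + "), group)
  } else {
    sprintf("(1 | %s)", group)
  }
  requested_structure <- if (grepl("\\+", re_term) || random == "intercept_and_slopes")
    random else "intercept_only"

  full_formula <- stats::as.formula(
    paste(deparse(formula[[2]]), "~", paste(deparse(formula[[3]], width.cutoff = 500), collapse = ""),
          "+", re_term))

  fitted <- fit_lmer_checked(full_formula, df, reml)
  fallback <- FALSE
  if (random == "intercept_and_slopes" && (fitted$singular || !fitted$converged)) {
    fb_formula <- stats::as.formula(
      paste(deparse(formula[[2]]), "~", paste(deparse(formula[[3]], width.cutoff = 500), collapse = ""),
            "+", sprintf("(1 | %s)", group)))
    fitted <- fit_lmer_checked(fb_formula, df, reml)
    fallback <- TRUE
  }

  new_novelty_lmm(fitted$fit, formula, group = group,
                  random_requested = random,
                  random_final = if (fallback || random == "intercept_only")
                    "intercept_only" else "intercept_and_slopes",
                  data = df,
                  fit_log = list(singular_fit = fitted$singular,
                                 converged = fitted$converged,
                                 fallback_applied = fallback),
                  n_dropped = n_dropped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_lmer_checked <- function(full_formula, df, reml) {
  warns <- character(0)
  fit <- withCallingHandlers(
    suppressMessages(lmerTest::lmer(full_formula, data = df, REML = reml)),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  conv_msgs <- unlist(fit@optinfo$conv$lme4$messages)
  converged <- fit@optinfo$conv$opt == 0 &&
    !any(grepl("failed to converge", c(warns, conv_msgs), ignore.case = TRUE))
  # boundary check: any random-effect variance below tol * residual variance
  vc <- lme4::VarCorr(fit)
  sigma2 <- stats::sigma(fit)^2
  vars <- unlist(lapply(vc, function(m) diag(m)))
  singular <- lme4::isSingular(fit, tol = 1e-4) ||
    any(vars < SINGULAR_TOL * sigma2)
  list(fit = fit, singular = singular, converged = converged)
}

new_novelty_lmm <- function(fit, formula, group, random_requested, random_final,
                            data, fit_log, n_dropped) {
  if (inherits(fit, "lm")) {
    sm <- summary(fit)$coefficients
    dfres <- stats::df.residual(fit)
    coefs <- data.frame(term = rownames(sm),
                        estimate = sm[, "Estimate"],
                        se = sm[, "Std. Error"],
                        df = dfres,
                        statistic = sm[, "t value"],
                        p_value = sm[, "Pr(>|t|)"],
                        stringsAsFactors = FALSE)
    varcor <- NULL
  } else {
    sm <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(sm),
                        estimate = sm[, "Estimate"],
                        se = sm[, "Std. Error"],
                        df = sm[, "df"],
                        statistic = sm[, "t value"],
                        p_value = sm[, "Pr(>|t|)"],
                        stringsAsFactors = FALSE)
    varcor <- as.data.frame(lme4::VarCorr(fit))
  }
  crit <- stats::qt(0.975, coefs$df)
  coefs$ci_lower <- coefs$estimate - crit * coefs$se
  coefs$ci_upper <- coefs$estimate + crit * coefs$se
  rownames(coefs) <- NULL
  structure(list(fit = fit, formula = formula, group = group,
                 random_requested = random_requested,
                 random_final = random_final,
                 coefficients = coefs, varcor = varcor,
                 fit_log = fit_log, n_dropped = n_dropped,
                 nobs = stats::nobs(fit), model_data = data),
            class = "novelty_lmm")
}

#' @export
#' @method print novelty_lmm
print.novelty_lmm <- function(x, digits = 3, ...) {
  cat("Participant-level mixed model\n")
  cat("  fixed:  ", deparse(x$formula), "\n")
  cat("  random: ", x$random_final,
      if (x$fit_log$fallback_applied) " (fallback from random slopes: singular/non-converged fit)" else "",
      "\n", sep = "")
  cat(sprintf("  n = %d observations", x$nobs))
  if (!is.null(x$group)) {
    cat(sprintf(", %d %s groups", nlevels(x$model_data[[x$group]]), x$group))
  }
  cat("\n\nFixed effects:\n")
  tab <- x$coefficients
  tab[, -1] <- lapply(tab[, -1], function(v) round(v, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
#' @method summary novelty_lmm
summary.novelty_lmm <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$varcor)) {
    cat("\nVariance components:\n")
    print(object$varcor, row.names = FALSE)
  }
  cat(sprintf("\nfit_log: singular_fit=%s, converged=%s, fallback_applied=%s; %d row(s) excluded\n",
              object$fit_log$singular_fit, object$fit_log$converged,
              object$fit_log$fallback_applied, object$n_dropped))
  invisible(object)
}

#' @export
coef.novelty_lmm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
confint.novelty_lmm <- function(object, parm, level = 0.95, ...) {
  tab <- object$coefficients
  crit <- stats::qt(1 - (1 - level) / 2, tab$df)
  out <- cbind(tab$estimate - crit * tab$se, tab$estimate + crit * tab$se)
  dimnames(out) <- list(tab$term,
                        sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
predict.novelty_lmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$fit, ...)
  else stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.novelty_lmm <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
fitted.novelty_lmm <- function(object, ...) stats::fitted(object$fit, ...)

#' @export
simulate.novelty_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$fit, nsim = nsim, seed = seed, ...)
}

#' @export
plot.novelty_lmm <- function(x, ...) {
  graphics::plot(stats::fitted(x$fit), stats::residuals(x$fit),
                 xlab = "Fitted values", ylab = "Residuals",
                 main = deparse(x$formula), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

emm_df_mode <- function(object) {
  if (inherits(object$fit, "lm") && !inherits(object$fit, "merMod")) list()
  else list(lmer.df = "satterthwaite")
}

#' Marginal-mean contrasts for a factor
#'
#' Computes model-based estimated marginal means for each level of `factor`
#' (continuous covariates held at their observed means) and all pairwise
#' level contrasts with Tukey-adjusted p-values from the studentized-range
#' distribution. Unadjusted p-values are reported alongside.
#'
#' @param object a `novelty_lmm` fit.
#' @param factor name of a categorical predictor in the model.
#' @return data.frame of class `novelty_contrasts`: one row per level pair
#'   with `estimate`, `se`, `df`, Tukey-adjusted 95% CI bounds,
#'   `p_unadjusted` and `p_tukey`. The per-level marginal means are attached
#'   as attribute `"emmeans"`.
#' @export
emm_contrasts <- function(object, factor) {
  stopifnot(inherits(object, "novelty_lmm"))
  if (!(factor %in% all.vars(object$formula[[3]]))) {
    nd_spec_error("factor '%s' is not a predictor in the fitted model", factor)
  }
  if (!is.factor(object$model_data[[factor]])) {
    nd_spec_error("'%s' is not categorical in the fitted model", factor)
  }
  args <- c(list(object$fit, specs = factor, data = object$model_data),
            emm_df_mode(object))
  emm <- do.call(emmeans::emmeans, args)
  prs <- emmeans::contrast(emm, method = "pairwise")
  tuk <- summary(prs, infer = c(TRUE, TRUE), adjust = "tukey")
  raw <- summary(prs, adjust = "none")
  lv <- strsplit(as.character(tuk$contrast), " - ", fixed = TRUE)
  out <- data.frame(level_a = vapply(lv, `[`, "", 1),
                    level_b = vapply(lv, `[`, "", 2),
                    estimate = tuk$estimate,
                    se = tuk$SE,
                    df = tuk$df,
                    ci_lower = tuk$lower.CL,
                    ci_upper = tuk$upper.CL,
                    p_unadjusted = raw$p.value,
                    p_tukey = tuk$p.value,
                    stringsAsFactors = FALSE)
  attr(out, "emmeans") <- summary(emm, infer = c(TRUE, TRUE))
  class(out) <- c("novelty_contrasts", "data.frame")
  out
}

#' @export
#' @method print novelty_contrasts
print.novelty_contrasts <- function(x, digits = 3, ...) {
  cat("Tukey-adjusted pairwise contrasts of marginal means\n")
  tab <- as.data.frame(x)
  tab[, -(1:2)] <- lapply(tab[, -(1:2)], function(v) signif(v, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Per-level simple slopes of a covariate
#'
#' For a model containing a `covariate * by_factor` interaction, returns the
#' covariate slope within each factor level as a linear combination of the
#' fixed effects, with delta-method standard errors, 95% CIs and p-values.
#' The difference between any two level slopes equals the corresponding
#' fitted interaction coefficient exactly.
#'
#' @param object a `novelty_lmm` fit.
#' @param covariate name of the continuous predictor.
#' @param by_factor name of the interacting categorical predictor.
#' @return data.frame: one row per factor level with `slope`, `se`, `df`,
#'   `ci_lower`, `ci_upper`, `p_value`.
#' @export
simple_slopes <- function(object, covariate, by_factor) {
  stopifnot(inherits(object, "novelty_lmm"))
  labs <- attr(stats::terms(object$formula), "term.labels")
  has_int <- any(labs %in% c(paste(covariate, by_factor, sep = ":"),
                             paste(by_factor, covariate, sep = ":")))
  if (!has_int) {
    nd_spec_error("model has no %s x %s interaction; simple slopes are undefined",
                  covariate, by_factor)
  }
  args <- c(list(object$fit, specs = by_factor, var = covariate,
                 data = object$model_data),
            emm_df_mode(object))
  emt <- do.call(emmeans::emtrends, args)
  sm <- summary(emt, infer = c(TRUE, TRUE))
  out <- data.frame(level = as.character(sm[[by_factor]]),
                    slope = sm[[paste0(covariate, ".trend")]],
                    se = sm$SE, df = sm$df,
                    ci_lower = sm$lower.CL, ci_upper = sm$upper.CL,
                    p_value = sm$p.value,
                    stringsAsFactors = FALSE)
  out
}

#' Likelihood-ratio comparison of nested mixed models
#'
#' Refits both models by maximum likelihood (REML likelihoods are not
#' comparable across fixed-effects specifications) and reports
#' `LR = 2 (logLik_full - logLik_reduced)` against a chi-squared reference
#' with df equal to the number of dropped fixed-effect parameters, plus the
#' AIC difference.
#'
#' @param full,reduced `novelty_lmm` fits on the same rows; `reduced`'s fixed
#'   terms must be a subset of `full`'s and both must share the same
#'   random-effects structure.
#' @return object of class `novelty_lrt`: list with `statistic`, `df`,
#'   `p_value`, `aic_delta` (full minus reduced).
#' @export
compare_models <- function(full, reduced) {
  stopifnot(inherits(full, "novelty_lmm"), inherits(reduced, "novelty_lmm"))
  if (full$nobs != reduced$nobs) {
    nd_spec_error("models were fitted to different numbers of rows (%d vs %d)",
                  full$nobs, reduced$nobs)
  }
  tf <- attr(stats::terms(full$formula), "term.labels")
  tr <- attr(stats::terms(reduced$formula), "term.labels")
  if (!all(tr %in% tf)) {
    nd_spec_error("models are not nested: reduced has term(s) absent from full (%s)",
                  paste(setdiff(tr, tf), collapse = ", "))
  }
  if (full$random_final != reduced$random_final) {
    nd_spec_error("models differ in random-effects structure (%s vs %s)",
                  full$random_final, reduced$random_final)
  }
  as_ml <- function(obj) {
    f <- obj$fit
    if (inherits(f, "merMod") && lme4::isREML(f)) lme4::refitML(f) else f
  }
  mf <- as_ml(full); mr <- as_ml(reduced)
  ll_f <- stats::logLik(mf); ll_r <- stats::logLik(mr)
  k_f <- if (inherits(mf, "merMod")) length(lme4::fixef(mf)) else length(stats::coef(mf))
  k_r <- if (inherits(mr, "merMod")) length(lme4::fixef(mr)) else length(stats::coef(mr))
  df <- k_f - k_r
  lr <- max(0, 2 * (as.numeric(ll_f) - as.numeric(ll_r)))
  p <- if (df == 0L) 1 else stats::pchisq(lr, df = df, lower.tail = FALSE)
  structure(list(statistic = lr, df = df, p_value = p,
                 aic_delta = stats::AIC(mf) - stats::AIC(mr)),
            class = "novelty_lrt")
}

#' @export
#' @method print novelty_lrt
print.novelty_lrt <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: LR = %.3f, df = %d, p = %.4g (AIC delta = %.2f)\n",
              x$statistic, x$df, x$p_value, x$aic_delta))
  invisible(x)
}

#' Pairwise correlations among the event emotion ratings
#'
#' Pearson correlation matrix of the seven emotion ratings across events.
#' A constant rating column makes its correlations undefined; the affected
#' entries are returned as `NA` with a warning (never silently zeroed).
#'
#' @param events a `diary_dataset` or an events data.frame with the seven
#'   emotion columns.
#' @return symmetric 7x7 numeric matrix with unit diagonal.
#' @export
emotion_correlations <- function(events) {
  if (inherits(events, "diary_dataset")) events <- events$events
  missing <- setdiff(EMOTION_NAMES, names(events))
  if (length(missing)) {
    nd_schema_error("events table lacks emotion column(s): %s",
                    paste(missing, collapse = ", "))
  }
  if (nrow(events) < 3L) nd_domain_error("need >= 3 events for emotion correlations")
  m <- as.matrix(events[, EMOTION_NAMES])
  const <- vapply(as.data.frame(m), function(v) stats::var(v) == 0, logical(1))
  if (any(const)) {
    warning(sprintf("constant rating column(s): %s; correlations flagged NA",
                    paste(EMOTION_NAMES[const], collapse = ", ")), call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(m))
  diag(r) <- 1
  r
}

#' Day-level positivity model
#'
#' Mixed model of end-of-day positivity on the indicator that the
#' participant-day contained at least one event labeled `new`, with a
#' participant random intercept.
#'
#' @param days a `diary_dataset` with a days table, or a days data.frame
#'   carrying `day_positivity` and `has_new_event`.
#' @return a `novelty_lmm` fit.
#' @export
day_level_model <- function(days) {
  if (inherits(days, "diary_dataset")) {
    if (is.null(days$days)) nd_spec_error("dataset has no days table")
    days <- days$days
  }
  need <- c("participant_id", "day_positivity", "has_new_event")
  missing <- setdiff(need, names(days))
  if (length(missing)) {
    nd_schema_error("days table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  if (length(unique(days$has_new_event)) < 2L) {
    nd_domain_error("has_new_event is constant (%s for every day); the day-level effect is not identifiable",
                    days$has_new_event[1])
  }
  tab <- table(days$participant_id)
  if (sum(tab >= 2L) < 2L) {
    nd_spec_error("day-level model needs >= 2 days for >= 2 participants")
  }
  days$has_new_event <- as.numeric(days$has_new_event)
  fit_mixed(day_positivity ~ has_new_event, days, random = "intercept_only")
}

#' Build the event-level analysis table
#'
#' Joins the metrics table into a modelling data.frame: `regularity` becomes a
#' factor with `new` as the reference level and `participant_id` a factor.
#'
#' @param metrics data.frame from [compute_metrics()].
#' @return data.frame ready for [fit_mixed()].
#' @export
as_analysis_table <- function(metrics) {
  out <- as.data.frame(metrics)
  out$regularity <- factor(out$regularity, levels = REGULARITY_LEVELS)
  out$participant_id <- factor(out$participant_id)
  out
}
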