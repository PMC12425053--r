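# mixed models, contrasts, simple slopes, model comparison

make_mlm_data <- function(n_pid = 12, n_obs = 10, beta = c(1.5, 0.5, -0.3, 2, 0, 0),
                          sd_res = 1, sd_int = 0.7, sd_slope = 0, seed = 1) {
  set.seed(seed)
  d <- data.frame(participant_id = rep(sprintf("P%02d", seq_len(n_pid)), each = n_obs),
                  x = rnorm(n_pid * n_obs),
                  g = factor(sample(c("a", "b", "c"), n_pid * n_obs, TRUE)))
  mm <- model.matrix(~ g * x, d)
  u <- rep(rnorm(n_pid, sd = sd_int), each = n_obs)
  s <- rep(rnorm(n_pid, sd = sd_slope), each = n_obs)
  d$y <- as.vector(mm %*% beta) + u + s * d$x + rnorm(nrow(d), sd = sd_res)
  d
}

test_that("noiseless data returns the generating coefficients to 8+ digits", {
  d <- make_mlm_data(sd_res = 0, sd_int = 0, seed = 2)
  fit <- fit_mixed(y ~ g * x, d, random = "intercept_only")
  expect_equal(unname(coef(fit)), c(1.5, 0.5, -0.3, 2, 0, 0), tolerance = 1e-8)
})

test_that("with zero random-effect variance the fit reproduces OLS", {
  d <- make_mlm_data(sd_int = 0, seed = 3)
  fit <- fit_mixed(y ~ g * x, d, random = "intercept_only")
  ols <- lm(y ~ g * x, d)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-6)
  expect_true(fit$fit_log$singular_fit)
})

test_that("zero slope variance triggers the intercept-only fallback, once,
           with fixed effects equal to a direct intercept-only fit", {
  d <- make_mlm_data(sd_slope = 0, seed = 4)
  fit <- fit_mixed(y ~ g * x, d, random = "intercept_and_slopes",
                   slope_terms = "x")
  expect_true(fit$fit_log$fallback_applied)
  expect_equal(fit$random_final, "intercept_only")
  direct <- fit_mixed(y ~ g * x, d, random = "intercept_only")
  expect_identical(unname(coef(fit)), unname(coef(direct)))
  # genuine slope variance keeps the requested structure
  d2 <- make_mlm_data(sd_slope = 1.5, n_pid = 30, seed = 5)
  fit2 <- fit_mixed(y ~ g * x, d2, random = "intercept_and_slopes",
                    slope_terms = "x")
  expect_false(fit2$fit_log$fallback_applied)
  expect_equal(fit2$random_final, "intercept_and_slopes")
})

test_that("rank-deficient fixed designs fail naming the aliased term", {
  d <- make_mlm_data(seed = 6)
  d$x2 <- 2 * d$x
  err <- tryCatch(fit_mixed(y ~ x + x2, d, random = "intercept_only"),
                  error = identity)
  expect_s3_class(err, "nd_spec_error")
  expect_match(conditionMessage(err), "x2")
})

test_that("coefficient table brackets estimates and flags propagate", {
  d <- make_mlm_data(seed = 7)
  fit <- fit_mixed(y ~ g * x, d, random = "intercept_only")
  tab <- fit$coefficients
  expect_true(all(tab$ci_lower < tab$estimate & tab$estimate < tab$ci_upper))
  expect_s4_class(fit$fit, "lmerModLmerTest")
  expect_identical(sort(names(fit$fit_log)),
                   sort(c("singular_fit", "converged", "fallback_applied")))
  # methods behave
  expect_length(residuals(fit), nrow(d))
  expect_length(predict(fit), nrow(d))
  expect_equal(dim(confint(fit)), c(6L, 2L))
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(nrow(d), 2L))
})

test_that("rows with non-finite metric values are excluded listwise", {
  d <- make_mlm_data(seed = 8)
  d$x[c(3, 9)] <- Inf
  expect_message(fit <- fit_mixed(y ~ g * x, d, random = "intercept_only"),
                 "excluded 2")
  expect_equal(fit$nobs, nrow(d) - 2L)
  expect_equal(fit$n_dropped, 2L)
})

test_that("emm contrasts: pair count, null behavior, and p-value ordering", {
  d <- make_mlm_data(n_pid = 40, n_obs = 12, beta = c(2, 0, 0, 0, 0, 0), seed = 9)
  fit <- fit_mixed(y ~ g + x, d, random = "intercept_only")
  con <- emm_contrasts(fit, "g")
  expect_equal(nrow(con), 3L)  # k(k-1)/2 for k = 3
  expect_true(all(con$p_tukey >= con$p_unadjusted - 1e-12))
  expect_true(all(con$p_tukey > 0.2))  # no true differences, large n
  expect_error(emm_contrasts(fit, "absent"), class = "nd_spec_error")
  expect_error(emm_contrasts(fit, "x"), class = "nd_spec_error")
})

test_that("on balanced one-way data emm_contrasts equals classical Tukey HSD", {
  set.seed(10)
  g <- factor(rep(c("a", "b", "c"), each = 25))
  y <- rnorm(75) + c(a = 0, b = 0.7, c = 0.2)[g]
  d <- data.frame(y = y, g = g)
  fit <- fit_mixed(y ~ g, d, random = "none")
  con <- emm_contrasts(fit, "g")
  oracle <- brute_tukey_hsd(y, g)
  expect_equal(con$estimate, unname(oracle$estimate), tolerance = 1e-9)
  expect_equal(con$se, unname(oracle$se), tolerance = 1e-9)
  expect_equal(con$p_tukey, unname(oracle$p), tolerance = 1e-7)
  expect_true(all(con$p_tukey >= con$p_unadjusted - 1e-12))
})

test_that("simple slopes reproduce the interaction parameterization identity", {
  d <- make_mlm_data(beta = c(1, 0.5, -0.5, 2, 1.2, -0.8), n_pid = 25, seed = 11)
  fit <- fit_mixed(y ~ g * x, d, random = "intercept_only")
  ss <- simple_slopes(fit, "x", "g")
  expect_equal(ss$level, c("a", "b", "c"))
  cf <- coef(fit)
  # slope(b) - slope(a) equals the fitted gb:x coefficient exactly
  expect_equal(ss$slope[2] - ss$slope[1], unname(cf["gb:x"]), tolerance = 1e-10)
  expect_equal(ss$slope[3] - ss$slope[1], unname(cf["gc:x"]), tolerance = 1e-10)
  expect_equal(ss$slope[1], unname(cf["x"]), tolerance = 1e-10)
  # no interaction term -> specification error
  fit0 <- fit_mixed(y ~ g + x, d, random = "intercept_only")
  expect_error(simple_slopes(fit0, "x", "g"), class = "nd_spec_error")
})

test_that("simple slopes recover generating signs (+2 / 0 / -2)", {
  hits <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    d <- make_mlm_data(n_pid = 30, n_obs = 12,
                       beta = c(1, 0, 0, 2, -2, -4), seed = 100 + r)
    fit <- fit_mixed(y ~ g * x, d, random = "intercept_only")
    ss <- simple_slopes(fit, "x", "g")
    ok <- ss$slope[1] > 0 && ss$p_value[1] < 0.05 &&  # slope a = +2
      ss$slope[3] < 0 && ss$p_value[3] < 0.05         # slope c = -2
    hits <- hits + ok
  }
  expect_gte(hits, ceiling(0.95 * n_rep) - 1L)
})

test_that("model comparison: self-test, bookkeeping, nesting guard", {
  d <- make_mlm_data(seed = 12)
  full <- fit_mixed(y ~ g * x, d, random = "intercept_only")
  same <- fit_mixed(y ~ g * x, d, random = "intercept_only")
  cmp <- compare_models(full, same)
  expect_equal(cmp$statistic, 0, tolerance = 1e-8)
  expect_equal(cmp$df, 0L)
  expect_equal(cmp$p_value, 1)

  reduced <- fit_mixed(y ~ g + x, d, random = "intercept_only")
  cmp2 <- compare_models(full, reduced)
  expect_equal(cmp2$df, 2L)  # the two dropped interaction columns
  expect_gte(cmp2$statistic, 0)

  other <- fit_mixed(y ~ g * x + I(x^2), d, random = "intercept_only")
  expect_error(compare_models(full, other), class = "nd_spec_error")
})

test_that("under the null the LR statistic is approximately chi-squared(1)", {
  set.seed(13)
  stats <- numeric(200)
  for (r in 1:200) {
    d <- make_mlm_data(n_pid = 15, n_obs = 6,
                       beta = c(1, 0, 0, 0.5, 0, 0), seed = 2000 + r)
    d$z <- rnorm(nrow(d))  # pure-noise extra predictor
    full <- fit_mixed(y ~ x + z, d, random = "intercept_only")
    red <- fit_mixed(y ~ x, d, random = "intercept_only")
    stats[r] <- compare_models(full, red)$statistic
  }
  ks <- suppressWarnings(ks.test(stats, pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("emotion correlations: identity, symmetry, constant-column flagging", {
  ev <- make_events_df(3)
  ev <- do.call(rbind, replicate(20, ev, simplify = FALSE))
  ev$day_index <- rep(1:60, each = 1)
  set.seed(14)
  for (col in c("happy", "positive", "sad", "negative", "excited", "calm", "afraid")) {
    ev[[col]] <- sample(1:5, 60, TRUE)
  }
  ev$positive <- ev$happy  # duplicated column
  r <- emotion_correlations(ev)
  expect_equal(dim(r), c(7L, 7L))
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 7))
  expect_equal(r["happy", "positive"], 1)
  ev$calm <- 3L
  expect_warning(r2 <- emotion_correlations(ev), "calm")
  expect_true(all(is.na(r2["calm", setdiff(colnames(r2), "calm")])))
  expect_equal(r2["calm", "calm"], 1)
})

test_that("independent ratings show near-zero correlations at n = 10000", {
  set.seed(15)
  ev <- data.frame(matrix(sample(1:5, 10000 * 7, TRUE), 10000, 7))
  names(ev) <- c("happy", "positive", "sad", "negative", "excited", "calm", "afraid")
  r <- emotion_correlations(ev)
  off <- r[upper.tri(r)]
  expect_true(all(abs(off) < 0.05))
})

test_that("day-level model: noiseless recovery and degenerate guard", {
  sdat <- simulate_diary(sim_config(n_participants = 12, seed = 16, text = FALSE,
                                    noise_sds = c(day_residual = 0, day_intercept = 0)))
  fit <- day_level_model(sdat$dataset)
  expect_equal(unname(coef(fit)), c(3.0, 0.22), tolerance = 1e-6)
  days <- sdat$dataset$days
  days$has_new_event <- TRUE
  expect_error(day_level_model(days), class = "nd_domain_error")
})
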