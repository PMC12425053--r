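# synthetic diary generator

test_that("default-size generation is deterministic with correct bookkeeping", {
  cfg <- sim_config(seed = 7, text = FALSE)
  a <- simulate_diary(cfg)
  b <- simulate_diary(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$dataset$events), 41L * 14L * 3L)
  expect_equal(length(unique(a$dataset$events$participant_id)), 41L)
  expect_equal(nrow(a$dataset$days), 41L * 14L)
  # one free recall per participant-day, i.e. one third of events
  er <- a$dataset$recalls[a$dataset$recalls$test_arm == "event_recall", ]
  expect_equal(nrow(er), 41L * 14L)
  expect_equal(max(table(paste(er$participant_id, er$day_index))), 1L)
  # vividness present for every event regardless of arm
  expect_false(anyNA(a$dataset$recalls$vividness))
})

test_that("recall-arm assignment partitions events, one per day, reproducibly", {
  sdat <- simulate_diary(sim_config(n_participants = 5, seed = 21, text = FALSE))
  ev <- sdat$dataset$events
  a1 <- select_recall_events(ev, seed = 99)
  a2 <- select_recall_events(ev, seed = 99)
  expect_identical(a1, a2)
  expect_equal(nrow(a1), nrow(ev))
  expect_true(all(a1$test_arm %in% c("event_recall", "temporal_pair")))
  per_day <- tapply(a1$test_arm == "event_recall",
                    paste(a1$participant_id, a1$day_index), sum)
  expect_true(all(per_day == 1L))
  # 14 days -> 14 recall-arm events per participant
  expect_equal(as.vector(table(a1$participant_id[a1$test_arm == "event_recall"])),
               rep(14L, 5L))
})

test_that("regularity mixture follows the configured multinomial probabilities", {
  probs <- c(new = 0.215, periodic = 0.627, routine = 0.158)
  cfg <- sim_config(n_participants = 120, n_days = 28, events_per_day = 3,
                    regularity_probs = probs, seed = 22, text = FALSE)
  sdat <- simulate_diary(cfg)
  n <- nrow(sdat$dataset$events)
  expect_gte(n, 10000L)
  tab <- table(factor(sdat$dataset$events$regularity,
                      levels = c("new", "periodic", "routine")))
  for (lev in names(probs)) {
    se <- sqrt(n * probs[lev] * (1 - probs[lev]))
    expect_lt(abs(tab[lev] - n * probs[lev]), 2 * se)
  }
})

test_that("noiseless generation is exactly consistent with its ground truth", {
  cfg <- sim_config(n_participants = 8, seed = 23, text = FALSE,
                    noise_sds = c(residual = 0, random_intercept = 0,
                                  random_slope = 0, day_residual = 0,
                                  day_intercept = 0),
                    true_effects = list(stability_noise = c(new = 0, periodic = 0,
                                                            routine = 0)))
  sdat <- simulate_diary(cfg)
  te <- sdat$truth$coefficients
  # vividness equals the discretized deterministic linear predictor
  reg <- sdat$dataset$events$regularity
  lp <- te$vividness_intercept + te$regularity_offsets[reg] +
    te$rss_slopes[reg] * unname(sdat$truth$rss_centered) +
    te$res_slope * (unname(sdat$truth$res) -
                      mean(sdat$truth$res[is.finite(sdat$truth$res)]))
  expect_equal(unname(sdat$truth$vividness_latent), unname(lp), tolerance = 1e-12)
  expect_equal(unname(sdat$truth$vividness),
               pmin(5, pmax(1, round(lp))))
  # zero stability noise: recall embeddings equal encodings, stability = 1
  expect_true(all(abs(sdat$truth$stability - 1) < 1e-12))
  # day positivity is exactly intercept + effect * has_new
  dy <- sdat$dataset$days
  expect_equal(dy$day_positivity,
               te$day_positivity_intercept +
                 te$day_positivity_effect * dy$has_new_event,
               tolerance = 1e-12)
})

test_that("pipeline metrics reproduce ground-truth RSS/RES to 10+ digits", {
  sdat <- simulate_diary(sim_config(n_participants = 10, seed = 24, text = FALSE))
  m <- compute_metrics(sdat$dataset, embeddings = sdat$truth$embeddings,
                       recall_embeddings = sdat$truth$recall_embeddings)
  expect_equal(m$rss, unname(sdat$truth$rss), tolerance = 1e-11)
  expect_equal(m$res, unname(sdat$truth$res), tolerance = 1e-11)
  key <- paste(m$participant_id, m$day_index, m$event_index, sep = ":")
  tested <- !is.na(m$stability)
  expect_equal(m$stability[tested],
               unname(sdat$truth$stability[key[tested]]), tolerance = 1e-11)
})

test_that("generated narratives carry their planted detail counts", {
  sdat <- simulate_diary(sim_config(n_participants = 4, seed = 25, text = TRUE))
  ev <- sdat$dataset$events
  scored <- score_details(ev$description)
  planted <- as.data.frame(sdat$truth$planted_description_counts)
  for (col in names(planted)) {
    expect_equal(scored[[col]], unname(planted[[col]]), info = col)
  }
  # recall texts too
  rc <- sdat$dataset$recalls
  er <- rc[rc$test_arm == "event_recall", ]
  scored_r <- score_details(er$recall_text)
  planted_r <- as.data.frame(sdat$truth$planted_recall_counts)
  for (col in names(planted_r)) {
    expect_equal(scored_r[[col]], unname(planted_r[[col]]), info = col)
  }
})

test_that("the generated similarity structure orders regularity levels", {
  sdat <- simulate_diary(sim_config(seed = 26, text = FALSE))
  m <- compute_metrics(sdat$dataset, embeddings = sdat$truth$embeddings,
                       recall_embeddings = sdat$truth$recall_embeddings)
  rss_by <- tapply(m$rss, m$regularity, mean)
  expect_gt(rss_by["routine"], rss_by["periodic"])
  expect_gt(rss_by["periodic"], rss_by["new"])
  res_by <- tapply(m$res[is.finite(m$res)], m$regularity[is.finite(m$res)], mean)
  expect_lt(res_by["new"], res_by["routine"])
  stab_by <- tapply(m$stability, m$regularity, mean, na.rm = TRUE)
  expect_gt(stab_by["new"], stab_by["routine"])
  expect_gt(stab_by["periodic"], stab_by["routine"])
})

test_that("per-day dropout removes whole days without imputation", {
  sdat <- simulate_diary(sim_config(n_participants = 20, dropout_prob = 0.1,
                                    seed = 27, text = FALSE))
  ev <- sdat$dataset$events
  expect_lt(nrow(ev), 20 * 14 * 3)
  per_day <- table(paste(ev$participant_id, ev$day_index))
  expect_true(all(per_day == 3L))  # days are dropped whole, never partially
  expect_equal(nrow(sdat$dataset$days), length(per_day))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(regularity_probs = c(0.5, 0.4, 0.2)),
               class = "nd_domain_error")
  expect_error(sim_config(noise_sds = c(residual = -1)), class = "nd_domain_error")
  expect_error(sim_config(events_per_day = 4), class = "nd_domain_error")
  expect_error(sim_config(dropout_prob = 1), class = "nd_domain_error")
})
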