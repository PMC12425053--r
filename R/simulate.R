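# Synthetic diary-study generator.
#
# Emulates the study design: participants report three events per day over a
# two-week diary window, label each as new / periodic / routine, rate seven
# emotions per event, rate every event's recall vividness at a delayed test,
# and give free recalls for one randomly selected event per day. The
# generator produces both latent event embeddings (fast, embedder-free tests)
# and template-assembled narratives with planted detail counts (end-to-end
# tests through the embedder and the detail scorer), plus full ground truth:
# latent vectors, true per-event RSS/RES, true stability, planted counts and
# the generating coefficients.
#
# Semantic geometry: each participant has a latent "home" vector anchoring
# their semantic space; every event is a perturbation of home whose spread
# grows with novelty (routine < periodic < new). This induces the
# relative-semantic-similarity ordering routine > periodic > new with
# level differences of a few hundredths on the cosine scale -- the same
# order of magnitude as the RSS dispersion itself, as observed in diary
# data. Emotion vectors get higher excitement/fear and lower calmness (with
# extra arousal spread) for new events, so new events are also the most
# emotionally distinct.

#' Simulation configuration
#'
#' Defaults encode the reference study conditions: 41 participants, 14 days,
#' 3 events/day, regularity mixture proportional to 359:1050:264, one
#' free-recall event per day (one third of events).
#'
#' @param n_participants,n_days,events_per_day design sizes.
#' @param regularity_probs named probabilities for (new, periodic, routine);
#'   must sum to 1.
#' @param true_effects named list of generating coefficients; see Details.
#' @param noise_sds named vector: `residual` (event-level vividness noise),
#'   `random_intercept`, `random_slope` (participant-level), `day_residual`,
#'   `day_intercept` (day-positivity model).
#' @param embedding_dim dimension of the latent semantic space.
#' @param dropout_prob per participant-day probability that the day is missed
#'   (its rows are absent, never imputed). Default 0 (complete data).
#' @param text if `TRUE`, assemble titles/descriptions/recall texts from the
#'   category-tagged template bank; if `FALSE`, texts are minimal
#'   placeholders and only latent embeddings are meaningful (fast path).
#' @param seed integer seed; fully determines the generated dataset.
#'
#' @details `true_effects` components (with defaults): `vividness_intercept`
#' (3.8, the 'new' baseline on the latent 1--5 scale), `regularity_offsets`
#' (new 0, periodic -0.79, routine -1.55), `rss_slopes` per regularity level
#' (new 2.18, periodic 0.35, routine -2.67, applied to the true RSS centered
#' within regularity level, so the offsets equal level-mean differences),
#' `res_slope` (-1.64, on mean-centered true RES), `stability_noise`
#' (per-regularity sd of the recall-embedding perturbation: new 0.35,
#' periodic 0.40, routine 0.65 -- larger perturbation = less stable memory),
#' `day_positivity_intercept` (3.0) and `day_positivity_effect` (0.22, the
#' shift on days with at least one new event).
#'
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 41, n_days = 14, events_per_day = 3,
                       regularity_probs = c(new = 359, periodic = 1050,
                                            routine = 264) / 1673,
                       true_effects = list(), noise_sds = c(),
                       embedding_dim = 32, dropout_prob = 0,
                       text = TRUE, seed = NULL) {
  defaults_te <- list(
    vividness_intercept = 3.8,
    regularity_offsets = c(new = 0, periodic = -0.79, routine = -1.55),
    rss_slopes = c(new = 2.18, periodic = 0.35, routine = -2.67),
    res_slope = -1.64,
    stability_noise = c(new = 0.5, periodic = 0.55, routine = 0.7),
    day_positivity_intercept = 3.0,
    day_positivity_effect = 0.22)
  defaults_ns <- c(residual = 0.8, random_intercept = 0.5, random_slope = 0.3,
                   day_residual = 0.5, day_intercept = 0.4)
  te <- utils::modifyList(defaults_te, as.list(true_effects))
  ns <- defaults_ns
  if (length(noise_sds)) ns[names(noise_sds)] <- noise_sds

  if (!is_whole(n_participants) || n_participants < 1) nd_domain_error("n_participants must be a positive integer")
  if (!is_whole(n_days) || n_days < 1) nd_domain_error("n_days must be a positive integer")
  if (!is_whole(events_per_day) || events_per_day < 1 || events_per_day > 3) {
    nd_domain_error("events_per_day must be in {1,2,3}")
  }
  if (length(regularity_probs) != 3L || any(regularity_probs < 0) ||
      abs(sum(regularity_probs) - 1) > 1e-9) {
    nd_domain_error("regularity_probs must be 3 non-negative values summing to 1")
  }
  names(regularity_probs) <- REGULARITY_LEVELS
  if (any(ns < 0)) nd_domain_error("noise sds must be >= 0")
  if (any(te$stability_noise < 0)) nd_domain_error("stability_noise must be >= 0")
  if (dropout_prob < 0 || dropout_prob >= 1) nd_domain_error("dropout_prob must be in [0, 1)")
  if (!is_whole(embedding_dim) || embedding_dim < 2) nd_domain_error("embedding_dim must be an integer >= 2")

  structure(list(n_participants = as.integer(n_participants),
                 n_days = as.integer(n_days),
                 events_per_day = as.integer(events_per_day),
                 regularity_probs = regularity_probs,
                 true_effects = te, noise_sds = ns,
                 embedding_dim = as.integer(embedding_dim),
                 dropout_prob = dropout_prob, text = isTRUE(text),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' @export
#' @method print sim_config
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: %d participants x %d days x %d events/day\n",
              x$n_participants, x$n_days, x$events_per_day))
  cat("  regularity probs:", paste(sprintf("%s=%.3f", names(x$regularity_probs),
                                           x$regularity_probs), collapse = ", "), "\n")
  cat(sprintf("  latent dim %d; dropout %.2f; text=%s; seed=%s\n",
              x$embedding_dim, x$dropout_prob, x$text,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

templates_path <- function() {
  system.file("extdata", "narrative_templates_v1.txt", package = "noveltydiary",
              mustWork = TRUE)
}

#' Read the category-tagged narrative template bank
#'
#' @param path template file; defaults to the shipped version-1 bank.
#' @return named list of character vectors (one per detail category plus
#'   `title`), with a `"version"` attribute.
#' @export
read_templates <- function(path = NULL) {
  if (is.null(path)) path <- templates_path()
  parse_sectioned_file(path)
}

# semantic perturbation sd around the participant home vector, by regularity
SEMANTIC_NOISE_SD <- c(new = 1.3, periodic = 1.0, routine = 0.9)

# emotion-generation constants (latent means on the 1-5 rating scale)
EMO_BASE <- c(happy = 3.2, positive = 3.3, sad = 1.8, negative = 1.9,
              excited = 2.6, calm = 3.0, afraid = 1.5)
EMO_REG_OFFSETS <- rbind(  # rows: regularity, cols: emotion
  new      = c(happy = 0, positive = 0, sad = 0, negative = 0,
               excited =  0.21, calm = -0.21, afraid =  0.11),
  periodic = c(happy = 0, positive = 0, sad = 0, negative = 0,
               excited =  0.00, calm =  0.00, afraid =  0.00),
  routine  = c(happy = 0, positive = 0, sad = 0, negative = 0,
               excited = -0.20, calm =  0.39, afraid = -0.11))
EMO_VALENCE_LOAD <- c(happy = 0.7, positive = 0.7, sad = 0, negative = 0,
                      excited = 0, calm = 0, afraid = 0)
EMO_NEGAFF_LOAD <- c(happy = 0, positive = 0, sad = 0.45, negative = 0.45,
                     excited = 0, calm = 0, afraid = 0.2)
EMO_NOISE_SD <- c(happy = 0.25, positive = 0.25, sad = 0.30, negative = 0.30,
                  excited = 0.60, calm = 0.60, afraid = 0.35)
AROUSAL_SPREAD_NEW <- 1.25  # extra arousal-channel spread for 'new' events

DESC_CATEGORY_PROBS <- c(event = 0.30, place = 0.15, time = 0.15,
                         thought_emotion = 0.15, perceptual = 0.10,
                         non_episodic = 0.15)
RECALL_KEEP_PROB <- c(new = 0.9, periodic = 0.8, routine = 0.6)

clamp_rating <- function(x) pmin(5L, pmax(1L, as.integer(round(x))))

#' Generate a synthetic diary dataset with ground truth
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_diary`: list with `dataset` (a validated
#'   `diary_dataset`) and `truth` (latent event/recall embeddings keyed by
#'   event, true per-event RSS/RES/stability, the latent and discretized
#'   vividness, planted per-category detail counts for descriptions and
#'   recalls, the generating coefficients and the config).
#' @export
simulate_diary <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  te <- config$true_effects
  ns <- config$noise_sds
  d <- config$embedding_dim
  pids <- sprintf("P%02d", seq_len(config$n_participants))

  grid <- expand.grid(event_index = seq_len(config$events_per_day),
                      day_index = seq_len(config$n_days),
                      participant_id = pids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("participant_id", "day_index", "event_index")]
  grid <- grid[order(match(grid$participant_id, pids), grid$day_index,
                     grid$event_index), ]
  rownames(grid) <- NULL
  n <- nrow(grid)
  key <- event_key(grid$participant_id, grid$day_index, grid$event_index)

  regularity <- sample(REGULARITY_LEVELS, n, replace = TRUE,
                       prob = config$regularity_probs)

  # --- latent semantic space -------------------------------------------------
  # event = participant home + noise whose spread grows with novelty
  emb <- matrix(0, n, d)
  for (pid in pids) {
    idx <- which(grid$participant_id == pid)
    home <- stats::rnorm(d)
    spread <- SEMANTIC_NOISE_SD[regularity[idx]]
    noise <- matrix(stats::rnorm(length(idx) * d), length(idx), d) * spread
    emb[idx, ] <- sweep(noise, 2, home, "+")
  }
  rownames(emb) <- key

  # --- emotion ratings -------------------------------------------------------
  pid_base <- matrix(stats::rnorm(length(pids) * 7, sd = 0.25), length(pids), 7,
                     dimnames = list(pids, EMOTION_NAMES))
  valence <- stats::rnorm(n)
  negaff <- stats::rnorm(n)
  noise_mult <- ifelse(regularity == "new", AROUSAL_SPREAD_NEW, 1)
  emo_latent <- matrix(rep(EMO_BASE, each = n), n, 7,
                       dimnames = list(NULL, EMOTION_NAMES)) +
    pid_base[grid$participant_id, ] +
    EMO_REG_OFFSETS[regularity, ] +
    outer(valence, EMO_VALENCE_LOAD) +
    outer(negaff, EMO_NEGAFF_LOAD)
  for (e in EMOTION_NAMES) {
    sd_e <- EMO_NOISE_SD[e] *
      (if (e %in% c("excited", "calm", "afraid")) noise_mult else rep(1, n))
    emo_latent[, e] <- emo_latent[, e] + stats::rnorm(n, sd = sd_e)
  }
  emotions <- apply(emo_latent, 2, clamp_rating)

  # --- true relative-similarity metrics -------------------------------------
  true_rss <- rep(NA_real_, n)
  true_res <- rep(NA_real_, n)
  for (pid in pids) {
    idx <- which(grid$participant_id == pid)
    if (length(idx) < 2L) next
    true_rss[idx] <- compute_rss(emb[idx, , drop = FALSE])
    true_res[idx] <- suppressWarnings(compute_res(emotions[idx, , drop = FALSE]))
  }
  # centered within regularity level: the per-level slopes are within-level
  # effects, so level-centering only re-anchors the level intercepts (the
  # regularity offsets then equal level mean differences at level-typical RSS)
  rss_c <- stats::setNames(
    true_rss - stats::ave(true_rss, regularity,
                          FUN = function(v) mean(v, na.rm = TRUE)), key)
  res_finite <- is.finite(true_res)
  res_c <- true_res - mean(true_res[res_finite])
  res_c[!res_finite] <- 0  # sentinel events get no RES contribution

  # --- vividness -------------------------------------------------------------
  u_int <- stats::rnorm(length(pids), sd = ns["random_intercept"])
  u_slo <- stats::rnorm(length(pids), sd = ns["random_slope"])
  names(u_int) <- names(u_slo) <- pids
  viv_latent <- te$vividness_intercept +
    te$regularity_offsets[regularity] +
    (te$rss_slopes[regularity] + u_slo[grid$participant_id]) * rss_c +
    te$res_slope * res_c +
    u_int[grid$participant_id] +
    stats::rnorm(n, sd = ns["residual"])
  vividness <- clamp_rating(viv_latent)

  # --- texts -----------------------------------------------------------------
  planted_desc <- matrix(0L, n, length(DETAIL_CATEGORIES),
                         dimnames = list(key, DETAIL_CATEGORIES))
  if (config$text) {
    tpl <- read_templates()
    titles <- sample(tpl$title, n, replace = TRUE)
    desc_sentences <- vector("list", n)
    descriptions <- character(n)
    n_sent <- sample(2:5, n, replace = TRUE)
    for (i in seq_len(n)) {
      cats <- sample(names(DESC_CATEGORY_PROBS), n_sent[i], replace = TRUE,
                     prob = DESC_CATEGORY_PROBS)
      sent <- vapply(cats, function(cc) sample(tpl[[cc]], 1), character(1))
      desc_sentences[[i]] <- list(sentences = unname(sent), categories = cats)
      descriptions[i] <- paste(sent, collapse = " ")
      tab <- table(factor(cats, levels = DETAIL_CATEGORIES))
      planted_desc[i, ] <- as.integer(tab)
    }
  } else {
    titles <- paste("event", key)
    descriptions <- paste("synthetic event", key)
  }

  events <- data.frame(grid, title = titles, description = descriptions,
                       regularity = regularity, stringsAsFactors = FALSE)
  events <- cbind(events, as.data.frame(emotions))

  # --- dropout ---------------------------------------------------------------
  pd_all <- unique(events[, c("participant_id", "day_index")])
  dropped <- stats::runif(nrow(pd_all)) < config$dropout_prob
  if (any(dropped)) {
    gone <- paste(pd_all$participant_id[dropped], pd_all$day_index[dropped])
    keep <- !(paste(events$participant_id, events$day_index) %in% gone)
    events <- events[keep, ]
    key <- key[keep]; regularity <- regularity[keep]
    viv_latent <- viv_latent[keep]; vividness <- vividness[keep]
    true_rss <- true_rss[keep]; true_res <- true_res[keep]
    emb <- emb[keep, , drop = FALSE]
    planted_desc <- planted_desc[keep, , drop = FALSE]
    if (config$text) desc_sentences <- desc_sentences[keep]
    rownames(events) <- NULL
  }

  # --- recall selection, recall embeddings/texts -----------------------------
  arm <- select_recall_events(events)
  sel <- which(arm$test_arm == "event_recall")
  rec_emb <- emb[sel, , drop = FALSE] +
    matrix(stats::rnorm(length(sel) * d), length(sel), d) *
      te$stability_noise[regularity[sel]]
  rownames(rec_emb) <- key[sel]
  enc_n <- unit_rows(emb[sel, , drop = FALSE])
  rec_n <- unit_rows(rec_emb)
  true_stab <- stats::setNames(rowSums(enc_n * rec_n), key[sel])

  recall_text <- rep(NA_character_, nrow(events))
  planted_recall <- matrix(NA_integer_, length(sel), length(DETAIL_CATEGORIES),
                           dimnames = list(key[sel], DETAIL_CATEGORIES))
  if (config$text) {
    for (j in seq_along(sel)) {
      i <- sel[j]
      ds <- desc_sentences[[i]]
      keep_s <- stats::runif(length(ds$sentences)) < RECALL_KEEP_PROB[regularity[i]]
      if (!any(keep_s)) keep_s[sample.int(length(keep_s), 1)] <- TRUE
      recall_text[i] <- paste(ds$sentences[keep_s], collapse = " ")
      tab <- table(factor(ds$categories[keep_s], levels = DETAIL_CATEGORIES))
      planted_recall[j, ] <- as.integer(tab)
    }
  } else {
    recall_text[sel] <- paste("synthetic recall", key[sel])
  }

  recalls <- data.frame(events[, c("participant_id", "day_index", "event_index")],
                        vividness = vividness,
                        recall_text = recall_text,
                        test_arm = arm$test_arm,
                        stringsAsFactors = FALSE)

  # --- day-level positivity --------------------------------------------------
  days <- unique(events[, c("participant_id", "day_index")])
  rownames(days) <- NULL
  new_days <- unique(paste(events$participant_id[events$regularity == "new"],
                           events$day_index[events$regularity == "new"]))
  has_new <- paste(days$participant_id, days$day_index) %in% new_days
  u_day <- stats::setNames(stats::rnorm(length(pids), sd = ns["day_intercept"]), pids)
  days$day_positivity <- te$day_positivity_intercept +
    te$day_positivity_effect * has_new +
    u_day[days$participant_id] +
    stats::rnorm(nrow(days), sd = ns["day_residual"])

  dataset <- as_diary_dataset(events, recalls, days)
  truth <- list(embeddings = emb, recall_embeddings = rec_emb,
                rss = stats::setNames(true_rss, key),
                res = stats::setNames(true_res, key),
                rss_centered = rss_c[key],
                stability = true_stab,
                vividness_latent = stats::setNames(viv_latent, key),
                vividness = stats::setNames(vividness, key),
                planted_description_counts = planted_desc,
                planted_recall_counts = planted_recall,
                random_intercepts = u_int, random_slopes = u_slo,
                coefficients = te, config = config)
  structure(list(dataset = dataset, truth = truth), class = "synthetic_diary")
}

#' Assign the free-recall arm: one event per participant-day
#'
#' Randomly selects exactly one reported event on each participant-day for
#' the free-recall (`event_recall`) arm; every other event goes to the
#' `temporal_pair` arm. All events keep a vividness rating regardless of arm.
#'
#' @param events an events data.frame (or a `diary_dataset` / `synthetic_diary`).
#' @param seed optional seed for reproducible selection.
#' @return data.frame `participant_id, day_index, event_index, test_arm`, in
#'   the row order of `events`.
#' @export
select_recall_events <- function(events, seed = NULL) {
  if (inherits(events, "synthetic_diary")) events <- events$dataset$events
  if (inherits(events, "diary_dataset")) events <- events$events
  if (!is.null(seed)) set.seed(seed)
  pd <- paste(events$participant_id, events$day_index)
  arm <- rep("temporal_pair", nrow(events))
  for (g in unique(pd)) {
    idx <- which(pd == g)
    arm[idx[sample.int(length(idx), 1)]] <- "event_recall"
  }
  data.frame(events[, c("participant_id", "day_index", "event_index")],
             test_arm = arm, stringsAsFactors = FALSE)
}

#' @export
#' @method print synthetic_diary
print.synthetic_diary <- function(x, ...) {
  cat("Synthetic diary dataset (with ground truth)\n")
  print(x$dataset)
  cat(sprintf("  truth: latent dim %d; rss slopes (new/periodic/routine) = %s\n",
              ncol(x$truth$embeddings),
              paste(format(x$truth$coefficients$rss_slopes, digits = 3),
                    collapse = "/")))
  invisible(x)
}
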