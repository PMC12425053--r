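# Event-level relative-novelty scores.
#
# All three scores are strictly within-participant:
#   RSS  -- relative semantic similarity: for event i, the mean cosine
#           similarity between its text embedding and the embeddings of every
#           OTHER event the same participant reported. Low RSS = semantically
#           novel.
#   RES  -- relative emotion similarity: the inverse of the mean Euclidean
#           distance between event i's 7-dimensional emotion-rating vector and
#           every other such vector from the participant. Low RES = emotionally
#           distinctive. Higher values of both scores mean greater similarity,
#           i.e. less novelty.
#   stability -- cosine similarity between the embedding of the diary-phase
#           description and the embedding of the delayed free recall.
# Self-pairs are always excluded from the averages.

#' Relative semantic similarity (RSS) for one participant
#'
#' For each of a participant's events, the mean pairwise cosine similarity to
#' all other events by the same participant (leave-self-out).
#'
#' @param embeddings numeric matrix, one row per event (>= 2 rows), in event
#'   order.
#' @return numeric vector of per-event RSS values in `[-1, 1]`.
#' @export
compute_rss <- function(embeddings) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (n < 2L) {
    nd_metric_error("RSS is undefined for a participant with fewer than 2 events (got %d)", n)
  }
  en <- unit_rows(embeddings)
  cs <- tcrossprod(en)
  unname((rowSums(cs) - diag(cs)) / (n - 1))
}

#' Relative emotion similarity (RES) for one participant
#'
#' For each event, the mean Euclidean distance between its emotion-rating
#' vector and every other event's vector from the same participant is taken,
#' and inverted: `1 / dbar` (default) or the bounded variant `1 / (1 + dbar)`.
#' When every other vector is identical to event i (`dbar = 0`) the reciprocal
#' transform returns an `Inf` infinite-similarity sentinel with a warning;
#' model-fitting code excludes such rows listwise.
#'
#' @param emotions numeric matrix, one row per event (>= 2 rows), one column
#'   per rating (the diary protocol uses 7 ratings on a 1--5 scale, used raw).
#' @param transform `"reciprocal"` (default) or `"shifted_reciprocal"`.
#' @return numeric vector of per-event RES values (positive; possibly `Inf`
#'   sentinels under `"reciprocal"`).
#' @export
compute_res <- function(emotions, transform = c("reciprocal", "shifted_reciprocal")) {
  transform <- match.arg(transform)
  emotions <- as.matrix(emotions)
  n <- nrow(emotions)
  if (n < 2L) {
    nd_metric_error("RES is undefined for a participant with fewer than 2 events (got %d)", n)
  }
  if (!all(is.finite(emotions))) nd_domain_error("emotion vectors must be finite")
  d <- as.matrix(stats::dist(emotions))
  dbar <- unname(rowSums(d) / (n - 1))
  if (transform == "reciprocal") {
    res <- ifelse(dbar == 0, Inf, 1 / dbar)
    if (any(dbar == 0)) {
      warning(sprintf("%d event(s) with zero mean emotion distance: RES set to the infinite-similarity sentinel (Inf)",
                      sum(dbar == 0)), call. = FALSE)
    }
  } else {
    res <- 1 / (1 + dbar)
  }
  res
}

#' Encoding-to-recall memory stability for one event
#'
#' Cosine similarity between the embedding of the diary-phase description and
#' the embedding of the delayed free-recall text.
#'
#' @param description diary-phase event description (non-empty).
#' @param recall_text delayed free-recall text; an error if missing, since
#'   stability is defined only for events tested in the free-recall arm.
#' @param spec an [embedder_spec()].
#' @return a number in `[-1, 1]`.
#' @export
compute_stability <- function(description, recall_text, spec = embedder_spec()) {
  if (length(recall_text) != 1L || is.na(recall_text) ||
      normalize_text(recall_text) == "") {
    nd_metric_error("memory stability is undefined without a recall text")
  }
  emb <- embed_texts(c(description, recall_text), spec)
  cosine_similarity(emb[1, ], emb[2, ])
}

#' Compute the per-event metrics table for a whole dataset
#'
#' Runs RSS, RES and (when free-recall texts or recall embeddings are present)
#' memory stability for every participant, strictly within participant.
#' Participants with fewer than 2 events get `NA` metrics and a warning.
#'
#' Embeddings are taken from `embeddings`/`recall_embeddings` when supplied
#' (rows keyed to events by `participant_id:day_index:event_index` rownames,
#' e.g. the latent vectors of a synthetic dataset); otherwise descriptions and
#' recall texts are embedded with `embedder`.
#'
#' @param dataset a `diary_dataset`.
#' @param embedder an [embedder_spec()]; used when embeddings are not supplied.
#' @param res_transform passed to [compute_res()].
#' @param embeddings optional numeric matrix of event embeddings with event-key
#'   rownames.
#' @param recall_embeddings optional numeric matrix of recall embeddings with
#'   event-key rownames (free-recall events only).
#' @param details if `TRUE`, score free-recall texts for episodic detail with
#'   [score_details()] and append the per-category counts.
#' @return data.frame with one row per event: identifiers, `regularity`,
#'   `vividness` (if recalls present), `rss`, `res`, `stability`, and detail
#'   count columns when `details = TRUE`.
#' @export
compute_metrics <- function(dataset, embedder = embedder_spec(),
                            res_transform = c("reciprocal", "shifted_reciprocal"),
                            embeddings = NULL, recall_embeddings = NULL,
                            details = FALSE) {
  stopifnot(inherits(dataset, "diary_dataset"))
  res_transform <- match.arg(res_transform)
  ev <- dataset$events
  key <- event_key(ev$participant_id, ev$day_index, ev$event_index)

  if (is.null(embeddings)) {
    embeddings <- embed_texts(ev$description, embedder)
    rownames(embeddings) <- key
  } else {
    embeddings <- as.matrix(embeddings)
    if (is.null(rownames(embeddings)) || !all(key %in% rownames(embeddings))) {
      nd_domain_error("supplied embeddings must carry event-key rownames covering every event")
    }
    embeddings <- embeddings[key, , drop = FALSE]
  }

  out <- data.frame(participant_id = ev$participant_id,
                    day_index = ev$day_index,
                    event_index = ev$event_index,
                    regularity = ev$regularity,
                    rss = NA_real_, res = NA_real_, stability = NA_real_,
                    stringsAsFactors = FALSE)

  few <- character(0)
  for (pid in unique(ev$participant_id)) {
    idx <- which(ev$participant_id == pid)
    if (length(idx) < 2L) { few <- c(few, pid); next }
    out$rss[idx] <- compute_rss(embeddings[idx, , drop = FALSE])
    out$res[idx] <- compute_res(as.matrix(ev[idx, EMOTION_NAMES]), res_transform)
  }
  if (length(few)) {
    warning(sprintf("RSS/RES undefined (left NA) for participant(s) with < 2 events: %s",
                    paste(few, collapse = ", ")), call. = FALSE)
  }

  rc <- dataset$recalls
  if (!is.null(rc)) {
    rkey <- event_key(rc$participant_id, rc$day_index, rc$event_index)
    out$vividness <- rc$vividness[match(key, rkey)]
    tested <- rc[rc$test_arm == "event_recall", , drop = FALSE]
    tkey <- event_key(tested$participant_id, tested$day_index, tested$event_index)
    if (nrow(tested)) {
      if (!is.null(recall_embeddings)) {
        # latent path: both sides are supplied vectors in the same space
        recall_embeddings <- as.matrix(recall_embeddings)
        if (is.null(rownames(recall_embeddings)) ||
            !all(tkey %in% rownames(recall_embeddings))) {
          nd_domain_error("recall_embeddings must carry event-key rownames covering every free-recall event")
        }
        enc <- unit_rows(embeddings[tkey, , drop = FALSE])
        rec <- unit_rows(recall_embeddings[tkey, , drop = FALSE])
      } else {
        # text path: embed description and recall with the same embedder
        desc <- dataset$events$description[match(tkey, key)]
        enc <- unit_rows(embed_texts(desc, embedder))
        rec <- unit_rows(embed_texts(tested$recall_text, embedder))
      }
      stab <- rowSums(enc * rec)
      out$stability[match(tkey, key)] <- stab
    }
    if (details) {
      counts <- score_details(tested$recall_text)
      for (col in c(DETAIL_CATEGORIES, "total_episodic")) {
        out[[col]] <- NA_integer_
        out[[col]][match(tkey, key)] <- counts[[col]]
      }
    }
  }
  class(out) <- c("event_metrics", "data.frame")
  out
}
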