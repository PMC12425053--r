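# Independent oracles, deliberately written as naive double loops and
# textbook formulas so they share no code with the package implementation.

brute_cosine <- function(a, b) {
  dot <- 0; na <- 0; nb <- 0
  for (k in seq_along(a)) {
    dot <- dot + a[k] * b[k]
    na <- na + a[k]^2
    nb <- nb + b[k]^2
  }
  dot / (sqrt(na) * sqrt(nb))
}

brute_rss <- function(emb) {
  n <- nrow(emb)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (j != i) acc <- acc + brute_cosine(emb[i, ], emb[j, ])
    }
    out[i] <- acc / (n - 1)
  }
  out
}

brute_res <- function(emo, transform = "reciprocal") {
  n <- nrow(emo)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (j != i) acc <- acc + sqrt(sum((emo[i, ] - emo[j, ])^2))
    }
    dbar <- acc / (n - 1)
    out[i] <- if (transform == "reciprocal") {
      if (dbar == 0) Inf else 1 / dbar
    } else 1 / (1 + dbar)
  }
  out
}

# independent re-derivation of the hashing embedder from its documented
# algorithm: polynomial hash mod 2^31-1 of lower-cased word unigrams and
# adjacent bigrams, signed bucket counts
brute_hash <- function(s, mult) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * mult + ch) %% 2147483647
  h
}

brute_embed_one <- function(text, dimension) {
  text <- gsub("[[:space:]]+", " ", trimws(text))
  words <- strsplit(tolower(text), "[^a-z0-9']+")[[1]]
  words <- words[nzchar(words)]
  feats <- words
  if (length(words) > 1L) {
    for (k in seq_len(length(words) - 1L)) {
      feats <- c(feats, paste0(words[k], "_", words[k + 1L]))
    }
  }
  v <- numeric(dimension)
  for (f in feats) {
    idx <- brute_hash(f, 31) %% dimension + 1
    sgn <- if (brute_hash(f, 131) %% 2 == 0) 1 else -1
    v[idx] <- v[idx] + sgn
  }
  v
}

brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# classical Tukey HSD on a balanced one-way layout: pairwise mean differences
# with SE = sqrt(2 * MSE / n_per_group) and p from the studentized range
brute_tukey_hsd <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g)
  npg <- table(g)[1]
  means <- tapply(y, g, mean)
  mse <- sum((y - ave(y, g))^2) / (length(y) - k)
  dfres <- length(y) - k
  pairs <- utils::combn(levels(g), 2)
  data.frame(
    level_a = pairs[1, ], level_b = pairs[2, ],
    estimate = means[pairs[1, ]] - means[pairs[2, ]],
    se = sqrt(2 * mse / npg),
    p = ptukey(abs(means[pairs[1, ]] - means[pairs[2, ]]) /
                 sqrt(mse / npg), k, dfres, lower.tail = FALSE),
    row.names = NULL
  )
}

# random orthogonal matrix via QR of a Gaussian matrix
random_orthogonal <- function(d) {
  qr.Q(qr(matrix(rnorm(d * d), d, d)))
}

# minimal valid tables for I/O tests
make_events_df <- function(n = 3, pid = "P01") {
  data.frame(
    participant_id = pid,
    day_index = seq_len(n),
    event_index = 1L,
    title = paste("event", seq_len(n)),
    description = paste("I walked the dog on day", seq_len(n)),
    regularity = rep(c("new", "periodic", "routine"), length.out = n),
    happy = 3L, positive = 4L, sad = 1L, negative = 2L,
    excited = 3L, calm = 5L, afraid = 1L,
    stringsAsFactors = FALSE
  )
}

make_recalls_df <- function(events, recall_day = 1L) {
  data.frame(
    participant_id = events$participant_id,
    day_index = events$day_index,
    event_index = events$event_index,
    vividness = 4L,
    recall_text = ifelse(events$day_index == recall_day,
                         "I walked the dog again.", NA_character_),
    test_arm = ifelse(events$day_index == recall_day,
                      "event_recall", "temporal_pair"),
    stringsAsFactors = FALSE
  )
}
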