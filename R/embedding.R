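# Text-embedding contract and similarity primitives.
#
# Two backends sit behind one contract:
#  * hashing_reference -- a deterministic, download-free bag-of-ngrams hashing
#    projector. Tokens (lower-cased words) and adjacent word bigrams are hashed
#    into `dimension` signed buckets. Fully reproducible across processes from
#    (dimension, text) alone; no RNG involved.
#  * pretrained_sbert -- a placeholder for a sentence-transformer model (the
#    768-dimensional "all-mpnet-base-v2" is the conventional choice for
#    paragraph-level diary text). This backend needs an externally supplied
#    encoder function; without one it fails loudly, never silently falling
#    back.
#
# Every downstream metric is defined on arbitrary real vectors, so the choice
# of backend changes numbers but not code paths.

#' Describe an embedding backend
#'
#' @param backend `"hashing_reference"` (default; deterministic, offline) or
#'   `"pretrained_sbert"` (requires `encoder`).
#' @param model_name model identifier, used for provenance only by the hashing
#'   backend. Default `"all-mpnet-base-v2"`.
#' @param dimension embedding dimension; defaults to 256 for the hashing
#'   backend and 768 for the pretrained backend.
#' @param encoder optional function `function(texts) -> numeric matrix` with
#'   one row per text, injected for the pretrained backend.
#' @return An object of class `embedder_spec`.
#' @export
embedder_spec <- function(backend = c("hashing_reference", "pretrained_sbert"),
                          model_name = "all-mpnet-base-v2",
                          dimension = NULL, encoder = NULL) {
  backend <- match.arg(backend)
  if (is.null(dimension)) {
    dimension <- if (backend == "hashing_reference") 256L else 768L
  }
  if (!is_whole(dimension) || dimension < 2L) {
    nd_domain_error("embedding dimension must be an integer >= 2")
  }
  if (!is.null(encoder) && !is.function(encoder)) {
    nd_domain_error("encoder must be a function(texts) -> matrix")
  }
  structure(list(backend = backend, model_name = model_name,
                 dimension = as.integer(dimension), encoder = encoder),
            class = "embedder_spec")
}

#' @export
#' @method print embedder_spec
print.embedder_spec <- function(x, ...) {
  cat(sprintf("Embedder: %s (%s), dimension %d\n",
              x$backend, x$model_name, x$dimension))
  invisible(x)
}

# 31-multiplier polynomial string hash mod (2^31 - 1); pure double arithmetic,
# exact because intermediates stay below 2^53.
hash_string <- function(s, mult) {
  b <- utf8ToInt(s)
  h <- 0
  for (ch in b) h <- (h * mult + ch) %% 2147483647
  h
}

hashing_features <- function(text) {
  words <- strsplit(tolower(text), "[^a-z0-9']+")[[1]]
  words <- words[nzchar(words)]
  if (length(words) == 0L) return(character(0))
  feats <- words
  if (length(words) > 1L) {
    feats <- c(feats, paste(words[-length(words)], words[-1], sep = "_"))
  }
  feats
}

hashing_embed <- function(texts, dimension) {
  # memoize feature hashes across the batch
  cache <- new.env(parent = emptyenv())
  feat_vec <- function(feat) {
    hit <- cache[[feat]]
    if (!is.null(hit)) return(hit)
    idx <- hash_string(feat, 31) %% dimension + 1L
    sign <- if (hash_string(feat, 131) %% 2 == 0) 1 else -1
    val <- c(idx, sign)
    cache[[feat]] <- val
    val
  }
  out <- matrix(0, nrow = length(texts), ncol = dimension)
  for (i in seq_along(texts)) {
    for (feat in hashing_features(texts[i])) {
      hv <- feat_vec(feat)
      out[i, hv[1]] <- out[i, hv[1]] + hv[2]
    }
  }
  out
}

#' Embed a batch of texts
#'
#' Returns one embedding per input text, in input order, as the rows of a
#' numeric matrix. Identical texts yield identical vectors; for the
#' `hashing_reference` backend this holds across calls and across processes.
#'
#' @param texts character vector; every element must be non-empty after
#'   whitespace normalization.
#' @param spec an [embedder_spec()].
#' @return numeric matrix, `length(texts)` rows by `spec$dimension` columns.
#' @export
embed_texts <- function(texts, spec = embedder_spec()) {
  stopifnot(inherits(spec, "embedder_spec"))
  texts <- normalize_text(texts)
  bad <- which(is.na(texts) | texts == "")
  if (length(bad)) {
    nd_domain_error("text %d is empty after normalization; cannot embed", bad[1])
  }
  if (spec$backend == "hashing_reference") {
    emb <- hashing_embed(texts, spec$dimension)
  } else {
    if (is.null(spec$encoder)) {
      nd_backend_error(paste(
        "pretrained_sbert backend has no encoder available in this session;",
        "inject one via embedder_spec(encoder = ...) or use the",
        "'hashing_reference' backend"))
    }
    emb <- spec$encoder(texts)
    emb <- as.matrix(emb)
    if (nrow(emb) != length(texts) || ncol(emb) != spec$dimension) {
      nd_backend_error("encoder returned a %dx%d matrix; expected %dx%d",
                       nrow(emb), ncol(emb), length(texts), spec$dimension)
    }
  }
  if (!all(is.finite(emb))) nd_backend_error("embedding contains non-finite entries")
  emb
}

#' Cosine similarity of two vectors
#'
#' `a . b / (|a| |b|)`: symmetric, scale-invariant, in `[-1, 1]`. Undefined
#' (and an error) when either vector has zero norm.
#'
#' @param a,b numeric vectors of equal length.
#' @return a number in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    nd_domain_error("vectors differ in dimension (%d vs %d)", length(a), length(b))
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    nd_domain_error("cosine similarity requires finite vectors")
  }
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) {
    nd_domain_error("cosine similarity is undefined for a zero-norm vector")
  }
  sum(a * b) / (na * nb)
}

# row-normalize to unit length; errors on zero rows
unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  zero <- which(nrm == 0)
  if (length(zero)) {
    nd_domain_error("embedding %d has zero norm; cosine undefined", zero[1])
  }
  m / nrm
}
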