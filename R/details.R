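# Autobiographical-Interview-style episodic detail scoring.
#
# A narrative is segmented into clause-level chunks, each chunk is assigned
# exactly one category -- event, place, time, thought_emotion, perceptual or
# non_episodic -- and category counts are tallied. The shipped backend
# (rule_reference) is a transparent, versioned cue lexicon with fixed category
# precedence; an external scorer (e.g. an LLM) can be injected behind the same
# contract as the llm_adapter backend. Agreement between two scorers is the
# Pearson correlation of their total-episodic counts, the same validation
# statistic used when checking automated scoring against human raters.

default_lexicon_path <- function() {
  system.file("extdata", "detail_lexicon_v1.txt", package = "noveltydiary",
              mustWork = TRUE)
}

parse_sectioned_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  version <- NA_character_
  vline <- grep("^version:", lines)
  if (length(vline)) version <- trimws(sub("^version:", "", lines[vline[1]]))
  sections <- list()
  current <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, "version:")) next
    if (grepl("^\\[.+\\]$", ln)) {
      current <- sub("^\\[(.+)\\]$", "\\1", ln)
      sections[[current]] <- character(0)
    } else if (!is.null(current)) {
      sections[[current]] <- c(sections[[current]], ln)
    }
  }
  attr(sections, "version") <- version
  sections
}

#' Read a cue lexicon for detail categorization
#'
#' The plain-text format has one lower-case cue word per line, grouped under
#' `[category]` section headers; a `version:` header line records the lexicon
#' version, which is attached to every scoring result.
#'
#' @param path lexicon file; defaults to the shipped version-1 lexicon.
#' @return named list of character cue vectors, one per category, with a
#'   `"version"` attribute.
#' @export
read_lexicon <- function(path = NULL) {
  if (is.null(path)) path <- default_lexicon_path()
  if (!file.exists(path)) nd_io_error("lexicon file not found: %s", path)
  lex <- parse_sectioned_file(path)
  missing <- setdiff(setdiff(DETAIL_CATEGORIES, "non_episodic"), names(lex))
  if (length(missing)) {
    nd_schema_error("lexicon is missing section(s): %s", paste(missing, collapse = ", "))
  }
  lapply_names <- names(lex)
  lex[lapply_names] <- lapply(lex[lapply_names], tolower)
  lex
}

# category precedence when several cue sets fire on one chunk
CATEGORY_PRECEDENCE <- c("place", "time", "perceptual", "thought_emotion", "event")

CLAUSE_BOUNDARY_RE <- paste0(
  "(,\\s+(and|but|so|or|then)\\s+(i|we|he|she|they|it|you)\\b)",
  "|(,\\s+(i|we|he|she|they|it|you)\\b)",
  "|(\\s(and|but|so|or|then)\\s+(i|we|he|she|they|it|you)\\b)")

#' Segment a narrative into clause-level chunks
#'
#' Deterministic segmentation: the text is split after sentence terminators
#' (`.`, `!`, `?`), and within sentences before a coordinating conjunction
#' (and/but/so/or/then) or comma that introduces a finite clause (i.e. is
#' followed by a subject pronoun). Spans are 0-based, half-open character
#' offsets into the source; they are ordered, non-overlapping, and jointly
#' cover all non-whitespace source text.
#'
#' @param text a single non-empty narrative.
#' @return data.frame with columns `start`, `end` (0-based half-open offsets)
#'   and `text` (the trimmed span).
#' @export
segment_text <- function(text) {
  if (length(text) != 1L || is.na(text) || normalize_text(text) == "") {
    nd_domain_error("cannot segment an empty narrative")
  }
  text <- as.character(text)
  n <- nchar(text)
  cuts <- integer(0)
  m <- gregexpr("[.!?]+[\"')]*", text)[[1]]
  if (m[1] != -1L) cuts <- c(cuts, as.integer(m) + attr(m, "match.length") - 1L)
  m <- gregexpr(CLAUSE_BOUNDARY_RE, text, ignore.case = TRUE)[[1]]
  if (m[1] != -1L) cuts <- c(cuts, as.integer(m) - 1L)  # split before the match
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < n]))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)

  out <- data.frame(start = integer(0), end = integer(0), text = character(0),
                    stringsAsFactors = FALSE)
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    piece <- substr(text, s, e)
    lead <- nchar(piece) - nchar(sub("^\\s+", "", piece))
    trail <- nchar(piece) - nchar(sub("\\s+$", "", piece))
    s2 <- s + lead; e2 <- e - trail
    if (s2 > e2) next  # whitespace-only span
    out <- rbind(out, data.frame(start = s2 - 1L, end = e2,
                                 text = substr(text, s2, e2),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

chunk_tokens <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9']+")[[1]]
  toks[nzchar(toks)]
}

#' Categorize segmented chunks
#'
#' The `rule_reference` backend assigns each chunk the highest-precedence
#' category whose cue lexicon contains at least one of the chunk's word
#' tokens (precedence place > time > perceptual > thought_emotion > event);
#' a chunk firing no cues is `non_episodic`. The `llm_adapter` backend
#' delegates to an injected `scorer` function with the same contract.
#'
#' @param chunks data.frame from [segment_text()].
#' @param backend `"rule_reference"` or `"llm_adapter"`.
#' @param scorer for `llm_adapter`: `function(texts) -> character` of category
#'   labels.
#' @param lexicon a lexicon from [read_lexicon()].
#' @return `chunks` with a `category` column added; the lexicon version is
#'   attached as attribute `"lexicon_version"`.
#' @export
categorize_chunks <- function(chunks, backend = c("rule_reference", "llm_adapter"),
                              scorer = NULL, lexicon = read_lexicon()) {
  backend <- match.arg(backend)
  stopifnot(is.data.frame(chunks), "text" %in% names(chunks))
  if (backend == "llm_adapter") {
    if (is.null(scorer)) {
      nd_backend_error("llm_adapter backend requires an injected scorer function")
    }
    cats <- as.character(scorer(chunks$text))
    bad <- which(!(cats %in% DETAIL_CATEGORIES))
    if (length(bad)) nd_backend_error("scorer returned unknown category '%s'", cats[bad[1]])
    chunks$category <- cats
    attr(chunks, "lexicon_version") <- NA_character_
    return(chunks)
  }
  chunks$category <- vapply(chunks$text, function(txt) {
    toks <- chunk_tokens(txt)
    for (cat in CATEGORY_PRECEDENCE) {
      if (any(toks %in% lexicon[[cat]])) return(cat)
    }
    "non_episodic"
  }, character(1), USE.NAMES = FALSE)
  attr(chunks, "lexicon_version") <- attr(lexicon, "version")
  chunks
}

#' Tally detail counts from categorized chunks
#'
#' @param chunks data.frame with a `category` column.
#' @return one-row data.frame of per-category counts plus `total_episodic`
#'   (sum of the five episodic categories).
#' @export
detail_counts <- function(chunks) {
  stopifnot("category" %in% names(chunks))
  tab <- table(factor(chunks$category, levels = DETAIL_CATEGORIES))
  out <- as.data.frame(as.list(tab))
  names(out) <- DETAIL_CATEGORIES
  out$total_episodic <- sum(tab[EPISODIC_CATEGORIES])
  out[] <- lapply(out, as.integer)
  out
}

#' Score narratives for episodic detail
#'
#' Segments and categorizes each narrative and returns per-category detail
#' counts. Deterministic and idempotent for the `rule_reference` backend.
#'
#' @param texts character vector of narratives.
#' @param backend,scorer,lexicon passed to [categorize_chunks()].
#' @return data.frame, one row per narrative, with the six category-count
#'   columns and `total_episodic`; lexicon version in attribute
#'   `"lexicon_version"`.
#' @export
score_details <- function(texts, backend = c("rule_reference", "llm_adapter"),
                          scorer = NULL, lexicon = read_lexicon()) {
  backend <- match.arg(backend)
  rows <- lapply(texts, function(txt) {
    ch <- categorize_chunks(segment_text(txt), backend = backend,
                            scorer = scorer, lexicon = lexicon)
    detail_counts(ch)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "lexicon_version") <- attr(lexicon, "version")
  out
}

#' Agreement between two scorers
#'
#' Pearson product-moment correlation between two per-item series of
#' total-episodic detail counts (e.g. an automated scorer against human
#' raters on the same items).
#'
#' @param counts_a,counts_b numeric vectors of equal length >= 3, each with
#'   nonzero variance.
#' @return object of class `agreement_result`: list with `pearson_r` and
#'   `n_items`.
#' @export
detail_agreement <- function(counts_a, counts_b) {
  counts_a <- as.numeric(counts_a); counts_b <- as.numeric(counts_b)
  if (length(counts_a) != length(counts_b)) {
    nd_domain_error("count series differ in length (%d vs %d)",
                    length(counts_a), length(counts_b))
  }
  if (length(counts_a) < 3L) {
    nd_domain_error("agreement needs at least 3 items (got %d)", length(counts_a))
  }
  if (stats::var(counts_a) == 0 || stats::var(counts_b) == 0) {
    nd_domain_error("agreement is undefined when a count series has zero variance")
  }
  structure(list(pearson_r = stats::cor(counts_a, counts_b),
                 n_items = length(counts_a)),
            class = "agreement_result")
}

#' @export
#' @method print agreement_result
print.agreement_result <- function(x, ...) {
  cat(sprintf("Scorer agreement: r = %.3f over %d items\n", x$pearson_r, x$n_items))
  invisible(x)
}
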