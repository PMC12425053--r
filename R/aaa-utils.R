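# shared internal helpers

#' Normalize free text
#'
#' Trims leading/trailing whitespace and collapses internal whitespace runs to
#' a single space. Case is preserved (downstream embedders may be
#' case-sensitive).
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
normalize_text <- function(x) {
  x <- as.character(x)
  gsub("[[:space:]]+", " ", trimws(x))
}

# classed condition constructors; every user-facing failure goes through one of
# these so callers can branch on condition class.
nd_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "nd_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

nd_schema_error      <- function(msg, ...) nd_stop("nd_schema_error", msg, ...)
nd_validation_error  <- function(msg, ...) nd_stop("nd_validation_error", msg, ...)
nd_referential_error <- function(msg, ...) nd_stop("nd_referential_error", msg, ...)
nd_domain_error      <- function(msg, ...) nd_stop("nd_domain_error", msg, ...)
nd_metric_error      <- function(msg, ...) nd_stop("nd_metric_error", msg, ...)
nd_backend_error     <- function(msg, ...) nd_stop("nd_backend_error", msg, ...)
nd_spec_error        <- function(msg, ...) nd_stop("nd_spec_error", msg, ...)
nd_io_error          <- function(msg, ...) nd_stop("nd_io_error", msg, ...)

# event key used to join events, recalls and metrics
event_key <- function(participant_id, day_index, event_index) {
  paste(participant_id, day_index, event_index, sep = ":")
}

is_whole <- function(x) {
  is.numeric(x) & is.finite(x) & (x == floor(x))
}

EMOTION_NAMES <- c("happy", "positive", "sad", "negative", "excited", "calm", "afraid")
REGULARITY_LEVELS <- c("new", "periodic", "routine")
DETAIL_CATEGORIES <- c("event", "place", "time", "thought_emotion", "perceptual",
                       "non_episodic")
EPISODIC_CATEGORIES <- DETAIL_CATEGORIES[1:5]
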