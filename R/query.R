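#' @title Tag-based event search and epoching
#' @description Queries are boolean combinations of tag terms. A term
#'   matches an event when any of the event's tags resolves to the term's
#'   path or to a descendant of it (subtree matching on path components),
#'   searching inside groups including the Event-context group. Matching
#'   events anchor epoch windows for time-locked analysis.
#' @name hed-query
NULL

#' Parse a tag query
#'
#' Mini-language: tag terms (short or long form, optionally `ns:`-prefixed
#' or carrying a `/value`), parentheses, and the keywords `AND`, `OR`,
#' `NOT` (case-insensitive). `AND` binds tighter than `OR`; `NOT` is a
#' prefix operator.
#'
#' @param text Query text, e.g. `"Sensory-event AND (Red OR Green)"`.
#' @return A `hed_query` expression tree.
#' @export
parse_query <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  src <- gsub("([()])", " \\1 ", text)
  tokens <- strsplit(trimws(src), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) {
    hed_error("PARSE_ERROR", "empty query")
  }
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else ""
  take <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  is_kw <- function(t, kw) toupper(t) == kw
  parse_or <- function() {
    left <- parse_and()
    while (is_kw(peek(), "OR")) {
      take()
      left <- list(op = "or", left = left, right = parse_and())
    }
    left
  }
  parse_and <- function() {
    left <- parse_unary()
    while (is_kw(peek(), "AND")) {
      take()
      left <- list(op = "and", left = left, right = parse_unary())
    }
    left
  }
  parse_unary <- function() {
    t <- peek()
    if (is_kw(t, "NOT")) {
      take()
      return(list(op = "not", operand = parse_unary()))
    }
    if (t == "(") {
      take()
      inner <- parse_or()
      if (peek() != ")") {
        hed_error("PARSE_ERROR", "unbalanced parentheses in query")
      }
      take()
      return(inner)
    }
    if (t == "" || t == ")" || is_kw(t, "AND") || is_kw(t, "OR")) {
      hed_error("PARSE_ERROR",
                sprintf("expected a tag term, found '%s'", t))
    }
    take()
    list(op = "term", term = t)
  }
  q <- parse_or()
  if (pos <= length(tokens)) {
    hed_error("PARSE_ERROR",
              sprintf("unexpected token '%s' after query", tokens[pos]))
  }
  structure(q, class = "hed_query")
}

# Resolve every TERM leaf once; errors on unresolvable terms.
resolve_query <- function(q, schemas) {
  schemas <- as_schema_set(schemas)
  rec <- function(node) {
    if (node$op == "term") {
      res <- resolve_tag_info(schemas, node$term)
      if (!res$ok) {
        hed_error("TAG_NOT_FOUND",
                  sprintf("query term '%s': %s", node$term, res$detail))
      }
      node$path <- if (nzchar(res$ns)) paste0(res$ns, ":", res$path) else res$path
      node$value <- res$value
      return(node)
    }
    if (node$op == "not") {
      node$operand <- rec(node$operand)
    } else {
      node$left <- rec(node$left)
      node$right <- rec(node$right)
    }
    node
  }
  structure(rec(unclass(q)), class = "hed_query")
}

# Resolved (path, value) pairs for every tag of an event annotation.
event_tag_paths <- function(event, schemas, include_context = TRUE) {
  tags <- flatten_tags(event$annotation, include_context = include_context)
  out <- list()
  for (t in tags) {
    res <- resolve_tag_info(schemas, t$text)
    if (!res$ok) next
    path <- if (nzchar(res$ns)) paste0(res$ns, ":", res$path) else res$path
    out[[length(out) + 1]] <- list(path = tolower(path),
                                   value = tolower(res$value))
  }
  out
}

term_hits <- function(paths, qpath, qvalue) {
  qpath <- tolower(qpath)
  any(vapply(paths, function(p) {
    if (nzchar(qvalue)) {
      p$path == qpath && p$value == tolower(qvalue)
    } else {
      p$path == qpath || startsWith(p$path, paste0(qpath, "/"))
    }
  }, logical(1)))
}

eval_query <- function(q, paths) {
  switch(q$op,
         term = term_hits(paths, q$path, q$value),
         and = eval_query(q$left, paths) && eval_query(q$right, paths),
         or = eval_query(q$left, paths) || eval_query(q$right, paths),
         not = !eval_query(q$operand, paths),
         stop("unknown query op"))
}

#' Test whether one event matches a query
#'
#' A term matches when any tag's long path equals the term's resolved path
#' or lies in its subtree. A term carrying a value (`Label/target`)
#' requires an exact value match instead. Matching searches inside groups,
#' including the Event-context group unless `include_context = FALSE`.
#'
#' @param event One assembled event (an element of
#'   `hed_assembled$events`), ideally with definitions and context
#'   expanded.
#' @param q A `hed_query` from [parse_query()], or query text.
#' @param schemas A `hed_schema` or `hed_schema_set`.
#' @param include_context Search inside Event-context groups (default yes;
#'   set to `FALSE` to restrict matching to an event's direct annotation).
#' @return `TRUE` or `FALSE`.
#' @export
query_matches <- function(event, q, schemas, include_context = TRUE) {
  schemas <- as_schema_set(schemas)
  if (is.character(q)) q <- parse_query(q)
  q <- resolve_query(q, schemas)
  eval_query(q, event_tag_paths(event, schemas, include_context))
}

#' Search assembled events by tag query
#'
#' @param assembled A `hed_assembled` (or list of assembled events),
#'   in onset order.
#' @inheritParams query_matches
#' @return Integer positions (in onset order) of the matching events.
#' @export
search_events <- function(assembled, q, schemas, include_context = TRUE) {
  events <- if (inherits(assembled, "hed_assembled")) assembled$events else assembled
  schemas <- as_schema_set(schemas)
  if (is.character(q)) q <- parse_query(q)
  q <- resolve_query(q, schemas)
  hits <- vapply(events, function(ev) {
    eval_query(q, event_tag_paths(ev, schemas, include_context))
  }, logical(1))
  which(hits)
}

#' Extract time-locked epoch windows around selected events
#'
#' Each window is `[anchor - pre, anchor + post]`, clipped conceptually to
#' the recording span: windows extending beyond the span are flagged and
#' dropped rather than truncated. Only time windows are returned; slicing
#' signal arrays is downstream of the annotation layer.
#'
#' @param assembled A `hed_assembled` (or list of assembled events).
#' @param hits Integer positions of anchor events, e.g. from
#'   [search_events()].
#' @param pre,post Seconds before/after the anchor (both `>= 0`,
#'   `pre + post > 0`).
#' @param record_span Two-element numeric, the recording's time span.
#' @return A list with `windows` (data frame `anchor`, `onset`, `start`,
#'   `end` of kept windows) and `dropped` (same shape, windows that
#'   crossed the span boundary).
#' @export
extract_epochs <- function(assembled, hits, pre, post, record_span) {
  events <- if (inherits(assembled, "hed_assembled")) assembled$events else assembled
  stopifnot(pre >= 0, post >= 0, pre + post > 0,
            length(record_span) == 2, record_span[1] <= record_span[2])
  stopifnot(all(hits >= 1 & hits <= length(events)))
  onsets <- vapply(events[hits], `[[`, numeric(1), "onset")
  df <- data.frame(anchor = as.integer(hits), onset = onsets,
                   start = onsets - pre, end = onsets + post,
                   stringsAsFactors = FALSE)
  ok <- df$start >= record_span[1] & df$end <= record_span[2]
  list(windows = df[ok, , drop = FALSE],
       dropped = df[!ok, , drop = FALSE])
}
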