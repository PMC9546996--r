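#' @title HED string objects
#' @description A HED string annotates one event: a comma-separated list of
#'   tags and parenthesized tag groups; groups bind modifiers to the items
#'   they modify and nest to arbitrary depth. Parsing is purely structural —
#'   no schema is consulted until validation or conversion.
#' @name hed-string
NULL

hed_tag <- function(text, span = c(NA_integer_, NA_integer_)) {
  structure(list(text = text, span = as.integer(span)), class = "hed_tag")
}

hed_group <- function(members, span = c(NA_integer_, NA_integer_)) {
  structure(list(members = members, span = as.integer(span)),
            class = "hed_group")
}

hed_string <- function(members) {
  structure(list(members = members), class = "hed_string")
}

is_tag <- function(x) inherits(x, "hed_tag")
is_group <- function(x) inherits(x, "hed_group")

#' Parse a HED annotation string
#'
#' Structure-preserving parse of the comma/parenthesis grammar. Whitespace
#' (including newlines and tabs) around separators is ignored. Empty tags
#' (`",,"`, trailing commas, `"()"`) and unbalanced parentheses are errors,
#' not silently dropped.
#'
#' @param text A single annotation string.
#' @return A `hed_string`: an ordered list of `hed_tag` / `hed_group`
#'   members, each carrying its character span in the input.
#' @examples
#' s <- parse_hed("Sensory-event, ((Triangle, Red), (Square, Green))")
#' format(s)
#' @export
parse_hed <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  src <- gsub("[\t\n\r]", " ", text)
  n <- nchar(src)
  if (!nzchar(trimws(src))) {
    hed_error("EMPTY_TAG", "empty annotation string", span = c(1L, n))
  }
  pos <- 1L
  peek <- function() if (pos <= n) substr(src, pos, pos) else ""
  skip_ws <- function() {
    while (pos <= n && substr(src, pos, pos) == " ") pos <<- pos + 1L
  }
  parse_sequence <- function(depth, open_at) {
    members <- list()
    repeat {
      skip_ws()
      item_start <- pos
      ch <- peek()
      if (ch == "(") {
        open <- pos
        pos <<- pos + 1L
        inner <- parse_sequence(depth + 1L, open)
        skip_ws()
        if (peek() != ")") {
          hed_error("UNBALANCED_PARENS",
                    sprintf("group opened at position %d is never closed", open),
                    span = c(open, n))
        }
        pos <<- pos + 1L
        if (length(inner) == 0) {
          hed_error("EMPTY_TAG",
                    sprintf("empty group at position %d", open),
                    span = c(open, pos - 1L))
        }
        members[[length(members) + 1L]] <- hed_group(inner, c(open, pos - 1L))
      } else if (ch == ")" || ch == "," || ch == "") {
        hed_error("EMPTY_TAG",
                  sprintf("empty tag at position %d", item_start),
                  span = c(item_start, item_start))
      } else {
        start <- pos
        while (pos <= n && !substr(src, pos, pos) %in% c(",", "(", ")")) {
          pos <<- pos + 1L
        }
        if (peek() == "(") {
          hed_error("UNBALANCED_PARENS",
                    sprintf("unexpected '(' at position %d: missing ','", pos),
                    span = c(pos, pos))
        }
        tag_text <- trimws(substr(src, start, pos - 1L))
        members[[length(members) + 1L]] <-
          hed_tag(tag_text, c(start, pos - 1L))
      }
      skip_ws()
      ch <- peek()
      if (ch == ",") {
        pos <<- pos + 1L
        next
      }
      if (ch == ")") {
        if (depth == 0L) {
          hed_error("UNBALANCED_PARENS",
                    sprintf("unmatched ')' at position %d", pos),
                    span = c(pos, pos))
        }
        return(members)
      }
      if (ch == "") {
        if (depth > 0L) {
          hed_error("UNBALANCED_PARENS",
                    sprintf("group opened at position %d is never closed",
                            open_at),
                    span = c(open_at, n))
        }
        return(members)
      }
    }
  }
  hed_string(parse_sequence(0L, 0L))
}

# Non-throwing parse: structural errors become an issue table.
parse_hed_safely <- function(text) {
  tryCatch(
    list(string = parse_hed(text), issues = hed_issues()),
    hedkit_error = function(e) {
      span <- if (is.null(e$span)) c(NA_integer_, NA_integer_) else e$span
      list(string = NULL,
           issues = hed_issue_row(e$code, severity = "error", span = span,
                                  detail = conditionMessage(e)))
    }
  )
}

# ---- serialization --------------------------------------------------------

#' @export
format.hed_tag <- function(x, ...) x$text

#' @export
format.hed_group <- function(x, ...) {
  paste0("(", paste(vapply(x$members, format, character(1)), collapse = ", "),
         ")")
}

#' @export
format.hed_string <- function(x, ...) {
  paste(vapply(x$members, format, character(1)), collapse = ", ")
}

#' @export
as.character.hed_string <- function(x, ...) format(x)

#' @export
print.hed_string <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
print.hed_group <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# ---- traversal helpers ----------------------------------------------------

# Apply `fn` to every tag, preserving structure. `fn` receives the hed_tag
# and must return a hed_tag (or list of members to splice when splice = TRUE).
map_tags <- function(x, fn) {
  rec <- function(m) {
    if (is_tag(m)) return(fn(m))
    m$members <- lapply(m$members, rec)
    m
  }
  if (is_tag(x)) return(fn(x))
  x$members <- lapply(x$members, rec)
  x
}

# All tags in document order. When `include_context` is FALSE, groups whose
# first tag resolves to Event-context are skipped (used by search).
flatten_tags <- function(x, include_context = TRUE) {
  out <- list()
  rec <- function(m) {
    if (is_tag(m)) {
      out[[length(out) + 1L]] <<- m
    } else {
      if (!include_context && is_context_group(m)) return()
      for (mm in m$members) rec(mm)
    }
  }
  for (m in x$members) rec(m)
  out
}

is_context_group <- function(g) {
  if (!is_group(g) || length(g$members) == 0) return(FALSE)
  first <- g$members[[1]]
  is_tag(first) && grepl("(^|/|:)event-context$", tolower(first$text))
}

# Deep copy with spans dropped (used when splicing generated structure).
strip_spans <- function(x) {
  rec <- function(m) {
    m$span <- c(NA_integer_, NA_integer_)
    if (is_group(m)) m$members <- lapply(m$members, rec)
    m
  }
  if (is_tag(x) || is_group(x)) return(rec(x))
  x$members <- lapply(x$members, rec)
  x
}
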