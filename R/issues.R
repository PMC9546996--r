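#' @title Issue records and error conditions
#' @description Internal helpers shared by the schema linter, the string
#'   validator, and the assembly pipeline. Issues are plain data frames so
#'   they can be row-bound, filtered, and serialized as JSON-lines; hard
#'   failures are signalled as classed conditions carrying a machine-readable
#'   `code`.
#' @name hedkit-issues
#' @keywords internal
NULL

# Canonical empty issue table; every producer returns this shape.
hed_issues <- function(code = character(), severity = character(),
                       path = character(), span_start = integer(),
                       span_end = integer(), detail = character()) {
  n <- max(length(code), length(severity), length(path),
           length(span_start), length(span_end), length(detail))
  rep_len0 <- function(x, default) {
    if (length(x) == 0 && n > 0) rep(default, n) else rep_len(x, max(n, 0))
  }
  data.frame(
    code = rep_len0(code, NA_character_),
    severity = rep_len0(severity, "error"),
    path = rep_len0(path, NA_character_),
    span_start = rep_len0(span_start, NA_integer_),
    span_end = rep_len0(span_end, NA_integer_),
    detail = rep_len0(detail, NA_character_),
    stringsAsFactors = FALSE
  )
}

hed_issue_row <- function(code, severity = "error", path = NA_character_,
                          span = c(NA_integer_, NA_integer_),
                          detail = NA_character_) {
  hed_issues(code = code, severity = severity, path = path,
             span_start = as.integer(span[1]), span_end = as.integer(span[2]),
             detail = detail)
}

bind_issues <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(parts) == 0) return(hed_issues())
  do.call(rbind, parts)
}

# Classed condition so callers can test on `code` (e.g. PARSE_ERROR,
# DUPLICATE_TERM, TAG_NOT_FOUND) rather than matching message text.
hed_error <- function(code, detail, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("hedkit_", tolower(code)), "hedkit_error",
              "error", "condition"),
    list(message = sprintf("[%s] %s", code, detail), call = call,
         code = code, ...)
  )
  stop(cond)
}

#' Serialize an issue table as JSON-lines
#'
#' One JSON object per issue with stable field order
#' (`code`, `severity`, `span`, `detail`), the diff-friendly report format
#' used by the command-line tools.
#'
#' @param issues An issue data frame as returned by [validate_string()],
#'   [check_uniqueness()] or [lint_structure()].
#' @param path Optional file to write to; when `NULL` the lines are returned.
#' @return A character vector of JSON lines, invisibly when written to file.
#' @export
issues_to_json <- function(issues, path = NULL) {
  lines <- vapply(seq_len(nrow(issues)), function(i) {
    rec <- list(
      code = issues$code[i],
      severity = issues$severity[i],
      span = c(issues$span_start[i], issues$span_end[i]),
      detail = if (is.na(issues$detail[i])) "" else issues$detail[i]
    )
    if (!is.na(issues$path[i])) rec$path <- issues$path[i]
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null")
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

has_errors <- function(issues) {
  nrow(issues) > 0 && any(issues$severity == "error")
}
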