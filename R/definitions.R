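#' @title Named definitions
#' @description Definitions let annotators register lab-jargon names for
#'   reusable tag groups once — `(Definition/ScreenSetup, (...))` — and then
#'   reference them as `Def/ScreenSetup`. At analysis time the reference is
#'   replaced by a `(Def-expand/ScreenSetup, (...))` group so the inserted
#'   tags keep their association with the definition. A definition whose
#'   contents contain a `#` placeholder takes a value:
#'   `Def/Name/value` substitutes the value for `#` in the copy.
#' @name hed-definitions
NULL

new_definitions <- function(defs = list()) {
  structure(list(defs = defs), class = "hed_definitions")
}

#' @export
print.hed_definitions <- function(x, ...) {
  cat(sprintf("<hed_definitions> %d definition(s)\n", length(x$defs)))
  for (d in x$defs) {
    cat(sprintf("  %s%s: %s\n", d$name, if (d$takes_value) "/#" else "",
                format(d$contents)))
  }
  invisible(x)
}

# Tag-text patterns for the definition machinery; they work on raw text so
# that definitions can be collected before any schema resolution, matching
# both short and long forms.
match_machinery <- function(text, kind) {
  m <- regmatches(tolower(text),
                  regexec(sprintf("(^|/)%s/(.*)$", kind), tolower(text)))[[1]]
  if (length(m) == 0) return(NULL)
  rest <- strsplit(m[3], "/", fixed = TRUE)[[1]]
  if (length(rest) == 0 || !nzchar(rest[1])) return(NULL)
  # recover original casing of name/value from the tail of the raw text
  tail_raw <- strsplit(text, "/", fixed = TRUE)[[1]]
  tail_raw <- tail_raw[(length(tail_raw) - length(rest) + 1):length(tail_raw)]
  list(name = tail_raw[1],
       value = if (length(rest) > 1) paste(tail_raw[-1], collapse = "/") else "")
}

is_machinery_tag <- function(text, kind) {
  grepl(sprintf("(^|/)%s(/|$)", kind), tolower(text))
}

contents_signature <- function(group) {
  tolower(canonical_members(group$members))
}

#' Collect definitions from a set of HED strings
#'
#' Scans every group of shape `(Definition/Name, (contents))` — at any
#' nesting level — and registers it. Name matching is case-insensitive;
#' registering the same definition twice identically is a no-op, while the
#' same name with different contents is a `DEF_DUPLICATE` error.
#'
#' @param strings A list of `hed_string` objects and/or character
#'   annotations (each parsed first).
#' @param defs An existing `hed_definitions` to add to.
#' @return A list with `defs` (a `hed_definitions`) and `issues`.
#' @examples
#' res <- collect_definitions("(Definition/Fix, (Visual-presentation))")
#' names(res$defs$defs)
#' @export
collect_definitions <- function(strings, defs = new_definitions()) {
  if (inherits(strings, "hed_string") || is.character(strings)) {
    strings <- as.list(strings)
  }
  issues <- hed_issues()
  register <- function(g) {
    def_tags <- Filter(function(m) is_tag(m) &&
                         is_machinery_tag(m$text, "definition"), g$members)
    if (length(def_tags) == 0) return(FALSE)
    others <- Filter(function(m) !(is_tag(m) &&
                                     is_machinery_tag(m$text, "definition")),
                     g$members)
    ok <- TRUE
    if (length(def_tags) > 1) {
      issues <<- bind_issues(issues, hed_issue_row(
        "DEF_SYNTAX", span = g$span,
        detail = "multiple Definition tags in one group"))
      ok <- FALSE
    }
    ref <- match_machinery(def_tags[[1]]$text, "definition")
    if (is.null(ref)) {
      issues <<- bind_issues(issues, hed_issue_row(
        "DEF_SYNTAX", span = def_tags[[1]]$span,
        detail = "Definition requires a name (Definition/Name)"))
      return(TRUE)
    }
    if (length(others) != 1 || !is_group(others[[1]])) {
      issues <<- bind_issues(issues, hed_issue_row(
        "DEF_SYNTAX", span = g$span,
        detail = sprintf("definition '%s' must have exactly one inner tag group",
                         ref$name)))
      return(TRUE)
    }
    contents <- strip_spans(others[[1]])
    for (t in flatten_tags(hed_string(list(contents)))) {
      if (is_machinery_tag(t$text, "definition") ||
          is_machinery_tag(t$text, "def") ||
          is_machinery_tag(t$text, "def-expand")) {
        issues <<- bind_issues(issues, hed_issue_row(
          "DEF_SYNTAX", span = g$span,
          detail = sprintf("definition '%s' contents may not contain '%s'",
                           ref$name, t$text)))
        ok <- FALSE
      }
    }
    if (!ok) return(TRUE)
    key <- tolower(ref$name)
    takes_value <- any(vapply(flatten_tags(hed_string(list(contents))),
                              function(t) grepl("#", t$text, fixed = TRUE),
                              logical(1))) || identical(ref$value, "#")
    entry <- list(name = ref$name, contents = contents,
                  takes_value = takes_value)
    existing <- defs$defs[[key]]
    if (!is.null(existing)) {
      if (contents_signature(existing$contents) != contents_signature(contents)) {
        issues <<- bind_issues(issues, hed_issue_row(
          "DEF_DUPLICATE", span = g$span,
          detail = sprintf("definition '%s' registered twice with different contents",
                           ref$name)))
      }
    } else {
      defs$defs[[key]] <<- entry
    }
    TRUE
  }
  walk <- function(members) {
    for (m in members) {
      if (is_group(m)) {
        register(m)
        walk(m$members)
      }
    }
  }
  for (s in strings) {
    if (is.character(s)) s <- parse_hed(s)
    walk(s$members)
  }
  list(defs = defs, issues = issues)
}

substitute_placeholder <- function(x, value) {
  map_tags(x, function(t) {
    t$text <- gsub("#", value, t$text, fixed = TRUE)
    t
  })
}

#' Expand Def references into Def-expand groups
#'
#' Every `Def/Name` tag is replaced by the group
#' `(Def-expand/Name, (contents))`, a copy of the definition's contents
#' with the `Def-expand` marker retaining the association with the
#' definition. For value-taking definitions, `Def/Name/value` substitutes
#' the value for `#` in the copy. Expansion is non-recursive (definition
#' contents may not reference definitions) and idempotent; the input is
#' not modified.
#'
#' @param s A `hed_string` or annotation text.
#' @param defs A `hed_definitions` from [collect_definitions()].
#' @return The expanded `hed_string`.
#' @export
expand_defs <- function(s, defs) {
  if (is.character(s)) s <- parse_hed(s)
  stopifnot(inherits(defs, "hed_definitions"))
  expand_member <- function(m) {
    if (is_group(m)) {
      m$members <- lapply(m$members, expand_member)
      return(m)
    }
    ref <- if (is_machinery_tag(m$text, "def") ) match_machinery(m$text, "def") else NULL
    if (is.null(ref)) return(m)
    entry <- defs$defs[[tolower(ref$name)]]
    if (is.null(entry)) {
      hed_error("DEF_UNDEFINED",
                sprintf("reference to undefined name '%s'", ref$name),
                span = m$span)
    }
    if (entry$takes_value && !nzchar(ref$value)) {
      hed_error("DEF_SYNTAX",
                sprintf("definition '%s' takes a value; use Def/%s/<value>",
                        entry$name, entry$name), span = m$span)
    }
    if (!entry$takes_value && nzchar(ref$value)) {
      hed_error("DEF_SYNTAX",
                sprintf("definition '%s' does not take a value", entry$name),
                span = m$span)
    }
    contents <- entry$contents
    marker <- paste0("Def-expand/", entry$name)
    if (nzchar(ref$value)) {
      contents <- substitute_placeholder(contents, ref$value)
      marker <- paste0(marker, "/", ref$value)
    }
    hed_group(list(hed_tag(marker), contents))
  }
  s$members <- lapply(s$members, expand_member)
  s
}

#' Contract Def-expand groups back to Def references
#'
#' Inverse of [expand_defs()]: each `(Def-expand/Name, (contents))` group
#' whose contents match the registered definition is replaced by the
#' original `Def/Name` reference. Groups whose contents do not match any
#' known definition are left untouched.
#'
#' @inheritParams expand_defs
#' @return The contracted `hed_string`.
#' @export
contract_defs <- function(s, defs) {
  if (is.character(s)) s <- parse_hed(s)
  contract_member <- function(m) {
    if (!is_group(m)) return(m)
    m$members <- lapply(m$members, contract_member)
    exp_tags <- Filter(function(x) is_tag(x) &&
                         is_machinery_tag(x$text, "def-expand"), m$members)
    if (length(exp_tags) != 1 || length(m$members) != 2) return(m)
    inner <- Filter(is_group, m$members)
    if (length(inner) != 1) return(m)
    ref <- match_machinery(exp_tags[[1]]$text, "def-expand")
    if (is.null(ref)) return(m)
    entry <- defs$defs[[tolower(ref$name)]]
    if (is.null(entry)) return(m)
    expected <- entry$contents
    if (nzchar(ref$value)) {
      expected <- substitute_placeholder(expected, ref$value)
    }
    if (contents_signature(inner[[1]]) != contents_signature(expected)) return(m)
    txt <- paste0("Def/", entry$name,
                  if (nzchar(ref$value)) paste0("/", ref$value) else "")
    hed_tag(txt)
  }
  s$members <- lapply(s$members, contract_member)
  s
}

# Remove definition-declaration groups from an annotation (declarations are
# not event content). Returns the stripped string; may be empty.
strip_definition_groups <- function(s) {
  keep <- Filter(function(m) {
    !(is_group(m) && any(vapply(m$members, function(x)
      is_tag(x) && is_machinery_tag(x$text, "definition"), logical(1))))
  }, s$members)
  hed_string(keep)
}

#' Read a definitions file
#'
#' A definitions file holds one HED string per line, each containing one or
#' more `(Definition/Name, (contents))` groups. Blank lines and lines
#' starting with `#` are skipped.
#'
#' @param path File path.
#' @param defs Existing `hed_definitions` to extend.
#' @return As [collect_definitions()].
#' @export
read_definitions <- function(path, defs = new_definitions()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  collect_definitions(as.list(lines), defs)
}
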