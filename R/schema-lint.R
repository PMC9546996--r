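#' Check the unique-mapping rule
#'
#' Every vocabulary term may appear at no more than one position in a
#' schema; this is what lets short-form tags resolve unambiguously.
#' Matching is case-insensitive, so `red` and `Red` under different parents
#' count as the same term. Load the schema with `permissive = TRUE` to lint
#' a schema that violates the rule.
#'
#' @param schema A `hed_schema`.
#' @return An issue data frame with one `DUPLICATE_TERM` error per
#'   duplicated term, listing all paths at which it occurs.
#' @export
check_uniqueness <- function(schema) {
  out <- hed_issues()
  # brute-force recount from the tree rather than trusting the index
  occurrences <- new.env(parent = emptyenv())
  walk <- function(node, prefix) {
    path <- if (nzchar(prefix)) paste(prefix, node$term, sep = "/") else node$term
    if (node$term != "#") {
      key <- tolower(node$term)
      assign(key, c(mget(key, occurrences, ifnotfound = list(NULL))[[1]], path),
             envir = occurrences)
    }
    for (ch in node$children) walk(ch, path)
  }
  for (r in schema$roots) walk(r, "")
  for (key in sort(ls(occurrences))) {
    paths <- get(key, envir = occurrences)
    if (length(paths) > 1) {
      out <- bind_issues(out, hed_issue_row(
        "DUPLICATE_TERM", severity = "error", path = paths[1],
        detail = sprintf("term '%s' occurs at %d paths: %s", key,
                         length(paths), paste(paths, collapse = "; "))
      ))
    }
  }
  out
}

#' Lint schema structure for sparsity
#'
#' Menu-usability guidance caps sub-categories at fewer than `max_children`
#' items, ideally within `ideal_range`. Nodes at or above the cap get a
#' `TOO_MANY_CHILDREN` warning; non-leaf nodes outside the ideal range get
#' an informational `SPARSITY_NOTE` (severity `"note"`).
#'
#' @param schema A `hed_schema`.
#' @param max_children Warning threshold: a node with this many or more
#'   children is flagged (default 10, i.e. "fewer than 10" passes).
#' @param ideal_range Two-element numeric, the ideal child-count band.
#' @return An issue data frame.
#' @export
lint_structure <- function(schema, max_children = 10, ideal_range = c(3, 7)) {
  out <- hed_issues()
  for (path in names(schema$nodes)) {
    info <- schema$nodes[[path]]
    n_kids <- length(info$children)
    if (n_kids >= max_children) {
      out <- bind_issues(out, hed_issue_row(
        "TOO_MANY_CHILDREN", severity = "warning", path = info$path,
        detail = sprintf("%d children (guideline: fewer than %d)",
                         n_kids, max_children)
      ))
    } else if (n_kids > 0 &&
               (n_kids < ideal_range[1] || n_kids > ideal_range[2])) {
      out <- bind_issues(out, hed_issue_row(
        "SPARSITY_NOTE", severity = "note", path = info$path,
        detail = sprintf("%d children (ideal range %d-%d)",
                         n_kids, ideal_range[1], ideal_range[2])
      ))
    }
  }
  out
}

# Term-character and description lint, used by the full lint pass.
lint_terms <- function(schema) {
  out <- hed_issues()
  for (path in names(schema$nodes)) {
    info <- schema$nodes[[path]]
    if (info$term != "#" && !grepl("^[A-Za-z0-9][A-Za-z0-9-]*$", info$term)) {
      out <- bind_issues(out, hed_issue_row(
        "BAD_TERM_CHARS", severity = "error", path = info$path,
        detail = sprintf("term '%s' contains characters outside [A-Za-z0-9-]",
                         info$term)
      ))
    }
    if (info$term != "#" && !nzchar(info$description)) {
      out <- bind_issues(out, hed_issue_row(
        "EMPTY_DESCRIPTION", severity = "note", path = info$path,
        detail = "node has no description"
      ))
    }
  }
  out
}

#' Full schema lint
#'
#' Combines [check_uniqueness()], [lint_structure()], and term-character /
#' empty-description checks into one report.
#'
#' @inheritParams lint_structure
#' @return An issue data frame.
#' @export
lint_schema <- function(schema, max_children = 10, ideal_range = c(3, 7)) {
  bind_issues(check_uniqueness(schema),
              lint_structure(schema, max_children, ideal_range),
              lint_terms(schema))
}

#' Schema summary counts
#'
#' @param schema A `hed_schema`.
#' @return A list with `n_top_level` (number of top-level categories),
#'   `children_per_top_level` (named integer vector of second-level counts),
#'   and `n_total` (all nodes, including `#` placeholders).
#' @examples
#' schema_stats(load_schema(hed_example_schema_path()))
#' @export
schema_stats <- function(schema) {
  n_total <- 0L
  count <- function(node) {
    n_total <<- n_total + 1L
    for (ch in node$children) count(ch)
  }
  for (r in schema$roots) count(r)
  kids <- vapply(schema$roots, function(r) length(r$children), integer(1))
  names(kids) <- vapply(schema$roots, `[[`, "", "term")
  list(n_top_level = length(schema$roots),
       children_per_top_level = kids,
       n_total = n_total)
}
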