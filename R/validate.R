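#' @title HED string validation
#' @name hed-validate
#' @description Validation checks an annotation against a vocabulary:
#'   every tag must resolve, values must sit under `#` placeholders, units
#'   must belong to the placeholder's unit class, duplicate tags within a
#'   group are flagged, `Def/Name` references must be known, and
#'   `Definition` groups must be well formed. All issues are returned, not
#'   just the first.
NULL

# Is this resolved tag one of the special definition-machinery tags?
special_term <- function(res) {
  tolower(utils::tail(strsplit(res$path, "/", fixed = TRUE)[[1]],
                      if (nzchar(res$value)) 1 else 1))
}

path_terminal <- function(path) {
  tolower(utils::tail(strsplit(path, "/", fixed = TRUE)[[1]], 1))
}

def_names <- function(defs) {
  if (is.null(defs)) return(character(0))
  if (inherits(defs, "hed_definitions")) return(names(defs$defs))
  tolower(defs)
}

check_units <- function(res, tag, schemas) {
  if (!nzchar(res$value) || is.null(res$value_node)) return(hed_issues())
  uc_name <- res$value_node$attributes$unitClass
  if (is.null(uc_name)) {
    if (nzchar(res$units)) {
      return(hed_issue_row("INVALID_UNITS", span = tag$span,
                           detail = sprintf("'%s' has no unit class but units '%s' given",
                                            res$path, res$units)))
    }
    return(hed_issues())
  }
  schemas <- as_schema_set(schemas)
  schema <- if (nzchar(res$ns)) schemas$libraries[[res$ns]] else schemas$base
  uc <- schema$unit_classes[[uc_name]]
  out <- hed_issues()
  if (nzchar(res$units) && (is.null(uc) || !res$units %in% uc$units)) {
    out <- bind_issues(out, hed_issue_row(
      "INVALID_UNITS", span = tag$span,
      detail = sprintf("units '%s' not in unit class '%s' (%s)", res$units,
                       uc_name,
                       if (is.null(uc)) "unknown class" else paste(uc$units, collapse = ", "))))
  }
  if (res$value != "#" && is.na(suppressWarnings(as.numeric(res$value)))) {
    out <- bind_issues(out, hed_issue_row(
      "INVALID_UNITS", span = tag$span,
      detail = sprintf("value '%s' for unit class '%s' is not numeric",
                       res$value, uc_name)))
  }
  out
}

#' Validate a HED string against a schema set
#'
#' @param s A `hed_string` (see [parse_hed()]); use [validate_hed()] to go
#'   straight from text, folding parse failures into the issue table.
#' @param schemas A `hed_schema` or `hed_schema_set`.
#' @param defs Known definition names: a character vector or a
#'   `hed_definitions` object. `Def/Name` references outside this set are
#'   reported as `DEF_UNDEFINED`.
#' @return An issue data frame (`code`, `severity`, `span_start`,
#'   `span_end`, `detail`); zero rows means the string is clean.
#' @examples
#' schemas <- hed_schemas(load_schema(hed_example_schema_path()))
#' validate_string(parse_hed("Sensory-event, Red"), schemas)
#' @export
validate_string <- function(s, schemas, defs = character(0)) {
  stopifnot(inherits(s, "hed_string"))
  schemas <- as_schema_set(schemas)
  known <- def_names(defs)
  out <- hed_issues()

  check_members <- function(members, in_group) {
    # duplicate detection is per group (top level counts as one group)
    long_texts <- character(0)
    spans <- list()
    for (m in members) {
      if (is_group(m)) {
        out <<- bind_issues(out, check_definition_group(m))
        check_members(m$members, TRUE)
        next
      }
      res <- resolve_tag_info(schemas, m$text)
      if (!res$ok) {
        code <- if (res$code == "INVALID_PARENT") "TAG_NOT_FOUND" else res$code
        out <<- bind_issues(out, hed_issue_row(
          code, span = m$span, detail = sprintf("%s: %s", m$text, res$detail)))
        next
      }
      out <<- bind_issues(out, check_units(res, m, schemas))
      if (res$is_extension) {
        out <<- bind_issues(out, hed_issue_row(
          "EXTENSION_WARNING", severity = "warning", span = m$span,
          detail = sprintf("'%s' extends the schema below an extensionAllowed node",
                           m$text)))
      }
      term <- path_terminal(res$path)
      if (term == "def") {
        if (!nzchar(res$value)) {
          out <<- bind_issues(out, hed_issue_row(
            "DEF_SYNTAX", span = m$span,
            detail = "Def requires a definition name (Def/Name)"))
        } else {
          name <- tolower(strsplit(res$value, "/", fixed = TRUE)[[1]][1])
          if (!name %in% known) {
            out <<- bind_issues(out, hed_issue_row(
              "DEF_UNDEFINED", span = m$span,
              detail = sprintf("reference to undefined name '%s'", name)))
          }
        }
      }
      if (term == "definition" && !in_group) {
        out <<- bind_issues(out, hed_issue_row(
          "DEF_SYNTAX", span = m$span,
          detail = "Definition tag must appear inside a tag group"))
      }
      lt <- tolower(resolved_long_text(res))
      dup_at <- which(long_texts == lt)
      if (length(dup_at) > 0) {
        out <<- bind_issues(out, hed_issue_row(
          "DUPLICATE_TAG_IN_GROUP", severity = "warning", span = m$span,
          detail = sprintf("tag '%s' repeated within one group", m$text)))
      }
      long_texts <- c(long_texts, lt)
      spans[[length(spans) + 1]] <- m$span
    }
  }

  check_definition_group <- function(g) {
    # a group containing a Definition tag must be exactly
    # (Definition/Name, (contents)); contents free of Def machinery
    iss <- hed_issues()
    def_tags <- Filter(function(m) {
      if (!is_tag(m)) return(FALSE)
      res <- resolve_tag_info(schemas, m$text)
      res$ok && path_terminal(res$path) == "definition"
    }, g$members)
    if (length(def_tags) == 0) return(iss)
    inner_groups <- Filter(is_group, g$members)
    if (length(def_tags) > 1) {
      iss <- bind_issues(iss, hed_issue_row(
        "DEF_SYNTAX", span = g$span,
        detail = "multiple Definition tags in one group"))
    }
    if (length(inner_groups) != 1 ||
        length(g$members) != length(def_tags) + length(inner_groups)) {
      iss <- bind_issues(iss, hed_issue_row(
        "DEF_SYNTAX", span = g$span,
        detail = "Definition group must be (Definition/Name, (contents))"))
    }
    for (ig in inner_groups) {
      for (t in flatten_tags(hed_string(list(ig)))) {
        res <- resolve_tag_info(schemas, t$text)
        if (res$ok &&
            path_terminal(res$path) %in% c("definition", "def", "def-expand")) {
          iss <- bind_issues(iss, hed_issue_row(
            "DEF_SYNTAX", span = t$span,
            detail = sprintf("'%s' may not appear inside definition contents",
                             t$text)))
        }
      }
    }
    iss
  }

  check_members(s$members, FALSE)
  out
}

#' Validate annotation text
#'
#' Convenience wrapper around [parse_hed()] + [validate_string()]: parse
#' failures (unbalanced parentheses, empty tags) are returned as issues
#' rather than raised.
#'
#' @param text Annotation text.
#' @inheritParams validate_string
#' @return An issue data frame.
#' @export
validate_hed <- function(text, schemas, defs = character(0)) {
  parsed <- parse_hed_safely(text)
  if (is.null(parsed$string)) return(parsed$issues)
  validate_string(parsed$string, schemas, defs)
}
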