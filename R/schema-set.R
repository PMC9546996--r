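#' Combine a base schema with namespaced library schemas
#'
#' Library schemas extend the base vocabulary for a research subfield.
#' Lookup is namespace-scoped: a tag prefixed `ns:` resolves only in library
#' `ns`, an unprefixed tag only in the base schema, so term collisions
#' across libraries (or with the base) are legal and never shadow anything.
#'
#' @param base A `hed_schema` (the base vocabulary).
#' @param libs A named list of `hed_schema` objects; names are the
#'   namespace identifiers (non-empty, no colon). May be empty.
#' @return A `hed_schema_set`.
#' @examples
#' base <- load_schema(hed_example_schema_path())
#' schemas <- merge_libraries(base, list())
#' @export
merge_libraries <- function(base, libs = list()) {
  stopifnot(inherits(base, "hed_schema"))
  if (length(libs) > 0) {
    ns <- names(libs)
    if (is.null(ns) || any(!nzchar(ns))) {
      hed_error("DUPLICATE_NAMESPACE",
                "every library needs a non-empty namespace identifier")
    }
    if (any(grepl(":", ns, fixed = TRUE))) {
      hed_error("DUPLICATE_NAMESPACE",
                "namespace identifiers may not contain ':'")
    }
    if (anyDuplicated(ns)) {
      hed_error("DUPLICATE_NAMESPACE",
                sprintf("namespace '%s' registered more than once",
                        ns[duplicated(ns)][1]))
    }
    for (i in seq_along(libs)) {
      dup <- check_uniqueness(libs[[i]])
      if (nrow(dup) > 0) {
        hed_error("DUPLICATE_TERM",
                  sprintf("library '%s' violates unique mapping: %s",
                          ns[i], dup$detail[1]))
      }
    }
  }
  structure(list(base = base, libraries = libs), class = "hed_schema_set")
}

#' @rdname merge_libraries
#' @param ... For `hed_schemas()`, library schemas given as
#'   `namespace = schema` pairs.
#' @export
hed_schemas <- function(base, ...) {
  merge_libraries(base, list(...))
}

as_schema_set <- function(x) {
  if (inherits(x, "hed_schema_set")) return(x)
  if (inherits(x, "hed_schema")) return(merge_libraries(x))
  stop("expected a hed_schema or hed_schema_set")
}

#' @export
print.hed_schema_set <- function(x, ...) {
  cat("<hed_schema_set>\n base: ")
  print(x$base)
  for (ns in names(x$libraries)) {
    cat(sprintf(" library '%s': ", ns))
    print(x$libraries[[ns]])
  }
  invisible(x)
}

# ---- tag resolution -------------------------------------------------------

# Split "ns:rest" only when the colon precedes any slash and the prefix is a
# plausible identifier; values ("Label/a:b") never contain a namespace.
split_namespace <- function(tag_text) {
  m <- regmatches(tag_text, regexec("^([A-Za-z][A-Za-z0-9-]*):(.+)$", tag_text))[[1]]
  if (length(m) == 3 && !grepl("/", m[2], fixed = TRUE)) {
    list(ns = m[2], rest = m[3])
  } else {
    list(ns = "", rest = tag_text)
  }
}

term_lookup <- function(schema, term) {
  hit <- schema$term_index[tolower(term)]
  if (length(hit) == 0 || is.na(hit)) NULL else unname(hit)
}

resolve_failure <- function(code, detail) {
  list(ok = FALSE, code = code, detail = detail)
}

# Core resolver shared by validation, conversion, and search. Returns a list:
#   ok, ns, path (schema casing, no namespace prefix), node (index record),
#   value, units, value_node, is_extension; or ok = FALSE with code/detail.
resolve_tag_info <- function(schemas, tag_text) {
  schemas <- as_schema_set(schemas)
  tag_text <- trimws(tag_text)
  if (!nzchar(tag_text)) return(resolve_failure("TAG_NOT_FOUND", "empty tag"))
  nsr <- split_namespace(tag_text)
  ns <- nsr$ns
  if (nzchar(ns)) {
    if (!ns %in% names(schemas$libraries)) {
      return(resolve_failure(
        "TAG_NOT_FOUND", sprintf("unknown library namespace '%s'", ns)))
    }
    schema <- schemas$libraries[[ns]]
  } else {
    schema <- schemas$base
  }
  segs <- strsplit(nsr$rest, "/", fixed = TRUE)[[1]]
  segs <- trimws(segs)
  if (length(segs) == 0 || any(!nzchar(segs))) {
    return(resolve_failure("TAG_NOT_FOUND",
                           sprintf("malformed tag '%s'", tag_text)))
  }
  anchor <- term_lookup(schema, segs[1])
  if (is.null(anchor)) {
    return(resolve_failure(
      "TAG_NOT_FOUND",
      sprintf("'%s' is not a term in %s", segs[1],
              if (nzchar(ns)) sprintf("library '%s'", ns) else "the base schema")))
  }
  path <- anchor
  info <- schema_node(schema, path)
  value <- ""
  units <- ""
  value_node <- NULL
  is_extension <- FALSE
  i <- 2
  while (i <= length(segs)) {
    seg <- segs[i]
    child_hit <- info$children[tolower(info$children) == tolower(seg)]
    child_hit <- child_hit[child_hit != "#"]
    if (length(child_hit) > 0) {
      path <- paste(path, child_hit[1], sep = "/")
      info <- schema_node(schema, path)
      i <- i + 1
    } else if (!is.na(info$value_child)) {
      value_node <- schema_node(schema, info$value_child)
      value <- paste(segs[i:length(segs)], collapse = "/")
      i <- length(segs) + 1
    } else if (info$ext_allowed) {
      rest <- segs[i:length(segs)]
      bad <- rest[!grepl("^[A-Za-z0-9][A-Za-z0-9-]*$", rest)]
      if (length(bad) > 0) {
        return(resolve_failure(
          "TAG_NOT_FOUND",
          sprintf("extension term '%s' contains invalid characters", bad[1])))
      }
      path <- paste(c(path, rest), collapse = "/")
      is_extension <- TRUE
      i <- length(segs) + 1
    } else if (!is.null(term_lookup(schema, seg))) {
      return(resolve_failure(
        "INVALID_PARENT",
        sprintf("'%s' is not a child of '%s'", seg, path)))
    } else {
      return(resolve_failure(
        "VALUE_WITHOUT_PLACEHOLDER",
        sprintf("'%s' does not take a value (trailing '%s')", path, seg)))
    }
  }
  # split trailing units off the value ("0.5 s") when the placeholder has a
  # unit class; otherwise the whole text is the value
  if (nzchar(value) && !is.null(value_node) &&
      !is.null(value_node$attributes$unitClass) &&
      grepl(" ", value, fixed = TRUE)) {
    parts <- regmatches(value, regexec("^(.*\\S)\\s+(\\S+)$", value))[[1]]
    value <- parts[2]
    units <- parts[3]
  }
  list(ok = TRUE, ns = ns, path = path, node = info, value = value,
       units = units, value_node = value_node, is_extension = is_extension)
}

# Long-form text of a resolved tag, namespace prefix and value preserved.
resolved_long_text <- function(res) {
  out <- res$path
  if (nzchar(res$value)) {
    out <- paste(out, res$value, sep = "/")
    if (nzchar(res$units)) out <- paste(out, res$units)
  }
  if (nzchar(res$ns)) out <- paste0(res$ns, ":", out)
  out
}

# Short-form text: terminal term only (plus value/units, namespace kept).
resolved_short_text <- function(res) {
  term <- utils::tail(strsplit(res$path, "/", fixed = TRUE)[[1]], 1)
  out <- term
  if (nzchar(res$value)) {
    out <- paste(out, res$value, sep = "/")
    if (nzchar(res$units)) out <- paste(out, res$units)
  }
  if (nzchar(res$ns)) out <- paste0(res$ns, ":", out)
  out
}

#' Resolve a (possibly short-form) tag to its full schema path
#'
#' Any partial path from a node name toward its root is a valid short form;
#' under the unique-mapping rule it resolves to exactly one full path.
#' Matching is case-insensitive; the returned path uses the schema's stored
#' casing. A trailing value segment after a value-taking (`#`) node is
#' preserved, as is a `ns:` library namespace prefix.
#'
#' @param schemas A `hed_schema` or `hed_schema_set`.
#' @param tag_text A single tag (no commas or parentheses).
#' @return A list with `path` (full path text, namespace and value
#'   included), `node` (the resolved node record), `value`, `units`, and
#'   `is_extension`.
#' @examples
#' schemas <- hed_schemas(load_schema(hed_example_schema_path()))
#' resolve_tag(schemas, "Visual-presentation")$path
#' @export
resolve_tag <- function(schemas, tag_text) {
  res <- resolve_tag_info(schemas, tag_text)
  if (!res$ok) hed_error(res$code, sprintf("%s: %s", tag_text, res$detail))
  list(path = resolved_long_text(res), node = res$node, value = res$value,
       units = res$units, is_extension = res$is_extension)
}
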