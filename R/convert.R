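#' Expand every tag in a HED string to its full long-form path
#'
#' Under the unique-mapping rule any short form (a node name or partial
#' path) expands to exactly one full path, so the long form is derivable
#' mechanically. Structure, values, units, and library namespace prefixes
#' are preserved; already-long tags are unchanged.
#'
#' @param s A `hed_string` (or annotation text, which is parsed first).
#' @param schemas A `hed_schema` or `hed_schema_set`.
#' @return A `hed_string` with every tag in long form.
#' @examples
#' schemas <- hed_schemas(load_schema(hed_example_schema_path()))
#' format(to_long(parse_hed("Visual-presentation"), schemas))
#' @export
to_long <- function(s, schemas) {
  if (is.character(s)) s <- parse_hed(s)
  schemas <- as_schema_set(schemas)
  map_tags(s, function(tag) {
    res <- resolve_tag_info(schemas, tag$text)
    if (!res$ok) {
      hed_error(res$code, sprintf("%s: %s", tag$text, res$detail),
                span = tag$span)
    }
    hed_tag(resolved_long_text(res), tag$span)
  })
}

#' Reduce every tag in a HED string to its terminal short form
#'
#' Each tag keeps only its final term (plus any value and namespace
#' prefix). `to_long(to_short(x))` equals `to_long(x)`.
#'
#' @inheritParams to_long
#' @return A `hed_string` with every tag in short form.
#' @export
to_short <- function(s, schemas) {
  if (is.character(s)) s <- parse_hed(s)
  schemas <- as_schema_set(schemas)
  map_tags(s, function(tag) {
    res <- resolve_tag_info(schemas, tag$text)
    if (!res$ok) {
      hed_error(res$code, sprintf("%s: %s", tag$text, res$detail),
                span = tag$span)
    }
    hed_tag(resolved_short_text(res), tag$span)
  })
}

# Order-insensitive normal form of a parsed member tree: tags before
# groups, tags sorted case-insensitively, groups by their own canonical
# text. Radix sort keeps the ordering locale-independent.
canonical_members <- function(members) {
  texts <- character(length(members))
  tags <- vapply(members, is_tag, logical(1))
  for (i in seq_along(members)) {
    m <- members[[i]]
    texts[i] <- if (is_tag(m)) {
      m$text
    } else {
      paste0("(", canonical_members(m$members), ")")
    }
  }
  key <- tolower(texts)
  ord <- order(!tags, key, method = "radix")
  paste(texts[ord], collapse = ", ")
}

#' Canonical text of a HED annotation
#'
#' Expands every tag to long form, then sorts members recursively (tags
#' before groups, both lexicographically), so two annotations that differ
#' only in member order — equally valid under the grammar — canonicalize to
#' identical text. This is the form used for equivalence testing.
#'
#' @inheritParams to_long
#' @return A single string, the canonical serialization.
#' @examples
#' schemas <- hed_schemas(load_schema(hed_example_schema_path()))
#' canonical("(Red, Triangle)", schemas) == canonical("(Triangle, Red)", schemas)
#' @export
canonical <- function(s, schemas) {
  long <- to_long(s, schemas)
  canonical_members(long$members)
}
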