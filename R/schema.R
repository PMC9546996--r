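#' @title HED schema objects
#' @description A HED schema is a forest of uniquely named vocabulary nodes.
#'   Nodes may carry attributes: `takesValue` (the node is a `#` value
#'   placeholder), `extensionAllowed`, `unitClass`, `suggestedTag`,
#'   `relatedTag`. The unique-mapping rule — every term appears at exactly
#'   one position in a schema — is what makes short-form annotation
#'   resolvable, so a strict load fails on duplicate terms.
#' @name hed-schema
NULL

LIST_ATTRS <- c("suggestedTag", "relatedTag")
FLAG_ATTRS <- c("takesValue", "extensionAllowed")

new_hed_node <- function(term, description = "", attributes = list(),
                         children = list()) {
  structure(list(term = term, description = description,
                 attributes = attributes, children = children),
            class = "hed_node")
}

new_unit_class <- function(name, units, default_unit = units[1]) {
  stopifnot(default_unit %in% units)
  list(name = name, units = units, default_unit = default_unit)
}

#' Load a HED vocabulary schema
#'
#' Reads a schema from the human-editable wiki dialect or the XML dialect
#' used for machine processing, builds the node tree, and indexes every term
#' for short-form resolution. A strict load fails when the unique-mapping
#' rule is violated; `permissive = TRUE` still builds the tree (and indexes
#' the first occurrence of each duplicated term) so that
#' [check_uniqueness()] can report all violations.
#'
#' Wiki dialect: one node per line, nesting depth given by the number of
#' leading asterisks (one = top level), then the term, optional attributes
#' in braces (`{takesValue, unitClass=time, suggestedTag=A;B}`), optional
#' description in square brackets. An optional header line
#' `HED version="..." library="..."` precedes the nodes, and a
#' `!# unit-classes` section lists unit classes as
#' `* name: unit1, unit2` (first unit is the default).
#'
#' @param source Schema text, a character vector of lines, or a file path
#'   (`.mediawiki` / `.xml`).
#' @param dialect `"wiki"` or `"xml"`. Guessed from the file extension when
#'   `source` is a path.
#' @param permissive Keep going on duplicate terms (for linting).
#' @return A `hed_schema` object.
#' @examples
#' sch <- load_schema(hed_example_schema_path("wiki"))
#' schema_stats(sch)
#' @export
load_schema <- function(source, dialect = c("wiki", "xml"),
                        permissive = FALSE) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    if (missing(dialect)) {
      dialect <- if (grepl("\\.xml$", source, ignore.case = TRUE)) "xml" else "wiki"
    }
    source <- readLines(source, encoding = "UTF-8", warn = FALSE)
    if (identical(dialect, "xml") || identical(dialect[1], "xml")) {
      source <- paste(source, collapse = "\n")
    }
  }
  dialect <- match.arg(dialect)
  parsed <- if (dialect == "wiki") {
    parse_wiki_schema(source)
  } else {
    parse_xml_schema(source)
  }
  build_schema(parsed$roots, name = parsed$name, version = parsed$version,
               unit_classes = parsed$unit_classes, permissive = permissive)
}

# ---- wiki dialect ---------------------------------------------------------

parse_wiki_attrs <- function(text, line_no) {
  out <- list()
  if (!nzchar(text)) return(out)
  for (piece in strsplit(text, ",", fixed = TRUE)[[1]]) {
    piece <- trimws(piece)
    if (!nzchar(piece)) next
    if (grepl("=", piece, fixed = TRUE)) {
      kv <- strsplit(piece, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      if (key %in% LIST_ATTRS) val <- trimws(strsplit(val, ";", fixed = TRUE)[[1]])
      out[[key]] <- val
    } else {
      out[[piece]] <- TRUE
    }
  }
  out
}

parse_wiki_schema <- function(lines) {
  if (length(lines) == 1 && grepl("\n", lines)) {
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  }
  name <- ""
  version <- ""
  unit_classes <- list()
  records <- list()  # (depth, node, line) in document order
  in_units <- FALSE
  for (i in seq_along(lines)) {
    line <- trimws(lines[i], which = "right")
    if (!nzchar(trimws(line))) next
    if (grepl("^HED\\b", line)) {
      m <- regmatches(line, regexec("version=\"([^\"]*)\"", line))[[1]]
      if (length(m) == 2) version <- m[2]
      m <- regmatches(line, regexec("library=\"([^\"]*)\"", line))[[1]]
      if (length(m) == 2) name <- m[2]
      next
    }
    if (grepl("^!#\\s*unit-classes", line)) {
      in_units <- TRUE
      next
    }
    m <- regmatches(line, regexec("^(\\*+)\\s*(.*)$", line))[[1]]
    if (length(m) == 0) {
      hed_error("PARSE_ERROR",
                sprintf("line %d: expected a node line starting with '*'", i),
                line = i)
    }
    body <- m[3]
    if (in_units) {
      um <- regmatches(body, regexec("^([^:]+):\\s*(.+)$", body))[[1]]
      if (length(um) == 0) {
        hed_error("PARSE_ERROR",
                  sprintf("line %d: malformed unit-class line", i), line = i)
      }
      units <- trimws(strsplit(um[3], ",", fixed = TRUE)[[1]])
      cname <- trimws(um[2])
      unit_classes[[cname]] <- new_unit_class(cname, units)
      next
    }
    depth <- nchar(m[2])
    attrs_text <- ""
    desc <- ""
    am <- regmatches(body, regexec("\\{([^}]*)\\}", body))[[1]]
    if (length(am) == 2) {
      attrs_text <- am[2]
      body <- sub("\\{[^}]*\\}", "", body)
    }
    dm <- regmatches(body, regexec("\\[([^]]*)\\]", body))[[1]]
    if (length(dm) == 2) {
      desc <- trimws(dm[2])
      body <- sub("\\[[^]]*\\]", "", body)
    }
    term <- trimws(body)
    if (!nzchar(term)) {
      hed_error("PARSE_ERROR", sprintf("line %d: empty term", i), line = i)
    }
    if (grepl("[,/()]", term)) {
      hed_error("PARSE_ERROR",
                sprintf("line %d: term '%s' contains a structural character",
                        i, term), line = i)
    }
    records[[length(records) + 1]] <- list(
      depth = depth, line = i,
      node = new_hed_node(term, desc, parse_wiki_attrs(attrs_text, i))
    )
  }
  if (length(records) == 0) {
    hed_error("PARSE_ERROR", "schema has no nodes (empty roots list)", line = 0L)
  }
  if (records[[1]]$depth != 1) {
    hed_error("PARSE_ERROR",
              sprintf("line %d: first node must be top level", records[[1]]$line),
              line = records[[1]]$line)
  }
  pos <- 1
  consume_level <- function(depth) {
    out <- list()
    while (pos <= length(records) && records[[pos]]$depth >= depth) {
      rec <- records[[pos]]
      if (rec$depth > depth) {
        hed_error("PARSE_ERROR",
                  sprintf("line %d: nesting depth %d has no parent",
                          rec$line, rec$depth), line = rec$line)
      }
      node <- rec$node
      pos <<- pos + 1
      if (pos <= length(records) && records[[pos]]$depth > depth) {
        node$children <- consume_level(depth + 1)
      }
      out[[length(out) + 1]] <- node
    }
    out
  }
  roots <- consume_level(1)
  list(roots = roots, name = name, version = version,
       unit_classes = unit_classes)
}

# ---- XML dialect ----------------------------------------------------------

parse_xml_node <- function(xnode) {
  term <- xml2::xml_text(xml2::xml_find_first(xnode, "./name"))
  desc_node <- xml2::xml_find_first(xnode, "./description")
  desc <- if (inherits(desc_node, "xml_missing")) "" else xml2::xml_text(desc_node)
  attrs <- list()
  for (a in xml2::xml_find_all(xnode, "./attribute")) {
    key <- xml2::xml_text(xml2::xml_find_first(a, "./name"))
    vals <- xml2::xml_text(xml2::xml_find_all(a, "./value"))
    attrs[[key]] <- if (length(vals) == 0) TRUE else vals
  }
  children <- lapply(xml2::xml_find_all(xnode, "./node"), parse_xml_node)
  new_hed_node(term, desc, attrs, children)
}

parse_xml_schema <- function(text) {
  doc <- tryCatch(xml2::read_xml(paste(text, collapse = "\n")),
                  error = function(e) {
                    hed_error("PARSE_ERROR",
                              paste("malformed XML:", conditionMessage(e)),
                              line = NA_integer_)
                  })
  root <- xml2::xml_root(doc)
  version <- xml2::xml_attr(root, "version")
  name <- xml2::xml_attr(root, "library")
  if (is.na(version)) version <- ""
  if (is.na(name)) name <- ""
  roots <- lapply(xml2::xml_find_all(doc, "/HED/schema/node"), parse_xml_node)
  if (length(roots) == 0) {
    hed_error("PARSE_ERROR", "schema has no nodes (empty roots list)",
              line = NA_integer_)
  }
  unit_classes <- list()
  for (uc in xml2::xml_find_all(doc, "/HED/unitClasses/unitClass")) {
    cname <- xml2::xml_text(xml2::xml_find_first(uc, "./name"))
    units <- xml2::xml_text(xml2::xml_find_all(uc, "./unit"))
    default <- xml2::xml_text(xml2::xml_find_first(uc, "./defaultUnit"))
    unit_classes[[cname]] <- new_unit_class(cname, units, default)
  }
  list(roots = roots, name = name, version = version,
       unit_classes = unit_classes)
}

# ---- indexing -------------------------------------------------------------

# Flatten the forest into lookup tables. Placeholder '#' nodes are indexed
# by path (for value/unit checks) but excluded from the term index: they are
# syntax shared by every takesValue parent, not vocabulary terms.
build_schema <- function(roots, name = "", version = "",
                         unit_classes = list(), permissive = FALSE) {
  nodes <- list()
  term_paths <- list()  # tolower(term) -> character vector of full paths
  walk <- function(node, prefix, ext_inherited) {
    path <- if (nzchar(prefix)) paste(prefix, node$term, sep = "/") else node$term
    ext <- isTRUE(node$attributes$extensionAllowed) || ext_inherited
    if (isTRUE(node$attributes$takesValue) && length(node$children) > 0) {
      hed_error("PARSE_ERROR",
                sprintf("takesValue node '%s' may not have children", path),
                line = NA_integer_)
    }
    child_terms <- vapply(node$children, `[[`, "", "term")
    value_child <- child_terms[vapply(node$children, function(ch)
      isTRUE(ch$attributes$takesValue), logical(1))]
    nodes[[tolower(path)]] <<- list(
      term = node$term, path = path, description = node$description,
      attributes = node$attributes, children = child_terms,
      takes_value = isTRUE(node$attributes$takesValue),
      value_child = if (length(value_child)) paste(path, value_child[1], sep = "/") else NA_character_,
      ext_allowed = ext
    )
    if (node$term != "#") {
      key <- tolower(node$term)
      term_paths[[key]] <<- c(term_paths[[key]], path)
    }
    for (ch in node$children) walk(ch, path, ext)
  }
  for (r in roots) walk(r, "", FALSE)
  dup <- Filter(function(p) length(p) > 1, term_paths)
  if (length(dup) > 0 && !permissive) {
    first <- dup[[1]]
    hed_error("DUPLICATE_TERM",
              sprintf("term occurs at multiple paths: %s",
                      paste(first, collapse = ", ")),
              paths = first)
  }
  term_index <- vapply(term_paths, `[[`, "", 1)
  structure(list(name = name, version = version, roots = roots,
                 nodes = nodes, term_index = term_index,
                 duplicates = dup, unit_classes = unit_classes),
            class = "hed_schema")
}

schema_node <- function(schema, path) schema$nodes[[tolower(path)]]

#' @export
print.hed_schema <- function(x, ...) {
  label <- if (nzchar(x$name)) sprintf("library '%s'", x$name) else "base"
  st <- schema_stats(x)
  cat(sprintf("<hed_schema> %s, version %s: %d top-level categories, %d terms\n",
              label, if (nzchar(x$version)) x$version else "?",
              st$n_top_level, st$n_total))
  counts <- st$children_per_top_level
  cat(paste(sprintf("%s(%d)", names(counts), counts), collapse = ", "), "\n")
  invisible(x)
}

# ---- serialization --------------------------------------------------------

format_wiki_attrs <- function(attributes) {
  if (length(attributes) == 0) return("")
  parts <- vapply(names(attributes), function(key) {
    val <- attributes[[key]]
    if (isTRUE(val)) key else paste0(key, "=", paste(val, collapse = ";"))
  }, character(1))
  paste0(" {", paste(parts, collapse = ", "), "}")
}

#' Serialize a schema to wiki or XML text
#'
#' Inverse of [load_schema()]: `load_schema(serialize_schema(s, d), d)`
#' reproduces the same tree, attributes, and unit classes in either dialect.
#'
#' @param schema A `hed_schema`.
#' @param dialect `"wiki"` or `"xml"`.
#' @param path Optional file to write to.
#' @return The serialized text (single string), invisibly when written.
#' @export
serialize_schema <- function(schema, dialect = c("wiki", "xml"), path = NULL) {
  dialect <- match.arg(dialect)
  text <- if (dialect == "wiki") {
    lines <- character(0)
    header <- sprintf("HED version=\"%s\"", schema$version)
    if (nzchar(schema$name)) {
      header <- paste0(header, sprintf(" library=\"%s\"", schema$name))
    }
    lines <- c(lines, header, "")
    emit <- function(node, depth) {
      desc <- if (nzchar(node$description)) paste0(" [", node$description, "]") else ""
      lines <<- c(lines, paste0(strrep("*", depth), " ", node$term,
                                format_wiki_attrs(node$attributes), desc))
      for (ch in node$children) emit(ch, depth + 1)
    }
    for (r in schema$roots) emit(r, 1)
    if (length(schema$unit_classes) > 0) {
      lines <- c(lines, "", "!# unit-classes")
      for (uc in schema$unit_classes) {
        units <- union(uc$default_unit, uc$units)
        lines <- c(lines, paste0("* ", uc$name, ": ",
                                 paste(units, collapse = ", ")))
      }
    }
    paste(lines, collapse = "\n")
  } else {
    doc <- xml2::xml_new_root("HED", version = schema$version,
                              library = schema$name)
    sch <- xml2::xml_add_child(doc, "schema")
    emit <- function(parent, node) {
      xn <- xml2::xml_add_child(parent, "node")
      xml2::xml_add_child(xn, "name", node$term)
      if (nzchar(node$description)) {
        xml2::xml_add_child(xn, "description", node$description)
      }
      for (key in names(node$attributes)) {
        xa <- xml2::xml_add_child(xn, "attribute")
        xml2::xml_add_child(xa, "name", key)
        val <- node$attributes[[key]]
        if (!isTRUE(val)) for (v in val) xml2::xml_add_child(xa, "value", v)
      }
      for (ch in node$children) emit(xn, ch)
    }
    for (r in schema$roots) emit(sch, r)
    if (length(schema$unit_classes) > 0) {
      ucs <- xml2::xml_add_child(doc, "unitClasses")
      for (uc in schema$unit_classes) {
        xu <- xml2::xml_add_child(ucs, "unitClass")
        xml2::xml_add_child(xu, "name", uc$name)
        xml2::xml_add_child(xu, "defaultUnit", uc$default_unit)
        for (u in uc$units) xml2::xml_add_child(xu, "unit", u)
      }
    }
    as.character(doc)
  }
  if (!is.null(path)) {
    writeLines(text, path, useBytes = TRUE)
    return(invisible(text))
  }
  text
}
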