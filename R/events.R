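#' @title BIDS-style event assembly
#' @description Events files (`_events.tsv`) record onset/duration plus
#'   arbitrary columns; sidecars (`_events.json`) map column values (or `#`
#'   placeholders) to HED strings. Assembly concatenates, per row, the
#'   annotations contributed by each column into one full HED string.
#' @name hed-events
NULL

looks_like_path <- function(x) {
  length(x) == 1 && is.character(x) && !grepl("\n", x) && file.exists(x)
}

#' Read a BIDS-style events table
#'
#' @param src A TSV file path or the TSV text itself. A header row with an
#'   `onset` column (seconds) is required; `duration` and arbitrary other
#'   columns are optional. The missing-value token is `"n/a"`.
#' @return A `hed_event_table` data frame sorted by onset, with numeric
#'   `onset`/`duration`, the original columns as character, and a
#'   `row_index` giving each row's position in the source file.
#' @export
read_events <- function(src) {
  txt <- if (looks_like_path(src)) {
    paste(readLines(src, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  } else {
    paste(src, collapse = "\n")
  }
  df <- utils::read.delim(text = txt, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "",
                          stringsAsFactors = FALSE)
  if (!"onset" %in% names(df)) {
    hed_error("MISSING_ONSET_COLUMN", "events table has no 'onset' column")
  }
  onset <- suppressWarnings(as.numeric(df$onset))
  bad <- which(is.na(onset) | !is.finite(onset) | onset < 0)
  if (length(bad) > 0) {
    hed_error("NON_NUMERIC_ONSET",
              sprintf("row %d: onset '%s' is not a finite non-negative number",
                      bad[1], df$onset[bad[1]]), row = bad[1])
  }
  df$onset <- onset
  if ("duration" %in% names(df)) {
    dur_raw <- df$duration
    dur <- suppressWarnings(as.numeric(dur_raw))
    bad <- which(is.na(dur) & tolower(dur_raw) != "n/a")
    if (length(bad) > 0) {
      hed_error("NON_NUMERIC_DURATION",
                sprintf("row %d: duration '%s' is neither numeric nor 'n/a'",
                        bad[1], dur_raw[bad[1]]), row = bad[1])
    }
    df$duration <- dur
  } else {
    df$duration <- NA_real_
  }
  df$row_index <- seq_len(nrow(df))
  df <- df[order(df$onset, df$row_index), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("hed_event_table", "data.frame")
  df
}

#' Read a JSON sidecar of column annotations
#'
#' Each entry with a `HED` field annotates one table column: a named list
#' of strings is a categorical map (cell value to HED string), a single
#' string containing one `#` is a value-column template (the placeholder is
#' replaced by the cell text), and a string with no `#` is a constant
#' annotation applied to every non-missing cell. Entries without `HED` are
#' kept as metadata.
#'
#' @param src A JSON file path or JSON text.
#' @return A `hed_sidecar`: `entries` (per-column annotation specs) and
#'   `meta` (non-HED entries, e.g. generator provenance).
#' @export
read_sidecar <- function(src) {
  txt <- if (looks_like_path(src)) {
    paste(readLines(src, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  } else {
    paste(src, collapse = "\n")
  }
  raw <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  entries <- list()
  meta <- list()
  for (col in names(raw)) {
    entry <- raw[[col]]
    if (!is.list(entry) || is.null(entry$HED)) {
      meta[[col]] <- entry
      next
    }
    hed <- entry$HED
    if (is.character(hed) && length(hed) == 1) {
      n_hash <- lengths(regmatches(hed, gregexpr("#", hed, fixed = TRUE)))
      if (n_hash > 1) {
        hed_error("MULTIPLE_PLACEHOLDERS",
                  sprintf("column '%s': template contains %d '#' placeholders",
                          col, n_hash), column = col)
      }
      entries[[col]] <- list(
        type = if (n_hash == 1) "value" else "constant",
        template = hed
      )
    } else if (is.list(hed) && !is.null(names(hed)) && all(nzchar(names(hed)))) {
      ok <- vapply(hed, function(v) is.character(v) && length(v) == 1,
                   logical(1))
      if (!all(ok)) {
        hed_error("NON_TEXT_ANNOTATION",
                  sprintf("column '%s': categorical entry '%s' is not a string",
                          col, names(hed)[!ok][1]), column = col)
      }
      entries[[col]] <- list(type = "categorical",
                             map = lapply(hed, as.character))
    } else {
      hed_error("NON_TEXT_ANNOTATION",
                sprintf("column '%s': HED entry must be a string or a named map",
                        col), column = col)
    }
  }
  structure(list(entries = entries, meta = meta), class = "hed_sidecar")
}

na_cell <- function(x) {
  is.na(x) || !nzchar(trimws(x)) || tolower(trimws(x)) == "n/a"
}

#' Assemble full per-event HED annotations
#'
#' Per row, the annotations contributed by each column are comma-joined in
#' a deterministic order: sidecar-annotated columns in sorted column-name
#' order, then any literal `HED` column. `"n/a"` cells contribute nothing.
#' Definition groups found anywhere are collected into the definition set
#' and removed from the row annotations (declarations are not events);
#' rows whose annotation was only definitions produce no assembled event.
#' Every remaining annotation is validated against the schema set.
#'
#' @param events A `hed_event_table` from [read_events()].
#' @param sidecar A `hed_sidecar` from [read_sidecar()], or `NULL`.
#' @param schemas A `hed_schema` or `hed_schema_set`.
#' @param defs A `hed_definitions` of pre-registered definitions
#'   (e.g. from [read_definitions()]); extended with definitions found in
#'   the rows.
#' @return A `hed_assembled` object: `events` (list of assembled events,
#'   each with `onset`, `duration`, `row_index`, `annotation`), `defs`
#'   (the full definition set), and `issues` (validation and assembly
#'   issues, with `path` naming the source row).
#' @export
assemble <- function(events, sidecar, schemas, defs = new_definitions()) {
  stopifnot(inherits(events, "hed_event_table"))
  schemas <- as_schema_set(schemas)
  if (is.null(sidecar)) sidecar <- structure(list(entries = list(), meta = list()),
                                             class = "hed_sidecar")
  issues <- hed_issues()
  note <- function(code, severity, row, detail) {
    issues <<- bind_issues(issues, hed_issue_row(
      code, severity = severity, path = sprintf("row %d", row),
      detail = detail))
  }
  ann_cols <- sort(as.character(intersect(names(sidecar$entries),
                                          names(events))),
                   method = "radix")
  has_hed_col <- "HED" %in% names(events)

  # pass 1: build raw annotation text per row
  texts <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    parts <- character(0)
    for (col in ann_cols) {
      cell <- events[[col]][i]
      if (na_cell(cell)) next
      spec <- sidecar$entries[[col]]
      if (spec$type == "categorical") {
        hit <- spec$map[[cell]]
        if (is.null(hit)) {
          note("UNMAPPED_CATEGORY", "warning", events$row_index[i],
               sprintf("column '%s': value '%s' not in sidecar map", col, cell))
        } else {
          parts <- c(parts, hit)
        }
      } else if (spec$type == "value") {
        parts <- c(parts, gsub("#", trimws(cell), spec$template, fixed = TRUE))
      } else {
        parts <- c(parts, spec$template)
      }
    }
    if (has_hed_col && !na_cell(events$HED[i])) {
      parts <- c(parts, events$HED[i])
    }
    texts[i] <- paste(parts, collapse = ", ")
  }

  # pass 2: parse, collect definitions from all rows, then validate
  parsed <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    if (!nzchar(texts[i])) next
    p <- parse_hed_safely(texts[i])
    if (is.null(p$string)) {
      iss <- p$issues
      iss$path <- sprintf("row %d", events$row_index[i])
      issues <- bind_issues(issues, iss)
      next
    }
    parsed[[i]] <- p$string
    coll <- collect_definitions(list(p$string), defs)
    defs <- coll$defs
    if (nrow(coll$issues) > 0) {
      coll$issues$path <- sprintf("row %d", events$row_index[i])
      issues <- bind_issues(issues, coll$issues)
    }
  }

  out <- list()
  for (i in seq_len(nrow(events))) {
    s <- parsed[[i]]
    if (is.null(s)) {
      if (!nzchar(texts[i])) {
        note("EMPTY_ANNOTATION", "warning", events$row_index[i],
             "row has no annotation content")
      }
      next
    }
    s <- strip_definition_groups(s)
    if (length(s$members) == 0) next  # pure definition carrier
    iss <- validate_string(s, schemas, defs)
    if (nrow(iss) > 0) {
      iss$path <- sprintf("row %d", events$row_index[i])
      issues <- bind_issues(issues, iss)
    }
    out[[length(out) + 1]] <- list(
      onset = events$onset[i], duration = events$duration[i],
      row_index = events$row_index[i], annotation = s
    )
  }
  structure(list(events = out, defs = defs, issues = issues),
            class = "hed_assembled")
}

#' Expand Def references in every assembled annotation
#'
#' Replaces each `Def/Name` reference with its `(Def-expand/Name, ...)`
#' group in every event's annotation, the form search and analysis operate
#' on. Usually applied after [resolve_scopes()] (which reads the compact
#' references) and before [insert_event_context()].
#'
#' @param assembled A `hed_assembled`.
#' @param defs A `hed_definitions`; defaults to the definitions collected
#'   during assembly.
#' @return The `hed_assembled` with expanded annotations.
#' @export
expand_assembled <- function(assembled, defs = assembled$defs) {
  assembled$events <- lapply(assembled$events, function(ev) {
    ev$annotation <- expand_defs(ev$annotation, defs)
    ev
  })
  assembled
}

#' @export
print.hed_assembled <- function(x, ...) {
  cat(sprintf("<hed_assembled> %d event(s), %d definition(s), %d issue(s)\n",
              length(x$events), length(x$defs$defs), nrow(x$issues)))
  invisible(x)
}

#' Tabulate assembled events
#'
#' @param assembled A `hed_assembled`.
#' @param schemas Optional schema set; when given, long-form and short-form
#'   annotation columns are added.
#' @return A data frame with `row_index`, `onset`, `duration`, and
#'   annotation column(s).
#' @export
assembled_table <- function(assembled, schemas = NULL) {
  ev <- assembled$events
  df <- data.frame(
    row_index = vapply(ev, `[[`, integer(1), "row_index"),
    onset = vapply(ev, `[[`, numeric(1), "onset"),
    duration = vapply(ev, `[[`, numeric(1), "duration"),
    annotation = vapply(ev, function(e) format(e$annotation), character(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(schemas)) {
    df$annotation_long <- vapply(ev, function(e)
      format(to_long(e$annotation, schemas)), character(1))
    df$annotation_short <- vapply(ev, function(e)
      format(to_short(e$annotation, schemas)), character(1))
  }
  df
}
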