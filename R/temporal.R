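#' @title Temporal scope and event context
#' @description Enduring events — events with temporal extent — are marked
#'   either by `(Def/Name, Onset)` ... `(Def/Name, Offset)` pairs sharing a
#'   definition name, or by a tag group carrying `Duration/value`, whose
#'   span ends at onset + duration. All tags in an Onset or Duration group
#'   apply throughout the enduring event. At analysis time, each event
#'   inherits copies of the annotations of all then-ongoing enduring events
#'   inside a single `(Event-context, ...)` group. Interval membership is
#'   half-open, `[start, end)`, and the marker rows that open or close an
#'   interval never receive that interval's context.
#' @name hed-temporal
NULL

ORG_TRACKS <- c("Task", "Time-block", "Condition-variable",
                "Experimental-trial", "Recording")

# seconds per unit for the bundled time unit class
TIME_UNIT_SCALE <- c(s = 1, ms = 1e-3)

tag_terminal_match <- function(text, term) {
  grepl(sprintf("(^|/|:)%s$", term), tolower(text))
}

# Duration value in seconds from a tag like "Duration/0.5 s" (long or short
# form); NULL when the tag is not a Duration value tag.
duration_seconds <- function(text) {
  ref <- match_machinery(text, "duration")
  if (is.null(ref)) return(NULL)
  raw <- paste(c(ref$name, if (nzchar(ref$value)) ref$value), collapse = "/")
  m <- regmatches(raw, regexec("^([0-9.eE+-]+)(\\s+(\\S+))?$", raw))[[1]]
  if (length(m) == 0) return(NULL)
  val <- suppressWarnings(as.numeric(m[2]))
  if (is.na(val)) return(NULL)
  unit <- m[4]
  scale <- if (is.na(unit) || !nzchar(unit)) 1 else TIME_UNIT_SCALE[[unit]]
  if (is.null(scale) || is.na(scale)) return(NULL)
  val * scale
}

group_def_ref <- function(g) {
  for (m in g$members) {
    if (!is_tag(m)) next
    ref <- match_machinery(m$text, "def")
    if (is.null(ref)) ref <- match_machinery(m$text, "def-expand")
    if (!is.null(ref)) return(ref)
  }
  NULL
}

# Group members with temporal-marker tags (Onset/Offset/Duration) removed,
# definitions expanded: the annotation that applies throughout the span.
scope_annotation <- function(g, defs) {
  keep <- Filter(function(m) {
    !(is_tag(m) && (tag_terminal_match(m$text, "onset") ||
                    tag_terminal_match(m$text, "offset") ||
                    !is.null(duration_seconds(m$text))))
  }, g$members)
  expanded <- expand_defs(hed_string(keep), defs)
  hed_group(expanded$members)
}

#' Resolve enduring events from Onset/Offset/Duration marks
#'
#' Walks assembled events in onset order. A `(Def/Name, Onset)` group opens
#' an interval; a later `(Def/Name, Offset)` group closes it; a repeated
#' Onset for the same name closes the prior interval at the new onset and
#' opens a new one. Any tag group containing `Duration/v` creates a closed
#' interval `[onset, onset + v]` directly (several per event are allowed).
#' Intervals still open after the last event are closed at the last event's
#' onset and flagged `UNCLOSED_ONSET` (warning); an Offset with no open
#' interval is an `OFFSET_WITHOUT_ONSET` error.
#'
#' @param assembled A `hed_assembled` from [assemble()], or a list of
#'   assembled events.
#' @param defs A `hed_definitions`; enduring-event annotations are stored
#'   with definitions expanded.
#' @return A `hed_scopes` object: `intervals` (each with `def_name`,
#'   `start`, `end`, `annotation`, `open_row`, `close_row`, `unclosed`)
#'   and `issues`.
#' @export
resolve_scopes <- function(assembled, defs = new_definitions()) {
  events <- if (inherits(assembled, "hed_assembled")) assembled$events else assembled
  if (inherits(assembled, "hed_assembled") && length(assembled$defs$defs) > 0) {
    for (key in names(assembled$defs$defs)) {
      if (is.null(defs$defs[[key]])) defs$defs[[key]] <- assembled$defs$defs[[key]]
    }
  }
  onsets <- vapply(events, `[[`, numeric(1), "onset")
  stopifnot(!is.unsorted(onsets))
  issues <- hed_issues()
  intervals <- list()
  open <- list()  # def name (lower) -> index into intervals
  last_onset <- if (length(onsets)) onsets[length(onsets)] else 0
  for (ev in events) {
    for (m in ev$annotation$members) {
      if (!is_group(m)) next
      dur_vals <- unlist(lapply(m$members, function(x)
        if (is_tag(x)) duration_seconds(x$text) else NULL))
      has_onset <- any(vapply(m$members, function(x)
        is_tag(x) && tag_terminal_match(x$text, "onset"), logical(1)))
      has_offset <- any(vapply(m$members, function(x)
        is_tag(x) && tag_terminal_match(x$text, "offset"), logical(1)))
      ref <- group_def_ref(m)
      if (length(dur_vals) > 0) {
        for (v in dur_vals) {
          intervals[[length(intervals) + 1]] <- list(
            def_name = if (is.null(ref)) "" else ref$name,
            start = ev$onset, end = ev$onset + v,
            annotation = scope_annotation(m, defs),
            open_row = ev$row_index, close_row = ev$row_index,
            unclosed = FALSE)
        }
        next
      }
      if (!has_onset && !has_offset) next
      if (is.null(ref)) {
        issues <- bind_issues(issues, hed_issue_row(
          "DEF_SYNTAX", severity = "error",
          path = sprintf("row %d", ev$row_index),
          detail = "temporal-marker group has no Def/Name"))
        next
      }
      key <- tolower(ref$name)
      if (has_onset) {
        prior <- open[[key]]
        if (!is.null(prior)) {
          intervals[[prior]]$end <- ev$onset
          intervals[[prior]]$close_row <- ev$row_index
        }
        intervals[[length(intervals) + 1]] <- list(
          def_name = ref$name, start = ev$onset, end = NA_real_,
          annotation = scope_annotation(m, defs),
          open_row = ev$row_index, close_row = NA_integer_,
          unclosed = FALSE)
        open[[key]] <- length(intervals)
      } else {
        prior <- open[[key]]
        if (is.null(prior)) {
          issues <- bind_issues(issues, hed_issue_row(
            "OFFSET_WITHOUT_ONSET", severity = "error",
            path = sprintf("row %d", ev$row_index),
            detail = sprintf("Offset for '%s' has no prior Onset", ref$name)))
          next
        }
        intervals[[prior]]$end <- ev$onset
        intervals[[prior]]$close_row <- ev$row_index
        open[[key]] <- NULL
      }
    }
  }
  for (key in names(open)) {
    idx <- open[[key]]
    if (is.null(idx)) next
    intervals[[idx]]$end <- last_onset
    intervals[[idx]]$unclosed <- TRUE
    issues <- bind_issues(issues, hed_issue_row(
      "UNCLOSED_ONSET", severity = "warning",
      path = sprintf("row %d", intervals[[idx]]$open_row),
      detail = sprintf("Onset for '%s' never closed; interval ends at last event (%g s)",
                       intervals[[idx]]$def_name, last_onset)))
  }
  structure(list(intervals = intervals, issues = issues),
            class = "hed_scopes")
}

#' @export
print.hed_scopes <- function(x, ...) {
  cat(sprintf("<hed_scopes> %d interval(s)\n", length(x$intervals)))
  for (iv in x$intervals) {
    cat(sprintf("  %-20s [%g, %g)%s\n",
                if (nzchar(iv$def_name)) iv$def_name else "(unnamed)",
                iv$start, iv$end, if (iv$unclosed) " UNCLOSED" else ""))
  }
  invisible(x)
}

#' @export
as.data.frame.hed_scopes <- function(x, ...) {
  data.frame(
    def_name = vapply(x$intervals, `[[`, character(1), "def_name"),
    start = vapply(x$intervals, `[[`, numeric(1), "start"),
    end = vapply(x$intervals, `[[`, numeric(1), "end"),
    unclosed = vapply(x$intervals, `[[`, logical(1), "unclosed"),
    stringsAsFactors = FALSE
  )
}

has_context_group <- function(s) {
  any(vapply(s$members, is_context_group, logical(1)))
}

#' Insert Event-context groups into intervening events
#'
#' Each event at time `t` gains exactly one `(Event-context, ...)` group
#' holding one copy of the annotation of every enduring event with
#' `start <= t < end` — excluding enduring events whose opening or closing
#' marker is this very row, since the context must not suggest that
#' intervening events share the onset/offset effects. Events with no
#' ongoing context gain no group. Context members are ordered by
#' `(start, def_name)` for determinism; inserting twice is an error.
#'
#' @param assembled A `hed_assembled`.
#' @param scopes A `hed_scopes` from [resolve_scopes()].
#' @param schemas Optional schema set; when given, inserted copies are
#'   converted to long form.
#' @return The `hed_assembled` with context groups inserted.
#' @export
insert_event_context <- function(assembled, scopes, schemas = NULL) {
  stopifnot(inherits(assembled, "hed_assembled"),
            inherits(scopes, "hed_scopes"))
  ivs <- scopes$intervals
  if (length(ivs) > 0) {
    ord <- order(vapply(ivs, `[[`, numeric(1), "start"),
                 tolower(vapply(ivs, `[[`, character(1), "def_name")),
                 method = "radix")
    ivs <- ivs[ord]
  }
  assembled$events <- lapply(assembled$events, function(ev) {
    if (has_context_group(ev$annotation)) {
      hed_error("CONTEXT_ALREADY_INSERTED",
                sprintf("row %d already has an Event-context group",
                        ev$row_index))
    }
    ongoing <- Filter(function(iv) {
      iv$start <= ev$onset && ev$onset < iv$end &&
        !identical(iv$open_row, ev$row_index) &&
        !identical(iv$close_row, ev$row_index)
    }, ivs)
    if (length(ongoing) == 0) return(ev)
    copies <- lapply(ongoing, function(iv) {
      g <- iv$annotation
      if (!is.null(schemas)) {
        g <- hed_group(to_long(hed_string(g$members), schemas)$members)
      }
      strip_spans(g)
    })
    ctx <- hed_group(c(list(hed_tag("Event-context")), copies))
    ev$annotation$members <- c(ev$annotation$members, list(ctx))
    ev
  })
  assembled
}

#' Extract an experiment timeline from enduring events
#'
#' Enduring events whose annotation carries an organizational tag (`Task`,
#' `Time-block`, `Condition-variable`, `Experimental-trial`, `Recording`)
#' are placed on the matching track, labelled by their definition name (or
#' by the organizational tag's value when unnamed). Gaps between intervals
#' correspond to recording time outside any enduring event's scope.
#'
#' @param scopes A `hed_scopes`.
#' @param defs A `hed_definitions` (labels fall back to definition names).
#' @param schemas A `hed_schema` or `hed_schema_set`, used to resolve tags.
#' @return A `hed_timeline` data frame: `track`, `label`, `start`, `end`,
#'   sorted by track then start.
#' @export
extract_timeline <- function(scopes, defs, schemas) {
  stopifnot(inherits(scopes, "hed_scopes"))
  schemas <- as_schema_set(schemas)
  rows <- list()
  for (iv in scopes$intervals) {
    tags <- flatten_tags(hed_string(iv$annotation$members))
    for (t in tags) {
      res <- resolve_tag_info(schemas, t$text)
      if (!res$ok) next
      comps <- tolower(strsplit(res$path, "/", fixed = TRUE)[[1]])
      hit <- ORG_TRACKS[tolower(ORG_TRACKS) %in% comps]
      for (track in hit) {
        label <- if (nzchar(iv$def_name)) {
          iv$def_name
        } else if (nzchar(res$value)) {
          res$value
        } else {
          path_terminal(res$path)
        }
        rows[[length(rows) + 1]] <- data.frame(
          track = track, label = label, start = iv$start, end = iv$end,
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (length(rows) == 0) {
    data.frame(track = character(0), label = character(0),
               start = numeric(0), end = numeric(0), stringsAsFactors = FALSE)
  } else {
    unique(do.call(rbind, rows))
  }
  df <- df[order(df$track, df$start, df$label, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("hed_timeline", "data.frame")
  df
}

#' Export a timeline as JSON records
#'
#' @param timeline A `hed_timeline`.
#' @param path Optional output file.
#' @return JSON text (one array of `{track, label, start, end}` records),
#'   invisibly when written to file.
#' @export
timeline_to_json <- function(timeline, path = NULL) {
  df <- as.data.frame(unclass(timeline), stringsAsFactors = FALSE)
  txt <- jsonlite::toJSON(df, dataframe = "rows", auto_unbox = TRUE,
                          digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
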