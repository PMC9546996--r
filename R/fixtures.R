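#' @title Bundled schema and synthetic experiment designs
#' @description The package ships a miniature base schema with the six
#'   top-level categories of the third-generation base vocabulary —
#'   Event(7), Agent(6), Action(5), Item(4), Property(7), Relation(5) —
#'   including the organizational and definition machinery, plus a small
#'   synthetic clinical library for namespace demonstrations. The design
#'   generators emit complete BIDS-style recordings (events TSV, sidecar
#'   JSON, definitions file) for three classic ways of organizing a simple
#'   two-task, two-condition study, so the whole pipeline is exercisable
#'   offline.
#' @name hed-fixtures
NULL

#' Path to the bundled example schemas
#'
#' @param dialect `"wiki"` or `"xml"` for the base schema.
#' @return A file path inside the installed package.
#' @export
hed_example_schema_path <- function(dialect = c("wiki", "xml")) {
  dialect <- match.arg(dialect)
  fname <- if (dialect == "wiki") "hedkit-base-schema.mediawiki" else "hedkit-base-schema.xml"
  path <- system.file("extdata", fname, package = "hedkit")
  if (!nzchar(path)) stop("bundled schema not found; is hedkit installed?")
  path
}

#' @rdname hed_example_schema_path
#' @export
hed_example_library_path <- function() {
  path <- system.file("extdata", "hedkit-clinical-minilib.mediawiki",
                      package = "hedkit")
  if (!nzchar(path)) stop("bundled library not found; is hedkit installed?")
  path
}

#' Build the bundled base schema
#'
#' Loads the miniature base schema (six top-level categories with the
#' second-level counts of the reorganized third-generation vocabulary) and
#' optionally writes wiki and XML copies of it.
#'
#' @param dir Optional directory; when given, `base-schema.mediawiki` and
#'   `base-schema.xml` are written there.
#' @return A `hed_schema`.
#' @export
build_fixture_schema <- function(dir = NULL) {
  schema <- load_schema(hed_example_schema_path("wiki"), dialect = "wiki")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    serialize_schema(schema, "wiki", file.path(dir, "base-schema.mediawiki"))
    serialize_schema(schema, "xml", file.path(dir, "base-schema.xml"))
  }
  schema
}

fmt_num <- function(x) sprintf("%g", x)

#' Generate a synthetic annotated recording for one experiment design
#'
#' Emits a complete BIDS-style recording for a simple study in which each
#' experimental trial comprises three events (a visual stimulus, a
#' participant response, and auditory feedback), organized one of three
#' ways:
#'
#' * **Design 1** — one `Task` and one `Condition-variable` enduring event
#'   span the recording; `n_blocks` `Time-block` enduring events, separated
#'   by relief-break gaps, each contain `trials_per_block` trials.
#' * **Design 2** — one `Task` + `Condition-variable` pair per
#'   `Time-block`, counterbalanced across blocks (odd blocks TaskA/CondA,
#'   even blocks TaskB/CondB).
#' * **Design 3** — a single `Task` and `Time-block`; the
#'   `Condition-variable` is drawn pseudo-randomly (CondA or CondB, equal
#'   probability) for each trial. All `n_blocks * trials_per_block` trials
#'   run in the one block.
#'
#' Structure is marked the recommended way: named `Definition` groups
#' referenced by `(Def/Name, Onset)` / `(Def/Name, Offset)` pairs; per-trial
#' scopes use `Duration` groups. Trials are spaced `trial_period` seconds
#' apart (stimulus at 0.25, response at 0.55, feedback at 0.85 of the
#' period; trial scope 0.7 of the period), and inter-block gaps are five
#' trial periods, so extracted timelines show visible gaps. Output is
#' deterministic given `seed`, which is recorded in the sidecar metadata.
#'
#' @param design 1, 2, or 3.
#' @param n_blocks Number of time blocks (design 3: trial multiplier).
#' @param trials_per_block Trials per block.
#' @param trial_period Seconds per trial slot (> 0).
#' @param seed Integer seed for the pseudo-random condition draws.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the written file paths (`events`,
#'   `sidecar`, `definitions`) plus the design parameters.
#' @examples
#' paths <- generate_design(1, dir = tempfile("d1_"))
#' nrow(read_events(paths$events))
#' @export
generate_design <- function(design = 1, n_blocks = 2, trials_per_block = 10,
                            trial_period = 2, seed = 42,
                            dir = tempfile("hedkit_design_")) {
  if (!design %in% 1:3 || n_blocks < 1 || trials_per_block < 1 ||
      trial_period <= 0) {
    hed_error("INVALID_SPEC",
              "design must be 1-3, counts >= 1, trial_period > 0")
  }
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  # design 3 runs everything in a single continuous block
  eff_blocks <- if (design == 3) 1L else n_blocks
  eff_trials <- if (design == 3) n_blocks * trials_per_block else trials_per_block
  p <- trial_period
  scope_dur <- fmt_num(0.7 * p)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  cond_draw <- sample(c("CondA", "CondB"), eff_blocks * eff_trials,
                      replace = TRUE)

  rows <- list()
  add_row <- function(onset, event_type = "n/a", trial = "n/a", hed = "n/a") {
    rows[[length(rows) + 1]] <<- c(onset = fmt_num(onset), duration = "n/a",
                                   event_type = event_type, trial = trial,
                                   HED = hed)
  }

  if (design %in% c(1, 3)) {
    opening <- "(Def/MainTask, Onset)"
    if (design == 1) opening <- paste0(opening, ", (Def/CondA, Onset)")
    add_row(0, hed = opening)
  }
  q <- 0L
  bs <- p
  for (k in seq_len(eff_blocks)) {
    block_open <- sprintf("(Def/Block%d, Onset)", k)
    block_close <- sprintf("(Def/Block%d, Offset)", k)
    if (design == 2) {
      x <- if (k %% 2 == 1) "A" else "B"
      block_open <- paste0(block_open,
                           sprintf(", (Def/Task%s, Onset), (Def/Cond%s, Onset)", x, x))
      block_close <- paste0(block_close,
                            sprintf(", (Def/Task%s, Offset), (Def/Cond%s, Offset)", x, x))
    }
    add_row(bs, hed = block_open)
    for (j in seq_len(eff_trials)) {
      q <- q + 1L
      ts <- bs + (j - 1) * p + 0.25 * p
      stim_hed <- sprintf("(Experimental-trial/%d, Duration/%s s)", q, scope_dur)
      if (design == 3) {
        stim_hed <- paste0(stim_hed,
                           sprintf(", (Def/%s, Duration/%s s)", cond_draw[q], scope_dur))
      }
      add_row(ts, "stimulus", as.character(q), stim_hed)
      add_row(ts + 0.3 * p, "response", as.character(q))
      add_row(ts + 0.6 * p, "feedback", as.character(q))
    }
    add_row(bs + eff_trials * p, hed = block_close)
    bs <- bs + eff_trials * p + 5 * p
  }
  t_end <- bs - 5 * p + p
  if (design %in% c(1, 3)) {
    closing <- "(Def/MainTask, Offset)"
    if (design == 1) closing <- paste0(closing, ", (Def/CondA, Offset)")
    add_row(t_end, hed = closing)
  }

  header <- c("onset", "duration", "event_type", "trial", "HED")
  tsv <- c(paste(header, collapse = "\t"),
           vapply(rows, function(r) paste(r[header], collapse = "\t"),
                  character(1)))

  sidecar <- list(
    event_type = list(HED = list(
      stimulus = "Sensory-event, Visual-presentation, ((Triangle, Red), (Square, Green))",
      response = "Agent-action, Move",
      feedback = "Sensory-event, Auditory-presentation, Feedback"
    )),
    trial = list(HED = "Experimental-trial/#"),
    provenance = list(generator = "hedkit", design = design, seed = seed)
  )

  block_defs <- sprintf("(Definition/Block%d, (Time-block, Label/block-%d))",
                        seq_len(eff_blocks), seq_len(eff_blocks))
  defs <- switch(design,
    c("(Definition/MainTask, (Task, Label/main-task))",
      "(Definition/CondA, (Condition-variable, Red))",
      block_defs),
    c("(Definition/TaskA, (Task, Label/task-a))",
      "(Definition/TaskB, (Task, Label/task-b))",
      "(Definition/CondA, (Condition-variable, Red))",
      "(Definition/CondB, (Condition-variable, Green))",
      block_defs),
    c("(Definition/MainTask, (Task, Label/main-task))",
      "(Definition/CondA, (Condition-variable, Red))",
      "(Definition/CondB, (Condition-variable, Green))",
      block_defs)
  )

  events_path <- file.path(dir, sprintf("design%d_events.tsv", design))
  sidecar_path <- file.path(dir, sprintf("design%d_events.json", design))
  defs_path <- file.path(dir, sprintf("design%d_defs.txt", design))
  writeLines(tsv, events_path, useBytes = TRUE)
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, pretty = TRUE),
             sidecar_path, useBytes = TRUE)
  writeLines(defs, defs_path, useBytes = TRUE)
  invisible(list(events = events_path, sidecar = sidecar_path,
                 definitions = defs_path, design = design,
                 n_blocks = n_blocks, trials_per_block = trials_per_block,
                 trial_period = trial_period, seed = seed,
                 record_span = c(0, t_end)))
}

#' Run the full annotation pipeline on a generated design
#'
#' Convenience wrapper used by tests and the command-line tools: reads the
#' generated files, assembles annotations, collects definitions, resolves
#' enduring-event scopes, and inserts Event-context groups.
#'
#' @param paths The list returned by [generate_design()] (or a list with
#'   `events`, `sidecar`, `definitions` paths).
#' @param schemas A schema set; defaults to the bundled base schema.
#' @return A list with `events` (the event table), `assembled` (context
#'   inserted), `defs`, `scopes`, and `timeline`.
#' @export
run_design_pipeline <- function(paths, schemas = NULL) {
  if (is.null(schemas)) schemas <- hed_schemas(build_fixture_schema())
  schemas <- as_schema_set(schemas)
  events <- read_events(paths$events)
  sidecar <- read_sidecar(paths$sidecar)
  defs <- read_definitions(paths$definitions)$defs
  assembled <- assemble(events, sidecar, schemas, defs)
  scopes <- resolve_scopes(assembled, assembled$defs)
  with_ctx <- insert_event_context(expand_assembled(assembled), scopes, schemas)
  timeline <- extract_timeline(scopes, assembled$defs, schemas)
  list(events = events, assembled = with_ctx, defs = assembled$defs,
       scopes = scopes, timeline = timeline)
}
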