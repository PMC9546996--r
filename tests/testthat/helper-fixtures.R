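# Shared fixtures: the bundled schema (loaded once per test run) and small
# generators for property-style tests.

base_schema <- function() {
  if (is.null(.fixture_env$schema)) {
    .fixture_env$schema <- load_schema(hed_example_schema_path("wiki"))
  }
  .fixture_env$schema
}

base_schemas <- function() {
  if (is.null(.fixture_env$schemas)) {
    .fixture_env$schemas <- hed_schemas(base_schema())
  }
  .fixture_env$schemas
}

clinical_lib <- function() {
  if (is.null(.fixture_env$lib)) {
    .fixture_env$lib <- load_schema(hed_example_library_path())
  }
  .fixture_env$lib
}

.fixture_env <- new.env(parent = emptyenv())

# All non-placeholder node paths of the bundled schema.
schema_paths <- function(schema = base_schema()) {
  paths <- vapply(schema$nodes, `[[`, "", "path")
  unname(paths[!endsWith(paths, "/#")])
}

# Random small schema in wiki text, with unique terms by construction.
random_wiki_schema <- function(seed, n_roots = 3, max_children = 4,
                               max_depth = 3) {
  set.seed(seed)
  counter <- 0
  lines <- c("HED version=\"0.0.1\"")
  emit <- function(depth) {
    counter <<- counter + 1
    attrs <- if (stats::runif(1) < 0.2) " {extensionAllowed}" else ""
    lines <<- c(lines, paste0(strrep("*", depth), " Node-", counter, attrs))
    if (depth < max_depth) {
      for (i in seq_len(sample(0:max_children, 1))) emit(depth + 1)
    }
  }
  for (r in seq_len(n_roots)) emit(1)
  paste(lines, collapse = "\n")
}

# Random HED string over fixture vocabulary: returns the text of a nested
# annotation with n_tags tags spread over random groups.
random_hed_text <- function(seed, n_tags = 10, p_group = 0.4) {
  set.seed(seed)
  terms <- c("Sensory-event", "Agent-action", "Triangle", "Square", "Red",
             "Green", "Blue", "Visual-presentation", "Auditory-presentation",
             "Move", "Perceive", "Human-agent", "Rectangle", "Sound")
  build <- function(budget) {
    members <- character(0)
    while (budget > 0) {
      if (budget >= 2 && stats::runif(1) < p_group) {
        take <- sample(2:min(4, budget), 1)
        members <- c(members, paste0("(", build(take), ")"))
        budget <- budget - take
      } else {
        members <- c(members, sample(terms, 1))
        budget <- budget - 1
      }
    }
    paste(members, collapse = ", ")
  }
  build(n_tags)
}

# Recursively shuffle the member order of a parsed string (same multiset of
# members at every level, different order).
shuffle_members <- function(s) {
  shuf <- function(x) {
    if (inherits(x, "hed_group")) {
      x$members <- lapply(sample(length(x$members)), function(i) shuf(x$members[[i]]))
    }
    x
  }
  s$members <- lapply(sample(length(s$members)), function(i) shuf(s$members[[i]]))
  s
}

# Minimal assembled-events object for synthetic temporal tests.
make_assembled <- function(onsets, annotations) {
  ev <- lapply(seq_along(onsets), function(i) {
    list(onset = onsets[i], duration = NA_real_, row_index = i,
         annotation = if (is.character(annotations[[i]])) {
           parse_hed(annotations[[i]])
         } else {
           annotations[[i]]
         })
  })
  structure(list(events = ev, defs = hedkit:::new_definitions(),
                 issues = hedkit:::hed_issues()),
            class = "hed_assembled")
}
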