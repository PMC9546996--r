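# Schema loading, linting, stats, and short-form resolution.

test_that("bundled schema has the six reorganized top-level categories", {
  st <- schema_stats(base_schema())
  expect_equal(st$n_top_level, 6)
  expect_equal(
    st$children_per_top_level,
    c(Event = 7L, Agent = 6L, Action = 5L, Item = 4L, Property = 7L,
      Relation = 5L)
  )
  expect_equal(st$n_total, length(base_schema()$nodes))
})

test_that("single-node schema has totals (1, [0], 1)", {
  s <- load_schema("* Solo", "wiki")
  st <- schema_stats(s)
  expect_equal(st$n_top_level, 1)
  expect_equal(unname(st$children_per_top_level), 0L)
  expect_equal(st$n_total, 1)
})

test_that("malformed and empty wiki input fail with PARSE_ERROR", {
  expect_error(load_schema("", "wiki"), class = "hedkit_parse_error")
  expect_error(load_schema("not a node line", "wiki"),
               class = "hedkit_parse_error")
  expect_error(load_schema("* A\n*** Skip-a-level", "wiki"),
               class = "hedkit_parse_error")
  expect_error(load_schema("<HED version='x'><schema></schema></HED>", "xml"),
               class = "hedkit_parse_error")
})

test_that("wiki and xml serialization round-trip the full tree", {
  for (seed in 1:5) {
    s <- load_schema(random_wiki_schema(seed), "wiki")
    for (dialect in c("wiki", "xml")) {
      s2 <- load_schema(serialize_schema(s, dialect), dialect)
      expect_identical(sort(names(s2$nodes)), sort(names(s$nodes)))
      expect_identical(
        lapply(s2$nodes[sort(names(s2$nodes))], `[[`, "attributes"),
        lapply(s$nodes[sort(names(s$nodes))], `[[`, "attributes")
      )
    }
  }
  # bundled schema round-trips with unit classes and descriptions
  s <- base_schema()
  for (dialect in c("wiki", "xml")) {
    s2 <- load_schema(serialize_schema(s, dialect), dialect)
    expect_identical(sort(names(s2$nodes)), sort(names(s$nodes)))
    expect_identical(s2$unit_classes, s$unit_classes)
  }
})

test_that("strict load fails on duplicate terms; permissive load lints them", {
  dup <- "* A\n** Red\n* B\n** Red"
  expect_error(load_schema(dup, "wiki"), class = "hedkit_duplicate_term")
  s <- load_schema(dup, "wiki", permissive = TRUE)
  issues <- check_uniqueness(s)
  expect_equal(nrow(issues), 1)
  expect_equal(issues$code, "DUPLICATE_TERM")
  expect_match(issues$detail, "A/Red")
  expect_match(issues$detail, "B/Red")
})

test_that("uniqueness is case-insensitive and agrees with brute-force counts", {
  s <- load_schema("* A\n** red\n* B\n** Red", "wiki", permissive = TRUE)
  expect_equal(nrow(check_uniqueness(s)), 1)
  expect_equal(nrow(check_uniqueness(base_schema())), 0)
  # randomly perturbed schemas: inject k duplicates, expect k issues
  for (seed in 1:5) {
    set.seed(seed)
    base_text <- random_wiki_schema(seed)
    lines <- strsplit(base_text, "\n")[[1]]
    node_lines <- grep("^\\*", lines)
    k <- sample(1:3, 1)
    victims <- sample(node_lines, k)
    extra <- sprintf("* Extra-%d-root", seed)
    dups <- vapply(victims, function(i) {
      term <- sub("^\\*+\\s*", "", lines[i])
      term <- sub("\\s*\\{.*$", "", term)
      paste0("** ", term)
    }, character(1))
    text <- paste(c(lines, extra, dups), collapse = "\n")
    s <- load_schema(text, "wiki", permissive = TRUE)
    expect_equal(nrow(check_uniqueness(s)), length(unique(dups)))
  }
})

test_that("sparsity lint warns at ten or more children, not below", {
  wide <- function(n) {
    paste(c("* Root", paste0("** Kid-", seq_len(n))), collapse = "\n")
  }
  nine <- lint_structure(load_schema(wide(9), "wiki"))
  ten <- lint_structure(load_schema(wide(10), "wiki"))
  expect_equal(sum(nine$code == "TOO_MANY_CHILDREN"), 0)
  expect_equal(sum(ten$code == "TOO_MANY_CHILDREN"), 1)
  expect_equal(ten$severity[ten$code == "TOO_MANY_CHILDREN"], "warning")
  # exhaustive count over the bundled schema
  s <- base_schema()
  brute <- sum(vapply(s$nodes, function(n) length(n$children) >= 10,
                      logical(1)))
  expect_equal(sum(lint_structure(s)$code == "TOO_MANY_CHILDREN"), brute)
  expect_equal(brute, 0)
  # nodes outside the 3-7 ideal band get notes, not warnings
  notes <- lint_structure(load_schema(wide(8), "wiki"))
  expect_equal(notes$code, "SPARSITY_NOTE")
  expect_equal(notes$severity, "note")
})

test_that("every suffix of every node path resolves to the same full path", {
  schemas <- base_schemas()
  for (path in schema_paths()) {
    segs <- strsplit(path, "/", fixed = TRUE)[[1]]
    for (i in seq_along(segs)) {
      suffix <- paste(segs[i:length(segs)], collapse = "/")
      expect_equal(resolve_tag(schemas, suffix)$path, path)
      # case-insensitive, schema casing restored
      expect_equal(resolve_tag(schemas, tolower(suffix))$path, path)
    }
  }
})

test_that("resolution errors distinguish unknown tags from bad parent chains", {
  schemas <- base_schemas()
  expect_error(resolve_tag(schemas, "Totally-unknown"),
               class = "hedkit_tag_not_found")
  expect_error(resolve_tag(schemas, "Sensory-event/Triangle"),
               class = "hedkit_invalid_parent")
  expect_error(resolve_tag(schemas, "Red/5"),
               class = "hedkit_value_without_placeholder")
})

test_that("extensionAllowed admits novel children, flagged as extensions", {
  schemas <- base_schemas()
  res <- resolve_tag(schemas, "Man-made-object/Joystick")
  expect_true(res$is_extension)
  expect_equal(res$path, "Item/Object/Man-made-object/Joystick")
  iss <- validate_hed("Man-made-object/Joystick", schemas)
  expect_equal(iss$code, "EXTENSION_WARNING")
  expect_equal(iss$severity, "warning")
})

test_that("library lookup is namespace-scoped and never shadows the base", {
  schemas <- merge_libraries(base_schema(), list(sc = clinical_lib()))
  expect_equal(resolve_tag(schemas, "sc:Spike")$path, "sc:Base/Spike")
  expect_equal(resolve_tag(schemas, "sc:Base/Spike")$path, "sc:Base/Spike")
  expect_error(resolve_tag(schemas, "Spike"), class = "hedkit_tag_not_found")
  # empty library list behaves as base alone
  plain <- merge_libraries(base_schema(), list())
  expect_equal(resolve_tag(plain, "Event")$path, "Event")
  # duplicate namespace registration is rejected
  expect_error(
    merge_libraries(base_schema(),
                    stats::setNames(list(clinical_lib(), clinical_lib()),
                                    c("sc", "sc"))),
    class = "hedkit_duplicate_namespace")
})

test_that("schema_stats totals equal an exhaustive depth-first traversal", {
  for (seed in 1:3) {
    s <- load_schema(random_wiki_schema(seed), "wiki")
    n <- 0
    walk <- function(node) {
      n <<- n + 1
      for (ch in node$children) walk(ch)
    }
    for (r in s$roots) walk(r)
    expect_equal(schema_stats(s)$n_total, n)
  }
})
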