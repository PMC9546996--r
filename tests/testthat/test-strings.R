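# Parsing, canonicalization, short/long conversion, and validation.

test_that("parser preserves nesting structure", {
  s <- parse_hed("A, (B, (C, D))")
  expect_length(s$members, 2)
  expect_s3_class(s$members[[1]], "hed_tag")
  expect_equal(s$members[[1]]$text, "A")
  g <- s$members[[2]]
  expect_s3_class(g, "hed_group")
  expect_equal(g$members[[1]]$text, "B")
  expect_equal(g$members[[2]]$members[[2]]$text, "D")

  s2 <- parse_hed("Sensory-event, ((Triangle, Red), (Square, Green))")
  expect_length(s2$members, 2)
  expect_length(s2$members[[2]]$members, 2)
  expect_true(all(vapply(s2$members[[2]]$members,
                         function(m) length(m$members) == 2, logical(1))))
})

test_that("parse and serialize are mutually inverse on generated strings", {
  for (seed in 1:20) {
    txt <- random_hed_text(seed)
    expect_identical(format(parse_hed(txt)), txt)
  }
})

test_that("grammar violations are rejected with positions", {
  expect_error(parse_hed("A, (B, C"), class = "hedkit_unbalanced_parens")
  expect_error(parse_hed("A, B)"), class = "hedkit_unbalanced_parens")
  expect_error(parse_hed("A (B)"), class = "hedkit_unbalanced_parens")
  expect_error(parse_hed("A,,B"), class = "hedkit_empty_tag")
  expect_error(parse_hed("A, B,"), class = "hedkit_empty_tag")
  expect_error(parse_hed("()"), class = "hedkit_empty_tag")
  expect_error(parse_hed("   "), class = "hedkit_empty_tag")
  err <- tryCatch(parse_hed("A, (B, C"), condition = identity)
  expect_false(any(is.na(err$span)))
})

test_that("to_long expands short forms and is idempotent", {
  schemas <- base_schemas()
  expect_equal(
    format(to_long(parse_hed("Visual-presentation"), schemas)),
    "Property/Sensory-property/Sensory-presentation/Visual-presentation")
  long <- to_long(parse_hed("Sensory-event, (Red, Triangle)"), schemas)
  expect_identical(format(to_long(long, schemas)), format(long))
  # values and units survive
  expect_equal(format(to_long(parse_hed("Duration/0.5 s"), schemas)),
               "Property/Data-property/Duration/0.5 s")
  expect_error(to_long(parse_hed("Nope-nope"), schemas),
               class = "hedkit_tag_not_found")
})

test_that("to_short inverts to_long over every fixture node", {
  schemas <- base_schemas()
  for (path in schema_paths()) {
    long <- to_long(parse_hed(path), schemas)
    short <- to_short(long, schemas)
    expect_identical(format(to_long(short, schemas)), format(long))
    term <- utils::tail(strsplit(path, "/", fixed = TRUE)[[1]], 1)
    expect_identical(format(short), term)
  }
  expect_equal(format(to_short(parse_hed("Event"), base_schemas())), "Event")
})

test_that("library tags convert with their namespace preserved", {
  schemas <- merge_libraries(base_schema(), list(sc = clinical_lib()))
  expect_equal(format(to_long(parse_hed("sc:Spike"), schemas)),
               "sc:Base/Spike")
  expect_equal(format(to_short(parse_hed("sc:Base/Spike"), schemas)),
               "sc:Spike")
})

test_that("canonical form is invariant under member permutations", {
  schemas <- base_schemas()
  expect_identical(canonical("(Red, Triangle)", schemas),
                   canonical("(Triangle, Red)", schemas))
  expect_identical(canonical("Event", schemas), "Event")
  target <- parse_hed(random_hed_text(99, n_tags = 10))
  ref <- canonical(target, schemas)
  set.seed(7)
  for (i in 1:100) {
    expect_identical(canonical(shuffle_members(target), schemas), ref)
  }
})

test_that("short/long round trip preserves canonical form", {
  schemas <- base_schemas()
  for (seed in 21:35) {
    x <- parse_hed(random_hed_text(seed))
    expect_identical(canonical(to_short(to_long(x, schemas), schemas), schemas),
                     canonical(to_long(x, schemas), schemas))
  }
})

test_that("validation checks values, units, duplicates, and defs", {
  schemas <- base_schemas()
  defs <- collect_definitions(
    "(Definition/ScreenSetup, (Visual-presentation, (Width/50 cm, Height/30 cm)))")$defs
  expect_equal(nrow(validate_hed("Def/ScreenSetup", schemas, defs)), 0)
  expect_equal(validate_hed("Def/Nonexistent", schemas)$code, "DEF_UNDEFINED")
  expect_equal(validate_hed("Duration/5 parsecs", schemas)$code,
               "INVALID_UNITS")
  expect_equal(validate_hed("Duration/fast", schemas)$code, "INVALID_UNITS")
  expect_equal(nrow(validate_hed("Duration/0.5 ms", schemas)), 0)
  expect_equal(validate_hed("Red/5", schemas)$code,
               "VALUE_WITHOUT_PLACEHOLDER")
  dup <- validate_hed("(Red, Red)", schemas)
  expect_equal(dup$code, "DUPLICATE_TAG_IN_GROUP")
  expect_equal(dup$severity, "warning")
  # identical tags in different groups are fine
  expect_equal(nrow(validate_hed("(Red, Triangle), (Red, Square)", schemas)), 0)
  # short and long spellings of one tag in a group still collide
  expect_equal(
    validate_hed("(Red, Property/Sensory-property/Sensory-attribute/Color/Red)",
                 schemas)$code,
    "DUPLICATE_TAG_IN_GROUP")
})

test_that("Definition group syntax is enforced", {
  schemas <- base_schemas()
  expect_equal(nrow(validate_hed(
    "(Definition/Ok, (Visual-presentation))", schemas)), 0)
  expect_true("DEF_SYNTAX" %in% validate_hed(
    "(Definition/Bad, Visual-presentation)", schemas)$code)
  expect_true("DEF_SYNTAX" %in% validate_hed(
    "(Definition/Bad, Definition/Worse, (Red))", schemas)$code)
  expect_true("DEF_SYNTAX" %in% validate_hed(
    "(Definition/Bad, (Def/Other))", schemas)$code)
  expect_true("DEF_SYNTAX" %in% validate_hed("Definition/Loose", schemas)$code)
})

test_that("k injected faults are recovered with exactly their issue codes", {
  schemas <- base_schemas()
  clean <- "Sensory-event, (Triangle, Red), Visual-presentation"
  faults <- list(
    list(text = "Unknown-term-xq", code = "TAG_NOT_FOUND"),
    list(text = "Duration/9 parsecs", code = "INVALID_UNITS"),
    list(text = "Def/Missing-def", code = "DEF_UNDEFINED"),
    list(text = "(Green, Green)", code = "DUPLICATE_TAG_IN_GROUP"),
    list(text = "Red/12", code = "VALUE_WITHOUT_PLACEHOLDER")
  )
  set.seed(11)
  for (rep in 1:10) {
    k <- sample(1:5, 1)
    chosen <- sample(faults, k)
    txt <- paste(c(clean, vapply(chosen, `[[`, "", "text")), collapse = ", ")
    issues <- validate_hed(txt, schemas)
    expect_equal(sort(issues$code),
                 sort(vapply(chosen, `[[`, "", "code")))
  }
})

test_that("issues serialize as stable JSON-lines", {
  schemas <- base_schemas()
  lines <- issues_to_json(validate_hed("Duration/5 parsecs", schemas))
  expect_length(lines, 1)
  rec <- jsonlite::fromJSON(lines[1])
  expect_named(rec, c("code", "severity", "span", "detail"))
  expect_equal(rec$code, "INVALID_UNITS")
})
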