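# Enduring-event resolution, Event-context insertion, timelines.

movie_defs <- function() {
  collect_definitions(list(
    "(Definition/PlayMovie, (Visual-presentation, Label/movie-clip))",
    "(Definition/Distract, (Auditory-presentation))"))$defs
}

movie_assembled <- function(onsets = c(10, 20, 30, 50, 90, 100, 110)) {
  ann <- list(
    "Sensory-event",
    "(Def/PlayMovie, Onset)",
    "Sensory-event, Red",
    "Agent-action",
    "Sensory-event, Green",
    "(Def/PlayMovie, Offset)",
    "Sensory-event, Blue")
  make_assembled(onsets, ann)
}

test_that("Onset/Offset pairs resolve to closed intervals", {
  sc <- resolve_scopes(movie_assembled(), movie_defs())
  expect_length(sc$intervals, 1)
  iv <- sc$intervals[[1]]
  expect_equal(iv$def_name, "PlayMovie")
  expect_equal(c(iv$start, iv$end), c(20, 100))
  expect_false(iv$unclosed)
  expect_equal(nrow(sc$issues), 0)
  # annotation holds the expanded definition, markers removed
  expect_match(format(iv$annotation), "Def-expand/PlayMovie", fixed = TRUE)
  expect_no_match(format(iv$annotation), "Onset")
})

test_that("re-onset closes the prior interval; stray offsets are errors", {
  defs <- movie_defs()
  asm <- make_assembled(c(10, 30, 50), list(
    "(Def/PlayMovie, Onset)", "(Def/PlayMovie, Onset)",
    "(Def/PlayMovie, Offset)"))
  sc <- resolve_scopes(asm, defs)
  spans <- t(vapply(sc$intervals, function(iv) c(iv$start, iv$end),
                    numeric(2)))
  expect_equal(spans, rbind(c(10, 30), c(30, 50)))

  stray <- resolve_scopes(make_assembled(5, list("(Def/PlayMovie, Offset)")),
                          defs)
  expect_equal(stray$issues$code, "OFFSET_WITHOUT_ONSET")
  expect_equal(stray$issues$severity, "error")
})

test_that("unclosed intervals end at the last event with a warning", {
  sc <- resolve_scopes(make_assembled(c(5, 40), list(
    "(Def/PlayMovie, Onset)", "Sensory-event")), movie_defs())
  expect_equal(sc$intervals[[1]]$end, 40)
  expect_true(sc$intervals[[1]]$unclosed)
  expect_equal(sc$issues$code, "UNCLOSED_ONSET")
  expect_equal(sc$issues$severity, "warning")
})

test_that("Duration groups create closed intervals, several per event", {
  sc <- resolve_scopes(make_assembled(10, list(
    "(Red, Duration/2 s), (Green, Duration/500 ms)")), movie_defs())
  spans <- t(vapply(sc$intervals, function(iv) c(iv$start, iv$end),
                    numeric(2)))
  expect_equal(spans[order(spans[, 2]), ], rbind(c(10, 10.5), c(10, 12)))
})

test_that("intervening events inherit a single Event-context group", {
  defs <- movie_defs()
  asm <- movie_assembled()
  sc <- resolve_scopes(asm, defs)
  out <- insert_event_context(asm, sc, base_schemas())
  texts <- vapply(out$events, function(e) format(e$annotation), character(1))
  with_ctx <- grepl("Event-context", texts, fixed = TRUE)
  # events at 30, 50, 90 are inside [20, 100); 10 and 110 outside;
  # the marker rows at 20 and 100 are excluded by construction
  expect_equal(with_ctx, c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_match(texts[3], "Def-expand/PlayMovie", fixed = TRUE)
  # a second insertion is rejected
  expect_error(insert_event_context(out, sc), class = "hedkit_error")
})

test_that("an event simultaneous with the Offset is outside the half-open span", {
  defs <- movie_defs()
  asm <- make_assembled(c(20, 100, 100), list(
    "(Def/PlayMovie, Onset)", "Sensory-event", "(Def/PlayMovie, Offset)"))
  sc <- resolve_scopes(asm, defs)
  out <- insert_event_context(asm, sc)
  expect_no_match(format(out$events[[2]]$annotation), "Event-context")
})

test_that("context insertion agrees with a brute-force overlap oracle", {
  set.seed(42)
  n_ev <- 300
  n_iv <- 30
  onsets <- sort(round(stats::runif(n_ev, 0, 1000), 3))
  asm <- make_assembled(onsets, as.list(rep("Sensory-event", n_ev)))
  starts <- round(stats::runif(n_iv, 0, 900), 3)
  ends <- starts + round(stats::runif(n_iv, 1, 120), 3)
  ivs <- lapply(seq_len(n_iv), function(k) {
    list(def_name = sprintf("Scope%02d", k), start = starts[k], end = ends[k],
         annotation = hedkit:::hed_group(list(hedkit:::hed_tag("Red"))),
         open_row = -1L, close_row = -2L, unclosed = FALSE)
  })
  scopes <- structure(list(intervals = ivs, issues = hedkit:::hed_issues()),
                      class = "hed_scopes")
  out <- insert_event_context(asm, scopes)
  for (i in seq_len(n_ev)) {
    expected <- sum(starts <= onsets[i] & onsets[i] < ends)
    ctx <- Filter(hedkit:::is_context_group, out$events[[i]]$annotation$members)
    got <- if (length(ctx) == 0) 0 else length(ctx[[1]]$members) - 1
    expect_equal(got, expected)
    expect_lte(length(ctx), 1)
  }
})

test_that("timelines place organizational scopes on their tracks", {
  schemas <- base_schemas()
  pl1 <- run_design_pipeline(generate_design(1, dir = tempfile("tl1_")))
  tb <- pl1$timeline[pl1$timeline$track == "Time-block", ]
  expect_equal(nrow(tb), 2)
  expect_setequal(tb$label, c("Block1", "Block2"))
  # Time-block intervals are disjoint (relief gap between blocks)
  expect_true(all(tb$end[-nrow(tb)] <= tb$start[-1]))
  expect_equal(sum(pl1$timeline$track == "Task"), 1)
  # every closed interval satisfies end >= start, sums within the recording
  df <- as.data.frame(pl1$scopes)
  expect_true(all(df$end >= df$start))
  for (tr in unique(pl1$timeline$track)) {
    seg <- pl1$timeline[pl1$timeline$track == tr, ]
    expect_lte(sum(seg$end - seg$start), max(pl1$events$onset))
  }
  # no organizational tags -> empty timeline
  defs <- movie_defs()
  sc <- resolve_scopes(movie_assembled(), defs)
  expect_equal(nrow(extract_timeline(sc, defs, schemas)), 0)
})

test_that("design 3 yields one Condition-variable interval per trial", {
  pl3 <- run_design_pipeline(generate_design(3, n_blocks = 2,
                                             trials_per_block = 10,
                                             dir = tempfile("tl3_")))
  cv <- pl3$timeline[pl3$timeline$track == "Condition-variable", ]
  expect_equal(nrow(cv), 20)
  expect_setequal(unique(cv$label), c("CondA", "CondB"))
})

test_that("timeline JSON export round-trips", {
  pl <- run_design_pipeline(generate_design(1, trials_per_block = 2,
                                            dir = tempfile("tlj_")))
  txt <- timeline_to_json(pl$timeline)
  back <- jsonlite::fromJSON(txt)
  expect_equal(nrow(back), nrow(pl$timeline))
  expect_named(back, c("track", "label", "start", "end"))
})
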