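# hedkit

Annotating events in electrophysiological and other time-series recordings
with third-generation Hierarchical Event Descriptors (HED), in R.

EEG/MEG analysis lives and dies by its event annotations, yet shared
datasets typically record little more than lab-jargon event codes. HED
addresses this with a hierarchical controlled vocabulary in which **every
term is unique**, so an annotation can be written in compact short form —

```
Sensory-event, ((Triangle, Red), (Square, Green))
```

— and expanded mechanically to full vocabulary paths, validated, searched,
and shared. `hedkit` implements the annotation engine for researchers and
tool builders working with BIDS-style datasets:

* **Schemas** — load the wiki (human-edited) and XML (machine) dialects,
  lint them (unique-mapping rule, structural sparsity: fewer than 10
  children per node, ideally 3–7), and merge namespaced library schemas
  (`sc:Spike`) for subfield vocabularies.
* **Strings** — parse the comma/parenthesis grammar, validate against a
  schema (values, unit classes, duplicates, definitions), convert
  short ↔ long form, and compute an order-insensitive canonical form.
* **Definitions** — register `(Definition/Name, (contents))` groups and
  expand `Def/Name` references into `(Def-expand/Name, ...)` groups,
  including valued definitions (`Def/Pause/2.5`).
* **BIDS event assembly** — combine `_events.tsv` tables with `_events.json`
  sidecars (categorical maps and `#` value templates) into validated
  per-event annotations.
* **Temporal scope** — resolve *enduring events* from
  `(Def/Name, Onset)`/`(Def/Name, Offset)` pairs and `Duration/v` groups,
  insert `(Event-context, ...)` copies of all ongoing scopes into
  intervening events, and extract experiment timelines from the
  organizational tags (`Task`, `Time-block`, `Condition-variable`,
  `Experimental-trial`, `Recording`).
* **Search and epochs** — boolean tag queries with subtree matching
  (`2D-shape` finds `.../2D-shape/Triangle`), and time-locked epoch-window
  extraction around matching events.
* **Synthetic fixtures** — a bundled miniature base schema (six top-level
  categories: Event(7), Agent(6), Action(5), Item(4), Property(7),
  Relation(5)) and generators for three classic experiment designs, so the
  whole pipeline runs offline.

A command-line front end (`exec/hedkit`, or `hed_cli()` from R) exposes
`validate`, `lint`, `convert`, `expand`, `assemble`, `context`, `timeline`,
`query`, `epochs`, and `generate` subcommands with JSON-lines issue
reports.

## Worked example

```r
library(hedkit)
schemas <- hed_schemas(build_fixture_schema())
schemas$base
#> <hed_schema> base, version 1.0.0: 6 top-level categories, 96 terms
#> Event(7), Agent(6), Action(5), Item(4), Property(7), Relation(5)

format(to_long(parse_hed(
  "Sensory-event, ((Triangle, Red), (Square, Green))"), schemas))
#> Event/Sensory-event, ((Item/Object/Geometric-object/2D-shape/Triangle,
#>   Property/Sensory-property/Sensory-attribute/Color/Red),
#>   (Item/Object/Geometric-object/2D-shape/Square,
#>   Property/Sensory-property/Sensory-attribute/Color/Green))
```

Generate a synthetic recording (design 1: one task and condition spanning
the recording, two time blocks of ten trials), run the pipeline, and look
at the extracted timeline:

```r
paths <- generate_design(1, dir = tempfile())
pl <- run_design_pipeline(paths)
pl$timeline[pl$timeline$track != "Experimental-trial", ]
#>                 track    label start end
#> 1  Condition-variable    CondA     0  54
#> 22               Task MainTask     0  54
#> 23         Time-block   Block1     2  22
#> 24         Time-block   Block2    32  52
```

The two `Time-block` intervals are separated by the relief-break gap; the
task and condition scopes span the recording. Search for participant
responses and cut epoch windows around them:

```r
hits <- search_events(pl$assembled, "Agent-action", schemas)
length(hits)
#> [1] 20                 # 2 blocks x 10 trials, one response each
ep <- extract_epochs(pl$assembled, hits, pre = 0.2, post = 0.8,
                     paths$record_span)
head(ep$windows, 3)
#>   anchor onset start end
#> 1      4   3.1   2.9 3.9
#> 2      7   5.1   4.9 5.9
#> 3     10   7.1   6.9 7.9
```

All 20 windows fit inside the recording span; windows that crossed the
boundary would be flagged and dropped rather than truncated.

See `vignettes/hedkit-methods.Rmd` for the full account of the model, the
numerical conventions (half-open scope membership, marker-row exclusion,
canonical ordering), and the design of the synthetic recordings.

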