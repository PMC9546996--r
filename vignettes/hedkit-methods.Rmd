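---
title: "Annotating events with hierarchical event descriptors: the hedkit methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating events with hierarchical event descriptors: the hedkit methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hedkit)
```

## The annotation model

Electrophysiological recordings (EEG, MEG, intracranial) are interpreted
relative to *events*: stimulus presentations, participant actions, data
features, experiment-control changes. A Hierarchical Event Descriptor (HED)
annotation describes one event as a comma-separated list of *tags* —
slash-delimited paths into a controlled vocabulary tree — and parenthesized
*tag groups* that bind modifiers to the items they modify, nested to any
depth:

```
Sensory-event, ((Triangle, Red), (Square, Green))
```

Two structural rules drive everything hedkit does:

1. **Unique mapping.** Every term name appears at exactly one position in a
   schema. Annotators may therefore write any *short form* — a node name or
   any partial path suffix — and tools expand it mechanically to the full
   *long form* path. `load_schema()` refuses schemas that violate the rule;
   `check_uniqueness()` lints permissively loaded ones.
2. **Grouping.** Parentheses carry meaning (a red triangle and a green
   square is not the same stimulus as a green triangle and a red square),
   but *member order does not*. `canonical()` defines the equivalence:
   expand to long form, then recursively sort members (tags before groups,
   both lexicographically, locale-independent radix order). Two annotations
   are equivalent iff their canonical texts are equal.

Schemas come in two dialects sharing one tree model: an indented wiki
dialect for human editing (asterisk depth, `{attribute}` braces,
`[description]` brackets, a `!# unit-classes` section) and an XML dialect
for machine processing. The two serializers are exact inverses; the test
suite round-trips randomly generated schemas through both.

### Libraries and namespaces

Subfield vocabularies are separate *library schemas* merged under short
namespace identifiers (`merge_libraries()`). Lookup is namespace-scoped: a
tag written `sc:Spike` resolves only in library `sc`, and an unprefixed tag
resolves only in the base schema. We considered allowing libraries to
shadow base terms and rejected it: with scoped lookup, collisions across
independently developed libraries are harmless and no resolution order has
to be specified. A consequence is that the cross-library "ambiguous tag"
error can never arise; unprefixed tags simply never enter a library.

### Values and unit classes

A `#` child node marked `takesValue` admits a trailing value segment
(`Experimental-trial/3`, `Duration/0.5 s`). When the placeholder carries a
`unitClass`, the text after the last space is interpreted as units and
checked for class membership, and the remainder must be numeric
(`Duration/5 parsecs` and `Duration/fast` both fail with
`INVALID_UNITS`). The bundled unit classes are `time` (`s` default, `ms`)
and `physicalLength` (`m` default, `cm`, `mm`) — the minimal set needed for
event durations and screen-geometry definitions. Values without units
assume the default unit.

### Validation order and severities

`validate_string()` reports *all* issues, in a fixed order per tag:
resolution, value/placeholder consistency, unit membership, duplicate tags
within one group, `Def` reference resolution, `Definition` group syntax,
extension warnings. Severity policy: structural and semantic violations are
errors; repeated identical tags within a group and schema extensions below
an `extensionAllowed` node are warnings (legal, but worth review); child
counts outside the ideal 3–7 band are notes, since the hard "fewer than 10"
guidance is the only count rule worth a warning. Empty parentheses and
trailing commas are parse errors rather than being silently dropped —
silently repairing an annotation hides exactly the kind of sloppiness
validation exists to catch.

## Definitions

`(Definition/Name, (contents))` registers a reusable named group;
`Def/Name` references it. At analysis time `expand_defs()` replaces the
reference with `(Def-expand/Name, (contents))`, keeping the inserted tags
associated with their definition; `contract_defs()` inverts the expansion,
and both directions are exercised as a lossless round trip. Contents may
not contain definition machinery, so expansion is guaranteed
non-recursive. Definitions whose contents contain a `#` placeholder take a
value (`Def/Pause/2.5` substitutes `2.5` for `#` in the copy); referencing
a valued definition without a value is an error rather than a silent
default, the minimal consistent extension of the `#` convention used in
sidecars and numbered trials. Definition declarations found during event
assembly are collected and *removed* from row annotations: they declare
vocabulary, they are not event content.

## Event assembly (BIDS dialect)

`assemble()` builds one annotation per events-table row from three sources:
categorical sidecar maps (cell value → HED string), value-column templates
(`#` replaced by the cell text, then unit-checked), and a literal `HED`
column. Column order is sorted column names with the literal column last —
the formats themselves fix no order, so determinism has to come from a
convention, and byte-identical reruns matter more than any particular
choice. When a categorical map and a literal column both annotate a row,
both contribute (concatenation loses nothing; precedence would). `n/a`
cells contribute nothing; unmapped categorical values and annotation-free
rows are warnings, not failures.

## Temporal scope and Event-context

Enduring events are opened by `(Def/Name, Onset)` and closed by
`(Def/Name, Offset)` or by a repeated Onset for the same name; a group
containing `Duration/v` yields a closed interval `[onset, onset + v]`
directly, several per event if needed. All tags in an Onset or Duration
group apply throughout the span. Numerical conventions, each chosen once:

* **Half-open membership `[start, end)`.** An event simultaneous with the
  Offset is outside; an event at the Onset instant (other than the marker
  row itself) is inside. Half-open intervals avoid double-counting at
  re-onset boundaries, where one instant both closes and opens a scope.
* **Marker rows are excluded** from their own scope's context: inheriting
  a movie's ongoing-presentation context must not suggest that ordinary
  intervening events share the distinct neural signatures of the
  presentation onset and offset events themselves.
* **Unclosed scopes** end at the last event's onset, with a warning — the
  events file does not know the recording's true end, and an unbounded
  interval would poison every downstream overlap computation.
* **Duration-created intervals** participate in context insertion exactly
  like Onset/Offset intervals.

`insert_event_context()` appends exactly one `(Event-context, ...)` group
per event, holding one copy of the annotation of each ongoing enduring
event, ordered by `(start, def_name)`; copies are stored long-form when a
schema is supplied, since context consumers should not need the original
short forms. Inserting twice is an error, not a no-op — double context is
an analysis bug worth surfacing. The insertion is verified against a
brute-force overlap oracle over all (event, interval) pairs (1000 random
events × 50 random intervals in the acceptance suite).

`extract_timeline()` places each enduring event whose annotation carries an
organizational tag (`Task`, `Time-block`, `Condition-variable`,
`Experimental-trial`, `Recording`) on the matching track, labelled by its
definition name (or the organizational tag's value for unnamed
Duration-scopes). Gaps between intervals are recording time outside any
scope — relief breaks, setup changes.

## Search and epochs

Query terms resolve through the same short-form machinery as annotations,
so `2D-shape` finds `.../2D-shape/Triangle` by subtree (path-prefix)
matching; terms carrying a value require an exact value match instead.
Boolean operators are standard, with `NOT` binding tightest, then `AND`,
then `OR`. Matching searches inside groups including Event-context by
default; an `--exclude-context` switch restricts matching to an event's
direct annotation, since context tags have a different causal status than
tags describing the event itself. Epoch extraction returns
`[anchor − pre, anchor + post]` windows, *dropping* (not truncating)
windows that cross the recording span — a truncated epoch has a different
baseline and biases averages. Slicing actual signal arrays is deliberately
out of scope: the package handles annotations, not EEG payloads.

## The synthetic recordings

`generate_design()` emulates the three standard ways of organizing a simple
two-task, two-condition study; it exists so that every stage — assembly,
definitions, scopes, context, timelines, search — can be tested offline on
data with known ground truth. Each trial holds exactly three events
(stimulus, response, feedback). Defaults are the study conditions used
throughout the tests: 2 blocks × 10 trials, a 2 s trial period. Within a
trial period the stimulus falls at 0.25, the response at 0.55, and the
feedback at 0.85 of the period, with a 0.7-period trial scope — offsets
chosen so that block-boundary marker rows never fall inside a trial scope
and consecutive scopes never touch. Inter-block gaps are five trial
periods, giving timelines visible gaps. Design 3 draws each trial's
condition from two labels with equal probability using one seeded
generator; the seed is recorded in the sidecar metadata and identical
seeds give byte-identical files. Counterbalancing *across* recordings
(design 1's study-level scheme) is representable only as independent
single-recording calls with different parameters.

What the generator does **not** emulate: real codebases' missing and
malformed cells beyond `n/a`, annotation typos, jittered inter-trial
timing, nested or overlapping task hierarchies, and any signal content.
Passing the pipeline on these fixtures therefore demonstrates the engine's
bookkeeping — resolution, expansion, scoping, context — not robustness to
the full messiness of shared datasets.

## Problem sizes and tolerances

The test and acceptance runs use desk-scale sizes chosen to exercise every
code path while keeping a full run to well under a minute per suite:
designs at 2 × 10 (and 2 × 3–5 for multi-seed smoke runs), 200 trials for
the design-3 balance check against 99% binomial bounds, 1000 × 50 for the
context oracle, and 100 random permutations for canonical-form invariance.
All comparisons on counts and interval endpoints are exact; nothing in the
engine is approximate except the usual floating-point representation of
onsets, which the half-open membership rule handles without tolerance
terms because generated onsets and bounds are identical binary values.

## Known limitations

* Orthogonality ("terms used independently belong in different subtrees")
  is a design guideline that cannot be machine-checked without usage data;
  only uniqueness and sparsity are linted.
* The wiki dialect is this package's own layout for the indented format;
  other tools' wiki layouts are not parsed.
* Definitions referencing library tags must carry their namespace prefix;
  there is no per-definition default namespace.
* A short form may include a namespace plus partial path
  (`sc:Base/Spike`); annotations relying on this should note that other
  toolchains may restrict short forms to single terms.
* `Recording`-level metadata harvesting from dataset auxiliary files, and
  rendering of timelines, are out of scope; `timeline_to_json()` exports
  records for external plotting.
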