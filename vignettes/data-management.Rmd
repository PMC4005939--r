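---
title: "Unified data and metadata management for electrophysiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unified data and metadata management for electrophysiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephystore)
```

## The object model

`ephystore` combines two complementary modelling ideas. Recorded data
follow a *fixed* schema, because sampled signals and sorted spikes have
a stable structure across experiments: a **block** (one dataset) holds
**segments** (experimental trials); each segment holds **analog
signals** (regularly sampled series defined by a start time, a sampling
rate and a value array), **spike trains** (sorted spike times of one
unit within `[t_start, t_stop)`) and stimulus **events**; **recording
channel groups** and **channels** describe the electrode layout, and
**units** are the spike-sorted neurons. Metadata follow a *maximally
flexible* schema, because experimental context varies without bound:
nested **sections** group **properties**, each holding **values**; any
data object can be *annotated* by linking it to metadata values, and
those links are what make data selectable by experimental context.

The attribute table for each kind — which attributes are required,
their types, their unit dimensions, and which parent links are
mandatory — is frozen in a declarative table (`object_schema()`). The
kinds themselves are a closed set. Published descriptions of this class
of data model name the objects but not a normative attribute list, so
the table here is this package's own reconstruction of the minimal
useful schema; `comment` is the one free-text attribute allowed
everywhere.

Two deliberately strict choices in validation:

* **Units form a closed table** (time: `s/ms/us`; frequency: `Hz/kHz`;
  voltage: `V/mV/uV`). Unknown symbols are errors, not pass-through —
  silent unit pollution is worse than an early failure. Conversion
  within a dimension is exact rescaling; round-tripping through the
  base unit reproduces values to better than 1e-12 relative.
* **Spike trains must arrive sorted**, with all times in
  `[t_start, t_stop)`. Unsorted input is rejected rather than silently
  sorted: a reordering the caller did not ask for can mask an upstream
  bug (swapped columns, concatenated trials).

Metadata values are plain text-or-number scalars. odML-style models
optionally give values units and uncertainties; we left both out — no
workflow in scope reads them, and a value with units can always be
modelled as a property in a section whose name carries that meaning.

## Versioning

Every mutation — create, update, annotation, delete — appends a new
version instead of overwriting. For one object id, version validity
intervals partition time contiguously from creation onward, so the
state at any instant `t` is the unique version with
`valid_from <= t < valid_to`. `at_time` reads are therefore exact time
travel, and an independent replay of the operation log is the oracle
the test suite checks them against.

Deletion writes a *tombstone* version: the object disappears from live
reads and queries (404 semantics) and refuses further updates (410),
but every pre-delete state remains readable through `at_time`. This is
the only interpretation that satisfies both halves of the contract
"removed objects no longer appear, yet all changes remain tracked".

Mechanical details that the protocol names but does not define, decided
here: the e-Tag is a 64-bit hash of (id, version start, version
counter) — opaque, cheap, and guaranteed to differ between successive
versions; `Last-Modified` is the current version's start;
timestamps are UTC with microsecond resolution, and an update whose
supplied timestamp does not advance past the current version start is
nudged forward by 1 µs rather than rejected, so the partition invariant
can never be violated by clock granularity. Annotation **does** create
a new version (the rule is "every change re-tags"); ACL changes do
**not**, because permissions are administrative state layered beside
the object, not object content — sharing a dataset should not appear
in its scientific history.

Object ids are 10 characters over the RFC 4648 base-32 alphabet,
drawn randomly with collision retry; 32^10 ≈ 1.1e15 tokens make
collisions a non-event at laboratory scales.

## Partial array requests

Arrays are stored one HDF5 dataset per file, at the file root. A sliced
download carries raw numbers only — units, start time and sampling rate
must be read from the owning object, which is what makes the slice file
self-consistently minimal.

A requested window resolves against the object's own attributes:
missing start defaults to `t_start`, the end comes from `end_time` or
`start + duration`, defaulting to the end of the signal. Windows are
**half-open** `[start, end)`. The published description of this feature
("samples falling within the window") does not fix boundary inclusion;
half-open is the only convention under which slices over a partition of
the time axis reconstruct the signal with no duplicate and no gap, and
it matches the `[t_start, t_stop)` convention of spike trains.

Sample `i` (0-based) sits at `t_start + i / rate`; the slice is
`{ i : start <= t_i < end }`, reported as *inclusive* first/last
indices (that is the printed protocol shape), clamped to the array.
Boundary comparison uses a relative tolerance of 1e-9 on canonical
seconds: converting `50 ms` through the unit table can land a hair off
an exact sample time, and without the tolerance an off-by-one at an
exact boundary would be seed-dependent. 1e-9 is far below one sample
period at any realistic rate (it would matter only above ~1 GHz
sampling) and far above double rounding error.

## Queries, visibility, access control

Filters use the Django lookup dialect (`field__lookup=value`), a closed
set of eleven lookups, and relationship paths of depth at most two
(`property__section__name__icontains=...`). Multiple filters AND
together — the dialect has no OR syntax, and none is invented here. A
`metadata=id1,id2` filter demands annotation with *all* listed values
(the plural "have these values as their metadata" reads as a
conjunction, and the disjunction is expressible as two queries).
Results are ordered stably by (version start, id) — no order is
specified anywhere, but pagination without a stable order is
meaningless — and paginated with a default page of 100 and a hard cap
of 1000. `at_time` in a query selects versions *before* filtering, so
historical queries see the store as it was.

Access control is one ACL per object: a safety level (`private` or
`public`) plus individual shares at `read` or `read-write`. The owner
always has read-write and cannot be demoted or listed as a share.
Groups are out of scope — the described sharing workflows ("open the
study to contributors, make certain trials read-only") only require
per-object ACLs, which is also why ACLs do not cascade implicitly; a
`recursive` flag on `set_acl()` applies one ACL down the containment
tree for convenience, touching only objects the caller owns. Query
visibility is definitionally `effective_access != "none"`, and a
property-based test holds the two accountable to each other.

## The request interface

`route_request()` is the single dispatcher: GET lists/filters or reads
one object, POST creates (201), updates (200), or bulk-updates via a
`{ids?/filters?, fields}` body, DELETE removes one object or
bulk-deletes by filter; `.../acl/` answers GET and POST and returns
405 on DELETE. Errors are JSON `{"message": ...}` with 400/403/404/
405/410/412. Conditional GET honours `If-None-Match` (e-Tag) and
`If-Modified-Since` with 304. The response envelope for lists
(`{objects, total, offset, max_results}`) and the ACL document shape
(`{safety_level, shared_with}`) are this package's own, as the source
protocol's figures for them are not reproduced in text.

The dispatcher is a pure function of (store, request); `serve_http()`
maps real sockets onto it via httpuv, and the client library speaks the
identical contract through an in-process transport. Every protocol
property — verbs, codes, caching, envelopes — is exercised on the
dispatcher itself, which keeps the tests hermetic. The client saves
with `If-Match` (optimistic concurrency; a stale e-Tag is a 412
conflict rather than a lost update), fetches arrays lazily, and keeps
an e-Tag cache that never serves an entry without revalidation — the
cache can change transfer counts, never data.

## The synthetic experiment

`generate_experiment()` emulates the structure of a visual-stimulation
receptive-field study: per trial, one segment with a stimulus event,
one LFP signal per channel, one spike train per unit, and a stimulus
metadata section (orientation, size) whose values annotate the
segment. Defaults: 4 trials, 12 channels (RC1–RC12), 3 units (U1–U3),
1000 samples at 1 kHz (1 s trials).

Only the *structure* is prescribed by the emulated figure; the numbers
are this package's choices, made once: LFPs are 5-point
moving-average-filtered Gaussian noise scaled to ~100 µV (the amplitude
scale of cortical LFPs; the filter gives mild temporal correlation so
slices are visually signal-like); spike trains are homogeneous Poisson
with per-unit rates drawn uniformly in 5–25 Hz (typical sustained
cortical firing); orientations are multiples of 30° and sizes come
from {0.5, 1, 2, 4}°. Generation is a pure function of the spec —
equal seeds give bit-identical graphs, and the generator restores the
caller's RNG state.

What the generator does **not** emulate: realistic LFP spectra (1/f
power, oscillations), spike waveforms, stimulus-locked responses,
cross-channel correlation, or recording artefacts. Passing tests
therefore demonstrate the *management* contract — storage, versioning,
querying, slicing, sharing round-trip fidelity — not any claim about
analysing real neural signals.

## Problem sizes and numerical choices

The test and acceptance runs use: 1,000 random windows for the slicing
oracle; 500 random operation logs (up to five operations each, probed
at and between every boundary) for the versioning oracle; random stores
of roughly 280 objects across four actors for the query oracle; and the
default 4x12x3 experiment (106 objects, 60 arrays) for the end-to-end
round-trip. These sizes give each property thousands of individual
checks while keeping a full run in the order of a minute.

Degenerate inputs are defined behaviour: empty arrays store and load
(HDF5 zero-length datasets); empty spike-train slices are empty
results, not errors; windows that miss every sample, empty windows, and
windows wholly outside the signal are 400s; an `offset` past the end
returns an empty page with the true total.

## Known limitations

Single-process, in-memory catalogue (arrays on disk): no concurrency
or durability guarantees — the store interface would admit a
transactional backend, but that is delegated infrastructure, not
modelled here. Identity is a pluggable stub mapping bearer tokens to
user ids; real authentication is out of scope. No full-text search, no
group ACLs, no file-format import of vendor recordings, no
downsampling of slices. Filters target scalar attributes and
relations, not array contents.
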