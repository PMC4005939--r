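# ephystore

Versioned data management for electrophysiology in R.

## The problem

Electrophysiology labs accumulate recordings whose meaning lives as much
in the surrounding context — stimulus parameters, electrode layout,
trial structure — as in the sampled numbers. `ephystore` implements a
data-management platform that keeps both together: a fixed object model
for the recorded data (a *block* of trials, each *segment* holding
*analog signals*, *spike trains* and stimulus *events*, with *recording
channels* and spike-sorted *units* as sources) combined with a fully
flexible hierarchy of key-value metadata (*sections* grouping
*properties*, each holding *values*). Any data object can be annotated
by linking it to metadata values, which makes the data selectable by
experimental context ("all trials with orientation = 30°").

It is aimed at labs and tool authors who want programmatic, queryable,
shareable access to recordings rather than a directory of files.

## What the package provides

- **Versioned object store** — every create, update, annotation and
  delete appends a new version; validity intervals partition time, so
  `at_time` retrieves any historical state. Deletes are tombstones:
  invisible live, readable historically. Every change assigns a fresh
  e-Tag.
- **HDF5-backed arrays** — signal samples and spike times are persisted
  as one HDF5 dataset in the root of their own file, and can be fetched
  partially: a requested time window `[start, end)` is converted to
  inclusive array index bounds from the object's `t_start`, sampling
  rate and units — sample *i* lives at `t_start + i / rate`, and the
  slice is the set `{ i : start ≤ t_i < end }`.
- **REST-style interface** — `route_request()` dispatches
  GET/POST/DELETE over `/namespace/object_type/[id/[acl/]]` URLs with
  JSON bodies, Django-style field lookups
  (`name__icontains=luminance`, `property__name__exact=orientation`),
  relationship traversal, metadata-driven selection, pagination,
  conditional GET (304 via e-Tags), and per-object ACLs
  (private/public plus individual read or read-write shares).
  `serve_http()` optionally exposes the same dispatcher on real sockets.
- **Native client** — `api_session()` maps remote objects to R
  structures, saves with optimistic concurrency (If-Match), keeps an
  e-Tag revalidation cache, and fetches arrays lazily, including
  server-computed time-window slices.
- **Fixture generator** — `generate_experiment()` builds a complete
  synthetic visual-stimulation experiment (multi-channel LFPs, Poisson
  spike trains, per-trial stimulus metadata), deterministic under a
  seed.

## Worked example

```r
library(ephystore)

store <- object_store()                     # arrays go to a temp dir
s     <- api_session(store, "alice")

graph <- generate_experiment(
  experiment_spec(n_trials = 4, n_channels = 12, n_units = 3, seed = 42))
experiment_counts(graph)
#>    kind                      n
#>  1 analogsignal             48      # 4 trials x 12 channels
#>  3 event                     4
#>  9 spiketrain               12      # 4 trials x 3 units
#> 11 value                     8      # orientation + size per trial
index <- push_experiment(s, graph)   # 106 objects created over the API

sig <- session_select(s, "analogsignal",
                      list(name__icontains = "RC3 trial 2"))[[1]]
sig
#> <analogsignal 6DDSNKXBI3> LFP RC3 trial 2

# fetch only the 100 ms window starting at 50 ms: the server converts
# the window to index bounds (50..149 at 1 kHz) and ships 100 samples
slice <- session_fetch_array(
  s, sig, window = list(start_time = quantity(50, "ms"),
                        duration   = quantity(100, "ms")))
length(slice)
#> [1] 100

# metadata-driven selection: stimulus orientations, then the trial
# annotated with the first one
vori <- session_select(s, "value", list(property__name__exact = "orientation"))
sapply(vori, function(v) v$fields$data)
#> [1] 180 210 150 180                 # degrees, multiples of 30
hits <- session_select(s, "segment", list(metadata = vori[[1]]$id))
sapply(hits, function(h) h$fields$name)
#> [1] "Trial 1"
```

Versioning in two lines:

```r
blk <- create_object(store, "block", list(name = "original"), "alice", now = 100)
update_object(store, blk$id, list(name = "renamed"), "alice", now = 200)
get_object(store, blk$id, "alice", at_time = 150)$fields$name
#> [1] "original"
```

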