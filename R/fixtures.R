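# Synthetic experiment generator. Emulates a visual-stimulation study of
# receptive fields: one dataset (block) of trials, each trial with its
# own stimulus configuration (orientation, size) described as metadata;
# multi-channel LFP signals from an electrode array (RC1..RC12 by
# default) and spike trains of sorted units (U1..U3) recorded per trial.
# Generation is a pure function of the spec: same spec, same seed ->
# bit-identical graphs.

#' Specification of a synthetic experiment
#'
#' Defaults emulate the canonical demonstration dataset: 4 trials, a
#' 12-channel electrode array, 3 sorted units, 1 s trials sampled at
#' 1 kHz.
#'
#' @param n_trials number of experimental trials (segments).
#' @param n_channels number of recording channels.
#' @param n_units number of spike-sorted units.
#' @param samples_per_trial samples per analog signal.
#' @param sampling_rate signal sampling rate ([quantity()], frequency).
#' @param seed integer RNG seed.
#' @return an `experiment_spec` list.
#' @export
experiment_spec <- function(n_trials = 4L, n_channels = 12L, n_units = 3L,
                            samples_per_trial = 1000L,
                            sampling_rate = quantity(1, "kHz"), seed = 42L) {
  counts <- c(n_trials = n_trials, n_channels = n_channels, n_units = n_units,
              samples_per_trial = samples_per_trial)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != floor(counts))) {
    stop_bad_request("all experiment counts must be integers >= 1")
  }
  if (!is_quantity(sampling_rate) ||
      !identical(unit_dimension(sampling_rate$units), "frequency") ||
      sampling_rate$value <= 0) {
    stop_bad_request("sampling_rate must be a positive frequency quantity")
  }
  structure(
    list(
      n_trials = as.integer(n_trials), n_channels = as.integer(n_channels),
      n_units = as.integer(n_units),
      samples_per_trial = as.integer(samples_per_trial),
      sampling_rate = sampling_rate, seed = as.integer(seed)
    ),
    class = "experiment_spec"
  )
}

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.orientations <- seq(0, 330, by = 30)   # degrees
.stim_sizes <- c(0.5, 1, 2, 4)          # degrees of visual angle

#' Generate a synthetic experiment object graph
#'
#' Produces, deterministically under the spec's seed: one block; one
#' recording channel group with `n_channels` channels and `n_units`
#' units; per trial a segment, a stimulus-onset event, one LFP signal per
#' channel (moving-average-smoothed Gaussian noise, ~100 µV scale), one
#' spike train per unit (homogeneous Poisson, per-unit rate drawn once in
#' 5–25 Hz); and per trial a stimulus metadata section with `orientation`
#' (a multiple of 30°) and `size` properties whose values annotate the
#' trial's segment.
#'
#' Objects reference each other by local keys; [push_experiment()] maps
#' them to server-assigned ids.
#'
#' @param spec an [experiment_spec()].
#' @return an `experiment_graph`: list with `spec`, `objects` (named list
#'   of `list(kind, fields)`), `order` (creation order of local keys),
#'   `annotations` (segment -> value-key links) and `params` (the drawn
#'   per-unit rates and trial duration).
#' @export
generate_experiment <- function(spec) {
  if (!inherits(spec, "experiment_spec")) spec <- do.call(experiment_spec, spec)
  with_preserved_seed(spec$seed, {
    rate_hz <- canonical_value(spec$sampling_rate, "frequency")
    dur_s <- spec$samples_per_trial / rate_hz
    unit_rates <- stats::runif(spec$n_units, min = 5, max = 25)

    objects <- list()
    order <- character()
    add <- function(key, kind, fields) {
      objects[[key]] <<- list(kind = kind, fields = fields)
      order <<- c(order, key)
    }

    add("block", "block", list(name = "synthetic receptive-field mapping dataset"))
    add("rcg", "recordingchannelgroup", list(name = "electrode array", block = "block"))
    for (c in seq_len(spec$n_channels)) {
      add(sprintf("channel_%d", c), "recordingchannel",
          list(name = sprintf("RC%d", c), index = c, recordingchannelgroup = "rcg"))
    }
    for (u in seq_len(spec$n_units)) {
      add(sprintf("unit_%d", u), "unit",
          list(name = sprintf("U%d", u), recordingchannelgroup = "rcg"))
    }
    add("sec_root", "section", list(name = "stimulus protocol", block = "block"))

    annotations <- list()
    for (t in seq_len(spec$n_trials)) {
      seg_key <- sprintf("seg_%d", t)
      add(seg_key, "segment", list(name = sprintf("Trial %d", t), block = "block"))
      add(sprintf("event_%d", t), "event",
          list(label = "stimulus", time = quantity(100, "ms"), segment = seg_key))
      for (c in seq_len(spec$n_channels)) {
        raw <- stats::rnorm(spec$samples_per_trial)
        lfp <- as.numeric(stats::filter(raw, rep(1 / 5, 5), sides = 2, circular = TRUE)) * 100
        add(sprintf("sig_%d_%d", t, c), "analogsignal", list(
          name = sprintf("LFP RC%d trial %d", c, t),
          t_start = quantity(0, "ms"),
          sampling_rate = spec$sampling_rate,
          signal = array_values(lfp, "uV"),
          segment = seg_key,
          recordingchannel = sprintf("channel_%d", c)
        ))
      }
      for (u in seq_len(spec$n_units)) {
        n_spikes <- stats::rpois(1L, unit_rates[u] * dur_s)
        times_ms <- sort(stats::runif(n_spikes, 0, dur_s)) * 1000
        add(sprintf("st_%d_%d", t, u), "spiketrain", list(
          name = sprintf("U%d spikes trial %d", u, t),
          t_start = quantity(0, "ms"),
          t_stop = quantity(dur_s * 1000, "ms"),
          times = array_values(times_ms, "ms"),
          segment = seg_key,
          unit = sprintf("unit_%d", u)
        ))
      }
      sec_key <- sprintf("sec_%d", t)
      add(sec_key, "section",
          list(name = sprintf("Trial %d stimulus", t), parent_section = "sec_root"))
      orientation <- sample(.orientations, 1L)
      stim_size <- sample(.stim_sizes, 1L)
      add(sprintf("prop_orientation_%d", t), "property",
          list(name = "orientation", section = sec_key))
      add(sprintf("val_orientation_%d", t), "value",
          list(data = orientation, property = sprintf("prop_orientation_%d", t)))
      add(sprintf("prop_size_%d", t), "property",
          list(name = "size", section = sec_key))
      add(sprintf("val_size_%d", t), "value",
          list(data = stim_size, property = sprintf("prop_size_%d", t)))
      annotations[[seg_key]] <- c(sprintf("val_orientation_%d", t),
                                  sprintf("val_size_%d", t))
    }

    structure(
      list(
        spec = spec, objects = objects, order = order, annotations = annotations,
        params = list(unit_rates = unit_rates, trial_duration_s = dur_s)
      ),
      class = "experiment_graph"
    )
  })
}

#' Object counts of a generated graph
#'
#' @param graph an [generate_experiment()] result.
#' @return tibble with columns `kind` and `n`.
#' @export
experiment_counts <- function(graph) {
  kinds <- vapply(graph$objects, `[[`, character(1), "kind")
  tab <- table(kinds)
  tibble::tibble(kind = names(tab), n = as.integer(tab))
}

#' Push a generated experiment through a client session
#'
#' Creates every object of the graph in creation order, resolving local
#' keys to server-assigned ids, then applies the segment annotations.
#'
#' @param session an [api_session()].
#' @param graph an [generate_experiment()] result.
#' @return tibble mapping `local_key` to `kind` and server `id`.
#' @export
push_experiment <- function(session, graph) {
  idmap <- character()
  remotes <- list()
  for (key in graph$order) {
    obj <- graph$objects[[key]]
    fields <- obj$fields
    for (p in names(object_schema(obj$kind)$parents)) {
      if (!is.null(fields[[p]])) fields[[p]] <- unname(idmap[[fields[[p]]]])
    }
    stored <- session$save(list(kind = obj$kind, fields = fields))
    idmap[[key]] <- stored$id
    remotes[[key]] <- stored
  }
  for (seg_key in names(graph$annotations)) {
    value_ids <- unname(idmap[graph$annotations[[seg_key]]])
    remotes[[seg_key]] <- session$annotate(remotes[[seg_key]], value_ids)
  }
  tibble::tibble(
    local_key = graph$order,
    kind = vapply(graph$order, function(k) graph$objects[[k]]$kind, character(1)),
    id = unname(idmap[graph$order])
  )
}
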