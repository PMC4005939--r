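# Shared builders for test stores and small object graphs.

`%||%` <- function(a, b) if (is.null(a)) b else a

new_test_store <- function() {
  object_store(dir = withr::local_tempdir(.local_envir = parent.frame()))
}

# a block/segment pair owned by `owner`, returning their ids
make_block_segment <- function(store, owner = "alice") {
  blk <- create_object(store, "block", list(name = "dataset"), owner)
  seg <- create_object(store, "segment", list(name = "Trial 1", block = blk$id), owner)
  list(block = blk$id, segment = seg$id)
}

# an analog signal with a deterministic ramp array
make_signal <- function(store, segment, owner = "alice", n = 1000,
                        rate = quantity(1, "kHz"), values = NULL, units = "uV") {
  if (is.null(values)) values <- as.numeric(seq_len(n) - 1)
  create_object(store, "analogsignal", list(
    name = "ramp signal",
    t_start = quantity(0, "ms"),
    sampling_rate = rate,
    signal = array_values(values, units),
    segment = segment
  ), owner)
}

# a section -> property -> value chain; returns ids
make_metadata_chain <- function(store, owner = "alice", prop_name = "orientation",
                                data = 30) {
  sec <- create_object(store, "section", list(name = "stimulus"), owner)
  prop <- create_object(store, "property", list(name = prop_name, section = sec$id), owner)
  val <- create_object(store, "value", list(data = data, property = prop$id), owner)
  list(section = sec$id, property = prop$id, value = val$id)
}

# a store populated with random objects, ACLs and annotations, for the
# query/visibility oracles; returns the store plus the user pool
make_random_store <- function(seed, n_blocks = 3, n_sections = 12, n_properties = 20,
                              n_values = 30, n_segments = 8, n_channels = 10) {
  store <- object_store(dir = withr::local_tempdir(.local_envir = parent.frame()))
  users <- c("alice", "bob", "carol")
  for (u in users) store$register_user(u)
  name_pool <- c(
    "luminance", "Luminance", "luminance1", "contrast", "orientation",
    "size", "background luminance", "spatial frequency", "phase"
  )
  withr::with_seed(seed, {
    rand_acl <- function(owner) {
      acl <- list(safety_level = sample(c("private", "public"), 1))
      others <- setdiff(users, owner)
      shared <- others[stats::runif(length(others)) < 0.3]
      if (length(shared) > 0) {
        acl$shared_with <- stats::setNames(
          sample(c("read", "read-write"), length(shared), replace = TRUE), shared
        )
      }
      acl
    }
    new_obj <- function(kind, fields) {
      owner <- sample(users, 1)
      rec <- create_object(store, kind, fields, owner)
      set_acl(store, rec$id, rand_acl(owner), owner)
      rec$id
    }
    blocks <- replicate(n_blocks, new_obj("block", list(name = sample(name_pool, 1))))
    rcgs <- vapply(blocks, function(b) {
      new_obj("recordingchannelgroup", list(name = "array", block = b))
    }, character(1))
    for (i in seq_len(n_channels)) {
      new_obj("recordingchannel", list(
        name = sprintf("RC%d", i), index = sample(1:20, 1),
        recordingchannelgroup = sample(rcgs, 1)
      ))
    }
    sections <- character()
    for (i in seq_len(n_sections)) {
      fields <- list(name = sample(name_pool, 1))
      if (length(sections) > 0 && stats::runif(1) < 0.5) {
        fields$parent_section <- sample(sections, 1)
      } else if (stats::runif(1) < 0.5) {
        fields$block <- sample(blocks, 1)
      }
      if (stats::runif(1) < 0.3) fields$comment <- "annotated by hand"
      sections <- c(sections, new_obj("section", fields))
    }
    props <- vapply(seq_len(n_properties), function(i) {
      new_obj("property", list(name = sample(name_pool, 1), section = sample(sections, 1)))
    }, character(1))
    values <- vapply(seq_len(n_values), function(i) {
      data <- if (stats::runif(1) < 0.5) sample(0:330, 1) else sample(name_pool, 1)
      new_obj("value", list(data = data, property = sample(props, 1)))
    }, character(1))
    segments <- vapply(seq_len(n_segments), function(i) {
      new_obj("segment", list(name = sprintf("Trial %d", i), block = sample(blocks, 1)))
    }, character(1))
    for (seg in segments) {
      if (stats::runif(1) < 0.7) {
        vids <- sample(values, sample(1:3, 1))
        owner <- store$peek(seg)$owner
        store$annotate(seg, vids, owner)
      }
    }
  })
  list(store = store, users = users)
}
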