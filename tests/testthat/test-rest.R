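test_that("every verb/URL cell of the action table behaves as specified", {
  store <- new_test_store()
  ids <- make_block_segment(store)
  m <- make_metadata_chain(store)
  st <- create_object(store, "spiketrain", list(
    name = "unit 1 spikes", t_start = quantity(0, "ms"), t_stop = quantity(5, "ms"),
    times = array_values(c(1, 2, 3), "ms"), segment = ids$segment
  ), "alice")

  # GET /ns/type/id/ -> single object document
  r <- route_request(store, "GET",
                     sprintf("/electrophysiology/spiketrain/%s/", st$id),
                     actor = "alice")
  expect_identical(r$status, 200L)
  expect_identical(r$body$id, st$id)
  expect_identical(r$body$fields$name, "unit 1 spikes")
  expect_identical(r$headers$ETag, st$etag)

  # POST /ns/type/id/ with two fields updates both
  r <- route_request(store, "POST",
                     sprintf("/electrophysiology/spiketrain/%s/", st$id),
                     body = list(name = "renamed", comment = "checked"),
                     actor = "alice")
  expect_identical(r$status, 200L)
  expect_identical(r$body$fields$name, "renamed")
  expect_identical(r$body$fields$comment, "checked")

  # POST /ns/type/ creates (201 + Location)
  r <- route_request(store, "POST", "/electrophysiology/event/",
                     body = list(label = "stimulus",
                                 time = list(value = 120, units = "ms"),
                                 segment = ids$segment),
                     actor = "alice")
  expect_identical(r$status, 201L)
  expect_match(r$headers$Location, "^/electrophysiology/event/[A-Z2-7]{10}/$")
  expect_equal(r$body$fields$time$value, 120)

  # GET /ns/type/ lists with envelope
  r <- route_request(store, "GET", "/electrophysiology/segment/", actor = "alice")
  expect_identical(r$body$total, 1L)
  expect_length(r$body$objects, 1)

  # bulk update via POST to the type URL
  r <- route_request(store, "POST", "/metadata/property/",
                     body = list(filters = list(name__icontains = "orient"),
                                 fields = list(comment = "bulk")),
                     actor = "alice")
  expect_identical(r$status, 200L)
  expect_identical(r$body$total, 1L)
  expect_identical(
    get_object(store, m$property, "alice")$fields$comment, "bulk")

  # DELETE /ns/type/id/, then DELETE /ns/type/ (bulk)
  r <- route_request(store, "DELETE",
                     sprintf("/electrophysiology/spiketrain/%s/", st$id),
                     actor = "alice")
  expect_identical(r$status, 200L)
  r <- route_request(store, "DELETE", "/metadata/value/", actor = "alice")
  expect_identical(r$body$total, 1L)
  expect_error(get_object(store, m$value, "alice"), class = "not_found")

  # ACL subresource: GET, POST, DELETE -> 405
  store$register_user("bob")
  r <- route_request(store, "GET",
                     sprintf("/electrophysiology/block/%s/acl/", ids$block),
                     actor = "alice")
  expect_identical(r$status, 200L)
  expect_identical(r$body$safety_level, "private")
  r <- route_request(store, "POST",
                     sprintf("/electrophysiology/block/%s/acl/", ids$block),
                     body = list(safety_level = "public",
                                 shared_with = list(bob = "read-write")),
                     actor = "alice")
  expect_identical(r$status, 200L)
  expect_identical(r$body$shared_with$bob, "read-write")
  r <- route_request(store, "DELETE",
                     sprintf("/electrophysiology/block/%s/acl/", ids$block),
                     actor = "alice")
  expect_identical(r$status, 405L)
})

test_that("errors map to 400/403/404 with JSON message bodies", {
  store <- new_test_store()
  ids <- make_block_segment(store)
  cases <- list(
    list(r = route_request(store, "GET",
                           "/electrophysiology/spiketrain/AAAA2222BB/",
                           actor = "alice"),
         status = 404L),
    list(r = route_request(store, "GET",
                           sprintf("/electrophysiology/block/%s/", ids$block),
                           actor = "mallory"),
         status = 403L),
    list(r = route_request(store, "POST", "/electrophysiology/event/",
                           body = list(label = "x"), actor = "alice"),
         status = 400L),
    list(r = route_request(store, "POST", "/electrophysiology/event/",
                           body = "{not json", actor = "alice"),
         status = 400L),
    list(r = route_request(store, "GET", "/electrophysiology/segment/",
                           params = list(name__regexx = "x"), actor = "alice"),
         status = 400L),
    list(r = route_request(store, "GET", "/astrology/segment/", actor = "alice"),
         status = 404L)
  )
  for (case in cases) {
    expect_identical(case$r$status, case$status)
    parsed <- jsonlite::fromJSON(response_json(case$r))
    expect_true(is.character(parsed$message) && nzchar(parsed$message))
  }
  # deleted object: 404 on GET, 410 on POST update
  delete_object(store, ids$segment, "alice")
  expect_identical(route_request(store, "GET",
    sprintf("/electrophysiology/segment/%s/", ids$segment), actor = "alice")$status,
    404L)
  expect_identical(route_request(store, "POST",
    sprintf("/electrophysiology/segment/%s/", ids$segment),
    body = list(name = "zombie"), actor = "alice")$status, 410L)
})

test_that("conditional GET returns 304 until the object changes", {
  store <- new_test_store()
  blk <- create_object(store, "block", list(name = "cached"), "alice")
  path <- sprintf("/electrophysiology/block/%s/", blk$id)

  r1 <- route_request(store, "GET", path, actor = "alice")
  expect_identical(r1$status, 200L)
  e <- r1$headers$ETag

  r2 <- route_request(store, "GET", path,
                      headers = list("If-None-Match" = e), actor = "alice")
  expect_identical(r2$status, 304L)
  expect_null(r2$body)

  r3 <- route_request(store, "GET", path,
                      headers = list("If-None-Match" = "stale"), actor = "alice")
  expect_identical(r3$status, 200L)

  update_object(store, blk$id, list(name = "changed"), "alice")
  r4 <- route_request(store, "GET", path,
                      headers = list("If-None-Match" = e), actor = "alice")
  expect_identical(r4$status, 200L)
  expect_false(identical(r4$headers$ETag, e))
  r5 <- route_request(store, "GET", path,
                      headers = list("If-None-Match" = r4$headers$ETag),
                      actor = "alice")
  expect_identical(r5$status, 304L)
})

test_that("documents round-trip through serialize/deserialize on fixtures", {
  store <- new_test_store()
  session <- api_session(store, "alice")
  graph <- generate_experiment(
    experiment_spec(n_trials = 2, n_channels = 2, n_units = 2, seed = 5,
                    samples_per_trial = 100))
  index <- push_experiment(session, graph)
  for (i in seq_len(nrow(index))) {
    rec <- get_object(store, index$id[i], "alice")
    doc <- serialize_record(rec, store)
    back <- deserialize_document(rec$kind, doc$fields)
    expect_identical(back, rec$fields,
                     info = sprintf("%s (%s)", index$local_key[i], rec$kind))
    expect_identical(doc$location,
                     sprintf("/%s/%s/%s/", object_schema(rec$kind)$namespace,
                             rec$kind, rec$id))
  }
  expect_error(deserialize_document("event", list(label = "x", frequency = 3)),
               class = "bad_request")
})

test_that("permalinks keep resolving to the same object across updates", {
  store <- new_test_store()
  blk <- create_object(store, "block", list(name = "v1"), "alice")
  loc1 <- serialize_record(get_object(store, blk$id, "alice"))$location
  for (i in 2:4) update_object(store, blk$id, list(name = sprintf("v%d", i)), "alice")
  rec <- get_object(store, blk$id, "alice")
  expect_identical(serialize_record(rec)$location, loc1)
  r <- route_request(store, "GET", loc1, actor = "alice")
  expect_identical(r$body$id, blk$id)
  expect_identical(r$body$fields$name, "v4")
})

test_that("datafile downloads serve full arrays and inclusive slices", {
  store <- new_test_store()
  ids <- make_block_segment(store)
  sig <- make_signal(store, ids$segment, n = 1000)
  fid <- sig$fields$signal$file_id

  r <- route_request(store, "GET", sprintf("/datafiles/%s/", fid), actor = "alice")
  expect_identical(r$status, 200L)
  expect_identical(as.numeric(unlist(r$body$data)), as.numeric(0:999))

  r <- route_request(store, "GET", sprintf("/datafiles/%s/", fid),
                     params = list(start_index = 50, end_index = 149),
                     actor = "alice")
  expect_identical(r$body$length, 100L)
  expect_identical(as.numeric(unlist(r$body$data)), as.numeric(50:149))

  expect_identical(route_request(store, "GET", sprintf("/datafiles/%s/", fid),
                                 params = list(start_index = 0, end_index = 1000),
                                 actor = "alice")$status, 400L)
  expect_identical(route_request(store, "GET", "/datafiles/AAAA2222CC/",
                                 actor = "alice")$status, 404L)

  # sliced HDF5 file written to disk holds exactly the slice at its root
  out <- tempfile(fileext = ".h5")
  serve_datafile(store, fid, 50, 149, path = out)
  expect_identical(as.numeric(rhdf5::h5read(out, "data")), as.numeric(50:149))

  # a sliced GET of the signal embeds the datafile URL with index bounds
  r <- route_request(store, "GET",
                     sprintf("/electrophysiology/analogsignal/%s/", sig$id),
                     params = list(start_time = 50, duration = 100),
                     actor = "alice")
  expect_identical(r$body$fields$signal$start_index, 50L)
  expect_identical(r$body$fields$signal$end_index, 149L)
  expect_match(r$body$fields$signal$url, "start_index=50&end_index=149")
})

test_that("requests are written to the structured log", {
  store <- new_test_store()
  blk <- create_object(store, "block", list(name = "b"), "alice")
  route_request(store, "GET", sprintf("/electrophysiology/block/%s/", blk$id),
                actor = "alice")
  route_request(store, "GET", "/electrophysiology/block/ZZZZZZZZZZ/",
                actor = "alice")
  log <- store$request_log()
  expect_identical(nrow(log), 2L)
  expect_identical(log$status, c(200L, 404L))
  expect_identical(log$actor, c("alice", "alice"))
})
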