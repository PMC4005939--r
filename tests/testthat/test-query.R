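test_that("URL parameters parse into filters, reserved slots and lookups", {
  spec <- parse_query_params(list(name__icontains = "luminance"), "property")
  expect_length(spec$filters, 1)
  expect_identical(spec$filters[[1]]$field, "name")
  expect_identical(spec$filters[[1]]$lookup, "icontains")
  expect_identical(spec$filters[[1]]$value, "luminance")

  spec2 <- parse_query_params(list(label = "stimulus", owner = "demo"), "event")
  expect_identical(spec2$filters[[1]]$lookup, "exact")
  expect_identical(spec2$owner, "demo")

  spec3 <- parse_query_params(
    list(property__name__icontains = "luminance", offset = "2",
         max_results = "5", metadata = "AAAAAAAAAA,BBBBBBBBBB"), "value")
  expect_identical(spec3$filters[[1]]$path, "property")
  expect_identical(spec3$offset, 2L)
  expect_identical(spec3$max_results, 5L)
  expect_identical(spec3$metadata_values, c("AAAAAAAAAA", "BBBBBBBBBB"))

  expect_error(parse_query_params(list(name__regexx = "x"), "property"),
               class = "bad_request")
  expect_error(parse_query_params(list(wavelength = "500"), "property"),
               class = "bad_request")
  expect_error(parse_query_params(list(section__wavelength = "x"), "property"),
               class = "bad_request")
})

test_that("substring filters match case-sensitively or not as requested", {
  store <- new_test_store()
  sec <- create_object(store, "section", list(name = "stim"), "alice")
  for (nm in c("luminance1", "contrast", "Luminance")) {
    create_object(store, "property", list(name = nm, section = sec$id), "alice")
  }
  ids <- query_ids(store, "property", "alice",
                   filters = list(qfilter("name", "icontains", "luminance")))
  expect_length(ids, 2)
  ids_cs <- query_ids(store, "property", "alice",
                      filters = list(qfilter("name", "contains", "luminance")))
  expect_length(ids_cs, 1)
})

test_that("relationship filters resolve through parent and child links", {
  store <- new_test_store()
  m1 <- make_metadata_chain(store, prop_name = "luminance", data = 40)
  m2 <- make_metadata_chain(store, prop_name = "contrast", data = 0.8)
  got <- query_ids(store, "value", "alice",
                   filters = list(qfilter("name", "icontains", "luminance",
                                          path = "property")))
  expect_identical(got, m1$value)
  # child direction: properties that have a value equal to 0.8
  got2 <- query_ids(store, "property", "alice",
                    filters = list(qfilter("data", "exact", "0.8", path = "value")))
  expect_identical(got2, m2$property)
  # two-hop: values under a section named "stimulus"
  got3 <- query_ids(store, "value", "alice",
                    filters = list(qfilter("name", "exact", "stimulus",
                                           path = c("property", "section"))))
  expect_setequal(got3, c(m1$value, m2$value))
})

test_that("metadata filters demand annotation with every listed value", {
  store <- new_test_store()
  ids <- make_block_segment(store)
  seg2 <- create_object(store, "segment",
                        list(name = "Trial 2", block = ids$block), "alice")
  m1 <- make_metadata_chain(store, prop_name = "orientation", data = 30)
  m2 <- make_metadata_chain(store, prop_name = "size", data = 2)
  annotate(store, ids$segment, c(m1$value, m2$value), "alice")
  annotate(store, seg2$id, m1$value, "alice")
  both <- query_ids(store, "segment", "alice", metadata = c(m1$value, m2$value))
  expect_identical(both, ids$segment)
  one <- query_ids(store, "segment", "alice", metadata = m1$value)
  expect_setequal(one, c(ids$segment, seg2$id))
})

test_that("pagination slices the stable order and pages tile the result", {
  store <- new_test_store()
  blk <- create_object(store, "block", list(name = "b"), "alice")
  segs <- vapply(1:5, function(i) {
    create_object(store, "segment",
                  list(name = sprintf("Trial %d", i), block = blk$id), "alice")$id
  }, character(1))
  page <- query_ids(store, "segment", "alice", offset = 2, max_results = 2)
  expect_identical(page, segs[3:4])
  tiled <- unlist(lapply(seq(0, 4, by = 2), function(off) {
    query_ids(store, "segment", "alice", offset = off, max_results = 2)
  }))
  expect_identical(tiled, segs)
  expect_identical(query_ids(store, "segment", "alice", offset = 10), character(0))
})

test_that("multiple filters intersect like single-filter result sets", {
  rs <- make_random_store(101)
  f1 <- qfilter("name", "icontains", "luminance")
  f2 <- qfilter("name", "startswith", "l")
  both <- query_ids(rs$store, "property", "alice", filters = list(f1, f2))
  solo <- intersect(
    query_ids(rs$store, "property", "alice", filters = list(f1)),
    query_ids(rs$store, "property", "alice", filters = list(f2))
  )
  expect_setequal(both, solo)
})

test_that("query results equal brute-force filtering on random stores", {
  for (seed in c(201, 202)) {
    rs <- make_random_store(seed)
    store <- rs$store
    actors <- c(as.list(rs$users), list(NULL))
    filter_cases <- list(
      list(kind = "property", f = list(qfilter("name", "exact", "luminance"))),
      list(kind = "property", f = list(qfilter("name", "iexact", "LUMINANCE"))),
      list(kind = "property", f = list(qfilter("name", "contains", "lum"))),
      list(kind = "property", f = list(qfilter("name", "icontains", "LUM"))),
      list(kind = "property", f = list(qfilter("name", "startswith", "lu"))),
      list(kind = "property", f = list(qfilter("name", "in", "contrast,size,phase"))),
      list(kind = "section", f = list(qfilter("comment", "isnull", "true"))),
      list(kind = "section", f = list(qfilter("comment", "isnull", "false"))),
      list(kind = "recordingchannel", f = list(qfilter("index", "gt", "10"))),
      list(kind = "recordingchannel", f = list(qfilter("index", "gte", "10"))),
      list(kind = "recordingchannel", f = list(qfilter("index", "lt", "5"))),
      list(kind = "recordingchannel", f = list(qfilter("index", "lte", "5"))),
      list(kind = "value", f = list(qfilter("name", "icontains", "luminance",
                                            path = "property"))),
      list(kind = "value", f = list(qfilter("name", "icontains", "lum",
                                            path = c("property", "section")))),
      list(kind = "section", f = list(qfilter("name", "exact", "contrast",
                                              path = "property"))),
      list(kind = "block", f = list(qfilter("name", "icontains", "trial",
                                            path = "segment"))),
      list(kind = "segment", f = list(qfilter("name", "icontains", "lum",
                                              path = "block")))
    )
    for (actor in actors) {
      for (case in filter_cases) {
        expect_identical(
          query_ids(store, case$kind, actor, filters = case$f),
          oracle_query_ids(store, case$kind, actor, filters = case$f),
          info = sprintf("seed %d kind %s actor %s", seed, case$kind,
                         actor %||% "<anon>")
        )
      }
      # owner restriction and metadata conjunction
      expect_identical(
        query_ids(store, "section", actor, owner = "bob"),
        oracle_query_ids(store, "section", actor, owner = "bob")
      )
      vals <- store$ids("value")[1:2]
      expect_identical(
        query_ids(store, "segment", actor, metadata = vals),
        oracle_query_ids(store, "segment", actor, metadata = vals)
      )
    }
  }
})

test_that("no query ever returns an object the actor cannot read directly", {
  rs <- make_random_store(303)
  store <- rs$store
  for (actor in c(as.list(rs$users), list(NULL))) {
    for (kind in c("section", "property", "value", "segment", "block")) {
      ids <- query_ids(store, kind, actor)
      for (id in ids) {
        expect_silent(get_object(store, id, actor))
      }
      # and the complement: hidden objects are really inaccessible
      hidden <- setdiff(vapply(store$snapshot(kind), `[[`, character(1), "id"), ids)
      for (id in hidden) {
        expect_error(get_object(store, id, actor), class = "forbidden")
      }
    }
  }
})
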