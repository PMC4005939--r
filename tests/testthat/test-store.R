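test_that("generated ids are well-formed base-32 tokens and unique", {
  store <- new_test_store()
  withr::with_seed(7, {
    ids <- replicate(10000, store$generate_id())
  })
  expect_true(all(grepl("^[A-Z2-7]{10}$", ids)))
  expect_identical(length(unique(ids)), 10000L)
})

test_that("created objects round-trip, including persisted arrays", {
  store <- new_test_store()
  ids <- make_block_segment(store)
  ev <- create_object(store, "event", list(
    label = "stimulus", time = quantity(120, "ms"), segment = ids$segment
  ), "alice")
  back <- get_object(store, ev$id, "alice")
  expect_identical(back$fields$label, "stimulus")
  expect_equal(back$fields$time$value, 120)

  sig <- make_signal(store, ids$segment, n = 1000)
  ref <- sig$fields$signal
  expect_s3_class(ref, "data_array")
  expect_identical(ref$length, 1000L)
  expect_identical(load_array(store, ref$file_id), as.numeric(0:999))

  expect_error(create_object(store, "oscilloscope", list(name = "x"), "alice"),
               class = "bad_request")
  expect_error(create_object(store, "event", list(label = "x"), "alice"),
               class = "bad_request")
})

test_that("every update re-tags the object and preserves history", {
  store <- new_test_store()
  blk <- create_object(store, "block", list(name = "original"), "alice", now = 100)
  v2 <- update_object(store, blk$id, list(name = "renamed"), "alice", now = 200)
  expect_false(identical(blk$etag, v2$etag))
  expect_identical(get_object(store, blk$id, "alice")$fields$name, "renamed")
  expect_identical(get_object(store, blk$id, "alice", at_time = 150)$fields$name,
                   "original")
  expect_identical(get_object(store, blk$id, "alice", at_time = 200)$fields$name,
                   "renamed")
  expect_error(get_object(store, blk$id, "alice", at_time = 50),
               class = "not_found")
})

test_that("soft delete hides objects live but keeps history readable", {
  store <- new_test_store()
  blk <- create_object(store, "block", list(name = "doomed"), "alice", now = 100)
  delete_object(store, blk$id, "alice", now = 200)
  expect_error(get_object(store, blk$id, "alice"), class = "not_found")
  expect_identical(get_object(store, blk$id, "alice", at_time = 150)$fields$name,
                   "doomed")
  expect_error(get_object(store, blk$id, "alice", at_time = 250),
               class = "not_found")
  expect_error(update_object(store, blk$id, list(name = "zombie"), "alice"),
               class = "gone")
  expect_error(delete_object(store, blk$id, "alice"), class = "not_found")
})

test_that("annotation links have set semantics and re-tag the target", {
  store <- new_test_store()
  ids <- make_block_segment(store)
  m1 <- make_metadata_chain(store, prop_name = "orientation", data = 30)
  m2 <- make_metadata_chain(store, prop_name = "size", data = 2)
  before <- get_object(store, ids$segment, "alice")
  v <- annotate(store, ids$segment, c(m1$value, m2$value), "alice")
  expect_setequal(v$fields$metadata, c(m1$value, m2$value))
  expect_false(identical(before$etag, v$etag))
  v2 <- annotate(store, ids$segment, m1$value, "alice")
  expect_setequal(v2$fields$metadata, c(m1$value, m2$value))
  expect_error(annotate(store, ids$segment, "ZZZZZZZZZZ", "alice"),
               class = "not_found")
  expect_error(annotate(store, ids$segment, ids$block, "alice"),
               class = "bad_request")
})

test_that("at_time reads equal replay-log reconstruction at every boundary", {
  store <- new_test_store()
  withr::with_seed(11, {
    for (obj in 1:25) {
      log <- list()
      t <- 1000 * obj
      id <- NULL
      log[[1]] <- list(op = "create", time = t,
                       fields = list(name = "v0", comment = "c0"))
      rec <- create_object(store, "block", log[[1]]$fields, "alice", now = t)
      id <- rec$id
      n_ops <- sample(2:8, 1)
      alive <- TRUE
      for (k in seq_len(n_ops)) {
        t <- t + sample(1:50, 1)
        if (!alive) break
        if (stats::runif(1) < 0.2) {
          delete_object(store, id, "alice", now = t)
          log[[length(log) + 1]] <- list(op = "delete", time = t, fields = NULL)
          alive <- FALSE
        } else {
          f <- list(name = sprintf("v%d", k))
          if (stats::runif(1) < 0.5) f$comment <- sprintf("c%d", k)
          update_object(store, id, f, "alice", now = t)
          log[[length(log) + 1]] <- list(op = "update", time = t, fields = f)
        }
      }
      times <- vapply(log, `[[`, numeric(1), "time")
      probes <- sort(unique(c(times, times + 0.5, times - 0.5, max(times) + 100)))
      for (p in probes) {
        expected <- oracle_replay_state(log, p)
        got <- tryCatch(get_object(store, id, "alice", at_time = p),
                        ephystore_error = function(e) NULL)
        if (is.null(expected)) {
          expect_null(got)
        } else {
          expect_identical(got$fields$name, expected$name)
          expect_identical(got$fields$comment, expected$comment)
        }
      }
      # e-Tags pairwise distinct; validity intervals partition time
      vs <- store$versions(id)
      etags <- vapply(vs, `[[`, character(1), "etag")
      expect_identical(anyDuplicated(etags), 0L)
      froms <- vapply(vs, `[[`, numeric(1), "valid_from")
      tos <- vapply(vs, `[[`, numeric(1), "valid_to")
      if (length(vs) > 1) {
        expect_identical(tos[-length(tos)], froms[-1])  # no gap, no overlap
      }
      expect_identical(sum(!is.finite(tos)), 1L)  # exactly one open interval
    }
  })
})

test_that("timestamps that do not advance are nudged, never overlapped", {
  store <- new_test_store()
  blk <- create_object(store, "block", list(name = "a"), "alice", now = 100)
  v2 <- update_object(store, blk$id, list(name = "b"), "alice", now = 100)
  expect_gt(v2$valid_from, 100)
  vs <- store$versions(blk$id)
  expect_identical(vs[[1]]$valid_to, vs[[2]]$valid_from)
})
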