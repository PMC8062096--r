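# Record store, delta computation, alias files, the incremental driver and
# the query partitioner.

test_that("record store does store/lookup round trips, most-recent-only", {
  store <- record_store(tmpfile(".json"))
  expect_null(record_lookup(store, "qd", "nt", "blastn", "pd"))
  db1 <- db_profile("nt", 1000, 10, files = "nt.00", molecule = "nucleotide",
                    timestamp = "t0")
  record_put(store, "qd", db1, "blastn", "pd", "/tmp/r1.xml")
  rec <- record_lookup(store, "qd", "nt", "blastn", "pd")
  expect_identical(rec$result_path, "/tmp/r1.xml")
  expect_s3_class(rec$db_snapshot, "db_profile")
  expect_identical(rec$db_snapshot$files, "nt.00")
  # storing again under the same keys replaces, never accumulates
  db2 <- db_profile("nt", 2000, 20, files = c("nt.00", "nt.01"),
                    molecule = "nucleotide", timestamp = "t1")
  record_put(store, "qd", db2, "blastn", "pd", "/tmp/r2.xml")
  expect_length(record_list(store), 1L)
  expect_identical(record_lookup(store, "qd", "nt", "blastn", "pd")$result_path,
                   "/tmp/r2.xml")
  # different parameters are a different record
  record_put(store, "qd", db2, "blastn", "pd2", "/tmp/r3.xml")
  expect_length(record_list(store), 2L)
})

test_that("query and parameter digests are content-based, order-insensitive", {
  q1 <- c(a = "ACGT", b = "GGGT")
  q2 <- c(b = "GGGT", a = "ACGT")
  expect_identical(query_set_digest(q1), query_set_digest(q2))
  expect_false(query_set_digest(q1) ==
                 query_set_digest(c(a = "ACGT", b = "GGGA")))
  expect_identical(params_digest(list(x = 1, y = "b")),
                   params_digest(list(y = "b", x = 1)))
})

test_that("delta computation is an exact set/size operation", {
  past <- db_profile("nt", 500, 5, files = "v0", molecule = "nucleotide")
  present <- db_profile("nt", 800, 9, files = c("v0", "v1"),
                        molecule = "nucleotide")
  d <- compute_delta(past, present)
  expect_identical(d$delta_files, "v1")
  expect_equal(d$delta_n + past$n, present$n)
  expect_equal(d$delta_N + past$N, present$N)
  same <- compute_delta(present, present)
  expect_length(same$delta_files, 0L)
  expect_equal(same$delta_n, 0)
  shrunk <- db_profile("nt", 400, 4, files = "v1", molecule = "nucleotide")
  expect_error(compute_delta(present, shrunk),
               class = "incblast_shrinkage_error")
})

test_that("alias files carry the delta volumes, byte-stably", {
  td <- tempfile("alias"); dir.create(td)
  past <- db_profile("nt", 500, 5, files = "nt.00", molecule = "nucleotide")
  present <- db_profile("nt", 900, 9, files = c("nt.00", "nt.01", "nt.02"),
                        molecule = "nucleotide")
  d <- compute_delta(past, present)
  p1 <- write_alias(d, "nt_delta", dir = td)
  expect_identical(basename(p1), "nt_delta.nal")
  lines <- readLines(p1)
  expect_identical(lines[grepl("^DBLIST", lines)], "DBLIST nt.01 nt.02")
  expect_identical(lines[grepl("^TITLE", lines)], "TITLE nt_delta")
  first <- readBin(p1, "raw", file.size(p1))
  write_alias(d, "nt_delta", dir = td)
  expect_identical(readBin(p1, "raw", file.size(p1)), first)
  # protein databases get the .pal extension
  p2 <- write_alias(c("nr.01"), "nr_delta", dir = td, molecule = "protein")
  expect_identical(basename(p2), "nr_delta.pal")
  # an empty delta is an explicit up-to-date no-op
  expect_message(p3 <- write_alias(compute_delta(present, present), "x", td),
                 "up to date")
  expect_null(p3)
})

test_that("incremental search follows the cold/cached/incremental contract", {
  sc <- generate_scenario(scenario_spec(seed = 51, type = "temporal",
                                        n_parts = 3))
  qs <- stats::setNames(sc$queries$seq, sc$queries$id)
  td <- tempfile("incr"); dir.create(td)
  store <- record_store(file.path(td, "records.json"))
  calls <- new.env(); calls$log <- list()
  ex <- local({
    inner <- mock_executor(sc)
    function(queries, db, program, params) {
      calls$log[[length(calls$log) + 1L]] <- db$files
      inner(queries, db, program, params)
    }
  })
  # cold: executor sees the full first snapshot
  r1 <- incremental_search(qs, sc$profiles[[1]], "blastn", executor = ex,
                           store = store)
  expect_identical(attr(r1, "mode"), "full")
  expect_identical(calls$log[[1]], sc$profiles[[1]]$files)
  # cache hit: executor not called, bit-identical result returned
  n_calls <- length(calls$log)
  r1b <- incremental_search(qs, sc$profiles[[1]], "blastn", executor = ex,
                            store = store)
  expect_identical(attr(r1b, "mode"), "cached")
  expect_length(calls$log, n_calls)
  expect_identical(readLines(attr(r1b, "path")), readLines(attr(r1, "path")))
  # growth: executor sees only the delta volumes; result equals a whole-db run
  r2 <- incremental_search(qs, sc$profiles[[2]], "blastn", executor = ex,
                           store = store)
  expect_identical(attr(r2, "mode"), "incremental")
  expect_identical(calls$log[[length(calls$log)]],
                   setdiff(sc$profiles[[2]]$files, sc$profiles[[1]]$files))
  ref2 <- parse_result(sc$reference_paths[2], "xml")
  for (i in seq_along(ref2)) {
    fr <- compare_results(r2[[i]], ref2[[i]], rel_tol = 1e-10)
    expect_equal(c(fr$hit_match, fr$evalue_match, fr$order_agreement),
                 c(100, 100, 100))
  }
  # a second growth step merges the merged result again
  r3 <- incremental_search(qs, sc$profiles[[3]], "blastn", executor = ex,
                           store = store)
  ref3 <- parse_result(sc$reference_paths[3], "xml")
  for (i in seq_along(ref3)) {
    fr <- compare_results(r3[[i]], ref3[[i]], rel_tol = 1e-10)
    expect_equal(c(fr$hit_match, fr$evalue_match, fr$order_agreement),
                 c(100, 100, 100))
  }
  # the store never accumulates: still one record for this key
  expect_length(record_list(store), 1L)
})

test_that("query partitioning balances residues, deterministically", {
  expect_identical(partition_queries(c(a = "ACGT"), 1), list("a"))
  eq <- stats::setNames(rep(100, 20), paste0("q", 1:20))
  p20 <- partition_queries(eq, 20, seed = 4)
  expect_true(all(lengths(p20) == 1L))
  expect_setequal(unlist(p20), names(eq))
  # heavy-tailed lengths: residue balancing beats count balancing
  set.seed(12)
  lens <- stats::setNames(round(stats::rlnorm(200, 6, 1.3)), paste0("q", 1:200))
  parts <- partition_queries(lens, 20, seed = 5)
  expect_setequal(unlist(parts), names(lens))
  tot <- vapply(parts, function(p) sum(lens[p]), numeric(1))
  count_bal <- split(names(lens), rep(1:20, length.out = 200))
  tot_cb <- vapply(count_bal, function(p) sum(lens[p]), numeric(1))
  expect_lt(max(tot) / min(tot), max(tot_cb) / min(tot_cb))
  # partition totals lie within one maximum query length of the mean
  expect_lt(max(tot) - mean(tot), max(lens))
  # deterministic given the seed; more partitions than queries is allowed
  expect_identical(partition_queries(lens, 20, seed = 5), parts)
  p_many <- partition_queries(eq, 30, seed = 6)
  expect_length(p_many, 30L)
  expect_true(any(lengths(p_many) == 0L))
})
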