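# Recalibration and merging of per-part results.

test_that("recalibrating against the result's own database changes nothing", {
  sc <- generate_scenario(scenario_spec(seed = 31, type = "spatial",
                                        n_parts = 2))
  r <- parse_result(sc$part_paths[1], "xml")[[1]]
  same <- recalibrate(r, sc$profiles[[1]])
  expect_identical(vapply(same$hits, `[[`, character(1), "subject_id"),
                   vapply(r$hits, `[[`, character(1), "subject_id"))
  for (i in seq_along(r$hits))
    expect_equal(hit_evalue(same$hits[[i]])$log_e,
                 hit_evalue(r$hits[[i]])$log_e, tolerance = 1e-12)
})

test_that("doubling the database doubles Spouge-family e-values exactly", {
  sc <- generate_scenario(scenario_spec(seed = 32, molecule = "protein",
                                        type = "spatial", n_parts = 2))
  r <- parse_result(sc$part_paths[1], "xml")[[1]]
  n1 <- sc$profiles[[1]]$n
  dbl <- db_profile("double", 2 * n1, 2 * sc$profiles[[1]]$N,
                    molecule = "protein")
  r2 <- recalibrate(r, dbl)
  ids <- vapply(r$hits, `[[`, character(1), "subject_id")
  for (id in ids) {
    a <- hit_evalue(r$hits[[which(ids == id)]])$log_e
    ids2 <- vapply(r2$hits, `[[`, character(1), "subject_id")
    b <- hit_evalue(r2$hits[[which(ids2 == id)]])$log_e
    expect_equal(b, a + log(2), tolerance = 1e-12)
  }
  expect_equal(r2$stats$db_len, 2 * n1)
})

test_that("Karlin-Altschul recalibration equals from-scratch evaluation", {
  sc <- generate_scenario(scenario_spec(seed = 33, type = "temporal",
                                        n_parts = 2))
  part <- parse_result(sc$part_paths[1], "xml")[[1]]
  union <- sc$profiles[[2]]
  re <- recalibrate(part, union)
  kp <- blastn_params()
  for (h in re$hits) for (s in h$hsps) {
    direct <- oracle_evalue(kp, re$query$m, union, s$raw_score)
    expect_equal(s$evalue$log_e, direct$log_e, tolerance = 1e-10)
  }
  expect_equal(re$stats$db_num, union$N)
  expect_equal(re$stats$db_len, union$n)
})

test_that("a shrinking database is refused", {
  sc <- generate_scenario(scenario_spec(seed = 34, type = "spatial",
                                        n_parts = 2))
  r <- parse_result(sc$part_paths[1], "xml")[[1]]
  small <- db_profile("small", 10, 2, molecule = "nucleotide")
  expect_error(recalibrate(r, small), class = "incblast_domain_error")
})

test_that("merging split searches reproduces the whole-database search", {
  for (mol in c("nucleotide", "protein")) {
    sc <- generate_scenario(scenario_spec(seed = 35, molecule = mol,
                                          type = "spatial", n_parts = 3))
    ms <- merge_scenario(sc)
    for (i in seq_along(ms$merged)) {
      fr <- compare_results(ms$merged[[i]], ms$reference[[i]], rel_tol = 1e-10)
      expect_equal(fr$hit_match, 100)
      expect_equal(fr$evalue_match, 100)
      expect_equal(fr$order_agreement, 100)
      # merged statistics reflect the union database, not either part's
      expect_equal(ms$merged[[i]]$stats$db_len, sc$union_db$n)
      expect_equal(ms$merged[[i]]$stats$db_num, sc$union_db$N)
    }
  }
})

test_that("merging an empty delta part is exactly a recalibration", {
  sc <- generate_scenario(scenario_spec(seed = 36, type = "temporal",
                                        n_parts = 2))
  a <- parse_result(sc$part_paths[1], "xml")[[1]]
  union <- sc$profiles[[2]]
  empty <- search_result(a$program, a$query,
                         db_profile("delta", sc$profiles[[2]]$n - sc$profiles[[1]]$n,
                                    sc$profiles[[2]]$N - sc$profiles[[1]]$N,
                                    molecule = "nucleotide"),
                         hits = list(),
                         stats = statistics_block(
                           db_num = sc$profiles[[2]]$N - sc$profiles[[1]]$N,
                           db_len = sc$profiles[[2]]$n - sc$profiles[[1]]$n,
                           kappa = a$stats$kappa, lambda = a$stats$lambda,
                           entropy = a$stats$entropy),
                         params = a$params)
  merged <- merge_results(list(a, empty), union_db = union)
  direct <- recalibrate(a, union)
  expect_identical(vapply(merged$hits, `[[`, character(1), "subject_id"),
                   vapply(direct$hits, `[[`, character(1), "subject_id"))
  for (i in seq_along(merged$hits))
    expect_equal(hit_evalue(merged$hits[[i]])$log_e,
                 hit_evalue(direct$hits[[i]])$log_e, tolerance = 1e-12)
})

test_that("merging is associative above the truncation cut", {
  sc <- generate_scenario(scenario_spec(seed = 37, type = "spatial",
                                        n_parts = 3))
  parts <- lapply(sc$part_paths, function(p) parse_result(p, "xml")[[1]])
  kway <- merge_results(parts, union_db = sc$union_db)
  ab <- merge_results(parts[1:2])
  ab_c <- merge_results(list(ab, parts[[3]]), union_db = sc$union_db)
  bc <- merge_results(parts[2:3])
  a_bc <- merge_results(list(parts[[1]], bc), union_db = sc$union_db)
  ids <- function(r) vapply(r$hits, `[[`, character(1), "subject_id")
  expect_identical(ids(ab_c), ids(kway))
  expect_identical(ids(a_bc), ids(kway))
  for (i in seq_along(kway$hits)) {
    expect_equal(hit_evalue(ab_c$hits[[i]])$log_e,
                 hit_evalue(kway$hits[[i]])$log_e, tolerance = 1e-10)
    expect_equal(hit_evalue(a_bc$hits[[i]])$log_e,
                 hit_evalue(kway$hits[[i]])$log_e, tolerance = 1e-10)
  }
})

test_that("duplicate subjects across parts keep the better hit, with warning", {
  sc <- generate_scenario(scenario_spec(seed = 38, type = "spatial",
                                        n_parts = 2))
  parts <- lapply(sc$part_paths, function(p) parse_result(p, "xml")[[1]])
  # inject a worse copy of part 1's best hit into part 2
  best <- parts[[1]]$hits[[1]]
  worse <- best
  worse$hsps <- list(best$hsps[[1]])
  worse$hsps[[1]]$raw_score <- worse$hsps[[1]]$raw_score - 10
  worse$hsps[[1]]$evalue <- blast_evalue(hit_evalue(best)$log_e + 5)
  parts[[2]]$hits <- sort_hits_for_test(c(parts[[2]]$hits, list(worse)))
  expect_warning(m <- merge_results(parts, union_db = sc$union_db),
                 "duplicate subject")
  ids <- vapply(m$hits, `[[`, character(1), "subject_id")
  expect_identical(sum(ids == best$subject_id), 1L)
  kept <- m$hits[[which(ids == best$subject_id)]]
  expect_equal(hit_score(kept), hit_score(best))
})

test_that("retention keeps 2x max_target_seqs and only drops the worst ranks", {
  sc <- generate_scenario(scenario_spec(seed = 39, type = "spatial",
                                        n_parts = 2, max_target_seqs = 3,
                                        subjects_per_vol = c(8, 10)))
  parts <- lapply(sc$part_paths, function(p) parse_result(p, "xml")[[1]])
  for (p in parts) expect_lte(length(p$hits), 3L)  # parts truncated upstream
  m <- merge_results(parts, union_db = sc$union_db, max_target_seqs = 3)
  expect_lte(length(m$hits), 6L)
  ref <- truncate_hits(parse_result(sc$reference_paths, "xml")[[1]], 3)
  # every hit ranked within max_target_seqs in the whole-db oracle is present
  expect_identical(vapply(m$hits[seq_along(ref$hits)], `[[`, character(1),
                          "subject_id"),
                   vapply(ref$hits, `[[`, character(1), "subject_id"))
})

test_that("merge plans reject inconsistent parts", {
  sc <- generate_scenario(scenario_spec(seed = 40, type = "spatial",
                                        n_parts = 2))
  parts <- lapply(sc$part_paths, function(p) parse_result(p, "xml")[[1]])
  bad <- parts[[2]]
  bad$program <- "blastp"
  expect_error(merge_plan(list(parts[[1]], bad)), class = "incblast_plan_error")
  bad2 <- parts[[2]]
  bad2$query$query_id <- "someone_else"
  expect_error(merge_plan(list(parts[[1]], bad2)), class = "incblast_plan_error")
  expect_error(merge_plan(list()), class = "incblast_plan_error")
})

test_that("fidelity reports quantify agreement and disagreement", {
  sc <- generate_scenario(scenario_spec(seed = 41, type = "spatial",
                                        n_parts = 2))
  r <- parse_result(sc$part_paths[1], "xml")[[1]]
  self <- compare_results(r, r)
  expect_equal(self$hit_match, 100)
  expect_equal(self$evalue_match, 100)
  expect_equal(self$order_agreement, 100)
  h <- length(r$hits)
  expect_gte(h, 2)
  pert <- r
  pert$hits[[1]]$hsps <- lapply(pert$hits[[1]]$hsps, function(s) {
    s$evalue <- blast_evalue(s$evalue$log_e + 1)  # far beyond tolerance
    s
  })
  fr <- compare_results(pert, r)
  expect_equal(fr$evalue_match, 100 * (h - 1) / h)
})
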