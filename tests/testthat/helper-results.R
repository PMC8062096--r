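# Builders shared across the suite. Everything is generated in code; no
# stored fixtures.

blastn_params <- function() {
  karlin_params(lambda = 1.28, K = 0.46, H = 0.85, alpha = 1.5, beta = -2)
}

blosum62_params <- function() {
  karlin_params(lambda = 0.267, K = 0.041, H = 0.14, alpha = 1.9, beta = -30)
}

# A random in-memory search_result restricted to fields the given dialect can
# carry, for round-trip properties.
random_result <- function(seed, dialect = c("xml", "tabular")) {
  dialect <- match.arg(dialect)
  set.seed(seed)
  protein <- runif(1) < 0.5
  program <- if (protein) sample(c("blastp", "blastx", "tblastn"), 1)
             else "blastn"
  kp <- if (protein) blosum62_params() else blastn_params()
  m <- sample(100:2000, 1)
  n <- sample(5e4:5e6, 1)
  N <- sample(5:500, 1)
  hits <- lapply(seq_len(sample(1:8, 1)), function(i) {
    slen <- sample(200:5000, 1)
    best <- sample(25:400, 1)
    hsps <- lapply(seq_len(sample(1:3, 1)), function(j) {
      s <- if (j == 1) best else max(20, best - sample(5:40, 1))
      alen <- sample(15:min(m, slen), 1)
      gaps <- sample(0:floor(alen / 10), 1)
      ident <- sample(ceiling(alen / 2):(alen - gaps), 1)
      qs <- sample(seq_len(max(1, m - alen)), 1)
      ss <- sample(seq_len(max(1, slen - alen)), 1)
      new_hsp(raw_score = s, bit_score = bit_score_from_raw(kp, s),
              evalue = blast_evalue(log(kp$K) + log(m) + log(n) -
                                      kp$lambda * s),
              q_start = qs, q_end = qs + alen - 1,
              s_start = ss, s_end = ss + alen - 1,
              identity = ident, align_len = alen, gaps = gaps,
              qseq = if (dialect == "xml") strrep("A", 10) else NA_character_,
              hseq = if (dialect == "xml") strrep("A", 10) else NA_character_,
              midline = if (dialect == "xml") strrep("|", 10) else NA_character_)
    })
    sid <- sprintf("subj_%03d", i)
    new_hit(sid, if (dialect == "xml") paste("def of", sid) else sid,
            slen, hsps)
  })
  stats <- if (dialect == "xml")
    statistics_block(db_num = N, db_len = n, hsp_len = 10,
                     eff_space = (m - 10) * (n - N * 10), kappa = kp$K,
                     lambda = kp$lambda, entropy = kp$H)
  params <- if (protein) list(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1)
            else list(reward = 1, penalty = -2, gap_open = 0, gap_extend = 0)
  search_result(program, query_profile(sprintf("query_%05d", seed), m),
                db_profile("toydb", n, N,
                           molecule = if (protein) "protein" else "nucleotide"),
                hits, stats = stats, params = params, sort = TRUE)
}

# Flatten a result into comparable vectors so a round trip is checked with a
# couple of expectations rather than thousands.
result_signature <- function(r, dialect) {
  hsp_num <- function(f) unlist(lapply(r$hits, function(h)
    vapply(h$hsps, `[[`, numeric(1), f)))
  hsp_chr <- function(f) unlist(lapply(r$hits, function(h)
    vapply(h$hsps, `[[`, character(1), f)))
  le <- unlist(lapply(r$hits, function(h) vapply(h$hsps, function(s)
    if (s$evalue$zero_rounded) NA_real_ else s$evalue$log_e, numeric(1))))
  sig <- list(
    program = r$program,
    query_id = r$query$query_id,
    m = r$query$m,
    subject_id = vapply(r$hits, `[[`, character(1), "subject_id"),
    subject_len = vapply(r$hits, `[[`, numeric(1), "subject_len"),
    n_hsps = vapply(r$hits, function(h) length(h$hsps), numeric(1)),
    num = lapply(c("raw_score", "bit_score", "q_start", "q_end", "s_start",
                   "s_end", "identity", "align_len", "gaps"), hsp_num),
    zero_rounded = unlist(lapply(r$hits, function(h)
      vapply(h$hsps, function(s) s$evalue$zero_rounded, logical(1)))),
    log_e = le)
  if (dialect == "xml") {
    sig$subject_def <- vapply(r$hits, `[[`, character(1), "subject_def")
    sig$aln <- lapply(c("qseq", "hseq", "midline"), hsp_chr)
    if (!is.null(r$stats)) sig$stats <- unlist(unclass(r$stats))
  }
  sig
}

expect_same_result <- function(a, b, dialect, log_tol = 1e-8) {
  expect_equal(result_signature(b, dialect), result_signature(a, dialect),
               tolerance = log_tol)
}

# Merge all parts of a generated scenario over the final database and return
# (merged, reference) for a given query index.
merge_scenario <- function(scenario, query_index = NULL) {
  parts <- lapply(scenario$part_paths, parse_result, dialect = "xml")
  final_ref <- parse_result(scenario$reference_paths[length(scenario$reference_paths)],
                            "xml")
  union_db <- scenario$union_db
  idx <- query_index %||% seq_along(final_ref)
  list(merged = lapply(idx, function(i)
         merge_results(lapply(parts, `[[`, i), union_db = union_db)),
       reference = final_ref[idx])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tmpfile <- function(ext) tempfile(fileext = ext)

# ranking rule replicated for test-side list manipulation
sort_hits_for_test <- function(hits) {
  le <- vapply(hits, function(h) hit_evalue(h)$log_e, numeric(1))
  sc <- vapply(hits, hit_score, numeric(1))
  id <- vapply(hits, `[[`, character(1), "subject_id")
  hits[order(le, -sc, id, method = "radix")]
}
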