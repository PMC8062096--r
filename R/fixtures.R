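# Synthetic scenarios and brute-force statistical oracles.
#
# The generator builds database timelines (nested snapshots) or disjoint
# partitions, queries, and internally consistent result files, so the whole
# incremental/merge machinery is testable offline. Scores are simulated, not
# alignments: the score of a (query, subject) pair comes from a seeded hash
# and is therefore identical however the database is partitioned — the
# property that makes split-vs-whole oracle comparisons meaningful.

#' Brute-force length adjustment (exhaustive integer scan)
#'
#' Reference implementation used as ground truth in tests: scans every
#' integer l with positive effective lengths and returns the largest one
#' satisfying l <= (alpha/lambda) ln(K (m-l)(n-N l)) + beta. No iterative
#' solver is involved.
#'
#' @inheritParams length_adjustment
#' @return Integer length adjustment.
#' @export
oracle_length_adjustment <- function(params, m, n, N) {
  if (!(m > 0) || !(n > 0) || !(N > 0))
    abort_domain("m, n, N must be > 0", "incblast_domain_error")
  lmax <- ka_lmax(m, n, N)
  if (lmax == 0) return(0L)
  ls <- 0:lmax
  f <- (params$alpha / params$lambda) *
    log(params$K * (m - ls) * (n - N * ls)) + params$beta
  ok <- which(ls <= f)
  if (!length(ok)) 0L else as.integer(max(ls[ok]))
}

#' Brute-force e-value (direct formula on the scanned length adjustment)
#'
#' @inheritParams length_adjustment
#' @param db A [db_profile()].
#' @param score Raw score.
#' @return A [blast_evalue()].
#' @export
oracle_evalue <- function(params, m, db, score) {
  l <- oracle_length_adjustment(params, m, db$n, db$N)
  blast_evalue(log(params$K) + log(m - l) + log(db$n - db$N * l) -
                 params$lambda * score)
}

#' Brute-force Spouge rescaling (plain log-space addition)
#'
#' @param log_e Log e-value.
#' @param n_part,n_total Actual database lengths.
#' @return Numeric log e-value.
#' @export
oracle_rescale <- function(log_e, n_part, n_total) {
  log_e + (log(n_total) - log(n_part))
}

#' Specification of a synthetic search scenario
#'
#' Defines a database timeline (temporal: strictly nested snapshots) or a set
#' of disjoint partitions (spatial), a query set, and the deterministic score
#' model. Defaults are desk scale: a few queries of a few hundred residues
#' against volumes of a handful of multi-kilobase subjects, so full suites
#' run in seconds.
#'
#' @param seed Integer; drives both sequence sampling and the score model.
#' @param molecule `"nucleotide"` (blastn, Karlin-Altschul statistics) or
#'   `"protein"` (blastp, Spouge statistics).
#' @param type `"temporal"` (growing database) or `"spatial"` (disjoint
#'   taxon-style parts).
#' @param n_parts Number of snapshots (temporal) or partitions (spatial).
#' @param n_queries,query_len Query count and length range (residues).
#' @param subjects_per_vol,subject_len Per-volume subject count and length
#'   ranges.
#' @param hit_prob Probability that a (query, subject) pair is a hit.
#' @param score_base,score_spread Raw scores are uniform on
#'   `[score_base, score_base + score_spread]`.
#' @param hsp_max Maximum HSPs per hit.
#' @param max_target_seqs Retention parameter carried by generated results.
#' @param round_tiny Emulate upstream zero-rounding: part-result e-values
#'   below exp(-180) serialize as `0` (the whole-database reference always
#'   keeps full precision so corrections remain verifiable).
#' @param total_n,snapshot_fractions Optional: engineer volume sizes so the
#'   cumulative snapshot residue totals equal
#'   `round(snapshot_fractions * total_n)` exactly (temporal only).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(seed = 1L, molecule = c("nucleotide", "protein"),
                          type = c("temporal", "spatial"), n_parts = 3L,
                          n_queries = 4L, query_len = c(200L, 800L),
                          subjects_per_vol = c(6L, 12L),
                          subject_len = c(300L, 3000L), hit_prob = 0.6,
                          score_base = 30, score_spread = 120, hsp_max = 3L,
                          max_target_seqs = 500, round_tiny = FALSE,
                          total_n = NULL, snapshot_fractions = NULL) {
  molecule <- match.arg(molecule)
  type <- match.arg(type)
  if (n_parts < 2L) abort_domain("need >= 2 parts/snapshots", "incblast_spec_error")
  if (!is.null(snapshot_fractions)) {
    if (type != "temporal")
      abort_domain("snapshot_fractions applies to temporal scenarios",
                   "incblast_spec_error")
    if (is.null(total_n) || any(diff(snapshot_fractions) <= 0) ||
        length(snapshot_fractions) != n_parts)
      abort_domain("snapshot_fractions must be increasing, one per snapshot, with total_n set",
                   "incblast_spec_error")
  }
  structure(list(seed = as.integer(seed), molecule = molecule, type = type,
                 n_parts = as.integer(n_parts),
                 n_queries = as.integer(n_queries), query_len = query_len,
                 subjects_per_vol = subjects_per_vol,
                 subject_len = subject_len, hit_prob = hit_prob,
                 score_base = score_base, score_spread = score_spread,
                 hsp_max = as.integer(hsp_max),
                 max_target_seqs = max_target_seqs, round_tiny = round_tiny,
                 total_n = total_n, snapshot_fractions = snapshot_fractions),
            class = "scenario_spec")
}

scenario_program <- function(spec)
  if (spec$molecule == "nucleotide") "blastn" else "blastp"

scenario_params <- function(spec) {
  if (spec$molecule == "nucleotide")
    list(reward = 1, penalty = -2, gap_open = 0, gap_extend = 0,
         expect = 10, max_target_seqs = spec$max_target_seqs)
  else
    list(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
         expect = 10, max_target_seqs = spec$max_target_seqs)
}

scenario_kparams <- function(spec) {
  p <- scenario_params(spec)
  lookup_karlin_params(scenario_program(spec), matrix = p$matrix %||% NA,
                       reward = p$reward %||% NA, penalty = p$penalty %||% NA,
                       gap_open = p$gap_open, gap_extend = p$gap_extend)
}

# Deterministic score model: whether (query, subject) is a hit, its HSP
# scores and schematic alignment geometry all derive from seeded hashes, so
# they are invariant to how the database is split.
model_hsps <- function(spec, qid, qlen, sid, slen) {
  if (hash_unit("hit", spec$seed, qid, sid) >= spec$hit_prob) return(NULL)
  best <- spec$score_base +
    floor(hash_unit("score", spec$seed, qid, sid) * spec$score_spread)
  nh <- 1L + floor(hash_unit("nh", spec$seed, qid, sid) * spec$hsp_max)
  lapply(seq_len(nh), function(j) {
    s <- if (j == 1L) best
         else max(20, best - j * (3 + floor(hash_unit("dec", spec$seed, qid,
                                                      sid, j) * 25)))
    alen <- max(10, floor(min(qlen, slen) *
                            (0.2 + 0.6 * hash_unit("al", spec$seed, qid, sid, j))))
    gaps <- floor(alen * 0.05 * hash_unit("gp", spec$seed, qid, sid, j))
    ident <- min(alen - gaps,
                 max(1, floor(alen * (0.7 + 0.3 * hash_unit("id", spec$seed,
                                                            qid, sid, j)))))
    qs <- 1 + floor(hash_unit("qs", spec$seed, qid, sid, j) *
                      max(0, qlen - alen))
    ss <- 1 + floor(hash_unit("ss", spec$seed, qid, sid, j) *
                      max(0, slen - alen))
    list(score = s, align_len = alen, gaps = gaps, identity = ident,
         q_start = qs, q_end = min(qlen, qs + alen - 1),
         s_start = ss, s_end = min(slen, ss + alen - 1))
  })
}

#' Deterministic mock search over a subject table
#'
#' Emulates what a search of `db` would report, with statistics computed by
#' the brute-force oracles: Karlin-Altschul e-values use the exhaustively
#' scanned length adjustment; Spouge-family e-values follow the ratio model
#' E = K n exp(-lambda S) with the statistics block's `eff_space` set to `n`
#' (the part search space). No e-value cutoff is applied — hit existence is
#' decided by the partition-invariant score model only — so split searches
#' and whole-database searches see exactly the same candidate set. Hits are
#' ranked and truncated at `max_target_seqs` like the upstream tool.
#'
#' @param spec A [scenario_spec()].
#' @param queries Data frame with columns `id`, `len`.
#' @param subjects Data frame with columns `id`, `len`.
#' @param db [db_profile()] the statistics are computed against.
#' @param round_tiny Zero-round e-values below exp(-180) (see
#'   [scenario_spec()]).
#' @return List of [search_result()], one per query.
#' @export
simulate_search <- function(spec, queries, subjects, db, round_tiny = FALSE) {
  kp <- scenario_kparams(spec)
  program <- scenario_program(spec)
  family <- stats_family(program)
  params <- scenario_params(spec)
  lapply(seq_len(nrow(queries)), function(qi) {
    qid <- queries$id[qi]; qlen <- queries$len[qi]
    if (family == "karlin-altschul") {
      l <- oracle_length_adjustment(kp, qlen, db$n, db$N)
      log_space <- log(qlen - l) + log(db$n - db$N * l)
      eff <- (qlen - l) * (db$n - db$N * l)
    } else {
      l <- 0L
      log_space <- log(db$n)
      eff <- db$n
    }
    hits <- list()
    for (si in seq_len(nrow(subjects))) {
      hs <- model_hsps(spec, qid, qlen, subjects$id[si], subjects$len[si])
      if (is.null(hs)) next
      hsps <- lapply(hs, function(h) {
        le <- log(kp$K) + log_space - kp$lambda * h$score
        ev <- if (round_tiny && le < -180) blast_evalue(-Inf, TRUE)
              else blast_evalue(le)
        new_hsp(raw_score = h$score,
                bit_score = bit_score_from_raw(kp, h$score),
                evalue = ev, q_start = h$q_start, q_end = h$q_end,
                s_start = h$s_start, s_end = h$s_end, identity = h$identity,
                align_len = h$align_len, gaps = h$gaps)
      })
      hits[[length(hits) + 1L]] <-
        new_hit(subjects$id[si], paste("synthetic subject", subjects$id[si]),
                subjects$len[si], hsps)
    }
    stats <- statistics_block(db_num = db$N, db_len = db$n, hsp_len = l,
                              eff_space = eff, kappa = kp$K,
                              lambda = kp$lambda, entropy = kp$H)
    r <- search_result(program, query_profile(qid, qlen), db, hits,
                       stats = stats, params = params, sort = TRUE)
    truncate_hits(r, spec$max_target_seqs)
  })
}

rand_seq <- function(len, molecule) {
  alphabet <- if (molecule == "nucleotide") c("A", "C", "G", "T")
              else strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

#' Generate a synthetic search scenario on disk
#'
#' Writes a self-contained bundle: query FASTA, per-volume subject tables and
#' database-profile sidecars (JSON), per-part/per-delta result XML as an
#' upstream search of each part would have produced, and whole-database
#' reference result XML for every snapshot (temporal) or the union (spatial).
#' All statistics in the result files are computed with the brute-force
#' oracles, independent of the package's iterative solver. Byte-for-byte
#' reproducible for a given spec.
#'
#' @param spec A [scenario_spec()].
#' @param dir Output directory (created).
#' @return A list describing the bundle: `spec`, `dir`, `queries` (data
#'   frame), `volumes` (named list of subject data frames), `profiles`
#'   (snapshot/part [db_profile()]s), `union_db`, and the result paths
#'   (`part_paths`, `reference_paths`, `query_fasta`).
#' @export
generate_scenario <- function(spec, dir = tempfile("scenario")) {
  stopifnot(inherits(spec, "scenario_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "results"), showWarnings = FALSE)
  dir.create(file.path(dir, "db"), showWarnings = FALSE)
  base <- if (spec$molecule == "nucleotide") "toy_nt" else "toy_nr"

  bundle <- with_seed(spec$seed, {
    queries <- data.frame(
      id = sprintf("query_%02d", seq_len(spec$n_queries)),
      len = sample(spec$query_len[1]:spec$query_len[2], spec$n_queries,
                   replace = TRUE))
    queries$seq <- vapply(queries$len, rand_seq, character(1),
                          molecule = spec$molecule)
    vol_targets <- if (!is.null(spec$snapshot_fractions))
      diff(c(0, round(spec$snapshot_fractions * spec$total_n))) else NULL
    volumes <- list()
    for (v in seq_len(spec$n_parts)) {
      k <- sample(spec$subjects_per_vol[1]:spec$subjects_per_vol[2], 1)
      lens <- sample(spec$subject_len[1]:spec$subject_len[2], k, replace = TRUE)
      if (!is.null(vol_targets)) {
        # engineer exact volume residue totals: scale, then absorb the
        # remainder into the last subject
        lens <- pmax(50, round(lens * vol_targets[v] / sum(lens)))
        lens[k] <- max(50, lens[k] + vol_targets[v] - sum(lens))
      }
      volumes[[sprintf("%s.%02d", base, v - 1)]] <-
        data.frame(id = sprintf("subj_v%02d_%03d", v, seq_len(k)), len = lens)
    }
    list(queries = queries, volumes = volumes)
  })
  queries <- bundle$queries
  volumes <- bundle$volumes
  vol_files <- names(volumes)
  vol_n <- vapply(volumes, function(v) sum(v$len), numeric(1))
  vol_N <- vapply(volumes, nrow, numeric(1))

  qfa <- file.path(dir, "queries.fasta")
  Biostrings::writeXStringSet(
    if (spec$molecule == "nucleotide")
      Biostrings::DNAStringSet(stats::setNames(queries$seq, queries$id))
    else Biostrings::AAStringSet(stats::setNames(queries$seq, queries$id)),
    qfa)
  for (vf in vol_files)
    jsonlite::write_json(volumes[[vf]], file.path(dir, "db", paste0(vf, ".json")),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)

  profiles <- list()
  part_paths <- character()
  reference_paths <- character()
  if (spec$type == "temporal") {
    for (i in seq_len(spec$n_parts)) {
      profiles[[i]] <- db_profile(base, sum(vol_n[1:i]), sum(vol_N[1:i]),
                                  files = vol_files[1:i],
                                  molecule = spec$molecule,
                                  timestamp = paste0("t", i - 1))
      # delta volumes searched at step i (step 1 = the full first snapshot)
      dsub <- do.call(rbind, volumes[if (i == 1) 1 else i])
      ddb <- if (i == 1) profiles[[1]]
             else db_profile(paste0(base, ".delta"), vol_n[i], vol_N[i],
                             files = vol_files[i], molecule = spec$molecule,
                             timestamp = paste0("t", i - 1))
      part_paths[i] <- file.path(dir, "results", sprintf("delta_%02d.xml", i))
      write_blast_xml(simulate_search(spec, queries, dsub, ddb,
                                      round_tiny = spec$round_tiny),
                      part_paths[i])
      refsub <- do.call(rbind, volumes[1:i])
      reference_paths[i] <- file.path(dir, "results",
                                      sprintf("reference_%02d.xml", i))
      write_blast_xml(simulate_search(spec, queries, refsub, profiles[[i]]),
                      reference_paths[i])
    }
    union_db <- profiles[[spec$n_parts]]
  } else {
    for (i in seq_len(spec$n_parts)) {
      profiles[[i]] <- db_profile(sprintf("%s_part%02d", base, i), vol_n[i],
                                  vol_N[i], files = vol_files[i],
                                  molecule = spec$molecule)
      part_paths[i] <- file.path(dir, "results", sprintf("part_%02d.xml", i))
      write_blast_xml(simulate_search(spec, queries, volumes[[i]],
                                      profiles[[i]],
                                      round_tiny = spec$round_tiny),
                      part_paths[i])
    }
    union_db <- db_profile(paste0(base, "_union"), sum(vol_n), sum(vol_N),
                           files = vol_files, molecule = spec$molecule)
    reference_paths <- file.path(dir, "results", "reference.xml")
    write_blast_xml(simulate_search(spec, queries, do.call(rbind, volumes),
                                    union_db),
                    reference_paths)
  }
  for (i in seq_along(profiles))
    jsonlite::write_json(unclass(profiles[[i]]),
                         file.path(dir, "db", sprintf("profile_%02d.json", i)),
                         auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(type = spec$type, molecule = spec$molecule, seed = spec$seed,
         program = scenario_program(spec), volumes = vol_files,
         part_results = basename(part_paths),
         reference_results = basename(reference_paths)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)

  list(spec = spec, dir = dir, queries = queries, volumes = volumes,
       profiles = profiles, union_db = union_db, part_paths = part_paths,
       reference_paths = reference_paths, query_fasta = qfa)
}

#' Deterministic executor over a generated scenario
#'
#' Returns a function satisfying the [incremental_search()] executor
#' contract, backed by [simulate_search()] on the scenario's subject tables.
#' Scores depend only on (query, subject, seed), never on the database
#' partitioning, and no result is cached: calling it on a delta database
#' searches exactly the delta volumes.
#'
#' @param scenario A [generate_scenario()] bundle.
#' @return `function(queries, db, program, params) -> list of search_result`.
#' @export
mock_executor <- function(scenario) {
  force(scenario)
  function(queries, db, program, params) {
    if (inherits(queries, "XStringSet"))
      queries <- data.frame(id = names(queries),
                            len = Biostrings::width(queries))
    if (is.character(queries))
      queries <- data.frame(id = names(queries), len = nchar(queries))
    unknown <- setdiff(db$files, names(scenario$volumes))
    if (length(unknown))
      abort_domain(paste0("executor has no volumes named: ",
                          paste(unknown, collapse = ", ")),
                   "incblast_domain_error")
    subjects <- do.call(rbind, scenario$volumes[db$files])
    simulate_search(scenario$spec, queries, subjects, db,
                    round_tiny = scenario$spec$round_tiny)
  }
}
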