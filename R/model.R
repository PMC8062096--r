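#' Query profile
#'
#' @param query_id Identifier (FASTA definition line of the query).
#' @param m Actual query length in residues, > 0.
#' @return An object of class `query_profile`.
#' @export
query_profile <- function(query_id, m) {
  if (!(m > 0)) abort_domain("query length m must be > 0", "incblast_domain_error")
  structure(list(query_id = as.character(query_id), m = as.numeric(m)),
            class = "query_profile")
}

#' Database snapshot profile
#'
#' Identity and size of a database instance at a point in time: total residue
#' count `n`, sequence count `N`, and the ordered list of member volume
#' files. Incremental logic compares snapshots by their file lists; `n` and
#' `N` drive all statistics.
#'
#' @param db_id Stable identifier of the logical database (e.g. `"nt"`).
#' @param n Total residues/bases (>= 0).
#' @param N Number of sequences (>= 0).
#' @param files Ordered member volume filenames (no duplicates).
#' @param molecule `"nucleotide"` or `"protein"`.
#' @param timestamp Free-form snapshot label.
#' @return An object of class `db_profile`.
#' @export
db_profile <- function(db_id, n, N, files = character(),
                       molecule = c("nucleotide", "protein"), timestamp = "") {
  molecule <- match.arg(molecule)
  if (n < 0 || N < 0) abort_domain("n and N must be >= 0", "incblast_domain_error")
  if ((n > 0 || N > 0) && n < N)
    abort_domain("n < N: every sequence has at least one residue",
                 "incblast_domain_error")
  if (anyDuplicated(files))
    abort_domain("duplicate member files in database profile",
                 "incblast_domain_error")
  structure(list(db_id = as.character(db_id), n = as.numeric(n),
                 N = as.numeric(N), files = as.character(files),
                 molecule = molecule, timestamp = as.character(timestamp)),
            class = "db_profile")
}

#' Snapshot content identity of a database profile
#'
#' Digest of the sorted volume file list plus sizes; timestamps are labels
#' only and do not participate.
#'
#' @param db A `db_profile`.
#' @return Character digest.
#' @export
db_identity <- function(db) {
  hash_hex(fnv1a(paste(c(sort(db$files), db$n, db$N), collapse = "|")))
}

#' @export
print.db_profile <- function(x, ...) {
  cat(sprintf("<db_profile> '%s'%s: n=%s residues, N=%s sequences, %d volume(s) [%s]\n",
              x$db_id,
              if (nzchar(x$timestamp)) paste0(" @", x$timestamp) else "",
              format(x$n, big.mark = ","), format(x$N, big.mark = ","),
              length(x$files), x$molecule))
  invisible(x)
}

#' High-scoring pair (HSP)
#'
#' One locally-optimal gapped local alignment between a query and a subject,
#' carrying its raw score, bit score and e-value plus 1-based inclusive
#' coordinates exactly as the search program reported them (minus-strand
#' nucleotide coordinates stay reversed).
#'
#' @param raw_score Integer alignment score.
#' @param bit_score Normalized score in bits.
#' @param evalue A [blast_evalue()] (or numeric log-e).
#' @param q_start,q_end,s_start,s_end 1-based inclusive coordinates.
#' @param identity,align_len,gaps Alignment summary counts.
#' @param positive Positive-scoring pairs (protein), optional.
#' @param q_frame,h_frame Reading frames, optional.
#' @param qseq,hseq,midline Alignment strings, optional.
#' @return An object of class `blast_hsp`.
#' @export
new_hsp <- function(raw_score, bit_score, evalue, q_start, q_end,
                    s_start, s_end, identity, align_len, gaps = 0,
                    positive = NA_real_, q_frame = NA_integer_,
                    h_frame = NA_integer_, qseq = NA_character_,
                    hseq = NA_character_, midline = NA_character_) {
  if (align_len < identity || identity < 0)
    abort_domain("need align_len >= identity >= 0", "incblast_domain_error")
  structure(list(raw_score = as.numeric(raw_score),
                 bit_score = as.numeric(bit_score),
                 evalue = as_evalue(evalue),
                 q_start = as.numeric(q_start), q_end = as.numeric(q_end),
                 s_start = as.numeric(s_start), s_end = as.numeric(s_end),
                 identity = as.numeric(identity),
                 align_len = as.numeric(align_len), gaps = as.numeric(gaps),
                 positive = as.numeric(positive),
                 q_frame = q_frame, h_frame = h_frame,
                 qseq = qseq, hseq = hseq, midline = midline),
            class = "blast_hsp")
}

#' Hit: a subject sequence with its HSPs
#'
#' The hit's reported score is the maximum raw score over its HSPs and its
#' reported e-value is the e-value of that highest-scoring HSP.
#'
#' @param subject_id Subject sequence identifier.
#' @param subject_def Subject definition line.
#' @param subject_len Subject length in residues.
#' @param hsps Nonempty list of [new_hsp()] objects.
#' @return An object of class `blast_hit`.
#' @export
new_hit <- function(subject_id, subject_def, subject_len, hsps) {
  if (!length(hsps)) abort_domain("a hit needs at least one HSP",
                                  "incblast_domain_error")
  structure(list(subject_id = as.character(subject_id),
                 subject_def = as.character(subject_def),
                 subject_len = as.numeric(subject_len),
                 hsps = hsps),
            class = "blast_hit")
}

#' @rdname new_hit
#' @param hit A `blast_hit`.
#' @export
hit_best_hsp <- function(hit) {
  hit$hsps[[which.max(vapply(hit$hsps, `[[`, numeric(1), "raw_score"))]]
}

#' @rdname new_hit
#' @export
hit_score <- function(hit) hit_best_hsp(hit)$raw_score

#' @rdname new_hit
#' @export
hit_evalue <- function(hit) hit_best_hsp(hit)$evalue

#' Per-result statistics block
#'
#' The per-query copy of N (`db_num`), n (`db_len`), length adjustment l
#' (`hsp_len`), effective search space D (`eff_space`) and the scoring
#' parameters K (`kappa`), lambda and H (`entropy`), as serialized by the
#' standard BLAST XML `Statistics` element.
#'
#' @param db_num,db_len,hsp_len,eff_space,kappa,lambda,entropy See above.
#' @return An object of class `statistics_block`.
#' @export
statistics_block <- function(db_num, db_len, hsp_len = NA_real_,
                             eff_space = NA_real_, kappa = NA_real_,
                             lambda = NA_real_, entropy = NA_real_) {
  structure(list(db_num = as.numeric(db_num), db_len = as.numeric(db_len),
                 hsp_len = as.numeric(hsp_len),
                 eff_space = as.numeric(eff_space),
                 kappa = as.numeric(kappa), lambda = as.numeric(lambda),
                 entropy = as.numeric(entropy)),
            class = "statistics_block")
}

#' One query's search result against one database instance
#'
#' @param program BLAST program name.
#' @param query A [query_profile()].
#' @param db A [db_profile()].
#' @param hits List of [new_hit()], sorted ascending by hit e-value (ties:
#'   descending score, then subject id); use `sort = TRUE` to establish the
#'   order.
#' @param stats A [statistics_block()] describing the statistics the
#'   e-values were computed under, or `NULL` (tabular input).
#' @param params Search parameter list; recognized entries include
#'   `max_target_seqs` (default 500) and the scoring scheme (`matrix` or
#'   `reward`/`penalty`, `gap_open`, `gap_extend`).
#' @param sort Re-sort hits by the ranking rule?
#' @return An object of class `search_result`.
#' @export
search_result <- function(program, query, db, hits = list(), stats = NULL,
                          params = list(), sort = FALSE) {
  program <- normalize_program(program)
  stats_family(program)  # validates the program name
  params$max_target_seqs <- params$max_target_seqs %||% 500
  if (sort) hits <- sort_hits(hits)
  structure(list(program = program, query = query, db = db, hits = hits,
                 stats = stats, params = params),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> %s: query '%s' (m=%g) vs db '%s' (n=%g, N=%g); %d hit(s)\n",
              x$program, x$query$query_id, x$query$m, x$db$db_id, x$db$n,
              x$db$N, length(x$hits)))
  invisible(x)
}

# Ranking rule: ascending e-value, ties broken by descending raw score, then
# lexicographic subject id for determinism. E-values are compared on log_e
# rounded to 6 decimals (a relative e-value difference below 1e-6) so that
# floating-point noise from different but equivalent computation routes
# (rescaling vs direct evaluation, serialization round trips) cannot shuffle
# genuine ties; distinct raw scores are always separated by at least lambda
# in log_e, far above the quantum.
hit_rank_keys <- function(hits) {
  list(le = round(vapply(hits, function(h) hit_evalue(h)$log_e, numeric(1)), 6),
       sc = vapply(hits, hit_score, numeric(1)),
       id = vapply(hits, `[[`, character(1), "subject_id"))
}

sort_hits <- function(hits) {
  if (length(hits) < 2L) return(hits)
  k <- hit_rank_keys(hits)
  hits[order(k$le, -k$sc, k$id, method = "radix")]
}

#' Keep only the `k` best-ranked hits
#'
#' @param result A `search_result` (hits already ranked).
#' @param k Number of hits to retain.
#' @return The truncated `search_result`.
#' @export
truncate_hits <- function(result, k) {
  result$hits <- utils::head(result$hits, k)
  result
}

#' Validate the internal invariants of a search result
#'
#' Checks hit ordering, nonempty HSP lists, coordinate/identity sanity and
#' that every e-value is either positive or explicitly zero-rounded.
#'
#' @param result A `search_result`.
#' @return Invisibly `TRUE`; aborts with a descriptive error otherwise.
#' @export
validate_search_result <- function(result) {
  stopifnot(inherits(result, "search_result"))
  for (hit in result$hits) {
    if (!length(hit$hsps)) abort_domain("hit with no HSPs", "incblast_invariant_error")
    for (hsp in hit$hsps) {
      if (hsp$align_len < hsp$identity)
        abort_domain("align_len < identity", "incblast_invariant_error")
      if (!hsp$evalue$zero_rounded && !is.finite(hsp$evalue$log_e))
        abort_domain("non-finite e-value without zero-rounded flag",
                     "incblast_invariant_error")
    }
  }
  if (length(result$hits) > 1L) {
    k <- hit_rank_keys(result$hits)
    if (!identical(order(k$le, -k$sc, k$id, method = "radix"),
                   seq_along(result$hits)))
      abort_domain("hits are not in ranking order", "incblast_invariant_error")
  }
  invisible(TRUE)
}
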