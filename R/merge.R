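#' Recalibrate a search result to a larger (union) database
#'
#' Replaces every HSP e-value so the result reads as if the search had been
#' run against `union_db`:
#'
#' * Karlin-Altschul programs (blastn, tblastx): the length adjustment is
#'   re-solved for the union database and every e-value is recomputed from
#'   its raw score on the new effective search space (the recompute form;
#'   the additive correction [correct_evalue_ka()] is provided and
#'   cross-checked in the test suite but needs more operations).
#' * Spouge programs (blastp, blastx, tblastn): e-values are rescaled by the
#'   ratio of actual database lengths, exactly in log space. Inputs flagged
#'   zero-rounded are first regenerated from their raw score as
#'   K * eff_space * exp(-lambda S) on the part search space.
#'
#' The statistics block and database profile are updated to the union, hit
#' e-values re-derive from their best HSPs, and ranking order is
#' re-established.
#'
#' @param result A [search_result()] with a statistics block (XML input) or
#'   a `part_db` override.
#' @param union_db [db_profile()] of the union database; must be at least as
#'   large as the part in both residues and sequences.
#' @param params_table Parameter table for alpha/beta lookup, see
#'   [ka_parameter_table()].
#' @param part_db Optional [db_profile()] giving the part-database sizes when
#'   the result has no statistics block (tabular input).
#' @return The recalibrated [search_result()].
#' @export
recalibrate <- function(result, union_db, params_table = ka_parameter_table(),
                        part_db = NULL) {
  stopifnot(inherits(result, "search_result"), inherits(union_db, "db_profile"))
  part <- part_db %||% result$db
  n_part <- if (!is.null(result$stats)) result$stats$db_len else part$n
  N_part <- if (!is.null(result$stats)) result$stats$db_num else part$N
  if (!(n_part > 0) || !(N_part > 0))
    abort_domain("part database sizes unknown: supply a statistics block or part_db",
                 "incblast_capability_error")
  if (union_db$n < n_part || union_db$N < N_part)
    abort_domain("union database smaller than the part: database shrank",
                 "incblast_domain_error")
  family <- stats_family(result$program)
  kappa <- if (!is.null(result$stats)) result$stats$kappa else NA_real_
  lambda <- if (!is.null(result$stats)) result$stats$lambda else NA_real_
  entropy <- if (!is.null(result$stats)) result$stats$entropy else NA_real_

  if (family == "karlin-altschul") {
    scores <- unlist(lapply(result$hits, function(h)
      vapply(h$hsps, `[[`, numeric(1), "raw_score")))
    if (length(scores) && anyNA(scores))
      abort_domain(paste0("raw scores unavailable (12-column tabular input?): ",
                          "Karlin-Altschul recalibration needs them"),
                   "incblast_capability_error")
    p <- lookup_karlin_params(result$program,
                              matrix = result$params$matrix %||% NA,
                              reward = result$params$reward %||% NA,
                              penalty = result$params$penalty %||% NA,
                              gap_open = result$params$gap_open %||% NA,
                              gap_extend = result$params$gap_extend %||% NA,
                              stats_lambda = lambda, stats_K = kappa,
                              stats_H = entropy, table = params_table)
    space <- effective_search_space(p, result$query$m, union_db$n, union_db$N)
    result$hits <- lapply(result$hits, function(h) {
      h$hsps <- lapply(h$hsps, function(s) {
        s$evalue <- evalue_from_score(p, space, s$raw_score)
        s
      })
      h
    })
    result$stats <- statistics_block(db_num = union_db$N, db_len = union_db$n,
                                     hsp_len = space$l, eff_space = space$D,
                                     kappa = p$K, lambda = p$lambda,
                                     entropy = p$H)
  } else {
    if (!(union_db$n > 0))
      abort_domain("union database length must be > 0", "incblast_domain_error")
    lratio <- log(union_db$n) - log(n_part)
    eff_part <- if (!is.null(result$stats)) result$stats$eff_space else NA_real_
    result$hits <- lapply(result$hits, function(h) {
      h$hsps <- lapply(h$hsps, function(s) {
        if (s$evalue$zero_rounded) {
          if (is.na(s$raw_score) || is.na(kappa) || is.na(lambda) ||
              is.na(eff_part))
            abort_domain(paste0("zero-rounded e-value needs the raw score and ",
                                "the part statistics block to regenerate"),
                         "incblast_capability_error")
          s$evalue <- blast_evalue(log(kappa) + log(eff_part) -
                                     lambda * s$raw_score + lratio)
        } else {
          s$evalue <- rescale_evalue_spouge(s$evalue, n_part, union_db$n)
        }
        s
      })
      h
    })
    result$stats <- statistics_block(
      db_num = union_db$N, db_len = union_db$n,
      hsp_len = if (!is.null(result$stats)) result$stats$hsp_len else NA_real_,
      eff_space = if (is.na(eff_part)) NA_real_ else exp(log(eff_part) + lratio),
      kappa = kappa, lambda = lambda, entropy = entropy)
  }
  result$db <- union_db
  result$hits <- sort_hits(result$hits)
  result
}

#' Plan a merge of per-part results for one query
#'
#' Validates that all parts share the program, query identity and scoring
#' scheme, that the part volume lists are pairwise disjoint, and constructs
#' the union database profile (n and N are sums, volume lists concatenate).
#'
#' @param parts List of [search_result()] objects for the same query against
#'   disjoint database parts.
#' @param union_db Optional precomputed union [db_profile()]; by default it
#'   is summed from the parts.
#' @param max_target_seqs Retention parameter; defaults to the largest value
#'   declared by any part. The merged result retains `2 * max_target_seqs`
#'   hits.
#' @return An object of class `merge_plan`.
#' @export
merge_plan <- function(parts, union_db = NULL, max_target_seqs = NULL) {
  if (!length(parts)) abort_domain("no parts to merge", "incblast_plan_error")
  prog <- unique(vapply(parts, `[[`, character(1), "program"))
  if (length(prog) != 1L)
    abort_domain(paste0("mixed programs in merge: ", paste(prog, collapse = ", ")),
                 "incblast_plan_error")
  qid <- unique(vapply(parts, function(p) p$query$query_id, character(1)))
  qm <- unique(vapply(parts, function(p) p$query$m, numeric(1)))
  if (length(qid) != 1L || length(qm) != 1L)
    abort_domain("parts are answers for different queries", "incblast_plan_error")
  scheme <- unique(vapply(parts, function(p)
    paste(p$params$matrix %||% NA, p$params$reward %||% NA,
          p$params$penalty %||% NA, p$params$gap_open %||% NA,
          p$params$gap_extend %||% NA), character(1)))
  if (length(scheme) != 1L)
    abort_domain("parts use different scoring schemes", "incblast_plan_error")
  files <- lapply(parts, function(p) p$db$files)
  allf <- unlist(files)
  if (anyDuplicated(allf))
    warning("part volume lists are not disjoint: ",
            paste(unique(allf[duplicated(allf)]), collapse = ", "),
            call. = FALSE)
  part_n <- vapply(parts, function(p)
    if (!is.null(p$stats)) p$stats$db_len else p$db$n, numeric(1))
  part_N <- vapply(parts, function(p)
    if (!is.null(p$stats)) p$stats$db_num else p$db$N, numeric(1))
  if (is.null(union_db))
    union_db <- db_profile(
      db_id = paste0("union:", paste(vapply(parts, function(p) p$db$db_id,
                                            character(1)), collapse = "+")),
      n = sum(part_n), N = sum(part_N), files = unique(allf),
      molecule = parts[[1L]]$db$molecule)
  mts <- max_target_seqs %||%
    max(vapply(parts, function(p) p$params$max_target_seqs %||% 500, numeric(1)))
  structure(list(parts = parts, union_db = union_db,
                 max_target_seqs = mts, retain = 2 * mts),
            class = "merge_plan")
}

#' Merge per-part search results into one union-database result
#'
#' Every part is recalibrated against the same union database (a k-way merge,
#' not a pairwise cascade, so association order cannot matter), the hit lists
#' are pooled, duplicate subjects across supposedly disjoint parts keep the
#' better e-value (with a warning), hits are ranked ascending by e-value
#' (ties: descending score, then subject id) and the best
#' `2 * max_target_seqs` are retained. The result's statistics block and
#' database profile reflect the union database.
#'
#' @param parts List of [search_result()] for one query, or a [merge_plan()].
#' @param union_db,max_target_seqs See [merge_plan()].
#' @param params_table See [recalibrate()].
#' @return The merged [search_result()].
#' @export
merge_results <- function(parts, union_db = NULL, max_target_seqs = NULL,
                          params_table = ka_parameter_table()) {
  plan <- if (inherits(parts, "merge_plan")) parts
          else merge_plan(parts, union_db, max_target_seqs)
  recal <- lapply(plan$parts, recalibrate, union_db = plan$union_db,
                  params_table = params_table)
  pooled <- unlist(lapply(recal, `[[`, "hits"), recursive = FALSE)
  ids <- vapply(pooled, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) {
    warning("duplicate subject(s) across parts, keeping the better hit: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
    keep <- rep(TRUE, length(pooled))
    for (dup in unique(ids[duplicated(ids)])) {
      idx <- which(ids == dup)
      best <- idx[order(vapply(pooled[idx], function(h) hit_evalue(h)$log_e,
                               numeric(1)),
                        -vapply(pooled[idx], hit_score, numeric(1)))[1L]]
      keep[setdiff(idx, best)] <- FALSE
    }
    pooled <- pooled[keep]
  }
  out <- recal[[1L]]
  out$hits <- utils::head(sort_hits(pooled), plan$retain)
  out$db <- plan$union_db
  out$params$max_target_seqs <- plan$max_target_seqs
  out
}

#' Fidelity report between two results for the same query
#'
#' Quantifies agreement the way incremental-vs-whole-database validations are
#' reported: the percentage of shared hits, the percentage of shared hits
#' whose e-values agree within a relative tolerance, and positional order
#' agreement over the shared hits.
#'
#' @param a,b [search_result()] objects for the same query.
#' @param rel_tol Relative tolerance for the e-value comparison (applied to
#'   linear e-values via their logs).
#' @return A list of class `fidelity_report` with `hit_match`,
#'   `evalue_match`, `order_agreement` (percentages) and supporting counts.
#' @export
compare_results <- function(a, b, rel_tol = 1e-6) {
  if (!identical(a$query$query_id, b$query$query_id))
    abort_domain("results answer different queries", "incblast_domain_error")
  ids_a <- vapply(a$hits, `[[`, character(1), "subject_id")
  ids_b <- vapply(b$hits, `[[`, character(1), "subject_id")
  common <- intersect(ids_a, ids_b)
  denom <- max(length(ids_a), length(ids_b))
  hit_match <- if (denom == 0L) 100 else 100 * length(common) / denom
  ev <- function(r, ids) {
    le <- vapply(r$hits, function(h) hit_evalue(h)$log_e, numeric(1))
    zr <- vapply(r$hits, function(h) hit_evalue(h)$zero_rounded, logical(1))
    list(le = stats::setNames(le, ids), zr = stats::setNames(zr, ids))
  }
  ea <- ev(a, ids_a); eb <- ev(b, ids_b)
  if (length(common)) {
    both_zr <- ea$zr[common] & eb$zr[common]
    dlog <- abs(ea$le[common] - eb$le[common])
    ok <- both_zr | (is.finite(dlog) & abs(expm1(-dlog)) <= rel_tol)
    evalue_match <- 100 * mean(ok)
    order_agreement <- 100 * mean(ids_a[ids_a %in% common] ==
                                    ids_b[ids_b %in% common])
  } else {
    evalue_match <- 100
    order_agreement <- 100
  }
  structure(list(hit_match = hit_match, evalue_match = evalue_match,
                 order_agreement = order_agreement,
                 n_a = length(ids_a), n_b = length(ids_b),
                 n_common = length(common), rel_tol = rel_tol),
            class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat(sprintf(paste0("<fidelity_report> hit match %.1f%%, e-value match %.1f%% ",
                     "(rel tol %g), order agreement %.1f%% ",
                     "[%d vs %d hits, %d shared]\n"),
              x$hit_match, x$evalue_match, x$rel_tol, x$order_agreement,
              x$n_a, x$n_b, x$n_common))
  invisible(x)
}
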