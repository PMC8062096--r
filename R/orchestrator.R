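# Incremental-search orchestration: record store, delta databases, alias
# files and the search driver itself.

#' Search-record store
#'
#' A lightweight persistent store of search metadata: for each
#' (query digest, database id, program, parameter digest) it keeps the
#' database snapshot at search time and a path to the stored result — never
#' sequence data. Only the most recent record per key is retained, so the
#' store stays O(1) per (query set, database, program, parameters). Backed by
#' a single JSON file.
#'
#' @param path Path of the store file (created on first write).
#' @return An object of class `record_store`.
#' @export
record_store <- function(path) {
  structure(list(path = path), class = "record_store")
}

read_store <- function(store) {
  if (!file.exists(store$path)) return(list())
  recs <- jsonlite::read_json(store$path, simplifyVector = FALSE)
  if (!is.list(recs)) abort_domain("record store corrupted",
                                   "incblast_integrity_error")
  recs
}

record_key <- function(query_digest, db_id, program, params_digest) {
  paste(query_digest, db_id, normalize_program(program), params_digest,
        sep = "::")
}

#' Store a search record
#'
#' @param store A [record_store()].
#' @param query_digest Content digest of the query set, see
#'   [query_set_digest()].
#' @param db_snapshot [db_profile()] at search time.
#' @param program BLAST program.
#' @param params_digest Digest of the search parameters, see
#'   [params_digest()].
#' @param result_path Where the stored result lives.
#' @return Invisibly, the record (a list).
#' @export
record_put <- function(store, query_digest, db_snapshot, program,
                       params_digest, result_path) {
  recs <- read_store(store)
  key <- record_key(query_digest, db_snapshot$db_id, program, params_digest)
  rec <- list(key = key, query_digest = query_digest,
              db_snapshot = unclass(db_snapshot),
              program = normalize_program(program),
              params_digest = params_digest, result_path = result_path,
              created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  recs <- Filter(function(r) !identical(r$key, key), recs)  # most recent only
  recs[[length(recs) + 1L]] <- rec
  jsonlite::write_json(recs, store$path, auto_unbox = TRUE, digits = NA)
  invisible(rec)
}

#' Look up the unique record for a search
#'
#' @inheritParams record_put
#' @param db_id Logical database identifier.
#' @return The record (with `db_snapshot` restored to a [db_profile()]) or
#'   `NULL` when no record exists.
#' @export
record_lookup <- function(store, query_digest, db_id, program, params_digest) {
  recs <- read_store(store)
  key <- record_key(query_digest, db_id, program, params_digest)
  hit <- Filter(function(r) identical(r$key, key), recs)
  if (!length(hit)) return(NULL)
  if (length(hit) > 1L)
    abort_domain("record store corrupted: duplicate key",
                 "incblast_integrity_error")
  rec <- hit[[1L]]
  s <- rec$db_snapshot
  rec$db_snapshot <- db_profile(s$db_id, s$n, s$N,
                                unlist(s$files) %||% character(),
                                s$molecule, s$timestamp %||% "")
  rec
}

#' @rdname record_lookup
#' @export
record_list <- function(store) read_store(store)

#' Content digest of a query set
#'
#' Order-insensitive over (id, sequence) pairs, so a reformatted but
#' identical FASTA maps to the same digest.
#'
#' @param queries A named character vector of sequences or a
#'   `Biostrings::XStringSet`.
#' @return Character digest.
#' @export
query_set_digest <- function(queries) {
  if (inherits(queries, "XStringSet"))
    queries <- stats::setNames(as.character(queries), names(queries))
  parts <- sort(paste0(names(queries) %||% seq_along(queries), "=", queries))
  hash_hex(fnv1a(paste(parts, collapse = "\n")))
}

#' Digest of search parameters
#'
#' Runs with different parameters are different records; this digest keys
#' them. Order of list entries does not matter.
#'
#' @param params Named list of search parameters.
#' @return Character digest.
#' @export
params_digest <- function(params) {
  if (!length(params)) return("00000000")
  kv <- sort(paste0(names(params), "=",
                    vapply(params, function(v) paste(format(v), collapse = ","),
                           character(1))))
  hash_hex(fnv1a(paste(kv, collapse = ";")))
}

#' Difference between two database snapshots
#'
#' The delta is computed from the volume file lists (as the incremental logic
#' does), with sizes by subtraction: `delta_n + past$n == present$n` exactly.
#' A present snapshot that lost files or shrank is a hard error — the stored
#' result cannot be reused and a full re-search is required.
#'
#' @param past,present [db_profile()] snapshots of the same logical database.
#' @return An object of class `delta_spec` with `delta_files` (ordered as in
#'   `present`), `delta_n`, `delta_N` and the two profiles.
#' @export
compute_delta <- function(past, present) {
  stopifnot(inherits(past, "db_profile"), inherits(present, "db_profile"))
  missing <- setdiff(past$files, present$files)
  if (length(missing))
    abort_domain(paste0("database shrank: volumes removed (",
                        paste(missing, collapse = ", "),
                        "); a full re-search is required"),
                 "incblast_shrinkage_error")
  if (present$n < past$n || present$N < past$N)
    abort_domain("database shrank in size; a full re-search is required",
                 "incblast_shrinkage_error")
  delta_files <- present$files[!(present$files %in% past$files)]
  structure(list(past = past, present = present, delta_files = delta_files,
                 delta_n = present$n - past$n, delta_N = present$N - past$N),
            class = "delta_spec")
}

#' @export
print.delta_spec <- function(x, ...) {
  cat(sprintf("<delta_spec> +%d volume(s), delta_n=%s, delta_N=%s\n",
              length(x$delta_files), format(x$delta_n, big.mark = ","),
              format(x$delta_N, big.mark = ",")))
  invisible(x)
}

#' Write a BLAST database alias file for a delta database
#'
#' Emits a standard `.nal` (nucleotide) / `.pal` (protein) alias file whose
#' `DBLIST` line enumerates the delta volume basenames, defining a virtual
#' database over just the newly added volumes. Output is byte-stable for
#' identical input (no timestamps).
#'
#' @param delta A [compute_delta()] result, or a character vector of volume
#'   files together with `molecule`.
#' @param title `TITLE` line of the alias.
#' @param dir Directory to write into.
#' @param molecule Used when `delta` is a plain file vector.
#' @return Path of the alias file, or `NULL` with an `"up to date"` message
#'   attribute-free no-op when the delta is empty.
#' @export
write_alias <- function(delta, title, dir = ".", molecule = NULL) {
  if (inherits(delta, "delta_spec")) {
    files <- delta$delta_files
    molecule <- delta$present$molecule
  } else {
    files <- delta
    if (is.null(molecule))
      abort_domain("molecule required when delta is a file vector",
                   "incblast_domain_error")
  }
  if (!length(files)) {
    message("database is up to date; no alias written")
    return(invisible(NULL))
  }
  ext <- if (molecule == "nucleotide") ".nal" else ".pal"
  path <- file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "_", title), ext))
  base <- sub("\\.[np](al|hr|in|sq|db)$", "",
              sub("\\.fa(sta)?$", "", basename(files)))
  writeLines(c("#", "# Alias file for an incremental (delta) database", "#",
               paste0("TITLE ", title),
               paste0("DBLIST ", paste(base, collapse = " "))),
             path)
  invisible(path)
}

#' Incremental search
#'
#' The driver of the incremental workflow:
#'
#' 1. no stored record for (queries, database, program, parameters): run the
#'    executor against the full present database and store a record;
#' 2. record present, zero delta: return the stored result, executor not
#'    called;
#' 3. record present, database grew: run the executor against the delta
#'    volumes only, recalibrate both the stored and the delta results to the
#'    present database, merge, store the merged result and update the record
#'    to the present snapshot.
#'
#' The executor is any function `(queries, db, program, params) -> list of
#' search_result` — the bundled deterministic [mock_executor()] and the
#' NCBI-binary adapter [executor_ncbi()] both satisfy the contract.
#'
#' @param queries Named character vector of query sequences (or
#'   `XStringSet`).
#' @param present_db [db_profile()] of the database as it is now.
#' @param program BLAST program name.
#' @param params Search parameters (see [search_result()]).
#' @param executor Search executor, see above.
#' @param store A [record_store()].
#' @param results_dir Directory for stored result files.
#' @param params_table See [recalibrate()].
#' @return List of merged/current [search_result()] objects (one per query),
#'   with attribute `"path"` giving the stored result file and attribute
#'   `"mode"` one of `"full"`, `"cached"`, `"incremental"`.
#' @export
incremental_search <- function(queries, present_db, program, params = list(),
                               executor, store,
                               results_dir = dirname(store$path),
                               params_table = ka_parameter_table()) {
  qd <- query_set_digest(queries)
  pd <- params_digest(params)
  rec <- record_lookup(store, qd, present_db$db_id, program, pd)
  store_result <- function(results, mode) {
    path <- file.path(results_dir,
                      paste0(qd, "_", present_db$db_id, "_",
                             normalize_program(program), "_", pd, ".xml"))
    write_result(results, path, dialect = "xml")
    record_put(store, qd, present_db, program, pd, path)
    structure(results, path = path, mode = mode)
  }
  if (is.null(rec)) {
    res <- executor(queries, present_db, program, params)
    return(store_result(res, "full"))
  }
  delta <- tryCatch(compute_delta(rec$db_snapshot, present_db),
                    incblast_shrinkage_error = function(e) e)
  if (inherits(delta, "condition")) {
    warning("database shrank since the stored search; running a full search",
            call. = FALSE)
    res <- executor(queries, present_db, program, params)
    return(store_result(res, "full"))
  }
  if (!length(delta$delta_files) && delta$delta_n == 0) {
    res <- parse_result(rec$result_path, "xml")
    return(structure(res, path = rec$result_path, mode = "cached"))
  }
  delta_db <- db_profile(db_id = paste0(present_db$db_id, ".delta"),
                         n = delta$delta_n, N = delta$delta_N,
                         files = delta$delta_files,
                         molecule = present_db$molecule,
                         timestamp = present_db$timestamp)
  past_res <- parse_result(rec$result_path, "xml")
  delta_res <- executor(queries, delta_db, program, params)
  if (length(past_res) != length(delta_res))
    abort_domain("executor returned a different number of queries than stored",
                 "incblast_integrity_error")
  merged <- mapply(function(p, d) {
    merge_results(list(p, d), union_db = present_db,
                  max_target_seqs = params$max_target_seqs %||% NULL,
                  params_table = params_table)
  }, past_res, delta_res, SIMPLIFY = FALSE)
  store_result(merged, "incremental")
}
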