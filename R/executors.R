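#' Executor adapter for the NCBI BLAST+ binaries
#'
#' Wraps locally installed `blastn`/`blastp`/... binaries behind the
#' [incremental_search()] executor contract. The database profile's volume
#' files are resolved against `db_dir` (formatted BLAST database basenames);
#' multi-volume databases are searched through a generated alias file.
#' Optional; the deterministic [mock_executor()] covers all offline testing.
#'
#' @param db_dir Directory containing the formatted database volumes.
#' @param extra_args Character vector of additional command-line arguments
#'   (e.g. `c("-task", "blastn")`).
#' @return `function(queries, db, program, params) -> list of search_result`.
#' @export
executor_ncbi <- function(db_dir, extra_args = character()) {
  force(db_dir); force(extra_args)
  function(queries, db, program, params) {
    program <- normalize_program(program)
    if (Sys.which(program) == "")
      abort_domain(paste0("BLAST binary not found on PATH: ", program),
                   "incblast_capability_error")
    td <- tempfile("ncbi_exec"); dir.create(td)
    on.exit(unlink(td, recursive = TRUE))
    qfa <- file.path(td, "q.fasta")
    if (inherits(queries, "XStringSet")) {
      Biostrings::writeXStringSet(queries, qfa)
    } else {
      writeLines(paste0(">", names(queries), "\n", unname(queries)), qfa)
    }
    vols <- file.path(db_dir, sub("\\.[np](hr|in|sq)$", "", db$files))
    dbspec <- if (length(vols) == 1L) vols else {
      alias <- file.path(td, paste0("delta",
                                    if (db$molecule == "nucleotide") ".nal"
                                    else ".pal"))
      writeLines(c(paste0("TITLE ", db$db_id),
                   paste0("DBLIST ", paste(vols, collapse = " "))), alias)
      sub("\\.[np]al$", "", alias)
    }
    out <- file.path(td, "r.xml")
    args <- c("-query", qfa, "-db", dbspec, "-outfmt", "5", "-out", out,
              "-evalue", as.character(params$expect %||% 10),
              "-max_target_seqs",
              as.character(params$max_target_seqs %||% 500),
              extra_args)
    status <- system2(program, args, stdout = TRUE, stderr = TRUE)
    if (!file.exists(out))
      abort_domain(paste0(program, " failed: ",
                          paste(status, collapse = "\n")),
                   "incblast_executor_error")
    res <- parse_result(out, "xml")
    # carry the true profile (the XML only knows the alias name)
    lapply(res, function(r) { r$db <- db; r })
  }
}
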