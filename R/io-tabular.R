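# BLAST tabular (outfmt 6/7) reader/writer.
#
# Column map (declared in the outfmt-7 header): the conventional 12 columns
# extended with the raw score and query/subject lengths. The 6th column
# carries total gaps (the XML Hsp_gaps quantity) rather than gap openings,
# because alignment strings are optional in this data model; the header
# names it explicitly so the layout is self-describing.
TAB_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gaps",
                 "qstart", "qend", "sstart", "send", "evalue", "bitscore",
                 "score", "qlen", "slen")
TAB_FIELDS_HEADER <- paste("# Fields: query id, subject id, % identity,",
                           "alignment length, mismatches, gaps, q. start,",
                           "q. end, s. start, s. end, evalue, bit score,",
                           "score, query length, subject length")

write_blast_tabular <- function(results, path, comments = TRUE) {
  if (inherits(results, "search_result")) results <- list(results)
  lines <- character()
  for (r in results) {
    if (comments) {
      lines <- c(lines,
                 paste0("# ", toupper(r$program), " 2.17.0+"),
                 paste0("# Query: ", r$query$query_id, " len=", r$query$m),
                 paste0("# Database: ", r$db$db_id),
                 TAB_FIELDS_HEADER)
    }
    rows <- character()
    for (h in r$hits) for (s in h$hsps) {
      mism <- s$align_len - s$identity - s$gaps
      rows <- c(rows, paste(
        r$query$query_id, h$subject_id,
        sprintf("%.3f", 100 * s$identity / s$align_len),
        s$align_len, mism, s$gaps, s$q_start, s$q_end, s$s_start, s$s_end,
        format_evalue(s$evalue), as.character(s$bit_score),
        if (is.na(s$raw_score)) "NA" else as.character(s$raw_score),
        r$query$m, h$subject_len,
        sep = "\t"))
    }
    if (comments)
      lines <- c(lines, paste0("# ", length(rows), " hits found"))
    lines <- c(lines, rows)
  }
  writeLines(lines, path)
  invisible(path)
}

parse_blast_tabular <- function(path) {
  lines <- read_lines_maybe_gz(path)
  comments <- lines[startsWith(lines, "#")]
  rows <- lines[!startsWith(lines, "#") & nzchar(lines)]
  program <- "blastn"
  pm <- grep("^# (BLASTN|BLASTP|BLASTX|TBLASTN|TBLASTX|MEGABLAST)",
             comments, value = TRUE)
  if (length(pm)) program <- tolower(sub("^# ([A-Z]+).*", "\\1", pm[[1]]))
  dbm <- grep("^# Database: ", comments, value = TRUE)
  db_name <- if (length(dbm)) sub("^# Database: ", "", dbm[[1]]) else "unknown"
  if (!length(rows)) return(list())
  fields <- strsplit(rows, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1L]])
  if (!all(lengths(fields) == ncol1))
    abort_domain(paste0("ragged tabular input in '", path, "'"),
                 "incblast_parse_error")
  if (ncol1 != length(TAB_COLUMNS) && ncol1 != 12L)
    abort_domain(paste0("unexpected column count (", ncol1, ") in '", path,
                        "'; expected 12 (standard) or ",
                        length(TAB_COLUMNS), " (extended)"),
                 "incblast_parse_error")
  has_ext <- ncol1 == length(TAB_COLUMNS)
  molecule <- if (normalize_program(program) == "blastn") "nucleotide" else "protein"
  qids <- vapply(fields, `[[`, character(1), 1L)
  out <- list()
  for (qid in unique(qids)) {
    qrows <- fields[qids == qid]
    qlen <- if (has_ext) as.numeric(qrows[[1L]][[14L]]) else NA_real_
    bysub <- split(qrows, vapply(qrows, `[[`, character(1), 2L))
    hits <- lapply(bysub, function(sr) {
      hsps <- lapply(sr, function(f) {
        len <- as.numeric(f[[4]])
        pid <- as.numeric(f[[3]])
        identity <- round(pid * len / 100)
        gaps <- as.numeric(f[[6]])
        new_hsp(raw_score = if (has_ext) suppressWarnings(as.numeric(f[[13]]))
                            else NA_real_,
                bit_score = as.numeric(f[[12]]),
                evalue = parse_evalue(f[[11]]),
                q_start = as.numeric(f[[7]]), q_end = as.numeric(f[[8]]),
                s_start = as.numeric(f[[9]]), s_end = as.numeric(f[[10]]),
                identity = identity, align_len = len, gaps = gaps)
      })
      new_hit(subject_id = sr[[1L]][[2L]], subject_def = sr[[1L]][[2L]],
              subject_len = if (has_ext) as.numeric(sr[[1L]][[15L]]) else NA_real_,
              hsps = hsps)
    })
    # preserve input order of first appearance, never re-sort at parse time
    first_seen <- vapply(bysub, function(sr)
      which(vapply(qrows, identical, logical(1), sr[[1L]]))[1L], numeric(1))
    hits <- hits[order(first_seen)]
    qlen_eff <- if (is.na(qlen)) {
      # standard 12-column input carries no query length; fall back to the
      # largest query coordinate so the profile stays valid
      max(vapply(hits, function(h)
        max(vapply(h$hsps, function(s) max(s$q_start, s$q_end), numeric(1))),
        numeric(1)))
    } else qlen
    out[[length(out) + 1L]] <- search_result(
      program = program,
      query = query_profile(qid, qlen_eff),
      db = db_profile(db_name, 0, 0, molecule = molecule),
      hits = unname(hits), stats = NULL,
      params = list(raw_scores_available = has_ext))
  }
  out
}

#' Read BLAST search results
#'
#' Parses a result file into one `search_result` per query. The XML dialect
#' captures scores, e-values (zero values flagged as zero-rounded),
#' coordinates, alignment strings and the statistics block losslessly. The
#' tabular dialect (outfmt 6/7) accepts the standard 12 columns or this
#' package's extended 15-column layout; without the extension no raw scores
#' are available, which later blocks Karlin-Altschul recalibration with a
#' capability error. Gzip-compressed files are read transparently.
#'
#' @param path Path to a result file (optionally `.gz`).
#' @param dialect `"xml"` or `"tabular"`.
#' @return List of [search_result()] objects, one per query.
#' @export
parse_result <- function(path, dialect = c("xml", "tabular")) {
  dialect <- match.arg(dialect)
  switch(dialect, xml = parse_blast_xml(path),
         tabular = parse_blast_tabular(path))
}

#' Write BLAST search results
#'
#' Serializes one result (or a list, one query per iteration/block) in the
#' requested dialect. Round-tripping through [parse_result()] reproduces
#' every field the dialect can carry; e-values are rendered so that values
#' below the double underflow range never collapse to `0`.
#'
#' @param results A [search_result()] or list of them.
#' @param path Output path.
#' @param dialect `"xml"` or `"tabular"`.
#' @param comments For tabular output, write outfmt-7 style header comments
#'   (includes the declared column map).
#' @param ncbi_compatible If `TRUE`, truncate each result to
#'   `max_target_seqs` hits on output (the in-memory/merged form retains
#'   2 x max_target_seqs).
#' @return Invisibly, `path`.
#' @export
write_result <- function(results, path, dialect = c("xml", "tabular"),
                         comments = TRUE, ncbi_compatible = FALSE) {
  dialect <- match.arg(dialect)
  if (inherits(results, "search_result")) results <- list(results)
  if (ncbi_compatible)
    results <- lapply(results, function(r)
      truncate_hits(r, r$params$max_target_seqs %||% 500))
  switch(dialect,
         xml = write_blast_xml(results, path),
         tabular = write_blast_tabular(results, path, comments = comments))
}
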