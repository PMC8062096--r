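# NCBI BLAST XML (outfmt 5, NCBI_BlastOutput DTD) reader/writer.
# One Iteration element per query; statistics and e-values are captured
# losslessly (zero e-values are flagged, not silently kept as 0).

read_lines_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    readLines(con, warn = FALSE)
  } else readLines(path, warn = FALSE)
}

xml_num <- function(node, xpath) {
  t <- xml2::xml_text(xml2::xml_find_first(node, xpath))
  if (is.na(t) || t == "") NA_real_ else as.numeric(t)
}
xml_chr <- function(node, xpath) {
  t <- xml2::xml_text(xml2::xml_find_first(node, xpath))
  if (length(t) == 0L) NA_character_ else t
}

parse_blast_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(paste(read_lines_maybe_gz(path), collapse = "\n")),
                  error = function(e)
                    abort_domain(paste0("malformed XML in '", path, "': ",
                                        conditionMessage(e)),
                                 "incblast_parse_error"))
  program <- xml_chr(doc, ".//BlastOutput_program")
  db_name <- xml_chr(doc, ".//BlastOutput_db")
  pnode <- xml2::xml_find_first(doc, ".//Parameters")
  params <- list(
    matrix = xml_chr(pnode, "Parameters_matrix"),
    reward = xml_num(pnode, "Parameters_sc-match"),
    penalty = xml_num(pnode, "Parameters_sc-mismatch"),
    gap_open = xml_num(pnode, "Parameters_gap-open"),
    gap_extend = xml_num(pnode, "Parameters_gap-extend"),
    expect = xml_num(pnode, "Parameters_expect")
  )
  molecule <- if (stats_family(program) == "karlin-altschul" &&
                  normalize_program(program) == "blastn")
    "nucleotide" else "protein"
  lapply(xml2::xml_find_all(doc, ".//Iteration"), function(it) {
    stnode <- xml2::xml_find_first(it, ".//Statistics")
    stats <- if (!inherits(stnode, "xml_missing"))
      statistics_block(db_num = xml_num(stnode, "Statistics_db-num"),
                       db_len = xml_num(stnode, "Statistics_db-len"),
                       hsp_len = xml_num(stnode, "Statistics_hsp-len"),
                       eff_space = xml_num(stnode, "Statistics_eff-space"),
                       kappa = xml_num(stnode, "Statistics_kappa"),
                       lambda = xml_num(stnode, "Statistics_lambda"),
                       entropy = xml_num(stnode, "Statistics_entropy"))
    hits <- lapply(xml2::xml_find_all(it, ".//Hit"), function(hn) {
      hsps <- lapply(xml2::xml_find_all(hn, ".//Hsp"), function(sn) {
        new_hsp(raw_score = xml_num(sn, "Hsp_score"),
                bit_score = xml_num(sn, "Hsp_bit-score"),
                evalue = parse_evalue(xml_chr(sn, "Hsp_evalue")),
                q_start = xml_num(sn, "Hsp_query-from"),
                q_end = xml_num(sn, "Hsp_query-to"),
                s_start = xml_num(sn, "Hsp_hit-from"),
                s_end = xml_num(sn, "Hsp_hit-to"),
                identity = xml_num(sn, "Hsp_identity"),
                align_len = xml_num(sn, "Hsp_align-len"),
                gaps = { g <- xml_num(sn, "Hsp_gaps"); if (is.na(g)) 0 else g },
                positive = xml_num(sn, "Hsp_positive"),
                q_frame = xml_num(sn, "Hsp_query-frame"),
                h_frame = xml_num(sn, "Hsp_hit-frame"),
                qseq = xml_chr(sn, "Hsp_qseq"),
                hseq = xml_chr(sn, "Hsp_hseq"),
                midline = xml_chr(sn, "Hsp_midline"))
      })
      new_hit(subject_id = xml_chr(hn, "Hit_id"),
              subject_def = xml_chr(hn, "Hit_def"),
              subject_len = xml_num(hn, "Hit_len"),
              hsps = hsps)
    })
    db <- db_profile(db_id = db_name,
                     n = if (is.null(stats)) 0 else stats$db_len,
                     N = if (is.null(stats)) 0 else stats$db_num,
                     molecule = molecule)
    search_result(program = program,
                  query = query_profile(xml_chr(it, "Iteration_query-def"),
                                        xml_num(it, "Iteration_query-len")),
                  db = db, hits = hits, stats = stats, params = params)
  })
}

num_chr <- function(x) if (is.na(x)) NA_character_ else as.character(x)

write_blast_xml <- function(results, path) {
  if (inherits(results, "search_result")) results <- list(results)
  stopifnot(length(results) > 0L)
  r1 <- results[[1L]]
  doc <- xml2::xml_new_root("BlastOutput")
  add <- function(parent, name, text = NULL) {
    node <- xml2::xml_add_child(parent, name)
    if (!is.null(text) && !is.na(text)) xml2::xml_set_text(node, as.character(text))
    node
  }
  add(doc, "BlastOutput_program", r1$program)
  add(doc, "BlastOutput_version", paste0(toupper(r1$program), " 2.17.0+"))
  add(doc, "BlastOutput_db", r1$db$db_id)
  add(doc, "BlastOutput_query-ID", "Query_1")
  add(doc, "BlastOutput_query-def", r1$query$query_id)
  add(doc, "BlastOutput_query-len", r1$query$m)
  pwrap <- add(doc, "BlastOutput_param")
  pn <- add(pwrap, "Parameters")
  if (!is.null(r1$params$matrix) && !is.na(r1$params$matrix %||% NA))
    add(pn, "Parameters_matrix", r1$params$matrix)
  add(pn, "Parameters_expect", num_chr(r1$params$expect %||% 10))
  if (!is.null(r1$params$reward)) add(pn, "Parameters_sc-match", num_chr(r1$params$reward))
  if (!is.null(r1$params$penalty)) add(pn, "Parameters_sc-mismatch", num_chr(r1$params$penalty))
  add(pn, "Parameters_gap-open", num_chr(r1$params$gap_open %||% NA))
  add(pn, "Parameters_gap-extend", num_chr(r1$params$gap_extend %||% NA))
  itw <- add(doc, "BlastOutput_iterations")
  for (i in seq_along(results)) {
    r <- results[[i]]
    it <- add(itw, "Iteration")
    add(it, "Iteration_iter-num", i)
    add(it, "Iteration_query-ID", paste0("Query_", i))
    add(it, "Iteration_query-def", r$query$query_id)
    add(it, "Iteration_query-len", r$query$m)
    hw <- add(it, "Iteration_hits")
    for (j in seq_along(r$hits)) {
      h <- r$hits[[j]]
      hn <- add(hw, "Hit")
      add(hn, "Hit_num", j)
      add(hn, "Hit_id", h$subject_id)
      add(hn, "Hit_def", h$subject_def)
      add(hn, "Hit_accession", sub("^[^|]*\\|", "", h$subject_id))
      add(hn, "Hit_len", h$subject_len)
      sw <- add(hn, "Hit_hsps")
      for (k in seq_along(h$hsps)) {
        s <- h$hsps[[k]]
        sn <- add(sw, "Hsp")
        add(sn, "Hsp_num", k)
        add(sn, "Hsp_bit-score", as.character(s$bit_score))
        add(sn, "Hsp_score", as.character(s$raw_score))
        add(sn, "Hsp_evalue", format_evalue(s$evalue))
        add(sn, "Hsp_query-from", s$q_start)
        add(sn, "Hsp_query-to", s$q_end)
        add(sn, "Hsp_hit-from", s$s_start)
        add(sn, "Hsp_hit-to", s$s_end)
        if (!is.na(s$q_frame)) add(sn, "Hsp_query-frame", s$q_frame)
        if (!is.na(s$h_frame)) add(sn, "Hsp_hit-frame", s$h_frame)
        add(sn, "Hsp_identity", s$identity)
        if (!is.na(s$positive)) add(sn, "Hsp_positive", s$positive)
        add(sn, "Hsp_gaps", s$gaps)
        add(sn, "Hsp_align-len", s$align_len)
        if (!is.na(s$qseq)) add(sn, "Hsp_qseq", s$qseq)
        if (!is.na(s$hseq)) add(sn, "Hsp_hseq", s$hseq)
        if (!is.na(s$midline)) add(sn, "Hsp_midline", s$midline)
      }
    }
    if (!is.null(r$stats)) {
      stw <- add(it, "Iteration_stat")
      sn <- add(stw, "Statistics")
      add(sn, "Statistics_db-num", as.character(r$stats$db_num))
      add(sn, "Statistics_db-len", as.character(r$stats$db_len))
      add(sn, "Statistics_hsp-len", num_chr(r$stats$hsp_len))
      add(sn, "Statistics_eff-space", num_chr(r$stats$eff_space))
      add(sn, "Statistics_kappa", num_chr(r$stats$kappa))
      add(sn, "Statistics_lambda", num_chr(r$stats$lambda))
      add(sn, "Statistics_entropy", num_chr(r$stats$entropy))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
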