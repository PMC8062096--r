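#' Bundled scoring-system parameter table
#'
#' Statistical parameters (lambda, K, H, alpha, beta) keyed by program and
#' scoring scheme: match/mismatch rewards and gap costs for nucleotide
#' searches, substitution matrix and gap costs for protein-level searches.
#' Values reproduce those used by NCBI BLAST+ (the alpha/beta entries were
#' validated against the length adjustments BLAST+ 2.17 reports across
#' database sizes and query lengths). Result files carry their own lambda, K
#' and H in the statistics block; the table primarily supplies alpha and
#' beta, which no output format serializes.
#'
#' @param path Optional override: a user table in the same tab-separated
#'   layout (columns `program, matrix, reward, penalty, gap_open, gap_extend,
#'   lambda, K, H, alpha, beta`; `matrix` is `.` for nucleotide rows).
#' @return A data.frame.
#' @export
ka_parameter_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "karlin_params.tsv",
                                package = "incblast", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Look up Karlin-Altschul parameters for a scoring scheme
#'
#' Falls back to the ungapped convention `alpha = lambda / H`, `beta = 0`
#' (with a warning) when the exact scheme is not tabulated but lambda, K and
#' H are known from the result's statistics block — the same convention NCBI
#' BLAST applies to non-tabulated nucleotide gap costs.
#'
#' @param program BLAST program name.
#' @param matrix Substitution matrix name (protein programs).
#' @param reward,penalty Match/mismatch scores (nucleotide programs).
#' @param gap_open,gap_extend Gap costs.
#' @param stats_lambda,stats_K,stats_H Values from a result's statistics
#'   block, used for the ungapped fallback and preferred over the table for
#'   lambda/K/H when supplied.
#' @param table Parameter table, see [ka_parameter_table()].
#' @return A [karlin_params()].
#' @export
lookup_karlin_params <- function(program, matrix = NULL,
                                 reward = NA, penalty = NA,
                                 gap_open = NA, gap_extend = NA,
                                 stats_lambda = NA, stats_K = NA, stats_H = NA,
                                 table = ka_parameter_table()) {
  program <- normalize_program(program)
  hit <- table[table$program == program &
                 (if (is.null(matrix) || is.na(matrix) || matrix == ".")
                    table$matrix == "." else table$matrix == matrix) &
                 (is.na(reward) | table$reward == reward) &
                 (is.na(penalty) | table$penalty == penalty) &
                 (is.na(gap_open) | table$gap_open == gap_open) &
                 (is.na(gap_extend) | table$gap_extend == gap_extend), ,
               drop = FALSE]
  if (nrow(hit) >= 1L) {
    r <- hit[1L, ]
    return(karlin_params(lambda = stats_lambda %|na|% r$lambda,
                         K = stats_K %|na|% r$K,
                         H = stats_H %|na|% r$H,
                         alpha = r$alpha, beta = r$beta))
  }
  lam <- stats_lambda; K <- stats_K; H <- stats_H
  if (is.na(lam) || is.na(K) || is.na(H))
    abort_domain(paste0("scoring scheme not tabulated and no statistics ",
                        "block to fall back on (program=", program, ")"),
                 "incblast_lookup_error")
  warning("scoring scheme not tabulated; using ungapped convention ",
          "alpha = lambda/H, beta = 0", call. = FALSE)
  karlin_params(lambda = lam, K = K, H = H, alpha = lam / H, beta = 0)
}

`%|na|%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
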