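#' Karlin-Altschul parameters of a scoring system
#'
#' `lambda` (nats per score unit) and `K` set the extreme-value distribution
#' of local alignment scores; `H` is the relative entropy of the scoring
#' system (nats per aligned pair); `alpha` and `beta` parameterize the
#' length-adjustment fixed point l = (alpha/lambda) ln(K (m-l)(n-N l)) + beta.
#'
#' @param lambda Positive decay rate.
#' @param K Positive scale constant.
#' @param H Relative entropy, positive if given.
#' @param alpha Length-adjustment slope numerator, >= 0.
#' @param beta Length-adjustment intercept (residues).
#' @return An object of class `karlin_params`.
#' @examples
#' karlin_params(lambda = 1.28, K = 0.46, H = 0.85, alpha = 1.5, beta = -2)
#' @export
karlin_params <- function(lambda, K, H = NA_real_, alpha = NA_real_,
                          beta = NA_real_) {
  stopifnot(is.numeric(lambda), is.numeric(K))
  if (!(lambda > 0)) abort_domain("lambda must be > 0", "incblast_domain_error")
  if (!(K > 0)) abort_domain("K must be > 0", "incblast_domain_error")
  if (!is.na(H) && !(H > 0)) abort_domain("H must be > 0 when given",
                                          "incblast_domain_error")
  if (!is.na(alpha) && alpha < 0) abort_domain("alpha must be >= 0",
                                               "incblast_domain_error")
  structure(list(lambda = lambda, K = K, H = H, alpha = alpha, beta = beta),
            class = "karlin_params")
}

#' @export
print.karlin_params <- function(x, ...) {
  cat(sprintf("<karlin_params> lambda=%g K=%g H=%g alpha=%g beta=%g\n",
              x$lambda, x$K, x$H, x$alpha, x$beta))
  invisible(x)
}

#' Statistics family used by a BLAST program
#'
#' Nucleotide-level programs (blastn, tblastx) compute e-values with plain
#' Karlin-Altschul statistics; protein-level programs (blastp, blastx,
#' tblastn) use Spouge's finite-size correction, whose e-values rescale by
#' the ratio of actual database lengths under growth.
#'
#' @param program One of blastn, blastp, blastx, tblastn, tblastx (megablast
#'   is treated as blastn).
#' @return `"karlin-altschul"` or `"spouge"`.
#' @export
stats_family <- function(program) {
  program <- normalize_program(program)
  switch(program,
         blastn = , tblastx = "karlin-altschul",
         blastp = , blastx = , tblastn = "spouge",
         abort_domain(paste0("unknown program: ", program),
                      "incblast_domain_error"))
}

normalize_program <- function(program) {
  p <- tolower(program)
  if (p == "megablast") p <- "blastn"
  p
}

ka_f <- function(l, params, m, n, N) {
  (params$alpha / params$lambda) * log(params$K * (m - l) * (n - N * l)) +
    params$beta
}

ka_lmax <- function(m, n, N) max(0, min(m - 1, floor((n - 1) / N)))

#' Karlin-Altschul length adjustment
#'
#' Solves the saturating fixed point
#' l = (alpha/lambda) ln(K (m - l)(n - N l)) + beta for the integer length
#' adjustment, clamped so the effective lengths m - l and n - N l stay >= 1.
#' The returned integer is the largest l with l <= f(l), matching the integer
#' semantics of NCBI's length-adjustment routine (verified against blastn's
#' reported `Statistics_hsp-len` across database sizes and scoring schemes).
#' The solver iterates the map (at most 20 rounds or until successive
#' iterates differ by less than 1) and then polishes to the exact integer.
#'
#' @param params `karlin_params` with `alpha`/`beta` present.
#' @param m Query length (residues, > 0).
#' @param n Database length (total residues, > 0).
#' @param N Number of database sequences (> 0).
#' @return Integer length adjustment.
#' @examples
#' p <- karlin_params(0.625, 0.41, 0.78, alpha = 0.8, beta = -2)
#' length_adjustment(p, m = 1000, n = 1e6, N = 100)
#' @export
length_adjustment <- function(params, m, n, N) {
  stopifnot(inherits(params, "karlin_params"))
  if (is.na(params$alpha) || is.na(params$beta))
    abort_domain("alpha/beta are required for length adjustment",
                 "incblast_domain_error")
  if (!(m > 0)) abort_domain("query length m must be > 0 (violated: m <= 0)",
                             "incblast_domain_error")
  if (!(n > 0)) abort_domain("database length n must be > 0 (violated: n <= 0)",
                             "incblast_domain_error")
  if (!(N > 0)) abort_domain("sequence count N must be > 0 (violated: N <= 0)",
                             "incblast_domain_error")
  lmax <- ka_lmax(m, n, N)
  if (lmax == 0) return(0L)
  if (params$alpha == 0) {
    # constant map: fixed point is beta itself, saturated into range
    return(as.integer(max(0, min(lmax, floor(params$beta)))))
  }
  x <- 0
  for (i in seq_len(20L)) {
    xn <- ka_f(min(x, lmax), params, m, n, N)
    xn <- max(0, min(xn, lmax))
    if (abs(xn - x) < 1) { x <- xn; break }
    x <- xn
  }
  l <- max(0L, min(as.integer(floor(x)), as.integer(lmax)))
  # integer polish: f is decreasing in l, so the stable point is the largest
  # integer with l <= f(l)
  while (l > 0L && l > ka_f(l, params, m, n, N)) l <- l - 1L
  while (l < lmax && (l + 1L) <= ka_f(l + 1L, params, m, n, N)) l <- l + 1L
  l
}

#' Effective search space after length adjustment
#'
#' @param m,n,N Actual query length, database length, database sequence count.
#' @param l Integer length adjustment (see [length_adjustment()]).
#' @return An object of class `search_space` with fields `l`, `m_eff`
#'   (m - l), `n_eff` (n - N l) and `D` (= m_eff * n_eff).
#' @export
search_space <- function(m, n, N, l) {
  m_eff <- m - l
  n_eff <- n - N * l
  if (!(m_eff > 0) || !(n_eff > 0))
    abort_domain("effective lengths must be positive (violated: m-l or n-N*l <= 0)",
                 "incblast_domain_error")
  structure(list(l = as.integer(l), m_eff = m_eff, n_eff = n_eff,
                 D = m_eff * n_eff),
            class = "search_space")
}

#' Compute the length adjustment and effective search space in one step
#'
#' @inheritParams length_adjustment
#' @return A `search_space`.
#' @export
effective_search_space <- function(params, m, n, N) {
  search_space(m, n, N, length_adjustment(params, m, n, N))
}

#' E-value of a raw score (Karlin-Altschul)
#'
#' E = K m' n' exp(-lambda S), evaluated in log space as
#' ln E = ln K + ln m' + ln n' - lambda S, so extreme scores never underflow.
#'
#' @param params `karlin_params`.
#' @param space A `search_space` (or list with `m_eff`, `n_eff`).
#' @param score Raw alignment score.
#' @return A [blast_evalue()].
#' @export
evalue_from_score <- function(params, space, score) {
  stopifnot(inherits(params, "karlin_params"))
  blast_evalue(log(params$K) + log(space$m_eff) + log(space$n_eff) -
                 params$lambda * score)
}

#' Bit score of a raw score
#'
#' S' = (lambda S - ln K) / ln 2. Bit scores are database-independent and are
#' unchanged by recalibration.
#'
#' @inheritParams evalue_from_score
#' @return Numeric bit score.
#' @export
bit_score_from_raw <- function(params, score) {
  (params$lambda * score - log(params$K)) / log(2)
}

#' Additive Karlin-Altschul e-value correction
#'
#' Corrects a part-database e-value to the union database by adding the
#' contribution of the search-space increment:
#' E_total = E_part + K exp(-lambda S) (D_total - D_part). Equivalent (to
#' floating-point accuracy) to recomputing E from the score on the union
#' search space; the recompute path ([evalue_from_score()]) is the default in
#' [recalibrate()] as it needs fewer operations.
#'
#' @param params `karlin_params`.
#' @param e_part Part-database e-value (`blast_evalue` or log-e numeric).
#' @param score Raw score the e-value derives from.
#' @param D_part,D_total Effective search spaces, `D_total >= D_part > 0`.
#' @return A [blast_evalue()].
#' @export
correct_evalue_ka <- function(params, e_part, score, D_part, D_total) {
  e_part <- as_evalue(e_part)
  if (!(D_part > 0)) abort_domain("D_part must be > 0", "incblast_domain_error")
  if (D_total < D_part)
    abort_domain("D_total < D_part: database shrank; correction undefined",
                 "incblast_domain_error")
  if (e_part$zero_rounded)
    abort_domain("zero-rounded e-value: regenerate from the raw score first",
                 "incblast_zero_rounded_error")
  if (D_total == D_part) return(e_part)
  inc <- log(params$K) - params$lambda * score + log(D_total - D_part)
  blast_evalue(logsumexp2(e_part$log_e, inc))
}

#' Rescale a finite-size-correction (Spouge) e-value to a larger database
#'
#' For the protein-program statistics the finite-size-corrected "area" term
#' depends only on the query and the scoring system, so under a change of
#' actual database length the e-value scales by the ratio of lengths:
#' ln E_total = ln E_part + ln n_total - ln n_part, exact in log space.
#'
#' @param e_part Part-database e-value (`blast_evalue` or log-e numeric).
#'   Zero-rounded inputs are refused: their magnitude was lost upstream and
#'   must be regenerated from the raw score (see [recalibrate()]).
#' @param n_part,n_total Actual database lengths (residues), both > 0.
#' @return A [blast_evalue()].
#' @export
rescale_evalue_spouge <- function(e_part, n_part, n_total) {
  if (!(n_part > 0) || !(n_total > 0))
    abort_domain("database lengths must be > 0", "incblast_domain_error")
  e_part <- as_evalue(e_part)
  if (e_part$zero_rounded)
    abort_domain(paste0("zero-rounded e-value cannot be rescaled; ",
                        "recompute it from its raw score (Karlin-Altschul ",
                        "formula on the part search space) instead"),
                 "incblast_zero_rounded_error")
  blast_evalue(e_part$log_e + log(n_total) - log(n_part))
}

#' Database growth as a percentage
#'
#' Returns 100 (present - past) / past truncated to one decimal place,
#' matching the convention used when reporting database growth (e.g. a
#' database going from 44.5 to 62.7 units grew by 40.8 percent).
#'
#' @param past,present Database sizes in any common unit; `past > 0`,
#'   `present >= past`.
#' @return Percent growth, one decimal.
#' @export
growth_fraction <- function(past, present) {
  if (!(past > 0)) abort_domain("past size must be > 0", "incblast_domain_error")
  if (present < past)
    abort_domain("present < past: negative growth", "incblast_domain_error")
  floor(1000 * (present - past) / past + 1e-9) / 10
}

#' Projected incremental-search speedup
#'
#' Searching only the newly added fraction delta of a database (and reusing
#' the stored result for the rest) costs delta of a full search plus the
#' already-spent unit, so relative to rerunning the whole search of size
#' 1 + delta the projected speedup is (1 + delta) / delta.
#'
#' @param delta Fractional database growth, > 0.
#' @return Speedup factor.
#' @examples
#' projected_speedup(0.48)  # ~3.08
#' projected_speedup(0.10)  # 11
#' @export
projected_speedup <- function(delta) {
  if (!(delta > 0)) abort_domain("delta must be > 0", "incblast_domain_error")
  (1 + delta) / delta
}
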