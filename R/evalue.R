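#' E-values stored on the natural-log scale
#'
#' An expect value (e-value) is the expected number of chance alignments with
#' score at least S in a search of a given query against a given database. It
#' scales linearly with the search space, so under database growth it can
#' range over hundreds of orders of magnitude. `blast_evalue` therefore keeps
#' `log_e = ln(E)` as the canonical representation; the linear value is only
#' ever derived at serialization time, so values far below the double
#' underflow threshold remain exact in log space.
#'
#' A value parsed from a result file as exactly `0` carries the
#' `zero_rounded` flag: its true magnitude was lost by upstream rounding
#' (NCBI BLAST rounds e-values below roughly exp(-180) to 0.0) and it must be
#' regenerated from its raw score, never rescaled.
#'
#' @param log_e Natural log of the e-value; may be any real (or `-Inf` only
#'   for zero-rounded placeholders).
#' @param zero_rounded Was the source value rounded to 0 upstream?
#' @return An object of class `blast_evalue`.
#' @examples
#' blast_evalue(log(1e-50))
#' evalue_linear(blast_evalue(-500))  # underflows linearly, exact in logs
#' @export
blast_evalue <- function(log_e, zero_rounded = FALSE) {
  stopifnot(is.numeric(log_e), length(log_e) == 1L, length(zero_rounded) == 1L)
  if (!zero_rounded && !is.finite(log_e))
    abort_domain("log_e must be finite for a non-zero-rounded e-value",
                 "incblast_domain_error")
  structure(list(log_e = as.numeric(log_e), zero_rounded = isTRUE(zero_rounded)),
            class = "blast_evalue")
}

as_evalue <- function(x) {
  if (inherits(x, "blast_evalue")) x else blast_evalue(as.numeric(x))
}

#' @export
print.blast_evalue <- function(x, ...) {
  cat("<e-value> ", format_evalue(x),
      if (x$zero_rounded) " (zero-rounded upstream)" else "",
      "  [ln E = ", format(x$log_e), "]\n", sep = "")
  invisible(x)
}

#' Linear e-value (may underflow; prefer the log form)
#' @param x A `blast_evalue`.
#' @return Numeric scalar `exp(log_e)`.
#' @export
evalue_linear <- function(x) exp(as_evalue(x)$log_e)

#' Render an e-value for serialization
#'
#' Values in a moderate range use R's shortest round-trip decimal rendering;
#' outside it a `mantissa e exponent` form is built directly from the log so
#' that values below the double underflow range (linear < ~1e-308) still
#' serialize faithfully and are never written as `0`.
#'
#' @param x A `blast_evalue` or numeric log-e value.
#' @return Character scalar.
#' @export
format_evalue <- function(x) {
  x <- as_evalue(x)
  if (x$zero_rounded) return("0")
  l10 <- x$log_e / log(10)
  if (l10 > -300 && l10 < 300) return(as.character(exp(x$log_e)))
  e10 <- floor(l10)
  mant <- 10^(l10 - e10)
  # keep mantissa in [1, 10)
  if (mant >= 10) { mant <- mant / 10; e10 <- e10 + 1 }
  paste0(as.character(mant), "e", if (e10 >= 0) "+" else "", as.character(e10))
}

#' Parse a serialized e-value into log space
#'
#' `"0"` (and numeric zero renderings) yield a zero-rounded placeholder.
#' Mantissa/exponent strings are decomposed so exponents beyond the double
#' range do not collapse to 0.
#'
#' @param s Character scalar as found in a result file.
#' @return A `blast_evalue`.
#' @export
parse_evalue <- function(s) {
  s <- trimws(s)
  if (grepl("^0(\\.0*)?$", s))
    return(blast_evalue(-Inf, zero_rounded = TRUE))
  m <- regmatches(s, regexec("^([0-9.]+)[eE]([+-]?[0-9]+)$", s))[[1]]
  if (length(m) == 3L) {
    mant <- as.numeric(m[2])
    if (mant == 0) return(blast_evalue(-Inf, zero_rounded = TRUE))
    return(blast_evalue(log(mant) + as.numeric(m[3]) * log(10)))
  }
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) abort_domain(paste0("cannot parse e-value: '", s, "'"),
                             "incblast_parse_error")
  if (v == 0) return(blast_evalue(-Inf, zero_rounded = TRUE))
  blast_evalue(log(v))
}
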