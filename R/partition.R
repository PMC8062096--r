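#' Residue-balanced query partitioning
#'
#' Splits a query set into `k` partitions with roughly equal residue totals
#' (rather than equal query counts), so that per-partition search wall time
#' is balanced even under heavy-tailed length distributions. The order of
#' queries is randomized under `seed`, then each query goes to the partition
#' with the smallest running residue total; the final totals therefore lie
#' within one maximum query length of the mean. Deterministic given `seed`.
#'
#' @param queries Named character vector of sequences, `XStringSet`, or a
#'   named numeric vector of query lengths.
#' @param k Number of partitions, >= 1. Partitions may come out empty when
#'   `k` exceeds the number of queries.
#' @param seed Integer seed for the randomized ordering.
#' @return List of `k` character vectors of query names.
#' @export
partition_queries <- function(queries, k, seed = 1L) {
  if (!(k >= 1)) abort_domain("k must be >= 1", "incblast_domain_error")
  if (inherits(queries, "XStringSet")) {
    lens <- stats::setNames(Biostrings::width(queries), names(queries))
  } else if (is.character(queries)) {
    lens <- stats::setNames(nchar(queries), names(queries))
  } else {
    lens <- queries
  }
  if (is.null(names(lens))) names(lens) <- as.character(seq_along(lens))
  ord <- with_seed(seed, sample.int(length(lens)))
  parts <- vector("list", k)
  totals <- numeric(k)
  for (i in ord) {
    j <- which.min(totals)
    parts[[j]] <- c(parts[[j]], names(lens)[i])
    totals[j] <- totals[j] + lens[[i]]
  }
  lapply(parts, function(p) p %||% character())
}
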