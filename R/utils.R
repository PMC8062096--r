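#' @keywords internal
"_PACKAGE"

# 32-bit FNV-1a over a character scalar. Non-cryptographic; used for cache
# keys, content digests and the deterministic fixture score model.
fnv1a <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  prime <- 16777619
  for (b in utf8ToInt(enc2utf8(x))) {
    # xor only touches the low byte (b < 256); h is kept as a double < 2^32
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply, split to stay exact in double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 2^32
  }
  h
}

# Hex rendering of a 32-bit hash kept in a double.
hash_hex <- function(h) {
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Unit-interval number derived deterministically from strings.
hash_unit <- function(...) {
  fnv1a(paste(..., sep = "\x1f")) / 2^32
}

# Evaluate an expression under a fixed RNG seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# log(exp(a) + exp(b)) without overflow/underflow.
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log1p(exp(pmin(a, b) - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_domain <- function(msg, class) {
  stop(structure(class = c(class, "incblast_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
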