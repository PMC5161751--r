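## Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a 32-bit sub-seed from a master seed and a stage label, so each
## simulated experiment draws from an independent, reproducible stream.
## Protocol (documented for independent re-implementation): FNV-1a over the
## UTF-8 bytes of the label, xor-folded with the master seed, modulo 2^31 - 1.
sub_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(label)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((abs(seed) + h) %% 2147483647)
}

## FNV-1a hash of a deparsed object; used to stamp pipeline outputs with a
## configuration fingerprint without a digest dependency.
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

## Trapezoidal integral of y over t (both sorted by t).
trapz <- function(t, y) {
  o <- order(t)
  t <- t[o]; y <- y[o]
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

assert_matrix <- function(m, what = "matrix") {
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must be a matrix with row and column names", call. = FALSE)
  invisible(m)
}

#' @importFrom utils head tail
NULL
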