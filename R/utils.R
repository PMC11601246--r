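`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fold a character string to a reproducible 31-bit integer seed
#'
#' Hashes `text` with MD5 and keeps the low 31 bits, giving a deterministic,
#' platform-independent seed for per-term pseudo-random embeddings.
#'
#' @param text character scalar to hash.
#' @return integer in `[0, 2^31 - 1]`.
#' @keywords internal
hash_seed <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeLines(text, tf, sep = "")
  h <- unname(tools::md5sum(tf))
  # low 7 hex digits + 3 bits of the 8th -> 31 bits
  v <- strtoi(substr(h, 1, 7), base = 16L)
  b <- strtoi(substr(h, 8, 8), base = 16L) %% 8L
  v * 8L + b
}

# run code with a local RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Glorot-uniform weight matrix
glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

stop_if_not_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(what, " must be a positive finite scalar", call. = FALSE)
}
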