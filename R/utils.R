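#' @keywords internal
"_PACKAGE"

## Small shared helpers. Nothing here is exported.

# Vectorized polynomial hash over the raw bytes of a payload; cheap content
# hash used for provenance (mesh identity checks), not cryptographic.
content_hash <- function(...) {
  parts <- list(...)
  raws <- lapply(parts, function(p) {
    if (is.character(p)) charToRaw(paste(p, collapse = "\x1f"))
    else writeBin(as.vector(p, mode = if (is.integer(p)) "integer" else "double"),
                  raw(), endian = "little")
  })
  b <- as.double(as.integer(do.call(c, raws)))
  n <- length(b)
  if (n == 0) return("00000000-0")
  w1 <- rep_len(c(1, 3, 7, 31, 127, 8191, 131071, 524287), n)
  w2 <- (seq_len(n) %% 9973) + 1
  h <- (sum((b + 1) * w1) %% 2147483647) * 65536 + (sum(b * w2) %% 65521)
  sprintf("%012.0f-%d", h %% 2^40, n)
}

next_pow2 <- function(n) 2^ceiling(log2(max(2, n)))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

# deterministic RNG scope: run expr with a seed, restore global state after
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}
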