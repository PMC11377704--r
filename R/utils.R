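# Internal helpers shared across modules.

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' @noRd
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Deterministic 31-bit hash of a string, used to derive per-record seeds.
#' @noRd
hash_string <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# Mix a root seed with an integer tag into a 31-bit seed.
#' @noRd
mix_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(tag) + 1) %% 2147483647)
}

# Run `expr` under `seed` without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Full-precision number formatting so text round-trips are lossless.
#' @noRd
format_full <- function(x) sprintf("%.17g", x)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
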