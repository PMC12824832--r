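#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a master seed and a stream label.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(master, ...) {
  labs <- paste(c(master, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(labs)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1L)
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring
# the caller's RNG state afterwards.
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

stop_mjm <- function(kind, msg) {
  cond <- structure(
    class = c(paste0("mjmcrt_", kind), "mjmcrt_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
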