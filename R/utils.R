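# internal helpers: classed conditions and seeded evaluation

glyco_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "glycomig_error"), call = call))
}

# Evaluate `code` under a fixed RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and an index, staying inside 32-bit
# integer range.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 9973) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
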