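# internal helpers shared across modules

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# seed = NULL leaves the RNG alone (caller controls reproducibility).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 1 && x == floor(x)

is_num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
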