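# Internal utilities.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# sample() without the scalar-x surprise: always samples from the set `x`.
resample <- function(x, size, replace = FALSE) {
  if (length(x) == 1L) {
    if (replace) return(rep(x, size))
    if (size == 1L) return(x)
    stop("cannot sample ", size, " items from a single element without replacement")
  }
  sample(x, size, replace = replace)
}

round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a child seed from a base seed, staying inside 32-bit integer range.
derive_seed <- function(base, mult, offset) {
  as.integer((as.numeric(base) * mult + offset) %% 2147483647)
}
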