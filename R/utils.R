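# Internal helpers: seeded evaluation without clobbering the caller's RNG,
# deterministic sub-stream derivation, and small argument checks.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# Deterministic sub-seed in [1, 2^31 - 2] from a base seed and integer tags.
# Keeps derived seeds valid 32-bit R integers however many tags are mixed in.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  h <- as.double(seed) %% 2147483647
  for (t in tags) h <- (h * 48271 + as.double(t) + 1) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

is_odd_window <- function(w) {
  is.numeric(w) && length(w) == 1L && is.finite(w) && w >= 1 && w %% 2 == 1
}
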