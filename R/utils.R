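# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stage label, staying < 2^31.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 1009L + as.integer(h %% 100000L)) %% 2147483629L
}

# Upper-triangle vector of a symmetric matrix (row/col labels ignored).
upper_vec <- function(m) m[upper.tri(m)]

# Symmetrize a nearly-symmetric matrix (guards accumulated FP asymmetry).
symm <- function(m) (m + t(m)) / 2

vec_norm <- function(x) sqrt(sum(x^2))

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
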