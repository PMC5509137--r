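# Run code with a local RNG state seeded by `seed`; the caller's RNG stream
# is untouched.  seed = NULL uses (and advances) the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Derive k child seeds below 2^31 from one root seed.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max, k))
}

upper_pairs <- function(p) {
  which(upper.tri(diag(p)), arr.ind = TRUE)
}
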