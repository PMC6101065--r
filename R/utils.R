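# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(name, " must be a single non-missing number", call. = FALSE)
  if (integer && x != as.integer(x))
    stop(name, " must be an integer", call. = FALSE)
  if (x < min || x > max)
    stop(name, " must be in [", min, ", ", max, "]", call. = FALSE)
  invisible(x)
}

check_dna <- function(seq, name = "seq") {
  bad <- grepl("[^ACGT]", seq)
  if (any(bad))
    stop(name, " contains non-ACGT characters", call. = FALSE)
  invisible(seq)
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
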