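AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Split a sequence string into an uppercase character vector and reject
# anything outside the standard 20-letter alphabet, naming the position.
validate_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  aa <- strsplit(toupper(sequence), "")[[1L]]
  bad <- which(!aa %in% AA20)
  if (length(bad) > 0L)
    stop("non-standard residue '", aa[bad[1L]], "' at position ", bad[1L])
  aa
}

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
# All stochastic operations in the package take explicit integer seeds and
# route through this helper, so nothing perturbs the user's global stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed for a pipeline stage: a small string hash folded
# with the global seed, kept inside the 32-bit integer range. Prevents
# accidental seed coupling between stages run under one global seed.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 131) %% .Machine$integer.max)
}
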