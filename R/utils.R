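# Internal helpers shared across modules.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "C")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run an expression under a local RNG state so package functions are
# reproducible from an explicit seed without clobbering the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single string", call. = FALSE)
}

# split a protein/nucleotide string into a character vector
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
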