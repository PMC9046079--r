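# Internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG; the caller's .Random.seed is
# restored afterwards so simulations never perturb the session stream.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Plate rows are letters in exports (A = 1); 16 rows -> A..P. Double letters
# (AA, AB, ...) cover geometries beyond 26 rows.
rowIndexToLetter <- function(i) {
  i <- as.integer(i)
  single <- i <= 26L
  out <- character(length(i))
  out[single] <- LETTERS[i[single]]
  if (any(!single)) {
    j <- i[!single] - 1L
    out[!single] <- paste0(LETTERS[j %/% 26L], LETTERS[j %% 26L + 1L])
  }
  out
}

rowLetterToIndex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  n <- nchar(x)
  out <- rep(NA_integer_, length(x))
  out[n == 1L] <- match(x[n == 1L], LETTERS)
  two <- n == 2L
  if (any(two))
    out[two] <- 26L * match(substr(x[two], 1L, 1L), LETTERS) +
      match(substr(x[two], 2L, 2L), LETTERS)
  numeric_like <- is.na(out) & grepl("^[0-9]+$", x)
  out[numeric_like] <- as.integer(x[numeric_like])
  out
}

# Sample skewness (method-of-moments, bias-uncorrected).
sampleSkewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  mean((x - m)^3) / s2^1.5
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
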