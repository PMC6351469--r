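## Small shared helpers. None of these are exported.

clip01 <- function(x) pmin(1, pmax(0, x))

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Sample skewness (biased, moment definition m3 / m2^(3/2)).
#' Returns 0 for zero-variance input so downstream tables stay finite.
#' @noRd
moment_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^3) / m2^1.5
}

#' Sample kurtosis, non-excess convention (normal distribution -> 3).
#' Zero-variance input -> 0 by the same finiteness convention as skewness.
#' @noRd
moment_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^4) / m2^2
}

#' FNV-1a hash of a character scalar, as 8 hex digits. Used to stamp run
#' artifacts with a config fingerprint without pulling in a digest package.
#' @noRd
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  prime <- 16777619
  h <- 2166136261
  for (b in bytes) {
    # XOR on the low 16 bits (h can exceed .Machine$integer.max, so split)
    lo <- bitwXor(as.integer(h %% 65536), b)
    hi <- h %/% 65536
    # 32-bit modular multiply, split to stay within double precision
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  # h can exceed .Machine$integer.max; format as two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Derive a child seed below 2^31 from a base seed and an index.
#' @noRd
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 1103 + as.numeric(k) * 12007) %% 2147483647
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 1 && x == floor(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
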