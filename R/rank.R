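# Exact integer matrix rank for +-1 model matrices.
#
# The headline coverage percentages must not depend on a floating-point
# tolerance. Rank over the rationals is computed by Gaussian elimination
# modulo a set of ~2^25 primes:
#   * rank mod p <= rank over Q for every prime (a minor nonzero mod p is
#     nonzero over Z);
#   * if every prime under-reports, each divides some fixed nonzero maximal
#     minor M, so their product divides M; with |M| bounded by the Hadamard
#     bound m^(m/2) (entries in {-1,0,1}... here {-1,+1}), choosing enough
#     primes that the product exceeds the bound makes this impossible.
# Hence max over the prime set equals the exact rank — deterministically.
# All modular products stay below 2^51, exact in doubles.

modpow <- function(base, exp, p) {
  r <- 1
  base <- base %% p
  while (exp > 0) {
    if (exp %% 2 == 1) r <- (r * base) %% p
    base <- (base * base) %% p
    exp <- exp %/% 2
  }
  r
}

# descending primes just below 2^25 (cached after first use)
.prime_cache <- new.env(parent = emptyenv())
rank_primes <- function(k) {
  have <- .prime_cache$primes
  if (is.null(have)) have <- numeric(0)
  cand <- if (length(have)) min(have) - 2 else 2^25 - 1
  while (length(have) < k) {
    if (is_odd_prime(cand)) have <- c(have, cand)
    cand <- cand - 2
  }
  .prime_cache$primes <- have
  have[seq_len(k)]
}

rank_mod_p <- function(M, p) {
  A <- M %% p
  nr <- nrow(A)
  nc <- ncol(A)
  r <- 0L
  for (col in seq_len(nc)) {
    if (r >= nr) break
    rows <- (r + 1L):nr
    piv <- rows[A[rows, col] != 0][1L]
    if (is.na(piv)) next
    r <- r + 1L
    if (piv != r) A[c(r, piv), ] <- A[c(piv, r), ]
    if (r < nr) {
      below <- (r + 1L):nr
      inv <- modpow(A[r, col], p - 2, p)
      fac <- (A[below, col] * inv) %% p
      A[below, ] <- (A[below, , drop = FALSE] -
                       outer(fac, A[r, ]) %% p) %% p
    }
  }
  r
}

#' Exact rank of an integer matrix
#'
#' Deterministic exact rank over the rationals for matrices with entries in
#' \{-1, 0, +1\} (model matrices of two-level designs), via modular
#' elimination over a certified prime set; see the source for the
#' certificate argument. Authoritative for all coverage statistics;
#' [rank_float()] is the independent floating cross-check.
#'
#' @param M an integer (or exactly integer-valued numeric) matrix.
#' @return the integer rank.
#' @export
rank_exact <- function(M) {
  if (!is.matrix(M)) M <- as.matrix(M)
  if (any(abs(M) > 1)) {
    stop("rank_exact is certified for entries in {-1, 0, +1} only",
         call. = FALSE)
  }
  m <- min(dim(M))
  if (m == 0L) return(0L)
  # need product of primes > m^(m/2); each prime contributes ~24.9 bits
  bits <- (m / 2) * log2(max(m, 2))
  k <- max(2L, as.integer(ceiling(bits / 24)))
  primes <- rank_primes(k)
  max(vapply(primes, function(p) rank_mod_p(M, p), 0L))
}

#' Floating-point rank (cross-check)
#'
#' Singular-value rank with tolerance `1e-8 * max(singular value)`. Used
#' only to cross-check [rank_exact()]; never authoritative.
#'
#' @param M a numeric matrix.
#' @return the integer rank estimate.
#' @export
rank_float <- function(M) {
  if (!is.matrix(M)) M <- as.matrix(M)
  d <- svd(M, nu = 0L, nv = 0L)$d
  if (!length(d) || d[1L] == 0) return(0L)
  sum(d > 1e-8 * d[1L])
}
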