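# Hadamard-matrix constructions: Sylvester tensor doubling and the two
# Paley quadratic-residue constructions over prime fields. These are the
# substrates for the strength-2 non-regular orthogonal arrays.

is_odd_prime <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || q != floor(q)) return(FALSE)
  q <- as.numeric(q)
  if (q < 3 || q %% 2 == 0) return(FALSE)
  d <- 3
  while (d * d <= q) {
    if (q %% d == 0) return(FALSE)
    d <- d + 2
  }
  TRUE
}

#' Quadratic residues modulo an odd prime
#'
#' The `(q-1)/2` non-zero squares mod `q`, the ingredient of the Paley
#' (Jacobsthal) constructions.
#'
#' @param q an odd prime.
#' @return sorted integer vector of the non-zero quadratic residues mod `q`.
#' @examples
#' quadratic_residues(11)  # 1 3 4 5 9
#' @export
quadratic_residues <- function(q) {
  if (!is_odd_prime(q)) stop("q must be an odd prime, got ", q, call. = FALSE)
  q <- as.numeric(q)
  x <- seq_len((q - 1) / 2)  # squares repeat symmetrically; half suffice
  sort(unique(as.integer((x * x) %% q)))
}

# Jacobsthal matrix Q[i, j] = chi(j - i) over GF(q), chi the quadratic
# character (0 at 0, +1 residue, -1 non-residue).
jacobsthal <- function(q) {
  res <- quadratic_residues(q)
  chi <- integer(q)            # chi[x+1] for x in 0..q-1
  chi[res + 1L] <- 1L
  chi[setdiff(seq_len(q - 1L), res) + 1L] <- -1L
  d <- outer(0:(q - 1L), 0:(q - 1L), function(i, j) (j - i) %% q)
  matrix(chi[d + 1L], q, q)
}

new_hadamard <- function(H, construction) {
  H <- matrix(as.integer(H), nrow(H), ncol(H))
  N <- nrow(H)
  if (!all(tcrossprod(H) == N * diag(N))) {
    stop("internal error: constructed matrix is not Hadamard", call. = FALSE)
  }
  structure(list(order = N, matrix = H, construction = construction),
            class = "hadamard")
}

#' @export
print.hadamard <- function(x, ...) {
  cat(sprintf("Hadamard matrix, order %d (%s construction), H %%*%% t(H) == %d I\n",
              x$order, x$construction, x$order))
  invisible(x)
}

# Negate columns then rows so the first row and first column are all +1.
# Row/column negation preserves H t(H) = N I.
normalize_hadamard <- function(H) {
  H <- sweep(H, 2L, H[1L, ], `*`)
  H <- sweep(H, 1L, H[, 1L], `*`)
  H
}

#' Paley type-I Hadamard matrix
#'
#' For a prime \eqn{q \equiv 3 \pmod 4}, builds the normalized Hadamard
#' matrix of order `q + 1` from the quadratic-residue (Jacobsthal) pattern:
#' `H = I + C` with `C` the skew conference matrix bordered around the
#' Jacobsthal matrix. Orthogonality `H %*% t(H) == (q+1) I` holds as an
#' exact integer identity and is asserted at construction.
#'
#' @param q a prime with `q %% 4 == 3`. Prime powers are not supported;
#'   every order needed here (12, 20, 420, ...) is reachable with prime `q`.
#' @return an object of class `hadamard` (fields `order`, `matrix`),
#'   normalized so the first row and column are all +1.
#' @examples
#' paley_type1(11)  # order 12, substrate of the 12-run design
#' @export
paley_type1 <- function(q) {
  if (!is_odd_prime(q)) {
    stop("Paley type I needs a prime q; ", q, " is not prime ",
         "(prime powers are not supported)", call. = FALSE)
  }
  if (q %% 4 != 3) {
    stop("Paley type I needs q = 3 (mod 4); q = ", q, " has q mod 4 = ",
         q %% 4, call. = FALSE)
  }
  Q <- jacobsthal(q)
  C <- rbind(c(0L, rep(1L, q)), cbind(rep(-1L, q), Q))
  H <- C + diag(q + 1L)
  new_hadamard(normalize_hadamard(H), "Paley I")
}

#' Paley type-II Hadamard matrix
#'
#' For a prime \eqn{q \equiv 1 \pmod 4}, builds the Hadamard matrix of
#' order `2(q + 1)` by the symmetric-conference-matrix doubling
#' \eqn{H = [[C + I, C - I], [C - I, -C - I]]}, then normalizes. Provides
#' the order-28 substrate (q = 13) for the six-factor drug-combination
#' design.
#'
#' @param q a prime with `q %% 4 == 1`.
#' @return an object of class `hadamard` of order `2 * (q + 1)`.
#' @examples
#' paley_type2(13)  # order 28
#' @export
paley_type2 <- function(q) {
  if (!is_odd_prime(q)) {
    stop("Paley type II needs a prime q; ", q, " is not prime ",
         "(prime powers are not supported)", call. = FALSE)
  }
  if (q %% 4 != 1) {
    stop("Paley type II needs q = 1 (mod 4); q = ", q, " has q mod 4 = ",
         q %% 4, call. = FALSE)
  }
  Q <- jacobsthal(q)
  C <- rbind(c(0L, rep(1L, q)), cbind(rep(1L, q), Q))  # symmetric, C C^T = qI
  I1 <- diag(q + 1L)
  H <- rbind(cbind(C + I1, C - I1),
             cbind(C - I1, -C - I1))
  new_hadamard(normalize_hadamard(H), "Paley II")
}

#' Sylvester Hadamard matrix
#'
#' Tensor (Kronecker) doubling: order `2^m`. The derived orthogonal arrays
#' are the regular saturated designs; used mainly for cross-checks.
#'
#' @param m non-negative integer.
#' @return an object of class `hadamard` of order `2^m`.
#' @export
sylvester <- function(m) {
  stopifnot(is.numeric(m), length(m) == 1L, m >= 0, m == floor(m))
  H <- matrix(1L, 1L, 1L)
  H2 <- matrix(c(1L, 1L, 1L, -1L), 2L, 2L, byrow = TRUE)
  for (i in seq_len(m)) H <- kronecker(H2, H)
  new_hadamard(H, "Sylvester")
}

#' Orthogonal-array design from a Hadamard matrix
#'
#' Drops the all-ones column of the normalized matrix and keeps the first
#' `n` remaining columns as factors. Any such selection is an
#' `OA(N, 2^n, 2)`: every pair of retained columns is orthogonal to each
#' other and to the all-ones column, so all four level pairs occur equally
#' often.
#'
#' @param H a `hadamard` object.
#' @param n number of factors, `1 <= n <= order - 1`.
#' @param columns optional explicit choice of `n` column indices from the
#'   `order - 1` candidate columns (after dropping the all-ones column);
#'   default `1:n`. The hidden-projection guarantees hold for any choice.
#' @return a [make_design()] object with `order` runs and `n` factors.
#' @examples
#' hadamard_to_oa(paley_type1(11), 6)  # the OA(12, 2^6, 2)
#' @export
hadamard_to_oa <- function(H, n, columns = NULL) {
  stopifnot(inherits(H, "hadamard"))
  candidates <- H$matrix[, -1L, drop = FALSE]  # first column is all +1
  if (n < 1L || n > ncol(candidates)) {
    stop("n must be between 1 and ", ncol(candidates), " (order - 1)",
         call. = FALSE)
  }
  if (is.null(columns)) columns <- seq_len(n)
  if (length(columns) != n || any(columns < 1L | columns > ncol(candidates))) {
    stop("columns must select ", n, " of the ", ncol(candidates),
         " candidate columns", call. = FALSE)
  }
  make_design(candidates[, columns, drop = FALSE])
}
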