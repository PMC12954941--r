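#' Verify orthogonal-array strength
#'
#' A design is an `OA(N, 2^n, t)` when every `t`-column submatrix contains
#' all `2^t` level combinations equally often (`N / 2^t` times each).
#' Verification is exhaustive: every `t`-subset of columns is counted. The
#' maximal strength is found by increasing `t` until a count fails (equal
#' counts at level `t` require `2^t` to divide `N`, so the scan is short).
#'
#' @param design a [make_design()] object.
#' @param t claimed strength, `1 <= t <= n`.
#' @param compute_max also compute the maximal strength (default `TRUE`).
#' @return an object of class `strength_report`: list with `claimed_t`,
#'   `holds`, `max_t` (`NA` if not computed), and for a failure `witness`
#'   (the column labels, the level combination, and its observed vs
#'   expected count).
#' @examples
#' d <- hadamard_to_oa(paley_type1(11), 6)
#' verify_strength(d, 2)  # holds, max_t = 2
#' @export
verify_strength <- function(design, t, compute_max = TRUE) {
  stopifnot(inherits(design, "design"))
  n <- design$n_factors
  if (!is.numeric(t) || length(t) != 1L || t < 1 || t > n) {
    stop("t must be an integer in 1..", n, call. = FALSE)
  }
  t <- as.integer(t)
  chk <- strength_holds(design, t)
  max_t <- NA_integer_
  if (compute_max) {
    max_t <- 0L
    cap <- min(n, floor(log2(design$runs)))
    for (tt in seq_len(cap)) {
      if (!strength_holds(design, tt)$holds) break
      max_t <- tt
    }
  }
  structure(
    list(claimed_t = t, holds = chk$holds, max_t = max_t,
         witness = chk$witness),
    class = "strength_report"
  )
}

# exhaustive count over all t-subsets, early exit at first unequal count
strength_holds <- function(design, t) {
  N <- design$runs
  if (N %% 2L^t != 0L) {
    # equal counts are impossible; still exhibit a concrete witness
    X01 <- (design$matrix[, seq_len(t), drop = FALSE] + 1L) / 2L
    idx <- as.vector(X01 %*% 2L^(0:(t - 1L)))
    counts <- tabulate(idx + 1L, nbins = 2L^t)
    bad <- which(counts != N / 2L^t)[1L]
    return(list(holds = FALSE, witness = witness_at(design, seq_len(t), bad,
                                                    counts[bad], N / 2^t)))
  }
  expected <- as.integer(N / 2^t)
  X01 <- (design$matrix + 1L) / 2L
  pow <- 2L^(0:(t - 1L))
  combos <- utils::combn(design$n_factors, t)
  for (i in seq_len(ncol(combos))) {
    cols <- combos[, i]
    idx <- as.vector(X01[, cols, drop = FALSE] %*% pow)
    counts <- tabulate(idx + 1L, nbins = 2L^t)
    if (any(counts != expected)) {
      bad <- which(counts != expected)[1L]
      return(list(holds = FALSE,
                  witness = witness_at(design, cols, bad, counts[bad],
                                       expected)))
    }
  }
  list(holds = TRUE, witness = NULL)
}

witness_at <- function(design, cols, combo_index, count, expected) {
  t <- length(cols)
  bits <- as.integer(intToBits(combo_index - 1L))[seq_len(t)]
  list(columns = design$labels[cols],
       levels = 2L * bits - 1L,
       count = count,
       expected = expected)
}

#' @export
print.strength_report <- function(x, ...) {
  cat(sprintf("Strength t = %d: %s", x$claimed_t,
              if (x$holds) "holds" else "FAILS"))
  if (!is.na(x$max_t)) cat(sprintf(" (maximal strength %d)", x$max_t))
  cat("\n")
  if (!is.null(x$witness)) {
    w <- x$witness
    cat(sprintf("  witness: columns {%s}, combination (%s) occurs %d times, expected %s\n",
                paste(w$columns, collapse = ","),
                paste(w$levels, collapse = ","), w$count,
                format(w$expected)))
  }
  invisible(x)
}

#' Maximal strength of a design
#'
#' Convenience wrapper: the largest `t` for which the design is an
#' `OA(N, 2^n, t)` (0 if not even level-balanced).
#'
#' @param design a [make_design()] object.
#' @return integer maximal strength.
#' @export
max_strength <- function(design) {
  verify_strength(design, 1L)$max_t
}

#' Full-rank test for a factor projection
#'
#' Forms the intercept + main-effects + two-factor-interaction model matrix
#' over `subset` and tests whether its column rank equals its column count
#' `p = 1 + m + m(m-1)/2`. Rank is computed exactly over the integers
#' ([rank_exact()]), with an optional floating cross-check. When `p > N`
#' full rank is impossible and the projection is reported as rank
#' deficient (not an error).
#'
#' @param design a [make_design()] object.
#' @param subset non-empty character vector of factor labels.
#' @param cross_check also compute [rank_float()] and stop if it disagrees
#'   with the exact rank (default `FALSE`; the test suite exercises it).
#' @return an object of class `projection_rank`: list with `full_rank`
#'   (logical), `rank`, `p` (column count), and `subset`.
#' @examples
#' d <- build_regular(generator_set(4, c(E = "ABC", F = "ACD")))
#' is_full_rank_projection(d, c("A", "B", "C", "E"))  # rank 8 of 11
#' @export
is_full_rank_projection <- function(design, subset, cross_check = FALSE) {
  X <- model_matrix(design, subset)
  r <- rank_exact(X)
  if (cross_check) {
    rf <- rank_float(X)
    if (rf != r) {
      stop(sprintf("rank oracle disagreement on {%s}: exact %d vs float %d",
                   paste(subset, collapse = ","), r, rf), call. = FALSE)
    }
  }
  structure(
    list(full_rank = r == ncol(X), rank = r, p = ncol(X),
         subset = canon_word(subset, design$labels)),
    class = "projection_rank"
  )
}

#' @export
print.projection_rank <- function(x, ...) {
  cat(sprintf("Projection {%s}: rank %d of %d — %s\n",
              paste(x$subset, collapse = ","), x$rank, x$p,
              if (x$full_rank) "full rank" else "rank deficient"))
  invisible(x)
}

#' Hidden-projection coverage at subset size k
#'
#' Applies [is_full_rank_projection()] to every `k`-factor subset (or to a
#' supplied list of subsets, for sampling large designs) and reports the
#' percentage achieving full column rank for the ME+2FI model, together
#' with the deficient subsets.
#'
#' @param design a [make_design()] object.
#' @param k projection subset size, `1 <= k <= n`.
#' @param subsets optional list of character vectors (each of length `k`)
#'   restricting the enumeration, e.g. a fixed random sample for the
#'   420-run design; default: all `choose(n, k)` subsets.
#' @return an object of class `projection_report`: list with `subset_size`,
#'   `total_subsets` (`choose(n, k)`), `evaluated`, `full_rank_count`,
#'   `coverage_pct` (exact rational times 100, relative to `evaluated`),
#'   and `deficient_subsets` (list of label vectors).
#' @examples
#' projection_coverage(hadamard_to_oa(paley_type1(11), 6), 4)  # 100%
#' @export
projection_coverage <- function(design, k, subsets = NULL) {
  stopifnot(inherits(design, "design"))
  n <- design$n_factors
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n) {
    stop("k must be an integer in 1..", n, call. = FALSE)
  }
  k <- as.integer(k)
  if (is.null(subsets)) {
    subsets <- utils::combn(design$labels, k, simplify = FALSE)
  } else {
    subsets <- lapply(subsets, canon_word, labels = design$labels)
    if (any(lengths(subsets) != k)) {
      stop("every supplied subset must have ", k, " distinct factors",
           call. = FALSE)
    }
  }
  deficient <- list()
  full <- 0L
  for (s in subsets) {
    pr <- is_full_rank_projection(design, s)
    if (pr$full_rank) full <- full + 1L else deficient <- c(deficient, list(s))
  }
  structure(
    list(subset_size = k,
         total_subsets = choose(n, k),
         evaluated = length(subsets),
         full_rank_count = full,
         coverage_pct = 100 * full / length(subsets),
         deficient_subsets = deficient),
    class = "projection_report"
  )
}

#' @export
print.projection_report <- function(x, ...) {
  scope <- if (x$evaluated == x$total_subsets) {
    sprintf("all %d subsets", x$total_subsets)
  } else {
    sprintf("%d of %d subsets (sampled)", x$evaluated, x$total_subsets)
  }
  cat(sprintf("k = %d projections (%s): %d full rank, coverage %.1f%%\n",
              x$subset_size, scope, x$full_rank_count, x$coverage_pct))
  if (length(x$deficient_subsets)) {
    cat("  deficient:",
        paste(vapply(x$deficient_subsets, word_string, ""), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Sufficient hidden-projection guarantee for orthogonal arrays
#'
#' Run-size conditions under which every projection of a given size has an
#' estimable ME+2FI model (higher-order interactions assumed negligible):
#' for a strength-2 array with `n >= 4` factors and `N` not a multiple of
#' 8, any 4 factors; for a strength-3 array with `n >= 5` and `N` not a
#' multiple of 16, any 5 factors.
#'
#' @param N run count.
#' @param n factor count.
#' @param t array strength, 2 or 3.
#' @return the guaranteed projection size (4 or 5) as an integer, or
#'   `NA_integer_` when these conditions give no guarantee.
#' @examples
#' cheng_guarantee(12, 6, 2)   # 4
#' cheng_guarantee(16, 6, 2)   # NA: 16 is a multiple of 8
#' @export
cheng_guarantee <- function(N, n, t) {
  if (!t %in% c(2L, 3L)) {
    stop("guarantee conditions are available for strength t = 2 or 3 only",
         call. = FALSE)
  }
  if (t == 2L && N %% 8L != 0L && n >= 4L) return(4L)
  if (t == 3L && N %% 16L != 0L && n >= 5L) return(5L)
  NA_integer_
}

#' Compare designs by runs, strength, and projection coverage
#'
#' Builds the comparison table underlying the case studies: one row per
#' projection size `k`, one column per design, cells = full-rank coverage
#' percent; plus run counts, maximal strengths, and each design's percent
#' run reduction versus a named baseline (rounded to the nearest integer).
#'
#' @param designs named list of [make_design()] objects.
#' @param k_values integer vector of projection sizes to compare.
#' @param baseline name (or index) of the baseline design for run-reduction
#'   accounting; default the first design.
#' @param coverage_subsets optional named list: for a design name, a list
#'   of subsets per `k` (named by `k`) to restrict enumeration (sampling).
#' @return an object of class `design_comparison` with fields `names`,
#'   `runs`, `strengths`, `reduction_pct`, `coverage` (matrix k x design),
#'   and `reports` (the underlying [projection_coverage()] objects).
#' @export
compare_designs <- function(designs, k_values, baseline = 1L,
                            coverage_subsets = NULL) {
  stopifnot(is.list(designs), length(designs) >= 1L)
  if (is.null(names(designs)) || any(!nzchar(names(designs)))) {
    names(designs) <- paste0("design", seq_along(designs))
  }
  for (d in designs) stopifnot(inherits(d, "design"))
  if (is.character(baseline)) baseline <- match(baseline, names(designs))
  if (is.na(baseline) || baseline < 1L || baseline > length(designs)) {
    stop("baseline must name one of the designs", call. = FALSE)
  }
  k_values <- as.integer(k_values)
  runs <- vapply(designs, function(d) d$runs, 0L)
  strengths <- vapply(designs, max_strength, 0L)
  base_runs <- runs[baseline]
  reduction <- stats::setNames(
    as.integer(round(100 * (base_runs - runs) / base_runs)), names(designs))
  cov <- matrix(NA_real_, length(k_values), length(designs),
                dimnames = list(as.character(k_values), names(designs)))
  reports <- list()
  for (j in seq_along(designs)) {
    nm <- names(designs)[j]
    reports[[nm]] <- list()
    for (i in seq_along(k_values)) {
      k <- k_values[i]
      sub <- NULL
      if (!is.null(coverage_subsets) && !is.null(coverage_subsets[[nm]])) {
        sub <- coverage_subsets[[nm]][[as.character(k)]]
      }
      rep_k <- projection_coverage(designs[[j]], k, subsets = sub)
      cov[i, j] <- rep_k$coverage_pct
      reports[[nm]][[as.character(k)]] <- rep_k
    }
  }
  structure(
    list(names = names(designs), runs = runs, strengths = strengths,
         baseline = names(designs)[baseline], reduction_pct = reduction,
         k_values = k_values, coverage = cov, reports = reports),
    class = "design_comparison"
  )
}

#' @export
print.design_comparison <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
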