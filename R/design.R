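#' Create a two-level design
#'
#' A design is an `N x n` matrix of experimental runs over `n` two-level
#' factors, internally coded -1 (low) / +1 (high). Matrices supplied in the
#' common orthogonal-array-library 0/1 coding are recoded with the fixed
#' convention `0 -> -1`, `1 -> +1`.
#'
#' @param matrix an integer (or numeric) matrix with entries in \{-1, +1\}
#'   or in \{0, 1\}.
#' @param labels optional character vector of unique factor labels; defaults
#'   to `A, B, C, ...` (see [default_labels()]).
#' @return an object of class `design`: a list with elements `matrix`
#'   (integer, -1/+1 coded), `labels`, `runs` (N) and `n_factors` (n).
#' @examples
#' d <- make_design(sylvester(3)$matrix[, 2:4])
#' d
#' @export
make_design <- function(matrix, labels = NULL) {
  if (!is.matrix(matrix)) matrix <- as.matrix(matrix)
  if (!is.numeric(matrix)) {
    stop("design matrix must be numeric with entries in {-1, +1}",
         call. = FALSE)
  }
  if (nrow(matrix) < 1L || ncol(matrix) < 1L) {
    stop("design must have at least one run and one factor", call. = FALSE)
  }
  vals <- unique(as.vector(matrix))
  if (all(vals %in% c(0, 1)) && any(vals == 0)) {
    matrix <- 2 * matrix - 1  # OA-library 0/1 coding
  }
  if (!all(matrix %in% c(-1, 1))) {
    offending <- setdiff(unique(as.vector(matrix)), c(-1, 1))
    stop("design entries must be -1/+1 (or 0/1); found: ",
         paste(utils::head(offending, 3L), collapse = ", "), call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- default_labels(ncol(matrix))
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(matrix)) {
    stop("need ", ncol(matrix), " labels, got ", length(labels),
         call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("factor labels must be unique", call. = FALSE)
  }
  m <- matrix(as.integer(matrix), nrow(matrix), ncol(matrix))
  dimnames(m) <- list(NULL, labels)
  structure(
    list(matrix = m, labels = labels,
         runs = nrow(m), n_factors = ncol(m)),
    class = "design"
  )
}

#' @export
print.design <- function(x, ...) {
  cat(sprintf("Two-level design: %d runs x %d factors (%s)\n",
              x$runs, x$n_factors,
              paste(utils::head(x$labels, 8L), collapse = ",")))
  nshow <- min(6L, x$runs)
  print(x$matrix[seq_len(nshow), , drop = FALSE])
  if (x$runs > nshow) cat("... (", x$runs - nshow, " more runs)\n", sep = "")
  invisible(x)
}

#' @export
dim.design <- function(x) dim(x$matrix)

#' Main-effects (+ two-factor-interaction) model specification
#'
#' Builds the canonical term list for a factor subset: the intercept (empty
#' word), each main effect, and — when `interactions = TRUE` — each
#' two-factor interaction. For an `m`-factor subset the ME+2FI spec has
#' `1 + m + m(m-1)/2` terms. Terms are ordered intercept, main effects,
#' interactions, each block in label order, so model matrices are
#' deterministic.
#'
#' @param subset character vector of factor labels.
#' @param interactions include all two-factor interactions?
#' @return an object of class `model_spec`: a list of terms, each a
#'   character vector of labels (the intercept is `character(0)`).
#' @export
model_spec <- function(subset, interactions = TRUE) {
  subset <- as.character(subset)
  if (length(subset) < 1L) stop("subset must be non-empty", call. = FALSE)
  if (anyDuplicated(subset)) stop("duplicate labels in subset", call. = FALSE)
  terms <- c(list(character(0)), lapply(subset, identity))
  if (interactions && length(subset) >= 2L) {
    terms <- c(terms, utils::combn(subset, 2L, simplify = FALSE))
  }
  structure(terms, class = "model_spec", subset = subset)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec (", length(x), " terms): ",
      paste(vapply(x, word_string, ""), collapse = " + "), "\n", sep = "")
  invisible(x)
}

validate_model_spec <- function(spec, subset) {
  # key includes the term order so the intercept never collides with a
  # factor literally labelled "I"
  keys <- vapply(spec, function(t) paste0(length(t), ":",
                                          paste(sort(t), collapse = ":")), "")
  if (anyDuplicated(keys)) stop("duplicate terms in model spec", call. = FALSE)
  used <- unique(unlist(spec))
  bad <- setdiff(used, subset)
  if (length(bad)) {
    stop("model spec references factor(s) outside the subset: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(spec)
}

#' Model matrix over a factor subset
#'
#' Column `j` is the elementwise product of the design columns named by term
#' `j`; the intercept term is the all-ones column. With the default spec
#' this is the intercept + main effects + two-factor interactions matrix
#' whose column rank decides hidden-projection estimability.
#'
#' @param design a [make_design()] object.
#' @param subset character vector of factor labels (subset of the design's
#'   labels).
#' @param spec a [model_spec()]; defaults to ME+2FI over `subset`.
#' @return an integer matrix of dimension `N x p`, `p` = number of terms,
#'   with words as column names (intercept column `"I"`).
#' @examples
#' d <- build_regular(generator_set(4, c(E = "ABC", F = "ACD")))
#' dim(model_matrix(d, c("A", "B", "C", "E")))  # 16 x 11
#' @export
model_matrix <- function(design, subset, spec = NULL) {
  stopifnot(inherits(design, "design"))
  subset <- canon_word(subset, design$labels)
  if (length(subset) < 1L) stop("subset must be non-empty", call. = FALSE)
  if (is.null(spec)) spec <- model_spec(subset)
  validate_model_spec(spec, subset)
  M <- design$matrix
  cols <- lapply(spec, function(term) {
    col <- rep(1L, design$runs)
    for (f in term) col <- col * M[, f]
    col
  })
  X <- do.call(cbind, cols)
  nm <- vapply(spec, word_string, "")
  nm[lengths(spec) == 0L] <- "(Intercept)"
  colnames(X) <- nm
  X
}
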