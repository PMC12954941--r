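#' Generator set for a regular fractional factorial
#'
#' A regular two-level \eqn{2^{n-g}} design is specified by `k` base factors
#' plus `g` generator words assigning each added factor to a product of base
#' columns, e.g. `E = ABC`. Generators may carry a sign (`F = "-ABC"`); an
#' unsigned word means `+`.
#'
#' @param k number of base factors (the design has `2^k` runs).
#' @param generators named character vector or named list mapping each new
#'   factor label to its generator word over the base labels, e.g.
#'   `c(E = "ABC", F = "ACD")`. May be empty (full factorial).
#' @param base_labels labels of the base factors; default `A, B, ...`.
#' @return an object of class `generator_set`.
#' @seealso [parse_generators()] for the `"E=ABC,F=ACD"` mini-language.
#' @export
generator_set <- function(k, generators = character(0), base_labels = NULL) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  k <- as.integer(k)
  if (is.null(base_labels)) base_labels <- default_labels(k)
  if (length(base_labels) != k || anyDuplicated(base_labels)) {
    stop("need ", k, " unique base labels", call. = FALSE)
  }
  generators <- as.list(generators)
  new_labels <- names(generators)
  if (length(generators) && (is.null(new_labels) || any(!nzchar(new_labels)))) {
    stop("every generator needs a new-factor label (e.g. c(E = \"ABC\"))",
         call. = FALSE)
  }
  if (anyDuplicated(new_labels) || any(new_labels %in% base_labels)) {
    stop("new-factor labels must be unique and disjoint from base labels",
         call. = FALSE)
  }
  gens <- lapply(seq_along(generators), function(i) {
    w <- parse_word(as.character(generators[[i]]), base_labels)
    if (length(w) == 0L) {
      stop("generator word for ", new_labels[i], " is empty", call. = FALSE)
    }
    list(label = new_labels[i], word = as.character(w),
         sign = attr(w, "sign"))
  })
  structure(
    list(k = k, base_labels = base_labels, gens = gens,
         labels = c(base_labels, new_labels)),
    class = "generator_set"
  )
}

#' @export
print.generator_set <- function(x, ...) {
  g <- length(x$gens)
  cat(sprintf("2^(%d-%d) generator set: %d base factors (%s)\n",
              x$k + g, g, x$k, paste(x$base_labels, collapse = ",")))
  for (gen in x$gens) {
    cat("  ", gen$label, " = ", if (gen$sign < 0) "-" else "",
        word_string(gen$word), "\n", sep = "")
  }
  invisible(x)
}

#' Parse the generator mini-language
#'
#' Parses strings like `"E=ABC,F=ACD"` (comma-separated `label=word` pairs)
#' into a [generator_set()].
#'
#' @param text specification string; `""` means no generators.
#' @param k number of base factors.
#' @param base_labels optional base labels (default `A, B, ...`).
#' @return a `generator_set`.
#' @export
parse_generators <- function(text, k, base_labels = NULL) {
  text <- trimws(text)
  if (!nzchar(text)) return(generator_set(k, base_labels = base_labels))
  parts <- strsplit(text, ",", fixed = TRUE)[[1L]]
  kv <- lapply(parts, function(p) {
    bits <- strsplit(p, "=", fixed = TRUE)[[1L]]
    if (length(bits) != 2L) {
      stop("cannot parse generator '", p, "' (expected label=word)",
           call. = FALSE)
    }
    trimws(bits)
  })
  gens <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  generator_set(k, gens, base_labels = base_labels)
}

#' Build a regular fractional factorial design
#'
#' The `k` base columns enumerate the full `2^k` factorial in standard
#' (Yates) order — base factor `j` alternates sign in blocks of `2^(j-1)` —
#' and each generated column is the (signed) elementwise product of its
#' generator-word columns.
#'
#' @param gen a [generator_set()].
#' @return a [make_design()] object with `2^k` runs and
#'   `k + length(generators)` factors.
#' @examples
#' build_regular(generator_set(4, c(E = "ABC", F = "ACD")))  # 16 x 6
#' @export
build_regular <- function(gen) {
  stopifnot(inherits(gen, "generator_set"))
  k <- gen$k
  N <- 2L^k
  base <- vapply(seq_len(k), function(j) {
    rep_len(rep(c(-1L, 1L), each = 2L^(j - 1L)), N)
  }, integer(N))
  colnames(base) <- gen$base_labels
  extra <- vapply(gen$gens, function(g) {
    col <- rep(g$sign, N)
    for (f in g$word) col <- col * base[, f]
    as.integer(col)
  }, integer(N))
  mat <- if (length(gen$gens)) cbind(base, extra) else base
  make_design(mat, labels = gen$labels)
}

#' Defining contrast subgroup
#'
#' Each generator `E = W` contributes the defining word `EW` (e.g.
#' `E = ABC` gives `ABCE`, since `E * ABC = I` on the design). The defining
#' contrast subgroup is the closure of these `g` words under
#' symmetric-difference multiplication; its `2^g - 1` non-identity elements
#' are returned. Signed generators propagate their signs through products.
#'
#' @param gen a [generator_set()].
#' @return a data frame of class `defining_subgroup` with columns `word`
#'   (canonical string), `length`, and `sign`, ordered by length then word;
#'   empty for a full factorial.
#' @examples
#' defining_contrast_subgroup(generator_set(4, c(E = "ABC", F = "ACD")))
#' # words ABCE, ACDF, BDEF
#' @export
defining_contrast_subgroup <- function(gen) {
  stopifnot(inherits(gen, "generator_set"))
  labels <- gen$labels
  defwords <- lapply(gen$gens, function(g) {
    list(word = canon_word(c(g$word, g$label), labels), sign = g$sign)
  })
  g <- length(defwords)
  out <- list()
  if (g > 0L) {
    for (mask in seq_len(2L^g - 1L)) {
      w <- character(0)
      s <- 1L
      for (i in seq_len(g)) {
        if (bitwAnd(mask, bitwShiftL(1L, i - 1L))) {
          w <- word_mul(w, defwords[[i]]$word, labels)
          s <- s * defwords[[i]]$sign
        }
      }
      out[[mask]] <- list(word = w, sign = s)
    }
  }
  df <- data.frame(
    word = vapply(out, function(x) word_string(x$word), ""),
    length = vapply(out, function(x) length(x$word), 0L),
    sign = vapply(out, function(x) x$sign, 0L),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$length, df$word), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("defining_subgroup", "data.frame"), labels = labels)
}

#' Word-length pattern of a defining contrast subgroup
#'
#' @param subgroup a [defining_contrast_subgroup()] result.
#' @param n total number of factors (defaults to the subgroup's label
#'   universe size); counts are reported for lengths `1..n`.
#' @return integer vector `counts` with `counts[l]` = number of defining
#'   words of length `l`.
#' @export
wordlength_pattern <- function(subgroup, n = NULL) {
  stopifnot(inherits(subgroup, "defining_subgroup"))
  if (is.null(n)) n <- length(attr(subgroup, "labels"))
  tabulate(subgroup$length, nbins = n)
}

#' Resolution of a regular design
#'
#' The minimum defining-word length. A full factorial (empty subgroup) has
#' no defining words; `Inf` is returned to flag it.
#'
#' @inheritParams wordlength_pattern
#' @return integer resolution, or `Inf` for a full factorial.
#' @export
resolution <- function(subgroup) {
  stopifnot(inherits(subgroup, "defining_subgroup"))
  if (nrow(subgroup) == 0L) return(Inf)
  min(subgroup$length)
}

#' Alias set of an effect word
#'
#' Returns the complete alias class of `term` under the defining contrast
#' subgroup: `term` itself plus every product `term * w`. On the coded
#' design the model-matrix columns of all words in one class are identical
#' up to the subgroup's signs (exactly identical for unsigned generators).
#'
#' @param term a word string (e.g. `"AB"`) or character vector of labels.
#' @param subgroup a [defining_contrast_subgroup()] result.
#' @return character vector of canonical word strings (the class, `term`
#'   first), with integer attribute `sign` giving each word's sign relative
#'   to `term`.
#' @examples
#' sg <- defining_contrast_subgroup(generator_set(4, c(E = "ABC", F = "ACD")))
#' alias_words("AB", sg)  # AB, CE, and two longer words
#' @export
alias_words <- function(term, subgroup) {
  stopifnot(inherits(subgroup, "defining_subgroup"))
  labels <- attr(subgroup, "labels")
  w0 <- if (is.character(term) && length(term) == 1L) {
    parse_word(term, labels)
  } else {
    canon_word(as.character(term), labels)
  }
  words <- c(word_string(as.character(w0)),
             vapply(seq_len(nrow(subgroup)), function(i) {
               wi <- parse_word(subgroup$word[i], labels)
               word_string(word_mul(as.character(w0), as.character(wi), labels))
             }, ""))
  signs <- c(1L, subgroup$sign)
  structure(words, sign = signs)
}
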