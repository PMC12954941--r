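#' Default factor labels
#'
#' Generates the canonical label sequence used when a design is created
#' without explicit labels: `A`, `B`, ..., `Z`, then `A1`, `B1`, ... for
#' more than 26 factors.
#'
#' @param n number of labels required.
#' @return character vector of length `n` with unique labels.
#' @examples
#' default_labels(3)
#' default_labels(28)[27:28]
#' @export
default_labels <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  blocks <- ceiling(n / 26L)
  out <- LETTERS
  if (blocks > 1L) {
    for (b in seq_len(blocks - 1L)) out <- c(out, paste0(LETTERS, b))
  }
  out[seq_len(n)]
}

# Canonical word: labels sorted by their position in the label universe.
# A word is a character vector of factor labels; the empty vector is the
# identity I.
canon_word <- function(factors, labels) {
  factors <- unique(factors)
  bad <- setdiff(factors, labels)
  if (length(bad)) {
    stop("unknown factor label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factors[order(match(factors, labels))]
}

#' Format an effect word as a string
#'
#' The identity (empty word) prints as `"I"`. Single-character labels are
#' concatenated (`"ABCE"`); multi-character labels are joined with `:`
#' (`"A:B1"`).
#'
#' @param w character vector of factor labels (possibly empty).
#' @return a length-one character string.
#' @export
word_string <- function(w) {
  if (length(w) == 0L) return("I")
  if (all(nchar(w) == 1L)) paste(w, collapse = "") else paste(w, collapse = ":")
}

#' Parse an effect word from a string
#'
#' Inverse of [word_string()]. Accepts an optional leading `-` sign (used by
#' signed generators), the identity `"I"`, contiguous single-character labels
#' (`"ABC"`), or `:`-separated labels (`"A:B1"`).
#'
#' @param s a word string.
#' @param labels the design's factor labels (the label universe).
#' @return character vector of labels, canonically ordered, with an integer
#'   attribute `sign` in `{-1, +1}`.
#' @export
parse_word <- function(s, labels) {
  stopifnot(is.character(s), length(s) == 1L)
  s <- trimws(s)
  sign <- 1L
  if (startsWith(s, "-")) {
    sign <- -1L
    s <- sub("^-\\s*", "", s)
  } else if (startsWith(s, "+")) {
    s <- sub("^\\+\\s*", "", s)
  }
  if (s == "I" || s == "") {
    w <- character(0)
  } else if (grepl(":", s, fixed = TRUE)) {
    w <- strsplit(s, ":", fixed = TRUE)[[1L]]
  } else if (all(nchar(labels) == 1L)) {
    w <- strsplit(s, "", fixed = TRUE)[[1L]]
  } else {
    # multi-char universe but no separator: try greedy longest-label match
    w <- character(0)
    rest <- s
    while (nchar(rest)) {
      hit <- labels[startsWith(rest, labels)]
      if (!length(hit)) stop("cannot parse word '", s, "'", call. = FALSE)
      hit <- hit[which.max(nchar(hit))]
      w <- c(w, hit)
      rest <- substring(rest, nchar(hit) + 1L)
    }
  }
  if (anyDuplicated(w)) {
    stop("word '", s, "' repeats a factor label", call. = FALSE)
  }
  structure(canon_word(w, labels), sign = sign)
}

#' Multiply two effect words
#'
#' Word multiplication is the symmetric difference of the factor sets:
#' shared factors square to the identity because every design column has
#' entries in \{-1, +1\}. The model-matrix column of `word_mul(w1, w2)`
#' equals the elementwise product of the columns of `w1` and `w2`.
#'
#' @param w1,w2 character vectors of factor labels.
#' @param labels the label universe fixing canonical order.
#' @return the product word (canonical character vector; empty = identity).
#' @export
word_mul <- function(w1, w2, labels) {
  canon_word(c(setdiff(w1, w2), setdiff(w2, w1)), labels)
}
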