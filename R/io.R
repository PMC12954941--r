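#' Read a design from a file
#'
#' Two plain-text dialects are supported:
#' \describe{
#'   \item{`csv`}{header row of factor labels, body of -1/+1 entries,
#'     comma-separated, no index column.}
#'   \item{`oa_text`}{one run per line as contiguous 0/1 digits (the dialect
#'     of public orthogonal-array catalogues); an optional first line
#'     `"N n t"` header is tolerated and ignored. Levels are recoded
#'     `0 -> -1`, `1 -> +1`; labels default to `A, B, ...`.}
#' }
#'
#' @param path file path.
#' @param format `"csv"` or `"oa_text"`.
#' @return a [make_design()] object.
#' @seealso [write_design()] — `read_design(write_design(d, p, f), f)`
#'   round-trips to an identical design.
#' @export
read_design <- function(path, format = c("csv", "oa_text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") read_design_csv(path) else read_design_oa(path)
}

read_design_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("csv design needs a header and at least one run",
                               call. = FALSE)
  labels <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  rows <- strsplit(body, ",", fixed = TRUE)
  n <- length(labels)
  mat <- matrix(NA_integer_, length(rows), n)
  for (i in seq_along(rows)) {
    r <- trimws(rows[[i]])
    if (length(r) != n) {
      stop(sprintf("line %d: expected %d fields, found %d",
                   i + 1L, n, length(r)), call. = FALSE)
    }
    if (!all(r %in% c("-1", "1", "+1"))) {
      stop(sprintf("line %d: non-level symbol '%s' (entries must be -1/+1)",
                   i + 1L, setdiff(r, c("-1", "1", "+1"))[1L]), call. = FALSE)
    }
    mat[i, ] <- as.integer(sub("^\\+", "", r))
  }
  make_design(mat, labels = trimws(labels))
}

read_design_oa <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty oa_text file", call. = FALSE)
  offset <- 0L
  # optional "N n t" header: whitespace-separated integers
  if (grepl("\\s", trimws(lines[1L]))) {
    offset <- 1L
    lines <- lines[-1L]
    if (!length(lines)) stop("oa_text file has a header but no runs",
                             call. = FALSE)
  }
  width <- nchar(trimws(lines[1L]))
  mat <- matrix(NA_integer_, length(lines), width)
  for (i in seq_along(lines)) {
    s <- trimws(lines[i])
    if (nchar(s) != width) {
      stop(sprintf("line %d: ragged row (%d symbols, expected %d)",
                   i + offset, nchar(s), width), call. = FALSE)
    }
    digits <- strsplit(s, "", fixed = TRUE)[[1L]]
    if (!all(digits %in% c("0", "1"))) {
      stop(sprintf("line %d: non-level symbol '%s' (oa_text is 0/1)",
                   i + offset, setdiff(digits, c("0", "1"))[1L]),
           call. = FALSE)
    }
    mat[i, ] <- 2L * as.integer(digits) - 1L
  }
  make_design(mat)
}

#' Write a design to a file
#'
#' @inheritParams read_design
#' @param design a [make_design()] object.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path, format = c("csv", "oa_text")) {
  stopifnot(inherits(design, "design"))
  format <- match.arg(format)
  if (format == "csv") {
    lines <- c(paste(design$labels, collapse = ","),
               apply(design$matrix, 1L, paste, collapse = ","))
  } else {
    lines <- apply((design$matrix + 1L) / 2L, 1L, paste, collapse = "")
  }
  writeLines(lines, path)
  invisible(path)
}
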