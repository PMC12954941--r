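# Config-driven case studies: a baseline design and a proposed design are
# constructed from declarative specs, analysed (strength, projection
# coverage, run accounting), rendered as a report, and self-checked against
# the expectations declared in the config.

#' Render a design comparison as a markdown table
#'
#' Deterministic formatting: identical inputs give byte-identical output.
#'
#' @param comparison a [compare_designs()] object.
#' @return character vector of report lines.
#' @export
render_report <- function(comparison) {
  stopifnot(inherits(comparison, "design_comparison"))
  x <- comparison
  lines <- character(0)
  header <- c("Design", "Runs", "Max strength", "Run reduction vs baseline")
  rows <- lapply(seq_along(x$names), function(j) {
    c(x$names[j], format(x$runs[j]), format(x$strengths[j]),
      if (x$names[j] == x$baseline) "(baseline)"
      else paste0(x$reduction_pct[j], "%"))
  })
  lines <- c(lines, md_table(header, rows))
  lines <- c(lines, "")
  header2 <- c("Subset size", paste0(x$names, ": full-rank (%)"))
  rows2 <- lapply(seq_along(x$k_values), function(i) {
    c(sprintf("%d factors", x$k_values[i]),
      vapply(seq_along(x$names),
             function(j) fmt_pct(x$coverage[i, j]), ""))
  })
  c(lines, md_table(header2, rows2))
}

fmt_pct <- function(p) {
  if (abs(p - round(p)) < 1e-9) sprintf("%d%%", as.integer(round(p)))
  else sprintf("%.1f%%", p)
}

md_table <- function(header, rows) {
  cells <- rbind(header, do.call(rbind, lapply(rows, as.character)))
  widths <- apply(nchar(cells), 2L, max)
  pad <- function(r) {
    padded <- mapply(function(s, w) formatC(s, width = w, flag = "-"),
                     as.character(r), widths)
    paste0("| ", paste(padded, collapse = " | "), " |")
  }
  sep <- paste0("|", paste(strrep("-", widths + 2L), collapse = "|"), "|")
  c(pad(header), sep, vapply(rows, pad, ""))
}

# ---- design spec resolution -------------------------------------------

#' Resolve a declarative design spec to a design
#'
#' Spec forms (lists, as parsed from YAML):
#' \itemize{
#'   \item `type: regular` with `k` and `generators` (mini-language string,
#'     e.g. `"E=ABC,F=ACD"`, possibly empty for a full factorial);
#'   \item `type: paley1` / `paley2` with `q` and `cols`;
#'   \item `type: sylvester` with `m` and `cols`;
#'   \item `type: file` with `path` and `format` (`csv` / `oa_text`).
#' }
#'
#' @param spec a named list.
#' @param base_dir directory against which a `file` path is resolved.
#' @return a [make_design()] object.
#' @export
resolve_design_spec <- function(spec, base_dir = ".") {
  if (is.null(spec$type)) stop("design spec needs a 'type'", call. = FALSE)
  switch(as.character(spec$type),
    regular = {
      if (is.null(spec$k)) stop("regular spec needs 'k'", call. = FALSE)
      gen <- parse_generators(spec$generators %||% "", as.integer(spec$k))
      build_regular(gen)
    },
    paley1 = hadamard_to_oa(paley_type1(as.integer(spec$q)),
                            as.integer(spec$cols)),
    paley2 = hadamard_to_oa(paley_type2(as.integer(spec$q)),
                            as.integer(spec$cols)),
    sylvester = hadamard_to_oa(sylvester(as.integer(spec$m)),
                               as.integer(spec$cols)),
    file = read_design(file.path(base_dir, spec$path),
                       format = spec$format %||% "csv"),
    stop("unknown design spec type '", spec$type, "'", call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a case-study config
#'
#' YAML with fields `name`, `baseline` and `proposal` (design specs, see
#' [resolve_design_spec()]), `k_values`, and an `expectations` block that
#' the runner self-checks: `runs` (named `baseline` / `proposal`),
#' `reduction_pct`, optional `strength` (claimed strength per design) and
#' `coverage` (per design, percent by subset size).
#'
#' @param path path to the YAML config.
#' @return a list of class `case_study_config`.
#' @export
read_case_study_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (field in c("name", "baseline", "proposal", "k_values")) {
    if (is.null(cfg[[field]])) {
      stop("config missing required field '", field, "'", call. = FALSE)
    }
  }
  if (!length(cfg$k_values)) stop("k_values must be non-empty", call. = FALSE)
  cfg$base_dir <- dirname(normalizePath(path))
  class(cfg) <- "case_study_config"
  cfg
}

#' Run a case study
#'
#' Constructs the baseline and proposed designs, verifies any claimed
#' strengths by exhaustive counting, computes projection coverage at the
#' configured subset sizes, renders a comparison report, and checks every
#' declared expectation.
#'
#' @param config a [read_case_study_config()] object or a path to one.
#' @param verbose print the report and check table (default `TRUE`).
#' @return an object of class `case_study_result`: list with `name`, `ok`
#'   (all expectations met), `checks` (data frame: check, expected, actual,
#'   pass), `comparison`, and `report` (character lines).
#' @export
run_case_study <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_case_study_config(config)
  stopifnot(inherits(config, "case_study_config"))
  designs <- list(
    baseline = resolve_design_spec(config$baseline, config$base_dir),
    proposal = resolve_design_spec(config$proposal, config$base_dir)
  )
  # optional subset sampling for large designs: per design, per k
  cov_subsets <- NULL
  if (!is.null(config$sample_subsets)) {
    cov_subsets <- list()
    for (nm in names(config$sample_subsets)) {
      sc <- config$sample_subsets[[nm]]
      set.seed(sc$seed %||% 1L)
      labs <- designs[[nm]]$labels
      cov_subsets[[nm]] <- list()
      for (k in config$k_values) {
        size <- sc$size %||% 200L
        cov_subsets[[nm]][[as.character(k)]] <-
          sample_factor_subsets(labs, k, size)
      }
    }
  }
  comparison <- compare_designs(designs, config$k_values,
                                baseline = "baseline",
                                coverage_subsets = cov_subsets)
  exp <- config$expectations
  checks <- list()
  add <- function(name, expected, actual) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, expected = as.character(expected),
      actual = as.character(actual),
      pass = isTRUE(all.equal(as.numeric(expected), as.numeric(actual))),
      stringsAsFactors = FALSE)
  }
  if (!is.null(exp)) {
    for (nm in names(exp$runs %||% list())) {
      add(paste0("runs.", nm), exp$runs[[nm]], designs[[nm]]$runs)
    }
    if (!is.null(exp$reduction_pct)) {
      add("reduction_pct", exp$reduction_pct,
          comparison$reduction_pct[["proposal"]])
    }
    for (nm in names(exp$strength %||% list())) {
      sr <- verify_strength(designs[[nm]], as.integer(exp$strength[[nm]]),
                            compute_max = FALSE)
      add(paste0("strength.", nm, ".holds"), 1L, as.integer(sr$holds))
    }
    for (nm in names(exp$coverage %||% list())) {
      for (kk in names(exp$coverage[[nm]])) {
        add(paste0("coverage.", nm, ".k", kk), exp$coverage[[nm]][[kk]],
            comparison$coverage[kk, nm])
      }
    }
  }
  checks <- if (length(checks)) do.call(rbind, checks) else
    data.frame(check = character(0), expected = character(0),
               actual = character(0), pass = logical(0))
  report <- c(sprintf("## Case study: %s", config$name), "",
              render_report(comparison))
  result <- structure(
    list(name = config$name, ok = all(checks$pass), checks = checks,
         comparison = comparison, report = report),
    class = "case_study_result"
  )
  if (verbose) print(result)
  invisible(result)
}

#' @export
print.case_study_result <- function(x, ...) {
  cat(x$report, sep = "\n")
  cat("\nSelf-checks:\n")
  if (nrow(x$checks)) {
    status <- ifelse(x$checks$pass, "ok", "MISMATCH")
    cat(sprintf("  [%-8s] %-24s expected %-8s actual %s\n", status,
                x$checks$check, x$checks$expected, x$checks$actual),
        sep = "")
  }
  cat(if (x$ok) "All expectations met.\n" else "EXPECTATION MISMATCH.\n")
  invisible(x)
}

#' Fixed random sample of factor subsets
#'
#' Draws `size` distinct `k`-subsets of `labels` under the current RNG
#' state (callers `set.seed` first for reproducibility). Used to sample
#' projections of designs too large for full enumeration at a given `k`.
#'
#' @param labels factor labels.
#' @param k subset size.
#' @param size number of subsets (capped at `choose(n, k)`).
#' @return list of character vectors.
#' @export
sample_factor_subsets <- function(labels, k, size) {
  n <- length(labels)
  total <- choose(n, k)
  size <- min(size, total)
  seen <- character(0)
  out <- list()
  while (length(out) < size) {
    s <- sort(sample.int(n, k))
    key <- paste(s, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- labels[s]
  }
  out
}

#' Paths of the shipped case-study configs
#'
#' @param name one of `"quit"`, `"hsv1"`, `"npi"`, or `NULL` for all.
#' @return file path(s) under the installed package's `extdata/`.
#' @export
case_study_config_path <- function(name = NULL) {
  dir <- system.file("extdata", package = "hiddenproj")
  all <- c(quit = "quit.yaml", hsv1 = "hsv1.yaml", npi = "npi.yaml")
  if (is.null(name)) return(file.path(dir, all))
  if (!name %in% names(all)) {
    stop("unknown case study '", name, "'; have: ",
         paste(names(all), collapse = ", "), call. = FALSE)
  }
  file.path(dir, all[[name]])
}
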