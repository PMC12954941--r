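# Shared fixture designs, all constructed in code. The large 420-run
# objects are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

oa12 <- function() cached("oa12", hadamard_to_oa(paley_type1(11), 6))
oa20 <- function() cached("oa20", hadamard_to_oa(paley_type1(19), 6))
oa28 <- function() cached("oa28", hadamard_to_oa(paley_type2(13), 6))
oa420 <- function() cached("oa420", hadamard_to_oa(paley_type1(419), 16))
h420 <- function() cached("h420", paley_type1(419))

regular16 <- function() {
  cached("regular16", build_regular(generator_set(4, c(E = "ABC", F = "ACD"))))
}

# the worked aliasing example: E = AB, F = AC
fig1_design <- function() {
  cached("fig1", build_regular(generator_set(4, c(E = "AB", F = "AC"))))
}

full_factorial <- function(k) build_regular(generator_set(k))

npi_generators <- "J=ABC,K=ADE,L=AFG,M=BDH,N=BEI,O=CDI,P=CFH"
regular512 <- function() {
  cached("regular512", build_regular(parse_generators(npi_generators, 9)))
}

# independent strength oracle: count level combinations with base::table
# over pasted rows, no shared code with verify_strength's tabulate path
oracle_strength_holds <- function(design, t) {
  M <- design$matrix
  N <- nrow(M)
  for (cols in utils::combn(ncol(M), t, simplify = FALSE)) {
    key <- apply(M[, cols, drop = FALSE], 1L, paste, collapse = "/")
    counts <- table(key)
    if (length(counts) != 2^t || any(counts != N / 2^t)) return(FALSE)
  }
  TRUE
}

# independent column oracle: elementwise product of named design columns
oracle_word_column <- function(design, word) {
  col <- rep(1L, design$runs)
  for (f in word) col <- col * design$matrix[, f]
  col
}

expect_design_equal <- function(a, b) {
  expect_identical(a$labels, b$labels)
  expect_identical(a$matrix, b$matrix)
}
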