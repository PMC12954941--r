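test_that("build_regular produces the stated run and factor counts", {
  d16 <- regular16()
  expect_identical(dim(d16), c(16L, 6L))
  expect_identical(d16$labels, c("A", "B", "C", "D", "E", "F"))

  d32 <- build_regular(generator_set(5, c(F = "ABCDE")))
  expect_identical(dim(d32), c(32L, 6L))

  d8 <- full_factorial(3)
  expect_identical(dim(d8), c(8L, 3L))
  expect_identical(nrow(unique(d8$matrix)), 8L)  # all runs distinct

  d512 <- regular512()
  expect_identical(dim(d512), c(512L, 16L))
})

test_that("base columns follow Yates order and generated columns obey words", {
  d <- regular16()
  expect_identical(d$matrix[1:4, "A"], c(-1L, 1L, -1L, 1L))
  expect_identical(d$matrix[1:4, "B"], c(-1L, -1L, 1L, 1L))
  expect_identical(d$matrix[, "E"], oracle_word_column(d, c("A", "B", "C")))
  expect_identical(d$matrix[, "F"], oracle_word_column(d, c("A", "C", "D")))
  # base-factor projection is the full factorial
  expect_identical(nrow(unique(d$matrix[, c("A", "B", "C", "D")])), 16L)
})

test_that("generator validation rejects malformed sets", {
  expect_error(generator_set(3, c(E = "AX")), "unknown factor")
  expect_error(generator_set(3, c(A = "BC")), "disjoint")
  expect_error(generator_set(3, "BC"), "label")
  expect_error(parse_generators("E-ABC", 3), "label=word")
})

test_that("defining contrast subgroup matches the hand-computed closures", {
  sg <- defining_contrast_subgroup(generator_set(4, c(E = "ABC", F = "ACD")))
  expect_setequal(sg$word, c("ABCE", "ACDF", "BDEF"))
  expect_identical(wordlength_pattern(sg), c(0L, 0L, 0L, 3L, 0L, 0L))
  expect_identical(resolution(sg), 4L)

  sg1 <- defining_contrast_subgroup(generator_set(5, c(F = "ABCDE")))
  expect_identical(sg1$word, "ABCDEF")
  expect_identical(resolution(sg1), 6L)

  sg0 <- defining_contrast_subgroup(generator_set(3))
  expect_identical(nrow(sg0), 0L)
  expect_identical(resolution(sg0), Inf)
})

test_that("subgroup closure: 2^g - 1 words, closed under products", {
  gen <- parse_generators(npi_generators, 9)
  sg <- defining_contrast_subgroup(gen)
  expect_identical(nrow(sg), 127L)
  expect_false(anyDuplicated(sg$word) > 0)
  labels <- attr(sg, "labels")
  words <- lapply(sg$word, function(s) as.character(parse_word(s, labels)))
  keys <- vapply(words, word_string, "")
  set.seed(7)
  for (i in sample(length(words), 25)) {
    j <- sample(length(words), 1)
    prod <- word_mul(words[[i]], words[[j]], labels)
    # product of two subgroup elements is the identity or another element
    expect_true(word_string(prod) %in% c("I", keys))
  }
  # reconstruction for the 16-factor case attains resolution IV
  expect_identical(resolution(sg), 4L)
})

test_that("column identity oracle: every defining word multiplies to +1", {
  for (case in list(list(d = regular16(),
                         gen = generator_set(4, c(E = "ABC", F = "ACD"))),
                    list(d = regular512(),
                         gen = parse_generators(npi_generators, 9)))) {
    sg <- defining_contrast_subgroup(case$gen)
    labels <- attr(sg, "labels")
    for (s in sg$word) {
      w <- as.character(parse_word(s, labels))
      expect_true(all(oracle_word_column(case$d, w) == 1L))
    }
  }
})

test_that("signed generators propagate to the design and subgroup", {
  gen <- generator_set(3, c(D = "-ABC"))
  d <- build_regular(gen)
  expect_identical(d$matrix[, "D"], -oracle_word_column(d, c("A", "B", "C")))
  sg <- defining_contrast_subgroup(gen)
  expect_identical(sg$word, "ABCD")
  expect_identical(sg$sign, -1L)
  expect_true(all(oracle_word_column(d, c("A", "B", "C", "D")) == -1L))
})

test_that("alias_words returns the full alias class", {
  sg_fig1 <- defining_contrast_subgroup(generator_set(4, c(E = "AB", F = "AC")))
  expect_true("E" %in% alias_words("AB", sg_fig1))

  sg <- defining_contrast_subgroup(generator_set(4, c(E = "ABC", F = "ACD")))
  cls <- alias_words("AB", sg)
  expect_true("CE" %in% cls)
  expect_identical(cls[1], "AB")
  # aliased words have identical model-matrix columns (unsigned generators)
  d <- regular16()
  expect_identical(oracle_word_column(d, c("A", "B")),
                   oracle_word_column(d, c("C", "E")))

  sg0 <- defining_contrast_subgroup(generator_set(3))
  expect_identical(as.character(alias_words("A", sg0)), "A")
})

test_that("regular designs have strength resolution - 1", {
  expect_identical(max_strength(regular16()), 3L)   # resolution IV
  d32 <- build_regular(generator_set(5, c(F = "ABCDE")))
  expect_identical(max_strength(d32), 5L)           # resolution VI
})
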