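test_that("verify_strength counts exhaustively and finds the maximum", {
  sr <- verify_strength(oa12(), 2)
  expect_true(sr$holds)
  expect_identical(sr$max_t, 2L)  # 12 is not divisible by 8

  expect_true(verify_strength(full_factorial(3), 3)$holds)
  expect_identical(max_strength(full_factorial(3)), 3L)

  sr16 <- verify_strength(regular16(), 3)
  expect_true(sr16$holds)
  expect_identical(sr16$max_t, 3L)

  expect_error(verify_strength(oa12(), 0), "t must be")
  expect_error(verify_strength(oa12(), 7), "t must be")
})

test_that("strength verification matches the independent counting oracle", {
  designs <- list(oa12(), regular16(), full_factorial(3), fig1_design())
  for (d in designs) {
    for (t in 1:3) {
      expect_identical(verify_strength(d, t, compute_max = FALSE)$holds,
                       oracle_strength_holds(d, t))
    }
  }
})

test_that("a failing strength check reports a faithful witness", {
  # 4 runs, second column constant: pairs (.,-1) never occur
  d <- make_design(cbind(c(-1L, 1L, -1L, 1L), rep(1L, 4)))
  sr <- verify_strength(d, 2, compute_max = FALSE)
  expect_false(sr$holds)
  w <- sr$witness
  expect_length(w$columns, 2L)
  expect_identical(w$expected, 1L)
  # the reported count is what the design actually contains
  cols <- match(w$columns, d$labels)
  hits <- sum(apply(d$matrix[, cols, drop = FALSE], 1,
                    function(r) all(r == w$levels)))
  expect_identical(hits, as.integer(w$count))
})

test_that("projection full-rank tests reproduce the worked examples", {
  expect_false(is_full_rank_projection(fig1_design(), c("A", "B", "E"))$full_rank)
  expect_true(is_full_rank_projection(oa12(), c("A", "B", "E"))$full_rank)

  pr <- is_full_rank_projection(regular16(), c("A", "B", "C", "E"))
  expect_false(pr$full_rank)
  expect_identical(pr$rank, 8L)
  expect_identical(pr$p, 11L)

  expect_true(is_full_rank_projection(oa12(), "A")$full_rank)

  # p > N: model larger than run count reports rank deficiency, not an error
  pr5 <- is_full_rank_projection(oa12(), default_labels(5))
  expect_false(pr5$full_rank)
  expect_identical(pr5$p, 16L)
  expect_lte(pr5$rank, 12L)
})

test_that("projection coverage enumerates subsets and lists deficiencies", {
  expect_identical(projection_coverage(oa12(), 3)$coverage_pct, 100)
  rep4 <- projection_coverage(oa12(), 4)
  expect_identical(rep4$coverage_pct, 100)
  expect_identical(rep4$total_subsets, 15)

  rep16 <- projection_coverage(regular16(), 4)
  expect_identical(rep16$coverage_pct, 80)
  expect_identical(rep16$full_rank_count, 12L)
  expect_setequal(vapply(rep16$deficient_subsets, word_string, ""),
                  c("ABCE", "ACDF", "BDEF"))
})

test_that("coverage is monotone: full coverage at k implies it below k", {
  for (d in list(oa12(), oa28())) {
    expect_identical(projection_coverage(d, 4)$coverage_pct, 100)
    for (j in 1:3) {
      expect_identical(projection_coverage(d, j)$coverage_pct, 100)
    }
  }
})

test_that("run-size guarantees follow the N mod 8 / mod 16 conditions", {
  expect_identical(cheng_guarantee(12, 6, 2), 4L)
  expect_identical(cheng_guarantee(16, 6, 2), NA_integer_)
  expect_identical(cheng_guarantee(24, 6, 3), 5L)
  expect_identical(cheng_guarantee(420, 16, 2), 4L)
  expect_identical(cheng_guarantee(12, 3, 2), NA_integer_)  # n too small
  expect_error(cheng_guarantee(12, 6, 4), "t = 2 or 3")
})

test_that("guarantee consistency holds for the 12- and 20-run arrays", {
  for (d in list(oa12(), oa20())) {
    t_ver <- verify_strength(d, 2, compute_max = FALSE)
    expect_true(t_ver$holds)
    g <- cheng_guarantee(d$runs, d$n_factors, 2)
    expect_identical(g, 4L)
    expect_identical(projection_coverage(d, g)$coverage_pct, 100)
  }
})

test_that("compare_designs reports coverage and run accounting", {
  cmp <- compare_designs(list(regular = regular16(), oa = oa12()),
                         k_values = c(3, 4), baseline = "regular")
  expect_identical(cmp$coverage["3", ], c(regular = 100, oa = 100))
  expect_identical(cmp$coverage["4", ], c(regular = 80, oa = 100))
  expect_identical(cmp$reduction_pct[["oa"]], 25L)
  expect_identical(cmp$strengths, c(regular = 3L, oa = 2L))

  # 512 -> 420 rounds to 18%; identical runs give 0%
  expect_identical(as.integer(round(100 * (512 - 420) / 512)), 18L)
  cmp0 <- compare_designs(list(a = oa12(), b = oa12()), 3, baseline = "a")
  expect_identical(cmp0$reduction_pct[["b"]], 0L)
})

test_that("sampled coverage subsets are honored and reported as such", {
  subs <- utils::combn(oa12()$labels, 4, simplify = FALSE)[1:5]
  rep_s <- projection_coverage(oa12(), 4, subsets = subs)
  expect_identical(rep_s$evaluated, 5L)
  expect_identical(rep_s$total_subsets, 15)
  expect_identical(rep_s$coverage_pct, 100)
  set.seed(3)
  drawn <- sample_factor_subsets(default_labels(16), 4, 25)
  expect_length(drawn, 25L)
  expect_false(anyDuplicated(vapply(drawn, paste, "", collapse = ",")) > 0)
})
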