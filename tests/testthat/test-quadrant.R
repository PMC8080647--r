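test_that("quadrant labels follow the sign pattern and the <=-low tie rule", {
  qa <- assign_quadrants(c(1, 1, -1, -1), c(1, -1, 1, -1),
                         split_method = "fixed", x_split = 0, y_split = 0)
  expect_identical(qa$data$quadrant, c("Q1", "Q4", "Q2", "Q3"))

  # identical points sit at the median on both axes -> all Q3
  qa2 <- assign_quadrants(rep(2, 5), rep(7, 5))
  expect_identical(unique(qa2$data$quadrant), "Q3")

  # hand-enumerated median example
  qa3 <- assign_quadrants(1:4, 4:1)
  expect_equal(qa3$x_split, 2.5)
  expect_identical(qa3$data$quadrant, c("Q2", "Q2", "Q4", "Q4"))

  expect_error(assign_quadrants(1:3, 3:1), "at least 4")
  expect_warning(qa4 <- assign_quadrants(c(1:4, NA), c(4:1, 2)), "excluded")
  expect_identical(nrow(qa4$data), 4L)
})

test_that("median splits halve each axis for tie-free even n", {
  set.seed(21)
  for (rep in 1:20) {
    n <- 2L * sample(3:30, 1)
    qa <- assign_quadrants(rnorm(n), rnorm(n))
    expect_identical(sum(qa$data$x > qa$x_split), n %/% 2L)
    expect_identical(sum(qa$data$y > qa$y_split), n %/% 2L)
    expect_identical(nrow(qa$data), n)   # quadrant counts sum to n
  }
})

test_that("contingency counts the target group against the rest", {
  qa <- assign_quadrants(c(-1, -1, 1, 1), c(-1, -1, 1, 1),
                         split_method = "fixed", x_split = 0, y_split = 0)
  ct <- quadrant_contingency(qa, c("sen", "sen", "non", "non"),
                             target_quadrant = "Q3", target_group = "sen")
  expect_identical(c(ct$a, ct$b, ct$c, ct$d), c(2L, 0L, 0L, 2L))

  # nobody in the target quadrant
  ct2 <- quadrant_contingency(qa, c("sen", "sen", "non", "non"),
                              target_quadrant = "Q2", target_group = "sen")
  expect_identical(c(ct2$a, ct2$c), c(0L, 0L))

  # all samples in Q1, groups of 3 and 5
  qa3 <- assign_quadrants(rep(1, 8), rep(1, 8), split_method = "fixed",
                          x_split = 0, y_split = 0)
  ct3 <- quadrant_contingency(qa3, rep(c("g1", "g2"), c(3, 5)),
                              target_quadrant = "Q1", target_group = "g1")
  expect_identical(c(ct3$a, ct3$b, ct3$c, ct3$d), c(3L, 0L, 5L, 0L))

  expect_error(quadrant_contingency(qa, rep("x", 4), target_group = "sen"),
               "absent")
  expect_error(quadrant_contingency(qa, c("a", "b", "c", "c"),
                                    target_group = "a"),
               "more than two")
  expect_warning(ct4 <- quadrant_contingency(qa, c("a", "b", "c", "c"),
                                             target_group = "a",
                                             other_group = "c"),
                 "excluded")
  expect_identical(ct4$a + ct4$b + ct4$c + ct4$d, 3L)
})

test_that("a separated cohort yields Q3 OR = Inf and Q1 OR = 0 for senescent", {
  st <- sim_scores(delta = 5, seed = 2, n_studies = 3, n_per_group = 6)
  # complete separation empties the off-diagonal quadrants (warned)
  scan <- suppressWarnings(enrichment_scan(st, target_group = "senescent"))
  df <- as.data.frame(scan)
  expect_identical(df$or[df$quadrant == "Q3" & df$group == "senescent"], Inf)
  expect_identical(df$or[df$quadrant == "Q1" & df$group == "senescent"], 0)
  # complementary group mirrors the pattern
  expect_identical(df$or[df$quadrant == "Q3" & df$group == "nonsenescent"], 0)
  expect_lt(df$p[df$quadrant == "Q3" & df$group == "senescent"], 1e-4)

  single <- enrichment_scan(st, target_group = "senescent",
                            quadrants = "Q3", both_groups = FALSE)
  expect_length(single$results, 1L)
})

test_that("randomly permuted labels reject at no more than the nominal rate", {
  st <- sim_scores(delta = 0, seed = 8, n_studies = 3, n_per_group = 5)
  n <- nrow(st)
  set.seed(99)
  reps <- 400
  qa <- assign_quadrants(st$TREXes, st$NCTFs)
  p <- replicate(reps, {
    g <- sample(st$group)
    ct <- quadrant_contingency(qa, g, target_quadrant = "Q3",
                               target_group = "senescent")
    fisher_exact_one_sided(ct)$p_value
  })
  rate <- mean(p <= 0.05)
  mc_se <- sqrt(0.05 * 0.95 / reps)
  expect_lte(rate, 0.05 + 2 * mc_se)
})

test_that("plot-data exports are deterministic tables with Inf serialized as text", {
  qa <- assign_quadrants(c(1, 1, -1, -1), c(1, -1, 1, -1),
                         split_method = "fixed", x_split = 0, y_split = 0)
  sc <- scatter_export(qa, c("a", "a", "b", "b"))
  expect_identical(nrow(sc), 4L)
  expect_identical(names(sc), c("sample", "x", "y", "quadrant", "group"))

  empty <- or_bar_export(list())
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("comparison", "quadrant", "group", "or", "ci_lower",
                    "ci_upper", "p") %in% names(empty)))

  st <- sim_scores(delta = 5, seed = 2)
  scan <- enrichment_scan(st, target_group = "senescent", quadrants = "Q3")
  bars <- or_bar_export(list(sen_vs_non = scan))
  f <- withr::local_tempfile(fileext = ".tsv")
  senquad:::.write_tsv(bars, f)
  txt <- readLines(f)
  expect_true(any(grepl("\tInf\t", txt)))   # boundary OR written as "Inf"
})
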