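test_that("z-standardization is per study with sample sd", {
  m <- matrix(c(1, 3), 1, dimnames = list("G1", c("s1", "s2")))
  co <- expression_cohort(m, data.frame(sample_id = c("s1", "s2"),
                                        study_id = "A"))
  z <- zstandardize(co)
  expect_equal(unname(z$values[1, ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  # constant gene is dropped (NA) with a warning, not coerced to 0
  m2 <- rbind(G1 = c(1, 3, 2), G2 = c(5, 5, 5))
  colnames(m2) <- paste0("s", 1:3)
  co2 <- expression_cohort(m2, data.frame(sample_id = paste0("s", 1:3),
                                          study_id = "A"))
  expect_warning(z2 <- zstandardize(co2), "zero-variance")
  expect_true(all(is.na(z2$values["G2", ])))
  expect_false(anyNA(z2$values["G1", ]))

  # per-study standardization removes between-study offsets
  m3 <- cbind(matrix(c(1, 5, 2, 6), 2), matrix(c(1, 5, 2, 6), 2) + 100)
  dimnames(m3) <- list(c("G1", "G2"), paste0("s", 1:4))
  co3 <- expression_cohort(m3, data.frame(sample_id = paste0("s", 1:4),
                                          study_id = c("A", "A", "B", "B")))
  z3 <- zstandardize(co3)$values
  expect_equal(z3[, 1:2], z3[, 3:4], ignore_attr = TRUE)

  # a study with fewer than 2 samples is refused by name
  co4 <- expression_cohort(m2[, 1:2], data.frame(
    sample_id = c("s1", "s2"), study_id = c("A", "B")))
  expect_error(zstandardize(co4), "fewer than 2 samples.*A")
})

test_that("z output has mean 0 / sd 1 per (gene, study) and is affine-invariant", {
  set.seed(11)
  n_g <- 10; ids <- paste0("s", 1:12)
  m <- matrix(rnorm(n_g * 12, 8), n_g, 12,
              dimnames = list(paste0("G", 1:n_g), ids))
  m[sample(length(m), 8)] <- NA   # missing entries stay missing
  md <- data.frame(sample_id = ids, study_id = rep(c("A", "B"), each = 6))
  co <- expression_cohort(m, md)
  z <- zstandardize(co)$values
  for (s in c("A", "B")) {
    zs <- z[, md$study_id == s]
    expect_equal(unname(rowMeans(zs, na.rm = TRUE)), rep(0, n_g),
                 tolerance = 1e-9)
    expect_equal(unname(apply(zs, 1, sd, na.rm = TRUE)), rep(1, n_g),
                 tolerance = 1e-9)
  }
  expect_identical(is.na(z), is.na(m))

  # per-gene affine transform within a study leaves z unchanged
  m2 <- m
  m2[3, md$study_id == "A"] <- 2.5 * m2[3, md$study_id == "A"] + 7
  z2 <- zstandardize(expression_cohort(m2, md))$values
  expect_equal(z2, z, tolerance = 1e-9)
})

test_that("gene-set scores are means of available member z-values", {
  m <- rbind(G1 = c(1, -1), G2 = c(-1, 3))
  colnames(m) <- c("s1", "s2")
  co <- expression_cohort(m, data.frame(sample_id = c("s1", "s2"),
                                        study_id = "A"))
  co$zscaled <- TRUE   # treat the toy values as already standardized
  gs <- geneset_score(co, c("G1", "G2"))
  expect_equal(unname(gs$score), c(0, 1))
  expect_equal(gs$coverage, 1)

  # 2 of 4 members present: coverage 0.5, mean over the available two
  gs2 <- geneset_score(co, c("G1", "G2", "G3", "G4"), min_coverage = 0.4)
  expect_equal(gs2$coverage, 0.5)
  expect_equal(unname(gs2$score), c(0, 1))
  expect_setequal(gs2$missing, c("G3", "G4"))
  expect_warning(geneset_score(co, c("G1", "G2", "G3", "G4", "G5")),
                 "coverage")   # 2 of 5 members: below the 0.5 default

  # single-gene set score equals that gene's z-value; matching ignores case
  gs3 <- geneset_score(co, "g1")
  expect_equal(unname(gs3$score), unname(m["G1", ]))

  expect_error(geneset_score(co, c("X1", "X2")), "zero genes")
})

test_that("score_table copies metadata, reports coverage, and validates names", {
  st <- sim_scores(delta = 0, seed = 3)
  expect_true(all(c("sample_id", "study_id", "group", "TREXes", "NCTFs")
                  %in% names(st)))
  expect_equal(attr(st, "coverage"), c(TREXes = 1, NCTFs = 1))
  expect_false(anyNA(st$TREXes))

  sim <- simulate_cohort(simulation_params(n_studies = 2,
                                           n_per_group_per_study = 3,
                                           n_background_genes = 5, seed = 1))
  z <- zstandardize(sim$cohort)
  reg <- default_registry()
  expect_error(score_table(z, reg, c("TREXes", "nope")), "unknown gene set")
  expect_warning(st2 <- score_table(z, reg, character(0)), "no gene sets")
  expect_false("TREXes" %in% names(st2))
  expect_warning(st3 <- score_table(z, reg, c("TREXes", "TREXes")),
                 "duplicate")
  expect_identical(sum(names(st3) == "TREXes"), 1L)
})

test_that("supergroup score is the size-weighted mean of category scores", {
  st_sets <- local({
    sim <- simulate_cohort(simulation_params(n_studies = 2,
                                             n_per_group_per_study = 4,
                                             n_background_genes = 10,
                                             seed = 5))
    z <- zstandardize(sim$cohort)
    score_table(z, default_registry(), c("NCTFs", "NPC", "NTR", "RAN"))
  })
  weighted <- (31 * st_sets$NPC + 11 * st_sets$NTR + 4 * st_sets$RAN) / 46
  expect_equal(st_sets$NCTFs, weighted, tolerance = 1e-12)
})

test_that("comparative-Ct fold changes follow 2^(-ddct)", {
  expect_equal(ddct_relative_expression(20, 20, 20, 20), 1.0)
  expect_equal(ddct_relative_expression(26, 18, 25, 18), 0.5)
  expect_equal(ddct_relative_expression(21, 18, 23, 18), 4.0)
  expect_error(ddct_relative_expression(Inf, 18, 25, 18), "finite")
  expect_error(ddct_relative_expression(NA, 18, 25, 18), "finite")
})
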