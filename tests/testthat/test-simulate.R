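test_that("simulation is reproducible from its seed and truth is consistent", {
  p <- simulation_params(n_studies = 2, n_per_group_per_study = 3,
                         n_background_genes = 15, seed = 123)
  s1 <- simulate_cohort(p)
  s2 <- simulate_cohort(p)
  expect_identical(s1$cohort$values, s2$cohort$values)
  expect_identical(s1$truth$samples, s2$truth$samples)

  expect_identical(dim(s1$cohort$values),
                   c(29L + 46L + 2L + 15L, 2L * 2L * 3L))
  expect_identical(s1$truth$samples$sample_id, s1$cohort$metadata$sample_id)
  expect_identical(sum(s1$truth$genes$is_target), 75L)
  expect_identical(s1$truth$genes$gene_id[s1$truth$genes$is_marker],
                   c("CDKN1A", "CDKN2A"))
  # balanced groups within every study
  tb <- table(s1$truth$samples$study_id, s1$truth$samples$group)
  expect_true(all(tb == 3L))

  s3 <- simulate_cohort(simulation_params(n_studies = 2,
                                          n_per_group_per_study = 3,
                                          n_background_genes = 15,
                                          seed = 124))
  expect_false(identical(s1$cohort$values, s3$cohort$values))
})

test_that("invalid simulation parameters are rejected before generation", {
  expect_error(simulation_params(n_studies = 0), ">= 1")
  expect_error(simulation_params(delta = -1), ">= 0")
  expect_error(simulation_params(rho = 1), "rho")
  expect_error(simulation_params(sigma = 0), "> 0")
  expect_error(simulation_params(tau = -0.1), ">= 0")
  expect_error(simulate_cohort(list(delta = 1)), "simulation_params")
})

test_that("null model has exchangeable groups and marker genes shift upward", {
  # under delta = 0, rho = 0, tau = 0 a per-gene two-sample t rejects at
  # roughly the nominal rate
  set.seed(31)
  seeds <- sample.int(1e6, 300)
  pvals <- vapply(seeds, function(s) {
    sim <- simulate_cohort(simulation_params(
      n_studies = 1, n_per_group_per_study = 8, n_background_genes = 1,
      delta = 0, delta_marker = 0, rho = 0, tau = 0, seed = s))
    x <- sim$cohort$values["THOC1", ]
    g <- sim$cohort$metadata$group
    t.test(x[g == "senescent"], x[g == "nonsenescent"])$p.value
  }, numeric(1))
  rate <- mean(pvals <= 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)

  # markers move up while targets move down in the senescent group
  sim <- simulate_cohort(simulation_params(n_studies = 4,
                                           n_per_group_per_study = 10,
                                           delta = 1, delta_marker = 1,
                                           seed = 77))
  g <- sim$cohort$metadata$group
  v <- sim$cohort$values
  mdiff <- rowMeans(v[, g == "senescent"]) - rowMeans(v[, g == "nonsenescent"])
  expect_lt(mean(mdiff[sim$truth$genes$is_target]), -0.6)
  expect_gt(mean(mdiff[sim$truth$genes$is_marker]), 0.6)
})

test_that("rho controls within-set gene-gene correlation", {
  cors <- vapply(c(0, 0.8), function(r) {
    sim <- simulate_cohort(simulation_params(
      n_studies = 1, n_per_group_per_study = 60, n_background_genes = 1,
      delta = 0, rho = r, tau = 0, seed = 55))
    npc <- sim$truth$genes$gene_id[sim$truth$genes$category %in% "NPC"]
    cm <- cor(t(sim$cohort$values[npc, ]))
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  expect_lt(abs(cors[1]), 0.05)           # rho = 0: no correlation
  expect_gt(cors[2], 0.5)                 # rho = 0.8: ~rho^2 = 0.64
  expect_lt(abs(cors[2] - 0.64), 0.1)
})

test_that("recovery_experiment summarizes replicates without averaging crashes", {
  res <- recovery_experiment(data.frame(delta = c(0, 2)), n_reps = 1,
                             base_params = simulation_params(
                               n_studies = 2, n_per_group_per_study = 4,
                               n_background_genes = 10),
                             seed = 7)
  expect_identical(nrow(res), 2L)
  expect_true(all(c("reject_rate", "mc_se", "mean_score_diff", "delta_hat")
                  %in% names(res)))
  expect_true(all(res$reject_rate %in% c(0, 1)))   # single replicate
  # strong effect separates, null mostly does not
  expect_identical(res$reject_rate[res$delta == 2], 1)
})
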