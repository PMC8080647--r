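#' Parameters for the synthetic multi-study cohort generator
#'
#' The generator emulates the statistical structure the quadrant analysis
#' assumes in pooled senescence cohorts: several small studies with
#' additive batch shifts, coordinated downregulation of the TREX/NCT target
#' genes in the senescent group, upregulated senescence markers
#' (CDKN1A/CDKN2A), and within-category gene-gene correlation
#' (multicollinearity) through one latent factor per functional category.
#'
#' Defaults describe a typical pooled in-vitro design: 5 studies of 6
#' senescent + 6 nonsenescent samples, 200 background genes, a one-residual-sd
#' downregulation (`delta = 1`) of target genes, an equal marker
#' upregulation, strong within-set correlation (`rho = 0.7`), unit batch sd
#' and unit residual sd.
#'
#' @param n_studies Number of study strata (>= 1).
#' @param n_per_group_per_study Samples per group per study (>= 1; groups
#'   are balanced within study).
#' @param n_background_genes Number of unrelated background genes.
#' @param registry Gene-set registry supplying the target (TREXes + NCTFs)
#'   and marker genes.
#' @param delta Downregulation of target genes in senescent samples, in
#'   residual-sd units (>= 0).
#' @param delta_marker Upregulation of marker genes in senescent samples,
#'   in residual-sd units (>= 0).
#' @param rho Latent-factor loading in `[0, 1)`; within-category gene-gene
#'   correlation is `rho^2` at `sigma = 1`.
#' @param tau Between-study batch standard deviation (>= 0).
#' @param sigma Residual standard deviation (> 0).
#' @param seed Integer RNG seed.
#' @return Object of class `"simulation_params"`.
#' @export
simulation_params <- function(n_studies = 5, n_per_group_per_study = 6,
                              n_background_genes = 200,
                              registry = default_registry(),
                              delta = 1, delta_marker = 1, rho = 0.7,
                              tau = 1, sigma = 1, seed = 1) {
  p <- list(n_studies = n_studies,
            n_per_group_per_study = n_per_group_per_study,
            n_background_genes = n_background_genes, registry = registry,
            delta = delta, delta_marker = delta_marker, rho = rho,
            tau = tau, sigma = sigma, seed = seed)
  with(p, {
    stopifnot(inherits(registry, "gene_set_registry"))
    if (!all(c(n_studies, n_per_group_per_study, n_background_genes) >= 1))
      stop("counts must be >= 1")
    if (delta < 0 || delta_marker < 0) stop("effects must be >= 0")
    if (rho < 0 || rho^2 >= 1) stop("rho must satisfy 0 <= rho^2 < 1")
    if (tau < 0) stop("tau must be >= 0")
    if (sigma <= 0) stop("sigma must be > 0")
    if (!is.finite(seed)) stop("seed must be a finite integer")
  })
  structure(p, class = "simulation_params")
}

#' Simulate a multi-study senescence expression cohort
#'
#' Generative model for gene g in sample i of study s(i):
#' \deqn{x_{gi} = \mu_g + b_{s(i)} + \rho L_g f_{i,c(g)} + \delta_g(grp_i)
#'   + \sigma \sqrt{1 - \rho^2}\, e_{gi}}
#' with baseline abundance `mu_g ~ N(8, 1)` (log2 scale), batch shifts
#' `b_s ~ N(0, tau)`, one standard-normal latent factor per sample and
#' functional category (loading `L_g = 1` for genes of that category, 0 for
#' background and markers), group effect `-delta * sigma` for target genes
#' and `+delta_marker * sigma` for marker genes in senescent samples, and
#' iid standard-normal residuals. Groups are balanced within study; the
#' whole draw is reproducible from `seed`.
#'
#' @param params A [simulation_params()] object.
#' @return List with `cohort` (an [expression_cohort()] whose metadata has
#'   `group` labels `"senescent"` / `"nonsenescent"`) and `truth` (lists
#'   `samples`, `genes` with `is_target` / `is_marker` / `category`, and
#'   the realized `params`).
#' @export
#' @examples
#' sim <- simulate_cohort(simulation_params(n_studies = 2,
#'                                          n_per_group_per_study = 3,
#'                                          n_background_genes = 10))
#' sim$cohort
simulate_cohort <- function(params) {
  if (!inherits(params, "simulation_params"))
    stop("params must come from simulation_params()")
  reg <- params$registry
  categories <- intersect(c("TREX", "TREX2", "TREXAF", "NPC", "NTR", "RAN"),
                          names(reg$sets))
  if (length(categories) == 0L)
    stop("registry has none of the target categories")
  target_syms <- lapply(categories, function(n) reg$sets[[n]]$symbols)
  names(target_syms) <- categories
  target_genes <- unlist(target_syms, use.names = FALSE)
  if (anyDuplicated(target_genes))
    stop("target categories overlap; simulation assumes disjoint categories")
  markers <- if ("MARKER" %in% names(reg$sets)) reg$sets$MARKER$symbols
             else character(0)
  bg <- sprintf("BG%04d", seq_len(params$n_background_genes))
  genes <- c(target_genes, markers, bg)
  gene_cat <- c(rep(categories, lengths(target_syms)),
                rep(NA_character_, length(markers) + length(bg)))
  is_target <- genes %in% target_genes
  is_marker <- genes %in% markers
  G <- length(genes)

  npg <- params$n_per_group_per_study
  study <- rep(sprintf("S%02d", seq_len(params$n_studies)), each = 2 * npg)
  group <- rep(rep(c("senescent", "nonsenescent"), each = npg),
               params$n_studies)
  sample_id <- sprintf("%s_%s_%02d", study, ifelse(group == "senescent",
                                                   "sen", "non"),
                       sequence(rep(npg, 2 * params$n_studies)))
  N <- length(sample_id)

  set.seed(params$seed)
  mu <- stats::rnorm(G, mean = 8, sd = 1)
  b <- stats::rnorm(params$n_studies, 0, params$tau)
  f <- matrix(stats::rnorm(N * length(categories)), N, length(categories),
              dimnames = list(NULL, categories))
  e <- matrix(stats::rnorm(G * N), G, N)

  L <- matrix(0, G, length(categories), dimnames = list(genes, categories))
  for (cc in categories) L[gene_cat %in% cc, cc] <- 1

  sen <- as.numeric(group == "senescent")
  delta_g <- numeric(G)
  delta_g[is_target] <- -params$delta * params$sigma
  delta_g[is_marker] <- params$delta_marker * params$sigma

  x <- matrix(mu, G, N) +
    matrix(b[as.integer(factor(study, levels = unique(study)))],
           G, N, byrow = TRUE) +
    params$rho * (L %*% t(f)) +
    outer(delta_g, sen) +
    params$sigma * sqrt(1 - params$rho^2) * e
  dimnames(x) <- list(genes, sample_id)

  md <- data.frame(sample_id = sample_id, study_id = study, group = group,
                   stringsAsFactors = FALSE)
  truth <- list(samples = md,
                genes = data.frame(gene_id = genes, category = gene_cat,
                                   is_target = is_target,
                                   is_marker = is_marker,
                                   stringsAsFactors = FALSE),
                params = params)
  list(cohort = expression_cohort(x, md), truth = truth)
}

# invert the attenuation of a standardized group difference: if the raw
# effect is u = delta * sigma and the per-gene within-group variance is
# v = rho^2 + sigma^2 (1 - rho^2), the per-study standardized difference is
# D = u / sqrt(v + u^2 / 4) for balanced groups, hence
# u = D sqrt(v) / sqrt(1 - D^2 / 4).
.delta_from_zdiff <- function(D, rho, sigma) {
  v <- rho^2 + sigma^2 * (1 - rho^2)
  if (abs(D) >= 2) return(sign(D) * Inf)
  D * sqrt(v) / sqrt(1 - D^2 / 4) / sigma
}

#' Operating characteristics of the quadrant pipeline by simulation
#'
#' Runs `simulate -> z-standardize -> score -> quadrant Fisher test` for
#' each row of a parameter grid, `n_reps` times per row, and summarizes the
#' rejection rate of the target-quadrant test, the odds ratios, the mean
#' senescent-minus-control score difference (on the z scale) and an
#' attenuation-corrected estimate of `delta` recovered from it.
#'
#' @param param_grid data.frame whose columns override
#'   [simulation_params()] fields (e.g. a `delta` column).
#' @param n_reps Replicates per grid row (>= 1).
#' @param alpha Test level; a replicate rejects when `p <= alpha`.
#' @param base_params Baseline [simulation_params()]; per-row overrides are
#'   applied on top.
#' @param x_set,y_set Score columns used for the quadrant plane.
#' @param target_quadrant Quadrant whose enrichment of the senescent group
#'   is tested (default `"Q3"`).
#' @param seed Master seed for the replicate seed stream.
#' @return data.frame, one row per grid point: the grid columns plus
#'   `n_reps`, `reject_rate`, `mc_se` (binomial Monte-Carlo standard
#'   error), `mean_or_finite`, `n_or_inf`, `mean_score_diff`,
#'   `se_score_diff`, `delta_hat`.
#' @export
recovery_experiment <- function(param_grid, n_reps, alpha = 0.05,
                                base_params = simulation_params(),
                                x_set = "TREXes", y_set = "NCTFs",
                                target_quadrant = "Q3", seed = 20201) {
  stopifnot(is.data.frame(param_grid), nrow(param_grid) >= 1, n_reps >= 1)
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             nrow(param_grid) * n_reps),
                  nrow(param_grid), n_reps)
  reg <- base_params$registry
  out <- vector("list", nrow(param_grid))
  for (i in seq_len(nrow(param_grid))) {
    p <- unclass(base_params)
    for (col in names(param_grid)) p[[col]] <- param_grid[[col]][i]
    pvals <- ors <- diffs <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      p$seed <- seeds[i, r]
      sim <- simulate_cohort(do.call(simulation_params, p))
      z <- suppressWarnings(zstandardize(sim$cohort))
      st <- score_table(z, reg, c(x_set, y_set))
      qa <- assign_quadrants(st[[x_set]], st[[y_set]])
      ct <- quadrant_contingency(qa, st$group,
                                 target_quadrant = target_quadrant,
                                 target_group = "senescent")
      ft <- fisher_exact_one_sided(ct, alternative = "greater",
                                   alpha = alpha)
      pvals[r] <- ft$p_value
      ors[r] <- ft$or_cmle
      sen <- st$group == "senescent"
      diffs[r] <- mean(c(st[[x_set]][sen], st[[y_set]][sen])) -
        mean(c(st[[x_set]][!sen], st[[y_set]][!sen]))
    }
    rate <- mean(pvals <= alpha)
    D <- mean(diffs)
    out[[i]] <- cbind(
      param_grid[i, , drop = FALSE],
      data.frame(n_reps = n_reps, reject_rate = rate,
                 mc_se = sqrt(rate * (1 - rate) / n_reps),
                 mean_or_finite = mean(ors[is.finite(ors)]),
                 n_or_inf = sum(is.infinite(ors)),
                 mean_score_diff = D,
                 se_score_diff = stats::sd(diffs) / sqrt(n_reps),
                 delta_hat = -.delta_from_zdiff(D, p$rho, p$sigma)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
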