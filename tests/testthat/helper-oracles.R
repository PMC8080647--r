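# Independent oracles for exact 2x2 inference, plus small fixture builders.

# hypergeometric tail by direct enumeration of choose() products
oracle_p_greater <- function(a, b, c, d) {
  n <- a + b + c + d; K <- a + b; t <- a + c
  lo <- max(0, t - (n - K)); hi <- min(K, t)
  x <- lo:hi
  w <- choose(K, x) * choose(n - K, t - x)
  sum(w[x >= a]) / sum(w)
}

# conditional MLE by dense log-psi grid search with local refinement of the
# noncentral hypergeometric log-likelihood (independent of the package's
# expectation-equation root-finding)
oracle_cmle <- function(a, b, c, d, span = 25, ngrid = 2001) {
  n <- a + b + c + d; K <- a + b; t <- a + c
  lo <- max(0, t - (n - K)); hi <- min(K, t)
  if (a <= lo) return(0)
  if (a >= hi) return(Inf)
  x <- lo:hi
  logw <- lchoose(K, x) + lchoose(n - K, t - x)
  ll <- function(lp) {
    v <- logw + x * lp
    m <- max(v)
    a * lp - (m + log(sum(exp(v - m))))
  }
  lps <- seq(-span, span, length.out = ngrid)
  vals <- vapply(lps, ll, numeric(1))
  i <- which.max(vals)
  opt <- stats::optimize(ll, c(lps[max(1, i - 2)], lps[min(ngrid, i + 2)]),
                         maximum = TRUE, tol = 1e-12)
  exp(opt$maximum)
}

# random 2x2 tables with informative margins
random_tables <- function(n_tables, max_n = 40, seed = 42) {
  set.seed(seed)
  out <- vector("list", n_tables)
  k <- 0
  while (k < n_tables) {
    n <- sample(4:max_n, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = stats::runif(4, 0.05, 1)))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
    k <- k + 1
    out[[k]] <- cells
  }
  out
}

# tiny two-study cohort with known values
toy_cohort <- function() {
  m <- matrix(c(1, 3, 2, 4,    # G1
                5, 5, 6, 8,    # G2
                2, 1, 3, 9),   # G3
              nrow = 3, byrow = TRUE,
              dimnames = list(c("G1", "G2", "G3"), paste0("s", 1:4)))
  expression_cohort(m, data.frame(
    sample_id = paste0("s", 1:4),
    study_id = c("A", "A", "B", "B"),
    group = c("senescent", "nonsenescent", "senescent", "nonsenescent"),
    stringsAsFactors = FALSE))
}

# quick simulated score table for quadrant tests
sim_scores <- function(delta = 1, seed = 1, n_studies = 3,
                       n_per_group = 4, ...) {
  sim <- simulate_cohort(simulation_params(
    n_studies = n_studies, n_per_group_per_study = n_per_group,
    n_background_genes = 20, delta = delta, seed = seed, ...))
  z <- suppressWarnings(zstandardize(sim$cohort))
  score_table(z, sim$truth$params$registry, c("TREXes", "NCTFs"))
}
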