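# Exact inference for a 2x2 table conditional on both margins.
#
# With cells (a, b / c, d), condition on the margins: the first cell follows
# Fisher's noncentral hypergeometric distribution with parameters
# n = a+b+c+d, K = a+b (group-1 size), t = a+c (quadrant size) and odds
# ratio psi:
#   P_psi(X = x) prop. choose(K, x) * choose(n-K, t-x) * psi^x
# on the support max(0, t-(n-K)) .. min(K, t). The conditional MLE of psi
# solves E_psi[X] = a (monotone in psi); the exact one-sided lower
# confidence bound solves P_psi(X >= a) = alpha.

.nchg_setup <- function(a, b, c, d) {
  n <- a + b + c + d
  K <- a + b
  t <- a + c
  lo <- max(0L, t - (n - K))
  hi <- min(K, t)
  x <- lo:hi
  list(n = n, K = K, t = t, lo = lo, hi = hi, x = x,
       logdc = lchoose(K, x) + lchoose(n - K, t - x))
}

.nchg_dens <- function(sup, log_psi) {
  d <- sup$logdc + sup$x * log_psi
  d <- exp(d - max(d))
  d / sum(d)
}

.nchg_mean <- function(sup, log_psi) {
  sum(sup$x * .nchg_dens(sup, log_psi))
}

.nchg_upper <- function(sup, log_psi, a) sum(.nchg_dens(sup, log_psi)[sup$x >= a])
.nchg_lower <- function(sup, log_psi, a) sum(.nchg_dens(sup, log_psi)[sup$x <= a])

# expand a bracket on log psi until f changes sign, then uniroot
.nchg_root <- function(f, tol = 1e-12) {
  lo <- -1; hi <- 1
  flo <- f(lo); fhi <- f(hi)
  while (flo * fhi > 0 && hi < 745) {   # exp(745) ~ double overflow edge
    lo <- lo * 2; hi <- hi * 2
    flo <- f(lo); fhi <- f(hi)
  }
  if (flo * fhi > 0) stop("root bracketing failed for noncentral hypergeometric")
  exp(stats::uniroot(f, c(lo, hi), tol = tol)$root)
}

.nchg_cmle <- function(sup, a) {
  if (a <= sup$lo) return(0)
  if (a >= sup$hi) return(Inf)
  .nchg_root(function(lp) .nchg_mean(sup, lp) - a)
}

# exact one-sided lower bound: P_psi(X >= a) = alpha (increasing in psi)
.nchg_ci_lower <- function(sup, a, alpha) {
  if (a <= sup$lo) return(0)
  .nchg_root(function(lp) .nchg_upper(sup, lp, a) - alpha, tol = 1e-14)
}

# exact one-sided upper bound: P_psi(X <= a) = alpha (decreasing in psi)
.nchg_ci_upper <- function(sup, a, alpha) {
  if (a >= sup$hi) return(Inf)
  .nchg_root(function(lp) .nchg_lower(sup, lp, a) - alpha, tol = 1e-14)
}

.as_2x2 <- function(table) {
  if (inherits(table, "contingency_2x2"))
    cells <- c(table$a, table$b, table$c, table$d)
  else if (is.matrix(table) && all(dim(table) == c(2L, 2L)))
    cells <- c(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  else if (is.numeric(table) && length(table) == 4L)
    cells <- as.vector(table)
  else stop("table must be a contingency_2x2, a 2x2 matrix, or c(a, b, c, d)")
  if (any(cells < 0) || any(abs(cells - round(cells)) > 1e-8))
    stop("2x2 cells must be nonnegative integers")
  as.integer(round(cells))
}

#' Exact Fisher test for a 2x2 table with conditional-MLE odds ratio
#'
#' Exact inference for a 2x2 contingency table `(a, b / c, d)` conditional
#' on both margins. The p-value for `alternative = "greater"` is the upper
#' hypergeometric tail `P(X >= a)`; the odds-ratio estimate is the
#' conditional maximum-likelihood estimate (the value maximizing Fisher's
#' noncentral hypergeometric likelihood; 0 or `Inf` when `a` sits at the
#' support boundary), and the confidence bound is the exact one-sided bound
#' solving `P_psi(X >= a) = alpha` (the upper limit is `Inf` for
#' `"greater"`). These are the conventions of classical exact 2x2 analysis,
#' so the printed `OR` and one-sided `CI lower–Inf` agree with
#' [stats::fisher.test()]. `"less"` is the mirror image; `"two.sided"` uses
#' the point-probability method for the p-value and `alpha/2` bounds on each
#' side.
#'
#' A table with an empty margin carries no information about the odds ratio:
#' p = 1 and the estimate and bounds are `NA`, with a warning.
#'
#' @param table A `"contingency_2x2"` (see [quadrant_contingency()]), a 2x2
#'   matrix, or a numeric vector `c(a, b, c, d)`.
#' @param alternative `"greater"` (default; over-enrichment of cell `a`),
#'   `"less"`, or `"two.sided"`.
#' @param alpha One-sided test level; the confidence level is `1 - alpha`.
#' @return Object of class `"quadrant_fisher"`: the table, `p_value`,
#'   `or_cmle`, `ci_lower`, `ci_upper`, `alpha`, `alternative`. Has `print`,
#'   `coef` and `confint` methods.
#' @export
#' @examples
#' f <- fisher_exact_one_sided(c(3, 1, 1, 3))
#' f$p_value            # 17/70
#' coef(f)              # conditional-MLE odds ratio ~ 6.41
fisher_exact_one_sided <- function(table, alternative = c("greater", "less",
                                                          "two.sided"),
                                   alpha = 0.05) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  cells <- .as_2x2(table)
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  tb <- matrix(cells, 2, byrow = TRUE,
               dimnames = list(group = c("target", "other"),
                               quadrant = c("in", "out")))
  if ((a + b) == 0L || (c + d) == 0L || (a + c) == 0L || (b + d) == 0L) {
    warning("empty margin: odds ratio undefined, p = 1")
    return(structure(list(table = tb, p_value = 1, or_cmle = NA_real_,
                          ci_lower = NA_real_, ci_upper = NA_real_,
                          alpha = alpha, alternative = alternative),
                     class = "quadrant_fisher"))
  }
  sup <- .nchg_setup(a, b, c, d)
  d1 <- .nchg_dens(sup, 0)   # central (psi = 1)
  or <- .nchg_cmle(sup, a)
  if (alternative == "greater") {
    p <- sum(d1[sup$x >= a])
    ci <- c(.nchg_ci_lower(sup, a, alpha), Inf)
  } else if (alternative == "less") {
    p <- sum(d1[sup$x <= a])
    ci <- c(0, .nchg_ci_upper(sup, a, alpha))
  } else {
    p <- min(1, sum(d1[d1 <= d1[a - sup$lo + 1L] * (1 + 1e-7)]))
    ci <- c(.nchg_ci_lower(sup, a, alpha / 2),
            .nchg_ci_upper(sup, a, alpha / 2))
  }
  structure(list(table = tb, p_value = p, or_cmle = or,
                 ci_lower = ci[1], ci_upper = ci[2],
                 alpha = alpha, alternative = alternative),
            class = "quadrant_fisher")
}

#' @export
print.quadrant_fisher <- function(x, digits = 4, ...) {
  cat("Exact Fisher test (conditional MLE odds ratio)\n")
  print(x$table)
  cat(sprintf("alternative: %s, alpha = %g\n", x$alternative, x$alpha))
  cat(sprintf("OR = %s; %d%% CI %s-%s; p = %s\n",
              format(x$or_cmle, digits = digits),
              round(100 * (1 - x$alpha)),
              format(x$ci_lower, digits = digits),
              format(x$ci_upper, digits = digits),
              format.pval(x$p_value, digits = digits)))
  invisible(x)
}

#' @export
coef.quadrant_fisher <- function(object, ...) {
  c("odds ratio" = object$or_cmle)
}

#' @export
confint.quadrant_fisher <- function(object, parm, level, ...) {
  ci <- matrix(c(object$ci_lower, object$ci_upper), 1,
               dimnames = list("odds ratio", c("lower", "upper")))
  attr(ci, "conf.level") <- 1 - object$alpha
  ci
}
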