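#' Assign samples to score quadrants
#'
#' Partitions samples by two gene-set scores into the four quadrants of the
#' (x, y) plane at the score medians (or user-fixed splits): Q1 upper right
#' (x and y high), Q2 upper left, Q3 lower left (the senescence-enriched
#' quadrant), Q4 lower right. The tie rule is `value <= split` goes to the
#' low side, so all-identical scores land in Q3 and the assignment is
#' deterministic.
#'
#' @param x,y Numeric score vectors of equal length. Samples with a missing
#'   score on either axis are excluded with a warning (listwise deletion);
#'   at least 4 complete samples are required.
#' @param split_method `"median"` (splits at the medians of the included
#'   samples) or `"fixed"` (use `x_split` / `y_split`).
#' @param x_split,y_split Fixed split values, required for
#'   `split_method = "fixed"`.
#' @param sample_ids Optional sample identifiers.
#' @return Object of class `"quadrant_assignment"`: data.frame `data`
#'   (`sample`, `x`, `y`, `quadrant`), `x_split`, `y_split`,
#'   `split_method`, and `included` (logical over the input samples). Has
#'   `print` and `plot` methods.
#' @export
#' @examples
#' qa <- assign_quadrants(c(1, 1, -1, -1), c(1, -1, 1, -1),
#'                        split_method = "fixed", x_split = 0, y_split = 0)
#' qa$data$quadrant
assign_quadrants <- function(x, y, split_method = c("median", "fixed"),
                             x_split = NULL, y_split = NULL,
                             sample_ids = NULL) {
  split_method <- match.arg(split_method)
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (is.null(sample_ids)) sample_ids <- as.character(seq_along(x))
  keep <- is.finite(x) & is.finite(y)
  if (any(!keep))
    warning(sum(!keep), " sample(s) with absent scores excluded")
  if (sum(keep) < 4L) stop("need at least 4 samples with complete scores")
  xs <- x[keep]; ys <- y[keep]; ids <- sample_ids[keep]
  if (split_method == "median") {
    x_split <- stats::median(xs)
    y_split <- stats::median(ys)
  } else if (is.null(x_split) || is.null(y_split)) {
    stop("split_method = 'fixed' requires x_split and y_split")
  }
  xhigh <- xs > x_split
  yhigh <- ys > y_split
  quadrant <- ifelse(xhigh & yhigh, "Q1",
                     ifelse(!xhigh & yhigh, "Q2",
                            ifelse(!xhigh & !yhigh, "Q3", "Q4")))
  structure(list(data = data.frame(sample = ids, x = xs, y = ys,
                                   quadrant = quadrant,
                                   stringsAsFactors = FALSE),
                 x_split = x_split, y_split = y_split,
                 split_method = split_method, included = keep),
            class = "quadrant_assignment")
}

#' @export
print.quadrant_assignment <- function(x, ...) {
  cat(sprintf("<quadrant_assignment> %d samples, splits (%.4g, %.4g) [%s]\n",
              nrow(x$data), x$x_split, x$y_split, x$split_method))
  print(table(factor(x$data$quadrant, levels = paste0("Q", 1:4))))
  invisible(x)
}

#' @export
#' @rdname assign_quadrants
#' @param groups Optional group labels for coloring the scatter.
#' @param ... Passed to [graphics::plot()].
plot.quadrant_assignment <- function(x, groups = NULL, ...) {
  col <- 1
  if (!is.null(groups)) {
    g <- factor(groups[x$included])
    col <- as.integer(g) + 1L
  }
  graphics::plot(x$data$x, x$data$y, col = col, pch = 19,
                 xlab = "x score", ylab = "y score", ...)
  graphics::abline(v = x$x_split, h = x$y_split, lty = 2)
  if (!is.null(groups))
    graphics::legend("topleft", legend = levels(g), col = seq_along(levels(g)) + 1L,
                     pch = 19, bty = "n")
  invisible(x)
}

#' Quadrant-by-group 2x2 contingency table
#'
#' Counts `a` = target-group samples in the target quadrant, `b` =
#' target-group samples elsewhere, `c` = other-group samples in the target
#' quadrant, `d` = other-group samples elsewhere.
#'
#' @param assignment A [assign_quadrants()] result.
#' @param groups Group labels, aligned with the samples passed to
#'   `assign_quadrants` (samples it excluded are dropped here too).
#' @param target_quadrant One of `"Q1"`..`"Q4"`.
#' @param target_group The group whose enrichment is tested; must be
#'   present.
#' @param other_group Optional explicit comparison group. With exactly two
#'   distinct labels it defaults to the complement of `target_group`; with
#'   more than two labels it must be given, and samples with any other
#'   label are excluded with a warning.
#' @return Object of class `"contingency_2x2"` with fields `a`, `b`, `c`,
#'   `d`, `target_quadrant`, `target_group`, `other_group`.
#' @export
quadrant_contingency <- function(assignment, groups, target_quadrant = "Q3",
                                 target_group, other_group = NULL) {
  stopifnot(inherits(assignment, "quadrant_assignment"))
  target_quadrant <- match.arg(target_quadrant, paste0("Q", 1:4))
  if (length(groups) == length(assignment$included))
    groups <- groups[assignment$included]
  if (length(groups) != nrow(assignment$data))
    stop("groups must align with the samples given to assign_quadrants")
  groups <- as.character(groups)
  if (!target_group %in% groups)
    stop("target group '", target_group, "' absent from groups")
  labs <- unique(groups)
  if (is.null(other_group)) {
    if (length(labs) != 2L)
      stop("more than two group labels; specify other_group")
    other_group <- setdiff(labs, target_group)
  }
  keep <- groups %in% c(target_group, other_group)
  if (any(!keep))
    warning(sum(!keep), " sample(s) outside {", target_group, ", ",
            other_group, "} excluded")
  q <- assignment$data$quadrant[keep]
  g <- groups[keep]
  in_q <- q == target_quadrant
  tg <- g == target_group
  structure(list(a = sum(tg & in_q), b = sum(tg & !in_q),
                 c = sum(!tg & in_q), d = sum(!tg & !in_q),
                 target_quadrant = target_quadrant,
                 target_group = target_group, other_group = other_group),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(group = c(x$target_group, x$other_group),
                              quadrant = c(x$target_quadrant, "elsewhere")))
  print(m)
  invisible(x)
}

#' Quadrant enrichment scan over a score table
#'
#' For each requested quadrant, tests whether the target group is enriched
#' in that quadrant (exact one-sided Fisher test, conditional-MLE odds
#' ratio, exact one-sided confidence bound), and — for the paired-bar
#' displays — also tests the complementary group. The quadrant split is the
#' per-axis median over all included samples by default.
#'
#' @param scores A score table from [score_table()] (or any data.frame with
#'   the two score columns and the group column).
#' @param x_set,y_set Names of the score columns (defaults `"TREXes"`,
#'   `"NCTFs"`).
#' @param group_col Metadata column holding the two group labels.
#' @param target_group Label of the group of interest (e.g.
#'   `"senescent"`).
#' @param quadrants Quadrants to test (default all four).
#' @param alternative,alpha Passed to [fisher_exact_one_sided()].
#' @param split_method,x_split,y_split Passed to [assign_quadrants()].
#' @param both_groups Also report the complementary group's enrichment per
#'   quadrant (default `TRUE`).
#' @param other_group Passed to [quadrant_contingency()].
#' @return Object of class `"enrichment_scan"`: list of
#'   `"enrichment_result"` records (each holding the group, quadrant,
#'   `"contingency_2x2"` table and `"quadrant_fisher"` test), plus the
#'   `"quadrant_assignment"` and the included group labels. Has `print`,
#'   `summary` and `as.data.frame` methods.
#' @export
enrichment_scan <- function(scores, x_set = "TREXes", y_set = "NCTFs",
                            group_col = "group", target_group,
                            quadrants = paste0("Q", 1:4),
                            alternative = "greater", alpha = 0.05,
                            split_method = "median", x_split = NULL,
                            y_split = NULL, both_groups = TRUE,
                            other_group = NULL) {
  for (col in c(x_set, y_set, group_col))
    if (!col %in% names(scores))
      stop("score table has no column '", col, "'")
  quadrants <- match.arg(quadrants, paste0("Q", 1:4), several.ok = TRUE)
  ids <- if ("sample_id" %in% names(scores)) scores$sample_id else
    rownames(scores)
  qa <- assign_quadrants(scores[[x_set]], scores[[y_set]],
                         split_method = split_method,
                         x_split = x_split, y_split = y_split,
                         sample_ids = ids)
  groups <- as.character(scores[[group_col]])
  results <- list()
  for (q in quadrants) {
    ct <- quadrant_contingency(qa, groups, target_quadrant = q,
                               target_group = target_group,
                               other_group = other_group)
    groups_used <- c(ct$target_group, ct$other_group)
    test <- fisher_exact_one_sided(ct, alternative = alternative,
                                   alpha = alpha)
    results[[length(results) + 1L]] <-
      structure(list(quadrant = q, group = target_group, table = ct,
                     test = test), class = "enrichment_result")
    if (both_groups) {
      ct2 <- quadrant_contingency(qa, groups, target_quadrant = q,
                                  target_group = ct$other_group,
                                  other_group = target_group)
      test2 <- fisher_exact_one_sided(ct2, alternative = alternative,
                                      alpha = alpha)
      results[[length(results) + 1L]] <-
        structure(list(quadrant = q, group = ct$other_group, table = ct2,
                       test = test2), class = "enrichment_result")
    }
  }
  structure(list(results = results, assignment = qa,
                 groups = groups[qa$included],
                 x_set = x_set, y_set = y_set, target_group = target_group,
                 alternative = alternative, alpha = alpha),
            class = "enrichment_scan")
}

#' @export
as.data.frame.enrichment_scan <- function(x, ...) {
  rows <- lapply(x$results, function(r)
    data.frame(quadrant = r$quadrant, group = r$group,
               a = r$table$a, b = r$table$b, c = r$table$c, d = r$table$d,
               or = r$test$or_cmle, ci_lower = r$test$ci_lower,
               ci_upper = r$test$ci_upper, p = r$test$p_value,
               alpha = r$test$alpha, alternative = r$test$alternative,
               stringsAsFactors = FALSE))
  if (length(rows) == 0L)
    return(data.frame(quadrant = character(0), group = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), or = numeric(0),
                      ci_lower = numeric(0), ci_upper = numeric(0),
                      p = numeric(0), alpha = numeric(0),
                      alternative = character(0)))
  do.call(rbind, rows)
}

#' @export
print.enrichment_scan <- function(x, digits = 4, ...) {
  cat(sprintf("Quadrant enrichment: %s x %s, target group '%s' (%s)\n",
              x$x_set, x$y_set, x$target_group, x$alternative))
  df <- as.data.frame(x)
  df$or <- signif(df$or, digits)
  df$ci_lower <- signif(df$ci_lower, digits)
  df$p <- signif(df$p, digits)
  print(df[, c("quadrant", "group", "a", "b", "c", "d", "or", "ci_lower",
               "ci_upper", "p")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.enrichment_scan <- function(object, ...) {
  df <- as.data.frame(object)
  df$significant <- df$p <= df$alpha
  df
}

#' Plot-ready scatter table for a quadrant assignment
#'
#' @param assignment A `"quadrant_assignment"`.
#' @param groups Group labels aligned with the samples given to
#'   [assign_quadrants()].
#' @return data.frame with columns `sample`, `x`, `y`, `quadrant`, `group`.
#' @export
scatter_export <- function(assignment, groups) {
  stopifnot(inherits(assignment, "quadrant_assignment"))
  if (length(groups) == length(assignment$included))
    groups <- groups[assignment$included]
  cbind(assignment$data, data.frame(group = as.character(groups),
                                    stringsAsFactors = FALSE))
}

#' Plot-ready odds-ratio bar table for enrichment results
#'
#' One row per (comparison, quadrant, group) with counts, OR, exact CI and
#' p-value; infinite odds ratios serialize as `"Inf"` in TSV output.
#'
#' @param results An `"enrichment_scan"`, or a list of them (optionally
#'   named; names become the `comparison` column).
#' @return data.frame of bar data (empty with the full header for an empty
#'   list).
#' @export
or_bar_export <- function(results) {
  if (inherits(results, "enrichment_scan")) results <- list(results)
  nm <- names(results)
  if (is.null(nm)) nm <- as.character(seq_along(results))
  rows <- lapply(seq_along(results), function(i) {
    df <- as.data.frame(results[[i]])
    if (nrow(df)) cbind(comparison = nm[i], df, stringsAsFactors = FALSE)
    else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(cbind(data.frame(comparison = character(0)),
                 as.data.frame(structure(list(results = list()),
                                         class = "enrichment_scan"))))
  do.call(rbind, rows)
}
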