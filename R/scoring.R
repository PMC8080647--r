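#' Z-standardize expression within study strata
#'
#' For each gene within each study, centers and scales the non-missing
#' log2 expression values to mean 0, sample standard deviation 1
#' (`n - 1` denominator). Standardizing per study removes between-study
#' location/scale (batch) differences so that samples from different
#' studies can be pooled in the downstream quadrant analysis. With
#' `by_study = FALSE` the whole cohort is standardized as one stratum.
#'
#' Zero-variance (gene, study) cells are set to `NA` rather than 0, so they
#' cannot deflate gene-set scores; they are reported in a warning. Missing
#' entries stay missing.
#'
#' @param cohort An [expression_cohort()].
#' @param by_study Standardize within each `study_id` stratum (default) or
#'   over the pooled cohort.
#' @return The cohort on the z scale (`zscaled = TRUE`).
#' @export
#' @examples
#' m <- matrix(c(1, 3, 2, 6), 1, dimnames = list("G1", paste0("s", 1:4)))
#' co <- expression_cohort(m, data.frame(sample_id = paste0("s", 1:4),
#'                                       study_id = "S1"))
#' zstandardize(co)$values
zstandardize <- function(cohort, by_study = TRUE) {
  stopifnot(inherits(cohort, "expression_cohort"))
  x <- cohort$values
  strata <- if (by_study) cohort$metadata$study_id else
    rep("pooled", ncol(x))
  small <- names(which(table(strata) < 2))
  if (length(small))
    stop("study stratum with fewer than 2 samples: ",
         paste(small, collapse = ", "))
  z <- x
  dropped <- character(0)
  for (s in unique(strata)) {
    cols <- strata == s
    xs <- x[, cols, drop = FALSE]
    nn <- rowSums(!is.na(xs))
    mu <- rowMeans(xs, na.rm = TRUE)
    ss <- rowSums((xs - mu)^2, na.rm = TRUE)
    sd <- sqrt(ss / pmax(nn - 1, 1))
    bad <- nn < 2 | sd == 0 | !is.finite(sd)
    zs <- (xs - mu) / sd
    zs[bad, ] <- NA_real_
    z[, cols] <- zs
    if (any(bad))
      dropped <- c(dropped, paste0(rownames(xs)[bad], "@", s))
  }
  if (length(dropped))
    warning("zero-variance (gene, study) cells set to NA: ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) sprintf(" ... (%d total)",
                                              length(dropped)) else "")
  out <- cohort
  out$values <- z
  out$zscaled <- TRUE
  out
}

#' Score samples on a gene set
#'
#' The gene-set score of a sample is the arithmetic mean of the available
#' (non-missing) z-standardized expression values of the set's member genes
#' in that sample. Symbols are matched against the matrix gene ids exactly
#' but case-insensitively.
#'
#' @param zcohort A z-scale [expression_cohort()] (output of
#'   [zstandardize()]).
#' @param set A `"gene_set"`, or a character vector of gene symbols.
#' @param min_coverage Warn (not filter) if the fraction of set members
#'   found in the matrix falls below this value.
#' @return List with `score` (named per-sample numeric; `NA` where no
#'   member gene is available), `coverage`, `matched` and `missing`
#'   symbol vectors.
#' @export
geneset_score <- function(zcohort, set, min_coverage = 0.5) {
  stopifnot(inherits(zcohort, "expression_cohort"))
  if (!isTRUE(zcohort$zscaled))
    warning("cohort does not look z-standardized; scores assume z-scale input")
  sym <- if (inherits(set, "gene_set")) set$symbols else as.character(set)
  set_name <- if (inherits(set, "gene_set")) set$name else "<ad hoc>"
  if (length(sym) == 0L) stop("empty gene set")
  idx <- match(toupper(sym), toupper(rownames(zcohort$values)))
  matched <- sym[!is.na(idx)]
  missing <- sym[is.na(idx)]
  if (length(matched) == 0L)
    stop("gene set '", set_name, "' resolves to zero genes in the matrix")
  coverage <- length(matched) / length(sym)
  if (coverage < min_coverage)
    warning(sprintf("gene set '%s': coverage %.2f below min_coverage %.2f",
                    set_name, coverage, min_coverage))
  sub <- zcohort$values[idx[!is.na(idx)], , drop = FALSE]
  score <- colMeans(sub, na.rm = TRUE)
  score[!is.finite(score)] <- NA_real_
  list(score = score, coverage = coverage, matched = matched,
       missing = missing)
}

#' Score a cohort on several registry sets
#'
#' Vectorizes [geneset_score()] over registry set (or supergroup) names and
#' returns one row per sample with metadata carried through and one score
#' column per set.
#'
#' @param zcohort A z-scale [expression_cohort()].
#' @param registry A `"gene_set_registry"`.
#' @param set_names Character vector of set / supergroup names. Duplicates
#'   are collapsed with a warning; an empty vector yields a metadata-only
#'   table with a warning.
#' @param min_coverage Passed to [geneset_score()].
#' @return A data.frame ("score table"): the metadata columns followed by
#'   one numeric column per set, with a `"coverage"` attribute (named
#'   numeric).
#' @export
score_table <- function(zcohort, registry, set_names, min_coverage = 0.5) {
  stopifnot(inherits(zcohort, "expression_cohort"),
            inherits(registry, "gene_set_registry"))
  if (anyDuplicated(set_names)) {
    warning("duplicate set names collapsed: ",
            paste(unique(set_names[duplicated(set_names)]), collapse = ", "))
    set_names <- unique(set_names)
  }
  out <- zcohort$metadata
  if (length(set_names) == 0L) {
    warning("no gene sets requested: returning metadata-only table")
    attr(out, "coverage") <- numeric(0)
    return(out)
  }
  cov <- numeric(length(set_names))
  names(cov) <- set_names
  for (n in set_names) {
    sym <- geneset_members(registry, n)  # errors on unknown name
    gs <- geneset_score(zcohort, sym, min_coverage = min_coverage)
    out[[n]] <- unname(gs$score)
    cov[n] <- gs$coverage
  }
  attr(out, "coverage") <- cov
  out
}

#' Comparative-Ct (delta-delta-Ct) relative expression
#'
#' qPCR relative expression of a target gene in a case sample versus a
#' control sample, each normalized to a housekeeping gene:
#' `ddct = (ct_target_case - ct_housekeeping_case) -
#' (ct_target_control - ct_housekeeping_control)`, fold change
#' `2^(-ddct)`. Vectorized over its arguments.
#'
#' @param ct_target_case,ct_housekeeping_case Critical-cycle values in the
#'   case condition.
#' @param ct_target_control,ct_housekeeping_control Critical-cycle values in
#'   the control condition.
#' @return Fold change(s), `2^(-ddct)`.
#' @export
#' @examples
#' ddct_relative_expression(26, 18, 25, 18)  # one cycle later -> 0.5
ddct_relative_expression <- function(ct_target_case, ct_housekeeping_case,
                                     ct_target_control,
                                     ct_housekeeping_control) {
  ct <- c(ct_target_case, ct_housekeeping_case, ct_target_control,
          ct_housekeeping_control)
  if (!is.numeric(ct) || any(!is.finite(ct)) || any(ct <= 0))
    stop("all Ct values must be finite and > 0")
  ddct <- (ct_target_case - ct_housekeeping_case) -
    (ct_target_control - ct_housekeeping_control)
  2^(-ddct)
}
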