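# Deterministic cohort grouping rules for the tissue analyses: age decade
# and median dichotomies, age quartiles, tumor-stage dichotomies. All are
# pure functions of their inputs; exclusions are explicit labels, never
# silent drops.

#' Dichotomize samples by age decade
#'
#' Decades 50/60/70 form the old group, 20/30/40 the young group (matching
#' portals that report age only in 10-year bins); anything else is
#' `"excluded"` with a warning. Codes may be numeric (50) or strings such
#' as `"50"`, `"50-59"`, `"50s"`; `NA` is excluded.
#'
#' @param decades Vector of decade codes.
#' @return Character labels `"old"` / `"young"` / `"excluded"`.
#' @export
#' @examples
#' group_age_decades(c(20, 50))      # young, old
group_age_decades <- function(decades) {
  if (length(decades) == 0L) return(character(0))
  dec <- as.character(decades)
  num <- suppressWarnings(as.integer(sub("^\\s*([0-9]+).*$", "\\1", dec)))
  bad <- !is.na(decades) & is.na(num)
  if (any(bad))
    stop("unparseable age decade code(s): ",
         paste(unique(dec[bad]), collapse = ", "))
  lab <- rep("excluded", length(dec))
  lab[num %in% c(50L, 60L, 70L)] <- "old"
  lab[num %in% c(20L, 30L, 40L)] <- "young"
  if (any(lab == "excluded"))
    warning(sum(lab == "excluded"),
            " sample(s) outside the 20-70 decade range excluded")
  lab
}

#' Dichotomize samples at the median age
#'
#' `age > median` is `"old"`, `age <= median` is `"young"` (ties go young,
#' mirroring the quadrant tie rule). The median is computed from the data
#' unless given.
#'
#' @param ages Numeric ages (>= 2 finite values required).
#' @param median Optional fixed median override (e.g. a cohort median of
#'   62 years).
#' @return Character labels `"old"` / `"young"` with the median used as
#'   attribute `"median"`.
#' @export
#' @examples
#' group_age_median(c(60, 64), median = 62)   # young, old
group_age_median <- function(ages, median = NULL) {
  if (!is.numeric(ages) || any(!is.finite(ages)))
    stop("ages must be finite numeric values")
  if (length(ages) < 2L) stop("need at least 2 ages")
  if (is.null(median)) median <- stats::median(ages)
  lab <- ifelse(ages > median, "old", "young")
  attr(lab, "median") <- median
  lab
}

#' Assign samples to age quartiles
#'
#' Bins at the empirical 25/50/75 percentiles (default quantile definition);
#' `value <= boundary` goes to the lower bin. Labels run `A1` (youngest) to
#' `A4` (oldest); all-equal ages all land in `A1`.
#'
#' @param ages Numeric ages (>= 4 finite values required).
#' @return Character labels `A1`..`A4` with the boundaries as attribute
#'   `"boundaries"`.
#' @export
group_age_quartiles <- function(ages) {
  if (!is.numeric(ages) || any(!is.finite(ages)))
    stop("ages must be finite numeric values")
  if (length(ages) < 4L) stop("need at least 4 ages for quartiles")
  q <- stats::quantile(ages, c(0.25, 0.5, 0.75), names = FALSE)
  lab <- ifelse(ages <= q[1], "A1",
                ifelse(ages <= q[2], "A2",
                       ifelse(ages <= q[3], "A3", "A4")))
  attr(lab, "boundaries") <- q
  lab
}

#' Dichotomize tumors by pathologic stage
#'
#' Stage strings are normalized by stripping a leading `"stage"` token and
#' trailing substage letters (`IA -> I`, `IIIB -> III`). Scheme `"A"` calls
#' stage I (the only noninvasive, localized state) early and II/III/IV
#' late; scheme `"B"` calls I/II early and III/IV late (advanced). Stage 0,
#' stage X, and anything unparseable is `"excluded"` with a warning, never
#' coerced.
#'
#' @param stages Character vector of pathologic-stage annotations.
#' @param scheme `"A"` (I vs II-IV) or `"B"` (I-II vs III-IV).
#' @return Character labels `"early"` / `"late"` / `"excluded"`.
#' @export
#' @examples
#' group_stage(c("Stage IA", "Stage II"), scheme = "A")  # early, late
#' group_stage("Stage II", scheme = "B")                 # early
group_stage <- function(stages, scheme = c("A", "B")) {
  scheme <- match.arg(scheme)
  if (length(stages) == 0L) return(character(0))
  s <- toupper(trimws(as.character(stages)))
  s <- sub("^STAGE\\s*", "", s)
  s <- sub("(?<=[IV])[A-C][0-9]?$", "", s, perl = TRUE)  # substage letters
  early <- if (scheme == "A") "I" else c("I", "II")
  late <- if (scheme == "A") c("II", "III", "IV") else c("III", "IV")
  lab <- rep("excluded", length(s))
  lab[s %in% early] <- "early"
  lab[s %in% late] <- "late"
  lab[is.na(stages)] <- "excluded"
  if (any(lab == "excluded"))
    warning(sum(lab == "excluded"),
            " sample(s) with unusable stage annotation excluded")
  lab
}
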