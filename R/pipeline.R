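# Config-driven pipeline layer: YAML config, typed input errors, provenance
# headers, TSV/JSON output. The command-line dispatcher at
# inst/cli/senquad.R is a thin wrapper over these functions.

.input_error <- function(msg) {
  structure(class = c("senquad_input_error", "error", "condition"),
            list(message = msg, call = NULL))
}

# FNV-1a 32-bit hash of the deparsed config, for provenance headers.
# Arithmetic is kept exact in doubles by splitting the 32-bit state into
# 16-bit halves for the multiply and xoring only the low byte.
.config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  p <- 16777619
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.provenance <- function(config, seed = NULL) {
  config$out_dir <- NULL   # output location is not part of the analysis
  c(sprintf("# senquad %s", as.character(utils::packageVersion("senquad"))),
    sprintf("# config_hash %s", .config_hash(config)),
    if (!is.null(seed)) sprintf("# seed %s", format(seed)))
}

#' Read a pipeline configuration file
#'
#' Configs are YAML maps; see [run_enrich()] for the recognized keys.
#'
#' @param path Path to a YAML file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(.input_error(paste0("no such config file: ", path)))
  yaml::read_yaml(path)
}

.as_config <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  if (!is.list(config)) stop(.input_error("config must be a list or a path"))
  config
}

.cfg <- function(config, key, default = NULL, required = FALSE) {
  v <- config[[key]]
  if (is.null(v)) {
    if (required) stop(.input_error(paste0("config key '", key,
                                           "' is required")))
    return(default)
  }
  v
}

.load_registry <- function(config) {
  gmt <- .cfg(config, "gmt")
  if (is.null(gmt)) return(default_registry())
  if (!file.exists(gmt)) stop(.input_error(paste0("no such GMT file: ", gmt)))
  message("registry overridden from GMT: ", gmt)
  parse_gmt(gmt)
}

.load_cohort <- function(config) {
  expr <- .cfg(config, "expression", required = TRUE)
  meta <- .cfg(config, "metadata", required = TRUE)
  expression_cohort(read_expression_tsv(expr), read_metadata_tsv(meta))
}

.out_dir <- function(config) {
  out <- .cfg(config, "out_dir", required = TRUE)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  out
}

#' Compute and write gene-set score tables
#'
#' Reads the expression/metadata TSV pair (and an optional GMT registry
#' override), z-standardizes per study, scores the configured sets, and
#' writes `scores.tsv` plus `coverage.tsv` under `out_dir`, each with a
#' provenance header.
#'
#' Config keys: `expression`, `metadata`, `out_dir` (required); `gmt`,
#' `sets` (default `TREXes`, `NCTFs`), `by_study` (default true),
#' `min_coverage` (default 0.5), `seed`.
#'
#' @param config Named list or path to a YAML config.
#' @return Invisibly, the score table.
#' @export
run_score <- function(config) {
  config <- .as_config(config)
  reg <- .load_registry(config)
  cohort <- .load_cohort(config)
  sets <- unlist(.cfg(config, "sets", c("TREXes", "NCTFs")))
  z <- zstandardize(cohort, by_study = .cfg(config, "by_study", TRUE))
  st <- score_table(z, reg, sets,
                    min_coverage = .cfg(config, "min_coverage", 0.5))
  out <- .out_dir(config)
  hdr <- .provenance(config, .cfg(config, "seed"))
  .write_tsv(st, file.path(out, "scores.tsv"), hdr)
  cov <- attr(st, "coverage")
  .write_tsv(data.frame(set = names(cov), coverage = unname(cov)),
             file.path(out, "coverage.tsv"), hdr)
  invisible(st)
}

.apply_grouping <- function(config, md) {
  gr <- .cfg(config, "grouping")
  if (is.null(gr)) return(md)
  rule <- .cfg(gr, "rule", required = TRUE)
  column <- .cfg(gr, "column",
                 switch(rule, age_decade_dichotomy = "age_decade",
                        age_median_dichotomy = "age",
                        age_quartiles = "age", "stage"))
  if (!column %in% names(md))
    stop(.input_error(paste0("grouping column '", column,
                             "' absent from metadata")))
  v <- md[[column]]
  md$group_derived <- switch(
    rule,
    age_decade_dichotomy = group_age_decades(v),
    age_median_dichotomy = as.character(group_age_median(
      as.numeric(v), median = .cfg(gr, "median"))),
    age_quartiles = as.character(group_age_quartiles(as.numeric(v))),
    stage_dichotomy_A = group_stage(v, scheme = "A"),
    stage_dichotomy_B = group_stage(v, scheme = "B"),
    stop(.input_error(paste0("unknown grouping rule '", rule, "'")))
  )
  md
}

#' Run the quadrant enrichment pipeline
#'
#' Scores the cohort (as [run_score()]), optionally derives group labels
#' from a grouping rule (age decades / median age / age quartiles / tumor
#' stage), runs [enrichment_scan()] over the requested quadrants, and
#' writes `enrichment.tsv`, `enrichment.json`, `scatter.tsv` and
#' `or_bars.tsv` under `out_dir`, all with provenance headers (infinite
#' odds ratios serialize as `"Inf"`).
#'
#' Config keys, beyond those of [run_score()]: `x_set` / `y_set` (defaults
#' `TREXes` / `NCTFs`), `group_col` (default `group`; a grouping rule
#' replaces it by `group_derived`), `target_group` (required),
#' `other_group`, `quadrants`, `alternative` (default `greater`), `alpha`
#' (default 0.05), `split_method` (default `median`),
#' `grouping: {rule, column, median}`.
#'
#' @param config Named list or path to a YAML config.
#' @return Invisibly, the `"enrichment_scan"`.
#' @export
run_enrich <- function(config) {
  config <- .as_config(config)
  alpha <- .cfg(config, "alpha", 0.05)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop(.input_error("alpha must be in (0, 1)"))
  reg <- .load_registry(config)
  cohort <- .load_cohort(config)
  cohort$metadata <- .apply_grouping(config, cohort$metadata)
  group_col <- if (!is.null(.cfg(config, "grouping"))) "group_derived"
               else .cfg(config, "group_col", "group")
  if (!group_col %in% names(cohort$metadata))
    stop(.input_error(paste0("group column '", group_col,
                             "' absent from metadata")))
  x_set <- .cfg(config, "x_set", "TREXes")
  y_set <- .cfg(config, "y_set", "NCTFs")
  z <- zstandardize(cohort, by_study = .cfg(config, "by_study", TRUE))
  st <- score_table(z, reg, unique(c(x_set, y_set)),
                    min_coverage = .cfg(config, "min_coverage", 0.5))
  target_group <- .cfg(config, "target_group", required = TRUE)
  groups_avail <- unique(stats::na.omit(st[[group_col]]))
  groups_avail <- setdiff(groups_avail, "excluded")
  if (length(groups_avail) < 2L)
    stop(.input_error("fewer than 2 groups after grouping"))
  keep <- !is.na(st[[group_col]]) & st[[group_col]] != "excluded"
  st <- st[keep, , drop = FALSE]
  scan <- enrichment_scan(st, x_set = x_set, y_set = y_set,
                          group_col = group_col,
                          target_group = target_group,
                          quadrants = unlist(.cfg(config, "quadrants",
                                                  paste0("Q", 1:4))),
                          alternative = .cfg(config, "alternative",
                                             "greater"),
                          alpha = alpha,
                          split_method = .cfg(config, "split_method",
                                              "median"),
                          other_group = .cfg(config, "other_group"))
  out <- .out_dir(config)
  hdr <- .provenance(config, .cfg(config, "seed"))
  res <- as.data.frame(scan)
  .write_tsv(res, file.path(out, "enrichment.tsv"), hdr)
  .write_tsv(scatter_export(scan$assignment, scan$groups),
             file.path(out, "scatter.tsv"), hdr)
  .write_tsv(or_bar_export(list(enrichment = scan)),
             file.path(out, "or_bars.tsv"), hdr)
  jsonlite::write_json(
    list(provenance = list(package = "senquad",
                           version = as.character(
                             utils::packageVersion("senquad")),
                           config_hash = .config_hash(
                             config[setdiff(names(config), "out_dir")])),
         results = res),
    file.path(out, "enrichment.json"), auto_unbox = TRUE, digits = NA,
    na = "string")
  invisible(scan)
}

#' Simulate a cohort and write it in the pipeline's TSV dialect
#'
#' Writes `expression.tsv`, `metadata.tsv`, `truth_genes.tsv` and a
#' `params.yaml` echo under `out_dir`; the emitted files round-trip through
#' [run_score()] / [run_enrich()].
#'
#' Config keys: `out_dir` (required), `seed` (default 1), and any
#' [simulation_params()] field under `sim:` (e.g. `sim: {delta: 1,
#' n_studies: 5}`).
#'
#' @param config Named list or path to a YAML config.
#' @return Invisibly, the simulation result.
#' @export
run_simulate <- function(config) {
  config <- .as_config(config)
  sim_cfg <- .cfg(config, "sim", list())
  if (!is.list(sim_cfg)) stop(.input_error("'sim' must be a map"))
  bad <- setdiff(names(sim_cfg), names(formals(simulation_params)))
  if (length(bad))
    stop(.input_error(paste0("unknown sim parameter(s): ",
                             paste(bad, collapse = ", "))))
  sim_cfg$seed <- .cfg(config, "seed", .cfg(sim_cfg, "seed", 1))
  params <- do.call(simulation_params, sim_cfg)
  sim <- simulate_cohort(params)
  out <- .out_dir(config)
  hdr <- .provenance(config, params$seed)
  write_cohort_tsv(sim$cohort, file.path(out, "expression.tsv"),
                   file.path(out, "metadata.tsv"), header = hdr)
  .write_tsv(sim$truth$genes, file.path(out, "truth_genes.tsv"), hdr)
  echo <- unclass(params)
  echo$registry <- NULL
  yaml::write_yaml(echo, file.path(out, "params.yaml"))
  invisible(sim)
}

#' Export the registry as GMT plus a size report
#'
#' Writes `registry.gmt` and `sizes.tsv` (unique-symbol counts per set and
#' supergroup) under `out_dir`.
#'
#' Config keys: `out_dir` (required); `gmt` to export a user registry
#' instead of the default.
#'
#' @param config Named list or path to a YAML config.
#' @return Invisibly, the registry.
#' @export
run_registry <- function(config) {
  config <- .as_config(config)
  reg <- .load_registry(config)
  out <- .out_dir(config)
  write_gmt(reg, file.path(out, "registry.gmt"))
  sz <- registry_sizes(reg)
  .write_tsv(data.frame(set = names(sz), n_genes = unname(sz)),
             file.path(out, "sizes.tsv"), .provenance(config))
  invisible(reg)
}
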