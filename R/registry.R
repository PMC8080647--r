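#' Construct a gene set
#'
#' A gene set is a named collection of HGNC gene symbols with a functional
#' category and, for nuclear pore complex (NPC) sets, an optional structural
#' subclass.
#'
#' @param name Short identifier, unique within a registry.
#' @param category Functional category. The curated categories are
#'   `"TREX"`, `"TREX2"`, `"TREXAF"`, `"NPC"`, `"NTR"`, `"RAN"` and
#'   `"MARKER"`; any other string is treated as user-defined.
#' @param symbols Character vector of HGNC gene symbols; nonempty, unique
#'   within the set.
#' @param subclass Optional NPC structural subclass, one of `"NPC_Y"`,
#'   `"NPC_FG_CENTRAL"`, `"NPC_FG_NUCLEAR"`, `"NPC_FG_CYTOPLASMIC"`,
#'   `"NPC_TM"`, `"NPC_BASKET"`, `"NPC_ELLP"`. Only allowed when
#'   `category = "NPC"`.
#' @param description Free-text description.
#' @param source Provenance note.
#'
#' @return An object of class `"gene_set"`.
#' @export
#' @examples
#' gene_set("RAN_CYCLE", "RAN", c("RAN", "RANBP1", "RANGAP1", "RCC1"))
gene_set <- function(name, category, symbols, subclass = NULL,
                     description = "", source = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(category), length(category) == 1L)
  if (length(symbols) == 0L || !is.character(symbols))
    stop("gene set '", name, "': symbols must be a nonempty character vector")
  if (anyDuplicated(symbols))
    stop("gene set '", name, "': duplicated symbols: ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "))
  if (!is.null(subclass)) {
    subclass <- match.arg(subclass, c("NPC_Y", "NPC_FG_CENTRAL",
                                      "NPC_FG_NUCLEAR", "NPC_FG_CYTOPLASMIC",
                                      "NPC_TM", "NPC_BASKET", "NPC_ELLP"))
    if (!identical(category, "NPC"))
      stop("gene set '", name, "': subclass is only valid for category 'NPC'")
  }
  structure(list(name = name, category = category, symbols = symbols,
                 subclass = subclass, description = description,
                 source = source),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s [%s%s] %d genes\n", x$name, x$category,
              if (is.null(x$subclass)) "" else paste0("/", x$subclass),
              length(x$symbols)))
  cat(" ", paste(x$symbols, collapse = " "), "\n")
  invisible(x)
}

.new_registry <- function(sets, supergroups = list()) {
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  for (sg in names(supergroups)) {
    missing <- setdiff(supergroups[[sg]], names(sets))
    if (length(missing))
      stop("supergroup '", sg, "' refers to unknown set(s): ",
           paste(missing, collapse = ", "))
  }
  structure(list(sets = sets, supergroups = supergroups),
            class = "gene_set_registry")
}

.default_supergroups <- function(set_names) {
  sg <- list(TREXes = c("TREX", "TREX2", "TREXAF"),
             NCTFs = c("NPC", "NTR", "RAN"))
  sg[vapply(sg, function(m) all(m %in% set_names), logical(1))]
}

#' Default TREX/NCT gene-set registry
#'
#' The bundled registry of curated mRNA-export and nucleocytoplasmic
#' transport gene sets: TREX (16 genes), TREX-2 (5), TREX-associated factors
#' (8), nuclear pore complex (NPC, 31), nuclear transport receptors
#' (NTR/Kaps, 11), Ran cycle (4), and the senescence marker pair
#' CDKN1A/CDKN2A (MARKER, 2). NPC structural subclasses (Y complex, central /
#' nuclear / cytoplasmic FG, transmembrane, basket, and the extremely
#' long-lived ELLP nucleoporins) are included as additional sets whose
#' symbols are subsets of the NPC set; the ELLP classification is orthogonal
#' and overlaps the other subclasses.
#'
#' Two supergroups are defined: `TREXes` (TREX + TREX-2 + TREX-AFs, 29 genes)
#' and `NCTFs` (NPC + NTR + RAN, 46 genes). Member lists are a documented
#' literature-based curation with the category sizes above as the hard
#' constraint; the whole registry can be replaced through [parse_gmt()].
#'
#' @return A `"gene_set_registry"`.
#' @export
#' @examples
#' reg <- default_registry()
#' registry_sizes(reg)[c("TREX", "NPC", "NCTFs")]
default_registry <- function() {
  prov <- "curated from mRNA export / NCT literature; sizes fixed by design"
  sets <- c(
    list(
      gene_set("TREX", "TREX", .SENQUAD_TREX,
               description = "THO/TREX transcription-export complex",
               source = prov),
      gene_set("TREX2", "TREX2", .SENQUAD_TREX2,
               description = "TREX-2 complex", source = prov),
      gene_set("TREXAF", "TREXAF", .SENQUAD_TREXAF,
               description = "TREX-associated factors (NXF/NXT transporters)",
               source = prov),
      gene_set("NPC", "NPC", .SENQUAD_NPC,
               description = "nuclear pore complex nucleoporins",
               source = prov),
      gene_set("NTR", "NTR", .SENQUAD_NTR,
               description = "nuclear transport receptors (Kaps)",
               source = prov),
      gene_set("RAN", "RAN", .SENQUAD_RAN,
               description = "Ran GTPase cycle", source = prov),
      gene_set("MARKER", "MARKER", .SENQUAD_MARKER,
               description = "senescence markers p21/p16", source = prov)
    ),
    lapply(names(.SENQUAD_NPC_SUBCLASS), function(sc)
      gene_set(sc, "NPC", .SENQUAD_NPC_SUBCLASS[[sc]], subclass = sc,
               description = paste("NPC subclass", sc), source = prov))
  )
  reg <- .new_registry(sets, .default_supergroups(
    vapply(sets, `[[`, character(1), "name")))
  reg
}

#' @export
print.gene_set_registry <- function(x, ...) {
  cat(sprintf("<gene_set_registry> %d sets, %d supergroups\n",
              length(x$sets), length(x$supergroups)))
  sz <- registry_sizes(x)
  print(sz)
  invisible(x)
}

#' Sizes of all sets and supergroups in a registry
#'
#' @param registry A `"gene_set_registry"`.
#' @return Named integer vector of unique-symbol counts, sets first, then
#'   supergroups.
#' @export
registry_sizes <- function(registry) {
  stopifnot(inherits(registry, "gene_set_registry"))
  s <- vapply(registry$sets, function(g) length(g$symbols), integer(1))
  sg <- vapply(names(registry$supergroups), function(n)
    length(geneset_members(registry, n)), integer(1))
  c(s, sg)
}

#' Resolve a set or supergroup name to its member symbols
#'
#' Supergroup members are the union of their constituent sets' symbols,
#' derived on demand (never stored).
#'
#' @param registry A `"gene_set_registry"`.
#' @param name A set or supergroup name.
#' @return Character vector of unique symbols.
#' @export
geneset_members <- function(registry, name) {
  stopifnot(inherits(registry, "gene_set_registry"),
            is.character(name), length(name) == 1L)
  if (name %in% names(registry$sets))
    return(registry$sets[[name]]$symbols)
  if (name %in% names(registry$supergroups)) {
    member_sets <- registry$supergroups[[name]]
    return(unique(unlist(lapply(registry$sets[member_sets], `[[`, "symbols"),
                         use.names = FALSE)))
  }
  stop("unknown gene set '", name, "'; available: ",
       paste(c(names(registry$sets), names(registry$supergroups)),
             collapse = ", "))
}

.encode_gmt_desc <- function(set) {
  kv <- c(category = set$category)
  if (!is.null(set$subclass)) kv <- c(kv, subclass = set$subclass)
  if (nzchar(set$description)) kv <- c(kv, note = set$description)
  paste(paste0(names(kv), "=", kv), collapse = ";")
}

.decode_gmt_desc <- function(desc) {
  out <- list(category = "user-defined", subclass = NULL, note = desc)
  if (grepl("=", desc, fixed = TRUE)) {
    parts <- strsplit(desc, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, "=", fixed = TRUE)
    for (p in kv) {
      if (length(p) != 2L) next
      if (p[1] == "category") out$category <- p[2]
      if (p[1] == "subclass") out$subclass <- p[2]
      if (p[1] == "note") out$note <- p[2]
    }
  }
  out
}

#' Read a registry from a GMT file
#'
#' Standard GMT: one set per nonempty line, tab-separated fields
#' `name`, `description`, then the member symbols. If the description field
#' is of the form `category=NPC;subclass=NPC_Y;note=...` (as written by
#' [write_gmt()]) the category and subclass are restored; otherwise the
#' category is `"user-defined"`. The `TREXes` / `NCTFs` supergroups are
#' attached whenever all their constituent sets are present.
#'
#' @param path Path to a GMT file, or a connection.
#' @return A `"gene_set_registry"`. An empty file yields an empty registry
#'   with a warning.
#' @export
parse_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    warning("empty GMT input: returning empty registry")
    return(.new_registry(list()))
  }
  sets <- vector("list", length(nonempty))
  for (j in seq_along(nonempty)) {
    i <- nonempty[j]
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)))
    meta <- .decode_gmt_desc(fields[2])
    sym <- fields[-(1:2)]
    sym <- sym[nzchar(sym)]
    sets[[j]] <- gene_set(fields[1], meta$category, sym,
                          subclass = meta$subclass,
                          description = meta$note, source = "GMT import")
  }
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("GMT input: duplicate set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  .new_registry(sets, .default_supergroups(nm))
}

#' Write a registry to a GMT file
#'
#' @param registry A `"gene_set_registry"`.
#' @param path Output file path or connection.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(registry, path) {
  stopifnot(inherits(registry, "gene_set_registry"))
  lines <- vapply(registry$sets, function(s)
    paste(c(s$name, .encode_gmt_desc(s), s$symbols), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Match registry symbols against the gene ids of an expression matrix
#'
#' Matching is exact but case-insensitive; no alias resolution is attempted.
#'
#' @param registry A `"gene_set_registry"`.
#' @param gene_ids Character vector of gene ids (e.g. the rownames of an
#'   expression matrix).
#' @return A data.frame with one row per set and per supergroup: `set`,
#'   `size`, `n_matched`, `coverage` (= `n_matched / size`), and a list
#'   column `missing` of unmatched symbols. Zero coverage is reported, not
#'   an error.
#' @export
resolve_symbols <- function(registry, gene_ids) {
  stopifnot(inherits(registry, "gene_set_registry"))
  ids_up <- toupper(as.character(gene_ids))
  nm <- c(names(registry$sets), names(registry$supergroups))
  rows <- lapply(nm, function(n) {
    sym <- geneset_members(registry, n)
    hit <- toupper(sym) %in% ids_up
    data.frame(set = n, size = length(sym), n_matched = sum(hit),
               coverage = if (length(sym)) sum(hit) / length(sym) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$missing <- lapply(nm, function(n) {
    sym <- geneset_members(registry, n)
    sym[!(toupper(sym) %in% ids_up)]
  })
  out
}
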