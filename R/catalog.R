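#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Recognized process classes for marker genes.
PROCESS_CLASSES <- c(
  "oxygenic_photosynthesis", "anoxygenic_phototrophy",
  "carbon_fixation", "nitrogen_cycle"
)

#' Marker-gene pathway catalogs
#'
#' A pathway catalog maps marker genes (e.g. `rbcL`, `nifH`, `amoA`) to the
#' metabolic pathway whose activity their transcripts indicate. Pathway
#' transcription is then quantified from the normalized abundance of reads
#' assigned to these indicator genes. Each gene belongs to exactly one
#' pathway; symbols are matched case-insensitively throughout the package
#' because annotation pipelines differ in casing conventions.
#'
#' `marker_catalog()` validates a data frame of markers and returns a catalog.
#' `default_catalog()` loads the catalog shipped with the package: 21 marker
#' genes over 11 pathways spanning oxygenic/anoxygenic phototrophy, three
#' carbon-fixation pathways (Calvin-Benson-Bassham cycle, 3-hydroxypropionate
#' bi-cycle, hydroxypropionate-hydroxybutyrate cycle) and six nitrogen-cycle
#' processes (N2 fixation, ammonia assimilation, ammonia oxidation, DNRA,
#' denitrification, anammox). The anammox marker `hzsA` is retained even
#' though it is often absent from mat metagenomes: pathways with no matching
#' features report zero activity rather than disappearing from outputs.
#'
#' @param markers Data frame with columns `symbol`, `pathway_id`,
#'   `pathway_name`, `process_class`.
#' @return A tibble of class `marker_catalog` with one row per marker gene.
#' @examples
#' cat <- default_catalog()
#' nrow(cat)            # 21 marker genes
#' catalog_pathways(cat)
#' @export
marker_catalog <- function(markers) {
  markers <- as_tibble(markers)
  required <- c("symbol", "pathway_id", "pathway_name", "process_class")
  missing <- setdiff(required, names(markers))
  if (length(missing) > 0) {
    abort(paste0("catalog is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  markers <- markers[required]
  for (col in required) markers[[col]] <- as.character(markers[[col]])
  if (nrow(markers) > 0) {
    if (any(!nzchar(markers$symbol) | is.na(markers$symbol))) {
      abort("catalog contains empty gene symbols")
    }
    dup <- duplicated(tolower(markers$symbol))
    if (any(dup)) {
      abort(paste0("duplicate marker symbol(s) in catalog: ",
                   paste(unique(markers$symbol[dup]), collapse = ", ")))
    }
    bad_class <- setdiff(unique(markers$process_class), PROCESS_CLASSES)
    if (length(bad_class) > 0) {
      abort(paste0("unknown process_class: ", paste(bad_class, collapse = ", "),
                   " (expected one of ",
                   paste(PROCESS_CLASSES, collapse = ", "), ")"))
    }
    # one pathway_id must map to a single display name / class
    pw <- unique(markers[c("pathway_id", "pathway_name", "process_class")])
    if (anyDuplicated(pw$pathway_id)) {
      bad <- pw$pathway_id[duplicated(pw$pathway_id)]
      abort(paste0("pathway_id with conflicting name/class: ",
                   paste(unique(bad), collapse = ", ")))
    }
  }
  class(markers) <- c("marker_catalog", class(markers))
  markers
}

#' @rdname marker_catalog
#' @export
default_catalog <- function() {
  path <- system.file("extdata", "porcelana_markers.tsv", package = "matflux")
  read_catalog(path)
}

#' Read and write catalog files
#'
#' Catalog files are tab-separated with header
#' `symbol  pathway_id  pathway_name  process_class`; lines starting with `#`
#' are comments. An empty file (header only, or no rows) yields an empty
#' catalog. Writing then re-reading a catalog reproduces it exactly.
#'
#' @param path Path to a catalog TSV file.
#' @return `read_catalog()` returns a `marker_catalog`; `write_catalog()`
#'   returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) abort(paste0("catalog file not found: ", path))
  df <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) {
    df <- tibble(symbol = character(), pathway_id = character(),
                 pathway_name = character(), process_class = character())
  }
  marker_catalog(df)
}

#' @rdname read_catalog
#' @param catalog A `marker_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "marker_catalog"))
  readr::write_tsv(as_tibble(unclass_catalog(catalog)), path, progress = FALSE)
  invisible(path)
}

unclass_catalog <- function(catalog) {
  class(catalog) <- setdiff(class(catalog), "marker_catalog")
  catalog
}

#' Pathways defined by a catalog
#'
#' @param catalog A `marker_catalog`.
#' @return Tibble with one row per pathway: `pathway_id`, `pathway_name`,
#'   `process_class`.
#' @export
catalog_pathways <- function(catalog) {
  stopifnot(inherits(catalog, "marker_catalog"))
  unique(as_tibble(unclass_catalog(catalog))[
    c("pathway_id", "pathway_name", "process_class")])
}

# Map arbitrary-cased gene symbols onto canonical catalog symbols.
# Returns a character vector of canonical symbols (NA where unmatched).
match_symbols <- function(symbols, catalog) {
  idx <- match(tolower(symbols), tolower(catalog$symbol))
  out <- catalog$symbol[idx]
  out[is.na(idx) | is.na(symbols) | !nzchar(symbols)] <- NA_character_
  out
}

#' Check an annotation table against a catalog
#'
#' Reports, for every marker gene in the catalog, how many annotated features
#' carry its symbol (case-insensitive). Catalog symbols with zero features
#' identify pathways that will report zero activity downstream — e.g. the
#' anammox marker `hzsA` when hydrazine synthase is absent from a metagenome.
#'
#' @param catalog A `marker_catalog`.
#' @param annotations Feature annotation table with columns `feature_id`,
#'   `gene_symbol`, `length_bp`, `taxon_lineage` (see [read_annotations()]).
#' @return Tibble with columns `symbol`, `pathway_id`, `n_features`,
#'   `matched` (logical), one row per catalog marker.
#' @export
validate_annotations <- function(catalog, annotations) {
  stopifnot(inherits(catalog, "marker_catalog"))
  canon <- character(0)
  if (!is.null(annotations) && nrow(annotations) > 0) {
    canon <- match_symbols(annotations$gene_symbol, catalog)
  }
  counts <- table(factor(canon, levels = catalog$symbol))
  tibble(
    symbol = catalog$symbol,
    pathway_id = catalog$pathway_id,
    n_features = as.integer(counts[catalog$symbol]),
    matched = as.integer(counts[catalog$symbol]) > 0
  )
}
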