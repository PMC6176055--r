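LINEAGE_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Read gene-level feature annotations
#'
#' Tab-separated, one row per predicted gene:
#' `feature_id  gene_symbol  length_bp  taxon_lineage`. `gene_symbol` may be
#' empty for features that are not catalog markers; `taxon_lineage` is a
#' semicolon-delimited lineage `domain;phylum;class;order;family;genus`
#' (shorter lineages are allowed and resolve to "Unclassified" at missing
#' ranks).
#'
#' @param path Path to an annotation TSV.
#' @return Tibble of annotations.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  df <- readr::read_tsv(path, comment = "#", progress = FALSE,
                        col_types = readr::cols(
                          feature_id = "c", gene_symbol = "c",
                          length_bp = "d", taxon_lineage = "c"))
  check_annotations(df)
  df
}

check_annotations <- function(annotations) {
  required <- c("feature_id", "gene_symbol", "length_bp", "taxon_lineage")
  missing <- setdiff(required, names(annotations))
  if (length(missing) > 0) {
    abort(paste0("annotation table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(annotations$feature_id)) {
    abort("duplicate feature_id in annotation table")
  }
  if (any(is.na(annotations$length_bp) | annotations$length_bp <= 0)) {
    abort("annotation length_bp must be positive")
  }
  invisible(annotations)
}

#' Read a wide count matrix
#'
#' Tab-separated wide matrix: first column `feature_id`, remaining columns one
#' per sample, holding non-negative integer read counts.
#'
#' @param path Path to a counts TSV.
#' @return Numeric matrix with feature ids as row names.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort(paste0("counts file not found: ", path))
  df <- readr::read_tsv(path, comment = "#", progress = FALSE,
                        col_types = readr::cols(feature_id = "c", .default = "d"))
  m <- as.matrix(df[, setdiff(names(df), "feature_id"), drop = FALSE])
  rownames(m) <- df$feature_id
  if (any(m < 0)) abort("counts must be non-negative")
  m
}

#' Read a sample sheet
#'
#' Tab-separated: `sample_id  temperature_C  library  time_of_day
#' library_size`. `library` is `DNA` (metagenome) or `cDNA`
#' (metatranscriptome); `library_size` is the total number of high-quality
#' non-rRNA reads of the library — the denominator of FPKM — which is larger
#' than the column sum of a marker-gene count matrix because marker features
#' are only a subset of the library.
#'
#' @param path Path to a sample sheet TSV.
#' @return Tibble of sample descriptors.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) abort(paste0("sample sheet not found: ", path))
  readr::read_tsv(path, comment = "#", progress = FALSE,
                  col_types = readr::cols(
                    sample_id = "c", temperature_C = "d", library = "c",
                    time_of_day = "c", library_size = "d"))
}

#' FPKM normalization of a count matrix
#'
#' Fragments per kilobase of gene length per million library reads:
#' \deqn{\mathrm{FPKM}_{fs} = \frac{c_{fs}}{(L_f/1000)\,(N_s/10^6)}}
#' with \eqn{c_{fs}} the raw count of feature \eqn{f} in sample \eqn{s},
#' \eqn{L_f} the gene length in bp and \eqn{N_s} the library size. FPKM is
#' invariant to jointly rescaling counts and library sizes.
#'
#' @param counts Numeric matrix (features x samples) with feature ids as
#'   row names.
#' @param annotations Annotation tibble supplying `length_bp` per feature.
#' @param library_sizes Named numeric vector of per-sample library sizes
#'   (names matching `colnames(counts)`), or an unnamed vector in column
#'   order.
#' @return Matrix of FPKM values, same dimnames as `counts`.
#' @export
normalize_fpkm <- function(counts, annotations, library_sizes) {
  check_annotations(annotations)
  missing <- setdiff(rownames(counts), annotations$feature_id)
  if (length(missing) > 0) {
    abort(paste0("features without annotation: ",
                 paste(utils::head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) paste0(" (and ", length(missing) - 10, " more)")))
  }
  if (!is.null(names(library_sizes))) {
    missing_s <- setdiff(colnames(counts), names(library_sizes))
    if (length(missing_s) > 0) {
      abort(paste0("no library size for sample(s): ",
                   paste(missing_s, collapse = ", ")))
    }
    library_sizes <- library_sizes[colnames(counts)]
  }
  stopifnot(length(library_sizes) == ncol(counts), all(library_sizes > 0))
  len <- annotations$length_bp[match(rownames(counts), annotations$feature_id)]
  sweep(counts / (len / 1000), 2, as.numeric(library_sizes) / 1e6, "/")
}

# Sum a feature-level matrix into symbol-level rows (canonical catalog casing
# when a catalog is given, lower-cased symbol otherwise). Unannotated features
# (empty symbol) are dropped.
aggregate_by_symbol <- function(profile, annotations, catalog = NULL) {
  sym <- annotations$gene_symbol[match(rownames(profile), annotations$feature_id)]
  if (!is.null(catalog)) {
    sym <- match_symbols(sym, catalog)
  } else {
    sym[!is.na(sym) & !nzchar(sym)] <- NA_character_
  }
  keep <- !is.na(sym)
  rowsum(profile[keep, , drop = FALSE], group = sym[keep])
}

#' Percent of a gene's total transcripts found in each sample
#'
#' For each gene symbol, sums the normalized abundance over every feature
#' carrying that symbol (case-insensitive), then expresses each sample's share
#' as a percent of the total over the selected sample set. This is the
#' per-gene, per-sample profile typically drawn as bar charts over
#' day/night x temperature panels. Genes with zero total are returned as all
#' zeros with `zero_total = TRUE` rather than NaN.
#'
#' @param profile Normalized abundance matrix (e.g. FPKM), features x samples.
#' @param annotations Annotation tibble.
#' @param symbols Gene symbols to profile (default: all annotated symbols).
#' @param samples Sample ids over which percentages are normalized
#'   (default: all columns of `profile`).
#' @return Long tibble: `symbol`, `sample_id`, `percent`, `zero_total`.
#' @export
gene_percent <- function(profile, annotations, symbols = NULL, samples = NULL) {
  check_annotations(annotations)
  samples <- samples %||% colnames(profile)
  missing_s <- setdiff(samples, colnames(profile))
  if (length(missing_s) > 0) {
    abort(paste0("unknown sample(s): ", paste(missing_s, collapse = ", ")))
  }
  by_sym <- aggregate_by_symbol(profile[, samples, drop = FALSE], annotations)
  if (is.null(symbols)) {
    symbols <- rownames(by_sym)
  } else {
    idx <- match(tolower(symbols), tolower(rownames(by_sym)))
    if (anyNA(idx)) {
      abort(paste0("symbol(s) not present in annotations: ",
                   paste(symbols[is.na(idx)], collapse = ", ")))
    }
    by_sym <- by_sym[idx, , drop = FALSE]
    rownames(by_sym) <- symbols
  }
  totals <- rowSums(by_sym)
  pct <- by_sym
  nz <- totals > 0
  pct[nz, ] <- 100 * by_sym[nz, , drop = FALSE] / totals[nz]
  pct[!nz, ] <- 0
  tibble(
    symbol = rep(rownames(pct), times = ncol(pct)),
    sample_id = rep(colnames(pct), each = nrow(pct)),
    percent = as.vector(pct),
    zero_total = rep(!nz, times = ncol(pct))
  )
}

#' Pathway activity from marker-gene abundance
#'
#' Sums normalized abundance over each pathway's marker genes, per sample.
#' Every catalog pathway is reported for every sample; pathways with no
#' matching features (or no reads) report 0 rather than being dropped, so an
#' absent marker such as `hzsA` shows up as zero anammox activity.
#'
#' @param profile Normalized abundance matrix, features x samples.
#' @param annotations Annotation tibble.
#' @param catalog A `marker_catalog`.
#' @return Long tibble: `pathway_id`, `process_class`, `sample_id`,
#'   `activity`.
#' @export
pathway_activity <- function(profile, annotations, catalog = default_catalog()) {
  check_annotations(annotations)
  stopifnot(inherits(catalog, "marker_catalog"))
  by_sym <- aggregate_by_symbol(profile, annotations, catalog)
  pw <- catalog_pathways(catalog)
  act <- matrix(0, nrow = nrow(pw), ncol = ncol(profile),
                dimnames = list(pw$pathway_id, colnames(profile)))
  if (nrow(by_sym) > 0) {
    pid <- catalog$pathway_id[match(rownames(by_sym), catalog$symbol)]
    summed <- rowsum(by_sym, group = pid)
    act[rownames(summed), ] <- summed
  }
  tibble(
    pathway_id = rep(pw$pathway_id, times = ncol(act)),
    process_class = rep(pw$process_class, times = ncol(act)),
    sample_id = rep(colnames(act), each = nrow(act)),
    activity = as.vector(act)
  )
}

#' Extract a taxon name at a given rank from a lineage string
#'
#' @param lineage Semicolon-delimited lineage strings
#'   (`domain;phylum;class;order;family;genus`).
#' @param rank One of `r toString(LINEAGE_RANKS)`.
#' @return Character vector of taxon names; `"Unclassified"` where the
#'   lineage does not reach the requested rank.
#' @export
lineage_at_rank <- function(lineage, rank = "genus") {
  rank <- match.arg(rank, LINEAGE_RANKS)
  idx <- match(rank, LINEAGE_RANKS)
  vapply(strsplit(ifelse(is.na(lineage), "", lineage), ";", fixed = TRUE),
         function(parts) {
           parts <- trimws(parts)
           if (length(parts) >= idx && nzchar(parts[idx])) parts[idx] else "Unclassified"
         }, character(1))
}

#' Per-taxon share of total normalized abundance in each sample
#'
#' Groups all features by taxon at the requested rank and expresses each
#' taxon's summed normalized abundance as a percent of the sample total.
#'
#' @inheritParams gene_percent
#' @param rank Taxonomic rank for grouping (`"genus"` or `"phylum"`, etc.).
#' @return Long tibble: `taxon`, `sample_id`, `percent`, `zero_total`.
#' @export
taxon_profile <- function(profile, annotations, rank = "genus") {
  check_annotations(annotations)
  taxon <- lineage_at_rank(
    annotations$taxon_lineage[match(rownames(profile), annotations$feature_id)],
    rank)
  by_tax <- rowsum(profile, group = taxon)
  totals <- colSums(by_tax)
  pct <- sweep(by_tax, 2, ifelse(totals > 0, totals, 1), "/") * 100
  pct[, totals == 0] <- 0
  tibble(
    taxon = rep(rownames(pct), times = ncol(pct)),
    sample_id = rep(colnames(pct), each = nrow(pct)),
    percent = as.vector(pct),
    zero_total = rep(totals == 0, each = nrow(pct))
  )
}

#' Percent contribution of taxa to each pathway's transcription
#'
#' Within each (pathway, sample) cell, groups the pathway's marker-gene
#' features by taxon at the requested rank and computes each taxon's percent
#' share of the summed normalized abundance. Taxa below `min_share` percent
#' are pooled into `"Other"`; lineages that do not reach the rank are counted
#' as `"Unclassified"`. Pathway-sample cells with zero total activity are
#' omitted (their zero is visible in [pathway_activity()]).
#'
#' @inheritParams pathway_activity
#' @param rank Taxonomic rank for grouping.
#' @param min_share Minimum percent share a taxon must reach to be listed by
#'   name (default 1, mirroring the usual treatment of taxa under 1%).
#' @return Long tibble: `pathway_id`, `sample_id`, `taxon`, `percent`.
#' @export
taxon_contribution <- function(profile, annotations, catalog = default_catalog(),
                               rank = "genus", min_share = 1) {
  check_annotations(annotations)
  stopifnot(inherits(catalog, "marker_catalog"), min_share >= 0, min_share <= 100)
  ann <- annotations[match(rownames(profile), annotations$feature_id), ]
  canon <- match_symbols(ann$gene_symbol, catalog)
  pid <- catalog$pathway_id[match(canon, catalog$symbol)]
  taxon <- lineage_at_rank(ann$taxon_lineage, rank)
  keep <- !is.na(pid)
  if (!any(keep)) {
    return(tibble(pathway_id = character(), sample_id = character(),
                  taxon = character(), percent = numeric()))
  }
  df <- tibble(
    pathway_id = rep(pid[keep], times = ncol(profile)),
    taxon = rep(taxon[keep], times = ncol(profile)),
    sample_id = rep(colnames(profile), each = sum(keep)),
    value = as.vector(profile[keep, , drop = FALSE])
  )
  shares <- dplyr::summarise(
    dplyr::group_by(df, .data$pathway_id, .data$sample_id, .data$taxon),
    value = sum(.data$value), .groups = "drop_last")
  shares <- dplyr::filter(
    dplyr::mutate(shares, total = sum(.data$value)), .data$total > 0)
  shares <- dplyr::mutate(shares, percent = 100 * .data$value / .data$total)
  shares <- dplyr::mutate(
    shares, taxon = ifelse(.data$percent < min_share, "Other", .data$taxon))
  out <- dplyr::summarise(
    dplyr::group_by(shares, .data$pathway_id, .data$sample_id, .data$taxon),
    percent = sum(.data$percent), .groups = "drop")
  dplyr::arrange(out, .data$pathway_id, .data$sample_id,
                 dplyr::desc(.data$percent))
}

#' DNA/cDNA decoupling of taxon abundance and transcription
#'
#' Pairs metagenome (DNA) and metatranscriptome (cDNA) libraries of the same
#' temperature and time of day, computes each taxon's share of the total
#' normalized abundance in either library, and reports their ratio
#' (cDNA share / DNA share) as an activity index: values above 1 mark taxa
#' transcribing more than their abundance predicts, values below 1 the
#' reverse, and a taxon absent from the metagenome but present in the
#' metatranscriptome is flagged with an infinite ratio.
#'
#' @inheritParams taxon_profile
#' @param samples Sample sheet tibble (see [read_sample_sheet()]) describing
#'   the columns of `profile`.
#' @return Tibble: `temperature_C`, `time_of_day`, `taxon`, `dna_share`,
#'   `cdna_share`, `ratio`.
#' @export
dna_rna_decoupling <- function(profile, annotations, samples, rank = "phylum") {
  stopifnot(all(c("sample_id", "temperature_C", "library", "time_of_day")
                %in% names(samples)))
  samples <- samples[samples$sample_id %in% colnames(profile), ]
  pairs <- tidyr::pivot_wider(
    samples[c("sample_id", "temperature_C", "library", "time_of_day")],
    names_from = "library", values_from = "sample_id")
  if (!all(c("DNA", "cDNA") %in% names(pairs)) ||
      any(is.na(pairs$DNA)) || any(is.na(pairs$cDNA))) {
    abort("unpaired samples: every (temperature, time) needs both a DNA and a cDNA library")
  }
  prof <- taxon_profile(profile, annotations, rank)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    dna <- prof[prof$sample_id == pairs$DNA[i], ]
    cdna <- prof[prof$sample_id == pairs$cDNA[i], ]
    merged <- dplyr::full_join(
      dna[c("taxon", "percent")], cdna[c("taxon", "percent")],
      by = "taxon", suffix = c("_dna", "_cdna"))
    merged[is.na(merged)] <- 0
    tibble(
      temperature_C = pairs$temperature_C[i],
      time_of_day = pairs$time_of_day[i],
      taxon = merged$taxon,
      dna_share = merged$percent_dna,
      cdna_share = merged$percent_cdna,
      ratio = ifelse(merged$percent_dna == 0,
                     ifelse(merged$percent_cdna == 0, NA_real_, Inf),
                     merged$percent_cdna / merged$percent_dna)
    )
  })
  dplyr::bind_rows(out)
}
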