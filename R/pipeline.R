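#' Pipeline run configuration
#'
#' Collects file paths and tuning parameters for the table-level pipeline
#' entry points [run_rates()], [run_quant()], [run_simulate()] and
#' [run_report()]. `read_run_config()` loads the same fields from a YAML
#' file; fields not present fall back to these defaults.
#'
#' @param incubations,annotations,counts,sample_sheet,catalog Input file
#'   paths (`catalog = NULL` uses the packaged default).
#' @param out_dir Output directory (created if needed).
#' @param nat_abundance Named numeric vector of natural-abundance overrides
#'   (atom %), names `"N"`/`"C"`.
#' @param tracer_atom_fraction,photoperiod_hours,detection_threshold,core_diameter_cm,dic_umol_l
#'   Passed to [rate_config()].
#' @param rank,min_share Passed to [taxon_contribution()].
#' @param use_fpkm If `FALSE`, quantify from raw counts instead of FPKM.
#' @param depth,seed Synthetic-data depth and the seed for [run_simulate()].
#' @param verbose Emit per-row diagnostics to stderr.
#' @return A list of class `run_config`.
#' @export
run_config <- function(incubations = NULL, annotations = NULL, counts = NULL,
                       sample_sheet = NULL, catalog = NULL, out_dir = ".",
                       nat_abundance = NATURAL_ABUNDANCE,
                       tracer_atom_fraction = 1, photoperiod_hours = 24,
                       detection_threshold = 1e-3, core_diameter_cm = 0.7,
                       dic_umol_l = 800, rank = "genus", min_share = 1,
                       use_fpkm = TRUE, depth = 1e5, seed = 1,
                       verbose = FALSE) {
  nat <- NATURAL_ABUNDANCE
  nat[names(nat_abundance)] <- unlist(nat_abundance)
  structure(list(
    incubations = incubations, annotations = annotations, counts = counts,
    sample_sheet = sample_sheet, catalog = catalog, out_dir = out_dir,
    nat_abundance = nat, tracer_atom_fraction = tracer_atom_fraction,
    photoperiod_hours = photoperiod_hours,
    detection_threshold = detection_threshold,
    core_diameter_cm = core_diameter_cm, dic_umol_l = dic_umol_l,
    rank = rank, min_share = min_share, use_fpkm = use_fpkm,
    depth = depth, seed = as.integer(seed), verbose = verbose
  ), class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML configuration file.
#' @param ... Overrides applied on top of the file's fields.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  fields <- yaml::read_yaml(path) %||% list()
  fields <- utils::modifyList(fields, list(...))
  if (!is.null(fields$nat_abundance)) {
    nat <- unlist(fields$nat_abundance)
    # YAML 1.1 reads a bare `N:` key as boolean no/FALSE; map it back to the
    # element symbol (and `Y`-as-TRUE defensively)
    names(nat)[names(nat) == "FALSE"] <- "N"
    names(nat)[names(nat) == "TRUE"] <- "Y"
    fields$nat_abundance <- nat
  }
  do.call(run_config, fields)
}

config_rate_config <- function(config) {
  rate_config(
    nat_abundance = config$nat_abundance,
    tracer_atom_fraction = config$tracer_atom_fraction,
    photoperiod_hours = config$photoperiod_hours,
    detection_threshold = config$detection_threshold,
    core_diameter_cm = config$core_diameter_cm,
    dic_umol_l = config$dic_umol_l)
}

config_catalog <- function(config) {
  if (is.null(config$catalog)) default_catalog() else read_catalog(config$catalog)
}

# Stable hash of the configuration, stamped into output headers so a table
# can be traced back to the settings that produced it.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  fields <- unclass(config)
  fields <- fields[order(names(fields))]
  yaml::write_yaml(fields, tmp)
  unname(tools::md5sum(tmp))
}

write_output_table <- function(df, path, config) {
  header <- c(
    paste0("# matflux ", as.character(utils::packageVersion("matflux"))),
    paste0("# config_hash=", config_hash(config)))
  writeLines(header, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read back a pipeline output table
#'
#' @param path Path to a TSV written by the pipeline (leading `#` header
#'   comments are skipped).
#' @return Tibble.
#' @export
read_output_table <- function(path) {
  if (!file.exists(path)) abort(paste0("missing output file: ", path))
  readr::read_tsv(path, comment = "#", progress = FALSE,
                  col_types = readr::cols())
}

log_msg <- function(config, ...) {
  if (isTRUE(config$verbose)) message(...)
  invisible(NULL)
}

#' Run the isotope-rate stage
#'
#' Reads the configured incubation table, computes per-vial assimilation
#' rates and replicate summaries, and writes `rates.tsv` and
#' `rate_summary.tsv` into the output directory.
#'
#' @param config A [run_config()] with `incubations` set.
#' @return Invisibly, a list with elements `rates` and `summary`.
#' @export
run_rates <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$incubations)) abort("config$incubations is not set")
  inc <- read_incubations(config$incubations)
  if (nrow(inc) == 0) abort("empty incubation table: nothing to compute")
  log_msg(config, "computing rates for ", nrow(inc), " vials")
  rates <- compute_rates(inc, config_rate_config(config))
  summary <- summarize_replicates(rates)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_output_table(rates, file.path(config$out_dir, "rates.tsv"), config)
  write_output_table(summary, file.path(config$out_dir, "rate_summary.tsv"),
                     config)
  invisible(list(rates = rates, summary = summary))
}

#' Run the transcript-quantification stage
#'
#' Reads the configured annotation, count and sample-sheet tables, checks
#' their consistency, normalizes (FPKM unless `use_fpkm = FALSE`), and writes
#' `pathway_activity.tsv`, `gene_percent.tsv`, `taxon_shares.tsv` and
#' `dna_rna_decoupling.tsv` into the output directory. Gene percentages are
#' computed across the cDNA samples (all samples when no library metadata
#' distinguishes them).
#'
#' @param config A [run_config()] with `annotations`, `counts` and
#'   `sample_sheet` set.
#' @return Invisibly, a list with the four output tibbles and the
#'   normalized matrix.
#' @export
run_quant <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (f in c("annotations", "counts", "sample_sheet")) {
    if (is.null(config[[f]])) abort(paste0("config$", f, " is not set"))
  }
  catalog <- config_catalog(config)
  ann <- read_annotations(config$annotations)
  counts <- read_counts(config$counts)
  samples <- read_sample_sheet(config$sample_sheet)

  unmatched <- setdiff(rownames(counts), ann$feature_id)
  if (length(unmatched) > 0) {
    abort(paste0("count features missing from annotations: ",
                 paste(utils::head(unmatched, 10), collapse = ", "),
                 if (length(unmatched) > 10)
                   paste0(" (and ", length(unmatched) - 10, " more)")))
  }
  missing_s <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing_s) > 0) {
    abort(paste0("count samples missing from sample sheet: ",
                 paste(missing_s, collapse = ", ")))
  }

  profile <- if (isTRUE(config$use_fpkm)) {
    libs <- stats::setNames(samples$library_size, samples$sample_id)
    normalize_fpkm(counts, ann, libs)
  } else {
    counts
  }
  cdna <- samples$sample_id[samples$library == "cDNA"]
  pct_samples <- if (length(cdna) > 0) cdna else colnames(profile)

  activity <- pathway_activity(profile, ann, catalog)
  gene_pct <- gene_percent(profile, ann, samples = pct_samples)
  shares <- taxon_contribution(profile, ann, catalog,
                               rank = config$rank, min_share = config$min_share)
  decoupling <- if (all(c("DNA", "cDNA") %in% samples$library)) {
    dna_rna_decoupling(profile, ann, samples, rank = config$rank)
  } else {
    NULL
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_output_table(activity,
                     file.path(config$out_dir, "pathway_activity.tsv"), config)
  write_output_table(gene_pct,
                     file.path(config$out_dir, "gene_percent.tsv"), config)
  write_output_table(shares,
                     file.path(config$out_dir, "taxon_shares.tsv"), config)
  if (!is.null(decoupling)) {
    write_output_table(decoupling,
                       file.path(config$out_dir, "dna_rna_decoupling.tsv"),
                       config)
  }
  invisible(list(pathway_activity = activity, gene_percent = gene_pct,
                 taxon_shares = shares, dna_rna_decoupling = decoupling,
                 profile = profile))
}

#' Generate a synthetic data set on disk
#'
#' Writes the synthetic community preset (annotations, counts, sample sheet)
#' and a set of synthetic incubations for the three substrates, plus a
#' `truth.tsv` of generating share vectors, into the output directory.
#' Deterministic given `config$seed`.
#'
#' @param config A [run_config()]; `depth`, `seed` and `out_dir` are used.
#' @return Invisibly, the list of written file paths.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  scen <- porcelana_like_scenario(depth = config$depth, seed = config$seed)
  sim <- simulate_counts(scen, config_catalog(config))

  counts_df <- dplyr::bind_cols(tibble(feature_id = rownames(sim$counts)),
                                as_tibble(sim$counts))
  inc <- dplyr::bind_rows(
    simulate_incubation(incubation_scenario(
      0.01, "ammonium", noise_sd = 0, seed = config$seed)),
    simulate_incubation(incubation_scenario(
      0.05, "nitrate", noise_sd = 0, seed = config$seed + 1)),
    simulate_incubation(incubation_scenario(
      0.86, "bicarbonate", noise_sd = 0, seed = config$seed + 2)))

  paths <- list(
    annotations = file.path(config$out_dir, "annotations.tsv"),
    counts = file.path(config$out_dir, "counts.tsv"),
    sample_sheet = file.path(config$out_dir, "sample_sheet.tsv"),
    incubations = file.path(config$out_dir, "incubations.tsv"),
    truth = file.path(config$out_dir, "truth.tsv"))
  write_output_table(sim$annotations, paths$annotations, config)
  write_output_table(counts_df, paths$counts, config)
  write_output_table(sim$samples, paths$sample_sheet, config)
  write_output_table(inc, paths$incubations, config)
  write_output_table(sim$truth$pathway_shares, paths$truth, config)
  invisible(paths)
}

#' Combine rate and transcription outputs into a run report
#'
#' Joins the replicate rate summary with per-sample pathway activity shares
#' (percent of each sample's total marker-gene activity), tabulated per
#' temperature and time of day, and writes `report.tsv` plus a plain-text
#' `report.txt`. Both stage outputs must already exist in `out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, the report tibble.
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rates_path <- file.path(config$out_dir, "rate_summary.tsv")
  act_path <- file.path(config$out_dir, "pathway_activity.tsv")
  for (p in c(rates_path, act_path)) {
    if (!file.exists(p)) {
      abort(paste0("missing stage output: ", p,
                   " (run run_rates()/run_quant() first)"))
    }
  }
  summary <- read_output_table(rates_path)
  activity <- read_output_table(act_path)
  activity <- dplyr::mutate(
    dplyr::group_by(activity, .data$sample_id),
    activity_share_pct = if (sum(.data$activity) > 0)
      100 * .data$activity / sum(.data$activity) else 0)
  activity <- dplyr::ungroup(activity)
  report <- dplyr::arrange(activity, .data$sample_id,
                           dplyr::desc(.data$activity_share_pct))

  txt <- c("Pathway activity shares per sample (percent of summed marker activity)",
           "",
           utils::capture.output(print(as.data.frame(report), row.names = FALSE)),
           "",
           "Replicate rate summary (daily areal rates, nmol cm-2 d-1)",
           "",
           utils::capture.output(print(as.data.frame(summary), row.names = FALSE)))
  write_output_table(report, file.path(config$out_dir, "report.tsv"), config)
  writeLines(txt, file.path(config$out_dir, "report.txt"))
  invisible(report)
}
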