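#' Define a synthetic tracer-incubation scenario
#'
#' Bundles a ground-truth uptake rate with the spike and pool parameters of a
#' tracer incubation, so that the observation model (the pool-mixing
#' enrichment followed by the particulate-excess rate equation, run forward)
#' can generate noisy atom-percent measurements whose true rate is known.
#' Defaults follow the dual-label field protocol the package targets: 1 mL of
#' spring water incubated for 6 h with triplicate vials; ammonium spikes of
#' 50 uL at 500 umol L^-1 into a 0.04 umol L^-1 ambient pool, nitrate spikes
#' of 30 uL at 500 umol L^-1 into 3.2 umol L^-1, bicarbonate spikes of 500 uL
#' at 500 umol L^-1 into a fixed 800 umol L^-1 dissolved inorganic carbon
#' pool.
#'
#' @param true_rho Ground-truth assimilation rate (nmol per mg dry mass per
#'   hour).
#' @param substrate `"ammonium"`, `"nitrate"` or `"bicarbonate"`; chooses the
#'   element (N or N or C) and the default spike/pool parameters.
#' @param v_add_ul,t_conc_umol_l,v_inc_ml,nat_conc_umol_l Spike volume (uL),
#'   tracer concentration (umol L^-1), incubation volume (mL) and ambient
#'   pool concentration (umol L^-1); defaults depend on `substrate`.
#' @param pom_mass_mg Particulate organic N or C recovered (mg); defaults to
#'   0.3 mg N or 1.5 mg C per 10 mg of dry mat.
#' @param mat_dry_mass_mg Dry mass analyzed on the mass spectrometer (mg).
#' @param core_dry_mass_mg Whole-core dry mass for areal extrapolation (mg).
#' @param time_inc_h Incubation duration (hours).
#' @param noise_sd Standard deviation of Gaussian atom-percent measurement
#'   noise applied to the enriched (tracer-amended) readings.
#' @param n_replicates Number of tracer-amended replicate vials.
#' @param tracer_atom_fraction Tracer isotopic purity in (0, 1].
#' @param nat_abundance Natural abundance (atom %); defaults by element.
#' @param light Logical; light or dark incubation (metadata only).
#' @param seed Integer seed making the simulation deterministic.
#' @return A list of class `incubation_scenario`.
#' @export
incubation_scenario <- function(true_rho,
                                substrate = c("ammonium", "nitrate", "bicarbonate"),
                                v_add_ul = NULL, t_conc_umol_l = 500,
                                v_inc_ml = 1, nat_conc_umol_l = NULL,
                                pom_mass_mg = NULL, mat_dry_mass_mg = 10,
                                core_dry_mass_mg = mat_dry_mass_mg,
                                time_inc_h = 6, noise_sd = 0,
                                n_replicates = 3, tracer_atom_fraction = 1,
                                nat_abundance = NULL, light = TRUE, seed = 1) {
  substrate <- match.arg(substrate)
  stopifnot(true_rho >= 0, noise_sd >= 0, n_replicates >= 1)
  element <- if (substrate == "bicarbonate") "C" else "N"
  defaults <- switch(substrate,
    ammonium    = list(v_add_ul = 50,  nat_conc_umol_l = 0.04, pom_mass_mg = 0.3),
    nitrate     = list(v_add_ul = 30,  nat_conc_umol_l = 3.2,  pom_mass_mg = 0.3),
    bicarbonate = list(v_add_ul = 500, nat_conc_umol_l = 800,  pom_mass_mg = 1.5)
  )
  structure(list(
    true_rho = true_rho, element = element, substrate = substrate,
    v_add_ul = v_add_ul %||% defaults$v_add_ul,
    t_conc_umol_l = t_conc_umol_l, v_inc_ml = v_inc_ml,
    nat_conc_umol_l = nat_conc_umol_l %||% defaults$nat_conc_umol_l,
    pom_mass_mg = pom_mass_mg %||% defaults$pom_mass_mg,
    mat_dry_mass_mg = mat_dry_mass_mg, core_dry_mass_mg = core_dry_mass_mg,
    time_inc_h = time_inc_h, noise_sd = noise_sd,
    n_replicates = as.integer(n_replicates),
    tracer_atom_fraction = tracer_atom_fraction,
    nat_abundance = nat_abundance %||% natural_abundance(element),
    light = light, seed = as.integer(seed)
  ), class = "incubation_scenario")
}

#' Simulate a tracer incubation with known true uptake rate
#'
#' Runs the rate model forward: the spike parameters give the dissolved-pool
#' excess enrichment, the ground-truth rate is inverted to the noise-free
#' final atom % it implies, and Gaussian measurement noise (sd = `noise_sd`,
#' clipped to the physical 0–100 atom % range) is added to the enriched
#' readings. Two un-amended control vials at exact natural abundance are
#' appended; the controls define the baseline the scenario asserts, so the
#' noise model applies only to the enriched measurements. Output is
#' deterministic given the scenario seed.
#'
#' @param scenario An [incubation_scenario()].
#' @return Tibble in the incubation-table layout accepted by
#'   [compute_rates()], with `n_replicates` amended vials plus 2 controls.
#' @export
simulate_incubation <- function(scenario) {
  stopifnot(inherits(scenario, "incubation_scenario"))
  s <- scenario
  r_exc <- excess_enrichment(
    v_add = s$v_add_ul * 1e-6, t_conc = s$t_conc_umol_l * 1e-6,
    v_inc = s$v_inc_ml * 1e-3, nat_conc = s$nat_conc_umol_l * 1e-6,
    nat_abundance = s$nat_abundance,
    tracer_atom_fraction = s$tracer_atom_fraction)
  pom_nmol <- s$pom_mass_mg / MOLAR_MASS[[s$element]] * 1e6
  # invert rho = (at_f - nat)/r_exc * pom_nmol / mat / t  for at_f
  at_clean <- s$nat_abundance +
    s$true_rho * r_exc * s$mat_dry_mass_mg * s$time_inc_h / pom_nmol
  if (at_clean > 100) {
    abort(paste0(
      "infeasible scenario: true_rho = ", s$true_rho,
      " implies a final atom % of ", signif(at_clean, 5),
      " > 100; the particulate pool (pom_mass_mg = ", s$pom_mass_mg,
      ") is too small to absorb that much tracer over ", s$time_inc_h, " h"))
  }
  set.seed(s$seed)
  at_obs <- at_clean + stats::rnorm(s$n_replicates, 0, s$noise_sd)
  at_obs <- pmin(pmax(at_obs, 0), 100)
  base <- tibble(
    element = s$element, substrate = s$substrate,
    V_add_uL = s$v_add_ul, T_conc_umol_L = s$t_conc_umol_l,
    V_inc_mL = s$v_inc_ml, Nat_conc_umol_L = s$nat_conc_umol_l,
    POM_mass_mg = s$pom_mass_mg, mat_dry_mass_mg = s$mat_dry_mass_mg,
    core_dry_mass_mg = s$core_dry_mass_mg,
    time_inc_h = s$time_inc_h, light = s$light
  )
  vials <- dplyr::bind_cols(
    tibble(sample_id = sprintf("%s_rep%d", s$substrate, seq_len(s$n_replicates)),
           AT_f_atom_pct = at_obs, is_control = FALSE),
    base[rep(1, s$n_replicates), ])
  controls <- dplyr::bind_cols(
    tibble(sample_id = sprintf("%s_ctrl%d", s$substrate, 1:2),
           AT_f_atom_pct = s$nat_abundance, is_control = TRUE),
    dplyr::mutate(base[rep(1, 2), ], V_add_uL = 0))
  out <- dplyr::bind_rows(vials, controls)
  out[, c(INCUBATION_COLS, "core_dry_mass_mg")]
}

#' Define a synthetic community-activity scenario
#'
#' Describes a community whose per-sample activity is known exactly, for
#' generating annotated marker-gene count tables: each taxon has a relative
#' activity in every sample (log-normal-like spread across taxa is up to the
#' caller) and a weight on each pathway it expresses; expected feature
#' abundance is taxon activity x pathway weight x gene-length exposure, and
#' integer counts are drawn from a Poisson (or negative binomial when
#' `overdispersion > 0`) at the requested per-sample depth.
#'
#' @param taxa Tibble with columns `taxon_id`, `lineage`
#'   (semicolon-delimited, domain to genus).
#' @param activity Numeric matrix taxa x samples of relative activities
#'   (row names = `taxon_id`, column names = sample ids); non-negative.
#' @param pathway_profile Tibble with columns `taxon_id`, `pathway_id`,
#'   `weight` (non-negative).
#' @param samples Sample sheet tibble (`sample_id`, `temperature_C`,
#'   `library`, `time_of_day`); `library_size` is derived.
#' @param depth Expected reads per sample falling on marker-gene features.
#' @param library_scale Library size as a multiple of `depth` (marker genes
#'   are a small subset of a real library); default 10.
#' @param length_range Gene lengths are drawn log-uniformly from this range
#'   (bp); default 600–3000 so FPKM length-correction is consequential.
#' @param overdispersion Negative-binomial overdispersion (0 = Poisson).
#' @param seed Integer seed.
#' @return A list of class `community_scenario`.
#' @export
community_scenario <- function(taxa, activity, pathway_profile, samples,
                               depth = 1e5, library_scale = 10,
                               length_range = c(600, 3000),
                               overdispersion = 0, seed = 1) {
  if (is.null(taxa) || nrow(taxa) == 0) abort("empty taxa list")
  stopifnot(all(c("taxon_id", "lineage") %in% names(taxa)),
            all(c("taxon_id", "pathway_id", "weight") %in% names(pathway_profile)),
            is.matrix(activity), all(activity >= 0),
            all(pathway_profile$weight >= 0),
            depth > 0, length_range[1] > 0, length_range[2] >= length_range[1],
            overdispersion >= 0)
  stopifnot(setequal(rownames(activity), taxa$taxon_id),
            setequal(colnames(activity), samples$sample_id))
  structure(list(
    taxa = as_tibble(taxa), activity = activity,
    pathway_profile = as_tibble(pathway_profile), samples = as_tibble(samples),
    depth = depth, library_scale = library_scale, length_range = length_range,
    overdispersion = overdispersion, seed = as.integer(seed)
  ), class = "community_scenario")
}

#' Simulate an annotated marker-gene count table
#'
#' Generates one feature per (taxon, marker gene of an expressed pathway),
#' with gene lengths drawn log-uniformly, expected counts proportional to
#' taxon activity x pathway weight x gene length (split evenly over the
#' pathway's markers and scaled so each sample's expected column sum equals
#' the scenario depth), and integer counts drawn Poisson (or negative
#' binomial). Every catalog marker gene receives annotation rows even when no
#' taxon expresses its pathway, so absent pathways are representable as
#' zero-count features. Returns the exact generating share vectors for
#' assertion: FPKM-scale shares are length-free (activity x weight), raw
#' count-scale shares carry the length exposure.
#'
#' @param scenario A [community_scenario()].
#' @param catalog A `marker_catalog`.
#' @return List with elements `annotations` (tibble), `counts` (integer
#'   matrix), `samples` (sample sheet with `library_size`), and `truth`
#'   (list: `pathway_shares`, `overall_shares`, `expected_counts`).
#' @export
simulate_counts <- function(scenario, catalog = default_catalog()) {
  stopifnot(inherits(scenario, "community_scenario"),
            inherits(catalog, "marker_catalog"))
  s <- scenario
  set.seed(s$seed)

  prof <- s$pathway_profile[s$pathway_profile$weight > 0, ]
  bad_pw <- setdiff(prof$pathway_id, catalog$pathway_id)
  if (length(bad_pw) > 0) {
    abort(paste0("pathway_profile references unknown pathway(s): ",
                 paste(bad_pw, collapse = ", ")))
  }
  n_genes <- table(catalog$pathway_id)

  # feature skeleton: every (taxon, pathway, marker) with weight > 0
  feat <- dplyr::inner_join(prof, as_tibble(unclass_catalog(catalog)),
                            by = "pathway_id", relationship = "many-to-many")
  # plus orphan markers of pathways no taxon expresses, hosted by the first
  # taxon with zero weight so the annotation covers the whole catalog
  orphan <- catalog$symbol[!catalog$pathway_id %in% prof$pathway_id]
  if (length(orphan) > 0) {
    extra <- as_tibble(unclass_catalog(catalog))[match(orphan, catalog$symbol), ]
    extra$taxon_id <- s$taxa$taxon_id[1]
    extra$weight <- 0
    feat <- dplyr::bind_rows(feat, extra[names(feat)])
  }
  feat$feature_id <- paste(feat$taxon_id, feat$symbol, sep = "_")
  feat$length_bp <- round(exp(stats::runif(
    nrow(feat), log(s$length_range[1]), log(s$length_range[2]))))
  feat$lineage <- s$taxa$lineage[match(feat$taxon_id, s$taxa$taxon_id)]

  # expected relative abundance per feature and sample
  act <- s$activity[feat$taxon_id, s$samples$sample_id, drop = FALSE]
  per_gene_w <- feat$weight / as.numeric(n_genes[feat$pathway_id])
  rel <- act * per_gene_w * (feat$length_bp / 1000)
  col_tot <- colSums(rel)
  expected <- sweep(rel, 2, ifelse(col_tot > 0, col_tot, 1), "/") * s$depth
  expected[, col_tot == 0] <- 0
  dimnames(expected) <- list(feat$feature_id, s$samples$sample_id)

  counts <- matrix(
    if (s$overdispersion > 0) {
      stats::rnbinom(length(expected), mu = as.vector(expected),
                     size = 1 / s$overdispersion)
    } else {
      stats::rpois(length(expected), as.vector(expected))
    },
    nrow = nrow(expected), dimnames = dimnames(expected))

  annotations <- tibble(
    feature_id = feat$feature_id, gene_symbol = feat$symbol,
    length_bp = feat$length_bp, taxon_lineage = feat$lineage)
  samples <- s$samples
  samples$library_size <- s$depth * s$library_scale

  # generating shares: FPKM-scale contribution of a taxon to a pathway is
  # activity x weight (gene count and length cancel under FPKM)
  aw <- dplyr::bind_cols(prof, as_tibble(
    s$activity[prof$taxon_id, s$samples$sample_id, drop = FALSE] * prof$weight))
  aw_long <- tidyr::pivot_longer(aw, cols = dplyr::all_of(s$samples$sample_id),
                                 names_to = "sample_id", values_to = "aw")
  pathway_shares <- dplyr::mutate(
    dplyr::group_by(aw_long, .data$pathway_id, .data$sample_id),
    share_pct = 100 * .data$aw / sum(.data$aw))
  pathway_shares <- dplyr::ungroup(
    dplyr::filter(pathway_shares, !is.nan(.data$share_pct)))
  overall <- dplyr::summarise(
    dplyr::group_by(aw_long, .data$taxon_id, .data$sample_id),
    aw = sum(.data$aw), .groups = "drop")
  overall <- dplyr::mutate(
    dplyr::group_by(overall, .data$sample_id),
    share_pct = 100 * .data$aw / sum(.data$aw))
  overall <- dplyr::ungroup(overall)

  list(
    annotations = annotations,
    counts = counts,
    samples = samples,
    truth = list(
      pathway_shares = pathway_shares[
        c("taxon_id", "pathway_id", "sample_id", "share_pct")],
      overall_shares = overall[c("taxon_id", "sample_id", "share_pct")],
      expected_counts = expected
    )
  )
}

#' A synthetic hot-spring mat community preset
#'
#' A six-sample (three temperatures x day/night) x two-library community of
#' eight taxa emulating the broad activity structure of a neutral hot-spring
#' mat: Cyanobacteria (*Mastigocladus*) dominate transcription at 48 degC by
#' day, Chloroflexi (*Chloroflexus*, *Roseiflexus*) dominate at 66 degC,
#' Proteobacteria transcription is elevated at night, Thaumarchaeota carry
#' ammonia oxidation, and an anammox Planctomycete is present in the
#' annotation but never active (its marker stays at zero counts). The preset
#' is synthetic: its magnitudes are chosen for well-separated dominance
#' orderings, not asserted against any published figure.
#'
#' @param depth Expected marker-gene reads per sample.
#' @param seed Integer seed.
#' @param overdispersion Negative-binomial overdispersion (0 = Poisson).
#' @return A [community_scenario()].
#' @export
porcelana_like_scenario <- function(depth = 1e5, seed = 1, overdispersion = 0) {
  taxa <- tibble(
    taxon_id = c("Mastigocladus", "Leptolyngbya", "Chloroflexus", "Roseiflexus",
                 "Elioraea", "Nitrososphaera", "Rhodothermus", "Scalindua"),
    lineage = c(
      "Bacteria;Cyanobacteria;Cyanophyceae;Stigonematales;Hapalosiphonaceae;Mastigocladus",
      "Bacteria;Cyanobacteria;Cyanophyceae;Oscillatoriales;Leptolyngbyaceae;Leptolyngbya",
      "Bacteria;Chloroflexi;Chloroflexia;Chloroflexales;Chloroflexaceae;Chloroflexus",
      "Bacteria;Chloroflexi;Chloroflexia;Chloroflexales;Roseiflexaceae;Roseiflexus",
      "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodospirillales;Acetobacteraceae;Elioraea",
      "Archaea;Thaumarchaeota;Nitrososphaeria;Nitrososphaerales;Nitrososphaeraceae;Nitrososphaera",
      "Bacteria;Bacteroidetes;Rhodothermia;Rhodothermales;Rhodothermaceae;Rhodothermus",
      "Bacteria;Planctomycetes;Planctomycetia;Candidatus Brocadiales;Candidatus Brocadiaceae;Scalindua"))

  grid <- expand.grid(temperature_C = c(66, 58, 48),
                      time_of_day = c("day", "night"),
                      library = c("DNA", "cDNA"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("T%d_%s_%s", grid$temperature_C,
                            grid$time_of_day, grid$library)
  samples <- as_tibble(grid[c("sample_id", "temperature_C", "library",
                              "time_of_day")])

  # relative abundance (DNA) by temperature; transcription (cDNA) modulates
  # it. Values are chosen so that the generating phylum shares are separated
  # by at least ~0.9 percentage points in every sample: the preset's dominance
  # orderings are meant to be recoverable, not marginal.
  abund <- rbind(
    Mastigocladus  = c(`66` = 0.032, `58` = 0.277, `48` = 0.494),
    Leptolyngbya   = c(`66` = 0.051, `58` = 0.037, `48` = 0.023),
    Chloroflexus   = c(`66` = 0.548, `58` = 0.353, `48` = 0.070),
    Roseiflexus    = c(`66` = 0.183, `58` = 0.091, `48` = 0.051),
    Elioraea       = c(`66` = 0.030, `58` = 0.194, `48` = 0.182),
    Nitrososphaera = c(`66` = 0.096, `58` = 0.062, `48` = 0.044),
    Rhodothermus   = c(`66` = 0.059, `58` = 0.032, `48` = 0.027),
    Scalindua      = c(`66` = 0.000, `58` = 0.000, `48` = 0.000))
  # cDNA day boosts phototrophs, cDNA night boosts heterotrophic Proteobacteria
  boost <- list(
    day = c(Mastigocladus = 1.55, Leptolyngbya = 1.12, Chloroflexus = 1.41,
            Roseiflexus = 0.89, Elioraea = 0.32, Nitrososphaera = 1.02,
            Rhodothermus = 0.64, Scalindua = 0),
    night = c(Mastigocladus = 0.47, Leptolyngbya = 0.31, Chloroflexus = 0.80,
              Roseiflexus = 0.67, Elioraea = 6.92, Nitrososphaera = 1.25,
              Rhodothermus = 2.32, Scalindua = 0))
  activity <- sapply(seq_len(nrow(samples)), function(i) {
    a <- abund[, as.character(samples$temperature_C[i])]
    if (samples$library[i] == "cDNA") a <- a * boost[[samples$time_of_day[i]]]
    a
  })
  colnames(activity) <- samples$sample_id

  pathway_profile <- tibble::tribble(
    ~taxon_id,        ~pathway_id,               ~weight,
    "Mastigocladus",  "oxygenic_photosynthesis", 1.0,
    "Mastigocladus",  "cbb",                     0.8,
    "Mastigocladus",  "n2_fixation",             0.5,
    "Mastigocladus",  "ammonia_assimilation",    0.3,
    "Leptolyngbya",   "oxygenic_photosynthesis", 0.6,
    "Leptolyngbya",   "cbb",                     0.4,
    "Chloroflexus",   "anoxygenic_phototrophy",  1.0,
    "Chloroflexus",   "hp_bicycle",              0.8,
    "Chloroflexus",   "ammonia_assimilation",    0.4,
    "Roseiflexus",    "anoxygenic_phototrophy",  0.7,
    "Roseiflexus",    "hp_bicycle",              0.4,
    "Roseiflexus",    "n2_fixation",             0.1,
    "Elioraea",       "anoxygenic_phototrophy",  0.3,
    "Elioraea",       "denitrification",         0.2,
    "Elioraea",       "ammonia_assimilation",    0.3,
    "Nitrososphaera", "ammonia_oxidation",       1.0,
    "Nitrososphaera", "hh_cycle",                0.6,
    "Rhodothermus",   "denitrification",         0.6,
    "Rhodothermus",   "dnra",                    0.3,
    "Rhodothermus",   "ammonia_assimilation",    0.2,
    "Scalindua",      "anammox",                 1.0)

  community_scenario(taxa, activity, pathway_profile, samples,
                     depth = depth, overdispersion = overdispersion,
                     seed = seed)
}
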