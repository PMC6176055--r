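# Molar masses (g mol^-1) used to convert particulate organic N/C mass to moles.
MOLAR_MASS <- c(N = 14.0067, C = 12.011)

# International-standard natural abundances of the heavy isotope (atom %).
NATURAL_ABUNDANCE <- c(N = 0.3663, C = 1.108)

#' Default natural abundance of the heavy isotope
#'
#' Atom % of 15N (0.3663) or 13C (1.108) in unlabeled material, by
#' international standard. Un-amended control incubations, when available,
#' override these defaults (see [compute_rates()]).
#'
#' @param element `"N"` or `"C"`.
#' @return Natural abundance in atom %.
#' @export
natural_abundance <- function(element) {
  element <- match.arg(element, c("N", "C"), several.ok = FALSE)
  unname(NATURAL_ABUNDANCE[element])
}

#' Excess enrichment of the dissolved pool after tracer addition
#'
#' When a volume `v_add` of tracer solution at concentration `t_conc` is mixed
#' into an incubation of volume `v_inc` whose ambient substrate pool is
#' `nat_conc` at natural isotopic abundance, the dissolved pool's heavy-atom
#' percentage rises above natural abundance by the excess enrichment
#' \deqn{\%R_{exc} = 100\,\frac{A f_t + C_{nat}\,a_{nat}/100}{C_{nat} + A} - a_{nat},
#'   \qquad A = \frac{V_{add} T_{conc}}{V_{inc}}}
#' where \eqn{f_t} is the tracer's isotopic purity (atom fraction of the heavy
#' isotope; commercial tracers are typically 0.98–1.0) and \eqn{a_{nat}} the
#' natural abundance in atom %. This is the standard pool-mixing atom-percent
#' identity: it equals heavy moles over total moles of the mixed pool, so any
#' consistent unit system for volumes and concentrations gives the same result.
#'
#' @param v_add Volume of tracer solution added (same volume unit as `v_inc`).
#' @param t_conc Tracer concentration (same concentration unit as `nat_conc`).
#' @param v_inc Incubated sample volume.
#' @param nat_conc Ambient (pre-spike) concentration of the tracked pool.
#' @param nat_abundance Natural abundance of the heavy isotope (atom %).
#' @param tracer_atom_fraction Isotopic purity of the tracer, in (0, 1].
#' @return Excess enrichment in atom % (vectorized over inputs).
#' @examples
#' # 50 uL of 500 umol/L 15N-ammonium into 1 mL with 0.04 umol/L ambient NH4+
#' excess_enrichment(50e-6, 500e-6, 1e-3, 0.04e-6, 0.3663)
#' @export
excess_enrichment <- function(v_add, t_conc, v_inc, nat_conc, nat_abundance,
                              tracer_atom_fraction = 1) {
  stopifnot(all(v_add >= 0), all(t_conc >= 0), all(v_inc > 0),
            all(nat_conc >= 0),
            all(nat_abundance >= 0), all(nat_abundance < 100),
            all(tracer_atom_fraction > 0), all(tracer_atom_fraction <= 1))
  added <- v_add * t_conc / v_inc
  total <- nat_conc + added
  if (any(total <= 0)) {
    abort("undefined pool: no ambient substrate and no tracer added (total pool is zero)")
  }
  100 * (added * tracer_atom_fraction + nat_conc * nat_abundance / 100) / total -
    nat_abundance
}

#' Assimilation rate from particulate isotopic excess
#'
#' Converts the measured heavy-isotope excess of the particulate fraction into
#' a substrate uptake rate per unit mat dry mass:
#' \deqn{\rho = \frac{\%AT_f - a_{nat}}{\%R_{exc}} \cdot
#'   \frac{\mathrm{POM\ (nmol)}}{\mathrm{mat\ dry\ mass\ (mg)}\cdot t_{inc}}}
#' where POM is the particulate organic N or C recovered after incubation,
#' converted from mg to nmol with the element's molar mass (N 14.0067,
#' C 12.011 g mol^-1). Measurements whose excess \eqn{\%AT_f - a_{nat}} does
#' not exceed `detection_threshold` (default 0.001 atom %, typical IRMS
#' precision) are flagged below detection and reported as zero rate —
#' measurement noise below detection must not produce negative uptake — while
#' the raw unclamped value is retained for diagnostics.
#'
#' @param at_f Final atom % of the heavy isotope in the particulate fraction.
#' @param nat_abundance Natural abundance (atom %), ideally control-derived.
#' @param r_exc Excess enrichment of the dissolved pool (atom %), from
#'   [excess_enrichment()]; must be positive.
#' @param pom_mass_mg Particulate organic N or C recovered (mg of N or C).
#' @param mat_dry_mass_mg Dry mass of mat analyzed (mg).
#' @param time_inc_h Incubation duration (hours).
#' @param element `"N"` or `"C"`.
#' @param detection_threshold Minimum atom % excess considered detectable.
#' @return Tibble with columns `rho` (nmol mg^-1 h^-1), `rho_raw` (unclamped),
#'   `below_detection` (logical).
#' @export
assimilation_rate <- function(at_f, nat_abundance, r_exc, pom_mass_mg,
                              mat_dry_mass_mg, time_inc_h, element,
                              detection_threshold = 1e-3) {
  stopifnot(all(at_f >= 0), all(at_f <= 100),
            all(pom_mass_mg > 0), all(mat_dry_mass_mg > 0),
            all(time_inc_h > 0))
  if (any(r_exc <= 0)) {
    abort("r_exc must be positive: cannot scale particulate excess by a non-positive pool enrichment")
  }
  element <- match.arg(element, c("N", "C"), several.ok = FALSE)
  pom_nmol <- pom_mass_mg / MOLAR_MASS[[element]] * 1e6  # mg / (g/mol) = mmol
  rho_raw <- (at_f - nat_abundance) / r_exc * pom_nmol / mat_dry_mass_mg / time_inc_h
  below <- (at_f - nat_abundance) <= detection_threshold
  tibble(
    rho = ifelse(below, 0, rho_raw),
    rho_raw = rho_raw,
    below_detection = below
  )
}

#' Cross-sectional area of a sampling core
#'
#' @param diameter_cm Core diameter in cm (default 0.7, a 7 mm cork borer).
#' @return Area in cm^2.
#' @export
core_area <- function(diameter_cm = 0.7) {
  stopifnot(all(diameter_cm > 0))
  pi * (diameter_cm / 2)^2
}

#' Extrapolate a per-mass hourly rate to a daily areal rate
#'
#' Scales the per-mg-per-hour assimilation rate by the dry mass of the core
#' and its cross-sectional area, then by the photoperiod, to express the rate
#' per cm^2 of mat per day. Light-dependent rates can be extrapolated over
#' daylight hours only by lowering `photoperiod_hours`; the default of 24 h
#' treats the hourly rate as holding around the clock.
#'
#' @param rho_mass Rate per dry mass (nmol mg^-1 h^-1).
#' @param core_dry_mass_mg Total dry mass of the core(s) behind one unit of
#'   mat area (mg).
#' @param area_cm2 Mat area sampled (cm^2); see [core_area()].
#' @param photoperiod_hours Hours per day over which the hourly rate applies.
#' @return Daily areal rate (nmol cm^-2 d^-1).
#' @export
areal_daily_rate <- function(rho_mass, core_dry_mass_mg,
                             area_cm2 = core_area(),
                             photoperiod_hours = 24) {
  stopifnot(all(core_dry_mass_mg > 0), all(area_cm2 > 0),
            all(photoperiod_hours > 0), all(photoperiod_hours <= 24))
  rho_mass * core_dry_mass_mg / area_cm2 * photoperiod_hours
}

#' Turnover time of a nutrient pool
#'
#' Standing ambient concentration divided by its volumetric uptake rate: the
#' time for the community to consume the pool once. A zero uptake rate flags
#' infinite turnover (`Inf`) rather than raising an error; a zero pool turns
#' over instantly (0 h).
#'
#' @param nat_conc Ambient concentration (any amount-per-volume unit).
#' @param uptake_rate Volumetric uptake rate (same amount unit per hour).
#' @return Turnover time in hours (vectorized).
#' @export
turnover_time <- function(nat_conc, uptake_rate) {
  stopifnot(all(nat_conc >= 0))
  if (any(uptake_rate < 0)) abort("uptake_rate must be non-negative")
  ifelse(nat_conc == 0, 0, ifelse(uptake_rate == 0, Inf, nat_conc / uptake_rate))
}

#' Configuration for rate computation
#'
#' Bundles the tunable constants of the isotope-rate pipeline. Defaults:
#' international natural abundances (15N 0.3663, 13C 1.108 atom %), tracer
#' purity 1.0, 24 h photoperiod, 0.001 atom % detection threshold, 7 mm core
#' diameter, and a fixed dissolved inorganic carbon pool of 800 umol L^-1
#' used for bicarbonate incubations when the incubation table does not supply
#' an ambient concentration.
#'
#' @param nat_abundance Named vector of default natural abundances (atom %),
#'   names `"N"` and `"C"`.
#' @param tracer_atom_fraction Tracer isotopic purity in (0, 1].
#' @param photoperiod_hours Hours used for daily extrapolation.
#' @param detection_threshold Atom % excess below which rates are zeroed.
#' @param core_diameter_cm Core diameter for areal extrapolation.
#' @param dic_umol_l Fallback dissolved inorganic carbon pool (umol L^-1).
#' @return A list of class `rate_config`.
#' @export
rate_config <- function(nat_abundance = NATURAL_ABUNDANCE,
                        tracer_atom_fraction = 1,
                        photoperiod_hours = 24,
                        detection_threshold = 1e-3,
                        core_diameter_cm = 0.7,
                        dic_umol_l = 800) {
  stopifnot(all(c("N", "C") %in% names(nat_abundance)))
  structure(list(
    nat_abundance = nat_abundance,
    tracer_atom_fraction = tracer_atom_fraction,
    photoperiod_hours = photoperiod_hours,
    detection_threshold = detection_threshold,
    core_diameter_cm = core_diameter_cm,
    dic_umol_l = dic_umol_l
  ), class = "rate_config")
}

INCUBATION_COLS <- c(
  "sample_id", "element", "substrate", "V_add_uL", "T_conc_umol_L", "V_inc_mL",
  "Nat_conc_umol_L", "AT_f_atom_pct", "POM_mass_mg", "mat_dry_mass_mg",
  "time_inc_h", "is_control", "light"
)

#' Read an incubation measurement table
#'
#' One row per incubated vial. Required columns (units fixed by the header
#' names): `sample_id`, `element` (N/C), `substrate` (ammonium, nitrate,
#' bicarbonate), `V_add_uL`, `T_conc_umol_L`, `V_inc_mL`, `Nat_conc_umol_L`,
#' `AT_f_atom_pct`, `POM_mass_mg`, `mat_dry_mass_mg`, `time_inc_h`,
#' `is_control` (logical; un-amended natural-abundance controls), `light`
#' (logical). An optional `core_dry_mass_mg` column supplies the whole-core
#' dry mass for areal extrapolation; it defaults to `mat_dry_mass_mg` (the
#' mass analyzed on the mass spectrometer) when absent.
#'
#' @param path Path to a tab-separated incubation table.
#' @return Tibble of incubation measurements.
#' @export
read_incubations <- function(path) {
  if (!file.exists(path)) abort(paste0("incubation file not found: ", path))
  df <- readr::read_tsv(path, comment = "#", progress = FALSE,
                        col_types = readr::cols(
                          sample_id = "c", element = "c", substrate = "c",
                          is_control = "l", light = "l",
                          .default = "d"))
  missing <- setdiff(INCUBATION_COLS, names(df))
  if (length(missing) > 0) {
    abort(paste0("incubation table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"core_dry_mass_mg" %in% names(df)) df$core_dry_mass_mg <- df$mat_dry_mass_mg
  df
}

#' Compute assimilation rates for an incubation table
#'
#' Runs the full rate pipeline on a table of incubation measurements (see
#' [read_incubations()]): un-amended controls (rows with `is_control = TRUE`)
#' are averaged per element to replace the default natural abundance; the
#' dissolved-pool excess enrichment is computed from the spike parameters of
#' each vial; particulate isotopic excess is converted to a per-mass rate,
#' extrapolated to a daily areal rate, and the ambient pool turnover time is
#' derived from the volumetric uptake in the vial. Bicarbonate rows lacking
#' `Nat_conc_umol_L` fall back to the configured dissolved inorganic carbon
#' pool.
#'
#' @param incubations Tibble as returned by [read_incubations()].
#' @param config A [rate_config()].
#' @return Tibble with one row per non-control vial: inputs plus
#'   `nat_abundance_used`, `spike_pct_of_pool` (added tracer as percent of
#'   the ambient pool — values far above ~10% mark additions that perturb
#'   rather than trace the pool), `r_exc_pct`, `rho_mass` (nmol mg^-1 h^-1),
#'   `rho_raw`, `below_detection`, `rho_areal_daily` (nmol cm^-2 d^-1),
#'   `uptake_umol_l_h`, `turnover_h`.
#' @export
compute_rates <- function(incubations, config = rate_config()) {
  stopifnot(inherits(config, "rate_config"))
  if (is.null(incubations) || nrow(incubations) == 0) {
    abort("empty incubation table: nothing to compute")
  }
  if (!"core_dry_mass_mg" %in% names(incubations)) {
    incubations$core_dry_mass_mg <- incubations$mat_dry_mass_mg
  }
  bad_el <- setdiff(unique(incubations$element), c("N", "C"))
  if (length(bad_el) > 0) {
    abort(paste0("unknown element(s): ", paste(bad_el, collapse = ", ")))
  }
  controls <- incubations[incubations$is_control, , drop = FALSE]
  vials <- incubations[!incubations$is_control, , drop = FALSE]
  if (nrow(vials) == 0) abort("incubation table contains only controls")

  nat_ab_for <- function(el) {
    ctl <- controls$AT_f_atom_pct[controls$element == el]
    if (length(ctl) > 0) mean(ctl) else unname(config$nat_abundance[[el]])
  }

  out <- lapply(seq_len(nrow(vials)), function(i) {
    row <- vials[i, ]
    nat_ab <- nat_ab_for(row$element)
    nat_conc <- row$Nat_conc_umol_L
    if (is.na(nat_conc)) {
      if (identical(row$substrate, "bicarbonate")) {
        nat_conc <- config$dic_umol_l
      } else {
        abort(paste0("row ", row$sample_id, ": Nat_conc_umol_L is missing"))
      }
    }
    # SI internally: uL -> L, umol/L -> mol/L, mL -> L
    r_exc <- excess_enrichment(
      v_add = row$V_add_uL * 1e-6,
      t_conc = row$T_conc_umol_L * 1e-6,
      v_inc = row$V_inc_mL * 1e-3,
      nat_conc = nat_conc * 1e-6,
      nat_abundance = nat_ab,
      tracer_atom_fraction = config$tracer_atom_fraction
    )
    rate <- assimilation_rate(
      at_f = row$AT_f_atom_pct, nat_abundance = nat_ab, r_exc = r_exc,
      pom_mass_mg = row$POM_mass_mg, mat_dry_mass_mg = row$mat_dry_mass_mg,
      time_inc_h = row$time_inc_h, element = row$element,
      detection_threshold = config$detection_threshold
    )
    areal <- areal_daily_rate(
      rate$rho, row$core_dry_mass_mg,
      area_cm2 = core_area(config$core_diameter_cm),
      photoperiod_hours = config$photoperiod_hours
    )
    # volumetric uptake in the vial (umol L^-1 h^-1): nmol/mg/h * mg / L / 1000
    uptake <- rate$rho * row$core_dry_mass_mg / (row$V_inc_mL * 1e-3) / 1e3
    # tracer-to-pool ratio: flags spikes that perturb the ambient pool far
    # beyond trace additions (a true tracer stays near 10% of the pool)
    added_umol_l <- row$V_add_uL * row$T_conc_umol_L / (row$V_inc_mL * 1000)
    tibble(
      row[c("sample_id", "element", "substrate", "light")],
      nat_abundance_used = nat_ab,
      spike_pct_of_pool = 100 * added_umol_l / nat_conc,
      r_exc_pct = r_exc,
      rho_mass = rate$rho,
      rho_raw = rate$rho_raw,
      below_detection = rate$below_detection,
      rho_areal_daily = areal,
      uptake_umol_l_h = uptake,
      turnover_h = turnover_time(nat_conc, uptake)
    )
  })
  dplyr::bind_rows(out)
}

#' Summarize replicate rate results
#'
#' Arithmetic mean and sample standard deviation of the daily areal rate
#' across biological replicates, grouped by element, substrate and
#' light/dark condition.
#'
#' @param rates Tibble from [compute_rates()].
#' @return Tibble with `element`, `substrate`, `light`, `n`,
#'   `mean_rho_areal_daily`, `sd_rho_areal_daily`, `mean_turnover_h`,
#'   `nat_abundance_used`.
#' @export
summarize_replicates <- function(rates) {
  if (is.null(rates) || nrow(rates) == 0) abort("empty rate table: nothing to summarize")
  dplyr::summarise(
    dplyr::group_by(rates, .data$element, .data$substrate, .data$light),
    n = dplyr::n(),
    mean_rho_areal_daily = mean(.data$rho_areal_daily),
    sd_rho_areal_daily = stats::sd(.data$rho_areal_daily),
    mean_turnover_h = mean(.data$turnover_h),
    nat_abundance_used = mean(.data$nat_abundance_used),
    .groups = "drop"
  )
}
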