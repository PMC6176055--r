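# Independent oracles: deliberately naive re-derivations used to check the
# package's closed-form implementations.

# Heavy/light mole bookkeeping for the post-spike pool: count heavy and total
# moles of the mixed dissolved pool explicitly, form atom% by division.
oracle_excess_enrichment <- function(v_add, t_conc, v_inc, nat_conc,
                                     nat_abundance, f_t = 1) {
  tracer_mol <- v_add * t_conc
  ambient_mol <- nat_conc * v_inc
  heavy_mol <- tracer_mol * f_t + ambient_mol * nat_abundance / 100
  total_mol <- tracer_mol + ambient_mol
  100 * heavy_mol / total_mol - nat_abundance
}

# Spreadsheet-style stepwise rate evaluation, one factor at a time with an
# explicit unit audit in the comments.
oracle_assimilation_rate <- function(at_f, nat_abundance, r_exc, pom_mass_mg,
                                     mat_dry_mass_mg, time_inc_h, molar_mass) {
  excess_fraction <- (at_f - nat_abundance) / r_exc   # atom% / atom% -> unitless
  pom_mmol <- pom_mass_mg / molar_mass                # mg / (g mol^-1) = mmol
  pom_nmol <- pom_mmol * 1e6                          # mmol -> nmol
  per_mg <- pom_nmol / mat_dry_mass_mg                # nmol per mg dry mass
  per_mg_per_h <- per_mg / time_inc_h                 # ... per hour
  excess_fraction * per_mg_per_h
}

# Minimal two-taxon, single-pathway community: taxon A holds a fraction p of
# the activity, taxon B the rest, in both samples. The single-gene pathway
# (rbcL) makes the generating FPKM-scale shares exactly {p, 1-p}.
two_taxon_scenario <- function(depth = 1e6, seed = 1, p = 0.8) {
  taxa <- tibble::tibble(
    taxon_id = c("A", "B"),
    lineage = c("Bacteria;PhylumA;ClassA;OrderA;FamilyA;GenusA",
                "Bacteria;PhylumB;ClassB;OrderB;FamilyB;GenusB"))
  samples <- tibble::tibble(
    sample_id = c("s1", "s2"), temperature_C = c(58, 48),
    library = "cDNA", time_of_day = "day")
  activity <- matrix(rep(c(p, 1 - p), 2), nrow = 2,
                     dimnames = list(c("A", "B"), c("s1", "s2")))
  profile <- tibble::tibble(taxon_id = c("A", "B"), pathway_id = "cbb",
                            weight = 1)
  community_scenario(taxa, activity, profile, samples,
                     depth = depth, seed = seed)
}

# Tiny annotated matrix shared by several quantification tests.
toy_quant <- function() {
  ann <- tibble::tibble(
    feature_id = c("f1", "f2", "f3"),
    gene_symbol = c("nifH", "rbcL", "rbcL"),
    length_bp = c(1000, 500, 2000),
    taxon_lineage = c(
      "Bacteria;Cyanobacteria;Cyanophyceae;Stigonematales;Hapalosiphonaceae;Mastigocladus",
      "Bacteria;Cyanobacteria;Cyanophyceae;Stigonematales;Hapalosiphonaceae;Mastigocladus",
      "Bacteria;Chloroflexi;Chloroflexia;Chloroflexales;Chloroflexaceae;Chloroflexus"))
  counts <- matrix(c(30, 10, 250, 0, 40, 40), nrow = 3, byrow = TRUE,
                   dimnames = list(c("f1", "f2", "f3"), c("day58", "night58")))
  list(ann = ann, counts = counts,
       libs = c(day58 = 5e6, night58 = 5e6))
}
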