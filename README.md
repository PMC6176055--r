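# matflux

Quantitative analysis of carbon and nitrogen cycling in microbial mats, from
two complementary measurements:

1. **Stable-isotope tracer incubations.** Mat cores are incubated with
   ¹⁵N-ammonium, ¹⁵N-nitrate or ¹³C-bicarbonate spikes and analyzed by
   isotope-ratio mass spectrometry. matflux computes the excess enrichment of
   the spiked dissolved pool,

   *%R*<sub>exc</sub> = 100 · (*A·f*<sub>t</sub> +
   *C*<sub>nat</sub>·*a*<sub>nat</sub>/100) / (*C*<sub>nat</sub> + *A*) −
   *a*<sub>nat</sub>, with *A* = *V*<sub>add</sub>·*T*<sub>conc</sub> /
   *V*<sub>inc</sub>,

   the assimilation rate per mat dry mass,

   *ρ* = [(%AT<sub>f</sub> − *a*<sub>nat</sub>) / %R<sub>exc</sub>] ·
   POM(nmol) / (*m*<sub>mat</sub> · *t*<sub>inc</sub>)   (nmol mg⁻¹ h⁻¹),

   areal daily extrapolations (nmol cm⁻² d⁻¹) over the core cross-section
   and photoperiod, and nutrient pool turnover times, with un-amended
   controls overriding the default natural abundances and below-detection
   clamping of negative excess.

2. **Marker-gene transcription profiles.** From annotated
   metagenome/metatranscriptome count tables, matflux normalizes to FPKM
   (fragments per kilobase per million library reads), aggregates indicator
   genes (psaA/psbA, pufM/pscA/fmoA/bchC, rbcL, mcl/mcr/prpE,
   atoB/crt/abfD/sucD, nifH, glnA/amt, amoA, nrfA, nosZ, hzsA — 21 markers
   over 11 pathways) into per-pathway activity, computes each gene's percent
   of total transcripts per sample, per-taxon contribution shares to each
   pathway, and DNA/cDNA decoupling ratios.

A synthetic-data generator produces incubation tables and annotated count
tables from known ground truth, so the entire pipeline is testable without
sequencing data. It is aimed at researchers analyzing hot-spring (or other)
mat communities who have gene-level count tables and IRMS measurements and
want reproducible, scriptable rate and activity tables.

## Worked example

Simulate a noisy triplicate ¹⁵N-nitrate incubation with a known true uptake
rate of 0.9 nmol mg⁻¹ h⁻¹ and run the rate pipeline:

```r
library(matflux)
inc <- simulate_incubation(incubation_scenario(
  true_rho = 0.9, substrate = "nitrate", noise_sd = 0.05, seed = 42))
rates <- compute_rates(inc)
rates[, c("sample_id", "r_exc_pct", "rho_mass", "rho_areal_daily", "turnover_h")]
#>      sample_id r_exc_pct rho_mass rho_areal_daily turnover_h
#> 1 nitrate_rep1     82.12   1.1980           747.1     0.2671
#> 2 nitrate_rep2     82.12   0.7773           484.7     0.4117
#> 3 nitrate_rep3     82.12   0.9789           610.5     0.3269
summarize_replicates(rates)
#>   element substrate light n mean_rho_areal_daily sd_rho_areal_daily mean_turnover_h
#>         N   nitrate  TRUE 3                614.1              131.2          0.3352
```

The 30 µL spike of 500 µmol L⁻¹ tracer into 1 mL over a 3.2 µmol L⁻¹
ambient pool enriches the dissolved pool by 82.1 atom % (`r_exc_pct`); the
three noisy atom-percent readings recover per-mass rates scattered around
the true 0.9, extrapolated to ~600 nmol cm⁻² d⁻¹ over the 7 mm core; the
standing pool would be consumed in ~0.3 h at this uptake.

Transcription profiles from a synthetic community (depth 10⁵ marker reads
per sample):

```r
sim <- simulate_counts(porcelana_like_scenario(depth = 1e5, seed = 42))
fpkm <- normalize_fpkm(sim$counts, sim$annotations,
                       setNames(sim$samples$library_size, sim$samples$sample_id))
pa <- pathway_activity(fpkm, sim$annotations)
head(dplyr::arrange(subset(pa, sample_id == "T48_day_cDNA"), dplyr::desc(activity)), 3)
#>                pathway_id           process_class    sample_id activity
#> 1 oxygenic_photosynthesis oxygenic_photosynthesis T48_day_cDNA    16970
#> 2                     cbb         carbon_fixation T48_day_cDNA    13639
#> 3             n2_fixation          nitrogen_cycle T48_day_cDNA     8364

taxon_contribution(fpkm, sim$annotations, rank = "genus") |>
  subset(pathway_id == "cbb" & sample_id == "T48_day_cDNA")
#>   pathway_id    sample_id         taxon percent
#> 1        cbb T48_day_cDNA Mastigocladus   98.35
#> 2        cbb T48_day_cDNA  Leptolyngbya    1.65
```

In the daytime 48 °C metatranscriptome, oxygenic photosynthesis is the most
transcribed pathway and Calvin-cycle (rbcL) transcription is almost entirely
attributable to the heterocystous cyanobacterium *Mastigocladus* — the
structure the generator encoded, recovered through FPKM normalization and
share computation.

A thin command-line wrapper over the same functions ships in
`inst/cli/matflux.R` with subcommands `simulate | rates | quant | report`:

```sh
Rscript inst/cli/matflux.R simulate --out run1 --seed 3
Rscript inst/cli/matflux.R rates --incubations run1/incubations.tsv --out run1
Rscript inst/cli/matflux.R quant --annotations run1/annotations.tsv \
    --counts run1/counts.tsv --sample-sheet run1/sample_sheet.tsv --out run1
Rscript inst/cli/matflux.R report --out run1
```

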