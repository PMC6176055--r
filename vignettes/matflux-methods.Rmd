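---
title: "Models and methods behind matflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind matflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matflux)
```

matflux quantifies microbial-mat activity from two independent directions:
bulk substrate uptake measured with stable-isotope tracers, and pathway-level
transcription measured from marker genes in metagenome/metatranscriptome
count tables. This vignette explains the models, their assumptions, the
tunable parameters, and the design choices made where the design was
genuinely open.

## The tracer uptake model

A dual-label incubation adds a small volume $V_{add}$ of a $^{15}$N- or
$^{13}$C-enriched tracer solution (concentration $T_{conc}$, isotopic purity
$f_t$) to an incubation of volume $V_{inc}$ containing the ambient substrate
pool at concentration $C_{nat}$ and natural heavy-isotope abundance
$a_{nat}$ (atom %). Immediately after mixing, the dissolved pool's atom
percent rises above natural abundance by the *excess enrichment*

$$
\%R_{exc} \;=\; 100\,\frac{A\,f_t + C_{nat}\,a_{nat}/100}{C_{nat}+A}
\;-\; a_{nat}, \qquad A = \frac{V_{add}\,T_{conc}}{V_{inc}}.
$$

This is nothing more than heavy moles over total moles of the mixed pool; the
package's unit tests check it against an explicit mole-bookkeeping
re-derivation to $10^{-9}$ relative error, and the identity is homogeneous in
units, so litres/mol L⁻¹ and mL/µmol L⁻¹ inputs agree exactly. The purity
$f_t$ is exposed (default 1) because commercial tracers are typically 98–99
atom % heavy.

After incubating for $t_{inc}$ hours the particulate fraction is analyzed by
isotope-ratio mass spectrometry (IRMS), yielding its final atom percent
$\%AT_f$. The assimilation rate per unit mat dry mass is

$$
\rho \;=\; \frac{\%AT_f - a_{nat}}{\%R_{exc}}\cdot
\frac{\mathrm{POM}}{m_{mat}\,t_{inc}},
$$

where POM is the particulate organic N or C recovered (converted from mg to
nmol with molar masses 14.0067 g mol⁻¹ for N and 12.011 g mol⁻¹ for C) and
$m_{mat}$ the dry mass analyzed, giving nmol mg⁻¹ h⁻¹. The model assumes the
pool enrichment is constant over the incubation (no significant pool
depletion or dilution) and that no isotope fractionation correction is
needed.

Rates are extrapolated to areal daily values by
$\rho_{areal} = \rho \cdot m_{core} / A_{core} \cdot h_{photo}$ with the core
cross-section from its diameter (default 7 mm) and `photoperiod_hours`
defaulting to 24. Whether a light-dependent rate should be extrapolated over
24 h or only over daylight is a genuine ambiguity of daily extrapolation; we
default to 24 h and expose the photoperiod so light incubations can be scaled
to daylight hours only. Turnover time is the ambient pool divided by the
volumetric uptake rate, in hours; a zero rate flags infinite turnover rather
than erroring.

Key parameter defaults, all overridable through `rate_config()`:

* natural abundances: $^{15}$N 0.3663 atom %, $^{13}$C 1.108 atom %
  (international standards). When a run includes un-amended control vials,
  their mean measured atom % replaces the default per element — controls are
  the preferred baseline because mat material can deviate slightly from the
  standards.
* detection threshold: 0.001 atom % excess, a typical IRMS precision scale.
  Measurements at or below it report a rate of zero with a `below_detection`
  flag; the unclamped value is kept in `rho_raw`. The clamp exists because
  instrument noise below detection would otherwise produce spurious negative
  uptake.
* dissolved inorganic carbon: bicarbonate incubations missing an ambient
  concentration fall back to a fixed 0.8 mmol L⁻¹ DIC pool, a realistic
  value for circumneutral spring water.

The per-vial output also reports `spike_pct_of_pool`, the added tracer as a
percent of the ambient pool. True tracer additions stay near 10% of the
pool; ammonium spikes of the targeted field protocol exceed the tiny ambient
ammonium pool many-fold, so their "uptake" rates are better read as
potential rates under substrate saturation. The package computes the rate
either way and leaves the interpretation to this flag.

One modelling note on the rate equation's masses: the dry mass dividing POM
is the aliquot analyzed on the IRMS, whereas areal extrapolation needs the
whole-core dry mass. The incubation table therefore accepts an optional
`core_dry_mass_mg` column, defaulting to `mat_dry_mass_mg` when the whole
core was analyzed.

## Marker-gene quantification

Pathway transcription is quantified from *indicator* genes: a curated
catalog maps each marker symbol to exactly one pathway. The default catalog
covers 21 genes over 11 pathways — photosystems I/II (psaA, psbA) for
oxygenic photosynthesis; reaction centres 1/2, the FMO protein and
bacteriochlorophyll synthesis (pscA, pufM, fmoA, bchC) for anoxygenic
phototrophy; rbcL for the Calvin–Benson–Bassham cycle; mcl, mcr, prpE for
the 3-hydroxypropionate bi-cycle of Chloroflexi; atoB, crt, abfD, sucD for
the archaeal hydroxypropionate–hydroxybutyrate cycle; and nifH, glnA/amt,
amoA, nrfA, nosZ, hzsA for nitrogen fixation, ammonia assimilation, ammonia
oxidation, DNRA, denitrification and anammox. The catalog is a plain TSV so
users can extend it (for example with the key genes of further
carbon-fixation pathways). hzsA is included although it is often absent from
mat metagenomes: absent markers yield pathways reported at zero activity,
never silently dropped. Symbol matching is case-insensitive because
annotation pipelines disagree on casing.

Counts are normalized to fragments per kilobase of gene length per million
library reads (FPKM). The library size is the total high-quality non-rRNA
read count of each library, supplied in the sample sheet — it cannot be
recomputed from the matrix, which holds only marker-gene features. Three
descriptive summaries follow:

* **per-gene percent across samples** — a gene's summed FPKM per sample as a
  percent of its total over the selected sample set (default: all cDNA
  samples jointly, so day/night × temperature panels share one scale; a
  per-temperature normalization is available by passing sample subsets);
* **pathway activity** — summed FPKM over each pathway's markers, reported
  for every catalog pathway in every sample;
* **taxon contributions** — within each pathway × sample, percent shares by
  taxon at a chosen rank (genus by default, with a phylum roll-up), pooling
  taxa under `min_share` (default 1%) into "Other" and counting lineages
  that stop short of the rank as "Unclassified".

A DNA/cDNA decoupling table pairs metagenome and metatranscriptome libraries
of the same temperature and time and reports each taxon's share in either
library plus their ratio, an activity index that exposes organisms
transcribing far more (or less) than their abundance predicts.

Whether published figure percentages of this kind are computed from FPKM or
raw mapped counts is generally not stated; FPKM is the default here because
it is the normalization such studies name, and a raw-count mode
(`use_fpkm = FALSE`) is provided for sensitivity analysis. All percent
vectors close to 100 within $10^{-9}$ or are explicitly zero-flagged; this
closure, permutation invariance, and invariance of FPKM to joint rescaling
of counts and library sizes are enforced by property tests.

## The synthetic-data generator

Real incubations and read libraries are not needed to test the pipeline: the
generator runs both observation models forward from known ground truth.

For incubations, `simulate_incubation()` computes the pool enrichment from
the spike, inverts the rate equation to the noise-free $\%AT_f$ implied by
the true rate, and adds Gaussian measurement noise (clipped to the physical
0–100 atom % range). Noise enters only through $\%AT_f$ — the IRMS readout
is the quantity with instrument noise, while volumes and masses are treated
as exact. The two appended un-amended controls are emitted at the exact
natural abundance: they define the baseline the scenario asserts, so the
control-override path can be tested without conflating it with measurement
noise; real controls, of course, carry instrument noise too. Scenario
defaults mirror the targeted field protocol (1 mL incubations, 6 h,
triplicates, the ammonium/nitrate/bicarbonate spike volumes and ambient
pools given above). A rate too large for the particulate pool to absorb is
rejected with the limiting parameter named, rather than producing an
impossible atom percent.

For count tables, `simulate_counts()` builds one feature per taxon × marker
gene of each pathway the taxon expresses, draws gene lengths log-uniformly
in 600–3000 bp (so FPKM length-correction is consequential, not cosmetic),
sets expected counts proportional to taxon activity × pathway weight × gene
length, scales each sample to the requested depth, and draws Poisson counts
(negative binomial when an overdispersion parameter is set — real libraries
are overdispersed, the default stays Poisson for exact binomial error
analysis). Because FPKM divides the length exposure back out, the generating
FPKM-scale share of a taxon in a pathway is simply activity × weight,
length-free; the generator returns these exact share vectors for assertion.

The packaged community preset emulates the qualitative structure of a
neutral hot-spring mat: a heterocystous cyanobacterium (*Mastigocladus*)
dominating transcription at 48 °C by day, filamentous anoxygenic
Chloroflexi (*Chloroflexus*, *Roseiflexus*) dominating at 66 °C,
Proteobacteria elevated at night, a Thaumarchaeote carrying ammonia
oxidation plus the HH cycle, and an anammox Planctomycete present in the
annotation but never active. Its numeric magnitudes are synthetic choices,
deliberately spaced so that every sample's generating phylum shares are
separated by at least ~0.9 percentage points — the preset is built for
unambiguous dominance orderings, and is never asserted against any published
figure. What passing tests on these tables show is that the quantification
recovers what the sampling model generated; they cannot show robustness to
upstream artefacts real data carry (mapping bias, chimeric assembly,
lineage misassignment, rRNA carryover), which are out of scope.

## Numerical choices and degenerate inputs

* An empty spike over an empty pool has no defined atom percent and raises
  an error; a spike of zero volume over a real pool returns exactly zero
  enrichment.
* Division guards: a non-positive pool enrichment is an error (a rate cannot
  be scaled by it); zero uptake yields `Inf` turnover; a zero ambient pool
  turns over in 0 h; a taxon absent from the DNA library but present in
  cDNA gets an `Inf` activity ratio, and 0/0 is `NA`.
* Zero-total percent vectors are returned as all-zero with a `zero_total`
  flag rather than NaN.
* Catalog validation rejects duplicate symbols (case-insensitively) and
  unknown process classes by name; count features lacking annotations are
  reported by feature id (first ten shown).
* All simulators are deterministic given their integer seed, and pipeline
  outputs carry a version line and a hash of the configuration so tables can
  be traced to their settings; identical inputs give byte-identical outputs.

## Problem sizes used by the test suite

The suite exercises the equations with 1000-draw oracle comparisons, a 3 × 3
forward–inverse grid, 200 noisy replicate simulations per substrate at
replicate counts 3/12/48, community tables at depths $10^4$–$10^6$, and 50
seeded preset runs for ordering recovery — sizes at which binomial and
$1/\sqrt{n}$ error predictions are sharp while the whole suite runs in a few
minutes on one CPU.

## Known limitations

* No gas-phase tracer model: $^{15}$N$_2$ fixation incubations involve
  headspace equilibration that this package does not model.
* No isotope fractionation corrections and no pool-depletion dynamics over
  the incubation.
* FPKM inherits all upstream mapping and annotation biases; marker-gene
  activity is a transcription proxy, not a flux measurement, and comparing
  it with isotope rates (as `run_report()` tabulates) is descriptive, not a
  calibration.
* The synthetic generator's Poisson default underestimates the dispersion of
  real libraries; set `overdispersion` to probe sensitivity.
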