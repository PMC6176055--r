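test_that("FPKM normalization is exact on hand-computed cases", {
  ann <- tibble::tibble(
    feature_id = c("a", "b"), gene_symbol = c("rbcL", ""),
    length_bp = c(1000, 500), taxon_lineage = "Bacteria;Cyanobacteria")
  counts <- matrix(c(1000, 50, 0, 250), nrow = 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  fpkm <- normalize_fpkm(counts, ann, c(s1 = 1e6, s2 = 5e6))
  expect_equal(fpkm["a", "s1"], 1000)       # both factors equal 1
  expect_equal(fpkm["b", "s2"], 100)        # 250 / 0.5 / 5
  expect_equal(fpkm["b", "s1"], 50 / 0.5)   # kilobase factor only
  expect_equal(fpkm["a", "s2"], 0)

  # features without annotation are named in the error
  rogue <- rbind(counts, orphan = c(1, 1))
  expect_error(normalize_fpkm(rogue, ann, c(s1 = 1e6, s2 = 5e6)), "orphan")

  # joint rescaling of counts and library sizes leaves FPKM unchanged
  expect_equal(normalize_fpkm(counts * 7, ann, c(s1 = 7e6, s2 = 35e6)), fpkm)
})

test_that("FPKM agrees with an independent rpkm implementation", {
  skip_if_not_installed("edgeR")
  set.seed(11)
  ann <- tibble::tibble(
    feature_id = paste0("f", 1:20), gene_symbol = "",
    length_bp = sample(600:3000, 20), taxon_lineage = "Bacteria;X")
  counts <- matrix(rpois(60, 50), nrow = 20,
                   dimnames = list(ann$feature_id, c("s1", "s2", "s3")))
  libs <- c(s1 = 2e6, s2 = 3e6, s3 = 1e6)
  ref <- edgeR::rpkm(counts, gene.length = ann$length_bp, lib.size = libs)
  expect_equal(normalize_fpkm(counts, ann, libs), ref, tolerance = 1e-12)
})

test_that("gene percentages distribute a gene's transcripts across samples", {
  toy <- toy_quant()
  fpkm <- normalize_fpkm(toy$counts, toy$ann, toy$libs)
  # nifH: day 30 vs night 10 on a single feature -> 75% / 25%
  gp <- gene_percent(fpkm, toy$ann, symbols = "nifH")
  expect_equal(gp$percent[gp$sample_id == "day58"], 75)
  expect_equal(gp$percent[gp$sample_id == "night58"], 25)

  # a symbol present in exactly one sample concentrates there
  one <- gene_percent(fpkm, toy$ann, symbols = "rbcL",
                      samples = c("day58", "night58"))
  expect_equal(sum(one$percent), 100)

  # equal abundance across samples splits evenly
  ann4 <- tibble::tibble(feature_id = "x", gene_symbol = "psbA",
                         length_bp = 1000, taxon_lineage = "B;C")
  m4 <- matrix(5, 1, 4, dimnames = list("x", paste0("s", 1:4)))
  even <- gene_percent(m4, ann4)
  expect_equal(even$percent, rep(25, 4))

  # zero totals are flagged, not NaN
  z <- gene_percent(m4 * 0, ann4)
  expect_equal(z$percent, rep(0, 4))
  expect_true(all(z$zero_total))

  expect_error(gene_percent(fpkm, toy$ann, symbols = "unheard_of"),
               "unheard_of")
  # matching is case-insensitive
  expect_equal(gene_percent(fpkm, toy$ann, symbols = "NIFH")$percent,
               gp$percent)
})

test_that("pathway activity sums markers and reports absent pathways as zero", {
  toy <- toy_quant()
  fpkm <- normalize_fpkm(toy$counts, toy$ann, toy$libs)
  pa <- pathway_activity(fpkm, toy$ann)
  # every catalog pathway reported for every sample
  expect_equal(nrow(pa), 11 * 2)
  expect_equal(sum(pa$activity[pa$pathway_id == "anammox"]), 0)
  # single-gene pathway equals the summed abundance of its one symbol
  expect_equal(pa$activity[pa$pathway_id == "cbb" & pa$sample_id == "day58"],
               sum(fpkm[c("f2", "f3"), "day58"]))

  # additivity over a multi-gene pathway: mcl 2 + mcr 3 + prpE 5 = 10
  ann3 <- tibble::tibble(
    feature_id = c("m1", "m2", "m3"),
    gene_symbol = c("mcl", "mcr", "prpE"),
    length_bp = 1000, taxon_lineage = "Bacteria;Chloroflexi")
  m3 <- matrix(c(2, 3, 5), 3, 1, dimnames = list(ann3$feature_id, "s"))
  pa3 <- pathway_activity(m3, ann3)
  expect_equal(pa3$activity[pa3$pathway_id == "hp_bicycle"], 10)
})

test_that("taxon contributions form closed percent shares with Other pooling", {
  ann <- tibble::tibble(
    feature_id = c("a", "b", "c"), gene_symbol = "rbcL",
    length_bp = 1000,
    taxon_lineage = paste0("Bacteria;P;C;O;F;Genus", 1:3))
  m <- matrix(c(80, 15, 5), 3, 1, dimnames = list(ann$feature_id, "s"))
  tc <- taxon_contribution(m, ann, rank = "genus", min_share = 10)
  expect_setequal(tc$taxon, c("Genus1", "Genus2", "Other"))
  expect_equal(tc$percent[tc$taxon == "Other"], 5)
  expect_equal(sum(tc$percent), 100)

  # two genera split 90/10, all from one genus gives 100
  m2 <- matrix(c(90, 10, 0), 3, 1, dimnames = list(ann$feature_id, "s"))
  tc2 <- taxon_contribution(m2, ann, rank = "genus", min_share = 0)
  expect_equal(sort(tc2$percent[tc2$percent > 0]), c(10, 90))
  m1 <- matrix(c(42, 0, 0), 3, 1, dimnames = list(ann$feature_id, "s"))
  tc1 <- taxon_contribution(m1, ann, rank = "genus", min_share = 0)
  expect_equal(tc1$percent[tc1$taxon == "Genus1"], 100)

  # lineages that stop before the rank are Unclassified
  expect_equal(lineage_at_rank("Bacteria;Cyanobacteria", "genus"),
               "Unclassified")
  expect_equal(lineage_at_rank("Bacteria;Cyanobacteria", "phylum"),
               "Cyanobacteria")
})

test_that("percent closures hold and grouping conserves reads", {
  sim <- simulate_counts(porcelana_like_scenario(depth = 2e4, seed = 5))
  fpkm <- normalize_fpkm(sim$counts, sim$annotations,
                         stats::setNames(sim$samples$library_size,
                                         sim$samples$sample_id))
  gp <- gene_percent(fpkm, sim$annotations)
  sums <- tapply(gp$percent, gp$symbol, sum)
  zero <- tapply(gp$zero_total, gp$symbol, all)
  expect_true(all(abs(sums[!zero] - 100) < 1e-9))
  expect_true(all(sums[zero] == 0))

  tc <- taxon_contribution(fpkm, sim$annotations, rank = "genus",
                           min_share = 1)
  cell <- tapply(tc$percent, paste(tc$pathway_id, tc$sample_id), sum)
  expect_true(all(abs(cell - 100) < 1e-9))

  # aggregation by symbol creates or loses no reads
  frac <- colSums(sim$counts) / sim$samples$library_size
  by_sym <- rowsum(sim$counts,
                   sim$annotations$gene_symbol[
                     match(rownames(sim$counts), sim$annotations$feature_id)])
  expect_equal(unname(colSums(by_sym) / sim$samples$library_size),
               unname(frac))
})

test_that("outputs are invariant to feature and sample permutation", {
  sim <- simulate_counts(porcelana_like_scenario(depth = 1e4, seed = 8))
  libs <- stats::setNames(sim$samples$library_size, sim$samples$sample_id)
  fpkm <- normalize_fpkm(sim$counts, sim$annotations, libs)
  set.seed(1)
  rperm <- sample(nrow(sim$counts))
  cperm <- sample(ncol(sim$counts))
  fpkm_p <- normalize_fpkm(sim$counts[rperm, cperm], sim$annotations, libs)
  expect_equal(fpkm_p, fpkm[rperm, cperm])

  sort_tbl <- function(x) x[do.call(order, as.list(x)), ]
  pa <- pathway_activity(fpkm, sim$annotations)
  pa_p <- pathway_activity(fpkm[rperm, cperm], sim$annotations)
  expect_equal(sort_tbl(pa_p), sort_tbl(pa), ignore_attr = TRUE)
  tc <- taxon_contribution(fpkm, sim$annotations)
  tc_p <- taxon_contribution(fpkm[rperm, cperm], sim$annotations)
  expect_equal(sort_tbl(tc_p), sort_tbl(tc), ignore_attr = TRUE)
})

test_that("DNA/cDNA decoupling ratios behave as an activity index", {
  ann <- tibble::tibble(
    feature_id = c("a", "b"), gene_symbol = c("rbcL", "pufM"),
    length_bp = 1000,
    taxon_lineage = c("Bacteria;Cyanobacteria;C;O;F;G1",
                      "Bacteria;Chloroflexi;C;O;F;G2"))
  samples <- tibble::tibble(
    sample_id = c("dna", "cdna"), temperature_C = 58,
    library = c("DNA", "cDNA"), time_of_day = "day", library_size = 1e6)

  # identical profiles: all ratios 1
  m <- matrix(c(60, 60, 40, 40), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("dna", "cdna")))
  dd <- dna_rna_decoupling(m, ann, samples)
  expect_equal(dd$ratio, c(1, 1))

  # 50% of DNA but 25% of cDNA reads -> ratio 0.5
  m2 <- matrix(c(50, 25, 50, 75), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("dna", "cdna")))
  dd2 <- dna_rna_decoupling(m2, ann, samples)
  expect_equal(dd2$ratio[dd2$taxon == "Cyanobacteria"], 0.5)

  # absent from DNA, present in cDNA -> infinite flag
  m3 <- matrix(c(0, 30, 100, 70), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("dna", "cdna")))
  dd3 <- dna_rna_decoupling(m3, ann, samples)
  expect_identical(dd3$ratio[dd3$taxon == "Cyanobacteria"], Inf)

  expect_error(dna_rna_decoupling(m, ann, samples[1, ]), "unpaired")
})
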