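test_that("incubation simulation is deterministic and inverts exactly at zero noise", {
  s <- incubation_scenario(0.05, "nitrate", noise_sd = 0.01, seed = 17)
  expect_identical(simulate_incubation(s), simulate_incubation(s))

  # zero true rate, zero noise: every reading sits at natural abundance
  flat <- simulate_incubation(incubation_scenario(0, "ammonium", seed = 2))
  expect_true(all(flat$AT_f_atom_pct == 0.3663))

  # zero noise: the rate pipeline recovers the true rate to machine accuracy
  for (sub in c("ammonium", "nitrate", "bicarbonate")) {
    true_rho <- 0.2
    rates <- compute_rates(simulate_incubation(
      incubation_scenario(true_rho, sub, seed = 4)))
    expect_lt(max(abs(rates$rho_mass - true_rho) / true_rho), 1e-6)
    expect_equal(nrow(rates), 3)  # controls consumed, not reported as vials
  }

  # a rate too large for the particulate pool is rejected with the culprit
  expect_error(
    simulate_incubation(incubation_scenario(1e5, "nitrate", seed = 1)),
    "true_rho")
})

test_that("a scenario tuned to a daily areal rate is recovered through the pipeline", {
  # choose true_rho so the noise-free daily areal rate is 534 nmol cm-2 d-1
  target <- 534
  core_mass <- 10
  true_rho <- target * core_area(0.7) / (24 * core_mass)
  rates <- compute_rates(simulate_incubation(incubation_scenario(
    true_rho, "bicarbonate", mat_dry_mass_mg = core_mass, seed = 6)))
  expect_equal(mean(rates$rho_areal_daily), target, tolerance = 1e-3)
})

test_that("noisy replication is unbiased and tightens with replicate count", {
  s0 <- incubation_scenario(0.1, "nitrate", seed = 1)
  clean <- simulate_incubation(s0)
  excess <- clean$AT_f_atom_pct[1] - 0.3663
  noise <- 0.1 * excess

  rec_mean <- function(n, seed) {
    inc <- simulate_incubation(incubation_scenario(
      0.1, "nitrate", noise_sd = noise, n_replicates = n, seed = seed))
    mean(compute_rates(inc)$rho_mass)
  }
  sims <- 120
  means3 <- vapply(seq_len(sims), function(i) rec_mean(3, i), numeric(1))
  means48 <- vapply(seq_len(sims), function(i) rec_mean(48, 1000 + i), numeric(1))
  expect_lt(abs(mean(means3) - 0.1) / 0.1, 0.02)
  expect_lt(sd(means48), sd(means3))  # spread shrinks with replication
})

test_that("simulated counts hit the requested depth and are seed-stable", {
  scen <- porcelana_like_scenario(depth = 5e4, seed = 21)
  sim <- simulate_counts(scen)
  expect_identical(sim, simulate_counts(scen))
  expect_true(all(abs(colSums(sim$counts) - 5e4) <= 3 * sqrt(5e4)))
  expect_true(all(colSums(sim$truth$expected_counts) - 5e4 < 1e-6))
  expect_true(all(sim$samples$library_size >= colSums(sim$counts)))
  # every catalog marker is annotated even if never expressed
  expect_setequal(unique(sim$annotations$gene_symbol), default_catalog()$symbol)
  # the never-active anammox Planctomycete stays at zero counts
  hzs <- grepl("hzsA", rownames(sim$counts))
  expect_true(all(sim$counts[hzs, ] == 0))

  expect_error(community_scenario(scen$taxa[0, ], scen$activity,
                                  scen$pathway_profile, scen$samples),
               "empty taxa")
})

test_that("taxon contributions recover generating shares within binomial error", {
  scen <- two_taxon_scenario(depth = 2e5, seed = 13, p = 0.8)
  sim <- simulate_counts(scen)
  fpkm <- normalize_fpkm(sim$counts, sim$annotations,
                         stats::setNames(sim$samples$library_size,
                                         sim$samples$sample_id))
  tc <- taxon_contribution(fpkm, sim$annotations, rank = "genus",
                           min_share = 0)
  truth <- sim$truth$pathway_shares
  for (i in seq_len(nrow(truth))) {
    got <- tc$percent[tc$sample_id == truth$sample_id[i] &
                      tc$taxon == sub(".*;", "", scen$taxa$lineage[
                        match(truth$taxon_id[i], scen$taxa$taxon_id)])]
    n_reads <- sum(sim$counts[, truth$sample_id[i]])
    se <- 100 * sqrt(0.8 * 0.2 / n_reads)
    expect_lt(abs(got - truth$share_pct[i]), 3 * se)
  }

  # single taxon expressing a pathway owns 100% of it
  solo <- simulate_counts(porcelana_like_scenario(depth = 1e4, seed = 3))
  fp <- normalize_fpkm(solo$counts, solo$annotations,
                       stats::setNames(solo$samples$library_size,
                                       solo$samples$sample_id))
  tcs <- taxon_contribution(fp, solo$annotations, rank = "genus",
                            min_share = 0)
  amo <- tcs[tcs$pathway_id == "ammonia_oxidation", ]
  expect_true(all(amo$taxon == "Nitrososphaera"))
  expect_equal(amo$percent, rep(100, nrow(amo)), tolerance = 1e-9)
})

test_that("the community preset preserves its dominance ordering per sample", {
  scen <- porcelana_like_scenario(depth = 1e5, seed = 31)
  sim <- simulate_counts(scen)
  fpkm <- normalize_fpkm(sim$counts, sim$annotations,
                         stats::setNames(sim$samples$library_size,
                                         sim$samples$sample_id))
  prof <- taxon_profile(fpkm, sim$annotations, rank = "phylum")
  truth <- sim$truth$overall_shares
  truth$phylum <- lineage_at_rank(
    scen$taxa$lineage[match(truth$taxon_id, scen$taxa$taxon_id)], "phylum")
  truth_ph <- dplyr::summarise(
    dplyr::group_by(truth, .data$phylum, .data$sample_id),
    share = sum(.data$share_pct), .groups = "drop")
  for (s in sim$samples$sample_id) {
    tr <- truth_ph[truth_ph$sample_id == s & truth_ph$share > 0, ]
    got <- prof[prof$sample_id == s, ]
    got <- got[match(tr$phylum, got$taxon), ]
    expect_equal(order(-tr$share), order(-got$percent))
  }
})
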