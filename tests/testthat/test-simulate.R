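test_that("simulator outputs are reproducible given the seed", {
  cfg <- sim_config(seed = 7, n_taxa = 20, reads_per_fraction = 5000)
  t1 <- simulate_community(cfg)
  t2 <- simulate_community(cfg)
  expect_identical(t1, t2)
  meta <- data.frame(gradient_id = "g", treatment = "C13", prey = "E_coli",
                     timepoint = 24)
  g1 <- simulate_gradient(t1, meta, cfg)
  g2 <- simulate_gradient(t1, meta, cfg)
  expect_identical(g1, g2)
  s1 <- simulate_sequences(2, 4, length = 150, seed = 7)
  s2 <- simulate_sequences(2, 4, length = 150, seed = 7)
  expect_identical(s1, s2)
  m1 <- simulate_metadata(20, seed = 7)
  m2 <- simulate_metadata(20, seed = 7)
  expect_identical(m1, m2)
  # and different seeds diverge
  expect_false(identical(simulate_community(sim_config(seed = 8, n_taxa = 20)),
                         t1))
})

test_that("community construction honors role mix and abundance contracts", {
  cfg <- sim_config(seed = 9, n_taxa = 50)
  tr <- simulate_community(cfg, roles = c(predator = 0.1, cross_feeder = 0,
                                          inactive = 0.9))
  taxa <- tr$taxa[tr$taxa$role != "prey_spike", ]
  expect_equal(sum(taxa$role == "predator"), 5L)
  expect_equal(sum(tr$taxa$baseline_relab), 1, tolerance = 1e-12)
  expect_true(all(taxa$alpha[taxa$role == "inactive"] == 0))
  expect_true(all(taxa$alpha[taxa$role == "predator"] >= 0.5))
  # predators stay above the genus-level abundance filter
  expect_true(all(taxa$baseline_relab[taxa$role == "predator"] > 0.01))
  # prey spike claims 40-50% at amendment time
  tr0 <- simulate_community(cfg, t0 = TRUE)
  spikes <- tr0$taxa[tr0$taxa$role == "prey_spike", ]
  # each spike drew 0.40-0.50 before joint normalization with the community
  expect_true(all(spikes$baseline_relab > 0.19))
  expect_error(simulate_community(cfg, roles = c(predator = 0.5,
                                                 cross_feeder = 0.1,
                                                 inactive = 0.1)),
               "sum to 1")
})

test_that("gradient fractions conserve read depth and density structure", {
  cfg <- sim_config(seed = 10, n_taxa = 30, reads_per_fraction = 20000)
  tr <- simulate_community(cfg, spike_alpha = 0,
                           roles = c(predator = 0, cross_feeder = 0,
                                     inactive = 1))
  meta <- data.frame(gradient_id = "null13", treatment = "C13",
                     prey = "E_coli", timepoint = 24)
  g <- simulate_gradient(tr, meta, cfg)
  expect_true(all(colSums(g$counts) == 20000))
  expect_equal(nrow(g$fractions), 13L)
  expect_true(all(g$fractions$copies >= 0))
  # unlabeled community: rRNA-mass-weighted mean density sits at mu0
  # (fractions are sequenced to fixed depth, so mass is carried by the
  # qPCR copy profile, not by read totals)
  wmean <- sum(g$fractions$density * g$fractions$copies) /
    sum(g$fractions$copies)
  expect_equal(wmean, cfg$mu0, tolerance = 0.004)
  expect_equal(classify_fraction(wmean), "light")
})

test_that("full incorporators band at the labeled density", {
  wmeans <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = 100 + s, n_taxa = 10, reads_per_fraction = 5000)
    tr <- simulate_community(cfg, predator_alpha = 1, spike_alpha = 0,
                             roles = c(predator = 1, cross_feeder = 0,
                                       inactive = 0))
    meta <- data.frame(gradient_id = "lab", treatment = "C13",
                       prey = "E_coli", timepoint = 24)
    g <- simulate_gradient(tr, meta, cfg)
    sum(g$fractions$density * g$fractions$copies) / sum(g$fractions$copies)
  }, numeric(1))
  # mu0 + atom_pct * delta_max = 1.812 + 0.97 * 0.045 = 1.85565
  expect_equal(mean(wmeans), 1.8557, tolerance = 0.003)
  expect_equal(unique(classify_fraction(wmeans)), "heavy")
})

test_that("pooled read shares recover baseline relative abundances", {
  cfg <- sim_config(seed = 12, n_taxa = 25, reads_per_fraction = 50000)
  tr <- simulate_community(cfg, spike_alpha = 0,
                           roles = c(predator = 0, cross_feeder = 0,
                                     inactive = 1))
  meta <- data.frame(gradient_id = "g12", treatment = "C12", prey = "E_coli",
                     timepoint = 24)
  g <- simulate_gradient(tr, meta, cfg)
  share <- rowSums(g$counts) / sum(g$counts)
  # the P. putida spike is absent from an E. coli gradient; remaining
  # baselines renormalize accordingly
  p <- tr$taxa$baseline_relab
  p[tr$taxa$role == "prey_spike" & tr$taxa$prey != "E_coli"] <- 0
  p <- p / sum(p)
  se <- sqrt(p * (1 - p) / sum(g$counts))
  expect_true(all(abs(share - p) < 4 * se + 2e-4))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(seed = 1, mu0 = 1.83), "light window")
  expect_error(sim_config(seed = 1, delta_max = 0.2), "grid")
  expect_error(sim_config(seed = 1, atom_pct = 0.5), "heavy window")
  expect_error(sim_config(n_taxa = 10), "seed")
  cfg <- sim_config(seed = 1, n_taxa = 4)
  tr <- simulate_community(cfg)
  expect_error(simulate_gradient(tr, data.frame(gradient_id = "x",
                                                treatment = "C14",
                                                prey = "E_coli",
                                                timepoint = 1), cfg),
               "treatment")
  expect_error(simulate_gradient(tr, data.frame(gradient_id = "x",
                                                treatment = "control",
                                                prey = "E_coli",
                                                timepoint = 1), cfg),
               "prey")
})

test_that("simulated sequences carry exact planted divergence when asked", {
  sim <- simulate_sequences(n_refs = 1, n_queries = 3, length = 500,
                            mutation_rates = c(0, 0.02, 0.1), seed = 13,
                            exact = TRUE)
  expect_identical(sim$queries[[1]], sim$refs[[1]])
  expect_equal(sim$truth$n_mut, c(0, 10, 50))
  expect_equal(sim$truth$expected_identity, c(100, 98, 90))
  # measured identity equals the planted identity exactly
  for (i in 1:3) {
    expect_equal(global_percent_identity(sim$queries[[i]], sim$refs[[1]]),
                 sim$truth$expected_identity[i])
  }
  expect_error(simulate_sequences(1, 1, 100, mutation_rates = 1.2, seed = 1),
               "\\[0, 1\\]")
})

test_that("sequence sets round-trip through FASTA", {
  ref_path <- tempfile(fileext = ".fasta")
  query_path <- tempfile(fileext = ".fasta")
  sim <- simulate_sequences(2, 3, length = 120, seed = 14,
                            ref_path = ref_path, query_path = query_path)
  expect_equal(read_fasta_seqs(ref_path), sim$refs)
  expect_equal(read_fasta_seqs(query_path), sim$queries)
})

test_that("planted metadata links have the requested sign and strength", {
  links <- data.frame(taxon = c("taxon001", "taxon002"),
                      variable = c("var1", "var2"),
                      sign = c(1, -1), strength = c(0.9, 0.9))
  ok_pos <- 0; ok_neg <- 0
  for (s in 1:10) {
    sim <- simulate_metadata(200, n_taxa = 5, n_variables = 3,
                             planted_links = links, seed = 500 + s)
    r1 <- spearman_assoc(sim$abundance["taxon001", ], sim$metadata$var1)
    r2 <- spearman_assoc(sim$abundance["taxon002", ], sim$metadata$var2)
    ok_pos <- ok_pos + (r1$rho > 0.6)
    ok_neg <- ok_neg + (r2$rho < -0.6)
  }
  expect_gte(ok_pos, 9)
  expect_gte(ok_neg, 9)
  dup <- rbind(links, links[1, ])
  expect_error(simulate_metadata(20, planted_links = dup, seed = 1),
               "duplicate")
})
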