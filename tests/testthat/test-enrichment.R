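test_that("relative abundance normalizes counts with optional pseudocount", {
  expect_equal(relative_abundance(c(A = 90, B = 10), pseudocount = 0),
               c(A = 0.9, B = 0.1))
  expect_equal(relative_abundance(c(A = 0, B = 10), pseudocount = 0.5),
               c(A = 0.5 / 11, B = 10.5 / 11))
  expect_error(relative_abundance(numeric(0)), "empty")
  expect_error(relative_abundance(c(A = 0, B = 0), pseudocount = 0),
               "degenerate")
})

test_that("enrichment factor follows the heavy/light ratio difference", {
  expect_equal(enrichment_factor(0.30, 0.10, 0.05, 0.05), 2.0)
  expect_equal(enrichment_factor(0.20, 0.10, 0.40, 0.20), 0.0)
  expect_equal(enrichment_factor(0.01, 0.10, 0.20, 0.10), -1.9)
  expect_true(is.na(enrichment_factor(0.3, 0, 0.1, 0.1)))
  expect_true(is.na(enrichment_factor(0.3, 0.1, 0.1, 0)))
})

test_that("paired-null identity: identical treatments give EF 0", {
  set.seed(21)
  for (i in 1:25) {
    a <- runif(1); b <- runif(1)
    expect_equal(enrichment_factor(a, b, a, b), 0)
  }
})

test_that("EF is invariant to per-fraction count rescaling", {
  set.seed(22)
  counts <- matrix(rpois(4 * 20, 50) + 1, nrow = 20)
  r <- lapply(1:4, function(j) relative_abundance(counts[, j], 0))
  ef0 <- enrichment_factor(r[[1]], r[[2]], r[[3]], r[[4]])
  # scale the 13C-heavy fraction by 7: relative abundances unchanged
  r1 <- relative_abundance(counts[, 1] * 7, 0)
  ef1 <- enrichment_factor(r1, r[[2]], r[[3]], r[[4]])
  expect_equal(ef1, ef0, tolerance = 1e-14)
})

test_that("abundance filter uses strict level-specific thresholds", {
  cfg <- filter_config()
  expect_true(passes_abundance_filter(c(0.015, 0.004), "genus", cfg))
  expect_false(passes_abundance_filter(c(0.01, 0.01), "genus", cfg))
  expect_true(passes_abundance_filter(0.002, "ASV", cfg))
  expect_false(passes_abundance_filter(0.001, "ASV", cfg))
  expect_error(passes_abundance_filter(numeric(0), "genus", cfg), "heavy")
})

test_that("labeling calls and display floor follow the printed rules", {
  expect_true(call_labeled(0.11, 0.1))
  expect_false(call_labeled(0.10, 0.1))
  expect_false(call_labeled(-0.5, 0.1))
  expect_equal(display_floor(0.001), 10^-1.5)
  expect_equal(display_floor(-2), 10^-1.5)
  expect_equal(display_floor(2), 2)
})

test_that("genus aggregation conserves reads and buckets unmapped ASVs", {
  counts <- matrix(c(10, 5, 3, 2, 1, 4), nrow = 3,
                   dimnames = list(c("a1", "a2", "a3"), c("f1", "f2")))
  tax <- data.frame(taxon = c("a1", "a2", "a3"),
                    genus = c("G", "G", NA),
                    family = c("FG", "FG", "F"))
  g <- aggregate_to_genus(counts, tax)
  expect_equal(g["G", ], c(f1 = 15, f2 = 3))
  expect_equal(g["unclassified:F", ], c(f1 = 3, f2 = 4))
  expect_equal(colSums(g), colSums(counts))
  # ASV absent from the map entirely
  counts2 <- rbind(counts, a4 = c(7, 7))
  g2 <- aggregate_to_genus(counts2, tax)
  expect_equal(g2["unclassified:unknown", ], c(f1 = 7, f2 = 7))
  expect_equal(colSums(g2), colSums(counts2))
})

test_that("ef_table pairs gradients, filters and calls labels", {
  # one clear incorporator (t1), everything else unlabeled
  c13H <- c(t1 = 600, t2 = 200, t3 = 200)
  c13L <- c(t1 = 100, t2 = 450, t3 = 450)
  c12H <- c(t1 = 100, t2 = 450, t3 = 450)
  c12L <- c(t1 = 100, t2 = 450, t3 = 450)
  ex <- make_experiment(c13H, c13L, c12H, c12L)
  ef <- ef_table(ex)
  expect_setequal(ef$taxon, c("t1", "t2", "t3"))
  expect_true(ef$labeled[ef$taxon == "t1"])
  expect_false(any(ef$labeled[ef$taxon != "t1"]))
  expect_true(all(ef$status == "ok"))
})

test_that("groups without usable 12C heavy data get status missing_12C", {
  c13H <- c(t1 = 600, t2 = 400)
  c13L <- c(t1 = 300, t2 = 700)
  ex <- make_experiment(c13H, c13L)  # no 12C gradient at all
  ef <- ef_table(ex)
  expect_true(all(ef$status == "missing_12C"))
  expect_true(all(is.na(ef$ef)))
  expect_true(all(is.na(ef$labeled)))
  # 12C gradient present but with zero heavy reads is equally unusable
  ex2 <- make_experiment(c13H, c13L, c(t1 = 0, t2 = 0), c(t1 = 50, t2 = 50))
  ef2 <- ef_table(ex2)
  expect_true(all(ef2$status == "missing_12C"))
})

test_that("an experiment without 13C gradients is an error", {
  ex <- make_experiment(c(t1 = 5, t2 = 5), c(t1 = 5, t2 = 5))
  ex$meta$treatment <- "C12"
  expect_error(ef_table(ex), "no 13C")
})

test_that("genus-level records appear when a taxonomy is supplied", {
  c13H <- c(a1 = 300, a2 = 300, a3 = 400)
  c13L <- c(a1 = 300, a2 = 300, a3 = 400)
  ex <- make_experiment(c13H, c13L, c13H, c13L)
  tax <- data.frame(taxon = c("a1", "a2", "a3"),
                    genus = c("G1", "G1", "G2"))
  ef <- ef_table(ex, taxonomy = tax)
  expect_setequal(unique(ef$level), c("ASV", "genus"))
  g <- ef[ef$level == "genus", ]
  expect_setequal(g$taxon, c("G1", "G2"))
  expect_equal(g$ef, c(0, 0), tolerance = 1e-12)  # paired null
})

test_that("EF summaries average only status-ok groups", {
  ef <- data.frame(
    taxon = c("G1", "G1", "G1"), level = "genus", prey = "E_coli",
    timepoint = c(24, 48, 96), r13H = 0.1, r13L = 0.1, r12H = 0.1,
    r12L = 0.1, ef = c(2, 4, NA), passed_filter = TRUE,
    labeled = c(TRUE, TRUE, NA),
    status = c("ok", "ok", "missing_12C"))
  s <- summarize_ef(ef, level = "genus")
  expect_equal(s$mean_ef, 3)
  expect_equal(s$max_ef, 4)
  expect_equal(s$n_groups, 2L)
  expect_equal(s$n_labeled, 2L)
})
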