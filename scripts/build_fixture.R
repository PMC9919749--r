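#!/usr/bin/env Rscript
# Regenerates the packaged synthetic fixture bundle (inst/extdata/fixture)
# used by the documentation walkthrough and the golden-file pipeline test.
# All files are simulator output with a fixed seed; goldens are the
# pipeline's own output on that bundle.

library(predsip)

fixture_dir <- file.path("inst", "extdata", "fixture")
golden_dir <- file.path(fixture_dir, "golden")
dir.create(golden_dir, recursive = TRUE, showWarnings = FALSE)

seed <- 20240801
cfg <- sim_config(seed = seed, n_taxa = 12, reads_per_fraction = 2000)
ex <- simulate_experiment(
  cfg,
  groups = data.frame(prey = "E_coli", timepoint = 24),
  roles = c(predator = 0.25, cross_feeder = 0, inactive = 0.75))

hdr <- c("predsip synthetic fixture (simulated SIP gradients)",
         paste0("simulator seed: ", seed))
write_count_table(ex$counts, file.path(fixture_dir, "counts.tsv"), hdr)

write_simple <- function(df, path) {
  con <- file(path, "wt")
  writeLines(paste0("# ", hdr), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(df, as.character), sep = "\t")), con)
  close(con)
}
fr <- ex$fractions
fr$density <- formatC(fr$density, digits = 10, format = "g")
fr$copies <- formatC(fr$copies, digits = 10, format = "g")
write_simple(fr, file.path(fixture_dir, "fractions.tsv"))
write_simple(ex$meta, file.path(fixture_dir, "meta.tsv"))
write_simple(ex$taxonomy, file.path(fixture_dir, "taxonomy.tsv"))

cfg_run <- run_config(
  counts = file.path(fixture_dir, "counts.tsv"),
  fractions = file.path(fixture_dir, "fractions.tsv"),
  meta = file.path(fixture_dir, "meta.tsv"),
  taxonomy = file.path(fixture_dir, "taxonomy.tsv"),
  seed = seed, out_dir = golden_dir)
res <- run_pipeline(cfg_run)
cat("golden EF records:", nrow(res$ef), "| labeled:",
    sum(res$ef$labeled, na.rm = TRUE), "\n")
cat("wrote", res$paths$ef, "and", res$paths$manifest, "\n")
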