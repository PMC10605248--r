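# Shared configuration for the analysis scripts. Every script can be run
# standalone from the repository root: Rscript analysis/0X_*.R
# The count matrix is regenerated deterministically from the seed, so later
# scripts do not depend on earlier ones having left files behind.

library(lensoid)

ANALYSIS_SEED <- 1L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

run_cfg <- default_run_config(ANALYSIS_SEED)

make_cm <- function() {
  cc <- run_cfg$counts
  simulate_counts(counts_sim_config(
    n_genes = cc$n_genes, planted_sets = cc$planted,
    shared_enriched_fraction_rho = cc$shared_enriched_fraction_rho,
    n_enriched = cc$n_enriched, dispersion_alpha = cc$dispersion_alpha,
    seed = run_cfg$seed))
}

save_tsv <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
}
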