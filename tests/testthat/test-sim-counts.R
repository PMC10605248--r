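test_that("invalid count configurations are rejected", {
  expect_error(counts_sim_config(dispersion_alpha = -1), "dispersion_alpha")
  expect_error(counts_sim_config(shared_enriched_fraction_rho = 2), "rho")
  expect_error(counts_sim_config(
    n_genes = 10L, n_enriched = 0L,
    planted_sets = list(list(genes = 11L, log2fc = 1, groups = "2D"))),
    "out of range")
  expect_error(simulate_counts(counts_sim_config(
    n_genes = 100L, n_enriched = 0L,
    planted_sets = list(list(genes = 1:5, log2fc = 1, groups = "2D"),
                        list(genes = 3:8, log2fc = -1, groups = "2D")))),
    "contradictory")
})

test_that("zero dispersion degenerates to Poisson", {
  cfg <- counts_sim_config(n_genes = 1L, group_sizes = c(A = 1000L),
                           baseline_log_mean_mu = log(50),
                           baseline_log_mean_sd = 0, dispersion_alpha = 0,
                           n_enriched = 0L, library_size_range = c(50, 50),
                           seed = 3L)
  x <- as.numeric(simulate_counts(cfg)$counts)
  expect_gt(var(x) / mean(x), 0.85)
  expect_lt(var(x) / mean(x), 1.15)
})

test_that("a planted +2 log2 fold is recovered in group mean ratios", {
  cfg <- counts_sim_config(
    n_genes = 500L, group_sizes = c("2D" = 50L, "3D" = 50L),
    n_enriched = 0L, dispersion_alpha = 0.1,
    planted_sets = list(list(genes = 1L, log2fc = 2, groups = "3D")),
    library_size_range = c(2e5, 2e5), seed = 5L)
  cm <- simulate_counts(cfg)
  y <- sweep(cm$counts, 2L, size_factors(cm), "/")
  g3 <- cm$sample_meta$group == "3D"
  ratio <- mean(y[1L, g3]) / mean(y[1L, !g3])
  expect_gt(ratio, 3.2)
  expect_lt(ratio, 5.0)
})

test_that("unplanted generation is symmetric between groups", {
  cfg <- counts_sim_config(n_genes = 10320L,
                           group_sizes = c(A = 20L, B = 20L),
                           n_enriched = 0L, seed = 9L)
  cm <- simulate_counts(cfg)
  y <- sweep(cm$counts, 2L, size_factors(cm), "/")
  g <- cm$sample_meta$group == "A"
  ma <- rowMeans(y[, g]); mb <- rowMeans(y[, !g])
  pos <- ma > 0 & mb > 0
  expect_lt(abs(mean(log2(ma[pos] / mb[pos]))), 0.05)
})

test_that("planted truth records folds, enrichment sets and their overlap", {
  cfg <- counts_sim_config(n_genes = 2000L, n_enriched = 200L,
                           shared_enriched_fraction_rho = 0.25,
                           planted_sets = list(
                             list(genes = 1:10, log2fc = 1.5,
                                  groups = c("internal"))),
                           seed = 2L)
  cm <- simulate_counts(cfg)
  expect_equal(sum(cm$truth$delta[, "internal"] == 1.5), 10L)
  expect_length(cm$truth$enriched_lens, 200L)
  expect_length(cm$truth$enriched_3d, 200L)
  expect_length(intersect(cm$truth$enriched_lens, cm$truth$enriched_3d), 50L)
  # enrichment planting never touches user-planted genes
  expect_length(intersect(cm$truth$enriched_lens, rownames(cm$counts)[1:10]), 0L)
  expect_length(cm$truth$baseline_cpm, 2000L)
})

test_that("count simulation is reproducible for a fixed seed", {
  cfg <- counts_sim_config(n_genes = 300L, seed = 11L, n_enriched = 30L)
  expect_identical(simulate_counts(cfg)$counts, simulate_counts(cfg)$counts)
})

test_that("count matrices round-trip through TSV", {
  cm <- simulate_counts(counts_sim_config(n_genes = 50L, n_enriched = 0L))
  cp <- file.path(tempdir(), "c.tsv"); mp <- file.path(tempdir(), "m.tsv")
  write_count_matrix(cm, cp, mp)
  back <- read_count_matrix(cp, mp)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$sample_meta$group, cm$sample_meta$group)
})
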