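test_that("cpm matches its closed form and normalizes columns to 1e6", {
  counts <- matrix(c(2, 8), 2L, 1L, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(as.numeric(cpm(counts)), c(2e5, 8e5))
  cm <- tiny_counts()
  expect_equal(unname(colSums(cpm(cm))), rep(1e6, 4L))
  expect_equal(unname(cpm(cm)["g3", ]), rep(0, 4L))
  zero <- matrix(0, 2L, 2L, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(cpm(zero), "library size")
})

test_that("expression filter keeps exactly the genes above the CPM cut", {
  cm <- tiny_counts()
  expect_false("g3" %in% expression_filter(cm))
  # 900 genes far above the cut, 100 at baseline 0.01 cpm: exact split
  set.seed(21)
  mu <- c(rep(22222, 900), rep(0.2, 100))
  counts <- matrix(rpois(1000L * 4L, rep(mu, 4L)), 1000L, 4L,
                   dimnames = list(sprintf("g%04d", 1:1000), paste0("s", 1:4)))
  cmx <- count_matrix(counts, data.frame(sample = paste0("s", 1:4),
                                         group = rep("A", 4L)))
  kept <- expression_filter(cmx, cpm_cut = 0.2)
  expect_setequal(kept, sprintf("g%04d", 1:900))
})

test_that("size factors follow the median-of-ratios closed form", {
  counts <- matrix(c(10, 20, 30, 20, 40, 60), 3L, 2L,
                   dimnames = list(paste0("g", 1:3), c("a", "b")))
  s <- size_factors(counts)
  expect_equal(unname(s["b"] / s["a"]), 2)
  expect_equal(exp(mean(log(s))), 1)
  same <- counts[, c(1L, 1L)]; colnames(same) <- c("a", "b")
  expect_equal(unname(size_factors(same)), c(1, 1))
  zero <- matrix(0, 2L, 3L, dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  expect_equal(unname(size_factors(zero)), rep(1, 3L))
})

test_that("identical groups give zero fold change and p = 1", {
  counts <- matrix(c(5, 9, 5, 9, 50, 80, 50, 80), 2L, 4L, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  cm <- count_matrix(counts, data.frame(sample = paste0("s", 1:4),
                                        group = rep(c("A", "B"), each = 2L)))
  de <- nb_de_test(cm, "A", "B")
  expect_equal(de$log2fc, c(0, 0))
  expect_equal(de$p_value, c(1, 1))
  expect_true(all(de$call == "ns"))
})

test_that("the NB Wald test is exactly symmetric in its groups", {
  cm <- simulate_counts(counts_sim_config(
    n_genes = 400L, group_sizes = c(internal = 4L, external = 3L),
    n_enriched = 0L,
    planted_sets = list(list(genes = 1:20, log2fc = 2, groups = "internal")),
    seed = 4L))
  ab <- nb_de_test(cm, "internal", "external")
  ba <- nb_de_test(cm, "external", "internal")
  expect_equal(ba$log2fc, -ab$log2fc)
  expect_equal(ba$p_value, ab$p_value)
  expect_equal(sum(ab$call == "up_A"), sum(ba$call == "up_B"))
  expect_error(nb_de_test(cm, "internal", "missing"), "2 samples")
})

test_that("reported FDR equals the BH step-up oracle", {
  cm <- simulate_counts(counts_sim_config(
    n_genes = 500L, group_sizes = c(A = 4L, B = 4L), n_enriched = 0L,
    seed = 6L))
  de <- nb_de_test(cm, "A", "B")
  expect_equal(de$fdr, bh_oracle(de$p_value))
  # exhaustive small-vector check of the step-up definition
  set.seed(8)
  for (k in 1:25) {
    p <- runif(sample(1:10, 1L))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p))
  }
})

test_that("Wald p-values are near-uniform under the null", {
  cm <- simulate_counts(counts_sim_config(
    n_genes = 10320L, group_sizes = c(A = 4L, B = 4L), n_enriched = 0L,
    dispersion_alpha = 0.1, seed = 13L))
  de <- nb_de_test(cm, "A", "B")
  ks <- suppressWarnings(ks.test(de$p_value, "punif")$statistic)
  expect_lt(unname(ks), 0.03)
})

test_that("enrichment scores follow the log-ratio closed form", {
  m <- c(g1 = 10, g2 = 20, g3 = 5)
  equal <- enrichment_ranking(m, m)
  expect_equal(equal$score, rep(0, 3L))
  expect_equal(equal$gene, c("g1", "g2", "g3"))  # tie-break by gene id
  fold4 <- enrichment_ranking(4 * m, m, pseudocount = 1e-9)
  expect_equal(fold4$score, rep(2, 3L), tolerance = 1e-6)
  expect_error(enrichment_ranking(m, m[1:2]), "universe")
})

test_that("cpm, size factors and rankings are gene-order invariant", {
  cm <- simulate_counts(counts_sim_config(n_genes = 200L, n_enriched = 0L,
                                          seed = 14L))
  perm <- sample(nrow(cm$counts))
  cmp <- count_matrix(cm$counts[perm, ], cm$sample_meta)
  expect_equal(cpm(cmp), cpm(cm)[perm, ])
  expect_equal(size_factors(cmp), size_factors(cm))
  r1 <- enrichment_ranking(cm, cm, "3D", "WB")
  r2 <- enrichment_ranking(cmp, cmp, "3D", "WB")
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("the NB Wald test agrees with an independent NB implementation", {
  skip_if_not_installed("edgeR")
  cm <- simulate_counts(counts_sim_config(
    n_genes = 2000L, group_sizes = c(A = 4L, B = 4L), n_enriched = 0L,
    dispersion_alpha = 0.1, seed = 77L,
    planted_sets = list(list(genes = 1:50, log2fc = 2, groups = "A"),
                        list(genes = 51:100, log2fc = -2, groups = "A"))))
  de <- nb_de_test(cm, "A", "B")
  y <- edgeR::DGEList(cm$counts[de$gene, ], group = cm$sample_meta$group)
  y <- edgeR::estimateCommonDisp(edgeR::calcNormFactors(y))
  et <- edgeR::exactTest(y, pair = c("B", "A"))
  expect_lt(abs(attr(de, "dispersion") - y$common.dispersion) /
              y$common.dispersion, 0.2)
  expect_gt(cor(de$log2fc, et$table$logFC), 0.98)
  theirs <- de$gene[p.adjust(et$table$PValue, "BH") < 0.05 &
                      abs(et$table$logFC) > 1]
  ours <- de$gene[de$call != "ns"]
  jacc <- length(intersect(ours, theirs)) / length(union(ours, theirs))
  expect_gte(jacc, 0.9)
})
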