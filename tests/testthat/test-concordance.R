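test_that("the 2x2 chi-squared follows its closed form and oracle", {
  r <- chi_square_2x2(30, 10, 10, 30)
  expect_equal(r$statistic, 20)
  expect_equal(r$expected, matrix(20, 2L, 2L), ignore_attr = TRUE)
  expect_equal(chi_square_2x2(5, 5, 5, 5)$statistic, 0)
  expect_equal(chi_square_2x2(5, 5, 5, 5)$p_value, 1)
  expect_error(chi_square_2x2(0, 0, 3, 4), "margin")

  # generic Pearson sum((O-E)^2/E) oracle on random tables
  set.seed(41)
  for (i in 1:50) {
    tb <- matrix(rpois(4L, 20) + 1L, 2L, 2L)
    r <- chi_square_2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    e <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    expect_equal(r$statistic, sum((tb - e)^2 / e), tolerance = 1e-12)
    expect_equal(r$expected, e, tolerance = 1e-12, ignore_attr = TRUE)
    # agreement with the stock implementation, both conventions
    expect_equal(r$statistic,
                 unname(suppressWarnings(
                   chisq.test(tb, correct = FALSE)$statistic)))
    ry <- chi_square_2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2],
                         continuity = TRUE)
    expect_equal(ry$statistic,
                 unname(suppressWarnings(
                   chisq.test(tb, correct = TRUE)$statistic)))
    expect_lte(ry$statistic, r$statistic)
  }
})

test_that("perfectly concordant DEGs give a zero off-diagonal table", {
  de <- fake_de_result(sprintf("g%02d", 1:40),
                       log2fc = rep(c(2, -2), each = 20L),
                       call = rep(c("up_A", "up_B"), each = 20L))
  fc <- sprintf("g%02d", 1:20); lec <- sprintf("g%02d", 21:40)
  r <- classify_degs(de, fc, lec)
  expect_equal(unname(r$table), matrix(c(20, 0, 0, 20), 2L, byrow = TRUE))
  expect_equal(r$chi_square, 40)
  expect_lt(r$p_value, 1e-9)
  expect_equal(r$n_classified, 40L)
})

test_that("ambiguous reference genes are dropped and rows/cols can swap", {
  de <- fake_de_result(sprintf("g%02d", 1:30),
                       log2fc = rep(c(2, -2), times = c(18L, 12L)),
                       call = rep(c("up_A", "up_B"), times = c(18L, 12L)))
  fc <- sprintf("g%02d", 1:16); lec <- sprintf("g%02d", c(16, 17:28))
  expect_message(r <- classify_degs(de, fc, lec), "both reference sets")
  expect_false("g16" %in% r$genes$gene[r$genes$identity != "neither"])
  # swapping both a row and a column leaves the statistic unchanged
  de_swap <- fake_de_result(de$gene, -de$log2fc,
                            ifelse(de$call == "up_A", "up_B", "up_A"))
  r2 <- classify_degs(de_swap, setdiff(lec, fc), setdiff(fc, lec))
  expect_equal(r2$chi_square, r$chi_square)
  expect_equal(r2$p_value, r$p_value)
  # gene-order invariance
  r3 <- classify_degs(de[rev(seq_len(nrow(de))), ], fc, lec)
  expect_equal(r3$chi_square, r$chi_square)
})

test_that("planted concordance is detected with high power", {
  set.seed(51)
  hits <- vapply(1:100, function(i) {
    n <- 400L
    genes <- sprintf("g%04d", 1:n)
    dir <- rep(c("up_A", "up_B"), each = n / 2L)
    conc <- runif(n) < 0.8
    identity <- ifelse(dir == "up_A", ifelse(conc, "FC", "LEC"),
                       ifelse(conc, "LEC", "FC"))
    de <- fake_de_result(genes, ifelse(dir == "up_A", 2, -2), dir)
    r <- classify_degs(de, genes[identity == "FC"], genes[identity == "LEC"])
    r$p_value < 0.01
  }, logical(1L))
  expect_gte(mean(hits), 0.99)
})

test_that("fold-change overlays summarize identity classes", {
  de <- fake_de_result(sprintf("g%02d", 1:40),
                       log2fc = rep(c(2, -2), each = 20L),
                       call = rep(c("up_A", "up_B"), each = 20L))
  ov <- fc_lec_overlay(de, sprintf("g%02d", 1:15), sprintf("g%02d", 21:35))
  expect_gt(ov$summary$mean_log2fc[ov$summary$identity == "FC"], 0)
  expect_lt(ov$summary$mean_log2fc[ov$summary$identity == "LEC"], 0)
  expect_lt(ov$rank_test$p_value, 0.01)
  expect_equal(sum(ov$genes$identity == "neither"), 10L)
  expect_warning(ov0 <- fc_lec_overlay(de, "nope1", "nope2"), "empty")
  expect_null(ov0$summary)
})

test_that("shuffled identity labels give a null rank test", {
  set.seed(61)
  pv <- vapply(1:150, function(i) {
    n <- 120L
    genes <- sprintf("g%03d", 1:n)
    lfc <- rnorm(n)
    de <- fake_de_result(genes, lfc, sample(c("up_A", "up_B"), n, TRUE))
    pick <- sample(genes)
    fc_lec_overlay(de, pick[1:60], pick[61:120])$rank_test$p_value
  }, numeric(1L))
  ks <- suppressWarnings(ks.test(pv, "punif")$statistic)
  expect_lt(unname(ks), 0.12)
})
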