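#' Pearson chi-squared test for a 2x2 contingency table
#'
#' Closed form \eqn{\chi^2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}; the
#' optional Yates continuity correction subtracts n/2 from |ad - bc| before
#' squaring (never past zero). p is the upper tail of the chi-squared
#' distribution with 1 degree of freedom; expected counts are
#' row total x column total / n — the bracketed values of a contingency-table
#' figure.
#'
#' @param a,b,c,d observed cell counts (row-major: a, b / c, d).
#' @param continuity apply the Yates correction.
#' @return list with `statistic`, `p_value`, `observed`, `expected`,
#'   `continuity`.
#' @export
chi_square_2x2 <- function(a, b, c, d, continuity = FALSE) {
  obs <- matrix(c(a, b, c, d), 2L, 2L, byrow = TRUE)
  if (any(obs < 0)) stop("cell counts must be non-negative")
  n <- sum(obs)
  if (n == 0) stop("empty table")
  rs <- rowSums(obs); cs <- colSums(obs)
  if (any(rs == 0) || any(cs == 0))
    stop("zero margin: chi-squared statistic undefined")
  dev <- abs(a * d - b * c)
  if (continuity) dev <- max(0, dev - n / 2)
  stat <- n * dev^2 / (rs[1L] * rs[2L] * cs[1L] * cs[2L])
  list(statistic = unname(stat),
       p_value = unname(pchisq(stat, df = 1L, lower.tail = FALSE)),
       observed = obs,
       expected = outer(rs, cs) / n,
       continuity = continuity)
}

#' Classify regional DEGs against reference identity gene sets
#'
#' Cross-tabulates differentially expressed genes by direction (up in group A
#' vs up in group B) against two exclusive reference identities — e.g.
#' internal-region vs external-region DEGs against fiber-cell (FC) and lens
#' epithelial cell (LEC) enriched sets — and tests the association with
#' [chi_square_2x2()]. Genes present in both reference sets violate the
#' exclusive 2x2 design and are dropped with a report; DEGs in neither set
#' are excluded from the table.
#'
#' @param de a `de_result` from [nb_de_test()] (direction comes from `call`).
#' @param fc_set,lec_set character vectors of reference gene ids (first /
#'   second column identity).
#' @param continuity apply the Yates correction to the chi-squared test.
#' @param labels optional `list(rows = c(.,.), cols = c(.,.))` display labels;
#'   defaults are derived from the DE groups and `FC` / `LEC`.
#' @return list of class `deg_concordance`: `table` (observed 2x2 with
#'   dimnames), `expected`, `chi_square`, `p_value`, `genes` (annotated data
#'   frame: gene, log2fc, fdr, direction, identity), `n_degs`, `n_classified`,
#'   `dropped_ambiguous`.
#' @export
classify_degs <- function(de, fc_set, lec_set, continuity = FALSE,
                          labels = NULL) {
  stopifnot(inherits(de, "de_result"))
  both <- intersect(fc_set, lec_set)
  if (length(both) > 0L) {
    message(length(both), " gene(s) in both reference sets dropped: ",
            paste(head(both, 5L), collapse = ", "),
            if (length(both) > 5L) ", ..." else "")
    fc_set <- setdiff(fc_set, both)
    lec_set <- setdiff(lec_set, both)
  }
  degs <- de[de$call != "ns", , drop = FALSE]
  identity <- ifelse(degs$gene %in% fc_set, "FC",
                     ifelse(degs$gene %in% lec_set, "LEC", "neither"))
  ann <- data.frame(gene = degs$gene, log2fc = degs$log2fc, fdr = degs$fdr,
                    direction = degs$call, identity = identity,
                    row.names = NULL)
  classified <- ann[ann$identity != "neither", , drop = FALSE]
  if (nrow(classified) == 0L)
    stop("no DEG falls in either reference set: contingency table is empty")
  if (is.null(labels))
    labels <- list(rows = paste0("up_", c(attr(de, "group_a"),
                                          attr(de, "group_b"))),
                   cols = c("FC", "LEC"))
  a <- sum(classified$direction == "up_A" & classified$identity == "FC")
  b <- sum(classified$direction == "up_A" & classified$identity == "LEC")
  cc <- sum(classified$direction == "up_B" & classified$identity == "FC")
  d <- sum(classified$direction == "up_B" & classified$identity == "LEC")
  chi <- chi_square_2x2(a, b, cc, d, continuity = continuity)
  obs <- chi$observed
  dimnames(obs) <- dimnames(chi$expected) <- labels[c("rows", "cols")]
  structure(list(table = obs, expected = chi$expected,
                 chi_square = chi$statistic, p_value = chi$p_value,
                 genes = ann, n_degs = nrow(ann),
                 n_classified = nrow(classified),
                 dropped_ambiguous = both, continuity = continuity),
            class = "deg_concordance")
}

#' @export
print.deg_concordance <- function(x, ...) {
  cat(sprintf("deg_concordance: %d/%d DEGs in a reference set\n",
              x$n_classified, x$n_degs))
  tab <- x$table
  for (i in 1:2) for (j in 1:2)
    tab[i, j] <- sprintf("%s (%.1f)", x$table[i, j], x$expected[i, j])
  print(tab, quote = FALSE)
  cat(sprintf("chi-squared = %.4g, p = %.3g%s\n", x$chi_square, x$p_value,
              if (x$continuity) " (Yates-corrected)" else ""))
  invisible(x)
}

#' Overlay DEG fold changes with reference identities
#'
#' Annotates every DEG with its reference identity (FC / LEC / neither) and
#' summarizes the fold-change distribution per identity class: mean log2fc
#' and a two-sample Wilcoxon rank test between FC-labelled and LEC-labelled
#' fold changes — the quantitative content of a fold-change density overlay.
#'
#' @inheritParams classify_degs
#' @return list: `genes` (annotated table as in [classify_degs()]),
#'   `summary` (per-identity n, mean and sd of log2fc), `rank_test`
#'   (`statistic`, `p_value` of the Wilcoxon test, NULL if a class is empty).
#' @export
fc_lec_overlay <- function(de, fc_set, lec_set) {
  cls <- classify_degs_annotation(de, fc_set, lec_set)
  lab <- cls[cls$identity != "neither", , drop = FALSE]
  if (nrow(lab) == 0L) {
    warning("no DEG labelled FC or LEC: empty summary")
    return(list(genes = cls, summary = NULL, rank_test = NULL))
  }
  sm <- do.call(rbind, lapply(split(lab$log2fc, lab$identity), function(v)
    data.frame(n = length(v), mean_log2fc = mean(v), sd_log2fc = sd(v))))
  sm <- cbind(identity = rownames(sm), sm, row.names = NULL)
  rt <- NULL
  if (all(c("FC", "LEC") %in% lab$identity)) {
    wt <- wilcox.test(lab$log2fc[lab$identity == "FC"],
                      lab$log2fc[lab$identity == "LEC"], exact = FALSE)
    rt <- list(statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  list(genes = cls, summary = sm, rank_test = rt)
}

# shared annotation step (no contingency table, so it tolerates empty cells)
classify_degs_annotation <- function(de, fc_set, lec_set) {
  stopifnot(inherits(de, "de_result"))
  both <- intersect(fc_set, lec_set)
  fc_set <- setdiff(fc_set, both); lec_set <- setdiff(lec_set, both)
  degs <- de[de$call != "ns", , drop = FALSE]
  identity <- ifelse(degs$gene %in% fc_set, "FC",
                     ifelse(degs$gene %in% lec_set, "LEC", "neither"))
  data.frame(gene = degs$gene, log2fc = degs$log2fc, fdr = degs$fdr,
             direction = degs$call, identity = identity, row.names = NULL)
}
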