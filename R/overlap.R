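#' Top-fraction gene set of an enrichment ranking
#'
#' The `floor(x * N)` highest-scoring genes of a ranking (deterministic under
#' the ranking's gene-id tie-break). With the 10,320-gene universe, x = 10%
#' gives exactly 1032 genes.
#'
#' @param ranking an [enrichment_ranking()].
#' @param x fraction in (0, 1].
#' @return character vector of gene ids.
#' @export
top_fraction_set <- function(ranking, x) {
  if (!is.numeric(x) || length(x) != 1L || x <= 0 || x > 1)
    stop("x must lie in (0, 1]")
  k <- floor(x * nrow(ranking))
  ranking$gene[seq_len(k)]
}

#' Hypergeometric tail probability for the overlap of two gene sets
#'
#' For two independent uniform subsets of sizes `k_a` and `k_b` drawn from a
#' universe of `n` genes, the overlap is
#' \eqn{X \sim \mathrm{Hypergeometric}(n, k_a, k_b)}. Returns the exact upper
#' tail: `P(X > o)` under convention `"greater"` (the default; with the
#' published organoid-vs-lens counts o = 198, k = 1032, n = 10320 this gives
#' 8.7e-22) or `P(X >= o)` under `"greater_or_equal"`.
#'
#' @param o observed overlap count.
#' @param k_a,k_b set sizes.
#' @param n universe size.
#' @param convention `"greater"` or `"greater_or_equal"`.
#' @return the tail probability.
#' @export
hypergeom_overlap_pvalue <- function(o, k_a, k_b, n,
                                     convention = c("greater",
                                                    "greater_or_equal")) {
  convention <- match.arg(convention)
  if (o < 0 || o > min(k_a, k_b) || max(k_a, k_b) > n)
    stop("inconsistent counts: need 0 <= o <= min(k_a, k_b) <= n")
  q <- if (convention == "greater") o else o - 1
  phyper(q, k_a, n - k_a, k_b, lower.tail = FALSE)
}

#' Top-x% overlap sweep between two enrichment rankings
#'
#' For each fraction x in `x_grid`, takes the top `K = floor(x N)` genes of
#' both rankings and reports the observed overlap `O(x)`, the
#' independence expectation `E(x) = K^2 / N`, and the hypergeometric tail
#' p-value. The intersection gene lists are kept as an attribute (the x = 1%
#' list is the headline shared-gene list).
#'
#' @param ranking_a,ranking_b [enrichment_ranking()] objects over the same
#'   gene universe.
#' @param x_grid fractions; default 0.25% steps over (0, 10%].
#' @param convention tail convention, see [hypergeom_overlap_pvalue()].
#' @return A data frame of class `overlap_sweep` with columns `x`, `k`,
#'   `observed`, `expected`, `p_value`; attribute `intersections` holds the
#'   per-x gene lists and attribute `n_universe` the universe size.
#' @export
overlap_sweep <- function(ranking_a, ranking_b,
                          x_grid = seq(0.0025, 0.10, by = 0.0025),
                          convention = "greater") {
  if (!identical(sort(ranking_a$gene), sort(ranking_b$gene)))
    stop("rankings must share the same gene universe")
  n <- nrow(ranking_a)
  rows <- lapply(x_grid, function(x) {
    sa <- top_fraction_set(ranking_a, x)
    sb <- top_fraction_set(ranking_b, x)
    k <- length(sa)
    inter <- intersect(sa, sb)
    data.frame(x = x, k = k, observed = length(inter), expected = k^2 / n,
               p_value = hypergeom_overlap_pvalue(length(inter), k, k, n,
                                                  convention))
  })
  inters <- lapply(x_grid, function(x)
    intersect(top_fraction_set(ranking_a, x), top_fraction_set(ranking_b, x)))
  names(inters) <- sprintf("%g", x_grid)
  structure(do.call(rbind, rows),
            class = c("overlap_sweep", "data.frame"),
            intersections = inters, n_universe = n, convention = convention)
}

#' Mean expression trajectory of gene sets across stages
#'
#' Arithmetic mean and standard deviation of expression per gene set per
#' stage, in stage (column) order — the construction behind plotting how the
#' culture-defined gene sets behave across lens development.
#'
#' @param sets named list of gene-id vectors.
#' @param stage_table numeric matrix genes x stages (rownames = gene ids).
#' @return data frame with columns `set`, `stage`, `mean`, `sd`, `n_genes`.
#'   Genes absent from the table are dropped with a warning.
#' @export
set_mean_trajectory <- function(sets, stage_table) {
  stopifnot(is.matrix(stage_table), !is.null(rownames(stage_table)))
  out <- list()
  for (nm in names(sets)) {
    genes <- sets[[nm]]
    missing <- setdiff(genes, rownames(stage_table))
    if (length(missing) > 0L) {
      warning(sprintf("set '%s': %d unknown gene(s) dropped (%s%s)", nm,
                      length(missing), paste(head(missing, 3L), collapse = ", "),
                      if (length(missing) > 3L) ", ..." else ""))
      genes <- setdiff(genes, missing)
    }
    if (length(genes) == 0L) next
    sub <- stage_table[genes, , drop = FALSE]
    out[[nm]] <- data.frame(
      set = nm, stage = colnames(stage_table),
      mean = colMeans(sub),
      sd = apply(sub, 2L, sd),
      n_genes = length(genes), row.names = NULL)
  }
  if (length(out) == 0L) stop("no genes left in any set")
  do.call(rbind, c(out, make.row.names = FALSE))
}
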