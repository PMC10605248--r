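#' Construct a count matrix with sample metadata
#'
#' @param counts gene x sample matrix of non-negative integers with unique
#'   rownames (gene ids) and colnames (sample ids).
#' @param sample_meta data frame with columns `sample` and `group` (and
#'   optionally `lib_size`; recomputed from column sums if absent).
#' @param truth optional list of planted ground truth (from the simulator).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, sample_meta, truth = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique gene rownames")
  if (!all(c("sample", "group") %in% names(sample_meta)))
    stop("sample_meta needs columns 'sample' and 'group'")
  if (!identical(colnames(counts), as.character(sample_meta$sample)))
    stop("colnames(counts) must match sample_meta$sample")
  if (anyNA(sample_meta$group)) stop("every sample needs a group")
  sample_meta$lib_size <- colSums(counts)
  structure(list(counts = counts, sample_meta = sample_meta, truth = truth),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$sample_meta$group)),
                            table(x$sample_meta$group)), collapse = ", ")))
  invisible(x)
}

samples_of <- function(x, groups) {
  x$sample_meta$sample[x$sample_meta$group %in% groups]
}

#' Counts per million
#'
#' `cpm[g, i] = counts[g, i] / library_size[i] * 1e6`, where the library size
#' is the sample's column sum.
#'
#' @param x a [count_matrix()] or a plain counts matrix.
#' @return gene x sample matrix of CPM values.
#' @export
cpm <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size: cpm undefined")
  sweep(counts, 2L, lib, "/") * 1e6
}

#' Expression filter on mean CPM
#'
#' A gene is retained iff its mean CPM across the given samples exceeds
#' `cpm_cut` (default 0.2 CPM, the conventional low-expression cut for 3'-end
#' counting). The mean is taken across all samples of the contrast.
#'
#' @param x a [count_matrix()].
#' @param cpm_cut CPM threshold; genes with mean CPM strictly above it pass.
#' @param samples optional character vector restricting to a subset of
#'   samples (e.g. those of one contrast); default all.
#' @return character vector of retained gene ids.
#' @export
expression_filter <- function(x, cpm_cut = 0.2, samples = NULL) {
  cp <- cpm(x)
  if (!is.null(samples)) cp <- cp[, samples, drop = FALSE]
  rownames(cp)[rowMeans(cp) > cpm_cut]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median across all-positive genes of
#' the ratio of a sample's counts to the per-gene geometric-mean reference,
#' rescaled to geometric mean 1. Falls back to library size over mean library
#' size when no gene is positive in every sample.
#'
#' @param x a [count_matrix()] or counts matrix.
#' @return named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) {
    lib <- colSums(counts)
    s <- if (all(lib == 0)) rep(1, ncol(counts)) else lib / mean(lib)
    return(setNames(s, colnames(counts)))
  }
  lg <- log(counts[ok, , drop = FALSE])
  ref <- rowMeans(lg)
  s <- exp(apply(lg - ref, 2L, median))
  s <- s / exp(mean(log(s)))
  setNames(s, colnames(counts))
}

#' Negative-binomial Wald differential-expression test
#'
#' A self-contained two-group NB test: counts are normalized by
#' [size_factors()]; a single common dispersion \eqn{\hat\alpha} is estimated
#' by method of moments (mean over well-expressed genes of
#' \eqn{\max(0, (\hat v - \hat m)/\hat m^2)} with pooled within-group moments);
#' the Wald statistic
#' \eqn{W = (\ln\hat\mu_A - \ln\hat\mu_B) / \mathrm{SE}} with
#' \eqn{\mathrm{SE}^2 = \sum_{j \in \{A,B\}} (1/\hat\mu_j + \hat\alpha)/n_j}
#' is referred to the standard normal (two-sided), and p-values are adjusted
#' by Benjamini-Hochberg. A gene is called `up_A` iff `fdr < fdr_cut` and
#' `log2fc > log2fc_cut` (symmetrically `up_B`), with
#' `log2fc = log2((mu_A + 0.5) / (mu_B + 0.5))` — the 0.5 pseudocount enters
#' the fold change only, not the test. Genes are pre-filtered with
#' [expression_filter()] over the contrast's samples; genes at zero in both
#' groups get p = 1 by convention.
#'
#' @param x a [count_matrix()].
#' @param group_a,group_b group labels to contrast (log2fc is A over B).
#' @param fdr_cut,log2fc_cut,cpm_cut significance, fold-change and expression
#'   thresholds (defaults 0.05, 1, 0.2; a stricter FDR of 0.01 matches the
#'   headline DEG counts of regional analyses).
#' @return A data frame of class `de_result` with one row per tested gene:
#'   `gene`, `mean_a`, `mean_b` (normalized group means), `mean_cpm`,
#'   `log2fc`, `p_value`, `fdr`, `call` in `{up_A, up_B, ns}`. Attributes
#'   record the thresholds, groups and the common dispersion estimate.
#' @export
nb_de_test <- function(x, group_a, group_b, fdr_cut = 0.05, log2fc_cut = 1,
                       cpm_cut = 0.2) {
  stopifnot(inherits(x, "count_matrix"))
  sa <- samples_of(x, group_a); sb <- samples_of(x, group_b)
  if (length(sa) < 2L || length(sb) < 2L)
    stop("each group needs at least 2 samples")
  contrast <- c(sa, sb)
  keep <- expression_filter(x, cpm_cut = cpm_cut, samples = contrast)
  if (length(keep) == 0L) stop("no genes pass the expression filter")
  cnt <- x$counts[keep, contrast, drop = FALSE]
  s <- size_factors(cnt)
  y <- sweep(cnt, 2L, s, "/")
  ia <- seq_along(sa); ib <- length(sa) + seq_along(sb)
  na <- length(sa); nb <- length(sb)
  ma <- rowMeans(y[, ia, drop = FALSE]); mb <- rowMeans(y[, ib, drop = FALSE])
  va <- apply(y[, ia, drop = FALSE], 1L, var)
  vb <- apply(y[, ib, drop = FALSE], 1L, var)
  vp <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  mp <- (na * ma + nb * mb) / (na + nb)
  ag <- pmax(0, (vp - mp) / mp^2)
  well <- mp >= 5
  alpha_hat <- max(if (any(well)) mean(ag[well]) else mean(ag[mp > 0]), 1e-8)
  # zero group means would put the log at -Inf; substitute half a normalized
  # count spread over the group so the statistic stays finite
  fa <- ifelse(ma > 0, ma, 0.5 / na)
  fb <- ifelse(mb > 0, mb, 0.5 / nb)
  se2 <- (1 / fa + alpha_hat) / na + (1 / fb + alpha_hat) / nb
  w <- (log(fa) - log(fb)) / sqrt(se2)
  p <- 2 * pnorm(-abs(w))
  p[ma == 0 & mb == 0] <- 1
  fdr <- p.adjust(p, method = "BH")
  log2fc <- log2((ma + 0.5) / (mb + 0.5))
  call <- rep("ns", length(p))
  call[fdr < fdr_cut & log2fc > log2fc_cut] <- "up_A"
  call[fdr < fdr_cut & log2fc < -log2fc_cut] <- "up_B"
  out <- data.frame(gene = keep, mean_a = ma, mean_b = mb,
                    mean_cpm = rowMeans(cpm(x)[keep, contrast, drop = FALSE]),
                    log2fc = log2fc, p_value = p, fdr = fdr, call = call,
                    row.names = NULL)
  structure(out, class = c("de_result", "data.frame"),
            group_a = group_a, group_b = group_b,
            fdr_cut = fdr_cut, log2fc_cut = log2fc_cut, cpm_cut = cpm_cut,
            dispersion = alpha_hat)
}

#' Tissue-enrichment ranking
#'
#' Scores every gene by \eqn{e_g = \log_2((m_t + c) / (m_r + c))} where
#' \eqn{m_t, m_r} are mean CPM in the target and reference and `c` a
#' pseudocount (default 1 CPM), then ranks genes by descending score. This is
#' the lens-enrichment construction: expression in a target tissue relative
#' to a whole-body reference. Ties are broken deterministically by gene id.
#'
#' @param target,reference either named mean-CPM vectors over the same gene
#'   universe, or [count_matrix()] objects together with `target_group` /
#'   `reference_group` labels.
#' @param target_group,reference_group group labels used when count matrices
#'   are supplied.
#' @param pseudocount CPM pseudocount `c`.
#' @param label dataset label stored on the ranking.
#' @return A data frame of class `enrichment_ranking` ordered by rank:
#'   `gene`, `score`, `rank` (1 = most enriched).
#' @export
enrichment_ranking <- function(target, reference, target_group = NULL,
                               reference_group = NULL, pseudocount = 1,
                               label = "enrichment") {
  mean_cpm_of <- function(x, grp) {
    if (inherits(x, "count_matrix")) {
      sel <- samples_of(x, grp)
      if (length(sel) == 0L) stop("group not found: ", grp)
      rowMeans(cpm(x)[, sel, drop = FALSE])
    } else {
      v <- unlist(x)
      if (is.null(names(v))) stop("mean-cpm vectors must be named by gene")
      v
    }
  }
  mt <- mean_cpm_of(target, target_group)
  mr <- mean_cpm_of(reference, reference_group)
  if (!identical(sort(names(mt)), sort(names(mr))))
    stop("target and reference must share the same gene universe")
  mr <- mr[names(mt)]
  e <- log2((mt + pseudocount) / (mr + pseudocount))
  ord <- order(-e, names(mt))
  out <- data.frame(gene = names(mt)[ord], score = unname(e[ord]),
                    rank = seq_along(e), row.names = NULL)
  structure(out, class = c("enrichment_ranking", "data.frame"), label = label)
}

#' Write / read a count matrix as TSV
#'
#' Counts go to a TSV with genes in rows (first column `gene`, remaining
#' columns one per sample); metadata to a TSV with columns `sample`, `group`,
#' `lib_size`.
#'
#' @param x a [count_matrix()].
#' @param counts_path,meta_path file paths.
#' @return `write_count_matrix`: invisibly, `counts_path`;
#'   `read_count_matrix`: a [count_matrix()].
#' @export
write_count_matrix <- function(x, counts_path, meta_path) {
  stopifnot(inherits(x, "count_matrix"))
  write.table(data.frame(gene = rownames(x$counts), x$counts,
                         check.names = FALSE),
              counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$sample_meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(counts_path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_path, meta_path) {
  tab <- read.table(counts_path, header = TRUE, sep = "\t",
                    check.names = FALSE)
  meta <- read.table(meta_path, header = TRUE, sep = "\t")
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(counts) <- tab$gene
  count_matrix(counts, meta)
}
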