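#' Configuration for the synthetic grouped count-matrix generator
#'
#' Counts emulate 3'-end RNA-seq of the study designs this package analyses:
#' 2D vs 3D whole-culture profiles, laser-microdissected internal vs external
#' organoid regions, and lens vs whole-embryonic-body (WB) reference tissue.
#' Gene baselines \eqn{q_g} are log-normal, library sizes are uniform over
#' `library_size_range`, and the count of gene g in sample i is drawn
#' NB(mean \eqn{= s_i q_g 2^{\delta(g, \mathrm{group}(i))}}, dispersion
#' `dispersion_alpha`), where \eqn{\delta} is the planted log2 fold change (0
#' if unplanted) and \eqn{s_i} scales \eqn{q} to the sample's library size.
#'
#' Cross-dataset enrichment is planted through two gene sets of size
#' `n_enriched` carrying a `enriched_log2fc` fold in the `"lens"` and `"3D"`
#' groups respectively, sharing a fraction `shared_enriched_fraction_rho` of
#' their genes — so the lens-vs-WB and 3D-vs-WB enrichment rankings overlap
#' above chance, as the real organoid does with the lens reference.
#'
#' @param n_genes number of genes (default 10320, the gene universe size of
#'   the enrichment analyses).
#' @param group_sizes named integer vector, samples per group. Defaults mirror
#'   the study designs: 3 + 3 whole-culture 2D/3D samples, 4 internal and 3
#'   external microdissected samples, 3 + 3 lens/WB reference samples.
#' @param baseline_log_mean_mu,baseline_log_mean_sd meanlog / sdlog of the
#'   log-normal gene baseline (relative abundance units).
#' @param dispersion_alpha NB dispersion (variance \eqn{= \mu + \alpha\mu^2});
#'   0 degenerates to Poisson.
#' @param planted_sets list of `list(genes =, log2fc =, groups =)` entries
#'   planting extra fold changes; contradictory folds for the same
#'   (gene, group) are an error.
#' @param shared_enriched_fraction_rho fraction in `[0, 1]` of the two
#'   enrichment sets forced to coincide.
#' @param n_enriched size of each planted enrichment set (0 disables).
#' @param enriched_log2fc log2 fold planted in the enrichment sets.
#' @param library_size_range range of expected total counts per sample.
#' @param seed integer RNG seed.
#'
#' @return A validated list of class `counts_sim_config`.
#' @export
counts_sim_config <- function(n_genes = 10320L,
                              group_sizes = c("2D" = 3L, "3D" = 3L,
                                              internal = 4L, external = 3L,
                                              lens = 3L, WB = 3L),
                              baseline_log_mean_mu = 3.9,
                              baseline_log_mean_sd = 1.5,
                              dispersion_alpha = 0.1,
                              planted_sets = list(),
                              shared_enriched_fraction_rho = 0.2,
                              n_enriched = 1032L,
                              enriched_log2fc = 2,
                              library_size_range = c(1e6, 2e6),
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
              baseline_log_mean_mu = baseline_log_mean_mu,
              baseline_log_mean_sd = baseline_log_mean_sd,
              dispersion_alpha = dispersion_alpha,
              planted_sets = planted_sets,
              shared_enriched_fraction_rho = shared_enriched_fraction_rho,
              n_enriched = as.integer(n_enriched),
              enriched_log2fc = enriched_log2fc,
              library_size_range = library_size_range,
              seed = as.integer(seed))
  if (cfg$n_genes < 1L) stop("invalid config: n_genes must be >= 1")
  if (is.null(names(cfg$group_sizes)) || any(names(cfg$group_sizes) == ""))
    stop("invalid config: group_sizes must be a named vector")
  if (any(cfg$group_sizes < 1L)) stop("invalid config: group sizes must be >= 1")
  if (cfg$dispersion_alpha < 0)
    stop("invalid config: dispersion_alpha must be >= 0")
  rho <- cfg$shared_enriched_fraction_rho
  if (rho < 0 || rho > 1)
    stop("invalid config: shared_enriched_fraction_rho must lie in [0, 1]")
  if (any(cfg$library_size_range <= 0))
    stop("invalid config: library sizes must be > 0")
  for (ps in cfg$planted_sets) {
    if (!all(c("genes", "log2fc", "groups") %in% names(ps)))
      stop("invalid config: each planted set needs genes, log2fc, groups")
    if (max(ps$genes) > cfg$n_genes || min(ps$genes) < 1L)
      stop("invalid config: planted gene index out of range")
    if (!all(ps$groups %in% names(cfg$group_sizes)))
      stop("invalid config: planted group not in group_sizes")
  }
  class(cfg) <- "counts_sim_config"
  cfg
}

gene_ids_for <- function(n) sprintf("g%05d", seq_len(n))

#' Simulate a grouped RNA-seq count matrix with planted truth
#'
#' Draws NB counts under [counts_sim_config()] and records the planted fold
#' changes and enrichment sets so downstream recovery can be scored against
#' ground truth. Deterministic for a fixed seed.
#'
#' @param cfg a [counts_sim_config()].
#' @return A [count_matrix()] whose `truth` element holds the per-(gene,
#'   group) planted log2 folds and the planted enrichment gene sets.
#' @export
simulate_counts <- function(cfg) {
  if (!inherits(cfg, "counts_sim_config")) cfg <- do.call(counts_sim_config, cfg)
  set.seed(cfg$seed)
  ng <- cfg$n_genes
  gid <- gene_ids_for(ng)
  groups <- rep(names(cfg$group_sizes), times = cfg$group_sizes)
  sample_ids <- unlist(lapply(names(cfg$group_sizes), function(g)
    paste0(g, "_", seq_len(cfg$group_sizes[[g]]))), use.names = FALSE)
  ns <- length(groups)

  q <- exp(rnorm(ng, cfg$baseline_log_mean_mu, cfg$baseline_log_mean_sd))
  L <- runif(ns, cfg$library_size_range[1L], cfg$library_size_range[2L])

  # delta[g, group]: planted log2 fold; contradictions are errors
  delta <- matrix(0, ng, length(cfg$group_sizes),
                  dimnames = list(gid, names(cfg$group_sizes)))
  planted_any <- rep(FALSE, ng)
  plant <- function(genes, lfc, grps) {
    for (g in grps) {
      cur <- delta[genes, g]
      clash <- cur != 0 & cur != lfc
      if (any(clash))
        stop("invalid config: contradictory planted folds for gene(s) ",
             paste(head(gid[genes[clash]], 5L), collapse = ", "),
             " in group ", g)
      delta[genes, g] <<- lfc
    }
    planted_any[genes] <<- TRUE
  }
  for (ps in cfg$planted_sets) plant(ps$genes, ps$log2fc, ps$groups)

  enriched <- list(lens = integer(0), `3D` = integer(0))
  if (cfg$n_enriched > 0L &&
      all(c("lens", "3D") %in% names(cfg$group_sizes))) {
    n_shared <- round(cfg$shared_enriched_fraction_rho * cfg$n_enriched)
    free <- which(!planted_any)
    need <- 2L * cfg$n_enriched - n_shared
    if (length(free) < need)
      stop("invalid config: not enough unplanted genes for enrichment sets")
    pick <- sample(free, need)
    shared <- pick[seq_len(n_shared)]
    only_lens <- pick[n_shared + seq_len(cfg$n_enriched - n_shared)]
    only_3d <- pick[(cfg$n_enriched) + seq_len(cfg$n_enriched - n_shared)]
    enriched$lens <- sort(c(shared, only_lens))
    enriched$`3D` <- sort(c(shared, only_3d))
    plant(enriched$lens, cfg$enriched_log2fc, "lens")
    plant(enriched$`3D`, cfg$enriched_log2fc, "3D")
  }

  s <- L / sum(q)
  mu <- (q * 2^delta[, groups, drop = FALSE]) %*% diag(s)
  counts <- if (cfg$dispersion_alpha == 0) {
    matrix(rpois(length(mu), lambda = mu), ng, ns)
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion_alpha), ng, ns)
  }
  dimnames(counts) <- list(gid, sample_ids)

  meta <- data.frame(sample = sample_ids, group = groups,
                     lib_size = colSums(counts))
  truth <- list(
    delta = delta,
    enriched_lens = gid[enriched$lens],
    enriched_3d = gid[enriched$`3D`],
    baseline_cpm = setNames(q / sum(q) * 1e6, gid),
    dispersion_alpha = cfg$dispersion_alpha,
    seed = cfg$seed
  )
  count_matrix(counts, meta, truth = truth)
}

#' Simulate a gene-by-stage expression table
#'
#' Emulates a developmental reference table (mean expression per gene per
#' stage): genes listed in `profiles` follow their stated stage means, all
#' others sit at `baseline_mean`; i.i.d. Gaussian noise of `noise_sd` is added
#' throughout.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param stages character vector of stage labels (column order = stage order).
#' @param profiles named list: set name -> `list(genes =, means =)` with
#'   `means` of length `length(stages)`.
#' @param baseline_mean expression level of unprofiled genes.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer RNG seed.
#' @return numeric matrix genes x stages.
#' @export
simulate_stage_table <- function(gene_ids,
                                 stages = c("E10.5", "E12.5", "E14.5",
                                            "E16.5", "E17.5", "E19.5"),
                                 profiles = list(), baseline_mean = 5,
                                 noise_sd = 0.2, seed = 1L) {
  set.seed(seed)
  tab <- matrix(baseline_mean, length(gene_ids), length(stages),
                dimnames = list(gene_ids, stages))
  for (pr in profiles) {
    if (length(pr$means) != length(stages))
      stop("profile means must match the number of stages")
    idx <- match(pr$genes, gene_ids)
    if (anyNA(idx)) stop("profile genes must be in gene_ids")
    tab[idx, ] <- matrix(pr$means, length(idx), length(stages), byrow = TRUE)
  }
  tab + matrix(rnorm(length(tab), sd = noise_sd), nrow(tab), ncol(tab))
}
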