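#' Default end-to-end pipeline configuration
#'
#' A single seeded configuration driving the full synthetic study: a grouped
#' count matrix with planted regional fold changes and planted cross-dataset
#' enrichment, reference identity sets built from the planted truth, the
#' 2D-vs-3D and internal-vs-external DE contrasts, the enrichment overlap
#' sweep and the optics dose-response.
#'
#' @param seed global integer seed; all stage seeds derive from it.
#' @return a nested configuration list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  cfg <- list(
    seed = seed,
    counts = list(
      n_genes = 10320L,
      planted = list(
        internal_up = list(genes = 1:200, log2fc = 2, groups = "internal"),
        external_up = list(genes = 201:400, log2fc = 2, groups = "external"),
        up_3d = list(genes = 401:500, log2fc = 2, groups = "3D"),
        dn_3d = list(genes = 501:600, log2fc = -2, groups = "3D")
      ),
      shared_enriched_fraction_rho = 0.2,
      n_enriched = 1032L,
      dispersion_alpha = 0.1
    ),
    reference_sets = list(frac_concordant = 0.8, n_background = 200L),
    thresholds = list(fdr_cut = 0.01, log2fc_cut = 1, cpm_cut = 0.2),
    x_grid = seq(0.0025, 0.10, by = 0.0025),
    convention = "greater",
    optics = list(taus = c(0, 0.3, 0.6, 0.9), n_per_dose = 12L,
                  image_side = 128L, n_slices = 25L, disk_radius = 45,
                  noise_model = "poisson")
  )
  class(cfg) <- "run_config"
  cfg
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the requested stages in dependency order — simulate counts,
#' 2D-vs-3D differential expression, enrichment ranking + overlap sweep,
#' regional DE + reference-set concordance, and the optics dose-response —
#' writing every result table under `out_dir` plus a `manifest.json` with a
#' content hash per output. Deterministic: two runs with the same config
#' produce byte-identical tables.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [default_run_config()]-shaped list.
#' @param stages subset of
#'   `c("counts", "de", "enrichment", "regional", "optics")`; dependencies of
#'   requested stages are added automatically.
#' @param figures also write PNG figures (focal curves, overlap sweep,
#'   volcano, fold-change density).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(out_dir, config = default_run_config(),
                         stages = c("counts", "de", "enrichment",
                                    "regional", "optics"),
                         figures = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (any(c("de", "enrichment", "regional") %in% stages))
    stages <- union(stages, "counts")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  files <- character(0)
  report <- c("# Synthetic lens-organoid analysis run", "",
              sprintf("seed: %d", config$seed), "")
  add <- function(path) files <<- c(files, path)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if ("counts" %in% stages) run_stage("counts", {
    cc <- config$counts
    ccfg <- counts_sim_config(
      n_genes = cc$n_genes, planted_sets = cc$planted,
      shared_enriched_fraction_rho = cc$shared_enriched_fraction_rho,
      n_enriched = cc$n_enriched, dispersion_alpha = cc$dispersion_alpha,
      seed = config$seed)
    cm <- simulate_counts(ccfg)
    res$counts <- cm
    add(write_tsv(data.frame(gene = rownames(cm$counts), cm$counts,
                             check.names = FALSE),
                  file.path(out_dir, "counts.tsv")))
    add(write_tsv(cm$sample_meta, file.path(out_dir, "sample_meta.tsv")))
    nz <- which(cm$truth$delta != 0, arr.ind = TRUE)
    truth <- list(
      planted = data.frame(gene = rownames(cm$truth$delta)[nz[, 1L]],
                           group = colnames(cm$truth$delta)[nz[, 2L]],
                           log2fc = cm$truth$delta[nz]),
      enriched_lens = cm$truth$enriched_lens,
      enriched_3d = cm$truth$enriched_3d,
      dispersion_alpha = cm$truth$dispersion_alpha, seed = cm$truth$seed)
    jsonlite::write_json(truth, file.path(out_dir, "planted_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    add(file.path(out_dir, "planted_truth.json"))
    report <- c(report, sprintf(
      "- counts: %d genes x %d samples simulated", nrow(cm$counts),
      ncol(cm$counts)))
  })

  th <- config$thresholds
  if ("de" %in% stages) run_stage("de", {
    de <- nb_de_test(res$counts, "3D", "2D", fdr_cut = th$fdr_cut,
                     log2fc_cut = th$log2fc_cut, cpm_cut = th$cpm_cut)
    res$de_3d_2d <- de
    add(write_tsv(as.data.frame(de), file.path(out_dir, "de_3d_vs_2d.tsv")))
    report <- c(report, sprintf(
      "- 2D vs 3D DE: %d genes tested, %d up in 3D, %d up in 2D (FDR < %g, |log2FC| > %g)",
      nrow(de), sum(de$call == "up_A"), sum(de$call == "up_B"),
      th$fdr_cut, th$log2fc_cut))
  })

  if ("enrichment" %in% stages) run_stage("enrichment", {
    r3d <- enrichment_ranking(res$counts, res$counts, "3D", "WB",
                              label = "3D vs WB")
    rlens <- enrichment_ranking(res$counts, res$counts, "lens", "WB",
                                label = "lens vs WB")
    sw <- overlap_sweep(r3d, rlens, x_grid = config$x_grid,
                        convention = config$convention)
    res$ranking_3d <- r3d; res$ranking_lens <- rlens; res$sweep <- sw
    add(write_tsv(as.data.frame(r3d), file.path(out_dir, "ranking_3d.tsv")))
    add(write_tsv(as.data.frame(rlens), file.path(out_dir, "ranking_lens.tsv")))
    add(write_tsv(as.data.frame(sw), file.path(out_dir, "overlap_sweep.tsv")))
    jsonlite::write_json(attr(sw, "intersections"),
                         file.path(out_dir, "overlap_intersections.json"),
                         auto_unbox = FALSE, digits = NA)
    add(file.path(out_dir, "overlap_intersections.json"))
    at10 <- sw[which.min(abs(sw$x - 0.10)), ]
    report <- c(report, sprintf(
      "- enrichment overlap at x = 10%%: %d shared genes observed, %.1f expected by chance (p = %.3g, %s)",
      at10$observed, at10$expected, at10$p_value, config$convention))
  })

  if ("regional" %in% stages) run_stage("regional", {
    de_r <- nb_de_test(res$counts, "internal", "external",
                       fdr_cut = th$fdr_cut, log2fc_cut = th$log2fc_cut,
                       cpm_cut = th$cpm_cut)
    res$de_regional <- de_r
    add(write_tsv(as.data.frame(de_r),
                  file.path(out_dir, "de_internal_vs_external.tsv")))
    refs <- reference_identity_sets(res$counts,
                                    frac = config$reference_sets$frac_concordant,
                                    n_background = config$reference_sets$n_background,
                                    seed = config$seed)
    conc <- classify_degs(de_r, refs$fc, refs$lec)
    over <- fc_lec_overlay(de_r, refs$fc, refs$lec)
    res$concordance <- conc; res$overlay <- over
    jsonlite::write_json(
      list(observed = conc$table, expected = conc$expected,
           chi_square = conc$chi_square, p_value = conc$p_value,
           n_degs = conc$n_degs, n_classified = conc$n_classified),
      file.path(out_dir, "contingency.json"),
      auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    add(file.path(out_dir, "contingency.json"))
    add(write_tsv(conc$genes, file.path(out_dir, "annotated_degs.tsv")))
    report <- c(report, sprintf(
      "- regional DE: %d DEGs, %d in a reference identity set; chi-squared = %.3g, p = %.3g",
      conc$n_degs, conc$n_classified, conc$chi_square, conc$p_value))
  })

  if ("optics" %in% stages) run_stage("optics", {
    op <- config$optics
    curves <- list()
    for (di in seq_along(op$taus)) {
      tau <- op$taus[[di]]
      cond <- sprintf("tau_%g", tau)
      curves[[cond]] <- lapply(seq_len(op$n_per_dose), function(k) {
        scfg <- stack_sim_config(
          image_side = op$image_side, n_slices = op$n_slices,
          disk_radius = op$disk_radius, opacity_tau = tau,
          noise_model = op$noise_model,
          seed = config$seed + 1000L * di + k)
        focal_ratio_curve(simulate_zstack(scfg))
      })
    }
    cmp <- compare_conditions(curves, dose = op$taus)
    res$optics <- cmp
    add(write_tsv(cmp$summary, file.path(out_dir, "optics_dose_summary.tsv")))
    add(write_tsv(cmp$curve_summary, file.path(out_dir, "optics_curves.tsv")))
    add(write_tsv(cmp$peaks, file.path(out_dir, "optics_peaks.tsv")))
    report <- c(report, sprintf(
      "- optics: mean peak ratio by opacity dose: %s (Spearman rho = %.2f)",
      paste(sprintf("%s=%.2f", cmp$summary$condition,
                    cmp$summary$mean_peak_ratio), collapse = ", "),
      cmp$trend$rho))
  })

  if (figures) run_stage("figures", {
    figs <- list()
    if (!is.null(res$optics))
      figs$focal_curves.png <- plot_focal_curve(res$optics)
    if (!is.null(res$sweep))
      figs$overlap_sweep.png <- plot_overlap_sweep(res$sweep)
    if (!is.null(res$de_regional))
      figs$volcano_regional.png <- plot_volcano(res$de_regional)
    if (!is.null(res$overlay))
      figs$fold_change_density.png <- plot_fc_density(res$overlay)
    for (nm in names(figs)) {
      path <- file.path(out_dir, nm)
      ggplot2::ggsave(path, figs[[nm]], width = 5, height = 3.5, dpi = 120)
      add(path)
      report <- c(report, sprintf("- figure: %s", nm))
    }
  })

  writeLines(report, file.path(out_dir, "report.md"))
  add(file.path(out_dir, "report.md"))
  manifest <- list(
    package = "lensoid",
    package_version = as.character(utils::packageVersion("lensoid")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config),
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  res$manifest <- manifest
  invisible(res)
}

#' Build synthetic reference identity gene sets from planted truth
#'
#' Emulates external epithelium (LEC) and fiber-cell (FC) reference DEG
#' lists: a fraction `frac` of the planted internal-up genes goes to the FC
#' set and the remainder to the LEC set (discordant assignments, as real
#' reference lists contain), symmetrically for the external-up genes; each
#' set is topped up with `n_background` unplanted genes (reference sets in
#' real data contain many genes the regional contrast never calls). The two
#' sets are disjoint by construction. Synthetic stand-ins — they are derived
#' from the simulator's planted truth, not from any real microdissection
#' data.
#'
#' @param cm a simulated [count_matrix()] with planted truth containing
#'   `internal` and `external` fold columns.
#' @param frac fraction of planted regional genes included in the matching
#'   reference set.
#' @param n_background unplanted genes added per set.
#' @param seed integer seed for the random picks.
#' @return list with character vectors `fc` and `lec`.
#' @export
reference_identity_sets <- function(cm, frac = 0.8, n_background = 200L,
                                    seed = 1L) {
  stopifnot(inherits(cm, "count_matrix"), !is.null(cm$truth))
  delta <- cm$truth$delta
  if (!all(c("internal", "external") %in% colnames(delta)))
    stop("planted truth lacks internal/external groups")
  set.seed(seed + 7L)
  int_up <- rownames(delta)[delta[, "internal"] > 0]
  ext_up <- rownames(delta)[delta[, "external"] > 0]
  unplanted <- rownames(delta)[rowSums(delta != 0) == 0]
  fc_int <- sample(int_up, round(frac * length(int_up)))
  lec_ext <- sample(ext_up, round(frac * length(ext_up)))
  bg <- sample(unplanted, 2L * n_background)
  list(fc = sort(c(fc_int, setdiff(ext_up, lec_ext),
                   bg[seq_len(n_background)])),
       lec = sort(c(lec_ext, setdiff(int_up, fc_int),
                    bg[n_background + seq_len(n_background)])))
}
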