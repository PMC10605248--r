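# Small in-code fixtures shared across test files.

# tiny noise-free lensing stack (fast to simulate, exact generator truth);
# odd image side puts the spot centre on a pixel, so closed forms are exact
small_stack_cfg <- function(...) {
  defaults <- list(image_side = 97L, n_slices = 13L, z_min = -30, z_max = 0,
                   z_f = -20, background_b = 500, spot_flux_F = 5e4,
                   sigma0 = 2, cone_slope_s = 0.3, disk_radius = 30,
                   noise_model = "none", seed = 1L)
  do.call(stack_sim_config, utils::modifyList(defaults, list(...)))
}

# peak values per unique distance from the focal plane (first occurrence)
by_distance <- function(values, z, z_f) {
  d <- abs(z - z_f)
  ud <- sort(unique(d))
  vapply(ud, function(u) values[which(d == u)[1L]], numeric(1L))
}

# hand-built count matrix: 4 genes x 4 samples, two groups
tiny_counts <- function() {
  counts <- matrix(c(10, 20, 12, 18,
                     100, 110, 95, 105,
                     0, 0, 0, 0,
                     5, 0, 8, 2), nrow = 4L, byrow = TRUE,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  count_matrix(counts, data.frame(sample = paste0("s", 1:4),
                                  group = rep(c("A", "B"), each = 2L)))
}

# a de_result built by hand (bypasses the test) for classification tests
fake_de_result <- function(genes, log2fc, call, group_a = "internal",
                           group_b = "external") {
  structure(data.frame(gene = genes, mean_a = 1, mean_b = 1, mean_cpm = 10,
                       log2fc = log2fc, p_value = 0.001, fdr = 0.001,
                       call = call),
            class = c("de_result", "data.frame"),
            group_a = group_a, group_b = group_b,
            fdr_cut = 0.05, log2fc_cut = 1, cpm_cut = 0.2)
}

# independent Benjamini-Hochberg step-up oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  adj[order(o)]
}

# brute-force log-space hypergeometric upper tail P(X >= o)
hyper_tail_oracle <- function(o, k_a, k_b, n) {
  j <- o:min(k_a, k_b)
  sum(exp(lchoose(k_a, j) + lchoose(n - k_a, k_b - j) - lchoose(n, k_b)))
}

# a reduced but complete pipeline configuration for fast end-to-end tests
small_run_config <- function(seed = 1L) {
  cfg <- default_run_config(seed)
  cfg$counts$n_genes <- 3000L
  cfg$counts$planted <- list(
    internal_up = list(genes = 1:60, log2fc = 2, groups = "internal"),
    external_up = list(genes = 61:120, log2fc = 2, groups = "external"),
    up_3d = list(genes = 121:150, log2fc = 2, groups = "3D"),
    dn_3d = list(genes = 151:180, log2fc = -2, groups = "3D"))
  cfg$counts$n_enriched <- 300L
  cfg$reference_sets$n_background <- 50L
  cfg$x_grid <- c(0.01, 0.05, 0.10)
  cfg$optics <- list(taus = c(0, 0.9), n_per_dose = 2L, image_side = 64L,
                     n_slices = 9L, disk_radius = 20, noise_model = "poisson")
  cfg
}
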