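# lensoid

Quantitative analysis of lens organoids: light-focusing optics from
spheroid z-stacks, and transcriptome comparisons against lens references.

Lens organoids are self-organized 3-D cultures of lens epithelial cells
that turn transparent and focus light, and whose layers adopt
epithelium-like and fiber-cell-like expression programs. Characterizing
them — and using them as a cataract model — rests on a small set of
quantitative readouts, which this package implements as tested, seeded,
reusable components:

* **Focal-ratio optics.** For every slice of a z-stack, the focal ratio
  R(z) = max intensity over the spheroid centre / mean background intensity
  around it. A focusing organoid shows R(z) ≫ 1 at a z below the focus; an
  opacified one stays near 1. Automatic ROI placement (Otsu segmentation),
  peak summaries, and per-condition dose-response comparisons with a
  Spearman trend statistic.
* **Negative-binomial differential expression.** A self-contained NB Wald
  test: CPM filter (> 0.2), median-of-ratios size factors, moment-based
  common dispersion, Wald statistic
  W = (ln μ̂_A − ln μ̂_B) / √(Σ_j (1/μ̂_j + α̂)/n_j), BH FDR, and calls at
  FDR < 0.05 (or 0.01) with |log2FC| > 1.
* **Enrichment overlap sweeps.** Genes ranked by tissue enrichment
  e_g = log2((m_target + c)/(m_ref + c)); the top-x% sets of two rankings
  compared over x ∈ (0, 10%] against the chance expectation E = K²/N with
  exact hypergeometric tail p-values (both P(X > O) and P(X ≥ O)
  conventions).
* **Regional concordance.** Regional DEGs cross-tabulated against exclusive
  fiber-cell / lens-epithelium reference sets; Pearson 2×2 chi-squared
  χ² = n(ad − bc)² / ((a+b)(c+d)(a+c)(b+d)) with expected counts row·col/n
  and optional Yates correction; fold-change overlays with a rank test.
* **Synthetic generators.** Seeded z-stacks under a flux-conserving
  defocus-cone model with an opacity knob τ (amplitude
  A(z) = F(1−τ)/(2πσ(z)²), σ(z) = σ₀ + s·|z − z_f|), and grouped NB count
  matrices with planted fold changes and planted cross-dataset enrichment —
  every downstream claim is validated against planted ground truth.

## Worked example

```r
library(lensoid)

# a transparent organoid: simulate a z-stack and measure its focal curve
cfg <- stack_sim_config(opacity_tau = 0, noise_model = "poisson", seed = 8)
st  <- simulate_zstack(cfg)
focus_summary(focal_ratio_curve(st))
#> peak ratio 8.016 at z = -20 um (focusing, margin 0.20)

# the same organoid fully opacified ceases to focus light
cfg1 <- stack_sim_config(opacity_tau = 1, noise_model = "poisson", seed = 8)
focus_summary(focal_ratio_curve(simulate_zstack(cfg1)))
#> peak ratio 1.180 at z = -12.5 um (not focusing, margin 0.20)

# overlap of two top-decile enrichment sets: 198 shared genes between two
# 1032-gene sets from a 10,320-gene universe, against the chance null
hypergeom_overlap_pvalue(198, 1032, 1032, 10320, "greater")
#> [1] 8.73e-22

# association between DEG direction and reference identity
r <- chi_square_2x2(153, 37, 35, 143)
c(r$statistic, r$p_value)
#> 136.2  1.77e-31
```

The peak ratio of ~8 at z = −20 µm is the planted focal plane of the
simulated spheroid; full opacity (τ = 1) collapses the curve to noise
around 1, the optical signature of cataract induction. The hypergeometric
p-value says 198 shared genes is ~21 orders of magnitude beyond what two
independent 10% rankings would share (expected: 103.2). The chi-squared
example is a concordant regional table (internal-up genes mostly
fiber-cell-enriched, external-up mostly epithelium-enriched).

## The analysis workflow

Numbered drivers under `analysis/` run the full synthetic study over the
package, writing tables and figures to `results/`:

```sh
Rscript analysis/01_simulate_data.R        # counts + example z-stack (TIFF)
Rscript analysis/02_optics_focal_curves.R  # R(z) curves, opacity dose-response
Rscript analysis/03_differential_expression.R   # 3D vs 2D DEGs, volcano
Rscript analysis/04_enrichment_overlap.R   # rankings, overlap sweep, trajectories
Rscript analysis/05_regional_concordance.R # regional DEGs, 2x2 chi-squared
```

`run_pipeline()` performs the same stages programmatically with a manifest
(seed, configuration, MD5 per output); identical seeds give byte-identical
outputs.

## Documentation

The methods vignette (`vignettes/lens-organoid-analysis.Rmd`) documents the
optical model, the count model and test derivation, the tail conventions,
all tunable parameters with their defaults and rationale, and known
limitations of the synthetic validation.
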