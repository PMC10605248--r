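---
title: "Models and methods behind lensoid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lensoid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lensoid)
```

# Scope

Lens organoids — self-organized 3-D cultures of lens epithelial cells — are
characterized by two families of quantitative readouts: an optical one (do
they focus light, and how does opacity-inducing treatment abolish that?) and
a transcriptomic one (how do their expression programs relate to the lens —
enrichment over a whole-body reference, 2D-vs-3D culture differences, and
the epithelium/fiber identity of their internal and external layers?).
`lensoid` implements both families as reusable, seeded, fully testable
components, together with synthetic generators that emulate the statistical
and optical structure of the real data so that every stage can be validated
against planted ground truth without any external download.

This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic validation does and does not
establish about real data.

# The optical model and the focal-ratio readout

## Measurement

The measurement itself follows the published protocol: a z-stack is acquired
starting at the focus and lowering the objective; on every slice, the
maximum intensity in a square region over the spheroid centre is divided by
the mean intensity of the field around the spheroid, giving the focal ratio
$R(z)$. A transparent, lens-like spheroid produces $R(z)$ well above 1 at
some z below the focus; an opaque one stays near 1. `focal_ratio_curve()`
computes $R(z)$, `focus_summary()` extracts the peak (ties broken toward the
focus), and `compare_conditions()` aggregates organoids per condition
(mean ± sd of the peak ratio and of $R(z)$ per z) and reports a Spearman
trend of peak ratio against dose.

The ratio is oriented max(centre)/mean(background). Descriptions of this
assay sometimes state the ratio in the opposite orientation, but only
max/mean yields values "well above 1" for a focusing spheroid, so that is
the orientation implemented.

## ROI placement

The original protocol displays the two regions as squares but does not state
their sizes. `auto_roi()` therefore segments the spheroid (Otsu threshold,
largest connected component, hole filling, via EBImage) and places a centre
square of half-side 10% of the spheroid's equivalent radius at the centroid;
the background region is the image-border band (10% of the side) minus a
1.2× dilation of the spheroid. When segmentation finds nothing (a uniform
field), the centre of the image is used and the result is flagged. Both the
mean — not the median — background statistic and the max-in-centre statistic
follow the verbatim protocol.

## The synthetic stack generator

`simulate_zstack()` renders a geometric defocus cone, not wave optics: at
the focal plane $z_f$ the transmitted light is a 2-D Gaussian spot of width
$\sigma_0$ (pixels); away from it the width grows linearly,
$\sigma(z) = \sigma_0 + s\,|z - z_f|$, while total flux $F$ is conserved, so
the amplitude is $A(z) = F(1-\tau)/(2\pi\sigma(z)^2)$. This is deliberately
the simplest model that produces the qualitative behaviour the measurement
is designed to detect — a bright, tight spot at exactly one z — plus a
single opacity knob $\tau \in [0,1]$ entering as multiplicative flux
attenuation $(1-\tau)$, the simplest monotone link between treatment dose
and lost focusing. At $\tau = 1$ the stack is indistinguishable from a
spheroid that transmits no light.

Key defaults, chosen once as plausible for a 16-bit inverted-microscope
acquisition of a ~0.5 mm spheroid: 256×256 px, 25 slices over
$z \in [-50, 10]$ µm (2.5 µm step; the acquisition step of the original
stacks is unstated, so this is a free parameter), $z_f = -20$ µm (below the
focus, as observed for real organoids), background 500 counts, $F = 2\times
10^5$ counts, $\sigma_0 = 3$ px, cone slope 0.4 px/µm, Poisson shot noise.
These give a peak ratio around 8 at $\tau = 0$ — comfortably "well above 1"
— decaying to ~1.7 at $\tau = 0.9$ and exactly 1 at $\tau = 1$. Values are
quantized to unsigned 16-bit with clipping, matching camera output, and
written as multi-page TIFF with a JSON sidecar carrying the z-positions.

Numerical notes: with an even image side the spot centre falls between
pixels, so closed-form peak checks in the tests use odd sides; on a uniform
z-grid with an interior focal plane, pairs of slices tie exactly in
$|z - z_f|$, so monotonicity is asserted across unique distances. Flux
conservation holds within 2% (quantization plus truncation of the Gaussian
at the disk edge). The spheroid body itself is invisible by default
(`disk_gain = 0`, so a zero-flux stack is exactly flat background);
segmentation-oriented scenarios set `disk_gain > 0` to render a visible
disk.

The generator does **not** model: realistic point-spread functions,
refraction through a graded index, multiple spheroids per field, uneven
illumination, or camera fixed-pattern noise. Passing the optics tests
therefore shows that the measurement pipeline is correct and monotone in
opacity under an idealized lensing geometry — not that it is robust to every
artefact of real microscopy.

# The count model and the differential-expression test

## Generator

`simulate_counts()` draws gene baselines $q_g$ log-normal
(meanlog 3.9, sdlog 1.5 — giving a realistic CPM distribution in which only
a fraction of a percent of genes falls below the 0.2 CPM expression filter),
library sizes uniform on [1, 2] million reads, and counts
$\mathrm{NB}(\mu = s_i q_g 2^{\delta(g,\mathrm{group}(i))},\ \alpha)$ with a
single common dispersion $\alpha$ (default 0.1, typical for laboratory
RNA-seq; $\alpha = 0$ degenerates to Poisson). $\delta$ is the planted log2
fold (0 unless planted). The default design mirrors the typical
characterization experiment: 3 + 3
whole-culture 2D/3D samples, 4 internal + 3 external microdissected samples,
3 + 3 lens/whole-body (WB) reference samples, over a universe of 10,320
genes. A common dispersion (rather than per-gene) keeps moment-based
estimation well-posed at n = 3–4; per-gene heterogeneity of real data is a
recognized gap, which is why the test's calibration is also checked against
an independent NB implementation rather than only against the generator.

Cross-dataset enrichment is planted directly: two sets of 1032 genes (10% of
the universe) carry a +2 log2 fold in the "lens" and "3D" groups
respectively, sharing 20% of their members. The shared fraction is the
generator's stand-in for the real biological overlap between organoid and
lens enrichment; 0.2 was chosen once as a round value giving an overlap
curve comfortably above chance, of the same order as the published one, and
is not calibrated against any measured number.

## The test

Differential expression in this setting is conventionally run through
edgeR. Here the test is instead a fully specified, self-contained NB Wald
procedure, so that the computation is reproducible from this package alone
(edgeR serves as an independent cross-check in the test suite, never as the
implementation):

1. genes with mean CPM ≤ 0.2 across the contrast's samples are removed (the
   published filter; the aggregation rule — mean across all samples of the
   contrast — is this package's choice, the simplest symmetric reading);
2. counts are normalized by median-of-ratios size factors (geometric-mean
   reference over genes positive in all samples, factors rescaled to
   geometric mean 1; fallback to relative library size for degenerate
   input);
3. a common dispersion is estimated by moments: per gene, pooled
   within-group variance $\hat v$ and pooled mean $\hat m$ give
   $\hat\alpha_g = \max(0, (\hat v - \hat m)/\hat m^2)$, and $\hat\alpha$ is
   the **mean** of $\hat\alpha_g$ over well-expressed genes (pooled mean
   normalized count ≥ 5), floored at $10^{-8}$. Averaging over
   well-expressed genes matters: low-count genes' moment estimates are
   dominated by Poisson noise and truncated at zero, so a median over all
   genes is biased low (≈0.085 for a true 0.1 at n = 4 + 4), which makes the
   test anticonservative; the trimmed mean recovers the truth (≈0.100) and
   with it nominal type-I control;
4. the Wald statistic
   $W = (\ln\hat\mu_A - \ln\hat\mu_B)\,/\,\sqrt{\sum_j (1/\hat\mu_j + \hat\alpha)/n_j}$
   (the delta-method variance of a log NB mean) is referred to the standard
   normal, two-sided; a group mean of exactly zero is replaced by half a
   normalized count spread over the group, and genes at zero in both groups
   get p = 1 by convention;
5. Benjamini–Hochberg adjustment; a gene is called `up_A` iff
   `fdr < fdr_cut` and `log2fc > log2fc_cut` (symmetrically `up_B`), with
   `log2fc` computed from pseudocounted means, $\log_2((\hat\mu_A +
   0.5)/(\hat\mu_B + 0.5))$ — the 0.5 enters the fold change only, never the
   test.

Thresholds follow the published analysis: FDR < 0.05 with |log2FC| > 1 as
the general default, FDR < 0.01 for the headline 2D-vs-3D and regional DEG
counts; both are recorded on every result. Validation is by properties, not
by output-matching: near-uniform null p-values (KS < 0.03 on 10,320 null
genes at n = 4 + 4), null discovery fractions at nominal level, ≥ 90%
sensitivity with realized FDP ≤ 10% for 200 genes planted at |log2FC| = 2 on
well-expressed baselines, exact group-swap antisymmetry, and close agreement
with edgeR's classic common-dispersion exact test on planted data (log-FC
correlation > 0.98, matching call sets).

## Enrichment ranking

Lens-style enrichment is the log-ratio of mean CPM in a target tissue to a
whole-body reference, $e_g = \log_2((m_t + c)/(m_r + c))$ with pseudocount
$c = 1$ CPM (configurable) guarding the log at zero expression. Ranks are
deterministic: descending score, ties broken by gene id.

# Overlap sweeps and the hypergeometric null

`top_fraction_set()` takes the $\lfloor xN \rfloor$ top-ranked genes;
`overlap_sweep()` scans $x$ over (0, 10%] in 0.25% steps (the published
figure's axis range) and reports the observed overlap $O(x)$, the
independence expectation $E(x) = K^2/N$, and an exact hypergeometric tail
probability via `phyper` (the intersection of two independent uniform
subsets of sizes $K_a, K_b$ from $N$ is hypergeometric). Two tail
conventions are exposed: the default `"greater"` returns $P(X > O)$, which
reproduces the published p = 8.7 × 10⁻²² from the printed counts (198 of
1032 vs 1032 in 10,320); `"greater_or_equal"` returns $P(X \ge O)$ ≈
2.1 × 10⁻²¹. The identity $P(X \ge O) = P(X > O - 1)$ holds exactly and is
tested against subset-enumeration and log-space summation oracles. No
multiple-testing correction is applied across the sweep grid — each $x$ is
reported as a single test, as in the original figure.

`set_mean_trajectory()` computes per-set, per-stage mean ± sd over a
gene × stage table, the construction behind "mean expression of the 2D/3D
genes across lens development"; `simulate_stage_table()` provides a
synthetic stand-in for a developmental reference table.

# Regional concordance

`classify_degs()` cross-tabulates regional DEGs (internal-up vs external-up)
against exclusive reference identity sets (fiber-cell FC vs lens-epithelium
LEC), dropping genes present in both sets (the 2×2 design requires exclusive
identity; drops are reported) and excluding DEGs in neither.
`chi_square_2x2()` implements the closed form
$\chi^2 = n(ad-bc)^2/((a{+}b)(c{+}d)(a{+}c)(b{+}d))$ with expected counts
row·col/n — the bracketed numbers of a contingency-table figure — and an
optional Yates correction. The correction is **off** by default: published
regional-concordance results of this kind (p = 2.1 × 10⁻⁶) do not state
whether a correction was used and do not print the four observed cells, so
neither choice can be validated against them; the flag exposes both.
`fc_lec_overlay()` adds the per-gene identity overlay and a Wilcoxon rank
test between FC- and LEC-labelled fold changes.

The synthetic reference sets (`reference_identity_sets()`) are built from
planted truth: 80% of planted internal-up genes go to FC and the remainder
to LEC (symmetrically for external-up), topped up with unplanted background
genes. They are synthetic stand-ins, not the real E14.5 microdissection
lists, and the headline published numbers (793 DEGs, 378 concordant, the
exact p) are out of reach by design — reproducing them would require the
deposited organoid data plus the external reference dataset. What the
synthetic route establishes is that the classification and test machinery
detects planted concordance with high power and is calibrated under the
null.

# The pipeline and reproducibility

`run_pipeline()` executes the stages in dependency order — simulate counts;
2D-vs-3D DE; enrichment rankings and the overlap sweep; regional DE,
concordance and overlay; the optics dose-response (default: opacity doses
0/0.3/0.6/0.9, 12 organoids per dose, matching the published treatment
design) — writing every table as TSV plus a `manifest.json` recording the
seed, the full configuration, and an MD5 hash of every output. All
randomness derives from the single configured seed, and two runs with the
same configuration are byte-identical; a failing stage aborts with the stage
named, retaining partial outputs. The numbered scripts under `analysis/`
drive the same package functions one analysis at a time with a narrative
log; `scripts/acceptance.R` recomputes the headline quantities from scratch
into a single JSON.

Problem sizes in the tests and the acceptance script are the package's
choices for a fast, fully seeded validation: the full 10,320-gene universe
wherever a published count depends on it, n = 4 + 4 calibration designs, 20
seeds for recovery, 200 Monte-Carlo permutations for the overlap null, 12
organoids per optics dose at 128 px (129 px where a closed-form peak check
needs an on-pixel centre), and a 3,000-gene pipeline configuration for
byte-determinism tests.

# Known limitations

* The optical model is geometric; no refraction, PSF or scattering physics.
  Opacity is a single multiplicative attenuation, not a spatial pattern.
* The count generator uses one common dispersion and independent genes; no
  per-gene dispersion trends, gene–gene correlation, or composition effects.
* Enrichment of the real lens reference (iSyTE) comes from microarray data;
  cross-platform normalization differences are not modelled — reference
  scores are treated as given numbers.
* The published headline counts that depend on the deposited organoid data
  and external references (198-gene overlap list, 291/191 and 793 DEG
  counts, 378/793 concordance, p = 2.1 × 10⁻⁶) are demonstrated as
  *machinery* on planted data, not reproduced as numbers.
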