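---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoscape)
```

# What this package models

MALDI mass spectrometry imaging of enzymatically released carbohydrates
records, at every pixel of a tissue section, the intensities of sodiated
ions of two analyte families: linear glucose chains released from glycogen
by isoamylase (a "DP ladder" of chains with 3–14 hexose units, spaced by
exactly one hexose residue, 162.052824 Da) and N-linked glycans released by
PNGase F. glycoscape turns such a raster of centroided spectra into
cluster maps, enrichment tables, chain-length profiles, absolute glycogen
estimates, and supervised biomarker scores.

All mass arithmetic is composition-based:

$$M(\text{comp}) = \sum_i n_i m_i + m_{\mathrm{H_2O}}, \qquad
  m/z\,[\mathrm{M+Na}]^+ = M + m_{\mathrm{Na^+}}$$

with monoisotopic residue masses Hex 162.052824, HexNAc 203.079373, dHex
146.057909, NeuAc 291.095417 Da, water 18.010565 Da and the
electron-corrected sodium cation 22.989218 Da. Imaging features are named
by the **floor** (integer truncation) of the sodiated m/z. Truncation, not
rounding, is the convention that reproduces all printed feature labels
simultaneously — e.g. 1444.507 → 1444 and 1485.534 → 1485, where rounding
to nearest would fail.

Two deliberate subtleties of the mass layer:

* The lock-mass ion (default 1257.4296) is treated as a *user-supplied
  constant*, not a computed quantity: the conventional value sits about
  7 mDa above the theoretical sodiated Hex5HexNAc2 (1257.4226 by residue
  sum). For the same reason Hex5HexNAc2 is excluded from the default
  quantified panel — the lock ion is consumed by recalibration, never
  integrated as a feature.
* The 1175 m/z ion is only mass-consistent with a **7**-hexose chain
  (7 × 162.052824 + 18.010565 + 22.989218 = 1175.3696), although it is
  sometimes verbally labelled "glucose polymer 6" in vendor-style
  descriptions. `dp_ladder()` derives DP labels from the formula; users who
  prefer a different verbal convention can relabel panel entries.

# The processing chain

## Lock-mass recalibration

Slow mass-axis drift over the acquisition is corrected per *time bin*
(default 64 consecutive scan indices): within each bin the shift is the
**median** of (observed lock m/z − nominal lock m/z) over pixels whose lock
peak lies within the tolerance (1 Da) and exceeds the minimum intensity
(100,000 counts); the median is robust to lock-peak dropouts, which is why
it was chosen over the mean (no estimator is prescribed by common practice
descriptions). Pixels failing the intensity gate are still recalibrated by
their bin's estimate — nothing is dropped at this stage. Bins with no
qualifying pixel inherit the nearest bin's shift and are flagged in the
shift table.

## Panel integration and TIC normalization

Each panel target integrates centroid intensity within ±0.4 Da (full
window 0.8 Da, satisfying the "< 1 Da" convention while keeping
neighbouring DP rungs, 162 Da apart, strictly disjoint). The per-pixel
total ion current (TIC) is summed over the **entire** spectrum, not only
panel windows, because images are conventionally normalized to total ion
current; a panel-only TIC is a documented alternative the user can compute
from the raw matrix. TIC division makes everything downstream invariant to
per-pixel multiplicative gain; zero-TIC pixels are dropped with a count.

## Clustering and matrix removal

Pixels are clustered spatially agnostically: Euclidean k-nearest-neighbor
graph (k = 15) on log1p-transformed normalized rows, Leiden community
detection under modularity at resolution 1.0. Neither k, the resolution,
nor the transform is prescribed by the source workflow; the defaults follow
common practice for count-like features and are all exposed.

**Why there is a merge step.** Modularity optimization on a kNN graph
*deterministically* splits large homogeneous point clouds: a 15-regular
graph on several hundred interchangeable pixels has higher modularity when
cut in two. Measured on phantoms, the two halves of one homogeneous region
end up with centroids about 1.0 pooled within-RMS apart, while genuinely
distinct regions sit at 3.9 within-RMS and beyond. `cluster_pixels()`
therefore iteratively merges community pairs whose centroid separation is
at most `merge_factor` (default 2) times their pooled within-community RMS
spread. The default sits between the theoretical ceiling for an artificial
bisection of a single Gaussian cluster (the two half-means of a Gaussian
split along its widest axis separate by ≈ 1.6 σ of that axis) and the
separations real region signatures produce. `merge_factor = 0` disables
merging and returns the raw Leiden partition. Zero-spread (noiseless)
clusters merge only at exactly zero separation, so the noiseless phantom
yields exactly one cluster per region.

Matrix (CHCA) clusters are flagged *automatically* by signal fraction —
mean over member pixels of (matrix-class signal / total panel signal) ≥ 0.5
— rather than by visual inspection of an embedding, which is not
reproducible. After removal the default is to **recluster** the retained
pixels (matching the practice of re-plotting the partition after matrix
removal); `keep_labels` is available for comparability. The UMAP embedding
(uwot, spectral-PCA init, single-threaded SGD for determinism) is
visualization-only; no downstream stage consumes it.

## Enrichment statistics

Cluster markers are one-vs-rest two-sided Wilcoxon rank-sum tests. The
implementation uses the exact null distribution for untied samples up to 50
per group and the tie-corrected normal approximation with continuity
correction otherwise; constant features return p = 1. Benjamini–Hochberg
correction is applied across features *within each cluster* (no
multiple-testing procedure is prescribed for cluster markers; this is the
scanpy-style convention). Fold changes use a pseudo-count of half the
smallest nonzero value.

"Total glycogen" is defined as the per-pixel **sum over all glycogen DP
panel features** — an operational definition made explicit here because no
formal one exists. Chain-length profiles are per-group means ± SEM at each
DP. Group designs: Welch two-sample t; one-way ANOVA; two-way ANOVA with
interaction; post-hoc pairwise comparisons are Holm–Šidák adjusted (the
concrete reading of a generic "multiple comparisons test").

A caveat the user should understand: pixels within a tissue are spatially
autocorrelated, so pixel-level p-values overstate evidence. The package
also supports ROI-level analysis via `tile_samples()` (aggregate pure
tiles into pseudo-replicates) without endorsing either unit of replication.

## Quantitation

The standard curve regresses spot signal on spotted amount (1, 10, 20, 40,
100, 1000 ng) by ordinary least squares with an estimated intercept; a
through-origin slope is reported alongside. The linear range is the widest
contiguous amount span with relative residuals below 20%. Back-calculation
is `ng = (signal − intercept)/slope`, clipped at zero (clipped and
extrapolated pixels flagged, not dropped). Quantitation runs on **raw**
counts, not TIC-normalized values, because standards and tissue share one
acquisition; normalizing only one side would break the unit equivalence.
The quantified ion defaults to the DP 7 rung at nominal 1175 m/z, with
`feature = "dp_sum"` to use the summed ladder instead — both modes exist
because the convention is ambiguous.

## Biomarker scoring

Per-sample tables are normalized by `log10(x + pseudo)` then auto-scaling
(unit variance). PLS-DA is NIPALS PLS1 against a ±1-coded response
(dependency-light, exactly testable); VIP scores follow the standard
weights/explained-variance formula, so mean(VIP²) = 1 algebraically, and
features with VIP > 1.5 are selected. Univariate AUC is the normalized
Mann–Whitney U. The multivariate ROC honors "linear SVM" as an
L2-regularized linear margin classifier (closed-form ridge on ±1 labels):
at desk scale the AUC depends only weakly on hinge vs squared loss, and
determinism and testability win. Cross-validation is 50 Monte-Carlo
repeats with a stratified 1/3 holdout; per-repeat feature ranking by
absolute weight precedes refitting on the top k, and the AUC is summarized
by its mean with a percentile interval.

# The phantom: what it emulates, what it does not

The generator draws, per pixel and panel feature, intensity
`mean × LN(1, cv)` — multiplicative lognormal noise with unit expectation —
at `theoretical m/z + drift(scan index)`. The multiplicative model makes
MSI-like heteroscedastic noise with a directly interpretable CV and an
exact noiseless limit. Drift (constant, linear or sinusoidal; bounded by
the amplitude) displaces *observed m/z only*, so recalibration is the
stage under test, and the amplitude must stay below the 1 Da lock
tolerance.

Stated-world defaults, chosen once: 40×40 grid with a 4-pixel off-tissue
border; matrix cluster ions at 5×10⁴ counts off-tissue with a 1%
carbohydrate bleed-through (capped at 2%) so matrix-cluster detection is
non-trivial; on-tissue residual matrix signal 200 counts (tissue matrix
fraction ≈ 0.04); a DP 3–14 ladder with Gaussian chain-length profile
centred at DP 8 (σ = 2.5 DP) totalling 3×10⁴ counts; N-glycans at 4×10³
counts; a fibrotic ellipse whose glycogen features are scaled 2.4-fold and
whose fucosylated (dHex-containing) N-glycans are scaled 3-fold; noise
cv 0.2; sinusoidal drift of 0.2 Da over the run; a lock ion at 2×10⁵
counts in every pixel. Calibration spots render as square ROIs whose DP 7
rung responds at `amount × slope` counts/pixel (default 50 counts/ng).

The phantom does **not** simulate isotope envelopes, profile peak shapes,
ion-mobility separation, spatial intensity gradients within a region, or
ion suppression between spot and tissue surfaces. A green test on the
phantom therefore establishes that the *computational* chain is correct
and calibrated — not that any instrumental effect beyond drift and
multiplicative noise is handled.

# Numerical and reproducibility choices

* Exact ties in label coding break by smallest member pixel id; heatmap
  ordering ties fall back to label order; both make outputs independent of
  pixel order.
* All stochastic stages take explicit seeds; the pipeline fans a single
  global seed into fixed per-stage seeds (kept below 2³¹), so any stage is
  independently reproducible.
* A full pipeline run with the same config and seed is bit-identical
  across runs in every artifact except `manifest.json`, which records
  wall-clock timings.
* The imzML pair uses a deterministic content digest as its UUID so that
  identical datasets write identical bytes; a UUID mismatch between the
  XML and binary part is reported as an ibd checksum error.
* m/z arrays are stored as 64-bit floats (lossless round trip);
  intensities as 32-bit floats, the common encoding, so intensity
  round-trips are exact only to float32.

# Known limitations

* The default peak panel is a reconstruction (DP 3–14, 13 canonical
  N-glycan compositions, 18 CHCA cluster ions), not the original curated
  50 + 155 list, which is not public in tabular form; panels are
  user-replaceable via TSV.
* No profile-mode centroiding, baseline subtraction, or vendor raw
  formats; conversion is upstream.
* Pixel-level inference ignores spatial autocorrelation (see above).
* Matrix-cluster flagging assumes the panel's matrix-class entries capture
  the matrix chemistry; exotic matrices need a custom panel.
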