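---
title: "Methods: quantifying covalent SEGRA pharmacology on synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying covalent SEGRA pharmacology on synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and numerical choices
behind `segraquant`. The package quantifies the assay battery used to
characterize covalent selective glucocorticoid receptor (GR) agonists:
translocation imaging, reporter-gene statistics, competition binding,
coregulator peptide-array profiling, and in-silico covalent-adduct mass
mapping. Every stage is exercised on synthetic data with known ground
truth; what that does and does not demonstrate is discussed at the end.

## The synthetic-data generators

The generators define the study conditions under which every downstream
claim is tested; their defaults are fixed once and shared by the tests,
the analysis drivers and the acceptance script.

**Images.** Cells are disc nuclei with a concentric annular cytoplasm —
the simplest geometry with an exact analytic N/C ground truth. Defaults:
256×256 px grid, 20 cells, nuclear radius uniform in 8–12 px, annulus
width 5 px, nuclear-channel background 100 AU and nuclear level 1000 AU,
GR annulus level 200 AU with the nuclear GR level set to
`nc_ratio_true × 200` so the pre-noise N/C ratio is exact by
construction. Pixel noise is additive Gaussian with
`sd = noise_cv × local mean` (clamped at zero), matching photon-noise
character without extra parameters; the default CV is 5%. A configurable
fraction of cells (default 0.2) is placed as overlapping pairs to
exercise watershed splitting; unrelated cells are placed by rejection
sampling with annuli kept disjoint, and placement failure within a retry
budget is an error. The imaging assay this emulates gives no cell
morphology or staining statistics to calibrate against, so these are
declared, realistic choices for cultured epithelial cells at ~20×–40×
magnification — not fits to any real image set.

**Luminescence and arrays.** Reporter wells and array spots draw
multiplicative lognormal noise parameterized by a coefficient of
variation (`meanlog` adjusted so the mean is exact); a CV of 5% is
typical of replicate luciferase wells. Displacement curves are
four-parameter logistic with multiplicative noise. Synthetic proteins
carry K/R and C residues exactly at requested positions, making the
cleavage structure of every digestion fixture fully known.

## Translocation imaging pipeline

Processing order: contrast enhancement → Gaussian smoothing → isodata
threshold → conditional watershed → Voronoi-restrained rings →
measurement. Enhancement and smoothing serve *segmentation only*;
per-cell intensities are always measured on the raw GR channel, since
any nonlinear enhancement would distort the ratio being estimated.

- **CLAHE** (tile ~32 px, clip limit 2, via EBImage) flattens
  illumination heterogeneity; output is clamped to [0, 1].
- **Gaussian smoothing** (σ = 2 px default) is an explicit separable
  convolution with reflecting boundary, so the kernel contract
  (normalization, impulse response) is exactly testable.
- **Isodata threshold** iterates the Ridler–Calvard fixed point from the
  global mean. The convergence tolerance defaults to 1/65536 of the
  dynamic range rather than an absolute half intensity unit, so the same
  code serves unit-scaled enhanced images and integer-scaled raw ones;
  exact fixed points are unaffected. Constant images are an error.
- **Conditional watershed**: connected components of the thresholded
  mask are split by nearest-seed assignment, with seeds at
  distance-transform maxima. Seed candidates are taken one per basin of
  a tolerance-merged watershed of the distance map (depth tolerance 1 px)
  so that shallow ridge maxima do not spawn seeds, then greedily
  suppressed to a minimum separation (default 5 px, deeper seed wins,
  ties to the lowest pixel index). The *conditional* rule: a split is
  accepted only if every fragment has area ≥ `min_area` (default 50 px);
  otherwise the component keeps one label. Undersized objects are
  discarded. The acceptance condition is defined here explicitly, as a
  design choice of this package.
- **Voronoi rings**: ring k is the set of non-nuclear pixels within
  `band_width` (default 5 px, matching the generator's annulus) of
  nucleus k, restricted to pixels whose nearest nucleus is k. Distances
  are exact Euclidean distance transforms per label; ties go to the
  lowest label. This is verified pixel-exactly against brute-force
  nearest-nucleus search in the tests.
- **Border cells** are excluded by default: their rings are truncated
  asymmetrically and would bias the cytoplasmic mean.
- **Summaries** report per-cell statistics with Welch t-tests against
  the control treatment; the analysis driver additionally reports
  per-image medians, since whether the per-cell or per-image unit is the
  replicate is a genuinely open convention — both are written out.

## Reporter statistics

Induction factors divide the treated mean by the control mean
(optionally protein-normalized per well); the SD is the spread of
per-replicate treated/control-mean ratios. Percent transrepression is
baseline-corrected by default — the solvent level is defined as IF = 1,
so the repressible signal is `IF − 1`:
`100 (1 − (IF_cmp − 1)/(IF_TNF − 1))`. The uncorrected convention
`100 (1 − IF_cmp/IF_TNF)` is also computed; at ~100-fold induction the
two differ by well under a percentage point, so either is consistent
with a reported "approximately 95%" repression, and the corrected form
is primary because it respects the IF ≡ 1 baseline definition. Values
outside [0, 100] are reported, never clipped.

ΔΔCt expression uses triplicate *medians* (robust to a single aberrant
well), GAPDH-style housekeeping normalization, and 100% amplification
efficiency (factor 2 per cycle) — no efficiency correction is applied
because none is defined for these assays.

Many-to-one comparisons use the one-way ANOVA F decomposition plus a
permutation max-|t| adjustment: pooled-MSE t statistics of each group
versus control, with group labels permuted (default 999–1999 draws,
seedable) and each observed |t| referred to the permutation distribution
of the maximum. This controls the familywise error like Dunnett's test
while avoiding its multivariate-t tables; the null familywise rejection
rate is verified by simulation in the tests (1000 runs, 199 permutations,
margin 2 Monte-Carlo standard errors).

## Competition binding

The 4PL fit parameterizes IC50 on the log10 scale, multi-starts it
across the sampled concentration range (8 starts), bounds the Hill slope
to [0.3, 5] to stabilize sparse curves, and keeps the best
residual-sum-of-squares solution; flat curves and universal
non-convergence are errors. The fit is scale-equivariant in
concentration, so units only need to be consistent. The Cheng–Prusoff
conversion `Ki = IC50/(1 + L/Kd)` defaults to L = 1.5 nM and Kd = 1.5 nM:
the radioligand concentration is an assay constant, and taking Kd equal
to it is the single assumption under which every tabulated (IC50, Ki)
pair of the reference competition assay is reproduced (Ki = IC50/2). It
is recorded as an overridable assumption, not a measurement. Reported Ki
values round halves *up* at two significant figures
(`signif_half_up`), the convention of the assay tables; R's default
round-half-even would turn 3.65 into 3.6.

## Coregulator profiling

Net intensity is spot minus local background, floored at ε = 1 AU
(configurable) so log-ratios stay defined; flooring is counted and
all-floored cells are flagged unreliable. The modulation index is
log10(mean ligand / mean solvent): replicates are aggregated by mean
*before* the ratio, matching a signal-then-modulation quantification
order, and base 10 is chosen so MI = ±1 means a 10-fold change — the
"log-fold modulation" reading of the index. Per-peptide significance is
a pooled-variance Student t-test.

Clustering is agglomerative Ward on Euclidean distances via the
Lance–Williams recurrence on squared dissimilarities (heights on the
distance scale, the `ward.D2` convention), with ties broken by the
lowest pair index. The implementation is cross-checked two ways: against
`stats::hclust(method = "ward.D2")` on random data, and against an
exhaustive greedy oracle that recomputes the within-cluster
sum-of-squares increase of every candidate merge at every step.

## Digestion and covalent-adduct mapping

Cleavage is after K/R; the C-terminal residue never yields a site. The
default allows cleavage when K/R precedes proline — the rule used by the
covalent-adduct search this reproduces — with classic no-P trypsin as a
toggle. With `s` internal sites and one missed cleavage allowed, the
digest has `(s+1) + s` peptides; this is verified against exhaustive
span enumeration. Monoisotopic masses use the standard residue table
plus one water; no fixed cysteine modification is applied (reduction
without alkylation). Adduct candidates follow variable-modification
semantics (0..k modified cysteines per peptide, k = cysteine count);
precursor matching uses a relative 10 ppm window. Peptide coordinates
carry a `numbering_offset` so expression constructs report full-length
receptor positions; the covalent-site assignment test uses a synthetic
surrogate construct (residues 524–777 with a lone cysteine at 622 inside
a tryptic peptide spanning 615–633) because the real receptor sequence
is an external download, not bundled data.

## Problem sizes and determinism

Default verification sizes — 256×256 px images with 20 cells, 10 seeds
per condition for ratio recovery, 100 simulated curves for IC50
recovery, 200 simulations for the transrepression estimate, 1000 null
runs for the familywise-error check — were chosen so the full suite
completes in about a minute on a laptop core while leaving Monte-Carlo
margins comfortably inside the tested tolerances. All stochastic
functions take explicit seeds and restore the RNG state, so runs are
bit-reproducible and order-independent.

## Limitations

The image generator emulates intensity structure (bright nuclei, dimmer
cytoplasmic halo, additive noise) but not optics: no point-spread
function, no 3-D sectioning, no spectral bleed-through, no textured
chromatin. Passing its tests shows the *quantification* is correct under
the declared geometry and noise model — not that segmentation would be
robust on arbitrary real micrographs. The transrepression and Ki
computations are exact arithmetic on estimated quantities; their
accuracy on real data is bounded by the assay noise, not by this code.
The peptide-array model treats motifs as labels with fold-change
effects; no binding kinetics or sequence information is modeled. The
digestion module does no spectral scoring or FDR control — it enumerates
candidates for precursor-mass matching only, and covalent ligand mass
shifts are user-supplied constants.
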