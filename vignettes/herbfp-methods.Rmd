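---
title: "Methods: fingerprinting, chemometrics and single-marker quantification in herbfp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprinting, chemometrics and single-marker quantification in herbfp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbfp)
```

# The problem

Herbal materials such as Allii Macrostemonis Bulbus (AMB, the bulb of
*Allium macrostemon*) are complex mixtures whose quality depends on
geographic origin and post-harvest processing. The standard quality-control
strategy combines three layers:

1. a **chromatographic fingerprint** — the pattern of common peaks shared by
   all batches of the material, scored against an averaged reference
   profile by a similarity coefficient;
2. **chemometrics** on the common-peak area matrix — PCA and hierarchical
   clustering to reveal batch groupings, and OPLS-DA with VIP scores to
   nominate the peaks that drive them; and
3. **quantification** of marker constituents, either by each analyte's own
   calibration curve (the external standard method, ESM) or by the
   single-marker QAMS route, which prices every analyte off one
   well-characterized internal reference via relative correction factors
   (RCFs).

herbfp implements all three layers plus a synthetic-data generator, so that
every stage can be exercised, validated and regression-tested without any
instrument data.

# Signal model of the generator

A chromatogram is simulated as

$$ y(t) = \sum_k A_k\, \phi(t; \mathrm{rt}_k + \delta + \epsilon_k,
\sigma_k) + b(t) + e(t), $$

where $\phi$ is a unit-area Gaussian (an exponentially modified Gaussian is
available for tailing studies via `shape = "emg"`), $A_k = \max(s_k C_k +
i_k, 0)$ is the ideal ELSD response of constituent $k$ at concentration
$C_k$ — the published regression lines of the six identified analytes are
the defaults (`amb_reference_curves()`) — $\delta$ is a per-batch retention
shift, $\epsilon_k$ a per-peak jitter, $b(t)$ a low-order baseline and
$e(t)$ white detector noise. Areas receive multiplicative log-normal noise
of coefficient of variation `area_noise_cv`.

A linear response is the default because the reference calibration data are
linear fits; ELSD response is classically a power law $A = aC^b$, and the
simulator's linear mode should be read as "local linearity over the
validated range", which is exactly what the downstream quantification
assumes anyway.

## The default panel: the stated world

`panel_config()` encodes an 18-batch panel in three groups: six southern
batches, four northern directly dried batches, and eight northern
freeze/post-steaming dried batches (layout in `amb_batch_layout()`). Two
disjoint constituent subsets carry multiplicative group effects:

* `origin_peaks` (six unnamed peaks) at `origin_effect = 2.5` in southern
  batches;
* `processing_peaks` (the three macrostemonosides A, T, U plus two unnamed
  peaks) at `processing_effect = 2.5` in the northern directly dried
  batches.

The 2.5-fold effects were chosen once, as the smallest round value
comfortably above the 2-fold floor needed for unsupervised clustering to
separate the three groups; noise defaults (`area_noise_cv = 0.01`,
`rt_shift_sd = 0.02` min, `rt_jitter_sd = 0.005` min) reflect a
well-behaved, temperature-controlled HPLC run. Each batch also receives two
batch-specific extra peaks at batch-unique positions, so common-peak
matching has something nontrivial to exclude.

The elution layout mirrors the reference fingerprint's numbering: adenosine
and syringin elute first (peaks 1–2), nineteen unnamed peaks fill the
window up to macrostemonoside T (peak 22), three sit between T and
macrostemonoside A (peak 26), macrostemonosides U and V follow (27–28), and
two late peaks close the run. Retention times of T and U are placed so
their relative retention times versus A are 0.9394 and 1.0098, the
published localization constants. Because the six identified markers
bracket nearly the whole run, marker-anchored retention correction is
interpolation rather than long extrapolation — with markers clustered early
this design would degrade quickly, which is worth knowing when modelling
other materials.

What a green test on this panel does *not* establish: real chromatograms
have drifting baselines with structure the morphological opening may track
imperfectly, tailing and co-eluting peaks that a perpendicular-drop split
biases, and batch effects far less tidy than two clean fold-changes on
disjoint subsets. The panel is a correctness harness, not an instrument
emulator; the reproduced quantities from the reference study (RD
arithmetic, LOD/LOQ scaling, RCF bands, durability RSDs) are the points of
contact with reality.

# Peak processing

Detection operates on the Savitzky–Golay-smoothed (window 11, order 3)
signal minus a morphological baseline (rolling-minimum opening, half-window
one minute, lightly mean-filtered). Peaks are local maxima with prominence
and height at least `min_snr` (default 5) times the noise sd, estimated
when not supplied as $\mathrm{mad}(\Delta y)/\sqrt2$. A relative height
floor (`min_rel_height = 1e-3` of the signal maximum) suppresses
smoothing/baseline ripple on effectively noiseless traces — without it, a
zero-noise simulation "detects" the numerical texture of the baseline
estimate. Bounds go at the valley minimum toward each retained neighbour
(perpendicular drop; no deconvolution) or at the near-baseline crossing,
whichever is nearer the apex; areas are trapezoids of the raw
baseline-subtracted signal, so detected areas on noiseless panels match the
seeded responses to well under 1%.

S/N is defined as baseline-corrected height over noise sd — one of several
conventions in use; the source material states none. LOD and LOQ follow the
3× and 10× signal-to-noise definition computed from calibration
sensitivity and measured noise (`lod_loq()`), hence LOQ/LOD = 10/3 exactly.
Two of the six published analyte rows (adenosine, syringin) violate that
identity in the last printed digit; we treat this as rounding of the LOD
before publication, and the acceptance test asserts the identity within
±0.02 for those rows rather than exactly.

# Fingerprint construction

Retention correction is marker-anchored piecewise-linear warping
(`correct_retention_times()`): identified marker apexes map exactly onto
the reference batch's marker times, other times interpolate linearly, and
times beyond the terminal markers extrapolate with the terminal segment
slopes. The published workflow names the procedure ("multipoint correction
and mark peak matching") but not the algorithm; piecewise-linear warping is
the standard realization and is exactly invertible for a pure shift.

Matching (`match_common_peaks()`) is one-pass greedy nearest-apex within a
±0.1 min window — the window the reference workflow states — taking
candidate pairs in order of increasing time difference, each peak used at
most once, ties broken toward the earlier apex. An optimal bipartite
assignment would differ only in pathological tie structures and is out of
scope. Reference peaks matched in every batch form the common set; the
averaged fingerprint is the per-peak arithmetic mean.

Similarity is the cosine (congruence) coefficient on the common-peak area
vectors. The 2012-era reference software's internals are unpublished;
whether it scores raw curves or peak vectors is unknown, so a full-curve
variant (`curve_similarity()`, `similarity_on = "curve"`) is provided and
the method used is recorded in the output. Reproducing the reference
study's printed similarity values is explicitly not a goal — they depend on
chromatograms that were never deposited.

# Chemometrics

Scaling defaults to unit variance (the vendor software's default; the
source is silent); `center`, `pareto` and `none` are available and the
choice is recorded. PCA is SVD-based with explained fractions
$d_i^2/\sum d^2$; its Q² uses row-wise 7-fold cross-validation
(reconstruction of held-out rows from training loadings). Vendor PCA Q²
commonly uses element-wise EM-style deletion; our scheme is cheaper,
labelled in the output, and should not be compared numerically against
vendor values.

HCA uses squared Euclidean distances — the distance the reference analysis
names — with Ward linkage (the reference names no linkage; average linkage
by flag). When no cluster count is given, k is selected by maximal mean
silhouette width over 2–6.

OPLS-DA is the standard sequence: for each orthogonal component,
$w \propto X'y$, $t = Xw$, $p = X't/t't$, $w_o \propto p - (w'p/w'w)w$,
deflate $X$ by $t_o p_o'$; then one predictive component on the filtered
matrix. Q² comes from 7-fold CV with round-robin fold assignment by row
order (deterministic; the vendor's assignment rule is unpublished) and
per-fold recentering. VIP is computed over the predictive component, so
$\mathrm{mean(VIP^2)} = 1$ holds as an algebraic identity and is asserted
on every fit. Permutation validation refits on permuted labels, regresses
R²Y and Q² on the absolute correlation with the original response
(original model included at |corr| = 1, matching the vendor plot), and
calls the model valid when the Q² intercept is negative and the original
statistics exceed 95% of the permuted ones. Multi-class OPLS-DA is out of
scope; contrasts are configurable two-group comparisons (default: southern
vs northern origin).

# Quantification

`compute_rcf()` implements
$\mathrm{RCF} = (A_s/C_s)/(A_i/C_i) = A_s C_i / (A_i C_s)$, the response
ratio of internal reference to analyte. The formula as printed in the
source ("$A_s A_i/(A_i C_s)$") is dimensionally inconsistent — it cancels
to $A_s/C_s$ — so the standard form above is used; computed over the
published calibration ranges it reproduces the published RCFs to within
0.9% (T, 2.583 vs 2.56) and 2.3% (U, 1.699 vs 1.74), inside the 2–3%
bands expected given that the exact level concentrations behind the
published means were not reported. Levels are paired by index in the
dilution series, and the RSD across levels is the dispersion statistic.

QAMS inverts the definition: $C_i = \mathrm{RCF} \cdot A_i C_s / A_s$, with
$C_s$ taken from the internal reference's own external-standard curve — the
workflow in which the internal reference's ESM content is tabulated
alongside the QAMS results. With the default 2.00 g sample mass and 2 mL
extract volume, content in µg/g numerically equals extract concentration
in µg/mL. On noiseless intercept-free responses QAMS equals ESM to
numerical precision; with the published intercepts the two differ by under
1% over the validated ranges — the intercept is the sole source of
discrepancy, mirroring the sub-1.2% relative deviations of the reference
content table. Relative deviations are rounded half-away-from-zero to two
decimals, the table-formatting convention, under which all 36 published
cells reproduce exactly.

`durability_study()` perturbs instrument factors (column, flow rate,
temperature, injection volume; three levels each) as per-condition
multiplicative response scales applied equally to all analytes, with 1%
area noise, and reports the RSD of the recomputed RCF across each factor's
levels against the 2.0% bound. Because a common response scale cancels in
the RCF, this design verifies the ratio-invariance that makes QAMS robust:
retention-only or common-bias perturbations leave the RCF exactly
unchanged, and noise alone sets the RSD floor.

# Pipeline, determinism, degenerate inputs

`run_pipeline()` chains the stages on either a simulated panel or a
manifest of chromatogram CSVs and writes the report tables (similarity,
validation, RCF/durability, ESM/QAMS/RD, scores, VIPs, clusters, a Newick
dendrogram) plus `manifest.json` recording configuration, seed and
package version. One global seed is expanded into per-stage seeds by a
fixed affine counter, so stages are independently reproducible; two runs
with the same configuration produce byte-identical tables, and a files-mode
rerun on exported chromatograms reproduces the synthetic run's tables to
round-trip precision.

Numerical/degenerate-input decisions worth knowing:

* zero or negative ideal response floors at zero (a constituent can be
  "absent");
* all-flat traces detect zero peaks (not an error); empty peak lists abort
  matching unless `allow_missing = TRUE`;
* zero-variance columns are an error under uv/pareto scaling, named;
* calibration with a single distinct concentration is rejected as
  degenerate; back-calculated negative concentrations clip to zero with a
  warning; contents outside the validated range are flagged
  `extrapolated`, not rejected;
* Rt-based localization fails loudly, naming the nearest candidate, when
  no peak sits within the (default 0.5%) tolerance, which brackets the
  published Rt dispersions of 0.18%/0.15%.

# Known limitations

No curve deconvolution of fused peaks, no mass-spectral dimension, no
weighted or robust calibration, no multi-reference QAMS, no modelling of
gradient programs or drift-tube physics (acquisition conditions are
carried as free-text metadata only). The printed whole-study statistics of
the reference analysis (similarity table, PCA/OPLS-DA variance fractions,
the 13-marker VIP list) are not reproduction targets: they derive from
undeposited chromatograms, and the package's claims about them are limited
to the structural properties the synthetic panel can check.
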