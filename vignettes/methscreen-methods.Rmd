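---
title: "Methods: integrative methylome-transcriptome screening and assay quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative methylome-transcriptome screening and assay quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methscreen)
```

# Scope and rationale

Tumor suppressor genes are frequently inactivated not by mutation but by
promoter hypermethylation. `methscreen` implements the computational
skeleton of such a discovery effort on a breast-cancer-style design: given
a gene x sample expression matrix and a CpG-probe x sample methylation
matrix over the same tumor/normal cohort, it calls differential expression
and differential methylation, screens for genes that are simultaneously
hypermethylated and down-expressed, intersects the candidate lists of two
independent cohorts, and follows candidates up with diagnostic ROC curves,
best-cutoff survival dichotomization, and quantitative microscopy readouts
(per-cell lipid-droplet counting, stained-area fractions) of the
downstream functional assays.

Everything is exercisable without external data: a synthetic-data module
generates cohorts, survival tables and microscopy scenes with known ground
truth, and the test suite validates each stage against independent
brute-force oracles and against that planted truth.

# Differential methylation

Methylation arrives as beta values (methylated fraction in [0,1], one CpG
probe per row). Testing happens on the M-value scale,
$M = \log_2\!\frac{\beta}{1-\beta}$, which stabilizes variance near the
boundaries; betas are clipped to $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 10^{-6}$ first so boundary values stay finite
(`beta_to_m()`, inverse `m_to_beta()`). Gene-level methylation is the
arithmetic mean beta over a gene's probes (`aggregate_gene()`); a
per-region profile over the Infinium relation-to-island classes (island,
N/S shore, N/S shelf, open sea) is available via `region_methylation()`.

The per-unit test (`dm_test()`) is a two-sided Wilcoxon–Mann–Whitney
rank-sum comparison of tumor versus normal samples. The exact null
distribution is used when the smaller group has at most 8 samples and the
pooled values are tie-free; otherwise the normal approximation with tie
correction and a 0.5 continuity correction applies. The reported effect is
the mean M-value difference (tumor − normal), which is itself a log2 fold
change of the methylated/unmethylated ratio. Benjamini–Hochberg q-values
are attached, and `call_dm()` applies the inclusive dual thresholds
$p \le 0.05$ and $|\Delta M| \ge 0.5$ at gene level. At probe/island level
the fold-change cut of 1.45 is interpreted on the methylated/unmethylated
ratio scale, i.e. $|\Delta M| \ge \log_2 1.45$; the scale of that
threshold is genuinely ambiguous in the source material, and this reading
was chosen because the testing already happens on the M scale — it is the
one deliberate interpretation in this module, and per-unit p-values from a
rank test will in any case not numerically match a moderated-t pipeline.
Probes with missing values are dropped rather than imputed.

# Differential expression

Counts are normalized to FPKM
($c \cdot 10^9 / (\ell \cdot N_j)$), TPM (length-normalized rates scaled
to $10^6$ per sample) or $\log_2(\mathrm{FPKM} + 10^{-4})$
(`normalize_counts()`). The test (`de_test()`) is the same rank-sum
machinery applied to TPM; because rank tests are invariant to monotone
per-gene rescaling, the choice of unit does not affect p-values. The
effect is $\log_2\frac{\bar{x}_{tumor}+c}{\bar{x}_{normal}+c}$ with
pseudocount $c = 10^{-4}$, the same constant as the log transform.
`call_de()` applies $p \le 0.05$, $|\mathrm{log_2FC}| \ge 1$, inclusive.
Dispersion-based count models (DESeq2-style shrinkage) are deliberately
out of scope; the rank test trades power for distribution-freeness.

# The integrative screen

`screen_cohort()` joins DE and DM records by gene and assigns a quadrant
(hyper/hypo x up/down) to every gene significant on both sides. A *hit*
is a gene in the hyper-down quadrant: $p_{DE} \le 0.05$,
$\mathrm{log_2FC}_{DE} \le -1$, $p_{DM} \le 0.05$,
$\Delta M \ge 0.5$. The expression threshold is applied as
$\le -1$: the screen targets *down*-expressed genes, so the cut is on the
negative side even though summary texts often quote the magnitude.
Raw p-values are thresholded (mirroring the printed cut-offs); q-values
remain in the records for stricter filtering. `intersect_cohorts()`
produces the two-cohort Venn and the shared candidate list — the analogue
of the 34-gene candidate tumor-suppressor list this design yields on real
discovery + TCGA cohorts.

Follow-up utilities: `correlate()` (Pearson product-moment with
t-distribution p on $n-2$ df; Spearman as Pearson on average ranks with
the same p machinery — deliberately one consistent approximation rather
than the exact small-n Spearman null), and `ora()`, a one-sided
hypergeometric over-representation test against user-supplied GMT gene
sets (`read_gmt()`), BH-adjusted, significant at raw $p < 0.05$. No
ontology databases are bundled.

# Diagnostics and survival

`roc()` builds the ROC curve by sweeping thresholds over the unique
marker values (ties grouped), from (0,0) to (1,1), and integrates by
trapezoid. Orientation must be stated — for a silenced suppressor, *low*
marker marks the tumor class — or `"auto"` picks the orientation with
AUC ≥ 0.5 and records the choice. `auc_mannwhitney()` computes the same
quantity as a tie-corrected rank statistic,
$(U + \mathrm{ties}/2)/(n_+ n_-)$; the exact equivalence of the two
routes is a standing test.

`km_estimate()` and `logrank_test()` delegate the product-limit estimate
and the two-group log-rank statistic to the `survival` package and
summarize the hazard ratio KM-Plotter-style from observed/expected event
counts, $HR = (O_1/E_1)/(O_2/E_2)$ — an O/E summary, not a Cox fit, and
mildly conservative for strong effects. `best_cutoff_scan()` emulates the
"best cutoff" filter of online survival tools: candidate cutoffs are the
marker quantiles from 10% to 90% in 5% steps (configurable, since the
exact grid of those tools is unpublished), each dichotomization is
log-rank-tested, and the minimal-p cutoff is selected. The minimum of
many correlated p-values is anticonservative by construction; the result
therefore always carries `multiplicity_biased = TRUE`, and no correction
is attempted.

# Microscopy quantification

Coordinates are row-major and 0-based with pixel centers on the integer
grid. The lipid-droplet pipeline (`quantify_ld_scene()`) mirrors a
two-channel confocal assay (nuclear stain + neutral-lipid stain):

1. **Nuclei** (`detect_nuclei()`): Gaussian smoothing (σ = 2 px), Otsu
   binarization, then watershed-style splitting of touching nuclei —
   seeds are regional maxima of the distance transform at least
   `min_distance = 10` px apart, mask pixels go to the geodesically
   nearest seed, and components under `min_area = 50` px are removed.
2. **Cytoplasm** (`propagate_cytoplasm()`): geodesic Voronoi propagation
   of the nucleus labels through a cytoplasm mask. A step of length $s$
   costs $s\sqrt{(\lambda + \Delta I^2)/(\lambda + \overline{\Delta I^2})}$;
   with uniform intensity (or large λ) this is exactly the nearest-seed
   partition, while small λ makes boundaries follow intensity ridges.
   Implemented as a multi-source Dijkstra in C++ with a deterministic
   tie-break (distance, then pixel index); validated pixel-by-pixel
   against a plain-R Dijkstra oracle.
3. **Droplets** (`segment_droplets()`): white top-hat with a disk of
   radius 4 px (larger than a droplet, smaller than a cell), sigmoidal
   contrast (gain 10) centered on the Otsu threshold of the top-hat
   image, binarization at 0.5, connected components, removal of dots
   under 2 px or with centroids outside every cell.
4. **Quantification** (`quantify_cells()`, `summarize_condition()`):
   per-cell dot count and dot area normalized to the cell area, averaged
   within view field, then across view fields per condition, with fold
   change versus control.

None of the numeric defaults above is printed in the source material for
this design; they are conventional choices for 20x confocal fields and
are all overridable. Dot-to-cell assignment uses centroid membership,
which is unambiguous for dots straddling boundaries. The sigmoid midpoint
defaults to the Otsu threshold of the current image so the transform is
parameter-free.

Stained-area assays (`area_fraction()`) convert to luminance if RGB,
normalize between the 1st and 99th intensity percentiles, invert when the
stain is dark on a light background, apply the sigmoid + Otsu
binarization, and report foreground pixels / total pixels;
`combine_replicates()` averages fields within replicate and then
replicates within condition. Constant images short-circuit to 0 or 1 by
comparing the (inverted) level to 0.5 — a blank insert is 0, a saturated
one is 1.

# Closed-form assay metrics

`ddct_fold_change()` implements $2^{-\Delta\Delta C_t}$ with per-condition
mean $\Delta C_t$; `knockdown_percent()` maps a fold change to
$(1 - FC)\cdot 100$, floored at 0 — note the legend-style phrase
"(1−ΔΔCt)×100" cannot produce a percentage from a Ct difference, so the
computation anchors on the fold-change scale, which reproduces the
canonical 92.5% at $FC = 0.075$. `tumor_volume()` is the ellipsoid
approximation $\pi/6 \cdot l \cdot w \cdot h$; `ihc_score()` tiers the
percentage of positive cells as <1% → 1, 1–20% (inclusive) → 2,
>20% → 3.

# Synthetic data: what it emulates and what it does not

`gen_cohort()` emulates the discovery design: 12 normal versus 31 tumor
samples (sample sizes of the motivating cohort), ~2000 genes with 3–8
CpG probes each. Counts are negative-binomial with gene-specific log-means
uniform on $\log(20)$–$\log(2000)$ and dispersion 0.4 (typical bulk
RNA-seq overdispersion); betas are Beta-distributed with a bimodal
baseline (modes 0.2/0.75, matching the unmethylated/methylated peaks of
real 450k data) re-parameterized by mean and precision (φ = 30). Planted
genes get a tumor-side beta shift (+0.25 by default) and a negative
expression log2FC (−2); planted probe baselines are drawn low enough that
the shifted mean never clips, so the realized group difference equals the
nominal delta and truth recovery is well-defined. Baseline means are
clipped to [0.01, 0.99] to keep logits finite. The effect sizes and noise
levels are calibration choices — the motivating study publishes no such
parameters — set once to values a methylation-array analyst would call
typical, not tuned to any downstream outcome.

`gen_survival()` draws exponential proportional-hazards event times,
$h(t\,|\,x) = h_0 e^{\beta x}$, with independent exponential censoring
whose rate is set from the marginal average hazard so the expected
censored fraction matches the requested rate (exact under a null effect,
approximate otherwise). `gen_fluor_scene()` renders disjoint disk cells
with concentric nuclei and non-overlapping cytoplasmic droplets as
anti-aliased disks (1 px rim ramp, emulating partial-volume edges) plus
additive Gaussian noise; `gen_stained_image()` accumulates dark blobs
until a target covered fraction is reached and records the exact realized
pixel fraction.

All generators take a single master seed and derive fixed-offset
substreams, restore the caller's RNG state, and are bit-reproducible.
What the simulations do **not** model: batch effects, tumor purity and
copy-number confounding, probe cross-reactivity, read-level noise,
illumination gradients, out-of-focus light, or cell shape irregularity.
Passing the recovery suites therefore demonstrates correctness of the
computations, not robustness to every artifact of real cohorts or real
microscopes.

# Numerical and design choices

* Percentages in summary tables are rounded half-away-from-zero to one
  decimal (`percent_of()`), the convention that reproduces printed
  figures such as 3073/4941 → 62.2%; base R's round-half-even would not.
* All significance thresholds are inclusive (`<=`/`>=`), matching the
  quoted cut-offs; a zero denominator yields `NA`, never 0.
* Degenerate rank tests (zero pooled variance) return p = 1.
* The propagation cost normalizes intensity differences by their in-mask
  mean square, making λ comparable across images of different contrast.
* Test problem sizes (2000-gene null cohorts, 1000 survival replicates,
  ≤64x64 propagation oracles, 192x192 scenes) were chosen so the whole
  validation runs in well under a minute while keeping Monte-Carlo
  standard errors comfortably inside the asserted tolerances.

# Known limitations

* Rank tests do not reproduce the per-gene p-values of moderated-t or
  negative-binomial pipelines; only threshold logic, directionality and
  calibration are preserved.
* The O/E hazard ratio is biased toward the null for large effects; the
  25%-band recovery check reflects that.
* The best-cutoff p-value is multiplicity-biased by design and flagged,
  not corrected.
* ROC confidence intervals, Cox models, competing risks, 3-D stacks and
  deep-learning segmentation are out of scope.
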